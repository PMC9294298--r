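#' Align two CAP sets with the Hungarian algorithm
#'
#' Finds the bijection between the states of `cap_a` and `cap_b` that
#' maximizes the total Pearson correlation of matched Z-maps (equivalently,
#' minimizes total `1 - r` cost via the Hungarian assignment algorithm).
#' Use it to match states discovered independently in different frequency
#' bands, or clustering runs with different seeds, before comparing them.
#'
#' @param cap_a,cap_b `cap_set` objects with the same number of states and
#'   the same ROI order.
#' @return A `cap_alignment`: list with `permutation` (state `i` of `cap_a`
#'   matches state `permutation[i]` of `cap_b`), `similarity` (Pearson r of
#'   each matched pair, in `cap_a`'s state order), and `total_similarity`.
#' @export
align_capsets <- function(cap_a, cap_b) {
  stopifnot(inherits(cap_a, "cap_set"), inherits(cap_b, "cap_set"))
  if (cap_a$k != cap_b$k) stop("state count mismatch", call. = FALSE)
  if (ncol(cap_a$zmaps) != ncol(cap_b$zmaps)) {
    stop("ROI count mismatch", call. = FALSE)
  }
  r_mat <- state_correlation(cap_a$zmaps, cap_b$zmaps)
  perm <- solve_max_assignment(r_mat)
  sim <- r_mat[cbind(seq_len(cap_a$k), perm)]
  structure(
    list(permutation = perm, similarity = sim,
         total_similarity = sum(sim)),
    class = "cap_alignment"
  )
}

# maximum-total-similarity bijection; Hungarian on cost = max - sim
solve_max_assignment <- function(sim) {
  cost <- max(sim) - sim
  as.integer(clue::solve_LSAP(cost, maximum = FALSE))
}

state_correlation <- function(zmaps_a, zmaps_b) {
  a <- standardize_frames(zmaps_a)
  b <- standardize_frames(zmaps_b)
  tcrossprod(a, b)
}

#' @export
print.cap_alignment <- function(x, ...) {
  cat("<cap_alignment>\n  permutation:", x$permutation,
      "\n  matched r:", sprintf("%.3f", x$similarity), "\n")
  invisible(x)
}

#' Spatial similarity of matched states across bands
#'
#' Given two aligned CAP sets, returns the Pearson correlation between each
#' state of `cap_a` and its match in `cap_b` — the per-state measure of how
#' well a state's spatial topography is preserved across frequency bands.
#'
#' @param cap_a,cap_b `cap_set` objects.
#' @param alignment A [align_capsets()] result; computed if missing.
#' @return Tibble with columns `state_a`, `state_b`, `r`.
#' @export
cross_band_similarity <- function(cap_a, cap_b, alignment = NULL) {
  if (is.null(alignment)) alignment <- align_capsets(cap_a, cap_b)
  r_mat <- state_correlation(cap_a$zmaps, cap_b$zmaps)
  k <- cap_a$k
  tibble::tibble(
    state_a = seq_len(k),
    state_b = alignment$permutation,
    r = r_mat[cbind(seq_len(k), alignment$permutation)]
  )
}

#' Pairwise spatial correlation between states of one CAP set
#'
#' The K x K Pearson correlation matrix of the Z-maps. Strongly negative
#' entries identify opposite pairs: two states whose coactivation
#' topographies mirror each other.
#'
#' @param caps A `cap_set`.
#' @return Symmetric K x K correlation matrix with unit diagonal.
#' @export
between_state_similarity <- function(caps) {
  stopifnot(inherits(caps, "cap_set"))
  r <- state_correlation(caps$zmaps, caps$zmaps)
  (r + t(r)) / 2  # enforce exact symmetry against rounding
}
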