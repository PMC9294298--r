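#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a CAP set into a long tibble
#'
#' @param x A `cap_set`.
#' @param ... Unused.
#' @return Tibble with columns `state`, `roi`, `z`.
#' @export
tidy.cap_set <- function(x, ...) {
  roi <- x$roi_names
  if (is.null(roi)) roi <- sprintf("roi_%03d", ncol(x$zmaps))
  tibble::tibble(
    state = rep(seq_len(x$k), each = ncol(x$zmaps)),
    roi = rep(roi, times = x$k),
    z = as.vector(t(x$zmaps))
  )
}

#' One-row summary of a CAP set
#'
#' @param x A `cap_set`.
#' @param ... Unused.
#' @return Tibble with `k`, `n_roi`, `band`, `n_frames`,
#'   `min_pair_correlation` (most negative between-state correlation, the
#'   signature of opposite pairs).
#' @export
glance.cap_set <- function(x, ...) {
  r <- between_state_similarity(x)
  tibble::tibble(
    k = x$k,
    n_roi = ncol(x$zmaps),
    band = if (inherits(x$band, "band_definition")) x$band$name else
      as.character(x$band),
    n_frames = sum(x$n_frames_per_state),
    min_pair_correlation = min(r[upper.tri(r)])
  )
}

#' Tidy an alignment between two CAP sets
#'
#' @param x A `cap_alignment`.
#' @param ... Unused.
#' @return Tibble with `state_a`, `state_b`, `similarity`.
#' @export
tidy.cap_alignment <- function(x, ...) {
  tibble::tibble(
    state_a = seq_along(x$permutation),
    state_b = x$permutation,
    similarity = x$similarity
  )
}
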