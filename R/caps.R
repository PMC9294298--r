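#' @importFrom stats cor sd setNames
NULL

# Row-standardize frames so squared Euclidean distance equals 2 * (1 - r):
# subtract each frame's mean over ROIs and scale to unit norm.
standardize_frames <- function(frames) {
  ctr <- frames - rowMeans(frames)
  nrm <- sqrt(rowSums(ctr^2))
  zero <- which(nrm < 1e-12)
  if (length(zero)) {
    stop("frame ", zero[1], " has zero variance across ROIs", call. = FALSE)
  }
  ctr / nrm
}

# seeded k-means++ initialization on row-standardized frames
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    probs <- d2 / sum(d2)
    centers[j] <- sample.int(n, 1, prob = probs)
    d2_new <- rowSums((x - matrix(x[centers[j], ], n, ncol(x),
                                  byrow = TRUE))^2)
    d2 <- pmin(d2, d2_new)
  }
  x[centers, , drop = FALSE]
}

#' Cluster pooled frames into coactivation-pattern states
#'
#' Runs k-means on all frames pooled from the reference cohort, in
#' correlation geometry: each frame is centred across ROIs and scaled to
#' unit norm, so squared Euclidean distance between rows is proportional to
#' one minus their Pearson correlation — the same similarity used later to
#' assign new frames. Initialization is seeded k-means++; `n_replicates`
#' restarts are run and the solution with the lowest total within-cluster
#' cost is kept. A replicate that ends with an empty cluster is re-seeded
#' (with a message). States are defined on the reference (control) cohort
#' only; patient frames are projected afterwards with [assign_frames()].
#'
#' @param ts_list A list of z-scored, filtered [roi_timeseries()] objects
#'   (the reference cohort), or a single frames-by-ROIs matrix.
#' @param k Number of states (default 6).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param n_replicates Number of k-means++ restarts (default 10).
#' @param band Band tag recorded in the result; defaults to the band of the
#'   first series.
#' @return A list with components:
#'   * `caps`: a `cap_set` of per-state Z-maps (see [compute_zmaps()]),
#'   * `sequences`: tibble with columns `subject_id`, `frame`, `state`,
#'   * `cost`: total within-cluster cost of the kept replicate,
#'   * `seed`, `k`, `n_frames_per_state`.
#' @export
cluster_caps <- function(ts_list, k = 6, seed = 1, n_replicates = 10,
                         band = NULL) {
  pooled <- pool_frames(ts_list)
  frames <- pooled$frames
  if (is.null(band)) band <- pooled$band
  n <- nrow(frames)
  if (k > n) stop("more clusters than frames", call. = FALSE)
  if (k < 2) stop("need at least 2 states", call. = FALSE)
  x <- standardize_frames(frames)

  best <- NULL
  rep_seeds <- derive_seeds(seed, n_replicates)
  for (r in seq_len(n_replicates)) {
    fit <- kmeans_one_replicate(x, k, rep_seeds[r])
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }

  labels <- best$cluster
  seq_tbl <- tibble::tibble(
    subject_id = pooled$subject_id,
    frame = pooled$frame,
    state = as.integer(labels)
  )
  caps <- compute_zmaps(frames, labels, k = k, band = band,
                        roi_names = pooled$roi_names)
  list(
    caps = caps,
    sequences = seq_tbl,
    cost = best$tot.withinss,
    seed = seed,
    k = k,
    n_frames_per_state = as.integer(tabulate(labels, nbins = k))
  )
}

# one seeded k-means++ + Lloyd replicate; re-seeds on empty clusters
kmeans_one_replicate <- function(x, k, rep_seed, max_tries = 25) {
  for (try in seq_len(max_tries)) {
    set.seed(rep_seed + try - 1L)
    init <- kmeanspp_init(x, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100,
                                     algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (!is.null(fit) && all(fit$size > 0)) return(fit)
    message("k-means replicate produced an empty cluster; re-seeding")
  }
  stop("k-means failed to produce ", k, " non-empty clusters", call. = FALSE)
}

derive_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

# accepts a list of roi_ts or a bare matrix; returns pooled frames + ids
pool_frames <- function(ts_list) {
  if (is.matrix(ts_list)) {
    return(list(frames = ts_list,
                subject_id = rep("pooled", nrow(ts_list)),
                frame = seq_len(nrow(ts_list)),
                roi_names = colnames(ts_list),
                band = "broadband"))
  }
  if (inherits(ts_list, "roi_ts")) ts_list <- list(ts_list)
  stopifnot(all(vapply(ts_list, inherits, logical(1), "roi_ts")))
  frames <- do.call(rbind, lapply(ts_list, function(ts) ts$data))
  list(
    frames = frames,
    subject_id = rep(vapply(ts_list, function(ts) ts$subject_id,
                            character(1)),
                     vapply(ts_list, function(ts) nrow(ts$data), integer(1))),
    frame = unlist(lapply(ts_list, function(ts) seq_len(nrow(ts$data)))),
    roi_names = ts_list[[1]]$roi_names,
    band = ts_list[[1]]$band
  )
}

#' Build per-state Z-maps from labelled frames
#'
#' For each state, the member frames are averaged and divided by their
#' standard deviation ROI-wise (population convention): `zmap[k, r] =
#' mean(frames in k, ROI r) / sd(frames in k, ROI r)`. The magnitude of a
#' Z-map entry expresses how consistently a region co-activates (or
#' co-deactivates) in that state.
#'
#' @param frames Frames-by-ROIs matrix.
#' @param labels Integer state label per frame (1..k).
#' @param k Number of states; defaults to `max(labels)`.
#' @param band Band tag.
#' @param roi_names Optional ROI names.
#' @return A `cap_set` object: list with `zmaps` (k x R matrix), `k`,
#'   `band`, `roi_names`, `n_frames_per_state`.
#' @export
compute_zmaps <- function(frames, labels, k = max(labels), band = "broadband",
                          roi_names = colnames(frames)) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(frames), all(labels >= 1), all(labels <= k))
  zmaps <- matrix(NA_real_, k, ncol(frames))
  sizes <- tabulate(labels, nbins = k)
  for (s in seq_len(k)) {
    if (sizes[s] < 2) {
      stop("state ", s, " has fewer than 2 member frames", call. = FALSE)
    }
    member <- frames[labels == s, , drop = FALSE]
    mu <- colMeans(member)
    sd_pop <- sqrt(colMeans(member^2) - mu^2)
    zero <- which(sd_pop < 1e-12)
    if (length(zero)) {
      stop(sprintf("zero within-state SD for state %d, ROI %d", s, zero[1]),
           call. = FALSE)
    }
    zmaps[s, ] <- mu / sd_pop
  }
  if (!is.null(roi_names)) colnames(zmaps) <- roi_names
  structure(
    list(zmaps = zmaps, k = k, band = band, roi_names = roi_names,
         n_frames_per_state = as.integer(sizes)),
    class = "cap_set"
  )
}

#' @export
print.cap_set <- function(x, ...) {
  band <- if (inherits(x$band, "band_definition")) x$band$name else x$band
  cat(sprintf("<cap_set: %d states x %d ROIs, band = %s>\n",
              x$k, ncol(x$zmaps), band))
  invisible(x)
}

#' Assign frames to the nearest CAP state
#'
#' Labels every frame of a (z-scored, filtered) series with the state whose
#' Z-map it correlates with most strongly (Pearson). This is how frames of
#' subjects outside the reference cohort — or from another band — are
#' projected onto an existing state set. Exact ties go to the lowest state
#' index, with a message.
#'
#' @param ts A [roi_timeseries()] with the same ROIs (and order) as `caps`.
#' @param caps A `cap_set` from [cluster_caps()] or [compute_zmaps()].
#' @return Tibble with columns `subject_id`, `frame`, `state`, `similarity`
#'   (the winning Pearson r).
#' @export
assign_frames <- function(ts, caps) {
  stopifnot(inherits(caps, "cap_set"))
  frames <- if (inherits(ts, "roi_ts")) ts$data else as.matrix(ts)
  subject_id <- if (inherits(ts, "roi_ts")) ts$subject_id else "subject"
  if (ncol(frames) != ncol(caps$zmaps)) {
    stop("ROI count mismatch between series and CAP set", call. = FALSE)
  }
  fx <- standardize_frames(frames)
  zx <- standardize_frames(caps$zmaps)
  r_mat <- fx %*% t(zx)  # frames x states Pearson correlations
  state <- max.col(r_mat, ties.method = "first")
  # max.col "first" already picks the lowest index; report genuine ties
  best <- r_mat[cbind(seq_len(nrow(r_mat)), state)]
  n_tie <- sum(rowSums(abs(r_mat - best) < 1e-15) > 1)
  if (n_tie > 0) {
    message(n_tie, " frame(s) had tied similarities; lowest state index used")
  }
  tibble::tibble(
    subject_id = subject_id,
    frame = seq_len(nrow(frames)),
    state = as.integer(state),
    similarity = as.numeric(best)
  )
}

#' Mean silhouette width across candidate state counts
#'
#' Clusters the pooled frames at each candidate `k` and returns the mean
#' silhouette width under the same 1 - Pearson distance used for
#' clustering. The curve's peak is the data-supported state count. For
#' large frame pools the silhouette (which is quadratic in the number of
#' frames) is computed on a seeded random subsample.
#'
#' @param frames Frames-by-ROIs matrix (or list of `roi_ts`).
#' @param k_range Integer vector of candidate state counts.
#' @param seed Seed for clustering and subsampling.
#' @param n_replicates Restarts per `k` (default 5).
#' @param max_frames Subsample cap for the silhouette computation
#'   (default 2000).
#' @return Tibble with columns `k`, `mean_silhouette`.
#' @export
silhouette_curve <- function(frames, k_range, seed = 1, n_replicates = 5,
                             max_frames = 2000) {
  pooled <- pool_frames(frames)
  x <- standardize_frames(pooled$frames)
  n <- nrow(x)
  stopifnot(all(k_range >= 2), all(k_range <= n - 1))
  sub <- seq_len(n)
  if (n > max_frames) {
    set.seed(seed)
    sub <- sort(sample.int(n, max_frames))
  }
  # 1 - r distance on the subsample
  d <- stats::as.dist(1 - tcrossprod(x[sub, , drop = FALSE]))
  purrr::map_dfr(k_range, function(k) {
    rep_seeds <- derive_seeds(seed, n_replicates)
    best <- NULL
    for (r in seq_len(n_replicates)) {
      fit <- kmeans_one_replicate(x, k, rep_seeds[r])
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    sil <- cluster::silhouette(best$cluster[sub], d)
    tibble::tibble(k = as.integer(k),
                   mean_silhouette = mean(sil[, "sil_width"]))
  })
}
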