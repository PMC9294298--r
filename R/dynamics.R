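#' Fraction of time per state
#'
#' Proportion of a subject's frames assigned to each state: `N_A / N` for
#' state A over `N` frames. Always sums to 1 across states.
#'
#' @param labels Integer vector of per-frame state labels in 1..k.
#' @param k Number of states.
#' @return Numeric length-`k` vector.
#' @export
fraction_of_time <- function(labels, k) {
  labels <- check_labels(labels, k)
  tabulate(labels, nbins = k) / length(labels)
}

#' Episode counts per state
#'
#' Number of distinct episodes (maximal runs of consecutive identical
#' labels) of each state within one scan.
#'
#' @inheritParams fraction_of_time
#' @return Integer length-`k` vector.
#' @export
count_episodes <- function(labels, k) {
  labels <- check_labels(labels, k)
  r <- rle(labels)
  as.integer(tabulate(r$values, nbins = k))
}

#' Mean persistence per state, in seconds
#'
#' Average duration of a state's episodes: the mean run length in frames
#' times the repetition time. Runs truncated by the scan boundary count in
#' full, so the identity `fraction * T * tr = counts * persistence` holds
#' exactly for every state with at least one episode. States that never
#' occur get `NA` (not zero) and are excluded from group summaries.
#'
#' @inheritParams fraction_of_time
#' @param tr Repetition time in seconds.
#' @return Numeric length-`k` vector of seconds; `NA` for absent states.
#' @export
persistence <- function(labels, k, tr) {
  labels <- check_labels(labels, k)
  r <- rle(labels)
  out <- rep(NA_real_, k)
  mean_len <- tapply(r$lengths, factor(r$values, levels = seq_len(k)), mean)
  seen <- !is.na(mean_len)
  out[seen] <- as.numeric(mean_len[seen]) * tr
  out
}

#' Frame-to-frame transition probability matrix
#'
#' Entry (a, b) is the probability that a frame in state a is followed by a
#' frame in state b: `N_{a->b} / N_a`, where `N_a` counts only frames that
#' have a successor (the scan's last frame is excluded from denominators).
#' Rows for states with no successor frames are `NA`; every defined row
#' sums to 1.
#'
#' @inheritParams fraction_of_time
#' @return `k` x `k` numeric matrix.
#' @export
transition_matrix <- function(labels, k) {
  labels <- check_labels(labels, k)
  if (length(labels) < 2) stop("need at least 2 frames", call. = FALSE)
  from <- labels[-length(labels)]
  to <- labels[-1]
  counts <- matrix(0, k, k)
  for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  denom <- rowSums(counts)
  tm <- counts / denom
  tm[denom == 0, ] <- NA_real_
  tm
}

#' Resilience: the tendency of a state to persist
#'
#' The diagonal of the transition probability matrix — the probability of
#' staying in the same state on the next frame.
#'
#' @param tm A transition matrix from [transition_matrix()].
#' @return Numeric vector of diagonal entries.
#' @export
resilience <- function(tm) {
  stopifnot(is.matrix(tm), nrow(tm) == ncol(tm))
  diag(tm)
}

#' Persistence in cycles of the band's center frequency
#'
#' Rescales persistence (seconds) by the band's center frequency, yielding
#' the number of cycles of the band's characteristic oscillation that one
#' episode spans. This makes dwell times comparable across bands whose
#' intrinsic time scales differ: if persistence merely tracked the filter's
#' period, the normalized value would be constant across bands.
#'
#' @param pers Persistence in seconds (vector allowed; `NA` passes through).
#' @param band A [band_definition()].
#' @return Dimensionless cycles per episode.
#' @export
normalized_persistence <- function(pers, band) {
  pers * band_center(band)
}

#' Per-subject state dynamics for a cohort
#'
#' Computes fraction of time, episode counts, persistence and (optionally)
#' center-frequency-normalized persistence for every subject and state, plus
#' each subject's transition matrix. Metrics are computed per subject and
#' never on concatenated sequences, which would manufacture spurious
#' between-subject transitions.
#'
#' @param sequences Tibble with columns `subject_id`, `frame`, `state`
#'   (as produced by [cluster_caps()] or [assign_frames()]), frames ordered
#'   within subject.
#' @param k Number of states.
#' @param tr Repetition time in seconds.
#' @param band Optional [band_definition()]; if supplied, a
#'   `normalized_persistence` column is included and the band name is
#'   recorded.
#' @return A list with:
#'   * `metrics`: tibble of `subject_id`, `band`, `state`, `fraction`,
#'     `counts`, `persistence_s` (and `normalized_persistence`),
#'   * `transitions`: named list of per-subject `k` x `k` matrices.
#' @export
cohort_dynamics <- function(sequences, k, tr, band = NULL) {
  stopifnot(all(c("subject_id", "frame", "state") %in% names(sequences)))
  band_name <- if (inherits(band, "band_definition")) band$name else
    if (is.null(band)) "broadband" else as.character(band)
  ord <- order(sequences$subject_id, sequences$frame)
  sequences <- sequences[ord, ]
  by_subj <- split(sequences, sequences$subject_id)
  metrics <- purrr::map_dfr(by_subj, function(d) {
    lab <- d$state
    tib <- tibble::tibble(
      subject_id = d$subject_id[1],
      band = band_name,
      state = seq_len(k),
      fraction = fraction_of_time(lab, k),
      counts = count_episodes(lab, k),
      persistence_s = persistence(lab, k, tr)
    )
    if (inherits(band, "band_definition")) {
      tib$normalized_persistence <-
        normalized_persistence(tib$persistence_s, band)
    }
    tib
  })
  transitions <- lapply(by_subj, function(d) transition_matrix(d$state, k))
  list(metrics = metrics, transitions = transitions)
}

#' Group summary of a dynamics table
#'
#' Mean and standard error of each metric per state (optionally within
#' groups), over subjects with defined values.
#'
#' @param metrics The `metrics` tibble from [cohort_dynamics()].
#' @param meta Optional subject metadata tibble with `subject_id` and
#'   `group`; if supplied, summaries are per group.
#' @return Tibble with one row per (group x) state x metric:
#'   `state`, `metric`, `mean`, `se`, `n`.
#' @export
summarize_dynamics <- function(metrics, meta = NULL) {
  long <- tidyr::pivot_longer(
    metrics,
    cols = dplyr::any_of(c("fraction", "counts", "persistence_s",
                           "normalized_persistence")),
    names_to = "metric", values_to = "value"
  )
  if (!is.null(meta)) {
    long <- dplyr::left_join(long, meta[, c("subject_id", "group")],
                             by = "subject_id")
    grp <- c("group", "band", "state", "metric")
  } else {
    grp <- c("band", "state", "metric")
  }
  long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}

check_labels <- function(labels, k) {
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 1) || any(labels > k)) {
    stop("state labels must be integers in 1..", k, call. = FALSE)
  }
  labels
}
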