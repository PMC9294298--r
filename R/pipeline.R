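#' Preprocess a subject for CAP analysis
#'
#' The standard chain: drop leading frames, band-pass filter, z-score each
#' ROI. For already band-limited (e.g. simulated) data use
#' `filter = FALSE` to skip the filtering step.
#'
#' @param ts A [roi_timeseries()].
#' @param band A [band_definition()].
#' @param n_discard Leading frames to drop (default 0; acquisitions that
#'   include equilibration volumes typically drop 5).
#' @param filter Whether to band-pass filter (default `TRUE`).
#' @return A z-scored `roi_ts` tagged with `band`.
#' @export
preprocess_subject <- function(ts, band, n_discard = 0, filter = TRUE) {
  if (n_discard > 0) ts <- discard_initial_frames(ts, n_discard)
  if (filter) {
    ts <- bandpass(ts, band)
  } else {
    ts$band <- band
  }
  zscore_rois(ts)
}

#' Hold-out CAP-definition classification experiment
#'
#' Avoids circularity between state definition and classification: in each
#' repetition a random subset of controls defines the CAP states by
#' clustering; the remaining controls and an equal number of age/sex-matched
#' patients are projected onto those states, their spatial features built,
#' and a leave-one-pair-out SVM run (repeated with fresh random pairings).
#' The distribution of accuracies over repetitions is returned, along with
#' per-repetition selected-feature sets for [consensus_features()].
#'
#' @param hc_ts Named list of preprocessed (z-scored) control `roi_ts`.
#' @param hc_meta Control metadata tibble (`subject_id`, `age`, `sex`).
#' @param sz_ts Named list of preprocessed patient `roi_ts`.
#' @param sz_meta Patient metadata tibble.
#' @param k Number of states (default 6).
#' @param n_definition Number of controls used for CAP definition per
#'   repetition (default 47).
#' @param n_classification Subjects per class in the classification set
#'   (default 50; capped at availability).
#' @param n_repetitions Hold-out repetitions (default 100).
#' @param n_lopo_repeats Random re-pairings of the leave-one-pair-out run
#'   per repetition (default 10).
#' @param config A [classifier_config()].
#' @param seed Master seed.
#' @param n_replicates K-means restarts per repetition (default 5).
#' @return A list with `reports` (tibble, one row per repetition with the
#'   averaged `acc`, `se`, `sp`, `auc`) and `selections` (list of lists of
#'   per-fold selected feature names, for consensus extraction).
#' @export
holdout_experiment <- function(hc_ts, hc_meta, sz_ts, sz_meta, k = 6,
                               n_definition = 47, n_classification = 50,
                               n_repetitions = 100, n_lopo_repeats = 10,
                               config = classifier_config(), seed = 1,
                               n_replicates = 5) {
  hc_ids <- names(hc_ts)
  sz_ids <- names(sz_ts)
  stopifnot(n_definition < length(hc_ids))
  n_classification <- min(n_classification, length(hc_ids) - n_definition,
                          length(sz_ids))
  rep_seeds <- derive_seeds(seed, n_repetitions)
  reports <- vector("list", n_repetitions)
  selections <- vector("list", n_repetitions)
  for (rep_i in seq_len(n_repetitions)) {
    rs <- rep_seeds[rep_i]
    set.seed(rs)
    def_ids <- sample(hc_ids, n_definition)
    held_ids <- setdiff(hc_ids, def_ids)
    stopifnot(!any(def_ids %in% held_ids))

    fit <- cluster_caps(hc_ts[def_ids], k = k, seed = rs,
                        n_replicates = n_replicates)

    # matched patients for the classification set
    held_meta <- hc_meta[hc_meta$subject_id %in% held_ids, ]
    set.seed(rs + 1L)
    cls_hc_meta <- held_meta[sample(nrow(held_meta),
                                    n_classification), ]
    matched_sz <- match_controls(sz_meta, cls_hc_meta)  # same machinery,
    # selecting patients nearest in age/sex to the held-out controls
    cls_ids <- c(cls_hc_meta$subject_id, matched_sz$subject_id)
    cls_ts <- c(hc_ts[cls_hc_meta$subject_id], sz_ts[matched_sz$subject_id])

    seqs <- dplyr::bind_rows(lapply(cls_ts, assign_frames, caps = fit$caps))
    feats <- build_feature_matrix(unname(cls_ts), seqs, k = k)
    labels <- ifelse(rownames(feats) %in% sz_ids, "SZ", "HC")

    runs <- vector("list", n_lopo_repeats)
    for (lr in seq_len(n_lopo_repeats)) {
      set.seed(rs + 1000L + lr)
      pair_hc <- sample(cls_hc_meta$subject_id)
      pairs <- cbind(matched_sz$subject_id, pair_hc)
      runs[[lr]] <- lopo_cv(feats, labels, pairs, config)
    }
    runs <- dplyr::bind_rows(runs)
    reports[[rep_i]] <- tibble::tibble(
      repetition = rep_i,
      acc = mean(runs$acc), se = mean(runs$se), sp = mean(runs$sp),
      auc = mean(runs$auc),
      chosen_feature_number = round(mean(runs$chosen_feature_number))
    )
    selections[[rep_i]] <- unlist(runs$selected_features, recursive = FALSE)
  }
  list(reports = dplyr::bind_rows(reports), selections = selections)
}
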