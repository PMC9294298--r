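#' Subject-level CAP spatial feature matrix
#'
#' For each subject and state, the per-ROI mean of the subject's (z-scored)
#' frames assigned to that state — the subject's expression of the group
#' state map. Features are the concatenation over states (and over bands,
#' for multi-band models): K states x R ROIs per band, e.g. 6 x 408 = 2448
#' features for the single-band model. A subject missing a state has no
#' defined features for it and raises an error naming subject and state.
#'
#' @param ts_list Named list of z-scored [roi_timeseries()] objects, or a
#'   list of such lists (one per band) for multi-band features.
#' @param sequences Tibble `subject_id`, `frame`, `state` (one per band if
#'   `ts_list` is a list of bands).
#' @param k Number of states.
#' @param subject_zscore If `TRUE`, divide each state-block mean by the
#'   member frames' SD (subject-level Z) instead of reporting the raw mean.
#' @return A `feature_matrix`: subjects x (k * R * n_bands) numeric matrix
#'   with rownames = subject ids and colnames `band.state.roi`.
#' @export
build_feature_matrix <- function(ts_list, sequences, k,
                                 subject_zscore = FALSE) {
  multi_band <- !inherits(ts_list[[1]], "roi_ts")
  if (!multi_band) {
    ts_list <- list(ts_list)
    sequences <- list(sequences)
  }
  stopifnot(length(ts_list) == length(sequences))
  blocks <- purrr::map2(ts_list, sequences, function(tss, seqs) {
    band_features(tss, seqs, k, subject_zscore)
  })
  ids <- rownames(blocks[[1]])
  for (b in blocks) stopifnot(identical(rownames(b), ids))
  out <- do.call(cbind, blocks)
  structure(out, class = c("feature_matrix", class(out)))
}

band_features <- function(tss, seqs, k, subject_zscore) {
  by_subj <- split(seqs, seqs$subject_id)
  band_name <- {
    b <- tss[[1]]$band
    if (inherits(b, "band_definition")) b$name else as.character(b)
  }
  ts_ids <- vapply(tss, function(ts) ts$subject_id, character(1))
  n_roi <- ncol(tss[[1]]$data)
  rows <- lapply(names(by_subj), function(sid) {
    ts <- tss[[match(sid, ts_ids)]]
    d <- by_subj[[sid]]
    d <- d[order(d$frame), ]
    vec <- numeric(k * n_roi)
    for (s in seq_len(k)) {
      idx <- d$frame[d$state == s]
      if (!length(idx)) {
        stop(sprintf("subject %s has no frames in state %d", sid, s),
             call. = FALSE)
      }
      member <- ts$data[idx, , drop = FALSE]
      mu <- colMeans(member)
      if (subject_zscore) {
        sd_pop <- sqrt(pmax(colMeans(member^2) - mu^2, 0))
        mu <- mu / pmax(sd_pop, 1e-12)
      }
      vec[((s - 1) * n_roi + 1):(s * n_roi)] <- mu
    }
    vec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(by_subj)
  roi_names <- tss[[1]]$roi_names
  if (is.null(roi_names)) roi_names <- sprintf("roi_%03d", seq_len(n_roi))
  colnames(out) <- as.vector(t(outer(seq_len(k), roi_names,
                                     function(s, r) paste(band_name, s, r,
                                                          sep = "."))))
  out
}

#' F-score feature ranking for a two-class problem
#'
#' For each feature, the ratio of between-class to within-class
#' variability:
#' \deqn{F = \frac{(\bar x^{+} - \bar x)^2 + (\bar x^{-} - \bar x)^2}
#'                {s^2_{+} + s^2_{-}}}
#' where the `s^2` are the sample variances within each class. Larger
#' scores mark features whose group difference is large relative to their
#' spread. Features with a zero denominator (constant in both classes) get
#' `NA` and rank last.
#'
#' @param features Subjects x features numeric matrix.
#' @param labels Two-level factor-like vector (positive class first level
#'   order does not matter — the score is symmetric).
#' @return Numeric vector of scores, one per feature.
#' @export
f_score <- function(features, labels) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2)
  g1 <- features[labels == levels(labels)[1], , drop = FALSE]
  g2 <- features[labels == levels(labels)[2], , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2) {
    stop("each class needs at least 2 members", call. = FALSE)
  }
  m_all <- colMeans(features)
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- colSums(sweep(g1, 2, m1)^2) / (nrow(g1) - 1)
  v2 <- colSums(sweep(g2, 2, m2)^2) / (nrow(g2) - 1)
  num <- (m1 - m_all)^2 + (m2 - m_all)^2
  den <- v1 + v2
  out <- num / den
  out[den < 1e-300] <- NA_real_
  out
}

#' Classifier configuration
#'
#' @param feature_grid Candidate feature counts for the selection sweep
#'   (default 20 to 1500 in steps of 20; trimmed to the number of features
#'   available at fit time).
#' @param cost Linear SVM penalty C (default 1).
#' @param seed Seed for any randomized step (pairing, permutations).
#' @param scale_in_fold If `TRUE`, features are z-scored within each
#'   training fold (means/SDs from the training set applied to the test
#'   set). Off by default.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(feature_grid = seq(20, 1500, by = 20),
                              cost = 1, seed = 1, scale_in_fold = FALSE) {
  stopifnot(cost > 0, all(feature_grid >= 1))
  structure(list(feature_grid = as.integer(feature_grid), cost = cost,
                 seed = seed, scale_in_fold = scale_in_fold),
            class = "classifier_config")
}

# fit linear SVM and return oriented decision values for newdata:
# positive decision value means the positive class
svm_decision <- function(x_train, y_train, x_test, cost, positive) {
  fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = cost,
                    scale = FALSE)
  pred <- stats::predict(fit, x_test, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  sign_flip <- if (first == positive) 1 else -1
  list(pred = as.character(pred), decision = sign_flip * dv[, 1])
}

# run one CV scheme over a list of folds (test index sets); feature
# selection happens inside each training fold
run_cv_folds <- function(features, labels, folds, config, positive) {
  grid <- config$feature_grid[config$feature_grid <= ncol(features)]
  if (!length(grid)) grid <- ncol(features)
  n <- nrow(features)
  preds <- matrix(NA_character_, n, length(grid))
  decs <- matrix(NA_real_, n, length(grid))
  for (fold in folds) {
    tr <- setdiff(seq_len(n), fold)
    x_tr <- features[tr, , drop = FALSE]
    x_te <- features[fold, , drop = FALSE]
    if (config$scale_in_fold) {
      mu <- colMeans(x_tr)
      sdv <- pmax(apply(x_tr, 2, stats::sd), 1e-12)
      x_tr <- sweep(sweep(x_tr, 2, mu), 2, sdv, "/")
      x_te <- sweep(sweep(x_te, 2, mu), 2, sdv, "/")
    }
    scores <- f_score(x_tr, labels[tr])
    ord <- order(scores, decreasing = TRUE, na.last = TRUE)
    for (gi in seq_along(grid)) {
      keep <- ord[seq_len(grid[gi])]
      res <- svm_decision(x_tr[, keep, drop = FALSE], factor(labels[tr]),
                          x_te[, keep, drop = FALSE], config$cost, positive)
      preds[fold, gi] <- res$pred
      decs[fold, gi] <- res$decision
    }
  }
  acc <- colMeans(preds == matrix(labels, n, length(grid)))
  best <- which(acc >= max(acc) - 1e-12)[1]  # smallest grid step at max acc
  metrics <- classification_metrics(labels, preds[, best], decs[, best],
                                    positive = positive)
  selected <- selected_features_per_fold(features, labels, folds, config,
                                         grid[best])
  tibble::tibble(
    acc = metrics$acc, se = metrics$se, sp = metrics$sp, auc = metrics$auc,
    chosen_feature_number = grid[best],
    accuracy_curve = list(tibble::tibble(n_features = grid, acc = acc)),
    selected_features = list(selected)
  )
}

selected_features_per_fold <- function(features, labels, folds, config, m) {
  feat_names <- colnames(features)
  if (is.null(feat_names)) feat_names <- as.character(seq_len(ncol(features)))
  lapply(folds, function(fold) {
    tr <- setdiff(seq_len(nrow(features)), fold)
    scores <- f_score(features[tr, , drop = FALSE], labels[tr])
    feat_names[order(scores, decreasing = TRUE, na.last = TRUE)[seq_len(m)]]
  })
}

#' Leave-one-pair-out cross-validation
#'
#' Each fold holds out one patient and their matched control; the F-score
#' ranking is recomputed inside every training fold (no leakage through
#' feature selection), the feature-count grid is swept, and the smallest
#' count achieving the highest accuracy is reported. AUC is computed from
#' the signed SVM decision values pooled over folds.
#'
#' @param features Subjects x features matrix (rownames = subject ids).
#' @param labels Class labels, one per subject.
#' @param pairs Two-column matrix or data frame of subject ids, one row per
#'   (patient, control) pair; the pairs must partition the subjects.
#' @param config A [classifier_config()].
#' @param positive Label of the positive class (default `"SZ"`).
#' @return One-row tibble: `acc`, `se`, `sp`, `auc`,
#'   `chosen_feature_number`, plus list-columns `accuracy_curve` and
#'   `selected_features` (per-fold selected names at the chosen count).
#' @export
lopo_cv <- function(features, labels, pairs, config = classifier_config(),
                    positive = "SZ") {
  pairs <- as.matrix(pairs)
  ids <- rownames(features)
  if (is.null(ids)) stop("features must have subject ids as rownames",
                         call. = FALSE)
  flat <- as.vector(pairs)
  if (anyDuplicated(flat)) stop("a subject appears in more than one pair",
                                call. = FALSE)
  if (!setequal(flat, ids) || length(flat) != length(ids)) {
    stop("pairs must partition the subjects exactly", call. = FALSE)
  }
  folds <- lapply(seq_len(nrow(pairs)), function(i) match(pairs[i, ], ids))
  run_cv_folds(features, labels, folds, config, positive)
}

#' Leave-one-out cross-validation
#'
#' As [lopo_cv()] with singleton test sets.
#'
#' @inheritParams lopo_cv
#' @return One-row tibble as in [lopo_cv()].
#' @export
loo_cv <- function(features, labels, config = classifier_config(),
                   positive = "SZ") {
  folds <- as.list(seq_len(nrow(features)))
  run_cv_folds(features, labels, folds, config, positive)
}

#' Confusion-matrix metrics and AUC
#'
#' Accuracy, sensitivity and specificity from the pooled confusion matrix
#' (patients as the positive class), and AUC computed as the Mann-Whitney
#' rank statistic on the decision values.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param decision_values Signed scores, larger meaning more
#'   positive-class; may be `NULL` to skip AUC.
#' @param positive Positive-class label.
#' @return One-row tibble `acc`, `se`, `sp`, `auc`.
#' @export
classification_metrics <- function(truth, predicted, decision_values = NULL,
                                   positive = "SZ") {
  stopifnot(length(truth) == length(predicted))
  is_pos <- truth == positive
  if (!any(is_pos) || all(is_pos)) {
    stop("both classes must be present in truth", call. = FALSE)
  }
  tp <- sum(is_pos & predicted == positive)
  fn <- sum(is_pos & predicted != positive)
  tn <- sum(!is_pos & predicted != positive)
  fp <- sum(!is_pos & predicted == positive)
  auc <- if (is.null(decision_values)) NA_real_ else
    auc_rank(decision_values, is_pos)
  tibble::tibble(
    acc = (tp + tn) / length(truth),
    se = tp / (tp + fn),
    sp = tn / (tn + fp),
    auc = auc
  )
}

# Mann-Whitney AUC with tie correction
auc_rank <- function(scores, is_pos) {
  r <- rank(scores)
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Greedy age- and sex-matched control selection
#'
#' Selects one control per patient with the same sex and the nearest age,
#' without replacement, so the matched control group reproduces the
#' patients' sex composition exactly and their age distribution closely.
#'
#' @param hc_meta,sz_meta Tibbles with `subject_id`, `age`, `sex`.
#' @return The matched subset of `hc_meta`, one row per patient, with a
#'   `matched_to` column giving the patient id.
#' @export
match_controls <- function(hc_meta, sz_meta) {
  stopifnot(all(c("subject_id", "age", "sex") %in% names(hc_meta)),
            all(c("subject_id", "age", "sex") %in% names(sz_meta)))
  avail <- hc_meta
  out <- vector("list", nrow(sz_meta))
  # match hardest-to-match first: stable order by patient age
  ord <- order(sz_meta$age)
  for (i in ord) {
    cand <- which(avail$sex == sz_meta$sex[i])
    if (!length(cand)) {
      stop("not enough controls of sex ", sz_meta$sex[i], call. = FALSE)
    }
    pick <- cand[which.min(abs(avail$age[cand] - sz_meta$age[i]))]
    row <- avail[pick, ]
    row$matched_to <- sz_meta$subject_id[i]
    out[[i]] <- row
    avail <- avail[-pick, ]
  }
  dplyr::bind_rows(out)
}

#' Consensus features over repeated selection
#'
#' Two-stage stability filter: a feature is *flagged* within a repetition
#' if it was selected in at least `within_threshold` of that repetition's
#' iterations, and enters the consensus set if flagged in at least
#' `across_threshold` of the repetitions.
#'
#' @param selections List (repetitions) of lists (iterations) of character
#'   vectors of selected feature names.
#' @param within_threshold,across_threshold Proportions in (0, 1]
#'   (default 0.80 each).
#' @return Character vector of consensus feature names (sorted).
#' @export
consensus_features <- function(selections, within_threshold = 0.80,
                               across_threshold = 0.80) {
  flagged <- lapply(selections, function(iters) {
    tab <- table(unlist(lapply(iters, unique)))
    names(tab)[tab / length(iters) >= within_threshold - 1e-12]
  })
  tab <- table(unlist(flagged))
  if (!length(tab)) return(character(0))
  sort(names(tab)[tab / length(selections) >= across_threshold - 1e-12])
}
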