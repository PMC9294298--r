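test_that("single-band feature matrix has K x R columns in state blocks", {
  # 2 subjects, 408 ROIs, 6 states -> 2448 features
  tpl <- make_cap_templates(n_roi = 408, k = 6, seed = 1)
  ts_list <- lapply(1:2, function(i) {
    lab <- rep(1:6, length.out = 36)
    simulate_subject(tpl, lab, noise_sd = 0.2, seed = i,
                     subject_id = sprintf("s%d", i))
  })
  seqs <- dplyr::bind_rows(lapply(1:2, function(i) {
    tibble::tibble(subject_id = sprintf("s%d", i), frame = 1:36,
                   state = rep(1:6, length.out = 36))
  }))
  fm <- build_feature_matrix(ts_list, seqs, k = 6)
  expect_equal(ncol(fm), 2448)
  expect_equal(nrow(fm), 2)
  # two bands concatenate
  fm2 <- build_feature_matrix(list(ts_list, ts_list), list(seqs, seqs),
                              k = 6)
  expect_equal(ncol(fm2), 4896)
})

test_that("a state's feature block is the member-frame mean", {
  v1 <- c(1, 2, 3, 4); v2 <- c(-1, 0, 1, 2)
  data <- rbind(v1, v1, v2, v2, v2)
  ts <- roi_timeseries(data, subject_id = "s1", tr = 2)
  seqs <- tibble::tibble(subject_id = "s1", frame = 1:5,
                         state = c(1, 1, 2, 2, 2))
  fm <- build_feature_matrix(list(ts), seqs, k = 2)
  expect_equal(unname(fm[1, 1:4]), v1)
  expect_equal(unname(fm[1, 5:8]), v2)
  # a missing state is an error naming subject and state
  seqs_bad <- tibble::tibble(subject_id = "s1", frame = 1:5,
                             state = c(1, 1, 1, 1, 1))
  expect_error(build_feature_matrix(list(ts), seqs_bad, k = 2),
               "s1 has no frames in state 2")
  # subject-level Z variant divides by the member-frame population SD
  data2 <- rbind(v1, v1 + 2, v2, v2)
  ts2 <- roi_timeseries(data2, subject_id = "s1", tr = 2)
  seqs2 <- tibble::tibble(subject_id = "s1", frame = 1:4,
                          state = c(1, 1, 2, 2))
  fmz <- build_feature_matrix(list(ts2), seqs2, k = 2,
                              subject_zscore = TRUE)
  expect_equal(unname(fmz[1, 1:4]), (v1 + 1) / 1)  # mean v1+1, pop SD 1
})

test_that("F-score follows the between/within variability formula", {
  X <- cbind(f = c(2, 4, 0, 2))
  expect_equal(unname(f_score(X, c("a", "a", "b", "b"))), 0.5)
  # identical class distributions give zero
  X2 <- cbind(f = c(1, 2, 1, 2))
  expect_equal(unname(f_score(X2, c("a", "a", "b", "b"))), 0)
  # scale invariance
  set.seed(1)
  X3 <- matrix(rnorm(40), 20, 2)
  lab <- rep(c("a", "b"), 10)
  expect_equal(f_score(X3 * 7, lab), f_score(X3, lab))
  # brute-force oracle from the formula, term by term
  oracle <- apply(X3, 2, function(x) {
    xp <- x[lab == "a"]; xn <- x[lab == "b"]
    ((mean(xp) - mean(x))^2 + (mean(xn) - mean(x))^2) /
      (var(xp) + var(xn))
  })
  expect_equal(f_score(X3, lab), oracle, tolerance = 1e-12)
  # constant-in-both-classes features rank last
  X4 <- cbind(good = c(rnorm(5), rnorm(5) + 3), dead = rep(1, 10))
  sc <- f_score(X4, rep(c("a", "b"), each = 5))
  expect_true(is.na(sc["dead"]))
})

test_that("confusion-matrix metrics and rank AUC match hand computation", {
  truth <- c("SZ", "SZ", "SZ", "SZ", "HC", "HC", "HC", "HC")
  pred <- c("SZ", "SZ", "SZ", "HC", "HC", "HC", "SZ", "SZ")
  m <- classification_metrics(truth, pred)  # TP=3 FN=1 TN=2 FP=2
  expect_equal(m$acc, 0.625)
  expect_equal(m$se, 0.75)
  expect_equal(m$sp, 0.5)
  perfect <- classification_metrics(truth, truth, ifelse(truth == "SZ", 1, -1))
  expect_equal(unlist(perfect), c(acc = 1, se = 1, sp = 1, auc = 1))
  expect_error(classification_metrics(rep("SZ", 3), rep("SZ", 3)),
               "both classes")
  # AUC equals the pairwise-comparison (Mann-Whitney) oracle
  set.seed(2)
  dv <- rnorm(8)
  is_pos <- truth == "SZ"
  pairs <- expand.grid(p = which(is_pos), n = which(!is_pos))
  oracle <- mean(ifelse(dv[pairs$p] > dv[pairs$n], 1,
                        ifelse(dv[pairs$p] == dv[pairs$n], 0.5, 0)))
  got <- classification_metrics(truth, pred, dv)$auc
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("LOPO and LOO are perfect on separable data and agree", {
  set.seed(3)
  n <- 24; p <- 40
  X <- rbind(matrix(rnorm(n / 2 * p), n / 2),
             matrix(rnorm(n / 2 * p, mean = 6), n / 2))  # 6 SD apart
  rownames(X) <- sprintf("s%02d", 1:n)
  lab <- rep(c("HC", "SZ"), each = n / 2)
  cfg <- classifier_config(feature_grid = c(5, 10, 20))
  pairs <- cbind(rownames(X)[lab == "SZ"], rownames(X)[lab == "HC"])
  r_lopo <- lopo_cv(X, lab, pairs, cfg)
  r_loo <- loo_cv(X, lab, cfg)
  expect_equal(r_lopo$acc, 1)
  expect_equal(r_lopo$auc, 1)
  expect_equal(r_loo$acc, 1)
  expect_equal(r_loo$se, 1)
  expect_equal(r_loo$sp, 1)
  expect_error(lopo_cv(X, lab, rbind(pairs, pairs[1, ]), cfg),
               "more than one pair")
})

test_that("a 4-pair toy LOPO matches a hand-executed trace", {
  # one informative feature; training folds always classify by its sign
  X <- cbind(sig = c(-2, -1.5, -1.8, -2.2, 2, 1.5, 1.8, 0.5),
             junk = c(0.1, -0.2, 0.15, 0.05, -0.1, 0.2, -0.15, -0.05))
  rownames(X) <- c(paste0("h", 1:4), paste0("z", 1:4))
  lab <- rep(c("HC", "SZ"), each = 4)
  pairs <- cbind(paste0("z", 1:4), paste0("h", 1:4))
  r <- lopo_cv(X, lab, pairs, classifier_config(feature_grid = 1))
  # manual trace: every subject is on the correct side of the margin
  # learned from the other three pairs, so all folds classify correctly
  expect_equal(r$acc, 1)
  expect_equal(r$chosen_feature_number, 1L)
  # independent oracle: run each fold directly with the SVM
  preds <- character(8)
  for (i in 1:4) {
    test_idx <- c(4 + i, i)
    fit <- e1071::svm(X[-test_idx, "sig", drop = FALSE],
                      factor(lab[-test_idx]), kernel = "linear", cost = 1,
                      scale = FALSE)
    preds[test_idx] <- as.character(predict(fit,
                                            X[test_idx, "sig",
                                              drop = FALSE]))
  }
  expect_equal(mean(preds == lab), r$acc)
})

test_that("permuted labels through the full LOPO stack stay at chance", {
  set.seed(4)
  n <- 200
  X <- matrix(rnorm(n * 100), n)
  rownames(X) <- sprintf("t%03d", 1:n)
  accs <- vapply(1:3, function(s) {
    set.seed(s)
    lab <- sample(rep(c("HC", "SZ"), each = n / 2))
    pairs <- cbind(rownames(X)[lab == "SZ"], rownames(X)[lab == "HC"])
    lopo_cv(X, lab, pairs,
            classifier_config(feature_grid = seq(20, 100, 20)))$acc
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("selecting features outside the folds inflates null accuracy", {
  set.seed(5)
  diffs <- vapply(1:3, function(i) {
    n <- 60; p <- 500
    X <- matrix(rnorm(n * p), n)
    rownames(X) <- sprintf("s%02d", 1:n)
    lab <- rep(c("HC", "SZ"), n / 2)
    clean <- loo_cv(X, lab, classifier_config(feature_grid = 10))$acc
    keep <- order(f_score(X, lab), decreasing = TRUE)[1:10]
    leaky <- loo_cv(X[, keep, drop = FALSE], lab,
                    classifier_config(feature_grid = 10))$acc
    leaky - clean
  }, numeric(1))
  expect_gt(mean(diffs), 0.1)  # leakage detector: inflation is visible
})

test_that("grid ties resolve to the smallest feature number", {
  set.seed(6)
  n <- 20
  X <- rbind(matrix(rnorm(n / 2 * 30), n / 2),
             matrix(rnorm(n / 2 * 30, 5), n / 2))
  rownames(X) <- sprintf("s%02d", 1:n)
  lab <- rep(c("HC", "SZ"), each = n / 2)
  r <- loo_cv(X, lab, classifier_config(feature_grid = c(5, 10, 20, 30)))
  curve <- r$accuracy_curve[[1]]
  expect_equal(r$chosen_feature_number,
               min(curve$n_features[curve$acc == max(curve$acc)]))
})

test_that("consensus features apply the two-stage 80% rule", {
  # feature A in every iteration of every repetition -> consensus;
  # feature B in 79% of iterations of every repetition -> excluded
  reps <- lapply(1:5, function(r) {
    lapply(1:100, function(i) {
      c("A", if (i <= 79) "B", if (r <= 3 && i <= 90) "C")
    })
  })
  got <- consensus_features(reps)
  expect_equal(got, "A")  # B fails within-rep, C fails across-rep (3/5)
  # brute-force two-pass counting oracle on random selection sets
  set.seed(7)
  pool <- sprintf("f%02d", 1:30)
  # stable core (always selected) plus random fill, so the consensus set
  # is non-empty and the oracle has real work to do
  reps2 <- lapply(1:10, function(r) {
    lapply(1:40, function(i) c(pool[1:8], sample(pool[9:30], 4)))
  })
  oracle <- {
    flagged <- lapply(reps2, function(iters) {
      cnt <- sapply(pool, function(f)
        sum(vapply(iters, function(s) f %in% s, logical(1))))
      pool[cnt / 40 >= 0.8]
    })
    cnt2 <- sapply(pool, function(f)
      sum(vapply(flagged, function(s) f %in% s, logical(1))))
    sort(pool[cnt2 / 10 >= 0.8])
  }
  expect_equal(consensus_features(reps2), oracle)
})

test_that("greedy matching balances sex exactly and tracks age", {
  set.seed(8)
  sz <- tibble::tibble(subject_id = sprintf("sz%02d", 1:30),
                       age = round(runif(30, 25, 60)),
                       sex = rep(c("M", "F"), c(16, 14)))
  # pool = copy of patients plus 28 much older controls
  hc <- dplyr::bind_rows(
    tibble::tibble(subject_id = sprintf("hc%02d", 1:30), age = sz$age,
                   sex = sz$sex),
    tibble::tibble(subject_id = sprintf("old%02d", 1:28),
                   age = round(runif(28, 85, 95)),
                   sex = rep(c("M", "F"), 14))
  )
  m <- match_controls(hc, sz)
  expect_equal(nrow(m), 30)
  expect_equal(table(m$sex), table(sz$sex))
  expect_false(any(grepl("^old", m$subject_id)))  # outliers never chosen
  expect_equal(mean(m$age) - mean(sz$age), 0)     # exact-copy pool
  expect_error(match_controls(hc[hc$sex == "M", ], sz), "sex F")
})

test_that("the hold-out experiment separates planted effects from null", {
  # scaled-down: effect on state occupancy/dwell for the patient group
  cfg_eff <- sim_config(n_subjects = 10, n_roi = 60, n_frames = 150,
                        group_effect = list(
                          dwell_multiplier = c(2, 2, 1, 1, 0.5, 0.5),
                          occupancy = c(.25, .25, .125, .125, .125, .125)),
                        master_seed = 21)
  coh <- simulate_cohort(cfg_eff)
  z <- lapply(coh$timeseries, zscore_rois)
  hc_ids <- coh$meta$subject_id[coh$meta$group == "HC"]
  sz_ids <- coh$meta$subject_id[coh$meta$group == "SZ"]
  res <- suppressMessages(holdout_experiment(
    z[hc_ids], coh$meta[coh$meta$group == "HC", ],
    z[sz_ids], coh$meta[coh$meta$group == "SZ", ],
    k = 6, n_definition = 5, n_classification = 5,
    n_repetitions = 3, n_lopo_repeats = 2,
    config = classifier_config(feature_grid = c(20, 60, 120)),
    seed = 31, n_replicates = 3))
  expect_equal(nrow(res$reports), 3)
  expect_gt(mean(res$reports$acc), 0.75)
  expect_equal(length(res$selections), 3)
})

test_that("definition-split CAPs match full-cohort CAPs at high SNR", {
  coh <- small_cohort(n_subjects = 8, master_seed = 41, noise_sd = 0.3)
  full <- suppressMessages(
    cluster_caps(coh$z[coh$hc_ids], k = 6, seed = 3, n_replicates = 5))
  split_fit <- suppressMessages(
    cluster_caps(coh$z[coh$hc_ids[1:4]], k = 6, seed = 3,
                 n_replicates = 5))
  al <- align_capsets(full$caps, split_fit$caps)
  expect_true(all(al$similarity > 0.95))
})
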