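test_that("clustering separates frames drawn from distinct templates", {
  tpl <- make_cap_templates(n_roi = 60, k = 6, seed = 2)
  labels <- rep(1:6, each = 100)
  frames <- template_frames(tpl, labels, noise_sd = 0.05, seed = 9)
  fit <- cluster_caps(frames, k = 6, seed = 4, n_replicates = 5)
  # each cluster contains exactly the frames of one template
  tab <- table(labels, fit$sequences$state)
  expect_true(all(rowSums(tab > 0) == 1), label = "one cluster per template")
  expect_true(all(colSums(tab > 0) == 1))
  al <- align_capsets(as_capset(tpl), fit$caps)
  expect_true(all(al$similarity > 0.99))
})

test_that("pipeline recovers planted templates from a noisy cohort", {
  coh <- small_cohort(n_subjects = 6, master_seed = 3)
  fit <- suppressMessages(
    cluster_caps(coh$z[coh$hc_ids], k = 6, seed = 11, n_replicates = 5))
  al <- align_capsets(as_capset(coh$ground_truth$templates), fit$caps)
  expect_gt(mean(al$similarity), 0.95)
})

test_that("two seeds give the same partition up to label permutation", {
  coh <- small_cohort(n_subjects = 4, master_seed = 8)
  fit1 <- suppressMessages(
    cluster_caps(coh$z[coh$hc_ids], k = 6, seed = 1, n_replicates = 5))
  fit2 <- suppressMessages(
    cluster_caps(coh$z[coh$hc_ids], k = 6, seed = 2, n_replicates = 5))
  al <- align_capsets(fit1$caps, fit2$caps)
  relabeled <- al$permutation[fit1$sequences$state]
  expect_gt(mean(relabeled == fit2$sequences$state), 0.99)
})

test_that("Z-maps are member mean over population SD", {
  frames <- rbind(c(1, 3), c(3, 1), c(0, 0), c(2, 2))
  caps <- compute_zmaps(frames, c(1, 1, 2, 2), k = 2)
  expect_equal(unname(caps$zmaps[1, ]), c(2, 2))  # mean [2,2] / SD [1,1]
  expect_error(compute_zmaps(rbind(c(1, 2), c(1, 2), c(0, 1), c(2, 0)),
                             c(1, 1, 2, 2), k = 2),
               "zero within-state SD")
  expect_error(compute_zmaps(frames, c(1, 1, 1, 2), k = 2), "fewer than 2")
})

test_that("Z-map of pure noise shrinks toward zero with many frames", {
  set.seed(5)
  frames <- matrix(rnorm(1e4 * 8), 1e4, 8)
  caps <- compute_zmaps(frames, rep(1L, 1e4), k = 1)
  expect_true(all(abs(caps$zmaps) < 0.05))
})

test_that("frame assignment picks the most correlated state", {
  tpl <- make_cap_templates(n_roi = 40, k = 6, seed = 3)
  caps <- as_capset(tpl)
  ts3 <- roi_timeseries(rbind(tpl[3, ], tpl[3, ]), tr = 2)
  a <- assign_frames(ts3, caps)
  expect_equal(a$state, c(3L, 3L))
  expect_equal(a$similarity, c(1, 1), tolerance = 1e-12)
  # the negation lands on the opposite-pair partner (template 4 = -3)
  neg <- roi_timeseries(rbind(-tpl[3, ], -tpl[3, ]), tr = 2)
  expect_equal(assign_frames(neg, caps)$state, c(4L, 4L))
})

test_that("assignment matches a brute-force argmax over state correlations", {
  set.seed(6)
  tpl <- make_cap_templates(n_roi = 30, k = 6, seed = 1)
  frames <- matrix(rnorm(50 * 30), 50, 30)
  got <- assign_frames(roi_timeseries(frames, tr = 2), as_capset(tpl))$state
  oracle <- apply(frames, 1, function(f) {
    which.max(vapply(1:6, function(k) cor(f, tpl[k, ]), numeric(1)))
  })
  expect_equal(got, as.integer(oracle))
})

test_that("zero-variance frames are rejected", {
  tpl <- make_cap_templates(n_roi = 20, k = 2, seed = 1)
  bad <- roi_timeseries(rbind(tpl[1, ], rep(3, 20)), tr = 2)
  expect_error(assign_frames(bad, as_capset(tpl)), "zero variance")
})

test_that("silhouette curve finds the planted cluster count", {
  set.seed(2)
  # two clouds well separated in the 1 - r metric (distinct patterns,
  # not mean offsets, since correlation removes each frame's mean)
  tpl2 <- make_cap_templates(n_roi = 10, k = 2, seed = 1)
  clouds <- template_frames(tpl2, rep(1:2, each = 60), noise_sd = 0.15,
                            seed = 2)
  sil2 <- silhouette_curve(clouds, 2:4, seed = 3)
  expect_equal(sil2$k[which.max(sil2$mean_silhouette)], 2L)
  expect_gt(max(sil2$mean_silhouette), 0.8)

  # six strong templates: argmax over 2..10 is 6
  tpl <- make_cap_templates(n_roi = 50, k = 6, seed = 4)
  frames <- template_frames(tpl, rep(1:6, each = 25), noise_sd = 0.15,
                            seed = 5)
  sil6 <- silhouette_curve(frames, 2:10, seed = 3)
  expect_equal(sil6$k[which.max(sil6$mean_silhouette)], 6L)

  # a single blob has no structure at any K
  blob <- matrix(rnorm(150 * 10), 150, 10)
  sil1 <- suppressMessages(silhouette_curve(blob, 2:4, seed = 3))
  expect_true(all(sil1$mean_silhouette < 0.3))
})

test_that("Hungarian alignment recovers planted permutations", {
  tpl <- make_cap_templates(n_roi = 48, k = 6, seed = 6)
  caps <- as_capset(tpl)
  al_id <- align_capsets(caps, caps)
  expect_equal(al_id$permutation, 1:6)
  expect_equal(al_id$similarity, rep(1, 6), tolerance = 1e-12)

  shift <- c(3:6, 1:2)  # cyclic shift by 2
  caps_b <- as_capset(tpl[shift, ])
  al <- align_capsets(caps, caps_b)
  expect_equal(al$permutation, order(shift))
  expect_error(align_capsets(caps, as_capset(tpl[1:4, ])), "mismatch")
})

test_that("Hungarian equals exhaustive enumeration on random matrices", {
  set.seed(99)
  for (i in 1:100) {
    sim <- matrix(runif(36, -1, 1), 6, 6)
    got <- capfreq:::solve_max_assignment(sim)
    oracle <- brute_force_assignment(sim)
    expect_equal(sum(sim[cbind(1:6, got)]), oracle$total, tolerance = 1e-8)
  }
})

test_that("assignment total is invariant to constant similarity shifts", {
  set.seed(17)
  sim <- matrix(runif(36), 6, 6)
  expect_equal(capfreq:::solve_max_assignment(sim),
               capfreq:::solve_max_assignment(sim + 5.3))
})

test_that("cross-band similarity matches direct correlations", {
  tpl <- make_cap_templates(n_roi = 408, k = 6, seed = 7)
  caps <- as_capset(tpl)
  cbs <- cross_band_similarity(caps, caps)
  expect_equal(cbs$r, rep(1, 6), tolerance = 1e-12)

  # negated maps match through the opposite-pair partner at r = 1
  caps_neg <- as_capset(-tpl)
  al <- align_capsets(caps, caps_neg)
  cbs_neg <- cross_band_similarity(caps, caps_neg, al)
  direct <- vapply(1:6, function(i) cor(tpl[i, ], -tpl[al$permutation[i], ]),
                   numeric(1))
  expect_equal(cbs_neg$r, direct, tolerance = 1e-12)
  expect_true(all(cbs_neg$r > 0.999))  # pair structure resolves the sign

  # uncorrelated random maps stay near zero even after optimal matching
  set.seed(31)
  rnd <- matrix(rnorm(6 * 408), 6)
  al2 <- align_capsets(caps, as_capset(rnd))
  expect_true(all(abs(cross_band_similarity(caps, as_capset(rnd),
                                            al2)$r) < 0.2))
})

test_that("between-state similarity is symmetric with opposite pairs at -1", {
  tpl <- make_cap_templates(n_roi = 408, k = 6, seed = 8)
  r <- between_state_similarity(as_capset(tpl))
  expect_equal(r, t(r))
  expect_equal(diag(r), rep(1, 6), tolerance = 1e-12)
  expect_equal(r[1, 2], -1, tolerance = 1e-12)
  expect_equal(r[3, 4], -1, tolerance = 1e-12)
  expect_equal(r[5, 6], -1, tolerance = 1e-12)
  # disjoint supports: cross-pair correlations vanish
  expect_lt(max(abs(r[1:2, 3:6])), 0.2)
})

test_that("clustering a sign-flipped cohort negates the Z-maps", {
  tpl <- make_cap_templates(n_roi = 40, k = 4, seed = 9)
  frames <- template_frames(tpl, rep(1:4, each = 15), noise_sd = 0.1,
                            seed = 10)
  fit_pos <- cluster_caps(frames, k = 4, seed = 5, n_replicates = 5)
  fit_neg <- cluster_caps(-frames, k = 4, seed = 5, n_replicates = 5)
  al <- align_capsets(fit_pos$caps,
                      as_capset(-fit_neg$caps$zmaps))
  relabeled <- al$permutation[fit_neg$sequences$state]
  expect_gt(mean(relabeled == fit_pos$sequences$state), 0.99)
  expect_true(all(al$similarity > 0.99))
})

test_that("reference frames reassigned to their own CAPs reproduce the partition", {
  tpl <- make_cap_templates(n_roi = 60, k = 6, seed = 12)
  frames <- template_frames(tpl, sample(rep(1:6, each = 30)),
                            noise_sd = 0.2, seed = 13)
  fit <- cluster_caps(frames, k = 6, seed = 2, n_replicates = 5)
  re <- assign_frames(roi_timeseries(frames, tr = 2), fit$caps)
  expect_gt(mean(re$state == fit$sequences$state), 0.99)
  # partition property: member counts sum to the total frame count
  expect_equal(sum(fit$n_frames_per_state), nrow(frames))
})
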