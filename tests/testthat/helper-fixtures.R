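# shared fixtures, built in code

# wrap a template matrix as a cap_set so alignment helpers accept it
as_capset <- function(zmaps, band = "broadband") {
  structure(
    list(zmaps = zmaps, k = nrow(zmaps), band = band,
         roi_names = colnames(zmaps),
         n_frames_per_state = rep(1L, nrow(zmaps))),
    class = "cap_set"
  )
}

# frames drawn from templates with Gaussian noise, labels returned
template_frames <- function(templates, labels, noise_sd = 0, seed = 1) {
  set.seed(seed)
  templates[labels, , drop = FALSE] +
    noise_sd * matrix(rnorm(length(labels) * ncol(templates)),
                      length(labels), ncol(templates))
}

# small z-scored cohort for clustering tests
small_cohort <- function(n_subjects = 6, master_seed = 3, ...) {
  cfg <- sim_config(n_subjects = n_subjects, master_seed = master_seed, ...)
  coh <- simulate_cohort(cfg)
  coh$z <- lapply(coh$timeseries, zscore_rois)
  coh$hc_ids <- coh$meta$subject_id[coh$meta$group == "HC"]
  coh$sz_ids <- coh$meta$subject_id[coh$meta$group == "SZ"]
  coh
}

# brute-force best assignment over all permutations (oracle for Hungarian)
brute_force_assignment <- function(sim) {
  k <- nrow(sim)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  totals <- apply(perms, 1, function(p) sum(sim[cbind(seq_len(k), p)]))
  list(permutation = as.integer(perms[which.max(totals), ]),
       total = max(totals))
}

# literal step-up BH definition (independent of stats::p.adjust)
bh_literal <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}
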