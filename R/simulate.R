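#' Simulation configuration
#'
#' Defaults mirror the dimensions of a typical clinical resting-state
#' acquisition: 408 ROIs, 235 frames at TR = 2 s, six states arranged as
#' three opposite-sign pairs, 20 subjects per group. Template amplitude 1
#' with noise SD 0.5 puts frame-to-template correlations high enough that
#' state assignment is reliable but not trivial.
#'
#' @param n_roi Number of ROIs (default 408).
#' @param k Number of states (default 6, must be even).
#' @param tr Repetition time, seconds (default 2).
#' @param n_frames Frames per subject (default 235).
#' @param n_subjects Subjects per group (default 20).
#' @param template_amplitude Signal amplitude in Z units (default 1).
#' @param noise_sd Noise SD in Z units (default 0.5).
#' @param dwell_frames Expected state run length in frames (default 5).
#' @param occupancy Target state occupancy (default uniform).
#' @param group_effect List with `dwell_multiplier` (per-state multiplier on
#'   dwell for the patient-like group) and `occupancy` (optional replacement
#'   occupancy vector); defaults to no group difference.
#' @param master_seed Seed from which all randomness derives.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_roi = 408, k = 6, tr = 2.0, n_frames = 235,
                       n_subjects = 20, template_amplitude = 1,
                       noise_sd = 0.5, dwell_frames = 5,
                       occupancy = rep(1 / k, k),
                       group_effect = list(dwell_multiplier = rep(1, k),
                                           occupancy = NULL),
                       master_seed = 1) {
  stopifnot(k %% 2 == 0, dwell_frames >= 1, noise_sd >= 0,
            abs(sum(occupancy) - 1) < 1e-8)
  structure(
    list(n_roi = n_roi, k = k, tr = tr, n_frames = n_frames,
         n_subjects = n_subjects, template_amplitude = template_amplitude,
         noise_sd = noise_sd, dwell_frames = dwell_frames,
         occupancy = occupancy, group_effect = group_effect,
         master_seed = master_seed),
    class = "sim_config"
  )
}

#' Generate CAP templates as opposite-sign pairs
#'
#' Builds `k/2` base spatial patterns with disjoint active ROI blocks
#' (emulating the block structure of large-scale networks: each state
#' recruits one coherent set of regions and leaves the rest near baseline),
#' then pairs each with its exact negation, as anticorrelated state pairs.
#' Active entries are +1/-1 in equal numbers so every template is exactly
#' mean-zero, and disjoint supports make cross-pair correlations zero.
#'
#' @param n_roi Number of ROIs.
#' @param k Number of states (even).
#' @param seed Seed for the sign pattern within blocks.
#' @return `k` x `n_roi` matrix; rows `2j-1` and `2j` are negations.
#' @export
make_cap_templates <- function(n_roi = 408, k = 6, seed = 1) {
  if (k %% 2 != 0) stop("k must be even (templates come in pairs)",
                        call. = FALSE)
  n_base <- k / 2
  block_id <- rep(seq_len(n_base), length.out = n_roi)
  set.seed(seed)
  templates <- matrix(0, k, n_roi)
  for (j in seq_len(n_base)) {
    idx <- which(block_id == j)
    n_blk <- length(idx)
    half <- floor(n_blk / 2)
    signs <- sample(rep(c(1, -1), c(half, n_blk - half)))
    base <- numeric(n_roi)
    base[idx] <- signs - mean(signs)  # exactly mean-zero row
    templates[2 * j - 1, ] <- base
    templates[2 * j, ] <- -base
  }
  colnames(templates) <- sprintf("roi_%03d", seq_len(n_roi))
  templates
}

#' Simulate a Markov state sequence with controlled dwell time
#'
#' First-order Markov chain with self-transition probability
#' `p = 1 - 1/dwell_frames` (so mean run length is exactly `dwell_frames`
#' in closed form: runs are geometric) and off-diagonal mass split in
#' proportion to the target occupancy of the other states. The initial
#' state is drawn from the occupancy.
#'
#' @param k Number of states.
#' @param n_frames Sequence length.
#' @param dwell_frames Expected run length, >= 1.
#' @param occupancy Target occupancy (sums to 1).
#' @param seed Seed.
#' @return Integer vector of length `n_frames` with values in 1..k.
#' @export
simulate_state_sequence <- function(k, n_frames, dwell_frames,
                                    occupancy = rep(1 / k, k), seed = 1) {
  stopifnot(dwell_frames >= 1, abs(sum(occupancy) - 1) < 1e-8)
  p_self <- 1 - 1 / dwell_frames
  set.seed(seed)
  labels <- integer(n_frames)
  labels[1] <- sample.int(k, 1, prob = occupancy)
  if (p_self >= 1) {
    labels[] <- labels[1]
    return(labels)
  }
  for (t in 2:n_frames) {
    if (stats::runif(1) < p_self) {
      labels[t] <- labels[t - 1]
    } else {
      others <- setdiff(seq_len(k), labels[t - 1])
      labels[t] <- others[sample.int(length(others), 1,
                                     prob = occupancy[others])]
    }
  }
  labels
}

#' Simulate one subject's ROI time series
#'
#' Each frame is `amplitude * template[state] + Gaussian noise`. If `band`
#' is given, the noise component is band-limited: white Gaussian noise is
#' passed through the same zero-phase Butterworth filter used by
#' [bandpass()] and rescaled to `noise_sd`, giving the autocorrelated
#' fluctuations characteristic of band-filtered BOLD while leaving the
#' planted state sequence (and hence all dwell-time ground truth) intact.
#'
#' @param templates `k` x `n_roi` template matrix.
#' @param labels Integer state sequence.
#' @param amplitude Signal amplitude.
#' @param noise_sd Noise SD after any band limiting.
#' @param tr Repetition time, seconds.
#' @param band Optional [band_definition()] for band-limited noise.
#' @param seed Seed.
#' @param subject_id Subject identifier.
#' @return A [roi_timeseries()].
#' @export
simulate_subject <- function(templates, labels, amplitude = 1,
                             noise_sd = 0.5, tr = 2.0, band = NULL,
                             seed = 1, subject_id = "subject") {
  n_t <- length(labels)
  n_roi <- ncol(templates)
  set.seed(seed)
  noise <- matrix(stats::rnorm(n_t * n_roi), n_t, n_roi)
  if (!is.null(band) && noise_sd > 0) {
    nts <- roi_timeseries(noise, subject_id = subject_id, tr = tr)
    noise <- bandpass(nts, band)$data
    noise <- noise / stats::sd(as.vector(noise))
  }
  data <- amplitude * templates[labels, , drop = FALSE] + noise_sd * noise
  rownames(data) <- NULL
  out <- roi_timeseries(data, subject_id = subject_id, tr = tr,
                        band = if (is.null(band)) "broadband" else band,
                        roi_names = colnames(templates))
  out
}

#' Simulate a two-group cohort with known ground truth
#'
#' Generates a control-like (HC) and a patient-like (SZ) group. The patient
#' group's state dynamics are modified through `group_effect` (per-state
#' dwell multipliers and/or a different occupancy target) while the spatial
#' templates are shared — group differences live in the temporal metrics,
#' not in the maps. Demographics: ages from overlapping normal
#' distributions, sexes balanced, mean framewise displacement from a
#' log-normal (right-skewed, as head motion is), slightly higher in the
#' patient group.
#'
#' @param config A [sim_config()].
#' @param band Optional [band_definition()] for band-limited noise.
#' @return A list with:
#'   * `timeseries`: named list of `roi_ts` (HC then SZ),
#'   * `meta`: tibble `subject_id`, `group`, `age`, `sex`, `mean_fd`,
#'   * `ground_truth`: list with `templates`, `sequences` (tibble
#'     `subject_id`, `frame`, `state`), `dwell_frames` per group,
#'     `occupancy` per group, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), band = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$master_seed, 4 * config$n_subjects + 2)
  templates <- make_cap_templates(config$n_roi, config$k, seeds[1])
  k <- config$k

  ge <- config$group_effect
  dwell_mult <- if (is.null(ge$dwell_multiplier)) rep(1, k) else
    ge$dwell_multiplier
  occ_sz <- if (is.null(ge$occupancy)) config$occupancy else ge$occupancy

  subjects <- list(); seq_rows <- list(); meta_rows <- list()
  si <- 1
  for (grp in c("HC", "SZ")) {
    occ <- if (grp == "HC") config$occupancy else occ_sz
    # per-state dwell: a multiplier > 1 on a state lengthens its runs by
    # lowering its leave-probability
    dwell_vec <- if (grp == "HC") rep(config$dwell_frames, k) else
      config$dwell_frames * dwell_mult
    for (i in seq_len(config$n_subjects)) {
      sid <- sprintf("%s_%02d", grp, i)
      s_seed <- seeds[1 + si]
      labels <- simulate_state_sequence_statewise(
        k, config$n_frames, dwell_vec, occ, s_seed)
      ts <- simulate_subject(templates, labels,
                             amplitude = config$template_amplitude,
                             noise_sd = config$noise_sd, tr = config$tr,
                             band = band, seed = seeds[1 + si + 1],
                             subject_id = sid)
      subjects[[sid]] <- ts
      seq_rows[[sid]] <- tibble::tibble(subject_id = sid,
                                        frame = seq_along(labels),
                                        state = labels)
      meta_rows[[sid]] <- tibble::tibble(subject_id = sid, group = grp)
      si <- si + 2
    }
  }
  meta <- dplyr::bind_rows(meta_rows)
  meta <- cbind(meta, simulate_demographics(nrow(meta), meta$group,
                                            seeds[length(seeds)]))
  list(
    timeseries = subjects,
    meta = tibble::as_tibble(meta),
    ground_truth = list(
      templates = templates,
      sequences = dplyr::bind_rows(seq_rows),
      dwell_frames = list(HC = rep(config$dwell_frames, k),
                          SZ = config$dwell_frames * dwell_mult),
      occupancy = list(HC = config$occupancy, SZ = occ_sz),
      config = config
    )
  )
}

# Markov chain with per-state dwell: leave-probability 1/dwell[state]
simulate_state_sequence_statewise <- function(k, n_frames, dwell_vec,
                                              occupancy, seed) {
  if (length(dwell_vec) == 1) dwell_vec <- rep(dwell_vec, k)
  set.seed(seed)
  labels <- integer(n_frames)
  labels[1] <- sample.int(k, 1, prob = occupancy)
  u <- stats::runif(n_frames)
  for (t in 2:n_frames) {
    prev <- labels[t - 1]
    if (u[t] < 1 - 1 / dwell_vec[prev]) {
      labels[t] <- prev
    } else {
      others <- setdiff(seq_len(k), prev)
      labels[t] <- others[sample.int(length(others), 1,
                                     prob = occupancy[others])]
    }
  }
  labels
}

simulate_demographics <- function(n, group, seed) {
  set.seed(seed)
  age <- round(stats::rnorm(n, mean = ifelse(group == "SZ", 46, 45),
                            sd = 11))
  age <- pmax(pmin(age, 75), 18)
  sex <- character(n)
  for (g in unique(group)) {
    idx <- which(group == g)
    half <- ceiling(length(idx) / 2)
    sex[idx] <- sample(rep(c("M", "F"), c(half, length(idx) - half)))
  }
  mean_fd <- stats::rlnorm(n, meanlog = log(0.12) +
                             ifelse(group == "SZ", 0.15, 0), sdlog = 0.45)
  data.frame(age = age, sex = sex, mean_fd = mean_fd)
}

#' Simulate one cohort per frequency band with band-specific dwell
#'
#' Lower-frequency bands get longer planted dwell times (defaults 6, 2.5,
#' 1.3, 1.1 frames for slow-5 through slow-2), with band-limited noise, so
#' the pipeline's recovered persistence should decrease monotonically from
#' slow-5 to slow-2.
#'
#' @param config A [sim_config()]; its `dwell_frames` is overridden per
#'   band.
#' @param dwell_by_band Named numeric vector of dwell (frames) per band
#'   name.
#' @return Named list of [simulate_cohort()] results, one per band.
#' @export
simulate_multiband_cohort <- function(config = sim_config(),
                                      dwell_by_band = c(slow5 = 6,
                                                        slow4 = 2.5,
                                                        slow3 = 1.3,
                                                        slow2 = 1.1)) {
  bands <- built_in_bands()
  out <- list()
  band_seeds <- derive_seeds(config$master_seed, length(dwell_by_band) + 10)
  for (i in seq_along(dwell_by_band)) {
    nm <- names(dwell_by_band)[i]
    cfg <- config
    cfg$dwell_frames <- dwell_by_band[[i]]
    cfg$master_seed <- band_seeds[i]
    out[[nm]] <- simulate_cohort(cfg, band = bands[[nm]])
  }
  out
}
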