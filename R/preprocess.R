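#' Zero-phase Butterworth band-pass filtering
#'
#' Filters each ROI column independently with a Butterworth band-pass
#' (two second-order sections, i.e. a 4th-order band-pass) applied forward
#' and backward with [signal::filtfilt()], so the net phase shift is zero and
#' state timing is not lagged — essential when individual frames are
#' clustered. Columns are linearly detrended first to stop scanner drift
#' leaking through the low band edge. When the band's upper edge reaches the
#' Nyquist frequency (as slow-2 does at TR = 2 s), the band-pass design is
#' degenerate and a high-pass of the same order is used instead.
#'
#' @param ts A [roi_timeseries()] object.
#' @param band A [band_definition()] (upper edge must not exceed Nyquist).
#' @param order Butterworth order per edge (default 2, giving a 4th-order
#'   band-pass before the forward-backward doubling).
#' @return A `roi_ts` with the same shape, tagged with `band`.
#' @export
bandpass <- function(ts, band, order = 2) {
  stopifnot(inherits(ts, "roi_ts"), inherits(band, "band_definition"))
  nyquist <- check_band_for_tr(band, ts$tr)
  n_t <- nrow(ts$data)
  # filtfilt needs a few filter lengths of signal to settle
  if (n_t < 12 * order) {
    stop(sprintf("time series too short to filter (%d frames)", n_t),
         call. = FALSE)
  }
  w_low <- band$f_low / nyquist
  w_high <- band$f_high / nyquist
  if (w_high >= 1 - 1e-9) {
    filt <- signal::butter(order, w_low, type = "high")
  } else {
    filt <- signal::butter(order, c(w_low, w_high), type = "pass")
  }
  x <- apply(ts$data, 2, detrend_linear)
  y <- apply(x, 2, function(col) signal::filtfilt(filt, col))
  out <- ts
  out$data <- y
  colnames(out$data) <- ts$roi_names
  out$band <- band
  out
}

detrend_linear <- function(x) {
  t <- seq_along(x)
  stats::lm.fit(cbind(1, t), x)$residuals
}

#' Z-score each ROI column
#'
#' Normalizes every ROI time course to mean 0, standard deviation 1 using
#' the population convention (divide by T, not T - 1). After this step the
#' absolute value of Z expresses how far a region has deviated from its own
#' baseline, which is what frame-wise clustering compares across regions.
#' A constant column is a data defect (a dead ROI) and raises an error
#' naming the ROI.
#'
#' @param ts A [roi_timeseries()] object.
#' @return A `roi_ts` of the same shape with standardized columns.
#' @export
zscore_rois <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  x <- ts$data
  n <- nrow(x)
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(x^2) - mu^2)
  dead <- which(sd_pop < 1e-12)
  if (length(dead)) {
    stop("constant (zero-variance) ROI: ", ts$roi_names[dead[1]],
         call. = FALSE)
  }
  out <- ts
  out$data <- sweep(sweep(x, 2, mu, "-"), 2, sd_pop, "/")
  colnames(out$data) <- ts$roi_names
  out
}

#' Drop initial frames of a scan
#'
#' Discards the first `n_discard` frames (scanner equilibration), applied
#' before any filtering. The default of 5 turns a 240-volume acquisition
#' into the 235 frames analysed per subject.
#'
#' @param ts A [roi_timeseries()] object.
#' @param n_discard Number of leading frames to drop (default 5).
#' @return A shorter `roi_ts`.
#' @export
discard_initial_frames <- function(ts, n_discard = 5) {
  stopifnot(inherits(ts, "roi_ts"), n_discard >= 0)
  if (nrow(ts$data) - n_discard < 2) {
    stop("discarding ", n_discard, " frames leaves fewer than 2",
         call. = FALSE)
  }
  out <- ts
  out$data <- ts$data[-seq_len(n_discard), , drop = FALSE]
  if (n_discard == 0) out$data <- ts$data
  out
}
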