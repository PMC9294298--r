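#' Frequency band definitions
#'
#' A band is a closed interval `[f_low, f_high]` in Hz. The built-in bands are
#' the typical resting-state low-frequency range and the four canonical
#' sub-bands: typical (0.01--0.08), slow-5 (0.01--0.027), slow-4
#' (0.027--0.073), slow-3 (0.073--0.198), slow-2 (0.198--0.25 Hz). Together
#' the four sub-bands tile 0.01--0.25 Hz with shared edges only.
#'
#' @param name Band name. One of `"typical"`, `"slow5"`, `"slow4"`,
#'   `"slow3"`, `"slow2"`, or `"custom"` (then `f_low`/`f_high` are required).
#' @param f_low,f_high Band edges in Hz; required only for `"custom"`.
#' @return A `band_definition` object (named list with `name`, `f_low`,
#'   `f_high`).
#' @examples
#' band_definition("slow5")
#' band_definition("custom", 0.02, 0.05)
#' @export
band_definition <- function(name, f_low = NULL, f_high = NULL) {
  built_in <- list(
    typical = c(0.010, 0.080),
    slow5   = c(0.010, 0.027),
    slow4   = c(0.027, 0.073),
    slow3   = c(0.073, 0.198),
    slow2   = c(0.198, 0.250)
  )
  name <- match.arg(name, c(names(built_in), "custom"))
  if (name == "custom") {
    if (is.null(f_low) || is.null(f_high)) {
      stop("custom bands need explicit `f_low` and `f_high`", call. = FALSE)
    }
  } else {
    f_low <- built_in[[name]][1]
    f_high <- built_in[[name]][2]
  }
  if (!(f_low > 0 && f_high > f_low)) {
    stop("band edges must satisfy 0 < f_low < f_high", call. = FALSE)
  }
  structure(list(name = name, f_low = f_low, f_high = f_high),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band %s: %.3f-%.3f Hz>\n", x$name, x$f_low, x$f_high))
  invisible(x)
}

#' The four sub-bands plus the typical range
#'
#' @return Named list of [band_definition()] objects in order typical,
#'   slow5, slow4, slow3, slow2.
#' @export
built_in_bands <- function() {
  nm <- c("typical", "slow5", "slow4", "slow3", "slow2")
  stats::setNames(lapply(nm, band_definition), nm)
}

#' Center frequency of a band
#'
#' The arithmetic midpoint `(f_low + f_high) / 2`, used to express a state's
#' persistence in cycles of the band's characteristic frequency (see
#' [normalized_persistence()]).
#'
#' @param band A [band_definition()].
#' @return Center frequency in Hz.
#' @examples
#' band_center(band_definition("slow5")) # 0.0185
#' @export
band_center <- function(band) {
  stopifnot(inherits(band, "band_definition"))
  (band$f_low + band$f_high) / 2
}

# validate band against sampling rate; returns Nyquist
check_band_for_tr <- function(band, tr) {
  nyquist <- 1 / (2 * tr)
  if (band$f_high > nyquist + 1e-12) {
    stop(sprintf("band upper edge %.4f Hz exceeds Nyquist %.4f Hz for TR = %g s",
                 band$f_high, nyquist, tr), call. = FALSE)
  }
  nyquist
}
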