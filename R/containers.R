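#' Transient-absorption map
#'
#' The central container: a matrix of pump-induced absorbance changes
#' \eqn{\Delta OD(\lambda, t)} with its wavelength and delay axes. Rows are
#' delays, columns are probe wavelengths. Values are in OD units (not mOD).
#'
#' @param wavelength Spectral axis (nm), see [spectral_axis()].
#' @param delay Delay axis (ps), see [delay_axis()].
#' @param dod Numeric matrix, `length(delay)` rows by `length(wavelength)`
#'   columns, finite.
#' @return An object of class `ta_map`.
#' @export
ta_map <- function(wavelength, delay, dod) {
  wavelength <- spectral_axis(wavelength, min_len = 2L)
  delay <- delay_axis(delay, min_len = 2L)
  dod <- as.matrix(dod)
  if (nrow(dod) != length(delay) || ncol(dod) != length(wavelength))
    stop(sprintf("dod matrix is %d x %d but axes imply %d x %d",
                 nrow(dod), ncol(dod), length(delay), length(wavelength)))
  if (!all(is.finite(dod)))
    stop("dod matrix contains non-finite values")
  structure(list(wavelength = wavelength, delay = delay, dod = unname(dod)),
            class = "ta_map")
}

#' @export
print.ta_map <- function(x, ...) {
  cat(sprintf("<ta_map> %d delays x %d wavelengths\n", length(x$delay), length(x$wavelength)))
  cat(sprintf("  probe  : %.1f-%.1f nm\n", min(x$wavelength), max(x$wavelength)))
  cat(sprintf("  delay  : %.3f-%.3f ps\n", min(x$delay), max(x$delay)))
  cat(sprintf("  dOD    : [%.3g, %.3g] OD\n", min(x$dod), max(x$dod)))
  invisible(x)
}

#' Steady-state or difference spectrum
#'
#' @param wavelength Spectral axis (nm).
#' @param od Values (OD or dOD), same length as the axis, finite.
#' @return An object of class `ta_spectrum`.
#' @export
ta_spectrum <- function(wavelength, od) {
  wavelength <- spectral_axis(wavelength, min_len = 2L)
  od <- as.numeric(od)
  if (length(od) != length(wavelength))
    stop("spectrum values and wavelength axis differ in length")
  if (!all(is.finite(od)))
    stop("spectrum contains non-finite values")
  structure(list(wavelength = wavelength, od = od), class = "ta_spectrum")
}

#' @export
print.ta_spectrum <- function(x, ...) {
  cat(sprintf("<ta_spectrum> %d points, %.1f-%.1f nm, values [%.3g, %.3g]\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$od), max(x$od)))
  invisible(x)
}

#' Single-wavelength kinetic trace
#'
#' A band-averaged time trace, carrying the probe window it was extracted from.
#'
#' @param delay Delay axis (ps).
#' @param dod Values (dOD), same length, finite.
#' @param center Probe window centre (nm), metadata.
#' @param bandwidth Probe window full width (nm), metadata.
#' @return An object of class `ta_trace`.
#' @export
ta_trace <- function(delay, dod, center = NA_real_, bandwidth = NA_real_) {
  delay <- delay_axis(delay, min_len = 2L)
  dod <- as.numeric(dod)
  if (length(dod) != length(delay))
    stop("trace values and delay axis differ in length")
  if (!all(is.finite(dod)))
    stop("trace contains non-finite values")
  structure(list(delay = delay, dod = dod,
                 center = as.numeric(center), bandwidth = as.numeric(bandwidth)),
            class = "ta_trace")
}

#' @export
print.ta_trace <- function(x, ...) {
  cat(sprintf("<ta_trace> %d delays, %.3f-%.3f ps, window %.1f +/- %.1f nm\n",
              length(x$delay), min(x$delay), max(x$delay),
              x$center, x$bandwidth / 2))
  invisible(x)
}
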