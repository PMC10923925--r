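#' Validate a probe-wavelength axis
#'
#' A spectral axis is a strictly ascending vector of probe wavelengths in
#' nanometres. TA experiments of retinal proteins typically span the visible
#' ESA/GSB region through the NIR stimulated-emission band (430--1400 nm).
#'
#' @param wavelengths Numeric vector of wavelengths (nm), strictly ascending,
#'   all positive and finite.
#' @param min_len Minimum number of points. Generators require the full
#'   default of 8; loaded files may be smaller.
#' @return The validated numeric vector (invisibly classed as plain numeric).
#' @export
spectral_axis <- function(wavelengths, min_len = 8L) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < min_len)
    stop("spectral axis must have at least ", min_len, " wavelength points")
  if (!all(is.finite(wavelengths)) || any(wavelengths <= 0))
    stop("spectral axis wavelengths must be finite and positive")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength axis must be strictly ascending")
  wavelengths
}

#' Validate a pump-probe delay axis
#'
#' Delays are in picoseconds, strictly ascending, first delay >= 0. The axis
#' may be nonuniform; the conventional layout is a linear segment through the
#' first few hundred femtoseconds followed by log-spaced delays.
#'
#' @param delays Numeric vector of delays (ps).
#' @param min_len Minimum number of points; generators require the default 8.
#' @return The validated numeric vector.
#' @export
delay_axis <- function(delays, min_len = 8L) {
  delays <- as.numeric(delays)
  if (length(delays) < min_len)
    stop("delay axis must have at least ", min_len, " delay points")
  if (!all(is.finite(delays)))
    stop("delay axis values must be finite")
  if (delays[1] < 0)
    stop("first delay must be >= 0")
  if (any(diff(delays) <= 0))
    stop("delay axis must be strictly ascending")
  delays
}

#' Linear-then-logarithmic delay axis
#'
#' Builds the delay grid used throughout: linear sampling up to `t_lin`
#' (step `dt_lin`), then `n_log` log-spaced points out to `t_max`.
#'
#' @param t_lin End of the linear segment (ps). Default 0.5.
#' @param dt_lin Linear step (ps). Default 0.02.
#' @param t_max Last delay (ps). Default 100.
#' @param n_log Number of log-spaced points after `t_lin`. Default 40.
#' @return Numeric delay vector (ps).
#' @export
linlog_delay_axis <- function(t_lin = 0.5, dt_lin = 0.02, t_max = 100, n_log = 40L) {
  stopifnot(t_lin > 0, dt_lin > 0, t_max > t_lin, n_log >= 2)
  lin <- seq(0, t_lin, by = dt_lin)
  lg <- exp(seq(log(t_lin), log(t_max), length.out = n_log + 1L))[-1L]
  delay_axis(c(lin, lg))
}

# speed of light in cm per picosecond; converts wavenumber (cm^-1) to
# frequency (1/ps): f = C_CM_PER_PS * nu_tilde
C_CM_PER_PS <- 2.99792458e-2
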