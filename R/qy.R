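# Quantum-yield estimation from wavenumber-domain band integrals of the
# long-delay difference spectrum, with the product/reactant dipole-strength
# correction.

#' Band integral of a spectrum in the wavenumber domain
#'
#' Trapezoidal integral over wavenumber \eqn{\tilde\nu = 10^7/\lambda}
#' (cm^-1) between the window edges, taken over increasing wavenumber.
#' Dipole strengths are energy-domain quantities, so integration happens in
#' wavenumber even though spectra are sampled in wavelength. Window edges not
#' on the grid are included by linear interpolation.
#'
#' @param spec A [ta_spectrum()].
#' @param lo,hi Wavelength window (nm), `lo < hi`, overlapping the axis.
#' @return Integral in OD cm^-1.
#' @export
band_integral <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "ta_spectrum"))
  if (lo >= hi) stop("window must satisfy lo < hi")
  wl <- spec$wavelength
  if (hi < min(wl) || lo > max(wl))
    stop("integration window lies outside the wavelength axis")
  lo <- max(lo, min(wl)); hi <- min(hi, max(wl))
  inside <- wl > lo & wl < hi
  xs <- c(lo, wl[inside], hi)
  ys <- c(stats::approx(wl, spec$od, lo)$y, spec$od[inside],
          stats::approx(wl, spec$od, hi)$y)
  nu <- 1e7 / xs               # descending as wavelength ascends
  pracma::trapz(rev(nu), rev(ys))
}

#' Photoisomerization quantum yield from difference-band integrals
#'
#' Per excited molecule, the long-delay difference spectrum is
#' \eqn{\phi(\epsilon_{prod} - \epsilon_{reac})}; its band integral over the
#' ground-state absorption region is \eqn{\phi D_{reac}(r - 1)} when the
#' product carries `r` times the reactant's dipole strength. The early bleach
#' integral measures \eqn{D_{reac}}, so
#' \deqn{\hat\phi = \frac{I_{long}}{|I_{bleach}| (r - 1)}.}
#' The caller must supply a bleach spectrum free of excited-state
#' contributions (e.g. from a decomposed map at an early delay); this
#' formula is a minimal reconstruction validated by round-trip recovery on
#' synthetic data, flagged `formula = "reconstructed"` in the result.
#'
#' @param diff_long Post-photochemistry difference [ta_spectrum()] (long
#'   delays, excited state fully decayed).
#' @param bleach_early Early ground-state-depletion [ta_spectrum()] (negative
#'   band at the reactant absorption).
#' @param r Product-to-reactant dipole strength ratio, > 1 (about 1.15 for
#'   the 13-cis to all-trans retinal case).
#' @param window Wavelength window (nm) covering the ground-state absorption
#'   region. Default c(480, 650).
#' @return A `qy_estimate`: `phi`, `dipole_ratio`, `long_integral`,
#'   `reference_integral`, `window`, `out_of_range` flag, `formula`.
#' @export
estimate_qy <- function(diff_long, bleach_early, r = 1.15,
                        window = c(480, 650)) {
  if (!is.finite(r) || r <= 1)
    stop("dipole ratio r must exceed 1")
  i_long <- band_integral(diff_long, window[1], window[2])
  i_bleach <- abs(band_integral(bleach_early, window[1], window[2]))
  scale <- max(abs(diff_long$od), abs(bleach_early$od), .Machine$double.xmin)
  if (i_bleach <= 1e-12 * scale)
    stop("bleach integral is (numerically) zero: quantum yield unidentifiable")
  phi <- i_long / (i_bleach * (r - 1))
  structure(list(phi = phi, dipole_ratio = r, long_integral = i_long,
                 reference_integral = i_bleach, window = window,
                 out_of_range = phi < 0 || phi > 1,
                 formula = "reconstructed"),
            class = "qy_estimate")
}

#' @export
print.qy_estimate <- function(x, ...) {
  cat(sprintf("<qy_estimate> phi = %.4f (dipole ratio %.3f, window %g-%g nm)%s\n",
              x$phi, x$dipole_ratio, x$window[1], x$window[2],
              if (x$out_of_range) "  [OUT OF RANGE]" else ""))
  cat(sprintf("  I_long = %.4g OD cm^-1, |I_bleach| = %.4g OD cm^-1, formula: %s\n",
              x$long_integral, x$reference_integral, x$formula))
  invisible(x)
}
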