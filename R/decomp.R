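# Pure-species isolation: every estimator reduces to a scalar least-squares
# scale c of a "pure" reference signal onto a mixture signal, restricted to a
# regime where only the reference species contributes. The estimators differ
# in the marker used: dynamic difference spectra (population evolution), the
# coherent-oscillation residual, raw NIR stimulated emission, or the
# time-averaged late spectrum.

check_shared_axes <- function(a, b) {
  if (!isTRUE(all.equal(a$wavelength, b$wavelength)) ||
      !isTRUE(all.equal(a$delay, b$delay)))
    stop("maps must share wavelength and delay axes")
}

#' Logical mask for a set of wavelength windows
#'
#' @param wavelength Spectral axis (nm).
#' @param windows List of length-2 `c(lo, hi)` windows (nm).
#' @return Logical vector, TRUE inside any window.
#' @export
spectral_mask <- function(wavelength, windows) {
  if (is.numeric(windows) && length(windows) == 2) windows <- list(windows)
  sel <- rep(FALSE, length(wavelength))
  for (w in windows) {
    if (length(w) != 2 || w[1] >= w[2]) stop("each window must be c(lo, hi) with lo < hi")
    sel <- sel | (wavelength >= w[1] & wavelength <= w[2])
  }
  sel
}

# default excited-state-dominated mask: visible ESA plus NIR SE
DEFAULT_ES_MASK <- list(c(440, 500), c(850, 1400))

new_scale_estimate <- function(factor, stderr, residual_norm, method,
                               t_range, window, n_obs) {
  structure(list(factor = factor, stderr = stderr,
                 residual_norm = residual_norm, method = method,
                 t_range = t_range, window = window, n_obs = n_obs),
            class = "scale_estimate")
}

#' @export
print.scale_estimate <- function(x, ...) {
  cat(sprintf("<scale_estimate> method=%s  c = %.4f +/- %.4f  (residual %.3g, n=%d)\n",
              x$method, x$factor, x$stderr, x$residual_norm, x$n_obs))
  invisible(x)
}

#' Dynamic difference spectra
#'
#' Computes \eqn{\Delta\Delta OD = \Delta OD(\cdot, t_2) - \Delta OD(\cdot,
#' t_1)} for each requested delay pair. Differencing cancels any contribution
#' that is static between the two delays, isolating evolving (excited-state)
#' signal.
#'
#' @param map A [ta_map()].
#' @param pairs Two-column integer matrix of delay indices, second > first.
#'   Default: all consecutive pairs.
#' @return List of `list(t1, t2, spectrum)` with `spectrum` a [ta_spectrum()].
#' @export
dynamic_difference <- function(map, pairs = NULL) {
  stopifnot(inherits(map, "ta_map"))
  nt <- length(map$delay)
  if (is.null(pairs)) pairs <- cbind(seq_len(nt - 1L), seq_len(nt - 1L) + 1L)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (any(pairs < 1L) || any(pairs > nt))
    stop("delay index out of range [1, ", nt, "]")
  if (any(pairs[, 2] <= pairs[, 1]))
    stop("second delay index must exceed the first in every pair")
  lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    list(t1 = map$delay[i], t2 = map$delay[j],
         spectrum = ta_spectrum(map$wavelength, map$dod[j, ] - map$dod[i, ]))
  })
}

# rows = delay pairs with both delays >= t_min, cols = masked wavelengths.
# Pairs stride a third of the post-t_min span: long baselines emphasise the
# slowly decaying species (suppressing any residual fast-species signal near
# t_min) while distinct endpoints keep pair noise uncorrelated.
ddod_matrix <- function(map, t_min, mask_sel) {
  idx <- which(map$delay >= t_min)
  if (length(idx) < 2) stop("fewer than two delays at t >= t_min")
  stride <- max(1L, ceiling(length(idx) / 3))
  if (stride >= length(idx)) stride <- length(idx) - 1L
  pairs <- cbind(idx[seq_len(length(idx) - stride)],
                 idx[seq_len(length(idx) - stride) + stride])
  dd <- dynamic_difference(map, pairs)
  t(vapply(dd, function(d) d$spectrum$od[mask_sel], numeric(sum(mask_sel))))
}

#' Scale factor from dynamic-difference-spectrum convergence
#'
#' After a fast-decaying species' excited state is extinct, the mixture's
#' dynamic difference spectra are those of the surviving pure species scaled
#' by its excited-population fraction c. The estimator solves
#' \deqn{\hat c = \mathrm{argmin}_c \sum (\Delta\Delta OD_{mix} - c\,
#'   \Delta\Delta OD_{pure})^2 = \frac{\langle \Delta\Delta OD_{mix},
#'   \Delta\Delta OD_{pure}\rangle}{\langle \Delta\Delta OD_{pure},
#'   \Delta\Delta OD_{pure}\rangle}}
#' over all consecutive delay pairs with both delays >= `t_min`, restricted
#' to excited-state-dominated wavelengths. Uncertainty is a delete-one-pair
#' jackknife.
#'
#' @param mix,pure [ta_map()]s on shared axes.
#' @param t_min Earliest delay used (ps). Default 0.6 (post-convergence
#'   regime for the dark-adapted isomer mixture).
#' @param mask List of wavelength windows (nm) dominated by excited-state
#'   signal. Default visible ESA 440--500 nm plus NIR SE 850--1400 nm.
#' @return A `scale_estimate`.
#' @export
estimate_scale_factor_ddod <- function(mix, pure, t_min = 0.6,
                                       mask = DEFAULT_ES_MASK) {
  check_shared_axes(mix, pure)
  if (t_min < min(mix$delay) || t_min > max(mix$delay))
    stop("t_min outside the delay range")
  sel <- spectral_mask(mix$wavelength, mask)
  if (!any(sel)) stop("spectral mask selects no wavelengths")
  dm <- ddod_matrix(mix, t_min, sel)
  dp <- ddod_matrix(pure, t_min, sel)
  denom <- sum(dp^2)
  if (denom <= .Machine$double.eps * length(dp))
    stop("factor unidentifiable: pure ddod is identically zero on the mask")
  c_hat <- sum(dm * dp) / denom
  k <- nrow(dp)
  cjack <- vapply(seq_len(k), function(i) {
    sum(dm[-i, , drop = FALSE] * dp[-i, , drop = FALSE]) /
      sum(dp[-i, , drop = FALSE]^2)
  }, numeric(1))
  stderr <- sqrt((k - 1) / k * sum((cjack - mean(cjack))^2))
  new_scale_estimate(c_hat, stderr,
                     residual_norm = sqrt(sum((dm - c_hat * dp)^2)),
                     method = "ddod", t_range = c(t_min, max(mix$delay)),
                     window = mask, n_obs = length(dp))
}

#' Weighted spectral subtraction
#'
#' Removes a pure species' contribution: `mix - c * pure`, pixelwise.
#'
#' @param mix,pure [ta_map()]s on shared axes.
#' @param c_factor Non-negative subtraction factor.
#' @return A [ta_map()] of the remaining species.
#' @export
subtract_species <- function(mix, pure, c_factor) {
  check_shared_axes(mix, pure)
  if (!is.finite(c_factor) || c_factor < 0) stop("c_factor must be >= 0")
  ta_map(mix$wavelength, mix$delay, mix$dod - c_factor * pure$dod)
}

#' Scale factor from coherent-oscillation amplitudes
#'
#' Uses the low-frequency vibrational coherence (observable near 520 nm) as a
#' species-selective population marker: when only the reference species
#' carries the coherence, the mixture's oscillatory residual is the pure
#' residual scaled by that species' excited fraction. Both traces are
#' band-averaged at the window, fitted with a multiexponential
#' ([fit_multiexp()]), and the oscillatory residuals are matched by scalar
#' least squares over `t_range`.
#'
#' @param mix,pure [ta_map()]s on shared axes.
#' @param window_center,window_width Probe window (nm). Default 520 +/- 15.
#' @param t_range Delay range (ps) used for matching. Default c(0.08, 1.5):
#'   after the coherent-artifact window, while the coherence is alive.
#' @param n_exp Exponentials in the detrending fit. Default 3 (the mixture
#'   trace superposes the two species' decays).
#' @param detrend_tau_min Lower lifetime bound (ps) for the detrending fits.
#'   Default 0.3, slower than a 180 cm^-1 period, so the smooth model cannot
#'   absorb the coherence it is meant to expose.
#' @param noise_floor Per-point noise RMS (OD); the pure residual must exceed
#'   3x this value or the marker is deemed absent.
#' @return A `scale_estimate`.
#' @export
estimate_factor_from_oscillations <- function(mix, pure, window_center = 520,
                                              window_width = 30,
                                              t_range = c(0.08, 1.5),
                                              n_exp = 3, detrend_tau_min = 0.3,
                                              noise_floor = 0) {
  check_shared_axes(mix, pure)
  bounds <- c(detrend_tau_min, 1000)
  tr_mix <- extract_trace(mix, window_center, window_width)
  tr_pure <- extract_trace(pure, window_center, window_width)
  # detrending components are expected to pile up at the slow-lifetime bound
  res_mix <- isolate_oscillations(
    tr_mix, suppressWarnings(
      fit_multiexp(tr_mix, n = n_exp, t_start = t_range[1],
                   tau_bounds = bounds)))
  res_pure <- isolate_oscillations(
    tr_pure, suppressWarnings(
      fit_multiexp(tr_pure, n = n_exp, t_start = t_range[1],
                   tau_bounds = bounds)))
  keep <- res_pure$delay <= t_range[2]
  rp <- res_pure$dod[keep]
  rm_ <- res_mix$dod[res_mix$delay <= t_range[2]]
  if (sqrt(mean(rp^2)) <= 3 * noise_floor)
    stop("no coherence marker: pure oscillatory residual is below the noise floor")
  denom <- sum(rp^2)
  if (denom <= .Machine$double.eps * length(rp))
    stop("no coherence marker: pure oscillatory residual is identically zero")
  c_hat <- sum(rm_ * rp) / denom
  resid <- rm_ - c_hat * rp
  dof <- max(length(rp) - 1L, 1L)
  stderr <- sqrt(sum(resid^2) / dof / denom)
  new_scale_estimate(c_hat, stderr, residual_norm = sqrt(sum(resid^2)),
                     method = "oscillation", t_range = t_range,
                     window = list(c(window_center - window_width / 2,
                                     window_center + window_width / 2)),
                     n_obs = length(rp))
}

#' Scale factor from NIR stimulated-emission amplitudes
#'
#' In the NIR stimulated-emission band only excited-state population emits,
#' so raw dOD there is a direct S1 population measure. Scalar least-squares
#' match of `pure` onto `mix` over `nir_window` x `t_range`.
#'
#' @param mix,pure [ta_map()]s on shared axes.
#' @param nir_window SE-dominated wavelength window (nm). Default c(900, 1400).
#' @param t_range Delay range (ps). Default c(0.6, 5): after the fast species
#'   has decayed.
#' @return A `scale_estimate`.
#' @export
estimate_factor_from_se <- function(mix, pure, nir_window = c(900, 1400),
                                    t_range = c(0.6, 5)) {
  check_shared_axes(mix, pure)
  sel <- spectral_mask(mix$wavelength, list(nir_window))
  if (!any(sel)) stop("NIR window selects no wavelengths")
  tidx <- mix$delay >= t_range[1] & mix$delay <= t_range[2]
  if (!any(tidx)) stop("t_range selects no delays")
  xm <- mix$dod[tidx, sel, drop = FALSE]
  xp <- pure$dod[tidx, sel, drop = FALSE]
  denom <- sum(xp^2)
  if (denom <= .Machine$double.eps * length(xp))
    stop("factor unidentifiable: pure SE signal is identically zero in the window")
  c_hat <- sum(xm * xp) / denom
  resid <- xm - c_hat * xp
  dof <- max(length(xp) - 1L, 1L)
  stderr <- sqrt(sum(resid^2) / dof / denom)
  new_scale_estimate(c_hat, stderr, residual_norm = sqrt(sum(resid^2)),
                     method = "nir_se", t_range = t_range,
                     window = list(nir_window), n_obs = length(xp))
}

#' Scale factor matching time-averaged late spectra
#'
#' Averages each map's spectra over delays >= `t_min` and returns the scalar
#' factor scaling `map_b`'s late spectrum onto `map_a`'s. Used to compare a
#' two-pump experiment with its single-pump counterpart once all transient
#' signal has settled.
#'
#' @param map_a,map_b [ta_map()]s on a shared wavelength axis.
#' @param t_min Earliest delay averaged (ps). Default 50.
#' @return A `scale_estimate` (factor applied to `map_b`).
#' @export
late_spectrum_match <- function(map_a, map_b, t_min = 50) {
  if (!isTRUE(all.equal(map_a$wavelength, map_b$wavelength)))
    stop("maps must share the wavelength axis")
  avg <- function(m) {
    idx <- m$delay >= t_min
    if (!any(idx)) stop("no delays at t >= t_min")
    colMeans(m$dod[idx, , drop = FALSE])
  }
  sa <- avg(map_a); sb <- avg(map_b)
  denom <- sum(sb^2)
  if (denom <= .Machine$double.eps * length(sb))
    stop("factor unidentifiable: late spectrum of map_b is zero")
  c_hat <- sum(sa * sb) / denom
  resid <- sa - c_hat * sb
  dof <- max(length(sb) - 1L, 1L)
  new_scale_estimate(c_hat, sqrt(sum(resid^2) / dof / denom),
                     residual_norm = sqrt(sum(resid^2)),
                     method = "late_spectrum",
                     t_range = c(t_min, max(map_a$delay)),
                     window = list(range(map_a$wavelength)),
                     n_obs = length(sb))
}

#' Isomer composition of a dark-adapted sample
#'
#' @param x_13c,x_at Fractions of the 13-cis and all-trans isomers; must sum
#'   to 1. Defaults 0.35 / 0.65, the dark composition inferred from the
#'   dynamic-difference analysis.
#' @return An `isomer_composition` list.
#' @export
isomer_composition <- function(x_13c = 0.35, x_at = 0.65) {
  if (x_13c < 0 || x_13c > 1 || x_at < 0 || x_at > 1)
    stop("fractions must be in [0, 1]")
  if (abs(x_13c + x_at - 1) > 1e-8) stop("fractions must sum to 1")
  structure(list(x_13c = x_13c, x_at = x_at), class = "isomer_composition")
}

#' Decompose a dark-adapted absorption spectrum
#'
#' With the light-adapted sample pure all-trans, the 13-cis absorption is
#' \deqn{A_{13C}(\lambda) = (A_{DA}(\lambda) - x_{AT} A_{LA}(\lambda)) / x_{13C}.}
#' The peak wavelength is located by 3-point parabolic interpolation (ties
#' broken toward the longer wavelength). Negative dips are kept (clipping
#' would bias the peak) but trigger a warning.
#'
#' @param a_da Dark-adapted absorption [ta_spectrum()].
#' @param a_la Light-adapted (pure all-trans) absorption [ta_spectrum()].
#' @param comp An [isomer_composition()].
#' @return List with `spectrum` (the 13-cis absorption) and `lambda_max` (nm).
#' @export
decompose_absorption <- function(a_da, a_la, comp = isomer_composition()) {
  stopifnot(inherits(a_da, "ta_spectrum"), inherits(a_la, "ta_spectrum"),
            inherits(comp, "isomer_composition"))
  if (!isTRUE(all.equal(a_da$wavelength, a_la$wavelength)))
    stop("spectra must share the wavelength axis")
  if (comp$x_13c == 0) stop("x_13c = 0: 13-cis spectrum unidentifiable")
  od <- (a_da$od - comp$x_at * a_la$od) / comp$x_13c
  if (any(od < 0))
    warning("decomposed 13-cis spectrum has negative dips (reported unclipped)")
  spec <- ta_spectrum(a_da$wavelength, od)
  list(spectrum = spec, lambda_max = peak_wavelength(spec))
}

#' Peak position by 3-point parabolic interpolation
#'
#' Locates the maximum of a sampled spectrum by fitting a parabola through
#' the largest sample and its two neighbours. Ties between equal maxima break
#' toward the longer wavelength; edge maxima return the grid point.
#'
#' @param spec A [ta_spectrum()].
#' @return Interpolated peak wavelength (nm).
#' @export
peak_wavelength <- function(spec) {
  x <- spec$wavelength; y <- spec$od
  m <- max(which(y == max(y)))
  if (m == 1L || m == length(y)) return(x[m])
  x3 <- x[(m - 1):(m + 1)]; y3 <- y[(m - 1):(m + 1)]
  # quadratic through three (possibly nonuniform) points
  co <- solve(cbind(1, x3, x3^2), y3)
  if (co[3] >= 0) return(x[m])  # degenerate: not a maximum
  -co[2] / (2 * co[3])
}
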