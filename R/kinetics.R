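# Trace-level analysis: band-averaged trace extraction, multiexponential
# fitting by variable projection (amplitudes solved linearly at each tau
# step, multistart over log-spaced tau grids), oscillation-residual
# isolation, damped-cosine fitting, power spectra, anisotropy.

TAU_BOUNDS <- c(0.01, 1000)  # ps

#' Extract a band-averaged kinetic trace from a TA map
#'
#' Unweighted mean over all wavelengths within `center +/- bandwidth/2`. A
#' window narrower than the grid spacing falls back to the nearest single
#' pixel with a warning.
#'
#' @param map A [ta_map()].
#' @param center Probe window centre (nm).
#' @param bandwidth Window full width (nm).
#' @return A [ta_trace()] carrying the window metadata.
#' @export
extract_trace <- function(map, center, bandwidth) {
  stopifnot(inherits(map, "ta_map"), bandwidth >= 0)
  wl <- map$wavelength
  sel <- which(wl >= center - bandwidth / 2 & wl <= center + bandwidth / 2)
  if (length(sel) == 0) {
    if (center < min(wl) || center > max(wl))
      stop("probe window does not intersect the wavelength axis")
    sel <- which.min(abs(wl - center))
    warning(sprintf(
      "bandwidth %.3g nm is below the grid spacing; using nearest pixel %.1f nm",
      bandwidth, wl[sel]))
  }
  ta_trace(map$delay, rowMeans(map$dod[, sel, drop = FALSE]),
           center = center, bandwidth = bandwidth)
}

multiexp_design <- function(t, tau, with_offset) {
  X <- exp(-outer(t, 1 / tau))
  if (with_offset) X <- cbind(X, 1)
  X
}

# linear amplitudes + rss for fixed taus (the projected objective)
multiexp_project <- function(t, y, tau, with_offset) {
  X <- multiexp_design(t, tau, with_offset)
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  list(coefs = coefs, rss = sum(fit$residuals^2))
}

#' Multiexponential fit by variable projection
#'
#' Fits `offset + sum_i A_i exp(-t / tau_i)` to a trace for `t >= t_start`.
#' At each step of the nonlinear search over log-lifetimes the amplitudes
#' (and offset) are solved exactly by linear least squares, which removes
#' them from the search space; the tau search is multistarted from 8
#' log-spaced grids spanning 0.05--200 ps because nonuniform linear+log delay
#' axes create local minima. Lifetimes are reported sorted ascending.
#'
#' @param trace A [ta_trace()].
#' @param n Number of exponentials, >= 1.
#' @param t_start Earliest delay fitted (ps). Default 0.08, excluding the
#'   coherent-artifact window.
#' @param with_offset Include a constant offset (the long-lived photoproduct
#'   plateau). Default TRUE.
#' @param tau_bounds Lifetime search bounds (ps). Tightening the lower bound
#'   (e.g. to exceed a coherence period) prevents the fit from absorbing
#'   oscillatory signal into ultrafast exponentials.
#' @return A `kinetic_fit`: `amplitudes`, `taus` (ascending), `offset`,
#'   `t_start`, `rss`, `stderr` (per parameter), `n_points`.
#' @export
fit_multiexp <- function(trace, n, t_start = 0.08, with_offset = TRUE,
                         tau_bounds = TAU_BOUNDS) {
  stopifnot(inherits(trace, "ta_trace"), n >= 1,
            length(tau_bounds) == 2, tau_bounds[1] > 0,
            tau_bounds[1] < tau_bounds[2])
  keep <- trace$delay >= t_start
  t <- trace$delay[keep]; y <- trace$dod[keep]
  if (length(t) < 3 * n + 2)
    stop(sprintf("need at least %d points at t >= t_start, have %d",
                 3 * n + 2, length(t)))
  obj <- function(logtau) multiexp_project(t, y, exp(logtau), with_offset)$rss

  centers <- exp(seq(log(max(0.05, tau_bounds[1] * 1.5)),
                     log(min(200, tau_bounds[2] / 1.5)), length.out = 8))
  spread <- 6
  best <- NULL
  for (ctr in centers) {
    tau0 <- pmin(pmax(ctr * spread^(seq_len(n) - (n + 1) / 2),
                      tau_bounds[1] * 1.5), tau_bounds[2] / 1.5)
    res <- tryCatch(
      stats::optim(log(tau0), obj, method = "L-BFGS-B",
                   lower = log(tau_bounds[1]), upper = log(tau_bounds[2]),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    stop("multiexponential fit failed to converge from every start")
  # derivative-free polish of the projected objective
  polish <- if (n == 1)
    stats::optim(best$par, obj, method = "Brent",
                 lower = log(tau_bounds[1]), upper = log(tau_bounds[2]))
  else
    stats::optim(best$par, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 5000))
  if (polish$value <= best$value &&
      all(polish$par >= log(tau_bounds[1]) & polish$par <= log(tau_bounds[2])))
    best <- polish

  tau <- exp(best$par)
  if (any(tau < tau_bounds[1] * 1.01 | tau > tau_bounds[2] * 0.99))
    warning(sprintf("a fitted lifetime sits at the search bound [%g, %g] ps",
                    tau_bounds[1], tau_bounds[2]))
  proj <- multiexp_project(t, y, tau, with_offset)
  ord <- order(tau)
  tau <- tau[ord]
  amps <- proj$coefs[seq_len(n)][ord]
  offset <- if (with_offset) proj$coefs[n + 1L] else 0

  se <- multiexp_stderr(t, y, amps, tau, offset, with_offset, proj$rss)
  structure(list(amplitudes = amps, taus = tau, offset = offset,
                 t_start = t_start, rss = proj$rss, stderr = se,
                 with_offset = with_offset, n_points = length(t)),
            class = "kinetic_fit")
}

# asymptotic stderr from the full nonlinear Jacobian at the optimum
multiexp_stderr <- function(t, y, amps, tau, offset, with_offset, rss) {
  n <- length(tau)
  J <- cbind(exp(-outer(t, 1 / tau)),
             sweep(exp(-outer(t, 1 / tau)) * outer(t, 1 / tau^2), 2, amps, `*`))
  if (with_offset) J <- cbind(J, 1)
  p <- ncol(J)
  dof <- length(t) - p
  empty <- list(amplitudes = rep(NA_real_, n), taus = rep(NA_real_, n),
                offset = NA_real_)
  if (dof <= 0) return(empty)
  cv <- tryCatch(rss / dof * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cv)) return(empty)
  se <- sqrt(pmax(diag(cv), 0))
  list(amplitudes = se[seq_len(n)], taus = se[n + seq_len(n)],
       offset = if (with_offset) se[2 * n + 1L] else NA_real_)
}

#' Evaluate a multiexponential model
#'
#' @param fit A `kinetic_fit`.
#' @param t Delays (ps).
#' @return Model values `offset + sum_i A_i exp(-t / tau_i)`.
#' @export
predict_multiexp <- function(fit, t) {
  stopifnot(inherits(fit, "kinetic_fit"))
  drop(exp(-outer(t, 1 / fit$taus)) %*% fit$amplitudes) + fit$offset
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %d exponentials on %d points (t >= %.3g ps)\n",
              length(x$taus), x$n_points, x$t_start))
  for (i in seq_along(x$taus))
    cat(sprintf("  tau %d = %.4g ps, amplitude %.4g\n", i, x$taus[i],
                x$amplitudes[i]))
  cat(sprintf("  offset %.4g, rss %.4g\n", x$offset, x$rss))
  invisible(x)
}

#' Isolate the coherent-oscillation residual of a trace
#'
#' Subtracts the multiexponential model from the trace, restricted to
#' `t >= max(t_start, 0.08)` ps -- the earliest delays contain coherent
#' pump-probe artifacts and are excluded.
#'
#' @param trace The fitted [ta_trace()].
#' @param fit The [fit_multiexp()] result computed on this trace.
#' @return A residual [ta_trace()].
#' @export
isolate_oscillations <- function(trace, fit) {
  stopifnot(inherits(trace, "ta_trace"), inherits(fit, "kinetic_fit"))
  t0 <- max(fit$t_start, 0.08)
  keep <- trace$delay >= t0
  if (!any(keep)) stop("no post-artifact window: all delays are below 0.08 ps")
  ta_trace(trace$delay[keep],
           trace$dod[keep] - predict_multiexp(fit, trace$delay[keep]),
           center = trace$center, bandwidth = trace$bandwidth)
}

#' Power spectrum of an oscillatory residual
#'
#' The (generally nonuniform) trace is linearly resampled to a uniform grid
#' at the minimum native spacing, mean-subtracted and Fourier transformed.
#' Frequencies convert to wavenumber via `nu_tilde = f / c` with c in cm/ps,
#' so a period T ps corresponds to `1 / (c T)` cm^-1.
#'
#' @param residual A [ta_trace()], typically from [isolate_oscillations()].
#' @return Data frame with `wavenumber` (cm^-1) and `power` columns
#'   (one-sided, DC included).
#' @export
power_spectrum <- function(residual) {
  stopifnot(inherits(residual, "ta_trace"))
  t <- residual$delay
  dt <- min(diff(t))
  tu <- seq(t[1], t[length(t)], by = dt)
  yu <- stats::approx(t, residual$dod, tu)$y
  yu <- yu - mean(yu)
  m <- length(yu)
  pw <- Mod(stats::fft(yu))^2 / m
  kmax <- floor(m / 2)
  freq <- (0:kmax) / (m * dt)            # 1/ps
  data.frame(wavenumber = freq / C_CM_PER_PS, power = pw[1:(kmax + 1L)])
}

osc_design <- function(t, wavenumber, damping) {
  cols <- lapply(seq_along(wavenumber), function(j) {
    om <- 2 * pi * C_CM_PER_PS * wavenumber[j]
    env <- exp(-t / damping[j])
    cbind(env * cos(om * t), env * sin(om * t))
  })
  do.call(cbind, cols)
}

# local maxima of a power spectrum, strongest first, DC excluded
spectrum_peaks <- function(ps) {
  p <- ps$power
  n <- length(p)
  if (n < 3) return(numeric(0))
  loc <- which(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n]) + 1L
  loc <- loc[ps$wavenumber[loc] > 0]
  ps$wavenumber[loc[order(p[loc], decreasing = TRUE)]]
}

#' Fit damped cosines to an oscillatory residual
#'
#' Model: `sum_j a_j exp(-t/d_j) cos(2 pi c nu_j t + phi_j)`. Amplitude and
#' phase enter linearly (cosine/sine quadrature pair per mode) and are
#' projected out; frequencies and damping times are optimized by multistart
#' L-BFGS-B seeded from the power-spectrum peaks.
#'
#' @param residual A [ta_trace()] from [isolate_oscillations()].
#' @param n_components Number of damped cosines.
#' @return An `osc_fit`: data frame `components` (wavenumber cm^-1 ascending,
#'   damping_tau ps, phase rad, amplitude OD) plus `rss`.
#' @export
fit_oscillations <- function(residual, n_components = 1) {
  stopifnot(inherits(residual, "ta_trace"), n_components >= 1)
  t <- residual$delay; y <- residual$dod
  if (sqrt(mean(y^2)) == 0)
    return(structure(list(components = data.frame(
      wavenumber = numeric(0), damping_tau = numeric(0),
      phase = numeric(0), amplitude = numeric(0)), rss = 0),
      class = "osc_fit"))
  ps <- power_spectrum(residual)
  nyquist <- max(ps$wavenumber)
  peaks <- spectrum_peaks(ps)
  if (length(peaks) < n_components) {
    warning(sprintf("requested %d components but only %d spectral peaks found",
                    n_components, length(peaks)))
    extra <- nyquist * seq_len(n_components - length(peaks)) /
      (n_components - length(peaks) + 1)
    peaks <- c(peaks, extra)
  }
  nu0 <- peaks[seq_len(n_components)]

  obj <- function(par) {
    nu <- exp(par[seq_len(n_components)])
    dp <- exp(par[n_components + seq_len(n_components)])
    X <- osc_design(t, nu, dp)
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  lower <- c(rep(log(1), n_components), rep(log(0.01), n_components))
  upper <- c(rep(log(nyquist), n_components), rep(log(100), n_components))
  best <- NULL
  for (d0 in c(0.2, 0.5, 2)) {
    par0 <- c(log(pmin(pmax(nu0, 1.1), nyquist * 0.99)),
              rep(log(d0), n_components))
    res <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best)) stop("damped-cosine fit failed to converge")
  nu <- exp(best$par[seq_len(n_components)])
  dp <- exp(best$par[n_components + seq_len(n_components)])
  X <- osc_design(t, nu, dp)
  lf <- stats::lm.fit(X, y)
  ab <- lf$coefficients
  ab[is.na(ab)] <- 0
  alpha <- ab[2 * seq_len(n_components) - 1L]
  beta <- ab[2 * seq_len(n_components)]
  comp <- data.frame(wavenumber = nu, damping_tau = dp,
                     phase = atan2(-beta, alpha),
                     amplitude = sqrt(alpha^2 + beta^2))
  comp <- comp[order(comp$wavenumber), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(components = comp, rss = sum(lf$residuals^2)),
            class = "osc_fit")
}

#' @export
print.osc_fit <- function(x, ...) {
  cat(sprintf("<osc_fit> %d damped cosine(s), rss %.4g\n",
              nrow(x$components), x$rss))
  if (nrow(x$components))
    print(format(x$components, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Pump-probe anisotropy
#'
#' Pointwise `r(t) = (par - perp) / (par + 2 perp)` together with the
#' magic-angle (isotropic) signal `(par + 2 perp) / 3`. Points where the
#' denominator is within `noise_floor` of zero are masked to NA instead of
#' propagating unstable ratios.
#'
#' @param par,perp [ta_trace()]s with parallel / perpendicular pump-probe
#'   polarization, on a shared delay axis.
#' @param noise_floor Denominator magnitude (OD) below which points are
#'   masked. Default 0 (mask only exact zeros).
#' @return List with `delay`, `r` (NA at masked points), `magic_angle`
#'   (a [ta_trace()]), and logical `masked`.
#' @export
anisotropy <- function(par, perp, noise_floor = 0) {
  stopifnot(inherits(par, "ta_trace"), inherits(perp, "ta_trace"))
  if (!isTRUE(all.equal(par$delay, perp$delay)))
    stop("traces must share the delay axis")
  denom <- par$dod + 2 * perp$dod
  masked <- abs(denom) <= noise_floor
  r <- (par$dod - perp$dod) / denom
  r[masked] <- NA_real_
  list(delay = par$delay, r = r,
       magic_angle = ta_trace(par$delay, denom / 3, par$center, par$bandwidth),
       masked = masked)
}
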