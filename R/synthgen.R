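# Forward generator: steady-state spectra and TA maps with the structural
# features the decomposition estimators assume (separable species signals,
# multiexponential survival, ballistic band shifts, windowed coherent
# oscillations, iid Gaussian noise).

gauss_profile <- function(wavelength, center, width) {
  exp(-(wavelength - center)^2 / (2 * width^2))
}

#' Sum-of-Gaussians absorption spectrum
#'
#' @param bands A [band()] or non-empty list of bands.
#' @param wavelength Spectral axis (nm).
#' @return A [ta_spectrum()] with value
#'   \eqn{\sum_k a_k \exp(-(\lambda - c_k)^2 / 2 w_k^2)}.
#' @export
gen_absorption <- function(bands, wavelength) {
  wavelength <- spectral_axis(wavelength)
  if (inherits(bands, "band")) bands <- list(bands)
  if (length(bands) == 0) stop("at least one band is required")
  od <- rep(0, length(wavelength))
  for (b in bands)
    od <- od + b$amplitude * gauss_profile(wavelength, b$center, b$width)
  ta_spectrum(wavelength, od)
}

# Excited-state survival P(t) = sum_i A_i exp(-t / tau_i)
survival_fraction <- function(kinetics, t) {
  if (abs(sum(kinetics$amplitude) - 1) > 1e-8)
    stop("kinetics amplitudes must sum to 1")
  drop(exp(-outer(t, 1 / kinetics$tau)) %*% kinetics$amplitude)
}

# n_delay x n_wl matrix of summed band profiles; shift (if given) relaxes
# every band centre as center_end + (center_start - center_end) exp(-t/tau)
band_matrix <- function(bands, shift, wavelength, delay) {
  out <- matrix(0, length(delay), length(wavelength))
  for (b in bands) {
    if (is.null(shift)) {
      out <- out + rep(1, length(delay)) %o%
        (b$amplitude * gauss_profile(wavelength, b$center, b$width))
    } else {
      centers <- shift$center_end +
        (shift$center_start - shift$center_end) * exp(-delay / shift$tau_shift)
      for (i in seq_along(delay))
        out[i, ] <- out[i, ] +
          b$amplitude * gauss_profile(wavelength, centers[i], b$width)
    }
  }
  out
}

# multiplicative oscillation term osc(lambda, t); zero when list is empty
oscillation_matrix <- function(oscillations, wavelength, delay) {
  out <- matrix(0, length(delay), length(wavelength))
  for (o in oscillations) {
    omega <- 2 * pi * C_CM_PER_PS * o$wavenumber
    temporal <- o$rel_amplitude * exp(-delay / o$damping_tau) *
      cos(omega * delay + o$phase)
    spatial <- gauss_profile(wavelength, o$window_center, o$window_width)
    out <- out + temporal %o% spatial
  }
  out
}

#' Generate one species' noiseless TA map
#'
#' Realizes the signal model
#' \deqn{\Delta OD(\lambda,t) = P(t)[\sigma_{ESA}(\lambda,t) -
#'   \sigma_{SE}(\lambda,t)](1 + osc(\lambda,t)) - P(t)\sigma_{GS}(\lambda) +
#'   \phi(1 - P(t))[\sigma_{prod}(\lambda) - \sigma_{GS}(\lambda)]}
#' so that at long delays the map converges to the product-minus-bleach
#' difference spectrum scaled by the quantum yield.
#'
#' @param spec A [species_spec()].
#' @param wavelength,delay Axes (nm / ps).
#' @param oscillations Set `FALSE` to suppress coherent modulation.
#' @return A [ta_map()].
#' @export
gen_species_map <- function(spec, wavelength, delay, oscillations = TRUE) {
  stopifnot(inherits(spec, "species_spec"))
  wavelength <- spectral_axis(wavelength)
  delay <- delay_axis(delay)
  p <- survival_fraction(spec$kinetics, delay)
  esa <- band_matrix(spec$esa_bands, spec$esa_shift, wavelength, delay)
  se <- band_matrix(spec$se_bands, spec$se_shift, wavelength, delay)
  gs <- gen_absorption(spec$gsb_band, wavelength)$od
  prod <- spec$product_band$amplitude *
    gauss_profile(wavelength, spec$product_band$center, spec$product_band$width)
  osc <- if (isTRUE(oscillations))
    oscillation_matrix(spec$oscillations, wavelength, delay)
  else matrix(0, length(delay), length(wavelength))
  dod <- p * (esa - se) * (1 + osc) - p %o% gs +
    (spec$phi_iso * (1 - p)) %o% (prod - gs)
  ta_map(wavelength, delay, dod)
}

# evaluate code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a noisy multi-species mixture map
#'
#' Weighted sum of per-species maps plus iid Gaussian pixel noise. The same
#' `mixture_spec` (including seed) always yields an identical map.
#'
#' @param spec A [mixture_spec()].
#' @param wavelength,delay Shared axes.
#' @param oscillations Passed through to [gen_species_map()].
#' @return A [ta_map()].
#' @export
gen_mixture <- function(spec, wavelength, delay, oscillations = TRUE) {
  stopifnot(inherits(spec, "mixture_spec"))
  wavelength <- spectral_axis(wavelength)
  delay <- delay_axis(delay)
  dod <- matrix(0, length(delay), length(wavelength))
  for (i in seq_along(spec$species))
    dod <- dod + spec$weights[i] *
      gen_species_map(spec$species[[i]], wavelength, delay, oscillations)$dod
  if (spec$noise_sigma > 0)
    dod <- dod + with_seed(spec$seed,
      matrix(stats::rnorm(length(dod), sd = spec$noise_sigma),
             nrow(dod), ncol(dod)))
  ta_map(wavelength, delay, dod)
}

#' Generate a two-pump (actinic + probe-pump) mixture map
#'
#' Emulates re-exciting, 60 ps after an actinic pulse, the relaxed mixture of
#' unreacted all-trans and K photoproduct: the observed map is
#' `f_at * AT + (1 - f_at) * K` plus noise.
#'
#' @param at_spec,k_spec [species_spec()]s for the two co-resident species.
#' @param f_at Fraction of the excited population that is all-trans, in \[0, 1\].
#' @param wavelength,delay Axes.
#' @param noise_sigma Gaussian pixel noise sigma (OD).
#' @param seed RNG seed for the noise.
#' @return A [ta_map()].
#' @export
gen_double_pump <- function(at_spec, k_spec, f_at, wavelength, delay,
                            noise_sigma = 0, seed = 1L) {
  if (!is.finite(f_at) || f_at < 0 || f_at > 1)
    stop("f_at must be in [0, 1]")
  gen_mixture(mixture_spec(list(at_spec, k_spec), c(f_at, 1 - f_at),
                           noise_sigma = noise_sigma, seed = seed),
              wavelength, delay)
}

# ---- JSON configuration -----------------------------------------------------

band_from_list <- function(x) band(x$center, x$width, x$amplitude)

species_from_list <- function(x) {
  mk_shift <- function(s) if (is.null(s)) NULL
    else shift_model(s$center_start, s$center_end, s$tau_shift)
  oscs <- lapply(x$oscillations, function(o)
    osc_component(o$wavenumber, o$damping_tau, o$phase, o$rel_amplitude,
                  o$window_center, o$window_width))
  species_spec(
    esa_bands = lapply(x$esa_bands, band_from_list),
    se_bands = lapply(x$se_bands, band_from_list),
    gsb_band = band_from_list(x$gsb_band),
    product_band = band_from_list(x$product_band),
    kinetics = data.frame(
      amplitude = vapply(x$kinetics, `[[`, 0, "amplitude"),
      tau = vapply(x$kinetics, `[[`, 0, "tau")),
    phi_iso = x$phi_iso,
    esa_shift = mk_shift(x$esa_shift), se_shift = mk_shift(x$se_shift),
    oscillations = oscs)
}

#' Read a mixture description from a JSON configuration
#'
#' The document mirrors [mixture_spec()]: fields `species` (list of species
#' objects with `esa_bands`, `se_bands`, `gsb_band`, `product_band`,
#' `kinetics`, `phi_iso`, optional `esa_shift`/`se_shift`/`oscillations`),
#' `weights`, `noise_sigma` and `seed`.
#'
#' @param path Path to a JSON file.
#' @return A [mixture_spec()].
#' @export
read_mixture_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  mixture_spec(lapply(cfg$species, species_from_list),
               weights = vapply(cfg$weights, as.numeric, 0),
               noise_sigma = if (is.null(cfg$noise_sigma)) 0 else cfg$noise_sigma,
               seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}
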