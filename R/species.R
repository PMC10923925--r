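#' Gaussian spectral band
#'
#' Parameterizes one ESA, SE, GSB or photoproduct band as a Gaussian in
#' wavelength.
#'
#' @param center Band centre (nm).
#' @param width Gaussian sigma (nm), > 0.
#' @param amplitude Peak cross-section on the OD scale, >= 0.
#' @return A `band` list.
#' @export
band <- function(center, width, amplitude) {
  if (!is.finite(width) || width <= 0) stop("band width must be > 0")
  if (!is.finite(amplitude) || amplitude < 0) stop("band amplitude must be >= 0")
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "band")
}

#' Ballistic band-shift model
#'
#' Continuous exponential relaxation of a band centre, emulating the blue/red
#' shifting of ESA/SE during ballistic excited-state motion:
#' `center(t) = center_end + (center_start - center_end) * exp(-t / tau_shift)`.
#'
#' @param center_start Centre at t = 0 (nm).
#' @param center_end Asymptotic centre (nm).
#' @param tau_shift Shift time constant (ps), > 0.
#' @return A `shift_model` list.
#' @export
shift_model <- function(center_start, center_end, tau_shift) {
  if (!is.finite(tau_shift) || tau_shift <= 0) stop("tau_shift must be > 0")
  structure(list(center_start = center_start, center_end = center_end,
                 tau_shift = tau_shift), class = "shift_model")
}

#' Damped coherent-oscillation component
#'
#' A low-frequency vibrational coherence that modulates the excited-state
#' signal multiplicatively, confined to a Gaussian spectral window (the
#' experimental modulation sits near 520 nm).
#'
#' @param wavenumber Mode frequency (cm^-1), > 0.
#' @param damping_tau Coherence damping time (ps).
#' @param phase Phase at t = 0 (rad).
#' @param rel_amplitude Peak fractional modulation depth, in \[0, 0.5\].
#' @param window_center,window_width Gaussian spectral window centre and sigma (nm).
#' @return An `osc_component` list.
#' @export
osc_component <- function(wavenumber, damping_tau = 0.5, phase = 0,
                          rel_amplitude = 0.2, window_center = 520,
                          window_width = 15) {
  if (!is.finite(wavenumber) || wavenumber <= 0) stop("wavenumber must be > 0")
  if (rel_amplitude < 0 || rel_amplitude > 0.5)
    stop("rel_amplitude must be in [0, 0.5]")
  structure(list(wavenumber = wavenumber, damping_tau = damping_tau,
                 phase = phase, rel_amplitude = rel_amplitude,
                 window_center = window_center, window_width = window_width),
            class = "osc_component")
}

#' Generative description of one species' TA signature
#'
#' Collects the spectral bands (ESA, SE, GSB, photoproduct), the
#' excited-state survival kinetics, the isomerization quantum yield and any
#' coherent oscillations of a single photoactive species. The generated
#' signal is
#' \deqn{\Delta OD(\lambda,t) = P(t)[\sigma_{ESA} - \sigma_{SE}](1 + osc)
#'   - P(t)\sigma_{GS} + \phi (1 - P(t))[\sigma_{prod} - \sigma_{GS}]}
#' with survival \eqn{P(t) = \sum_i A_i e^{-t/\tau_i}}.
#'
#' @param esa_bands,se_bands Lists of [band()]s (may be empty lists).
#' @param gsb_band Ground-state bleach [band()], amplitude > 0.
#' @param product_band Photoproduct absorption [band()].
#' @param kinetics Data frame with columns `amplitude` (fractions summing to 1)
#'   and `tau` (ps, > 0).
#' @param phi_iso Isomerization quantum yield in \[0, 1\].
#' @param esa_shift,se_shift Optional [shift_model()]s applied to every
#'   ESA/SE band centre.
#' @param oscillations List of [osc_component()]s.
#' @return A `species_spec` list.
#' @export
species_spec <- function(esa_bands, se_bands, gsb_band, product_band,
                         kinetics, phi_iso, esa_shift = NULL, se_shift = NULL,
                         oscillations = list()) {
  if (inherits(esa_bands, "band")) esa_bands <- list(esa_bands)
  if (inherits(se_bands, "band")) se_bands <- list(se_bands)
  stopifnot(inherits(gsb_band, "band"), inherits(product_band, "band"))
  if (gsb_band$amplitude <= 0) stop("gsb_band amplitude must be > 0")
  kinetics <- as.data.frame(kinetics)
  if (!all(c("amplitude", "tau") %in% names(kinetics)))
    stop("kinetics needs columns 'amplitude' and 'tau'")
  if (any(kinetics$tau <= 0) || any(kinetics$amplitude < 0))
    stop("kinetic components need tau > 0 and amplitude >= 0")
  if (abs(sum(kinetics$amplitude) - 1) > 1e-8)
    stop("kinetics amplitudes must sum to 1")
  if (!is.finite(phi_iso) || phi_iso < 0 || phi_iso > 1)
    stop("phi_iso must be in [0, 1]")
  if (inherits(oscillations, "osc_component")) oscillations <- list(oscillations)
  structure(list(esa_bands = esa_bands, se_bands = se_bands,
                 gsb_band = gsb_band, product_band = product_band,
                 kinetics = kinetics, phi_iso = phi_iso,
                 esa_shift = esa_shift, se_shift = se_shift,
                 oscillations = oscillations),
            class = "species_spec")
}

#' Mixture description for synthetic dark-adapted-like samples
#'
#' Weights are excited-population fractions; with isosbestic-point pumping
#' (equal excitation probability for co-resident isomers) they track the
#' ground-state composition.
#'
#' @param species List of [species_spec()]s.
#' @param weights Non-negative fractions summing to 1, one per species.
#' @param noise_sigma iid Gaussian noise sigma per pixel (OD), >= 0.
#' @param seed Integer RNG seed; identical specs generate identical maps.
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(species, weights, noise_sigma = 0, seed = 1L) {
  if (inherits(species, "species_spec")) species <- list(species)
  if (length(weights) != length(species))
    stop("weights and species lists differ in length")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be >= 0 and sum to 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(species = species, weights = as.numeric(weights),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "mixture_spec")
}

# ---- reference species ------------------------------------------------------
# Band positions follow the experimental picture: AT resting state absorbs at
# 570 nm with ESA near 480 nm and NIR SE near 900 nm; 13C absorbs at 543 nm,
# decays in ~150 fs with ballistically shifting ESA/SE; K absorbs at 590 nm
# and its excited state decays biexponentially (1.7 / 11 ps, equal weight).

#' Reference all-trans (light-adapted) species
#'
#' Single-exponential 0.5 ps excited-state decay, quantum yield 0.65 for
#' forming the red-shifted K photoproduct, and one 180 cm^-1 coherent mode
#' windowed at 520 nm.
#'
#' @param phi Isomerization quantum yield. Default 0.65.
#' @param osc_amplitude Fractional depth of the coherent modulation; 0 disables.
#' @return A [species_spec()].
#' @export
species_at <- function(phi = 0.65, osc_amplitude = 0.3) {
  osc <- if (osc_amplitude > 0)
    list(osc_component(180, damping_tau = 0.5, phase = 0,
                       rel_amplitude = osc_amplitude,
                       window_center = 520, window_width = 15))
  else list()
  species_spec(
    esa_bands = band(480, 25, 0.008),
    se_bands = band(900, 60, 0.006),
    gsb_band = band(570, 40, 0.010),
    product_band = band(590, 45, 0.009),
    kinetics = data.frame(amplitude = 1, tau = 0.5),
    phi_iso = phi,
    oscillations = osc)
}

#' Reference 13-cis (dark-adapted component) species
#'
#' Ultrafast 0.15 ps decay so the excited-state signal is numerically extinct
#' by ~0.6 ps, with blue-shifting ESA (480 to 450 nm) and red-shifting SE
#' (900 to 1000 nm). The photoproduct is the all-trans chromophore at 570 nm
#' whose amplitude is calibrated so the wavenumber-domain band integral is
#' `dipole_ratio` times the bleach band's over `qy_window`.
#'
#' @param phi Isomerization quantum yield. Default 0.55.
#' @param dipole_ratio Product-to-reactant dipole strength ratio. Default 1.15.
#' @param qy_window Wavelength window (nm) over which the dipole ratio is
#'   defined. Default c(480, 650).
#' @return A [species_spec()].
#' @export
species_13c <- function(phi = 0.55, dipole_ratio = 1.15,
                        qy_window = c(480, 650)) {
  gsb <- band(543, 40, 0.010)
  prod_amp <- calibrate_product_amplitude(gsb, product_center = 570,
                                          product_width = 40,
                                          ratio = dipole_ratio,
                                          window = qy_window)
  species_spec(
    esa_bands = band(480, 25, 0.008),
    se_bands = band(900, 60, 0.006),
    gsb_band = gsb,
    product_band = band(570, 40, prod_amp),
    kinetics = data.frame(amplitude = 1, tau = 0.15),
    phi_iso = phi,
    esa_shift = shift_model(480, 450, 0.1),
    se_shift = shift_model(900, 1000, 0.1))
}

#' Reference K-intermediate species
#'
#' Red-shifted bleach at 590 nm and slow biexponential excited-state decay
#' with equal-amplitude 1.7 and 11 ps components. No coherent modulation, so
#' in two-pump mixtures the oscillation marker reports the all-trans fraction
#' alone.
#'
#' @param phi Quantum yield for the K photoreaction. Default 0.4.
#' @return A [species_spec()].
#' @export
species_k <- function(phi = 0.4) {
  species_spec(
    esa_bands = band(480, 30, 0.008),
    se_bands = band(870, 60, 0.006),
    gsb_band = band(590, 45, 0.010),
    product_band = band(570, 40, 0.009),
    kinetics = data.frame(amplitude = c(0.5, 0.5), tau = c(1.7, 11)),
    phi_iso = phi)
}

#' Calibrate a product band amplitude to a target dipole-strength ratio
#'
#' Returns the amplitude making the wavenumber-domain band integral of a
#' Gaussian product band equal `ratio` times the integral of `gsb` over
#' `window`, evaluated on a dense 0.1 nm grid.
#'
#' @param gsb Reference bleach [band()].
#' @param product_center,product_width Product band centre and sigma (nm).
#' @param ratio Target integral ratio (> 0).
#' @param window Length-2 wavelength window (nm).
#' @return Amplitude (OD scale).
#' @export
calibrate_product_amplitude <- function(gsb, product_center, product_width,
                                        ratio, window = c(480, 650)) {
  stopifnot(ratio > 0, length(window) == 2, window[1] < window[2])
  grid <- seq(window[1], window[2], by = 0.1)
  nu <- 1e7 / grid
  gauss <- function(center, width) exp(-(grid - center)^2 / (2 * width^2))
  i_gsb <- abs(pracma::trapz(rev(nu), rev(gsb$amplitude * gauss(gsb$center, gsb$width))))
  i_unit <- abs(pracma::trapz(rev(nu), rev(gauss(product_center, product_width))))
  ratio * i_gsb / i_unit
}
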