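# Shared fixtures: small axes and species keep the suite fast while retaining
# the structural features the estimators rely on.

full_wl <- function(by = 5) seq(430, 1400, by = by)      # visible + NIR probe
vis_wl <- function(by = 1) seq(430, 700, by = by)        # visible only

short_tax <- function() linlog_delay_axis(t_max = 100)

# species without coherent oscillation, single exponential, for clean algebra
plain_species <- function(tau = 0.5, phi = 0, gsb_amp = 0.01) {
  species_spec(
    esa_bands = band(480, 25, 0.008),
    se_bands = band(900, 60, 0.006),
    gsb_band = band(570, 40, gsb_amp),
    product_band = band(590, 45, 0.009),
    kinetics = data.frame(amplitude = 1, tau = tau),
    phi_iso = phi)
}

# dark-adapted-like mixture: slow AT plus ultrafast 13C, known AT fraction
da_fixture <- function(f_at = 0.65, noise_sigma = 0, seed = 1L,
                       wl = full_wl(), tax = short_tax()) {
  at <- species_at(osc_amplitude = 0)
  c13 <- species_13c()
  list(
    mix = gen_mixture(mixture_spec(list(at, c13), c(f_at, 1 - f_at),
                                   noise_sigma = noise_sigma, seed = seed),
                      wl, tax),
    pure = gen_species_map(at, wl, tax),
    c13_map = gen_species_map(c13, wl, tax),
    f_at = f_at)
}

expect_scale <- function(est, value, tol) {
  expect_s3_class(est, "scale_estimate")
  expect_lt(abs(est$factor - value), tol)
}
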