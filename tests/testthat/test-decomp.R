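# Pure-species isolation: dynamic differences, scale-factor estimators,
# subtraction, steady-state absorption decomposition.

# brute-force oracle: scan c over [0, 1] in 1e-4 steps minimizing the same
# least-squares objective the closed form solves
grid_search_factor <- function(target, reference, step = 1e-4, lo = 0, hi = 1) {
  cs <- seq(lo, hi, by = step)
  rss <- vapply(cs, function(c) sum((target - c * reference)^2), numeric(1))
  cs[which.min(rss)]
}

test_that("dynamic difference spectra are exact pixel differences", {
  wl <- full_wl(20); tax <- linlog_delay_axis(n_log = 10)
  # constant in t -> all-zero ddod
  m_const <- ta_map(wl, tax, matrix(rep(sin(wl / 50), each = length(tax)),
                                    length(tax), length(wl)))
  dd <- dynamic_difference(m_const)
  expect_true(all(vapply(dd, function(d) max(abs(d$spectrum$od)), 0) == 0))
  # dOD(lambda, t) = t -> every ddod equals t2 - t1
  m_t <- ta_map(wl, tax, matrix(tax, length(tax), length(wl)))
  dd <- dynamic_difference(m_t)
  for (d in dd) expect_equal(d$spectrum$od, rep(d$t2 - d$t1, length(wl)))
  # single-exponential closed form between 0.5 and 1.0 ps
  s_shape <- exp(-(wl - 480)^2 / 800)
  tax2 <- delay_axis(c(0, 0.1, 0.25, 0.5, 0.75, 1.0, 2, 5))
  m_exp <- ta_map(wl, tax2, exp(-tax2 / 0.5) %o% s_shape)
  d <- dynamic_difference(m_exp, cbind(4L, 6L))[[1]]
  expect_equal(d$t1, 0.5); expect_equal(d$t2, 1.0)
  expect_equal(d$spectrum$od, s_shape * (exp(-2) - exp(-1)), tolerance = 1e-14)
  expect_error(dynamic_difference(m_exp, cbind(1L, 99L)), "out of range")
  expect_error(dynamic_difference(m_exp, cbind(3L, 2L)), "exceed")
})

test_that("ddod factor is exact on identical and scaled maps", {
  fx <- da_fixture()
  est <- estimate_scale_factor_ddod(fx$pure, fx$pure)
  expect_scale(est, 1, 1e-12)
  expect_lt(est$residual_norm, 1e-12)
  scaled <- ta_map(fx$pure$wavelength, fx$pure$delay, 0.65 * fx$pure$dod)
  expect_scale(estimate_scale_factor_ddod(scaled, fx$pure), 0.65, 1e-12)
})

test_that("ddod factor recovers the all-trans fraction of a DA-like mixture", {
  fx <- da_fixture(f_at = 0.65, noise_sigma = 1e-5, seed = 2)
  est <- estimate_scale_factor_ddod(fx$mix, fx$pure, t_min = 0.6)
  expect_lt(abs(est$factor - 0.65), 0.01)
  expect_gt(est$stderr, 0)
  # agrees with the brute-force grid search on its own objective
  sel <- spectral_mask(fx$mix$wavelength, list(c(440, 500), c(850, 1400)))
  dm <- tadecomp:::ddod_matrix(fx$mix, 0.6, sel)
  dp <- tadecomp:::ddod_matrix(fx$pure, 0.6, sel)
  expect_lt(abs(est$factor - grid_search_factor(dm, dp)), 2e-4)
})

test_that("ddod factor is unidentifiable on a statically evolving reference", {
  wl <- full_wl(20); tax <- linlog_delay_axis(n_log = 10)
  static <- ta_map(wl, tax, matrix(1e-3, length(tax), length(wl)))
  fx <- da_fixture(wl = wl, tax = tax)
  expect_error(estimate_scale_factor_ddod(fx$mix, static), "unidentifiable")
})

test_that("weighted subtraction removes a species exactly", {
  fx <- da_fixture(f_at = 0.65)
  expect_identical(subtract_species(fx$mix, fx$pure, 0)$dod, fx$mix$dod)
  # mix = A + 0.5 B minus A leaves 0.5 B
  sum_map <- ta_map(fx$pure$wavelength, fx$pure$delay,
                    fx$pure$dod + 0.5 * fx$c13_map$dod)
  expect_equal(subtract_species(sum_map, fx$pure, 1)$dod, 0.5 * fx$c13_map$dod,
               tolerance = 1e-14)
  # generator-truth residual: mix - c_true * pure = (1 - c_true) * 13C map
  resid <- subtract_species(fx$mix, fx$pure, 0.65)
  expect_equal(resid$dod, 0.35 * fx$c13_map$dod, tolerance = 1e-12)
  wrong_axis <- ta_map(fx$pure$wavelength + 1, fx$pure$delay, fx$pure$dod)
  expect_error(subtract_species(fx$mix, wrong_axis, 1), "share")
})

test_that("subtracting the estimated factor leaves the 13-cis map within noise", {
  fx <- da_fixture(f_at = 0.65, noise_sigma = 1e-5, seed = 8)
  est <- estimate_scale_factor_ddod(fx$mix, fx$pure, t_min = 0.6)
  resid <- subtract_species(fx$mix, fx$pure, est$factor)
  err <- resid$dod - 0.35 * fx$c13_map$dod
  # residual error is bounded by noise plus the factor error on the pure map
  bound <- 5 * 1e-5 + abs(est$factor - 0.65) * max(abs(fx$pure$dod))
  expect_lt(max(abs(err)), bound)
})

test_that("oscillation marker returns unity for identical maps", {
  wl <- full_wl(); tax <- short_tax()
  pure <- gen_species_map(species_at(), wl, tax)
  expect_scale(estimate_factor_from_oscillations(pure, pure), 1, 1e-6)
})

test_that("oscillation marker recovers the two-pump all-trans fraction", {
  wl <- full_wl(); tax <- short_tax()
  at <- species_at(); k <- species_k()
  pure <- gen_species_map(at, wl, tax)
  mixed <- gen_double_pump(at, k, 0.6, wl, tax, noise_sigma = 1e-5, seed = 4)
  expect_scale(estimate_factor_from_oscillations(mixed, pure), 0.6, 0.02)
})

test_that("a coherent K contribution biases the oscillation factor upward", {
  # quantifies the "oscillation exclusively due to AT" assumption: give K 10%
  # of AT's modulation depth and the marker over-counts the AT fraction
  wl <- full_wl(); tax <- short_tax()
  at <- species_at()
  k_osc <- species_spec(band(480, 30, 0.008), band(870, 60, 0.006),
                        band(590, 45, 0.010), band(570, 40, 0.009),
                        data.frame(amplitude = c(0.5, 0.5), tau = c(1.7, 11)),
                        phi_iso = 0.4,
                        oscillations = osc_component(180, 0.5, 0, 0.03, 520, 15))
  pure <- gen_species_map(at, wl, tax)
  mixed <- gen_double_pump(at, k_osc, 0.6, wl, tax)
  est <- estimate_factor_from_oscillations(mixed, pure)
  expect_gt(est$factor, 0.6)
  # closed form still minimizes its own objective (grid-search oracle)
  tr_m <- extract_trace(mixed, 520, 30); tr_p <- extract_trace(pure, 520, 30)
  bounds <- c(0.3, 1000)
  rm_ <- isolate_oscillations(tr_m, suppressWarnings(
    fit_multiexp(tr_m, 3, t_start = 0.08, tau_bounds = bounds)))
  rp <- isolate_oscillations(tr_p, suppressWarnings(
    fit_multiexp(tr_p, 3, t_start = 0.08, tau_bounds = bounds)))
  keep_m <- rm_$delay <= 1.5; keep_p <- rp$delay <= 1.5
  expect_lt(abs(est$factor -
                  grid_search_factor(rm_$dod[keep_m], rp$dod[keep_p])), 2e-4)
})

test_that("oscillation marker refuses a coherence-free reference", {
  wl <- full_wl(); tax <- short_tax()
  flat <- gen_species_map(species_at(osc_amplitude = 0), wl, tax)
  expect_error(
    estimate_factor_from_oscillations(flat, flat, noise_floor = 1e-6),
    "no coherence marker")
})

test_that("NIR stimulated-emission factor matches scaled and mixed maps", {
  fx <- da_fixture(f_at = 0.65)
  scaled <- ta_map(fx$pure$wavelength, fx$pure$delay, 0.65 * fx$pure$dod)
  expect_scale(estimate_factor_from_se(scaled, fx$pure), 0.65, 1e-12)
  # valid regime: after the 13C excited state is gone
  est <- estimate_factor_from_se(fx$mix, fx$pure, t_range = c(0.6, 5))
  expect_lt(abs(est$factor - 0.65), 0.01)
  # contaminated regime: surviving 13C emission inflates the factor
  early <- estimate_factor_from_se(fx$mix, fx$pure, t_range = c(0, 0.3))
  expect_gt(early$factor, 0.65)
})

test_that("ddod and NIR-SE estimators agree within joint uncertainty", {
  for (seed in 1:3) {
    fx <- da_fixture(f_at = 0.6, noise_sigma = 5e-5, seed = seed)
    e1 <- estimate_scale_factor_ddod(fx$mix, fx$pure, t_min = 0.6)
    e2 <- estimate_factor_from_se(fx$mix, fx$pure)
    expect_lt(abs(e1$factor - e2$factor), 2 * (e1$stderr + e2$stderr))
  }
})

test_that("late-spectrum matching returns reciprocal and unit factors", {
  wl <- full_wl(); tax <- short_tax()
  a <- gen_species_map(species_at(), wl, tax)
  b <- ta_map(wl, tax, 0.8 * a$dod)
  expect_scale(late_spectrum_match(a, b, t_min = 50), 1.25, 1e-12)
  expect_scale(late_spectrum_match(a, a, t_min = 50), 1, 1e-12)
  expect_error(late_spectrum_match(a, b, t_min = 1e4), "t_min")
})

test_that("two-pump late spectra need a factor above one to match single-pump", {
  wl <- full_wl(); tax <- short_tax()
  at <- species_at(); k <- species_k()
  single <- gen_species_map(at, wl, tax)
  double <- gen_double_pump(at, k, 0.6, wl, tax)
  expect_gt(late_spectrum_match(single, double, t_min = 50)$factor, 1)
})

test_that("absorption decomposition inverts constructed isomer mixtures", {
  wl <- vis_wl(1)
  a_la <- gen_absorption(band(570, 40, 1), wl)
  # identity: DA == LA forces the 13C spectrum onto LA
  same <- decompose_absorption(a_la, a_la, isomer_composition(0.35, 0.65))
  expect_equal(same$spectrum$od, a_la$od, tolerance = 1e-12)
  # constructed inverse: 0.65 AT + 0.35 13C at 543 nm
  a_13 <- gen_absorption(band(543, 40, 1), wl)
  a_da <- ta_spectrum(wl, 0.65 * a_la$od + 0.35 * a_13$od)
  out <- decompose_absorption(a_da, a_la, isomer_composition(0.35, 0.65))
  expect_lt(abs(out$lambda_max - 543), 0.5)
  expect_equal(out$spectrum$od, a_13$od, tolerance = 1e-12)
  # x_at = 0 passes DA through
  pass <- decompose_absorption(a_da, a_la, isomer_composition(1, 0))
  expect_equal(pass$spectrum$od, a_da$od)
  expect_error(decompose_absorption(a_da, a_la, isomer_composition(0, 1)),
               "unidentifiable")
})

test_that("negative dips in a decomposed spectrum warn but are not clipped", {
  wl <- vis_wl(2)
  a_la <- gen_absorption(band(570, 40, 1), wl)
  a_da <- ta_spectrum(wl, 0.5 * a_la$od)  # less than x_at * LA -> negative
  expect_warning(
    out <- decompose_absorption(a_da, a_la, isomer_composition(0.35, 0.65)),
    "negative")
  expect_true(any(out$spectrum$od < 0))
})

test_that("every estimator returns exactly one for mix == pure", {
  fx <- da_fixture()
  pure_osc <- gen_species_map(species_at(), fx$pure$wavelength, fx$pure$delay)
  expect_scale(estimate_scale_factor_ddod(fx$pure, fx$pure), 1, 1e-12)
  expect_scale(estimate_factor_from_se(fx$pure, fx$pure), 1, 1e-12)
  expect_scale(late_spectrum_match(fx$pure, fx$pure), 1, 1e-12)
  expect_scale(estimate_factor_from_oscillations(pure_osc, pure_osc), 1, 1e-6)
})
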