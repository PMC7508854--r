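test_that("SVD extracts the melting curve from a rank-2 series", {
  sc <- tjump_scenario("duplex", noise_sigma = 0)
  ser <- generate_melting_series(sc)
  cv <- svd_melting_curve(ser, sample = sc$sample)
  theta_true <- attr(ser, "theta_true")
  # recovered curve equals theta up to an affine map (the noise-free fit is
  # essentially perfect, which summary.lm warns about)
  expect_gt(suppressWarnings(
    summary(stats::lm(cv$theta ~ theta_true))$r.squared), 0.999)
  expect_equal(cv$observable, "ir_svd")
  expect_equal(length(cv$signal), length(ser$temperatures))
  # temperature-independent series is degenerate
  flat <- spectrum_series(ser$wavenumbers, ser$temperatures,
                          matrix(ser$absorbance[, 1],
                                 nrow = nrow(ser$absorbance),
                                 ncol = length(ser$temperatures)))
  expect_error(svd_melting_curve(flat), "degenerate")
})

test_that("SVD extraction survives 1% noise across 33 temperatures", {
  sc <- tjump_scenario("duplex", noise_sigma = 0.01, seed = 7)
  Tm <- melting_temperature(sc$thermo, sc$sample)
  ser <- generate_melting_series(
    sc, temperatures_C = kelvin_to_celsius(seq(Tm - 45, Tm + 45,
                                               length.out = 33)))
  cv <- svd_melting_curve(ser, sample = sc$sample)
  expect_gt(abs(stats::cor(cv$theta, attr(ser, "theta_true"))), 0.99)
})

test_that("SVD curve is invariant to spectra scaling and static background", {
  # scaling invariance holds exactly even for noisy spectra
  sc <- tjump_scenario("complex", noise_sigma = 0.005, seed = 3)
  ser <- suppressWarnings(generate_melting_series(sc))
  base <- suppressWarnings(svd_melting_curve(ser))
  scaled <- spectrum_series(ser$wavenumbers, ser$temperatures,
                            7.3 * ser$absorbance)
  expect_equal(suppressWarnings(svd_melting_curve(scaled))$signal,
               base$signal, tolerance = 1e-8)
  # a temperature-independent background leaves the rank-2 structure and
  # hence the extracted transition untouched (exact for noise-free data)
  sc0 <- tjump_scenario("complex", noise_sigma = 0)
  ser0 <- generate_melting_series(sc0)
  base0 <- suppressWarnings(svd_melting_curve(ser0))
  bg <- spectrum_series(ser0$wavenumbers, ser0$temperatures,
                        ser0$absorbance + 0.5 * exp(-(ser0$wavenumbers -
                                                        1650)^2 / 2e4))
  expect_equal(suppressWarnings(svd_melting_curve(bg))$signal,
               base0$signal, tolerance = 1e-8)
})

test_that("global two-state fit recovers generating thermodynamics", {
  # concerted complex, three concentrations (IR at 1 mM + fluorescence at
  # 2 uM and 200 nM), noise-free: sub-0.5% recovery
  curves <- list(spanning_ir_curve("complex", 1e-3))
  for (cd in c(2e-6, 2e-7)) {
    sc <- tjump_scenario("complex", C_D = cd, noise_sigma = 0)
    Tm <- melting_temperature(sc$thermo, sc$sample)
    curves <- c(curves, list(generate_fluorescence_curve(
      sc, seq(Tm - 45, Tm + 45, length.out = 40))))
  }
  fit <- fit_two_state(curves, "complex")
  expect_equal(fit$dH0, 415e3, tolerance = 5e-3)
  expect_equal(fit$dS0, 1000, tolerance = 5e-3)
  expect_lt(fit$residual_rms, 1e-6)
  # native duplex from a single IR curve
  fitn <- fit_two_state(spanning_ir_curve("duplex", 1e-3), "duplex")
  expect_equal(fitn$dH0, 403e3, tolerance = 5e-3)
  expect_equal(fitn$dS0, 1088, tolerance = 5e-3)
  # a step-like curve (infinitely cooperative limit) errors or is flagged
  Tg <- celsius_to_kelvin(seq(40, 120, by = 2.5))
  step <- melting_curve(Tg, as.numeric(Tg > celsius_to_kelvin(80)),
                        sample = sample_spec(1e-3))
  res <- tryCatch(suppressWarnings(fit_two_state(step, "duplex")),
                  error = function(e) "fit-error")
  expect_true(identical(res, "fit-error") || isTRUE(res$boundary_flag))
  # curves that do not span the transition are refused
  part <- melting_curve(Tg[1:10], seq(0, 0.2, length.out = 10),
                        sample = sample_spec(1e-3))
  expect_error(fit_two_state(part, "duplex"), "span")
})

test_that("median enthalpy recovery error stays below 2% at 1% noise", {
  errs <- vapply(1:50, function(s) {
    cv <- spanning_ir_curve("complex", 1e-3, noise_sigma = 0.01, seed = s)
    abs(fit_two_state(cv, "complex")$dH0 / 415e3 - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)
})

test_that("three-state K_b is recovered exactly from three-state data", {
  dup <- params_native()
  K_b_true <- 3e6
  p3 <- three_state_params(dup, K_b_true)
  for (cd in c(1e-3, 2e-5, 2e-7)) {
    s <- sample_spec(cd)
    Tg <- celsius_to_kelvin(seq(5, 98, by = 3))
    fdh <- vapply(Tg, function(T) solve_three_state(p3, T, s)$f_DH,
                  numeric(1))
    cv <- melting_curve(Tg, 1 - fdh, sample = s)
    fit <- fit_three_state_Kb(cv, dup)
    expect_equal(fit$K_b, K_b_true, tolerance = 0.01)
    expect_false(fit$at_boundary)
  }
})

test_that("K_b fitted to three-state data is concentration-stable", {
  dup <- params_native()
  p3 <- three_state_params(dup, 3e6)
  Tg <- celsius_to_kelvin(seq(5, 98, by = 3))
  kbs <- vapply(c(1e-3, 2e-6, 2e-7), function(cd) {
    s <- sample_spec(cd)
    fdh <- vapply(Tg, function(T) solve_three_state(p3, T, s)$f_DH,
                  numeric(1))
    fit_three_state_Kb(melting_curve(Tg, 1 - fdh, sample = s), dup)$K_b
  }, numeric(1))
  expect_lt(diff(range(kbs)) / mean(kbs), 0.10)
})

test_that("K_b fitted to concerted-model data drifts with concentration", {
  # as-measured curves on the 5-98 degC instrument window (the 1 mM complex
  # transition is cut off by the window, as in the experiments)
  dup <- params_native()
  Tg <- celsius_to_kelvin(seq(5, 98, by = 3))
  kbs <- vapply(c(1e-3, 2e-7), function(cd) {
    sc <- tjump_scenario("complex", C_D = cd, noise_sigma = 0)
    x <- vapply(Tg, function(T)
      1 - predicted_complex_fraction(sc$thermo, sc$sample, T), numeric(1))
    sig <- (x - mean(x[1:3])) / (mean(x[30:32]) - mean(x[1:3]))
    cv <- suppressWarnings(melting_curve(Tg, sig, sample = sc$sample))
    fit_three_state_Kb(cv, dup)$K_b
  }, numeric(1))
  # the model-rejection signature: two orders of magnitude or more
  expect_gte(log10(kbs[2] / kbs[1]), 2)
})

test_that("predicted complex fraction behaves across the transition", {
  p <- params_bound()
  s <- sample_spec(1e-3)
  expect_equal(predicted_complex_fraction(p, s, 280), 1, tolerance = 1e-6)
  Tm <- melting_temperature(p, s)
  expect_equal(predicted_complex_fraction(p, s, Tm), 0.5, tolerance = 1e-4)
  expect_error(predicted_complex_fraction(params_native(), s, 300),
               "complex")
  # concerted-model fractions scale linearly with synthetic fluorescence
  # generated from the same model across three decades of concentration
  cds <- 10^seq(log10(2e-7), log10(1e-3), length.out = 8)
  T_fix <- celsius_to_kelvin(80)
  frac <- vapply(cds, function(cd)
    predicted_complex_fraction(p, sample_spec(cd), T_fix), numeric(1))
  fluor <- 0.83 * frac  # intensity proportional to [DH]/C_D
  expect_gt(stats::cor(frac, fluor), 0.9999)
})
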