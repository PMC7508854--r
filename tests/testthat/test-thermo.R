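test_that("Gibbs free energy of dissociation follows dH0 - T*dS0", {
  # zero crossing at T = dH/dS
  expect_equal(gibbs_free_energy(params_bound(), 415.0), 0)
  # direct arithmetic
  expect_equal(gibbs_free_energy(params_native(), 298.15),
               403000 - 298.15 * 1088)
  expect_equal(gibbs_free_energy(params_bound(), 343.15), 71850)
  expect_error(gibbs_free_energy(params_native(), -1), "positive")
  expect_error(gibbs_free_energy(params_native(), 0), "positive")
})

test_that("dissociation constant is exp(-dG/RT) with log form carried", {
  # K_d = 1 at the reference temperature
  K0 <- dissociation_constant(params_bound(), 415.0)
  expect_equal(K0$Kd, 1)
  expect_equal(K0$log_Kd, 0)
  # frozen values from direct evaluation of exp(-dG/(R T))
  expect_equal(dissociation_constant(params_bound(), 343.15)$Kd,
               exp(-71850 / (8.314 * 343.15)), tolerance = 1e-12)
  expect_equal(dissociation_constant(params_bound(), 343.15)$Kd,
               1.1548e-11, tolerance = 1e-4)
  expect_equal(dissociation_constant(params_native(), 333.15)$Kd,
               4.4119e-7, tolerance = 1e-4)
  expect_equal(dissociation_constant(params_bound(), 343.15)$kd_units_power, 2L)
  expect_equal(dissociation_constant(params_native(), 343.15)$kd_units_power, 1L)
})

test_that("duplex equilibrium solver finds the unique mass-action root", {
  s <- sample_spec(1e-3)
  expect_equal(solve_duplex_equilibrium(0, s)$x, 0)
  expect_equal(solve_duplex_equilibrium(0, s)$theta, 1)
  # K_d = 2 C_D puts the transition midpoint at x = 0.5
  expect_equal(solve_duplex_equilibrium(2e-3, s)$x, 0.5, tolerance = 1e-12)
  # frozen oracle value (uniroot on the quadratic)
  st <- solve_duplex_equilibrium(4.41e-7, s)
  expect_equal(st$x, 0.01044502, tolerance = 1e-6)
  expect_equal(st$conc_S, 2 * st$x * 1e-3)
  expect_equal(st$conc_D_or_DH, (1 - st$x) * 1e-3)
  expect_equal(st$conc_H, 0)
  expect_error(solve_duplex_equilibrium(-1e-9, s), "non-negative")
})

test_that("concerted complex solver finds the unique cubic root", {
  s <- sample_spec(1e-3)
  expect_equal(solve_complex_equilibrium(0, s)$x, 0)
  # K_d = C_D^2 puts the midpoint at x = 0.5
  expect_equal(solve_complex_equilibrium(1e-6, s)$x, 0.5, tolerance = 1e-12)
  st <- solve_complex_equilibrium(2.2e-7, s)
  expect_equal(st$x, 0.3323772, tolerance = 1e-6)
  expect_equal(st$conc_H, st$x * 1e-3)
  expect_error(solve_complex_equilibrium(-1, s), "non-negative")
})

test_that("solvers match an independent uniroot oracle over random draws", {
  set.seed(101)
  n <- 1000
  C_D <- 10^stats::runif(n, -8, -2)
  for (power in 1:2) {
    # K_d spanning far below to far above the transition
    K_d <- if (power == 1) 10^stats::runif(n, -14, 2) * C_D
           else 10^stats::runif(n, -14, 2) * C_D^2
    x_pkg <- vapply(seq_len(n), function(i) {
      s <- sample_spec(C_D[i])
      if (power == 1) solve_duplex_equilibrium(K_d[i], s)$x
      else solve_complex_equilibrium(K_d[i], s)$x
    }, numeric(1))
    x_ora <- vapply(seq_len(n), function(i)
      oracle_x(K_d[i], C_D[i], power), numeric(1))
    expect_lt(max(abs(x_pkg - x_ora)), 1e-10)
    # mass-action residual, relative
    resid <- abs(K_d * (1 - x_pkg) - 4 * x_pkg^(power + 1) * C_D^power) /
      pmax(K_d, 1e-300)
    expect_lt(max(resid[K_d > 0]), 1e-9)
  }
})

test_that("dissociated fraction increases with temperature, theta in [0,1]", {
  s <- sample_spec(1e-3)
  for (p in list(params_native(), params_bound())) {
    Tg <- seq(278.15, 420, by = 2)
    x <- vapply(Tg, function(T) solve_equilibrium(p, s, T)$x, numeric(1))
    expect_true(all(diff(x) > 0))
    expect_true(all(x >= 0 & x <= 1))
  }
})

test_that("three-state solver satisfies all balances and matches an oracle", {
  dup <- params_native()
  s <- sample_spec(1e-3)
  p3 <- three_state_params(dup, K_b = 1e6)
  T <- 333.15
  sol <- solve_three_state(p3, T, s)
  K_d <- dissociation_constant(dup, T)$Kd
  expect_equal(sol$S^2 / sol$D, K_d, tolerance = 1e-9)
  expect_equal(sol$DH / (sol$D * sol$H), 1e6, tolerance = 1e-9)
  expect_equal(2 * sol$D + 2 * sol$DH + sol$S, 2e-3, tolerance = 1e-9)
  expect_equal(sol$H + sol$DH, 1e-3, tolerance = 1e-9)

  # independent oracle: root in [H] with the species eliminated the other
  # way round (D from the binding equilibrium, S from the balances); the
  # physical branch needs S = 2(H - D) >= 0, i.e. H above the crossing of
  # H = D(H), so that crossing brackets the search interval
  oracle <- function(K_d, K_b, C_D) {
    Dof <- function(H) (C_D - H) / (K_b * H)
    f <- function(H) 4 * (H - Dof(H))^2 - K_d * Dof(H)
    H_lo <- stats::uniroot(function(H) H - Dof(H),
                           c(C_D * 1e-12, C_D * (1 - 1e-12)),
                           tol = 1e-18)$root
    H <- stats::uniroot(f, c(H_lo, C_D * (1 - 1e-12)), tol = 1e-18)$root
    list(H = H, DH = C_D - H, D = Dof(H))
  }
  ora <- oracle(K_d, 1e6, 1e-3)
  expect_equal(sol$H, ora$H, tolerance = 1e-7)
  expect_equal(sol$D, ora$D, tolerance = 1e-7)

  # K_b -> 0 limit reduces to the ligand-free duplex equilibrium
  weak <- solve_three_state(three_state_params(dup, 1e-10), T, s)
  free <- solve_duplex_equilibrium(K_d, s)
  expect_equal(weak$DH / 1e-3, 0, tolerance = 1e-6)
  expect_equal(weak$S, free$conc_S, tolerance = 1e-6 * free$conc_S)

  # strong binding with a stable duplex saturates [DH] -> C_D
  sat <- solve_three_state(three_state_params(dup, 1e12),
                           celsius_to_kelvin(25), s)
  expect_equal(sat$f_DH, 1, tolerance = 1e-3)
})

test_that("melting temperature matches its closed form and rises with C_D", {
  p <- params_native()
  s <- sample_spec(1e-3)
  Tm <- melting_temperature(p, s)
  expect_equal(Tm, 403000 / (1088 - 8.314 * log(2e-3)), tolerance = 1e-6)
  # K_d(T_m) equals the midpoint constant for each model
  expect_equal(dissociation_constant(p, Tm)$Kd, 2e-3, tolerance = 1e-4)
  pc <- params_bound()
  Tmc <- melting_temperature(pc, s)
  expect_equal(dissociation_constant(pc, Tmc)$Kd, 1e-6, tolerance = 1e-4)
  # strictly increasing in concentration over 3 decades
  Tms <- vapply(c(1e-6, 1e-5, 1e-4, 1e-3), function(cd)
    melting_temperature(p, sample_spec(cd)), numeric(1))
  expect_true(all(diff(Tms) > 0))
})

test_that("reference temperature T0 = dH0/dS0, independent of concentration", {
  expect_equal(kelvin_to_celsius(reference_temperature(params_native())),
               97.25, tolerance = 1e-3)
  expect_equal(kelvin_to_celsius(reference_temperature(params_bound())),
               141.85, tolerance = 1e-3)
  expect_equal(reference_temperature(thermo_params(350 * 1000, 1000)), 350)
  expect_error(reference_temperature(thermo_params(4e5, -10)), "positive")
})

test_that("model melting curve is monotone with theta = 0.5 at T_m", {
  p <- params_bound()
  s <- sample_spec(1e-3)
  Tm <- melting_temperature(p, s)
  mc <- melting_curve_model(p, s, seq(Tm - 60, Tm + 60, by = 1))
  expect_true(all(diff(mc$theta) < 0))
  expect_equal(mc$theta[1], 1, tolerance = 1e-3)
  expect_equal(mc$theta[nrow(mc)], 0, tolerance = 1e-2)
  # T_m is located to 1e-4 K, so theta(T_m) matches 0.5 at that resolution
  expect_equal(melting_curve_model(p, s, Tm)$theta, 0.5, tolerance = 1e-4)
})

test_that("thermodynamic cycle closes: K_complex = K_duplex / K_b", {
  # binding step DH -> D + H with its own enthalpy/entropy; the concerted
  # constant must equal the product of the stepwise constants at any T
  dH_rel <- 12e3; dS_rel <- -88
  dup <- params_native()
  comp <- thermo_params(dup$dH0 + dH_rel, dup$dS0 + dS_rel, "complex")
  for (T in c(298.15, 333.15, 368.15)) {
    K_b <- exp((dH_rel - T * dS_rel) / (8.314 * T))  # association sense
    expect_equal(dissociation_constant(comp, T)$log_Kd,
                 dissociation_constant(dup, T)$log_Kd - log(K_b),
                 tolerance = 1e-10)
  }
})
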