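test_that("a noiseless 1:1 titration is inverted to ka and n within 0.1%", {
  s <- simulate_titration(ka = 1.75e4, n = 1, f0 = 1000,
                          ligand_conc = 3.28e-6,
                          quencher_grid = seq(0, 2e-4, length.out = 11))
  fit <- binding_fit(s)
  expect_lt(abs(fit$ka / 1.75e4 - 1), 0.001)
  expect_lt(abs(fit$n - 1), 0.001)
  expect_equal(fit$n_points_used, 10)
  expect_equal(fit$n_points_excluded, 0)
  expect_gt(fit$r, 0.9999)
})

test_that("a flat series carries no binding signal", {
  s <- titration_series(seq(0, 4e-4, 1e-4), rep(800, 5), 298.15, 3.28e-6)
  expect_error(binding_fit(s), "usable points")
})

test_that("median parameter recovery holds under 1% multiplicative noise", {
  errs_ka <- errs_n <- numeric(100)
  for (i in 1:100) {
    s <- simulate_titration(ka = 1.75e4, n = 1, f0 = 1000,
                            ligand_conc = 3.28e-6,
                            quencher_grid = seq(0, 2e-4, length.out = 11),
                            noise_sd_fraction = 0.01, seed = 5000 + i)
    fit <- binding_fit(s)
    errs_ka[i] <- abs(fit$ka / 1.75e4 - 1)
    errs_n[i] <- abs(fit$n - 1)
  }
  expect_lte(median(errs_ka), 0.05)
  expect_lte(median(errs_n), 0.03)
})

test_that("van't Hoff fit of the printed binding constants matches the least-squares oracle", {
  th <- vant_hoff(ka_by_temp_fixture)
  # frozen from an independent lm() oracle on the same rounded inputs
  expect_equal(th$delta_h, -20.467174, tolerance = 1e-6)
  expect_equal(th$delta_s, 12.814518, tolerance = 1e-6)
  # within 2% of the value obtained from the unrounded laboratory data
  expect_lt(abs(th$delta_h / -20.68 - 1), 0.02)
  expect_identical(th$force_verdict, "hydrogen_bond_and_hydrophobic")
})

test_that("two-temperature input reproduces the closed-form enthalpy exactly", {
  th <- vant_hoff(ka_by_temp_fixture[1:2])
  expect_equal(th$delta_h, -9.6993004481, tolerance = 1e-9)
})

test_that("temperature-independent ka gives zero enthalpy", {
  th <- vant_hoff(c("298.15" = 5e3, "304.15" = 5e3, "310.15" = 5e3))
  expect_equal(th$delta_h, 0, tolerance = 1e-9)
  expect_equal(th$delta_g_by_temperature[["298.15"]],
               -log(10) * 8.314 * 298.15 * log10(5e3) / 1000,
               tolerance = 1e-9)
})

test_that("forward-generated ka values invert to the chosen dH and dS exactly", {
  R <- 8.314
  dh <- -30.5   # kJ/mol
  ds <- 40.2    # J/(mol K)
  temps <- c(288.15, 298.15, 308.15, 318.15)
  ka <- 10^(-dh * 1000 / (log(10) * R * temps) + ds / (log(10) * R))
  th <- vant_hoff(stats::setNames(ka, temps))
  expect_equal(th$delta_h, dh, tolerance = 1e-9)
  expect_equal(th$delta_s, ds, tolerance = 1e-9)
  expect_equal(unname(th$delta_g_by_temperature),
               gibbs(dh, ds, temps), tolerance = 1e-12)
})

test_that("stored Gibbs energies equal gibbs(dH, dS, T) by construction", {
  th <- vant_hoff(ka_by_temp_fixture)
  temps <- as.numeric(names(th$delta_g_by_temperature))
  expect_identical(unname(th$delta_g_by_temperature),
                   gibbs(th$delta_h, th$delta_s, temps))
})

test_that("gibbs reproduces the tabulated free energies", {
  expect_equal(gibbs(-20.68, 12.05, 298.15), -24.27, tolerance = 0.005)
  expect_equal(gibbs(-20.68, 12.05, 310.15), -24.42, tolerance = 0.005)
  expect_equal(gibbs(0, 0, 500), 0)
})

test_that("van't Hoff input validation", {
  expect_error(vant_hoff(c("298.15" = 1e4)), ">= 2 temperatures")
  expect_error(vant_hoff(c("298.15" = 1e4, "304.15" = -1)), "positive")
})

test_that("driving-force classification follows the sign rules with the near-zero electrostatic band first", {
  expect_identical(classify_forces(-20.68, 12.05),
                   "hydrogen_bond_and_hydrophobic")
  expect_identical(classify_forces(10, 30), "hydrophobic")
  expect_identical(classify_forces(-2, 15), "electrostatic")
  expect_identical(classify_forces(-15, -40), "hbond_vdw")
  expect_identical(classify_forces(10, -5), "indeterminate")
})

test_that("points breaking the free-quencher positivity constraint are excluded and reported", {
  s <- simulate_titration(ka = 1.75e4, f0 = 1000, ligand_conc = 3.28e-6,
                          quencher_grid = seq(0, 2e-4, length.out = 11))
  # corrupt two points so F >= F0
  s$f_measured[c(4, 7)] <- c(1000, 1200)
  fit <- binding_fit(s)
  expect_equal(fit$n_points_excluded, 2)
  expect_equal(fit$n_points_used, 8)
})
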