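test_that("one-set-of-sites heats honour limits and mass balance", {
  ex <- titration_experiment()
  expect_equal(one_set_of_sites_heat(ex, 1, 1e-7, 0), rep(0, 19))
  # total heat equals dH * Vcell * [bound] at the final composition,
  # within the displaced-volume dilution corrections
  dH <- -1e4
  qs <- one_set_of_sites_heat(ex, 0.98, 176e-9, dH)
  sol <- titration_concentrations(ex)
  b_end <- tail((function(Mt, Xt) {
    bq <- 0.98 * Mt + Xt + 176e-9
    (bq - sqrt(bq^2 - 4 * 0.98 * Mt * Xt)) / 2
  })(sol$Mt, sol$Xt), 1)
  # displaced-bound-material corrections amount to ~n_inj*dV/(2 V0) ~ 6%
  expect_equal(sum(qs), dH * 300e-6 * b_end * 1e6, tolerance = 0.1)
  # heats scale linearly in dH
  expect_equal(one_set_of_sites_heat(ex, 0.98, 176e-9, -2e4), 2 * qs)
})

test_that("thermodynamic bookkeeping follows the Gibbs relation", {
  expect_equal(thermodynamics(1, -5000)$dG_cal_mol, 0)
  td <- thermodynamics(176e-9, -10000, 298.15)
  # dG = -R T ln(1/Kd), R = 1.98 cal/(mol K)
  expect_equal(td$dG_cal_mol, -1.98 * 298.15 * log(1 / 176e-9))
  expect_equal(td$dG_cal_mol / 1000, -9.2, tolerance = 0.01)
  expect_equal(thermodynamics(176e-9, td$dG_cal_mol)$dS_cal_mol_K, 0)
})

test_that("noise-free isotherms refit to the generating parameters", {
  ex <- titration_experiment()
  for (p in list(c(0.98, 176e-9, -1e4), c(1.5, 1e-6, -6e3),
                 c(0.7, 2e-8, 5e3))) {
    sim <- simulate_itc(ex, p[1], p[2], p[3], noise_spec(itc_frac = 0))
    ft <- fit_itc(sim, n_baseline = 0)
    expect_equal(ft$N, p[1], tolerance = 1e-4)
    expect_equal(ft$Kd_M, p[2], tolerance = 1e-3)
    expect_equal(ft$dH_cal_mol, p[3], tolerance = 1e-4)
  }
})

test_that("1% noise replicates recover Kd and N within 10% (median)", {
  ex <- titration_experiment()
  est <- t(vapply(1:40, function(s) {
    sim <- simulate_itc(ex, 0.98, 176e-9, -1e4,
                        noise_spec(itc_frac = 0.01, seed = s))
    ft <- fit_itc(sim)
    c(ft$N, ft$Kd_M)
  }, numeric(2)))
  expect_equal(median(est[, 1]), 0.98, tolerance = 0.1)
  # compare in nM so the tolerance is genuinely relative
  expect_equal(median(est[, 2]) * 1e9, 176, tolerance = 0.1)
})

test_that("isotherm CSV round-trips and permuted injections are rejected", {
  ex <- simulate_itc(titration_experiment(), 0.98, 176e-9, -1e4,
                     noise_spec(itc_frac = 0.01, seed = 2))
  f <- tempfile(fileext = ".csv")
  write_itc_csv(ex, f)
  ex2 <- read_itc_csv(f)
  expect_equal(ex2$heats_ucal, ex$heats_ucal, tolerance = 1e-6)
  bad <- ex
  bad$injection_volume_ul <- -2 # non-monotone cumulative volume
  expect_error(fit_itc(bad))
})
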