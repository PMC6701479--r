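# reduced-size dimer keeps these optimisation tests fast
small_template <- function(dA = 40, dB = 70) {
  dimer_template(cc_separation = 120, module_radius = 16, module_arm = 30,
                 n_linker = 60, n_mobile_beads = 50, mobile_radius = 10,
                 dA = dA, dB = dB, max_D = 90)
}

test_that("fitting a model to its own profile is a fixed point", {
  tp <- small_template()
  m <- build_full_dimer(tp, seed = 2)
  q <- default_q_grid(61)
  calc <- debye_profile(m, q)
  I0 <- n_beads(m)^2
  target <- scattering_profile(q, calc$I,
                               0.01 * sqrt(pmax(calc$I, 1e-12 * I0) * I0))
  res <- flexfit(m, target, flexfit_config(n_iter = 8))
  expect_lt(res$chi2_init, 1e-6)
  expect_false(any(res$trajectory$accepted))
  expect_equal(res$chi2_final, res$chi2_init)
  expect_identical(res$model$xyz, m$xyz)
})

test_that("accepted chi2 sequence is non-increasing and blocks stay rigid", {
  tp <- small_template()
  target <- simulate_saxs_ensemble(tp, default_q_grid(61),
                                   noise_spec(seed = 4), n_avg = 4)
  start <- randomize_termini(build_full_dimer(tp, seed = 2), tp, seed = 31)
  res <- flexfit(start, target, flexfit_config(n_iter = 10))
  tr <- res$trajectory
  expect_true(all(diff(tr$chi2) <= 1e-12))
  expect_lt(res$chi2_final, res$chi2_init)
  # rigid-domain internal geometry preserved through the whole fit
  for (dom in c("RB1B2", "PHDBR")) {
    idx <- select_beads(start, domain = dom, chain = "B")[1:12]
    expect_lt(max(abs(dist(res$model$xyz[idx, ]) -
                      dist(start$xyz[idx, ]))), 1e-6)
  }
  expect_true(is_topologically_valid(res$model))
})

test_that("ensemble runs are deterministic and reject empty input", {
  tp <- small_template()
  target <- simulate_saxs_ensemble(tp, default_q_grid(61),
                                   noise_spec(seed = 4), n_avg = 4)
  starts <- lapply(1:2, function(i)
    randomize_termini(build_full_dimer(tp, seed = 2), tp, seed = 40 + i))
  cfg <- flexfit_config(n_iter = 5)
  e1 <- run_ensemble(starts, target, cfg)
  e2 <- run_ensemble(starts, target, cfg)
  expect_identical(e1$summary, e2$summary)
  expect_equal(nrow(e1$summary), 2)
  expect_true(all(e1$summary$chi2_final <= e1$summary$chi2_init))
  expect_error(run_ensemble(list(), target, cfg), "empty")
})
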