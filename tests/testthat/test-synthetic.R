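test_that("default dumbbell reproduces the designed architecture", {
  m <- default_core()
  expect_true(is_topologically_valid(m))
  comA <- center_of_mass(m, domain = "RB1B2", chain = "A")
  comB <- center_of_mass(m, domain = "RB1B2", chain = "B")
  expect_equal(sqrt(sum((comA - comB)^2)), 160, tolerance = 1 / 160)
  expect_equal(max_dimension(m), 370, tolerance = 0.10)
})

test_that("zero module radius degenerates to a pure rod", {
  tp <- dimer_template(module_radius = 0, module_arm = 0)
  m <- build_dumbbell_dimer(tp)
  expect_true(is_topologically_valid(m))
  # all beads close to the long axis
  expect_lt(max(sqrt(m$xyz[, 2]^2 + m$xyz[, 3]^2)), 10)
})

test_that("planted full-length dimer carries its ground truth", {
  m <- default_full()
  expect_true(is_topologically_valid(m))
  expect_equal(unname(compute_cvs(m)), c(60, 120), tolerance = 0.02)
  expect_equal(attr(m, "dA"), 60)
  expect_equal(attr(m, "dB"), 120)
  # deterministic rebuild
  m2 <- build_full_dimer(dimer_template(), seed = 7)
  expect_identical(m2$xyz, m$xyz)
})

test_that("randomized termini stay within D and reach near D empirically", {
  tp <- dimer_template()
  m <- default_full()
  d <- unlist(lapply(1:500, function(s) {
    attr2 <- randomize_termini(m, tp, D = 140, seed = s)
    c(attr(attr2, "dA"), attr(attr2, "dB"))
  }))
  expect_true(all(d <= 140))
  expect_gt(max(d), 130)
  # determinism and validity
  r1 <- randomize_termini(m, tp, seed = 77)
  r2 <- randomize_termini(m, tp, seed = 77)
  expect_identical(r1$xyz, r2$xyz)
  expect_true(is_topologically_valid(r1))
  expect_error(randomize_termini(m, tp, D = 5), "placement error")
})

test_that("linker growth bridges anchors with valid bonds and no clashes", {
  with_seed(5, {
    a0 <- c(0, 0, 0); a1 <- c(60, 0, 0)
    ch <- grow_linker(a0, a1, 200)
    steps <- sqrt(rowSums(diff(rbind(a0, ch))^2))
    expect_true(all(abs(steps - 3.8) < 0.05))
    expect_lte(sqrt(sum((ch[200, ] - a1)^2)), 3.8 + 1e-9)
    expect_gt(min(dist(ch)), 2.0)
    # near-straight forced geometry
    seg <- grow_linker(c(0, 0, 0), c(7.6, 0, 0), 2)
    expect_lt(max(abs(seg[, 2:3])), 1.5)
    expect_error(grow_linker(c(0, 0, 0), c(1000, 0, 0), 10), "infeasible")
  })
})

test_that("free linker chains follow ideal-chain statistics", {
  e2e <- with_seed(8, vapply(1:300, function(i) {
    ch <- grow_linker(c(0, 0, 0), NULL, 100)
    sqrt(sum(ch[100, ]^2))
  }, 0))
  expect_equal(sqrt(mean(e2e^2)), 3.8 * sqrt(100), tolerance = 0.15)
})

test_that("simulated SAXS matches the Debye truth and calibrates to chi2 ~ 1", {
  m <- default_core()
  q <- default_q_grid(81)
  clean <- simulate_saxs(m, q, noise_spec(saxs_rel = 0))
  expect_equal(clean$I, debye_profile(m, q)$I)
  chis <- vapply(1:25, function(s) {
    noisy <- simulate_saxs(m, q, noise_spec(seed = s))
    chi2_fit(debye_profile(m, q), noisy)$chi2
  }, 0)
  expect_equal(mean(chis), 1, tolerance = 0.2)
  n1 <- simulate_saxs(m, q, noise_spec(seed = 3))
  n2 <- simulate_saxs(m, q, noise_spec(seed = 3))
  expect_identical(n1$I, n2$I)
})

test_that("simulated trace dwell times follow the kinetic model", {
  km <- kinetic_model(0.25, 87, 2.26, 13, 3.64e6, 3e-9)
  trs <- simulate_smtirf_traces(km, n_traces = 200, n_frames = 4000,
                                label_efficiency = 1, dimer_fraction = 0,
                                noise = noise_spec(seed = 2))
  ev <- do.call(rbind, lapply(trs, `[[`, "events"))
  expect_gt(nrow(ev), 300)
  # mixture mean of recorded durations, conditioned on the >= 1 frame
  # cut (memoryless: E[d | d > c] = c + tau, weights reweighted by the
  # survival at the cut)
  cut <- 1 / 20
  s1 <- exp(-cut / 0.25); s2 <- exp(-cut / 2.26)
  w1 <- 0.87 * s1 / (0.87 * s1 + 0.13 * s2)
  mix_mean <- w1 * (cut + 0.25) + (1 - w1) * (cut + 2.26)
  expect_equal(mean(ev$duration_s), mix_mean, tolerance = 0.1)
  # all-monomer, full labelling: all plateaus at 1 dye unit
  expect_true(all(ev$n_dyes == 1))
  trs2 <- simulate_smtirf_traces(km, n_traces = 2, n_frames = 1000,
                                 noise = noise_spec(seed = 2))
  trs3 <- simulate_smtirf_traces(km, n_traces = 2, n_frames = 1000,
                                 noise = noise_spec(seed = 2))
  expect_identical(trs2[[1]]$intensity, trs3[[1]]$intensity)
})

test_that("simulated ITC heats honour forced and degenerate limits", {
  ex <- titration_experiment()
  z <- simulate_itc(ex, N = 0.98, Kd = 176e-9, dH = 0,
                    noise = noise_spec(itc_frac = 0))
  expect_true(all(z$heats_ucal == 0))
  z2 <- simulate_itc(ex, N = 0.98, Kd = 176e-9, dH = -1e4,
                     noise = noise_spec(itc_frac = 0))
  expect_equal(z2$heats_ucal,
               one_set_of_sites_heat(ex, 0.98, 176e-9, -1e4))
  # stoichiometric limit: constant heats until molar ratio N, then ~ 0
  zs <- one_set_of_sites_heat(ex, N = 1, Kd = 1e-12, dH = -1e4)
  mr <- molar_ratio(ex)
  pre <- zs[mr < 0.85]
  post <- zs[mr > 1.15]
  expect_lt(diff(range(pre)) / abs(mean(pre)), 0.05)
  expect_lt(max(abs(post)) / abs(mean(pre)), 0.02)
})
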