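test_that("Debye calculator limits: single bead, two-bead q->0, I(0)=N^2", {
  q <- seq(0.005, 0.5, length.out = 40)
  one <- debye_profile(matrix(0, 1, 3), q, bead_width = 0)
  expect_equal(one$I, rep(1, 40))
  two <- debye_profile(rbind(c(0, 0, 0), c(0, 0, 3.8)),
                       c(1e-5, q), bead_width = 0)
  expect_equal(two$I[1], 4, tolerance = 1e-4)
})

test_that("Debye profile is invariant under rotation/translation and bead order", {
  m <- default_core()
  q <- seq(0.01, 0.4, length.out = 30)
  base <- debye_profile(m$xyz, q)
  R <- random_rotation(11)
  moved <- debye_profile(sweep(m$xyz %*% t(R), 2, c(5, 6, -7), "+"), q)
  shuffled <- debye_profile(m$xyz[rev(seq_len(nrow(m$xyz))), ], q)
  expect_equal(moved$I, base$I, tolerance = 1e-4)
  expect_equal(shuffled$I, base$I, tolerance = 1e-12)
})

test_that("Guinier fit recovers exact Gaussian parameters and sphere Rg", {
  q <- default_q_grid()
  exact <- scattering_profile(q, 7 * exp(-q^2 * 50^2 / 3))
  gu <- guinier_fit(exact)
  expect_equal(gu$Rg, 50, tolerance = 1e-6)
  expect_equal(gu$I0, 7, tolerance = 1e-6)
  expect_lte(gu$qmaxRg, 1.3)
  # Debye profile of a uniform sphere: Guinier Rg within 2% of coordinate Rg
  x <- sphere_beads(n = 2000, R = 50)
  pr <- debye_profile(x, q)
  expect_equal(guinier_fit(pr)$Rg, radius_of_gyration(x), tolerance = 0.02)
})

test_that("rod Guinier recovers the exact cross-section radius", {
  q <- default_q_grid()
  prof <- scattering_profile(q, exp(-q^2 * 20^2 / 2) / q)
  expect_equal(rod_guinier_fit(prof, Rg_hint = 80)$Rgc, 20, tolerance = 1e-6)
})

test_that("rod Guinier matches the cross-section second moment of a bead cylinder", {
  # solid cylinder of beads with Gaussian width w: the cross-section second
  # moment gives Rgc^2 = R^2/2 + 2 w^2 (form-factor smearing included)
  R <- 14; L <- 420; w <- 3
  xyz <- with_seed(9, {
    n <- 4000
    r <- R * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    cbind(runif(n, -L / 2, L / 2), r * cos(th), r * sin(th))
  })
  pr <- debye_profile(xyz, default_q_grid(), bead_width = w)
  fit <- rod_guinier_fit(pr, Rg_hint = radius_of_gyration(xyz))
  expect_equal(fit$Rgc, sqrt(R^2 / 2 + 2 * w^2), tolerance = 0.05)
})

test_that("dimensionless Kratky peaks at (sqrt(3), 1.104) for Guinier-exact profiles", {
  q <- default_q_grid()
  for (Rg in c(30, 80)) {
    prof <- scattering_profile(q, 5 * exp(-q^2 * Rg^2 / 3))
    gu <- guinier_fit(prof)
    kr <- dimensionless_kratky(prof, gu)
    expect_equal(kr$peak_x, sqrt(3), tolerance = 1e-3)
    expect_equal(kr$peak_y, 3 / exp(1), tolerance = 1e-3)
    expect_true(kr$globular_like)
    # scaling invariance
    kr2 <- dimensionless_kratky(
      scattering_profile(q, 13 * prof$I),
      guinier_fit(scattering_profile(q, 13 * prof$I)))
    expect_equal(kr2$curve$y, kr$curve$y, tolerance = 1e-9)
  }
})

test_that("flexible-chain-like profile shows no globular Kratky peak", {
  # Debye chain form factor: I(x) = 2 (exp(-x) - 1 + x) / x^2, x = (q Rg)^2
  q <- default_q_grid()
  Rg <- 60
  x <- (q * Rg)^2
  prof <- scattering_profile(q, 2 * (exp(-x) - 1 + x) / x^2)
  gu <- guinier_fit(prof)
  kr <- dimensionless_kratky(prof, gu)
  y <- kr$curve$y[kr$curve$x <= 1.2 / 1] # low-x region
  expect_false(kr$globular_like)
  # monotonically rising through the globular-peak region
  reg <- kr$curve$y[kr$curve$x > 0.5 & kr$curve$x < 3]
  expect_true(all(diff(reg) > 0))
})

test_that("P(r) inversion of a sphere peaks where the closed form peaks", {
  # closed-form sphere p(r) maximum at r ~ 0.525 * Dmax
  x <- sphere_beads(n = 2000, R = 50)
  pr <- debye_profile(x, default_q_grid())
  pz <- pofr_invert(pr, Dmax = 100)
  # tolerance allows the finite-bead smearing shift of the maximum
  expect_equal(pz$r[which.max(pz$p)], 0.525 * 100, tolerance = 0.07)
  expect_equal(pz$Rg, radius_of_gyration(x), tolerance = 0.02)
  # back-transform self-consistency
  expect_lte(pz$chi2, 1.5)
  # derived I0 consistent with the q->0 limit within 1%
  expect_equal(pz$I0, 2000^2, tolerance = 0.01)
})

test_that("P(r) invariants hold: endpoints zero, positive mass", {
  pz <- pofr_invert(core_profile(), Dmax = 410)
  expect_equal(pz$p[1], 0)
  expect_equal(pz$p[length(pz$p)], 0)
  expect_gt(sum(pz$p) * (pz$r[2] - pz$r[1]), 0)
  expect_lte(pz$chi2, 1.5)
})

test_that("Dmax scan recovers the support of a sphere within one grid step", {
  x <- sphere_beads(n = 2000, R = 50)
  pr <- debye_profile(x, default_q_grid())
  dm <- select_dmax(pr)
  expect_lte(abs(dm$Dmax - 100), 10)
})

test_that("model-based p(r): forced peak, dumbbell bimodality, Rg oracle", {
  two <- rbind(c(0, 0, 0), c(100, 0, 0))
  pz <- pofr_from_model(two, bead_width = 3)
  expect_equal(pz$r[which.max(pz$p)], 100, tolerance = 0.02)
  # compact dumbbell (no outward arms): clean bimodal pair distribution
  m <- build_dumbbell_dimer(dimer_template(module_radius = 20,
                                           module_arm = 0))
  pm <- pofr_from_model(m)
  sm <- stats::filter(pm$p, rep(1 / 9, 9), sides = 2)
  far <- pm$r > 100 & pm$r < 220 & !is.na(sm)
  pk_far <- pm$r[far][which.max(sm[far])]
  expect_equal(pk_far, 160, tolerance = 0.08)
  # local maximum, i.e. genuinely bimodal
  near <- pm$r < 100 & !is.na(sm)
  valley <- pm$p[pm$r > 100 & pm$r < 140]
  expect_gt(max(sm[near]), max(sm[far]))
  expect_lt(min(valley), 0.8 * max(sm[far]))
  expect_equal(pm$Rg, radius_of_gyration(m), tolerance = 0.02)
})

test_that("chi2 fit recovers identity and affine transforms, and calibrates noise", {
  q <- seq(0.005, 0.1, length.out = 60)
  I <- 1e5 * exp(-q^2 * 40^2 / 3)
  sg <- 0.01 * I
  expy <- scattering_profile(q, I, sg)
  calc <- scattering_profile(q, I)
  f0 <- chi2_fit(calc, expy)
  expect_equal(f0$scale, 1, tolerance = 1e-9)
  expect_equal(f0$offset, 0, tolerance = 1e-6)
  expect_equal(f0$chi2, 0, tolerance = 1e-12)
  f1 <- chi2_fit(scattering_profile(q, (I - 10) / 3), expy)
  expect_equal(f1$scale, 3, tolerance = 1e-9)
  expect_equal(f1$offset, 10, tolerance = 1e-6)
  # chi2 ~ 1 under correctly-specified noise (averaged over replicates)
  chis <- with_seed(21, vapply(1:40, function(i) {
    chi2_fit(calc, scattering_profile(q, I + rnorm(60, 0, sg), sg))$chi2
  }, 0))
  expect_equal(mean(chis), 1, tolerance = 0.2)
})

test_that("dat IO round-trips and rejects empty files", {
  pr <- scattering_profile(seq(0.01, 0.3, 0.01), exp(-seq(0.01, 0.3, 0.01)),
                           rep(0.01, 30))
  f <- tempfile(fileext = ".dat")
  write_saxs_dat(pr, f)
  pr2 <- read_saxs_dat(f)
  expect_equal(pr2$q, pr$q)
  expect_equal(pr2$I, pr$I, tolerance = 1e-6)
  expect_equal(pr2$sigma, pr$sigma, tolerance = 1e-6)
  bad <- tempfile(fileext = ".dat")
  writeLines("# only a header", bad)
  expect_error(read_saxs_dat(bad), "format error")
})
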