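test_that("two beads with one spring give the analytic diatomic mode", {
  m <- toy_two_beads(d = 5, chains = c("A", "B"))
  net <- build_enm(m, cutoff = 12, linker_block_size = 1)
  expect_equal(length(net$springs$i), 1)
  # treat each bead as its own block: full-dimensional NMA
  m2 <- bead_model(m$xyz, m$chain, c("D1", "D2"),
                   rigid = c(D1 = TRUE, D2 = TRUE))
  md <- compute_modes(build_enm(m2, cutoff = 12), n_modes = 10)
  expect_equal(length(md$rigid_values), 5) # diatomic: 5 rigid freedoms
  expect_equal(md$values[1], 2, tolerance = 1e-9) # stretch mode, k = 1
})

test_that("connected networks have exactly six near-zero modes", {
  md <- compute_modes(build_enm(default_full()), n_modes = 20)
  expect_equal(length(md$rigid_values), 6)
  expect_lt(max(abs(md$rigid_values)), 1e-8 * max(md$all_values))
  expect_true(all(diff(md$values) >= -1e-12))
  expect_true(all(md$values > 0))
})

test_that("sub-cutoff networks are rejected as disconnected", {
  m <- toy_two_beads(d = 4.4)
  expect_error(build_enm(m, cutoff = 2), "disconnected")
})

test_that("RTB eigenvalues bound the all-bead eigenvalues from above", {
  # Rayleigh: restricting to the block subspace can only stiffen modes;
  # compact 50-bead random-walk chain vs a dense all-bead Hessian oracle
  xyz <- with_seed(31, {
    n <- 50
    st <- matrix(rnorm(n * 3), n, 3)
    st <- 3.8 * st / sqrt(rowSums(st^2))
    apply(st, 2, cumsum)
  })
  m <- bead_model(xyz, rep("A", 50), rep(c("D1", "D2"), each = 25),
                  rigid = c(D1 = TRUE, D2 = TRUE))
  cutoff <- 14
  net <- build_enm(m, cutoff = cutoff)
  md <- compute_modes(net, n_modes = 6)
  Hd <- dense_enm_hessian(m$xyz, cutoff)
  ev <- sort(eigen(Hd, symmetric = TRUE, only.values = TRUE)$values)
  ev_nonrigid <- ev[ev > 1e-8 * max(ev)]
  for (k in seq_len(md$n_modes)) {
    expect_gte(md$values[k] + 1e-10, ev_nonrigid[k])
  }
})

test_that("mode eigenvalues are invariant under rigid transformation", {
  m <- default_core()
  md1 <- compute_modes(build_enm(m), n_modes = 10)
  R <- random_rotation(13)
  m2 <- set_coords(m, sweep(m$xyz %*% t(R), 2, c(4, -2, 9), "+"))
  md2 <- compute_modes(build_enm(m2), n_modes = 10)
  expect_equal(md2$values, md1$values, tolerance = 1e-6)
})

test_that("nonlinear deformation is the identity at zero amplitude and rigid within blocks", {
  m <- default_full()
  md <- compute_modes(build_enm(m), n_modes = 10)
  d0 <- nonlinear_deform(m, md, 3, 0)
  expect_lt(max(abs(d0$xyz - m$xyz)), 1e-12)
  d1 <- nonlinear_deform(m, md, 3, 8)
  for (dom in c("RB1B2", "PHDBR")) {
    idx <- select_beads(m, domain = dom, chain = "A")[1:15]
    expect_lt(max(abs(dist(d1$xyz[idx, ]) - dist(m$xyz[idx, ]))), 1e-9)
  }
})

test_that("screw extrapolation deviates quadratically from the linear field", {
  m <- default_full()
  md <- compute_modes(build_enm(m), n_modes = 5)
  lin <- mode_displacement(md, m, 2)
  dev_at <- function(a) {
    d <- nonlinear_deform(m, md, 2, a)
    max(sqrt(rowSums((d$xyz - (m$xyz + a * lin))^2)))
  }
  a <- 4
  r <- dev_at(a) / dev_at(a / 2)
  expect_gt(r, 3.3)
  expect_lt(r, 4.7)
})

test_that("topology regularization restores stretched bonds and spares rigid blocks", {
  m <- default_full()
  ref <- m
  # model already matching the reference: unchanged
  m0 <- regularize_topology(m, ref)
  expect_lt(max(abs(m0$xyz - m$xyz)), 1e-6)
  # stretch one linker bond to 6 A
  li <- select_beads(m, domain = "LINKER", chain = "A")
  i <- li[100]
  xyz <- m$xyz
  u <- xyz[i + 1, ] - xyz[i, ]
  shift <- (6 / sqrt(sum(u^2)) - 1) * u
  xyz[(i + 1):nrow(xyz), ] <- sweep(xyz[(i + 1):nrow(xyz), , drop = FALSE],
                                    2, shift, "+")
  stretched <- set_coords(m, xyz)
  fixed <- regularize_topology(stretched, ref)
  dfix <- sqrt(sum((fixed$xyz[i + 1, ] - fixed$xyz[i, ])^2))
  expect_equal(dfix, 3.8, tolerance = 0.03)
  # rigid-domain internal geometry untouched
  idx <- select_beads(m, domain = "PHDBR", chain = "B")[1:12]
  expect_lt(max(abs(dist(fixed$xyz[idx, ]) - dist(stretched$xyz[idx, ]))),
            1e-9)
})
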