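sim_two_clouds <- function(n = 300, c1 = c(60, 120), sd = 6, seed = 2) {
  with_seed(seed, {
    half <- matrix(rnorm(n, mean = rep(c1, each = n / 2), sd = sd), n / 2, 2)
    swap <- half[sample(n / 2, n / 2 / 2), 2:1, drop = FALSE]
    rbind(half[seq_len(n / 2 / 2), ], swap,
          matrix(rnorm(n, mean = rep(c1, each = n / 2), sd = sd),
                 n / 2, 2))
  })
}

test_that("collective variables match construction and symmetry", {
  m <- default_full()
  cv <- compute_cvs(m)
  expect_equal(unname(cv), c(60, 120), tolerance = 0.02)
  # mirror-symmetric model: dA = dB exactly
  core <- default_core()
  xyzA <- core$xyz[core$chain == "A", ]
  # fabricate symmetric mobile domains by mirroring one shell
  tp <- dimer_template(dA = 80, dB = 80)
  ms <- build_full_dimer(tp, seed = 3)
  cvs <- compute_cvs(ms)
  expect_equal(unname(cvs[1]), unname(cvs[2]), tolerance = 0.02)
  expect_error(compute_cvs(core), "selection error")
})

test_that("relabeling protomers leaves the reported centre set unchanged", {
  m <- default_full()
  cv1 <- unname(compute_cvs(m))
  swapped <- bead_model(m$xyz,
                        chain = ifelse(m$chain == "A", "B", "A"),
                        domain = m$domain,
                        rigid = c(RB1B2 = TRUE, CC = TRUE, LINKER = FALSE,
                                  PHDBR = TRUE))
  # beads must be reordered so chains stay contiguous
  o <- order(match(swapped$chain, c("A", "B")))
  swapped <- bead_model(m$xyz[o, ], swapped$chain[o], m$domain[o],
                        rigid = c(RB1B2 = TRUE, CC = TRUE, LINKER = FALSE,
                                  PHDBR = TRUE))
  cv2 <- unname(compute_cvs(swapped))
  expect_equal(sort(cv1), sort(cv2), tolerance = 1e-9)
})

test_that("symmetrised mixture recovers well-separated cloud means", {
  pts <- sim_two_clouds()
  cl <- gaussian_cluster(pts, k = 2, seed = 1)
  got <- cl$centers[order(cl$centers[, 1]), ]
  expect_equal(got[1, ], c(60, 120), tolerance = 0.03,
               ignore_attr = TRUE)
  expect_equal(got[2, ], c(120, 60), tolerance = 0.03,
               ignore_attr = TRUE)
  # mirror components with near-equal weights
  expect_lt(cl$swap_symmetry_dev, 3)
  expect_equal(cl$weights[1], 0.5, tolerance = 0.02)
  # deterministic
  cl2 <- gaussian_cluster(pts, k = 2, seed = 1)
  expect_identical(cl$centers, cl2$centers)
})

test_that("independent mixture cross-check agrees with the symmetrised fit", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  pts <- sim_two_clouds(n = 400)
  xs <- rbind(pts, pts[, 2:1])
  mc <- mclust::Mclust(xs, G = 2, verbose = FALSE)
  ours <- gaussian_cluster(pts, k = 2, seed = 1)
  a <- ours$centers[order(ours$centers[, 1]), ]
  b <- t(mc$parameters$mean)[order(t(mc$parameters$mean)[, 1]), ]
  expect_equal(a, b, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("a single cloud fitted with k = 2 is flagged as overlapping", {
  pts <- with_seed(6, matrix(rnorm(400, mean = 90, sd = 8), 200, 2))
  cl <- gaussian_cluster(pts, k = 2, seed = 1)
  d <- sqrt(sum((cl$centers[1, ] - cl$centers[2, ])^2))
  cov_scale <- sqrt(mean(vapply(cl$covariances,
                                function(S) mean(diag(S)), 0)))
  expect_lt(d, 3 * cov_scale)
})

test_that("density levels are nested quantile sets ordered by Mahalanobis", {
  pts <- sim_two_clouds(n = 1000)
  cl <- gaussian_cluster(pts, k = 2, seed = 1)
  lv <- density_levels(cl, fractions = c(0.10, 0.5, 1.0), n_closest = 50)
  all10 <- unlist(lv$levels[["f0.1"]])
  all50 <- unlist(lv$levels[["f0.5"]])
  expect_true(all(all10 %in% all50))
  expect_equal(length(unlist(lv$levels[["f1"]])), nrow(pts))
  expect_equal(length(all10), 100, tolerance = 0.05)
  # members of the 10% level beat any non-member of the same component
  for (j in 1:2) {
    mem <- lv$levels[["f0.1"]][[j]]
    non <- setdiff(which(cl$assignments == j), mem)
    expect_lt(max(cl$mahalanobis[mem]), min(cl$mahalanobis[non]))
    expect_equal(length(lv$closest[[j]]), 50)
  }
})

test_that("1-D two-Gaussian fit separates planted modes and flags controls", {
  d <- with_seed(3, c(rnorm(400, 60, 5), rnorm(400, 120, 5)))
  fit <- density_1d(d)
  expect_true(fit$bimodal)
  expect_equal(fit$means[1], 60, tolerance = 2 / 60)
  expect_equal(fit$means[2], 120, tolerance = 2 / 120)
  # unimodal control: a forced two-component split of one Gaussian cannot
  # reach the bimodality separation (theoretical ceiling ~1.6)
  single <- with_seed(4, rnorm(500, 90, 10))
  fit1 <- density_1d(single)
  expect_false(fit1$bimodal)
  expect_lt(fit1$separation, 2)
  expect_false(fit1$bic_prefers_two)
})
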