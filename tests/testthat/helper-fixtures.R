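# shared fixtures, built once per test run

# small two-bead toy model
toy_two_beads <- function(d = 2, chains = c("A", "A")) {
  bead_model(rbind(c(0, 0, 0), c(d, 0, 0)), chain = chains,
             domain = c("D1", "D1"), rigid = c(D1 = TRUE))
}

# beads filling a solid sphere (deterministic given seed)
sphere_beads <- function(n = 1500, R = 50, seed = 42) {
  with_seed(seed, {
    x <- matrix(runif(3 * n * 3, -R, R), ncol = 3)
    x <- x[rowSums(x^2) < R^2, , drop = FALSE]
    while (nrow(x) < n) {
      y <- matrix(runif(3 * n, -R, R), ncol = 3)
      x <- rbind(x, y[rowSums(y^2) < R^2, , drop = FALSE])
    }
    x[seq_len(n), ]
  })
}

# cached default-template models (built lazily, reused across tests)
.fixture_env <- new.env()

default_core <- function() {
  if (is.null(.fixture_env$core)) {
    .fixture_env$core <- build_dumbbell_dimer(dimer_template())
  }
  .fixture_env$core
}

default_full <- function() {
  if (is.null(.fixture_env$full)) {
    .fixture_env$full <- build_full_dimer(dimer_template(), seed = 7)
  }
  .fixture_env$full
}

core_profile <- function() {
  if (is.null(.fixture_env$core_prof)) {
    .fixture_env$core_prof <- debye_profile(default_core(), default_q_grid())
  }
  .fixture_env$core_prof
}

# dense all-bead elastic-network Hessian, independent oracle for RTB tests
dense_enm_hessian <- function(xyz, cutoff, k = 1) {
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      u <- xyz[i, ] - xyz[j, ]
      d <- sqrt(sum(u^2))
      if (d > cutoff || d < 1e-12) next
      uu <- k * tcrossprod(u / d)
      ii <- 3 * (i - 1) + 1:3
      jj <- 3 * (j - 1) + 1:3
      H[ii, ii] <- H[ii, ii] + uu
      H[jj, jj] <- H[jj, jj] + uu
      H[ii, jj] <- H[ii, jj] - uu
      H[jj, ii] <- H[jj, ii] - uu
    }
  }
  H
}

random_rotation <- function(seed = 1) {
  with_seed(seed, {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}
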