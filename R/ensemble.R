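#' Collective variables of a fitted dimer model
#'
#' For each protomer, the distance between the centre of mass of its
#' C-terminal mobile domain and the centre of mass of the closest
#' N-terminal terminal module (either protomer's).
#'
#' @param model a [bead_model()].
#' @param mobile domain name of the mobile module (default "PHDBR").
#' @param anchor domain name of the terminal module (default "RB1B2").
#' @return named numeric c(dA, dB) in Angstrom.
#' @export
compute_cvs <- function(model, mobile = "PHDBR", anchor = "RB1B2") {
  chains <- sort(unique(model$chain))
  if (length(chains) != 2) stop("selection error: expected two protomers")
  anchors <- lapply(chains, function(ch)
    center_of_mass(model, domain = anchor, chain = ch))
  d <- vapply(chains, function(ch) {
    mcom <- center_of_mass(model, domain = mobile, chain = ch)
    min(vapply(anchors, function(a) sqrt(sum((mcom - a)^2)), 0))
  }, 0)
  names(d) <- c("dA", "dB")
  d
}

# deterministic farthest-point seeding for mixture initialisation
farthest_point_seeds <- function(x, k) {
  ctr <- colMeans(x)
  d0 <- rowSums(sweep(x, 2, ctr)^2)
  seeds <- which.max(d0)
  while (length(seeds) < k) {
    dmin <- apply(x, 1, function(p)
      min(colSums((t(x[seeds, , drop = FALSE]) - p)^2)))
    seeds <- c(seeds, which.max(dmin))
  }
  x[seeds, , drop = FALSE]
}

# full-covariance Gaussian mixture EM in d dimensions
gmm_em <- function(x, centers, max_iter = 300, tol = 1e-8,
                   cov_floor = NULL) {
  n <- nrow(x); d <- ncol(x); k <- nrow(centers)
  if (is.null(cov_floor)) cov_floor <- 1e-6 * mean(apply(x, 2, var))
  mu <- centers
  S <- lapply(seq_len(k), function(j) diag(apply(x, 2, var), d))
  w <- rep(1 / k, k)
  ll_old <- -Inf
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- sapply(seq_len(k), function(j) {
      Sj <- S[[j]]
      ch <- tryCatch(chol(Sj), error = function(e) NULL)
      if (is.null(ch)) {
        Sj <- Sj + cov_floor * diag(d)
        ch <- chol(Sj)
        floored <<- TRUE
      }
      z <- forwardsolve(t(ch), t(sweep(x, 2, mu[j, ])))
      exp(-0.5 * colSums(z^2)) / ((2 * pi)^(d / 2) * prod(diag(ch)))
    })
    num <- sweep(dens, 2, w, "*")
    tot <- rowSums(num) + 1e-300
    ll <- sum(log(tot))
    g <- num / tot
    nk <- colSums(g)
    w <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(g[, j] * x) / nk[j]
      xc <- sweep(x, 2, mu[j, ])
      Sj <- crossprod(xc * sqrt(g[, j])) / nk[j]
      ev <- eigen(Sj, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < cov_floor) {
        Sj <- Sj + (cov_floor - min(ev)) * diag(d)
        floored <- TRUE
      }
      S[[j]] <- Sj
    }
    if (abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(mu = mu, S = S, w = w, loglik = ll, responsibilities = g,
       floored = floored)
}

#' Symmetry-aware Gaussian clustering of (dA, dB) points
#'
#' The two protomers of a homodimer are interchangeable, so the point set
#' is symmetrised (each point plus its swap image) before a full-covariance
#' Gaussian-mixture fit with deterministic farthest-point seeding; the
#' fitted centres form a mirror pair. Each original point is assigned to
#' the component with the highest responsibility and annotated with its
#' Mahalanobis distance.
#'
#' @param points n x 2 matrix or data.frame of (dA, dB).
#' @param k number of components (default 2).
#' @param seed RNG seed (the fit is deterministic; the seed is recorded).
#' @return object of class `cluster_result`: centers, covariances, weights,
#'   assignments, mahalanobis, swap-symmetry deviation, loglik.
#' @export
gaussian_cluster <- function(points, k = 2, seed = 1) {
  x <- as.matrix(points)
  if (nrow(x) < 10) stop("need at least 10 points")
  stopifnot(ncol(x) == 2, k >= 1)
  xs <- rbind(x, x[, 2:1, drop = FALSE])
  ctrs <- farthest_point_seeds(xs, k)
  fit <- gmm_em(xs, ctrs)
  if (fit$floored) warning("singular covariance regularised with floor")
  # responsibilities of the original points only
  g <- fit$responsibilities[seq_len(nrow(x)), , drop = FALSE]
  assign <- max.col(g)
  maha <- vapply(seq_len(nrow(x)), function(i) {
    j <- assign[i]
    v <- x[i, ] - fit$mu[j, ]
    sqrt(drop(v %*% solve(fit$S[[j]], v)))
  }, 0)
  # swap-symmetry diagnostic: distance between the centre set and its mirror
  mirror <- fit$mu[, 2:1, drop = FALSE]
  swap_dev <- max(apply(fit$mu, 1, function(m)
    min(sqrt(rowSums(sweep(mirror, 2, m)^2)))))
  structure(list(centers = fit$mu, covariances = fit$S, weights = fit$w,
                 assignments = assign, mahalanobis = maha,
                 swap_symmetry_dev = swap_dev, loglik = fit$loglik,
                 seed = seed, points = x),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("gaussian clusters (symmetrised):\n")
  for (j in seq_len(nrow(x$centers))) {
    cat(sprintf("  center %d: (%.1f, %.1f) A, weight %.2f\n", j,
                x$centers[j, 1], x$centers[j, 2], x$weights[j]))
  }
  invisible(x)
}

#' BIC sweep over mixture sizes
#' @param points n x 2 matrix of (dA, dB).
#' @param k_max largest mixture size tried (default 4).
#' @return data.frame with k, loglik, bic.
#' @export
cluster_bic_sweep <- function(points, k_max = 4) {
  x <- as.matrix(points)
  xs <- rbind(x, x[, 2:1, drop = FALSE])
  out <- lapply(seq_len(k_max), function(k) {
    fit <- gmm_em(xs, farthest_point_seeds(xs, k))
    npar <- k * (2 + 3) + (k - 1)
    data.frame(k = k, loglik = fit$loglik,
               bic = -2 * fit$loglik + npar * log(nrow(xs)))
  })
  do.call(rbind, out)
}

#' Nested density-level membership sets
#'
#' For each fraction f, the members of each component whose Mahalanobis
#' distance lies within the f-quantile of that component's members
#' (nested by construction). `n_closest` additionally returns the n models
#' closest to each centre.
#'
#' @param cluster_result a [gaussian_cluster()] result.
#' @param fractions density levels (default 0.10).
#' @param n_closest optional count for closest-model sets.
#' @return list `levels` (per fraction, per component index vectors) and
#'   optionally `closest`.
#' @export
density_levels <- function(cluster_result, fractions = 0.10,
                           n_closest = NULL) {
  cr <- cluster_result
  k <- nrow(cr$centers)
  levels <- lapply(fractions, function(f) {
    lapply(seq_len(k), function(j) {
      idx <- which(cr$assignments == j)
      if (length(idx) == 0) return(integer())
      cut <- quantile(cr$mahalanobis[idx], probs = f, type = 1)
      idx[cr$mahalanobis[idx] <= cut]
    })
  })
  names(levels) <- paste0("f", fractions)
  out <- list(levels = levels)
  if (!is.null(n_closest)) {
    out$closest <- lapply(seq_len(k), function(j) {
      idx <- which(cr$assignments == j)
      idx[order(cr$mahalanobis[idx])][seq_len(min(n_closest, length(idx)))]
    })
  }
  out
}

em_1d_once <- function(d, mu, sdv = NULL, w = c(0.5, 0.5)) {
  if (is.null(sdv)) sdv <- rep(sd(d) / 2, 2)
  for (it in 1:500) {
    r1 <- w[1] * stats::dnorm(d, mu[1], sdv[1])
    r2 <- w[2] * stats::dnorm(d, mu[2], sdv[2])
    tot <- r1 + r2
    if (any(!is.finite(tot)) || all(tot == 0)) return(NULL)
    g <- r2 / (tot + 1e-300)
    w <- c(mean(1 - g), mean(g))
    if (min(w) < 1e-6) return(NULL)
    mu_new <- c(sum((1 - g) * d) / sum(1 - g), sum(g * d) / sum(g))
    sd_new <- pmax(c(sqrt(sum((1 - g) * (d - mu_new[1])^2) / sum(1 - g)),
                     sqrt(sum(g * (d - mu_new[2])^2) / sum(g))),
                   1e-3 * sd(d))
    done <- max(abs(mu_new - mu)) < 1e-10
    mu <- mu_new; sdv <- sd_new
    if (done) break
  }
  ll <- sum(log(w[1] * stats::dnorm(d, mu[1], sdv[1]) +
                  w[2] * stats::dnorm(d, mu[2], sdv[2]) + 1e-300))
  list(mu = mu, sdv = sdv, w = w, loglik = ll)
}

#' Two-Gaussian fit of pooled 1-D distances
#'
#' Maximum-likelihood two-component 1-D normal mixture of the pooled
#' per-protomer distances (multi-start EM, best likelihood kept), with a
#' separation statistic |mu1 - mu2| / pooled sd. The distribution is
#' flagged bimodal when the separation reaches 2; a forced split of a
#' genuinely unimodal Gaussian cannot exceed ~1.6. A BIC comparison
#' against a single Gaussian is reported as a diagnostic. Falls back to a
#' single Gaussian (flagged) on non-convergence or degeneracy.
#'
#' @param distances numeric vector (>= 20 values).
#' @return list with means, sds, weights, separation, bimodal flag,
#'   bic_prefers_two diagnostic, converged flag.
#' @export
density_1d <- function(distances) {
  d <- distances[is.finite(distances)]
  if (length(d) < 20) stop("need at least 20 distances")
  qs <- quantile(d, c(0.1, 0.25, 0.5, 0.75, 0.9))
  inits <- list(c(qs[[2]], qs[[4]]), c(qs[[1]], qs[[5]]),
                c(mean(d[d <= qs[[3]]]), mean(d[d > qs[[3]]])))
  best <- NULL
  for (ini in inits) {
    fit <- em_1d_once(d, ini)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(list(means = mean(d), sds = sd(d), weights = 1, separation = 0,
                bimodal = FALSE, bic_prefers_two = FALSE,
                converged = FALSE))
  }
  o <- order(best$mu)
  mu <- best$mu[o]; sdv <- best$sdv[o]; w <- best$w[o]
  sd1 <- sqrt(mean((d - mean(d))^2))
  ll1 <- sum(stats::dnorm(d, mean(d), sd1, log = TRUE))
  n <- length(d)
  bic2_wins <- (-2 * best$loglik + 5 * log(n)) < (-2 * ll1 + 2 * log(n))
  pooled <- sqrt(sum(w * sdv^2))
  sep <- abs(diff(mu)) / pooled
  list(means = mu, sds = sdv, weights = w, separation = sep,
       bimodal = sep >= 2, bic_prefers_two = bic2_wins, converged = TRUE)
}

#' Write collective variables and cluster assignments as CSV
#' @param cvs matrix/data.frame with columns dA, dB (one row per model).
#' @param cluster_result matching [gaussian_cluster()] result.
#' @param path output path.
#' @export
write_cvs_csv <- function(cvs, cluster_result, path) {
  write.csv(data.frame(model_id = seq_len(nrow(cvs)),
                       dA = cvs[, 1], dB = cvs[, 2],
                       component = cluster_result$assignments,
                       mahalanobis = cluster_result$mahalanobis),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
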