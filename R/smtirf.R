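#' Detect binding events in a fluorescence trace
#'
#' Robust hysteresis thresholding: baseline = median, high threshold =
#' baseline + k_mad * MAD, low threshold = baseline + low_k * MAD.
#' Candidate events are contiguous runs above the low threshold; a
#' candidate qualifies when it contains at least `min_frames` frames above
#' the high threshold. The two-level rule keeps event boundaries stable
#' under changes of k_mad (event counts are monotone non-increasing in
#' k_mad) and heals single-frame dips. Intervals touching the trace
#' boundaries are flagged as truncated.
#'
#' @param trace a list with `time_s` and `intensity` (uniform sampling).
#' @param k_mad high (qualification) threshold factor (default 3).
#' @param min_frames minimum number of supra-high-threshold frames
#'   (default 2).
#' @param low_k low (boundary) threshold factor (default 1.5).
#' @return object of class `event_list`: data.frames `bright` and `dark`
#'   with duration_s, mean_intensity (bright), truncated flag; plus
#'   threshold and frame interval.
#' @export
detect_events <- function(trace, k_mad = 3, min_frames = 2, low_k = 1.5) {
  y <- trace$intensity
  if (length(y) < 100) stop("trace too short (< 100 frames)")
  dt <- trace$time_s[2] - trace$time_s[1]
  base <- median(y)
  s <- mad(y)
  if (s == 0) {
    warning("zero MAD: constant trace, no events")
    s <- Inf
  }
  thr <- base + k_mad * s
  low <- base + min(low_k, k_mad) * s
  r <- rle(y > low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  bright <- cand[vapply(cand, function(i)
    sum(y[starts[i]:ends[i]] > thr) >= min_frames, TRUE)]
  bseg <- data.frame(start = starts[bright], end = ends[bright])
  if (nrow(bseg) > 0) {
    bright_df <- data.frame(
      t_on_s = (bseg$start - 1) * dt,
      duration_s = (bseg$end - bseg$start + 1) * dt,
      frames = bseg$end - bseg$start + 1,
      mean_intensity = vapply(seq_len(nrow(bseg)), function(i)
        mean(y[bseg$start[i]:bseg$end[i]]) - base, 0),
      truncated = bseg$start == 1 | bseg$end == length(y))
  } else {
    bright_df <- data.frame(t_on_s = numeric(), duration_s = numeric(),
                            frames = integer(), mean_intensity = numeric(),
                            truncated = logical())
  }
  # dark intervals between consecutive bright events (and the flanks)
  bounds <- rbind(c(0, 0), cbind(bseg$start, bseg$end),
                  c(length(y) + 1, length(y) + 1))
  dark_df <- do.call(rbind, lapply(seq_len(nrow(bounds) - 1), function(i) {
    a <- bounds[i, 2] + 1
    b <- bounds[i + 1, 1] - 1
    if (b < a) return(NULL)
    data.frame(duration_s = (b - a + 1) * dt,
               truncated = a == 1 | b == length(y))
  }))
  if (is.null(dark_df)) {
    dark_df <- data.frame(duration_s = numeric(), truncated = logical())
  }
  structure(list(bright = bright_df, dark = dark_df, threshold = thr,
                 baseline = base, dt = dt),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("events: %d bright, %d dark (threshold %.3g)\n",
              nrow(x$bright), nrow(x$dark), x$threshold))
  invisible(x)
}

pool_durations <- function(event_lists, which = c("bright", "dark")) {
  which <- match.arg(which)
  if (inherits(event_lists, "event_list")) event_lists <- list(event_lists)
  d <- unlist(lapply(event_lists, function(e) {
    df <- e[[which]]
    df$duration_s[!df$truncated]
  }))
  d[is.finite(d) & d > 0]
}

#' Cumulative survival histogram of dwell times
#'
#' Empirical survival function 1 - CDF of the pooled (non-truncated)
#' durations, evaluated at the unique observed durations.
#'
#' @param event_lists one `event_list` or a list of them.
#' @param which "bright" or "dark" intervals.
#' @return data.frame with t_s and survival (starts at 1, non-increasing).
#' @export
dwell_histograms <- function(event_lists, which = c("bright", "dark")) {
  d <- pool_durations(event_lists, which)
  if (length(d) < 30) stop("need at least 30 pooled intervals")
  t <- sort(unique(d))
  n <- length(d)
  surv <- vapply(t, function(tt) sum(d >= tt) / n, 0)
  data.frame(t_s = t, survival = surv)
}

# weighted least-squares double-exponential survival fit; amplitudes
# constrained to sum to 1 via a logistic share. The time axis is measured
# from the shortest recordable dwell (one frame): durations below one
# frame are censored by acquisition, so the empirical survival is 1 at the
# first observable duration, not at t = 0.
fit_biexp_survival <- function(t, s, tau1_0, tau2_0, a1_0 = 0.8) {
  dat <- data.frame(t = t, s = s)
  w <- rep(1, length(t))
  ft <- minpack.lm::nlsLM(
    s ~ plogis(la1) * exp(-t / exp(lt1)) +
      (1 - plogis(la1)) * exp(-t / exp(lt2)),
    data = dat, weights = w,
    start = list(la1 = qlogis(min(max(a1_0, 0.05), 0.95)),
                 lt1 = log(tau1_0), lt2 = log(tau2_0)),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- coef(ft)
  tau <- exp(c(cf[["lt1"]], cf[["lt2"]]))
  a <- c(plogis(cf[["la1"]]), 1 - plogis(cf[["la1"]]))
  if (tau[1] > tau[2]) { tau <- rev(tau); a <- rev(a) }
  list(tau1 = tau[1], A1 = a[1], tau2 = tau[2], A2 = a[2],
       rss = sum(residuals(ft)^2))
}

fit_monoexp_survival <- function(t, s) {
  ft <- minpack.lm::nlsLM(s ~ exp(-t / exp(lt)), data = data.frame(t = t,
                                                                   s = s),
                          start = list(lt = log(max(mean(t), 1e-6))),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
  tau <- exp(coef(ft)[["lt"]])
  ss <- exp(-t / tau)
  r2 <- 1 - sum((s - ss)^2) / sum((s - mean(s))^2)
  list(tau = tau, r2 = r2, rss = sum((s - ss)^2))
}

#' Fit dissociation kinetics to a bright-time survival curve
#'
#' Least squares of A1 exp(-t/tau1) + A2 exp(-t/tau2) with A1 + A2 = 1 and
#' tau1 < tau2 by convention; uncertainties by bootstrap over intervals.
#' Falls back to (and flags) a mono-exponential fit when the two time
#' constants are not separated (tau2/tau1 < 2) or the slow amplitude is not
#' significant.
#'
#' @param durations pooled bright durations in seconds (alternatively an
#'   `event_list` list, from which bright durations are pooled).
#' @param n_boot bootstrap replicates (default 100; 0 disables).
#' @return object of class `dissociation_fit`: tau_off_1_s, A1_pct,
#'   tau_off_2_s, A2_pct, mono flag, n, bootstrap quantiles (boot, a matrix
#'   of 2.5/97.5 percent quantiles) when requested.
#' @export
fit_dissociation <- function(durations, n_boot = 100) {
  if (!is.numeric(durations)) durations <- pool_durations(durations, "bright")
  d <- durations[is.finite(durations) & durations > 0]
  if (length(d) < 30) stop("need at least 30 dwell times")
  fit_once <- function(dd) {
    t <- sort(unique(dd)) - min(dd) # time from the censoring cut
    s <- vapply(sort(unique(dd)), function(tt) sum(dd >= tt) / length(dd), 0)
    m <- mean(dd)
    bi <- try(fit_biexp_survival(t, s, tau1_0 = 0.5 * m, tau2_0 = 4 * m),
              silent = TRUE)
    if (inherits(bi, "try-error")) {
      mono <- fit_monoexp_survival(t, s)
      return(c(tau1 = mono$tau, A1 = 1, tau2 = mono$tau, A2 = 0, mono = 1))
    }
    c(tau1 = bi$tau1, A1 = bi$A1, tau2 = bi$tau2, A2 = bi$A2, mono = 0)
  }
  est <- fit_once(d)
  boot <- NULL
  a2_lo <- NA_real_
  if (n_boot > 0) {
    bs <- vapply(seq_len(n_boot), function(b) {
      fit_once(sample(d, replace = TRUE))
    }, numeric(5))
    boot <- apply(bs[1:4, , drop = FALSE], 1, quantile,
                  probs = c(0.025, 0.975))
    a2_lo <- boot[1, "A2"]
  }
  mono <- est[["mono"]] == 1 || est[["tau2"]] / est[["tau1"]] < 2 ||
    (!is.na(a2_lo) && a2_lo <= 0.001)
  if (mono && est[["mono"]] == 0) {
    t <- sort(unique(d)) - min(d)
    s <- vapply(sort(unique(d)), function(tt) sum(d >= tt) / length(d), 0)
    mf <- fit_monoexp_survival(t, s)
    est <- c(tau1 = mf$tau, A1 = 1, tau2 = mf$tau, A2 = 0, mono = 1)
  }
  structure(list(tau_off_1_s = est[["tau1"]], A1_pct = 100 * est[["A1"]],
                 tau_off_2_s = est[["tau2"]], A2_pct = 100 * est[["A2"]],
                 mono = mono, n = length(d), boot = boot),
            class = "dissociation_fit")
}

#' @export
print.dissociation_fit <- function(x, ...) {
  if (x$mono) {
    cat(sprintf("dissociation: mono-exponential, tau = %.3f s (n = %d)\n",
                x$tau_off_1_s, x$n))
  } else {
    cat(sprintf(
      "dissociation: tau1 = %.3f s (%.0f%%), tau2 = %.2f s (%.0f%%), n = %d\n",
      x$tau_off_1_s, x$A1_pct, x$tau_off_2_s, x$A2_pct, x$n))
  }
  invisible(x)
}

#' Fit association kinetics to dark-time dwell times
#'
#' Mono-exponential survival fit of the dark times gives tau_dark;
#' k_on = 1 / (tau_dark * concentration).
#'
#' @param durations pooled dark durations in seconds (or event lists).
#' @param concentration fluorescent-ligand concentration in M.
#' @return list with k_on_per_M_s, tau_dark_s, r2, n; warns when the
#'   mono-exponential fit is poor (R^2 < 0.9).
#' @export
fit_association <- function(durations, concentration) {
  stopifnot(concentration > 0)
  if (!is.numeric(durations)) durations <- pool_durations(durations, "dark")
  d <- durations[is.finite(durations) & durations > 0]
  if (length(d) < 30) stop("need at least 30 dark times")
  t <- sort(unique(d)) - min(d) # time from the censoring cut
  s <- vapply(sort(unique(d)), function(tt) sum(d >= tt) / length(d), 0)
  mf <- fit_monoexp_survival(t, s)
  if (mf$r2 < 0.9) warning("poor mono-exponential fit (R^2 < 0.9)")
  list(k_on_per_M_s = 1 / (mf$tau * concentration), tau_dark_s = mf$tau,
       r2 = mf$r2, n = length(d))
}

#' Oligomer quantification from per-event intensities
#'
#' Fits a two-Gaussian mixture to normalised per-event intensities at the
#' 1x and 2x dye levels, reports the observed 2-dye fraction, and inverts
#' the binomial labelling model to an inferred true dimer fraction: with
#' labelling probability p, a visible dimer shows two dyes with probability
#' p/(2 - p) relative to one dye, so
#' f_dimer = F2 / (p - F2 (1 - p)) for observed 2-dye fraction F2.
#'
#' @param event_lists event lists with per-event mean intensities (or a
#'   numeric vector of intensities).
#' @param label_efficiency dye labelling probability p (0 < p <= 1).
#' @return list with observed_2dye_fraction, inferred_dimer_fraction,
#'   component means/sds/weights, n, and a `resolved` flag (FALSE when the
#'   two intensity levels could not be separated; inferred fraction NA).
#' @export
intensity_oligomers <- function(event_lists, label_efficiency = 0.6) {
  stopifnot(label_efficiency > 0, label_efficiency <= 1)
  x <- if (is.numeric(event_lists)) event_lists else {
    if (inherits(event_lists, "event_list")) event_lists <- list(event_lists)
    unlist(lapply(event_lists, function(e)
      e$bright$mean_intensity[!e$bright$truncated]))
  }
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 30) stop("need at least 30 event intensities")
  # normalise by the dominant (1-dye) level: histogram mode
  dens <- stats::density(x, n = 512)
  lvl1 <- dens$x[which.max(dens$y)]
  z <- x / lvl1
  # 1-D EM with means anchored near 1 and 2
  mu <- c(1, 2); sdv <- c(0.25, 0.25); w <- c(0.9, 0.1)
  for (it in 1:200) {
    r1 <- w[1] * stats::dnorm(z, mu[1], sdv[1])
    r2 <- w[2] * stats::dnorm(z, mu[2], sdv[2])
    tot <- r1 + r2 + 1e-300
    g <- r2 / tot
    w_new <- c(mean(1 - g), mean(g))
    mu_new <- c(sum((1 - g) * z) / sum(1 - g), sum(g * z) / sum(g))
    sd_new <- c(sqrt(sum((1 - g) * (z - mu_new[1])^2) / sum(1 - g)),
                sqrt(sum(g * (z - mu_new[2])^2) / sum(g)))
    sd_new <- pmax(sd_new, 0.05)
    if (max(abs(mu_new - mu), abs(w_new - w)) < 1e-8) break
    mu <- mu_new; sdv <- sd_new; w <- w_new
  }
  resolved <- is.finite(mu[2]) && (mu[2] - mu[1]) > 2 * max(sdv) &&
    w[2] > 1e-4
  F2 <- w[2]
  p <- label_efficiency
  inferred <- if (resolved) F2 / (p - F2 * (1 - p)) else NA_real_
  list(observed_2dye_fraction = if (resolved) F2 else NA_real_,
       inferred_dimer_fraction = inferred,
       means = mu * lvl1, sds = sdv * lvl1, weights = w,
       level1 = lvl1, n = length(x), resolved = resolved)
}

#' Write traces as two-column CSV files
#' @param traces list of traces from [simulate_smtirf_traces()].
#' @param dir output directory.
#' @return the file paths.
#' @export
write_traces_csv <- function(traces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(traces))
  for (i in seq_along(traces)) {
    paths[i] <- file.path(dir, sprintf("trace_%04d.csv", i))
    write.csv(data.frame(time_s = traces[[i]]$time_s,
                         intensity = traces[[i]]$intensity),
              paths[i], row.names = FALSE, quote = FALSE)
  }
  paths
}

#' Read a two-column trace CSV
#' @param path CSV with columns time_s, intensity.
#' @return a trace list.
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  list(time_s = d$time_s, intensity = d$intensity, metadata = list(
    source = path))
}
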