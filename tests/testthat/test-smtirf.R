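ref_km <- function(row = 1, conc = 3e-9) {
  tab <- hp1_kinetics_reference()
  kinetic_model(tab$tau_off1_s[row], tab$A1_pct[row], tab$tau_off2_s[row],
                tab$A2_pct[row], tab$k_on_1e6[row] * 1e6, conc)
}

test_that("event detection recovers a noiseless square wave exactly", {
  n <- 400
  y <- rep(0, n)
  starts <- c(50, 150, 300)
  for (s in starts) y[s:(s + 9)] <- 1
  y <- y + 1e-4 * sin(seq_len(n)) # avoid a literally zero MAD
  tr <- list(time_s = (seq_len(n) - 1) / 20, intensity = y)
  ev <- detect_events(tr)
  expect_equal(nrow(ev$bright), 3)
  expect_true(all(ev$bright$frames == 10))
  expect_true(all(abs(ev$bright$mean_intensity - 1) < 0.01))
  expect_false(any(ev$bright$truncated))
  # dark intervals tile the rest of the trace
  expect_equal(sum(ev$bright$frames) + sum(ev$dark$duration_s) * 20, n)
})

test_that("events at moderate noise match the simulator's ground truth", {
  km <- ref_km()
  trs <- simulate_smtirf_traces(km, n_traces = 40, n_frames = 5000,
                                label_efficiency = 1, dimer_fraction = 0,
                                noise = noise_spec(trace_sd = 0.2, seed = 6))
  hits <- 0; total <- 0
  for (tr in trs) {
    truth <- tr$events[tr$events$frames >= 3, , drop = FALSE]
    if (nrow(truth) == 0) next
    ev <- detect_events(tr)
    for (i in seq_len(nrow(truth))) {
      total <- total + 1
      match <- which(abs(ev$bright$t_on_s - truth$t_on_s[i]) <= 0.1)
      if (length(match) > 0 &&
          any(abs(ev$bright$frames[match] - truth$frames[i]) <= 1)) {
        hits <- hits + 1
      }
    }
  }
  expect_gt(total, 50)
  expect_gte(hits / total, 0.95)
})

test_that("pure-noise traces yield almost no events and thresholds are monotone", {
  false_pos <- with_seed(14, vapply(1:400, function(i) {
    tr <- list(time_s = (1:2000) / 20, intensity = rnorm(2000, 0, 0.2))
    nrow(detect_events(tr)$bright)
  }, 0))
  expect_gte(mean(false_pos == 0), 0.99)
  # raising k_mad never increases the event count
  km <- ref_km()
  trs <- simulate_smtirf_traces(km, n_traces = 5, n_frames = 5000,
                                noise = noise_spec(seed = 9))
  for (tr in trs) {
    n_by_k <- vapply(c(2, 3, 4, 6), function(k)
      nrow(detect_events(tr, k_mad = k)$bright), 0)
    expect_true(all(diff(n_by_k) <= 0))
  }
})

test_that("survival histograms are proper survival functions", {
  d <- c(1, 2, 3)
  ev <- list(bright = data.frame(duration_s = rep(d, 12),
                                 truncated = FALSE),
             dark = data.frame(duration_s = rep(d, 12), truncated = FALSE))
  class(ev) <- "event_list"
  h <- dwell_histograms(ev, "bright")
  expect_equal(h$survival[1], 1)
  expect_equal(h$survival[h$t_s == 2.5], numeric(0)) # only observed times
  expect_equal(h$survival[h$t_s == 3], 1 / 3)
  expect_true(all(diff(h$survival) <= 0))
  # exponential sample: log-survival approximately linear
  d2 <- with_seed(4, rexp(1000, 2))
  ev2 <- list(bright = data.frame(duration_s = d2, truncated = FALSE),
              dark = data.frame(duration_s = numeric(),
                                truncated = logical()))
  class(ev2) <- "event_list"
  h2 <- dwell_histograms(ev2, "bright")
  keep <- h2$survival > 0.01
  r2 <- summary(lm(log(h2$survival[keep]) ~ h2$t_s[keep]))$r.squared
  expect_gt(r2, 0.95)
})

test_that("double-exponential fit recovers mixture parameters from 5000 dwells", {
  km <- ref_km()
  d <- simulate_bright_dwells(km, 5000, seed = 3)
  fit <- fit_dissociation(d, n_boot = 60)
  expect_false(fit$mono)
  expect_equal(fit$tau_off_1_s, 0.25, tolerance = 0.1)
  expect_equal(fit$tau_off_2_s, 2.26, tolerance = 0.2)
  expect_equal(fit$A1_pct, 87, tolerance = 0.06)
  # generating values inside the bootstrap intervals
  expect_true(fit$boot[1, "tau1"] <= 0.25 && 0.25 <= fit$boot[2, "tau1"])
  expect_true(fit$boot[1, "tau2"] <= 2.26 * 1.1 &&
                2.26 * 0.9 <= fit$boot[2, "tau2"])
})

test_that("mono-exponential samples fall back to a flagged mono fit", {
  d <- with_seed(10, {
    x <- rexp(2000, 1 / 0.25)
    floor(x * 20)[floor(x * 20) >= 1] / 20
  })
  fit <- fit_dissociation(d, n_boot = 30)
  expect_true(fit$mono)
  expect_equal(fit$tau_off_1_s, 0.25, tolerance = 0.1)
})

test_that("association fit inverts tau_dark at known concentration", {
  km <- ref_km()
  d <- simulate_dark_dwells(km, 2000, seed = 5)
  fit <- fit_association(d, concentration = 3e-9)
  expect_equal(fit$k_on_per_M_s, 3.64e6, tolerance = 0.15)
  # arithmetic inversion at the exact tau
  expect_equal(1 / (91.6 * 3e-9) / 1e6, 3.64, tolerance = 0.01)
  # doubling concentration halves tau_dark at fixed k_on
  km2 <- kinetic_model(km$tau_off1, km$A1_pct, km$tau_off2, km$A2_pct,
                       km$k_on, 6e-9)
  d2 <- simulate_dark_dwells(km2, 2000, seed = 5)
  expect_equal(mean(d2) / mean(d), 0.5, tolerance = 0.1)
})

test_that("intensity analysis infers the planted dimer fraction", {
  km <- ref_km()
  trs <- simulate_smtirf_traces(km, n_traces = 150, n_frames = 5000,
                                label_efficiency = 0.6, dimer_fraction = 0.4,
                                noise = noise_spec(trace_sd = 0.15,
                                                   seed = 12))
  evs <- lapply(trs, detect_events)
  res <- intensity_oligomers(evs, label_efficiency = 0.6)
  expect_true(res$resolved)
  expect_equal(res$inferred_dimer_fraction, 0.4, tolerance = 0.15)
  # all-monomer control with full labelling: no 2-dye observations
  trs0 <- simulate_smtirf_traces(km, n_traces = 60, n_frames = 5000,
                                 label_efficiency = 1, dimer_fraction = 0,
                                 noise = noise_spec(trace_sd = 0.15,
                                                    seed = 13))
  res0 <- intensity_oligomers(lapply(trs0, detect_events),
                              label_efficiency = 1)
  obs0 <- if (res0$resolved) res0$observed_2dye_fraction else 0
  expect_lt(obs0, 0.03)
})

test_that("more dimers raise the observed 2-dye fraction (co-factor direction)", {
  km <- ref_km()
  frac2 <- vapply(c(0.14, 0.45), function(fd) {
    trs <- simulate_smtirf_traces(km, n_traces = 120, n_frames = 4000,
                                  label_efficiency = 0.6,
                                  dimer_fraction = fd,
                                  noise = noise_spec(trace_sd = 0.15,
                                                     seed = 15))
    res <- intensity_oligomers(lapply(trs, detect_events), 0.6)
    res$observed_2dye_fraction
  }, 0)
  expect_gt(frac2[2], frac2[1])
})
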