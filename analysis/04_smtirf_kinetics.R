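#!/usr/bin/env Rscript
# Single-molecule dwell-time analysis: simulate binding/unbinding
# processes at each reference co-factor concentration, re-fit the
# cumulative dwell-time histograms, and tabulate the recovered kinetic
# parameters next to the generating values. Also reproduces the
# oligomer-state readout from normalised event intensities.

suppressPackageStartupMessages(library(flexdimer))
dir.create("results", showWarnings = FALSE)

ref <- hp1_kinetics_reference()
conc <- 3e-9
rows <- list()
for (i in seq_len(nrow(ref))) {
  km <- kinetic_model(ref$tau_off1_s[i], ref$A1_pct[i], ref$tau_off2_s[i],
                      ref$A2_pct[i], ref$k_on_1e6[i] * 1e6, conc)
  bright <- simulate_bright_dwells(km, 5000, seed = 100 + i)
  dark <- simulate_dark_dwells(km, 2000, seed = 200 + i)
  fit <- fit_dissociation(bright, n_boot = 0)
  assoc <- fit_association(dark, conc)
  rows[[i]] <- data.frame(
    kap1_nM = ref$kap1_nM[i],
    tau1_in = ref$tau_off1_s[i], tau1_fit = fit$tau_off_1_s,
    A1_in = ref$A1_pct[i], A1_fit = fit$A1_pct,
    tau2_in = ref$tau_off2_s[i], tau2_fit = fit$tau_off_2_s,
    kon_in_1e6 = ref$k_on_1e6[i], kon_fit_1e6 = assoc$k_on_per_M_s / 1e6)
}
tab <- do.call(rbind, rows)
print(tab, digits = 3)
write.csv(tab, "results/smtirf_recovery.csv", row.names = FALSE)

# oligomer quantification at 60% labelling: a co-factor that stabilises
# dimers raises the observed 2-dye fraction
km0 <- kinetic_model(ref$tau_off1_s[1], ref$A1_pct[1], ref$tau_off2_s[1],
                     ref$A2_pct[1], ref$k_on_1e6[1] * 1e6, conc)
olig <- lapply(c(no_cofactor = 0.14, with_cofactor = 0.45), function(fd) {
  trs <- simulate_smtirf_traces(km0, n_traces = 150, n_frames = 5000,
                                label_efficiency = 0.6, dimer_fraction = fd,
                                noise = noise_spec(trace_sd = 0.15,
                                                   seed = 31))
  intensity_oligomers(lapply(trs, detect_events), 0.6)
})
cat(sprintf("\nobserved 2-dye fraction: %.0f%% (monomer-rich) -> %.0f%% (dimer-stabilised)\n",
            100 * olig$no_cofactor$observed_2dye_fraction,
            100 * olig$with_cofactor$observed_2dye_fraction))
cat(sprintf("inferred dimer fractions: %.2f and %.2f (planted 0.14 / 0.45)\n",
            olig$no_cofactor$inferred_dimer_fraction,
            olig$with_cofactor$inferred_dimer_fraction))
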