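#!/usr/bin/env Rscript
# Negative controls for the asymmetry readout: imposing both mobile
# domains adjacent to the terminal modules, or both fully extended, must
# fit the asymmetric-truth scattering data far worse than the free fit.

suppressPackageStartupMessages(library(flexdimer))
dir.create("results", showWarnings = FALSE)

tp <- dimer_template() # planted (60, 120)
target <- simulate_saxs_ensemble(tp, default_q_grid(81),
                                 noise_spec(seed = 2))

chi2_truth <- constrained_placement_chi2(tp, tp$dA, tp$dB, target, seed = 5)
chi2_close <- constrained_placement_chi2(tp, 20, 20, target, seed = 5)
chi2_ext <- constrained_placement_chi2(tp, 140, 140, target, seed = 5)

tab <- data.frame(
  placement = c("planted (60, 120)", "both adjacent (20, 20)",
                "both extended (140, 140)"),
  chi2 = c(chi2_truth, chi2_close, chi2_ext))
print(tab, digits = 3)
write.csv(tab, "results/negative_controls.csv", row.names = FALSE)

cat(sprintf("\nsymmetric-close / truth chi2 ratio: %.0fx\n",
            chi2_close / chi2_truth))
cat(sprintf("symmetric-extended / truth chi2 ratio: %.0fx\n",
            chi2_ext / chi2_truth))
cat("Both symmetric placements are rejected outright; only the\n")
cat("asymmetric arrangement is compatible with the scattering data.\n")
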