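#!/usr/bin/env Rscript
# Flexible-fitting recovery of a planted asymmetric architecture.
# 50 randomised starting models (mobile domains placed up to 140 A from
# the core) are fitted to the ensemble-averaged scattering profile of a
# dimer with planted displacements (60, 120) A, then clustered in the
# (dA, dB) collective-variable plane. Desk scale: ~15 min on one CPU.

suppressPackageStartupMessages(library(flexdimer))
dir.create("results", showWarnings = FALSE)

cfg <- pipeline_config(seed = 1)
res <- run_asymmetry_pipeline(cfg, out_dir = "results/asymmetry",
                              verbose = TRUE)

cat("\nplanted displacements:", res$truth$dA, res$truth$dB, "A\n")
cat("fits converged (chi2 <= 1.5):", sum(res$converged), "of",
    nrow(res$cvs_all), "\n")
cat("final chi2, converged subset: median",
    round(median(res$ensemble$chi2_final[res$converged]), 2), "\n")
print(res$clusters)
cat("pooled 1-D distance mixture: means",
    paste(round(res$density_1d$means, 1), collapse = " / "),
    "A, separation", round(res$density_1d$separation, 2),
    if (res$density_1d$bimodal) "(bimodal)" else "(not bimodal)", "\n")
cat(sprintf("Rg: starts %.1f +/- %.1f A -> fitted %.1f +/- %.1f A\n",
            mean(res$ensemble$rg_init), sd(res$ensemble$rg_init),
            mean(res$ensemble$rg_final), sd(res$ensemble$rg_final)))
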