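# flexdimer

Integrative modelling of elongated, flexible multidomain protein dimers in
solution. The motivating system is a transcription-regulator dimer whose
antiparallel coiled-coil core carries a compact module at each end while
two C-terminal modules hang from ~200-residue disordered linkers: small-
angle X-ray scattering (SAXS) shows where those mobile modules sit, and
single-molecule plus calorimetric measurements show what that placement
does to partner binding.

The package implements the complete analysis chain:

* **Model-free SAXS** — Guinier fits (Rg from the slope of ln I vs q²,
  window bounded by q·Rg ≤ 1.3), cross-section ("rod") Guinier fits
  (ln(qI) vs q², Rgc = √(−2·slope)), dimensionless Kratky classification
  (globular particles peak at (√3, 1.104)), and a regularised indirect
  Fourier transform P(r) with automatic maximum-dimension (Dmax)
  selection.
* **Normal-mode flexible fitting** — coarse-grained bead models (one bead
  per residue), an elastic network with rotations-translations-of-blocks
  (RTB) projection, nonlinear screw deformations along the 60 slowest
  modes, and a greedy χ²-minimising loop against a target profile
  (Debye calculator with Gaussian bead form factors, closed-form
  scale/offset χ²).
* **Conformational-ensemble clustering** — per-protomer collective
  variables (dA, dB): the distance from each mobile module to its nearest
  core module; swap-symmetrised Gaussian-mixture clustering with
  Mahalanobis density levels and a pooled 1-D two-Gaussian readout.
* **Single-molecule TIRF kinetics** — hysteresis event detection in
  fluorescence traces, cumulative dwell-time survival histograms,
  double-exponential dissociation fits (τ_off,1, A1, τ_off,2, A2),
  association rates (k_on = 1/(τ_dark·c)), and intensity-based oligomer
  quantification under partial dye labelling.
* **ITC** — the one-set-of-sites binding model with displaced-volume
  dilution bookkeeping, Levenberg–Marquardt fitting of (N, Kd, ΔH), and
  ΔG = −RT ln Ka thermodynamics (R = 1.98 cal mol⁻¹ K⁻¹).
* **Synthetic data for everything** — a geometry generator that plants
  known mobile-module displacements, ensemble-averaged noisy scattering
  profiles, fluorescence traces with ground-truth event lists, and noisy
  isotherms, so the whole pipeline is testable end to end.

## Worked example

Simulate dwell times from the reference kinetics of a chromatin-binding
protein at 3 nM, and re-fit them exactly as measured traces would be:

```r
library(flexdimer)

ref <- hp1_kinetics_reference()[1, ]      # no co-factor condition
km  <- kinetic_model(ref$tau_off1_s, ref$A1_pct, ref$tau_off2_s,
                     ref$A2_pct, ref$k_on_1e6 * 1e6, 3e-9)

bright <- simulate_bright_dwells(km, 5000, frame_rate = 20, seed = 1)
fit_dissociation(bright, n_boot = 0)
#> dissociation: tau1 = 0.251 s (85%), tau2 = 2.29 s (15%), n = 5000

dark <- simulate_dark_dwells(km, 2000, frame_rate = 20, seed = 2)
fit_association(dark, concentration = 3e-9)$k_on_per_M_s / 1e6
#> [1] 3.64
```

The fast residence time (0.251 s vs 0.25 s planted), slow residence time
(2.29 s vs 2.26 s) and association rate (3.64 × 10⁶ M⁻¹s⁻¹) come back
within sampling error: the dwell-time machinery is unbiased despite the
20 Hz frame discretisation.

The structural pipeline runs the same way from a single call:

```r
res <- run_asymmetry_pipeline(pipeline_config(seed = 1))
res$clusters      # mirror-pair (dA, dB) cluster centres
res$density_1d    # pooled 1-D two-Gaussian fit of the distances
```

which generates a planted asymmetric dimer (displacements 60 and 120 Å),
simulates its ensemble-averaged scattering profile, flexibly fits 50
randomised starting models and clusters the fitted (dA, dB) ensemble
(~15 min on one CPU at the default desk scale).

## Analysis scripts

The `analysis/` directory holds numbered drivers that reproduce the
package's headline analyses and write tables under `results/`:

| script | what it does |
| --- | --- |
| `01_model_free_saxs.R` | model-free SAXS table for the synthetic core and full-length constructs |
| `02_flexfit_asymmetry.R` | 50-start flexible-fitting asymmetry recovery + clustering |
| `03_negative_controls.R` | imposed symmetric placements vs the asymmetric truth |
| `04_smtirf_kinetics.R` | dwell-time parameter recovery at five co-factor concentrations |
| `05_itc_binding.R` | 100-replicate isotherm refits (Kd, N recovery) |

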