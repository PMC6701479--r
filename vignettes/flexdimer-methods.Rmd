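---
title: "Methods: SAXS flexible fitting and single-molecule analysis of flexible dimers"
author: "flexdimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAXS flexible fitting and single-molecule analysis of flexible dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`flexdimer` characterises elongated, flexible multidomain protein dimers in
solution. Its motivating system is a transcriptional-regulator dimer built
from an antiparallel coiled-coil core with compact N-terminal modules at
both ends and two C-terminal modules tethered by ~200-residue disordered
linkers. The package covers four experimental readouts end to end:

1. model-free SAXS analysis (Guinier, cross-section Guinier, dimensionless
   Kratky, regularised P(r) inversion with automatic Dmax selection);
2. chi-square-minimising flexible fitting of coarse-grained bead models to
   scattering profiles, driven by elastic-network normal modes;
3. single-molecule TIRF dwell-time kinetics and intensity-based oligomer
   quantification;
4. one-set-of-sites isothermal titration calorimetry.

Every input can be generated synthetically with planted ground truth, so
the full pipeline is testable without any external data.

# Coarse-grained representation

Structures are one bead per residue at the C-alpha position with uniform
unit mass (`bead_model`). Each bead belongs to one protomer (chain) and
one named domain; domains carry a rigid flag. Pseudo-bonds connect
consecutive beads (ideal length 3.8 Å) and a model is *topologically
valid* when every bond is below 4.5 Å. Residue ranges are 0-based and
half-open everywhere; all lengths are in Ångström. Domain labels live in a
CSV sidecar next to the CA-only PDB because the PDB format has no domain
column.

# The synthetic dimer

`dimer_template()` encodes the study conditions:

* terminal-module centres of mass exactly 160 Å apart (the length of the
  antiparallel coiled coil);
* each terminal module is a spherical-shell head (radius 32 Å) with a thin
  arm extending 100 Å outward, so the tip-to-tip dimension is ~370-400 Å;
* the coiled-coil path of each protomer runs out and back (a four-helix
  bundle-like core), so each chain's C-terminal exit sits next to its own
  terminal module;
* per protomer, a 200-residue random-coil linker tethers a compact
  ~190-bead mobile module (shell radius 15 Å) whose centre of mass is
  planted at distance dA (protomer A) or dB (protomer B) from its
  proximal terminal module — defaults (60, 120) Å;
* `randomize_termini()` re-places the mobile modules uniformly within
  D = 140 Å of their anchors with uniform random rotations, regrowing the
  linkers.

The head/arm radii were calibrated once, by construction, against the
printed solution dimensions of the motivating system (Guinier Rg ≈ 83 Å
and cross-section Rgc ≈ 20 Å for the core construct, Dmax ≈ 370 Å,
full-length Rg ≈ 90 Å); they are geometry choices, not fit results. The
mobile-module bead budget (190) matches the residue count of the real
C-terminal domain — an earlier 40-bead stand-in under-weighted the
domain's scattering mass five-fold and made its placement nearly
invisible in the profile.

Linkers grow as Brownian bridges: each 3.8 Å step is a random direction
biased toward the far anchor in proportion to the remaining contour
length, with rejection of self-clashes below 2 Å. Free (unbridged) chains
reproduce ideal-chain statistics (RMS end-to-end b·sqrt(n)).

# Scattering

`debye_profile()` implements the classical Debye sum with a Gaussian
dummy-bead form factor f(q) = exp(-(q·w)²/2), w = 3 Å by default. The
double sum is evaluated through a pair-distance histogram (0.5 Å bins;
relative error O((q·bin)²/24)), and on uniform q grids the sine terms use
a rotation recurrence, giving ~1 ms evaluations for ~1300 beads. There is
no hydration shell or excluded-volume term: absolute chi-square values
against real data will differ from full-featured calculators, but the
pipeline's logic does not depend on that.

Model-free analyses follow standard practice:

* **Guinier**: ln I vs q², window expanded from 8 points while
  qmax·Rg ≤ 1.3 and a runs test on the residuals passes at 5%.
* **Cross-section (rod) Guinier**: ln(qI) vs q² beyond q·Rg > 2, with the
  upper bound iterated to self-consistency (qmax·Rgc ≤ 1.3). Note that
  the Gaussian bead width enters the apparent cross section:
  Rgc² = R²/2 + 2w² for a solid bead cylinder of radius R.
* **Dimensionless Kratky**: (qRg)²·I/I0 vs qRg with parabolic sub-grid
  peak interpolation; globular particles peak at (sqrt(3), 3/e = 1.104).
* **P(r) inversion** (`pofr_invert`): regularised least squares on a
  201-point r grid with second-difference smoothing and clamped endpoints
  p(0) = p(Dmax) = 0. The smoothing weight is chosen by a
  quasi-discrepancy rule — the largest weight whose residual stays within
  10% of the best achievable — which is stabler than an L-curve corner on
  noise-free synthetic profiles. When a profile carries no uncertainties,
  sigma defaults to 1% of I.
* **Dmax selection** (`select_dmax`): scan from 2·Rg to 5·Rg in 10 Å
  steps; accept the smallest Dmax whose inversion has a negative-lobe
  fraction below 1%, a monotone terminal 5% of p(r), and a chi-square
  within 2x (+0.5) of the scan's best. The last condition rejects
  truncated supports whose over-smoothed inversion is positive yet no
  longer fits the data.

`chi2_fit()` uses closed-form weighted least squares for a scale and a
constant offset, reduced by N - 2; profiles are resampled by linear
interpolation in q (sigma in quadrature) when grids differ.

# Normal-mode flexible fitting

`build_enm()` connects all bead pairs within 12 Å with uniform springs at
their current lengths. The normal modes come from a
rotations-translations-of-blocks (RTB) projection: each rigid domain is
one block; linker beads are grouped into 5-residue mini-segments (40
hinge points per 200-residue linker). Per-residue linker blocks would
give a ~1240-dimensional dense eigenproblem re-solved every iteration;
5-residue segments keep the coil's freedom while making the eigenproblem
~20x cheaper, which is what lets the desk-scale ensemble run finish in
minutes. Per-block mass matrices are diagonalised and near-null
directions (single-bead or collinear blocks) dropped before a standard
symmetric eigensolve, so the six global rigid-body modes always come out
at numerically zero eigenvalues and the non-rigid modes are
mass-orthonormal.

Mode vectors are stored as per-block instantaneous screws (translation
plus angular velocity about the block centre of mass).
`nonlinear_deform()` integrates the screw exactly: rotation by
amplitude·|omega| about the mode axis through the screw centre plus the
pitch translation. Rigid-block internal geometry is preserved to machine
precision and the motion deviates from the linearised field only at
second order in the amplitude.

`flexfit()` runs the optimisation loop: per iteration it rebuilds the
network, computes the 60 slowest modes, sweeps nonlinear trial
deformations along every mode over a geometric amplitude grid
{±w·2^k, k = 0..4} (w scaled per mode so the largest trial moves the most
mobile block ~8 Å), screens the trials with a stride-4 bead subsample of
the Debye calculator, re-evaluates the best few candidates at full
resolution, restores local topology toward the starting structure by
steepest descent on bond/angle restraints (rigid domains moving only as
rigid bodies), and accepts one move per iteration only if the
full-resolution chi-square strictly decreases; accepted amplitudes are
extended geometrically while the chi-square keeps dropping. Moves that
would disconnect the elastic network are rejected. The loop stops early
after five consecutive iterations without a meaningful improvement. The
8 Å amplitude target (rather than a more conservative ~5 Å) was set
because the mobile domains start up to ~140 Å from their fitted
positions: with 40-iteration budgets, smaller steps cannot cover the
travel and fits stall short of the data.

# The synthetic target is an ensemble average

A SAXS measurement averages over the conformational ensemble in the beam.
A single frozen linker conformation used as the fitting target imprints
coil-specific detail that a real profile does not carry — and, as the
package's own landscape analysis shows, lets clearly wrong domain
placements fit as well as the truth. `simulate_saxs_ensemble()` therefore
averages the Debye profiles of 12 replicas of the planted dimer (same
placements, independent linkers) before adding noise. Noise is Gaussian
with sigma(q) = a·sqrt(I(q)·I(0)) — a counting-statistics shape — with
a = 0.01 by default, which makes the reduced chi-square of the generative
truth against its own noisy profile equal 1 in expectation.

# Collective variables and clustering

For each protomer, `compute_cvs()` measures the distance between the
centre of mass of its mobile C-terminal module and that of the *closest*
terminal module. Because the protomers of a homodimer are
interchangeable, the fitted (dA, dB) points are symmetrised (each point
plus its swap image) before a full-covariance two-component Gaussian
mixture fit with deterministic farthest-point seeding
(`gaussian_cluster`); the reported centres form a mirror pair and a BIC
sweep over k is available but not used for headline outputs. Density
levels (`density_levels`) are Mahalanobis quantile sets per component;
`density_1d()` fits a two-component 1-D mixture to the pooled distances
and reports a separation statistic, falling back to a single Gaussian
when BIC prefers it. Only fits that converged (final chi-square at or
below 1.5, the same bar used for the headline ensembles) enter the
clustered ensemble; models that never reached the data are not part of
the structural solution.

# Single-molecule kinetics

`simulate_smtirf_traces()` generates alternating dark/bright renewal
processes at 20 Hz: dark durations are exponential with rate
k_on·[ligand]; bright durations come from a double-exponential mixture
(fast/slow residence times with percentage amplitudes); binders are
dimers with a set probability, each subunit labelled independently, and
unlabelled arrivals stay invisible. Durations are drawn in continuous
time and floored to the frame grid; sub-frame events are dropped, as in
real acquisition.

`detect_events()` uses robust hysteresis thresholding: baseline = median,
high threshold = baseline + 3·MAD, low threshold = baseline + 1.5·MAD.
Candidate events are runs above the low threshold; they qualify when they
contain at least two frames above the high threshold. The two-level rule
keeps boundaries stable (event counts are monotone non-increasing in the
high threshold) and heals single-frame dips.

Dwell-time fitting works on the empirical survival function of the
pooled, non-truncated durations. Because sub-frame events are censored,
the time axis is measured from the shortest recordable dwell (one frame);
this removes the discretisation bias exactly for exponential mixtures
(the survival of floored data evaluated at frame multiples equals the
continuous survival). The double-exponential fit constrains the
amplitudes to sum to one, orders tau1 < tau2, bootstraps uncertainties
over intervals, and falls back to a flagged mono-exponential when the
time constants are not separated (tau2/tau1 < 2) or the slow amplitude is
not significant. `fit_association()` inverts the mono-exponential dark
time: k_on = 1/(tau_dark·concentration).

`intensity_oligomers()` fits a two-Gaussian mixture to normalised
per-event intensities at the 1x and 2x dye levels and inverts the
binomial labelling model: with labelling probability p, a visible dimer
shows two dyes with probability p/(2 - p) relative to one, so the true
dimer fraction is F2/(p - F2·(1 - p)) for an observed 2-dye fraction F2.

# Isothermal titration calorimetry

`one_set_of_sites_heat()` advances the cell composition injection by
injection under the displaced-volume convention (each injection expels an
equal volume of the pre-injection average), solves the single-site
quadratic equilibrium, and converts bound-concentration increments to
microcalories with the standard displaced-material correction. The
default experiment is 19 x 2 µl of 170 µM titrant into 300 µl of 15 µM
macromolecule at 298.15 K. `fit_itc()` fits (N, Kd, dH) by
Levenberg-Marquardt least squares (Kd on a log scale) and derives
dG = -RT·ln(1/Kd) and dS via R = 1.98 cal mol⁻¹ K⁻¹. Baseline
subtraction from the final injections is available but off by default:
this titration ends at molar ratio ~1.5, well short of saturation, so a
tail-estimated line removes genuine binding heat (it biases Kd by ~3x on
ideal data), and simulated isotherms carry no dilution heat to remove.

# Problem sizes, determinism and limitations

The headline ensemble run uses 50 randomised starts, 40 iterations and 60
modes on a ~1280-bead dimer with an 81-point q grid — a deliberate
desk-scale setting that finishes in roughly a quarter of an hour on one
CPU; publication-scale settings (1000 starts, 100 iterations) are a
configuration change only. All generators take explicit seeds, record
them in their outputs, and restore the caller's RNG state; identical
seeds reproduce results bit for bit.

What passing the synthetic tests does *not* show: the generator's uniform
bead masses, Gaussian form factor and shell-like domains are a coarse
stand-in for atomic contrast — absolute chi-squares and fine placement
sensitivity on real data will differ; dye photophysics beyond a single
on/off level (blinking, stepwise bleaching) are not modelled; the
identifiability of the two collective variables from a single noisy
profile is limited to a diagonal valley around the true placements, so
cluster centres carry a few tens of percent of spread at desk-scale
ensemble sizes even when the optimisation is exact.
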