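#' Isothermal titration experiment
#'
#' Geometry, concentrations and (optionally) measured per-injection heats of
#' a single-cell ITC titration. Defaults match a standard small-cell
#' instrument run: 19 x 2 ul injections of 170 uM titrant into 300 ul of
#' 15 uM macromolecule at 25 C.
#'
#' @param cell_volume_ul working cell volume (default 300).
#' @param injection_volume_ul volume per injection (default 2).
#' @param n_injections number of injections (default 19).
#' @param cell_conc_M macromolecule concentration in the cell (default 15e-6).
#' @param syringe_conc_M titrant concentration in the syringe (default 170e-6).
#' @param temperature_K absolute temperature (default 298.15).
#' @param heats_ucal optional measured heats, length `n_injections`.
#' @return a `titration_experiment` list.
#' @export
titration_experiment <- function(cell_volume_ul = 300,
                                 injection_volume_ul = 2,
                                 n_injections = 19,
                                 cell_conc_M = 15e-6,
                                 syringe_conc_M = 170e-6,
                                 temperature_K = 298.15,
                                 heats_ucal = NULL) {
  stopifnot(cell_volume_ul > 0, injection_volume_ul > 0, n_injections >= 1,
            cell_conc_M > 0, syringe_conc_M > 0, temperature_K > 0)
  if (!is.null(heats_ucal) && length(heats_ucal) != n_injections) {
    stop("heats length must equal the injection count")
  }
  structure(list(cell_volume_ul = cell_volume_ul,
                 injection_volume_ul = injection_volume_ul,
                 n_injections = n_injections, cell_conc_M = cell_conc_M,
                 syringe_conc_M = syringe_conc_M,
                 temperature_K = temperature_K, heats_ucal = heats_ucal),
            class = "titration_experiment")
}

#' @export
print.titration_experiment <- function(x, ...) {
  cat(sprintf(
    "ITC: %d x %.1f ul of %.3g M into %.0f ul of %.3g M at %.2f K%s\n",
    x$n_injections, x$injection_volume_ul, x$syringe_conc_M,
    x$cell_volume_ul, x$cell_conc_M, x$temperature_K,
    if (is.null(x$heats_ucal)) " (no heats)" else ""))
  invisible(x)
}

#' Cumulative molar ratio after each injection
#' @param experiment a [titration_experiment()].
#' @return numeric vector (titrant over macromolecule, in-cell).
#' @export
molar_ratio <- function(experiment) {
  sol <- titration_concentrations(experiment)
  sol$Xt / sol$Mt
}

# in-cell total concentrations after each injection, displaced-volume
# convention: each injection expels an equal volume of the pre-injection
# average composition
titration_concentrations <- function(experiment) {
  V0 <- experiment$cell_volume_ul
  dV <- experiment$injection_volume_ul
  f <- 1 - dV / V0
  n <- experiment$n_injections
  Mt <- Xt <- numeric(n)
  m <- experiment$cell_conc_M
  x <- 0
  for (i in seq_len(n)) {
    m <- m * f
    x <- x * f + experiment$syringe_conc_M * dV / V0
    Mt[i] <- m
    Xt[i] <- x
  }
  list(Mt = Mt, Xt = Xt)
}

# equilibrium bound concentration for one class of independent sites
bound_conc <- function(Mt, Xt, N, Kd) {
  b <- N * Mt + Xt + Kd
  (b - sqrt(pmax(b * b - 4 * N * Mt * Xt, 0))) / 2
}

#' Per-injection heats of the one-set-of-sites model
#'
#' Sequential mass-balance solution: after each injection the total in-cell
#' concentrations follow the displaced-volume dilution scheme, the bound
#' concentration comes from the quadratic equilibrium solution, and the
#' injection heat is dH * Vcell * delta(bound) corrected for displaced
#' bound material.
#'
#' @param experiment a [titration_experiment()].
#' @param N sites per monomer.
#' @param Kd dissociation constant (M).
#' @param dH binding enthalpy (cal/mol).
#' @return per-injection heats in microcalories.
#' @export
one_set_of_sites_heat <- function(experiment, N, Kd, dH) {
  stopifnot(N > 0, Kd > 0)
  sol <- titration_concentrations(experiment)
  V0_L <- experiment$cell_volume_ul * 1e-6
  dV <- experiment$injection_volume_ul / experiment$cell_volume_ul
  Qcum <- dH * V0_L * bound_conc(sol$Mt, sol$Xt, N, Kd) * 1e6 # ucal
  Qprev <- c(0, head(Qcum, -1))
  Qcum - Qprev + dV * (Qcum + Qprev) / 2
}

#' Binding thermodynamics from Kd and dH
#'
#' dG = -R T ln(Ka) with R = 1.98 cal/(mol K) and Ka = 1/Kd;
#' dS = (dH - dG) / T.
#'
#' @param Kd dissociation constant (M).
#' @param dH binding enthalpy (cal/mol).
#' @param T_K absolute temperature (default 298.15).
#' @return list with dG_cal_mol and dS_cal_mol_K.
#' @export
thermodynamics <- function(Kd, dH, T_K = 298.15) {
  stopifnot(Kd > 0, T_K > 0)
  R <- 1.98 # cal / (mol K)
  dG <- -R * T_K * log(1 / Kd)
  list(dG_cal_mol = dG, dS_cal_mol_K = (dH - dG) / T_K)
}

#' Fit a one-set-of-sites binding model to an ITC isotherm
#'
#' Optionally, a straight-line heat-of-dilution baseline is estimated from
#' the last `n_baseline` injections (versus molar ratio) and subtracted,
#' then (N, Kd, dH) are fitted by nonlinear least squares; dG and dS
#' follow from the Gibbs relation.
#'
#' @param experiment a [titration_experiment()] with heats.
#' @param n_baseline injections used for the baseline line. Default 0 (no
#'   subtraction): simulated isotherms carry no dilution heat, and when
#'   the titration end-point is not fully saturated a tail-estimated
#'   baseline removes genuine binding heat. Set to ~3 for real data whose
#'   dilution heats need removing.
#' @param discard_first drop the first injection before fitting (common for
#'   real data; default FALSE).
#' @return object of class `binding_fit`: N, Kd_M, dH_cal_mol, dG_cal_mol,
#'   dS_cal_mol_K, baseline, fitted heats, rms residual, c_value and a
#'   `low_c` warning flag.
#' @export
fit_itc <- function(experiment, n_baseline = 0, discard_first = FALSE) {
  q <- experiment$heats_ucal
  if (is.null(q)) stop("experiment carries no heats")
  n <- experiment$n_injections
  mr <- molar_ratio(experiment)
  if (any(diff(mr) <= 0)) stop("non-monotone cumulative volume")
  keep <- seq_len(n)
  if (discard_first) keep <- keep[-1]
  if (length(keep) < 8) stop("need at least 8 informative injections")
  baseline <- c(intercept = 0, slope = 0)
  qb <- q
  if (n_baseline > 0) {
    tailidx <- (n - n_baseline + 1):n
    bl <- lm(q[tailidx] ~ mr[tailidx])
    baseline <- c(intercept = unname(coef(bl)[1]),
                  slope = unname(coef(bl)[2]))
    qb <- q - (baseline["intercept"] + baseline["slope"] * mr)
  }
  # starting values: dH from the initial plateau, N from the inflection
  dH0 <- sum(qb[1:3]) / 3 /
    (experiment$syringe_conc_M * experiment$injection_volume_ul * 1e-6 * 1e6)
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -1e4
  N0 <- mr[which.min(abs(cumsum(qb) - 0.5 * sum(qb)))]
  if (!is.finite(N0) || N0 <= 0) N0 <- 1
  dat <- data.frame(idx = keep, y = qb[keep])
  model_fun <- function(N, logKd, dH) {
    one_set_of_sites_heat(experiment, N, exp(logKd), dH)[dat$idx]
  }
  ft <- minpack.lm::nlsLM(
    y ~ model_fun(N, logKd, dH), data = dat,
    start = list(N = N0, logKd = log(1e-7), dH = dH0),
    lower = c(1e-3, log(1e-15), -1e8), upper = c(100, log(1), 1e8),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(ft)
  Kd <- exp(est[["logKd"]])
  td <- thermodynamics(Kd, est[["dH"]], experiment$temperature_K)
  cval <- est[["N"]] * experiment$cell_conc_M / Kd
  if (cval < 1) warning("low c-value: parameters poorly constrained")
  structure(list(N = est[["N"]], Kd_M = Kd, dH_cal_mol = est[["dH"]],
                 dG_cal_mol = td$dG_cal_mol, dS_cal_mol_K = td$dS_cal_mol_K,
                 baseline = baseline,
                 fitted_ucal = model_fun(est[["N"]], est[["logKd"]],
                                         est[["dH"]]),
                 rms_ucal = sqrt(mean(residuals(ft)^2)),
                 c_value = cval, low_c = cval < 1),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "one-set-of-sites fit: N = %.3f, Kd = %.3g M, dH = %.3g kcal/mol, dG = %.3g kcal/mol\n",
    x$N, x$Kd_M, x$dH_cal_mol / 1000, x$dG_cal_mol / 1000))
  invisible(x)
}

#' Write an ITC isotherm as CSV
#' @param experiment a [titration_experiment()] with heats.
#' @param path output path.
#' @export
write_itc_csv <- function(experiment, path) {
  write.csv(data.frame(injection = seq_len(experiment$n_injections),
                       volume_ul = experiment$injection_volume_ul,
                       cumulative_molar_ratio = molar_ratio(experiment),
                       heat_ucal = experiment$heats_ucal),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ITC isotherm CSV written by [write_itc_csv()]
#' @param path CSV path.
#' @param ... experiment-design fields passed to [titration_experiment()].
#' @return a [titration_experiment()].
#' @export
read_itc_csv <- function(path, ...) {
  d <- read.csv(path)
  titration_experiment(n_injections = nrow(d),
                       injection_volume_ul = d$volume_ul[1],
                       heats_ucal = d$heat_ucal, ...)
}
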