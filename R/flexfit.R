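#' Configuration for flexible fitting
#'
#' @param n_iter optimisation iterations (default 100).
#' @param n_modes slowest non-rigid modes per iteration (default 60).
#' @param n_amplitudes geometric amplitude-grid size per sign (default 5,
#'   giving trials w * 2^(0..4) in both signs).
#' @param max_step target displacement of the most mobile block for the
#'   largest trial amplitude, in Angstrom (default 8).
#' @param cutoff elastic-network cutoff (default 12).
#' @param linker_block_size flexible-segment size for the RTB projection
#'   (default 5 residues).
#' @param screen_stride bead subsampling stride for trial screening
#'   (default 4; chosen trials are always re-evaluated at full resolution).
#' @param top_k number of screened candidates re-evaluated at full
#'   resolution per iteration, in screened order, until one lowers chi^2
#'   (default 4).
#' @param stall_tol,stall_iters early stop when the chi^2 improvement stays
#'   below `stall_tol` for `stall_iters` consecutive iterations.
#' @param bead_width,bin Debye form-factor width and histogram bin.
#' @return a `flexfit_config` list.
#' @export
flexfit_config <- function(n_iter = 100, n_modes = 60, n_amplitudes = 5,
                           max_step = 8, cutoff = 12,
                           linker_block_size = 5, screen_stride = 4,
                           top_k = 4, stall_tol = 1e-3, stall_iters = 5,
                           bead_width = 3, bin = 0.5) {
  structure(list(n_iter = n_iter, n_modes = n_modes,
                 n_amplitudes = n_amplitudes, max_step = max_step,
                 cutoff = cutoff, linker_block_size = linker_block_size,
                 screen_stride = screen_stride, top_k = top_k,
                 stall_tol = stall_tol, stall_iters = stall_iters,
                 bead_width = bead_width, bin = bin),
            class = "flexfit_config")
}

# largest per-block speed (|t| + |omega| * block radius) of each mode;
# used to normalise trial amplitudes so the biggest trial moves the most
# mobile block by ~max_step
mode_speed <- function(modes, model) {
  nb <- nrow(modes$bcom)
  # block radius: max bead distance from block COM
  rad <- numeric(nb)
  for (b in seq_len(nb)) {
    idx <- which(modes$block == b)
    rad[b] <- sqrt(max(rowSums(sweep(model$xyz[idx, , drop = FALSE], 2,
                                     modes$bcom[b, ])^2)))
  }
  vapply(seq_len(modes$n_modes), function(m) {
    s <- modes$screws[, , m]
    tn <- sqrt(colSums(s[1:3, , drop = FALSE]^2))
    wn <- sqrt(colSums(s[4:6, , drop = FALSE]^2))
    max(tn + wn * rad)
  }, 0)
}

model_chi2 <- function(model, exp_profile, config) {
  calc <- debye_profile(model, exp_profile$q, config$bead_width, config$bin)
  chi2_fit(calc, exp_profile)$chi2
}

#' Flexible fitting of a bead model to a scattering profile
#'
#' Greedy normal-mode optimisation: each iteration rebuilds the elastic
#' network, computes the slowest modes, evaluates nonlinear screw
#' deformations along every mode over a geometric amplitude grid (both
#' signs), picks the least-chi^2 trial, regularises local topology toward
#' the starting structure, and accepts the move only if the full-resolution
#' chi^2 strictly decreases. Stops early after a stall (config).
#'
#' @param start_model a topologically valid [bead_model()].
#' @param exp_profile target [scattering_profile()] with uncertainties.
#' @param config a [flexfit_config()].
#' @param reference topology reference (default the start model).
#' @param verbose print per-iteration progress.
#' @return list with `model` (fitted), `trajectory` (data.frame iteration,
#'   mode, amplitude, chi2, rg, accepted), `chi2_init`, `chi2_final`,
#'   `converged` flag.
#' @export
flexfit <- function(start_model, exp_profile, config = flexfit_config(),
                    reference = start_model, verbose = FALSE) {
  model <- start_model
  chi2_cur <- model_chi2(model, exp_profile, config)
  chi2_init <- chi2_cur
  traj <- list()
  stall <- 0L
  accepted_any <- FALSE
  for (it in seq_len(config$n_iter)) {
    net <- build_enm(model, cutoff = config$cutoff,
                     linker_block_size = config$linker_block_size)
    modes <- compute_modes(net, config$n_modes)
    spd <- mode_speed(modes, model)
    base <- config$max_step / (spd * 2^(config$n_amplitudes - 1))
    pos <- outer(base, 2^(0:(config$n_amplitudes - 1)))
    amps <- cbind(pos, -pos)
    chi2m <- cpp_sweep_trials(model$xyz, modes$block, modes$bcom,
                              as.numeric(modes$screws), modes$n_modes,
                              amps, exp_profile$q, config$bead_width,
                              config$bin, exp_profile$I, exp_profile$sigma,
                              config$screen_stride)
    ord <- order(chi2m)[seq_len(min(config$top_k, length(chi2m)))]
    accept <- FALSE
    improvement <- 0
    mode_i <- NA_integer_; amp <- NA_real_
    for (cand in ord) {
      ij <- arrayInd(cand, dim(chi2m))
      mode_i <- ij[1]; amp <- amps[ij[1], ij[2]]
      trial <- nonlinear_deform(model, modes, mode_i, amp)
      trial <- suppressWarnings(regularize_topology(trial, reference))
      chi2_new <- model_chi2(trial, exp_profile, config)
      if (chi2_new < chi2_cur) {
        if (!enm_connected(trial$xyz, config$cutoff)) next
        # extend the accepted amplitude along the same mode while the
        # full-resolution chi^2 keeps dropping
        for (ext in 1:3) {
          amp2 <- amp * 1.6^ext
          tr2 <- nonlinear_deform(model, modes, mode_i, amp2)
          tr2 <- suppressWarnings(regularize_topology(tr2, reference))
          if (!enm_connected(tr2$xyz, config$cutoff)) break
          c2 <- model_chi2(tr2, exp_profile, config)
          if (c2 < chi2_new) {
            trial <- tr2
            chi2_new <- c2
          } else break
        }
        improvement <- chi2_cur - chi2_new
        model <- trial
        chi2_cur <- chi2_new
        accept <- TRUE
        accepted_any <- TRUE
        break
      }
    }
    traj[[it]] <- data.frame(iteration = it, mode = mode_i, amplitude = amp,
                             chi2 = chi2_cur,
                             rg = radius_of_gyration(model),
                             accepted = accept)
    if (verbose) {
      message(sprintf("iter %3d: chi2 = %.4f (%s mode %d)", it, chi2_cur,
                      if (accept) "accepted" else "rejected", mode_i))
    }
    stall <- if (accept && improvement >= config$stall_tol) 0L else stall + 1L
    if (stall >= config$stall_iters) break
  }
  trajectory <- do.call(rbind, traj)
  list(model = model, trajectory = trajectory, chi2_init = chi2_init,
       chi2_final = chi2_cur,
       converged = accepted_any || chi2_init < 1.5)
}

#' Fit an ensemble of starting models
#'
#' Independent [flexfit()] runs (results independent of execution order);
#' failures are logged per start, not fatal.
#'
#' @param start_models non-empty list of starting [bead_model()]s.
#' @param exp_profile target profile.
#' @param config a [flexfit_config()].
#' @param verbose print progress per start.
#' @return list with `fits` (per-start results or NULL on failure) and
#'   `summary` data.frame (model, chi2_init, chi2_final, rg_init, rg_final,
#'   converged).
#' @export
run_ensemble <- function(start_models, exp_profile,
                         config = flexfit_config(), verbose = FALSE) {
  if (length(start_models) == 0) stop("empty model list")
  fits <- vector("list", length(start_models))
  rows <- vector("list", length(start_models))
  for (i in seq_along(start_models)) {
    res <- tryCatch(flexfit(start_models[[i]], exp_profile, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("start ", i, " failed: ", conditionMessage(res))
      rows[[i]] <- data.frame(model = i, chi2_init = NA, chi2_final = NA,
                              rg_init = NA, rg_final = NA, converged = FALSE)
    } else {
      fits[[i]] <- res
      rows[[i]] <- data.frame(
        model = i, chi2_init = res$chi2_init, chi2_final = res$chi2_final,
        rg_init = radius_of_gyration(start_models[[i]]),
        rg_final = radius_of_gyration(res$model),
        converged = res$converged)
      if (verbose) {
        message(sprintf("start %d/%d: chi2 %.2f -> %.2f", i,
                        length(start_models), res$chi2_init,
                        res$chi2_final))
      }
    }
  }
  list(fits = fits, summary = do.call(rbind, rows))
}
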