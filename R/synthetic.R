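# ---- seeding ----------------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so generators are
#' seed-deterministic without disturbing the caller's stream.
#' @param seed integer seed.
#' @param expr expression.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- templates --------------------------------------------------------

#' Geometry template for an antiparallel dumbbell dimer
#'
#' Defaults describe an elongated antiparallel coiled-coil dimer whose two
#' terminal modules sit 160 Angstrom apart, each carrying a thin arm that
#' extends outward so the full particle reaches ~370 Angstrom tip to tip,
#' with ~200-residue disordered linkers tethering a compact C-terminal
#' module per protomer.
#'
#' @param cc_separation distance between terminal-module centres of mass
#'   (Angstrom, default 160).
#' @param module_radius radius of the terminal-module shell (default 21.5;
#'   0 collapses the module to a point, leaving a pure rod).
#' @param module_arm outward arm length beyond the module shell (default 83).
#' @param cc_offset lateral half-separation of the two coiled-coil strands
#'   (default 2.5).
#' @param mobile_radius radius of the C-terminal mobile-module shell
#'   (default 15, a compact ~190-residue domain).
#' @param n_mobile_beads beads per mobile module (default 190, one per
#'   residue of the tandem C-terminal domain).
#' @param n_linker linker residues per protomer (default 200).
#' @param bond bead spacing along chains (default 3.8).
#' @param dA,dB planted displacements of the two mobile modules from their
#'   proximal terminal module (Angstrom; defaults 60 and 120).
#' @param max_D maximum mobile-domain placement distance used by
#'   [randomize_termini()] (default 140).
#' @return a `dimer_template` list.
#' @export
dimer_template <- function(cc_separation = 160, module_radius = 32,
                           module_arm = 100, cc_offset = 2.5,
                           mobile_radius = 15, n_mobile_beads = 190,
                           n_linker = 200, bond = 3.8,
                           dA = 60, dB = 120, max_D = 140) {
  stopifnot(cc_separation > 0, module_radius >= 0, module_arm >= 0,
            n_linker >= 2, bond > 0, dA >= 0, dB >= 0, max_D > 0)
  if (dA > max_D || dB > max_D) {
    stop("planted displacements must not exceed the maximum placement distance")
  }
  structure(list(cc_separation = cc_separation,
                 module_radius = module_radius, module_arm = module_arm,
                 cc_offset = cc_offset, mobile_radius = mobile_radius,
                 n_mobile_beads = n_mobile_beads, n_linker = n_linker,
                 bond = bond, dA = dA, dB = dB, max_D = max_D),
            class = "dimer_template")
}

# continuous spiral path on a sphere shell with ~`spacing` arc steps,
# running pole to pole; returns a k x 3 matrix (centred at origin)
sphere_spiral <- function(radius, spacing, turns = 4) {
  turns <- max(turns, 1)
  if (radius <= 0) return(matrix(0, 1, 3))
  pts <- list()
  tcur <- 0
  pt <- function(t) {
    th <- acos(1 - 2 * t)
    ph <- 2 * pi * turns * t
    radius * c(cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  }
  cur <- pt(0)
  pts[[1]] <- cur
  while (tcur < 1) {
    dt <- 1e-4
    nxt <- tcur
    repeat {
      nxt <- nxt + dt
      if (nxt >= 1) break
      if (sqrt(sum((pt(nxt) - cur)^2)) >= spacing) break
    }
    if (nxt >= 1) break
    cur <- pt(nxt)
    pts[[length(pts) + 1]] <- cur
    tcur <- nxt
  }
  do.call(rbind, pts)
}

# one terminal module: outward arm rod + spherical-shell head, chain-ordered
# from the arm tip to the head pole facing the dimer centre. `outward` is
# the unit vector pointing away from the particle centre.
build_module <- function(radius, arm, bond, outward) {
  if (radius <= 0 && arm <= 0) return(matrix(0, 1, 3))
  head <- sphere_spiral(radius, bond)
  # orient spiral poles along the x axis by construction; flip so the path
  # ends at the pole facing inward (-outward side handled by caller mirror)
  n_arm <- max(ceiling(arm / bond), 0)
  if (n_arm > 0) {
    tipd <- radius + arm
    arm_x <- seq(tipd, radius + bond, length.out = n_arm)
    # arm runs parallel to the outward axis, tangent to the head shell
    armm <- cbind(arm_x, radius, 0)
  } else {
    armm <- NULL
  }
  # path runs arm tip -> arm base -> (connector) -> head outer pole ->
  # head inner pole
  conn <- NULL
  if (!is.null(armm)) {
    conn <- straight_path(armm[nrow(armm), ], head[1, ], bond)
    conn <- conn[-nrow(conn), , drop = FALSE]
  }
  m <- rbind(armm, conn, head)
  m_out <- m[, 1] %o% outward
  lat <- m[, 2:3, drop = FALSE]
  # orthonormal frame completing `outward`
  ref <- if (abs(outward[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e2 <- ref - sum(ref * outward) * outward
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(outward[2] * e2[3] - outward[3] * e2[2],
          outward[3] * e2[1] - outward[1] * e2[3],
          outward[1] * e2[2] - outward[2] * e2[1])
  m_out + lat[, 1] %o% e2 + lat[, 2] %o% e3
}

# straight bead path from `from` (exclusive) to `to` (inclusive)
straight_path <- function(from, to, bond) {
  len <- sqrt(sum((to - from)^2))
  k <- max(ceiling(len / bond), 1)
  tt <- seq_len(k) / k
  sweep(tt %o% (to - from), 2, from, "+")
}

#' Build an antiparallel dumbbell dimer (N-terminal core)
#'
#' Two protomers, each a terminal module (outward arm plus spherical-shell
#' head, domain "RB1B2") and a straight coiled-coil strand (domain "CC")
#' spanning the distance between the modules. Module centres of mass sit
#' exactly `cc_separation` apart on the x axis; the strands run antiparallel
#' with a small lateral offset. The model is topologically valid by
#' construction.
#'
#' @param template a [dimer_template()].
#' @return a [bead_model()] with chains A and B.
#' @export
build_dumbbell_dimer <- function(template) {
  tp <- template
  half <- tp$cc_separation / 2
  mod <- build_module(tp$module_radius, tp$module_arm, tp$bond, c(-1, 0, 0))
  # recentre so the module COM is exactly at the origin
  mod <- sweep(mod, 2, colMeans(mod))
  modA <- sweep(mod, 2, c(-half, 0, 0), "+")
  endA <- modA[nrow(modA), ]
  # coiled-coil path of protomer A: an outgoing strand toward module B and
  # a return strand packing back against it (four-helix-bundle-like core),
  # so the chain's C-terminal exit sits next to its own terminal module
  turn_x <- half - tp$module_radius - tp$bond
  out1 <- straight_path(endA, c(turn_x, tp$cc_offset, 0), tp$bond)
  back0 <- c(turn_x, tp$cc_offset, tp$bond)
  ccA <- rbind(out1, back0,
               straight_path(back0,
                             c(-half + tp$module_radius + tp$bond,
                               tp$cc_offset, tp$bond), tp$bond))
  xyzA <- rbind(modA, ccA)
  domA <- c(rep("RB1B2", nrow(modA)), rep("CC", nrow(ccA)))
  # protomer B: 180-degree rotation about the z axis
  flip <- function(m) cbind(-m[, 1], -m[, 2], m[, 3])
  xyzB <- flip(xyzA)
  xyz <- rbind(xyzA, xyzB)
  chain <- rep(c("A", "B"), each = nrow(xyzA))
  domain <- c(domA, domA)
  m <- bead_model(xyz, chain, domain,
                  rigid = c(RB1B2 = TRUE, CC = TRUE))
  if (!is_topologically_valid(m)) {
    stop("construction error: dumbbell template yields broken topology")
  }
  m
}

#' Grow a random-coil linker chain
#'
#' Brownian-bridge growth: each 3.8-Angstrom step is a random direction
#' biased toward the far anchor in proportion to the remaining contour
#' length, with rejection of self-clashes below `clash`. With `anchor_end =
#' NULL` the walk is a free ideal chain.
#'
#' @param anchor_start 3-vector, the existing bead the linker grows from.
#' @param anchor_end 3-vector the final bead must come within one bond of,
#'   or NULL for a free chain.
#' @param n_residues number of linker beads.
#' @param bond step length (default 3.8).
#' @param clash minimum allowed self-distance (default 2.0).
#' @param max_restarts chain-level restarts before giving up.
#' @return n_residues x 3 coordinate matrix. Uses the current RNG stream;
#'   wrap in [with_seed()] for reproducibility.
#' @export
grow_linker <- function(anchor_start, anchor_end = NULL, n_residues,
                        bond = 3.8, clash = 2.0, max_restarts = 60) {
  if (!is.null(anchor_end)) {
    gap <- sqrt(sum((anchor_end - anchor_start)^2))
    if (gap >= (n_residues + 1) * bond) {
      stop("infeasible linker: anchors ", round(gap, 1),
           " A apart exceed contour length ", (n_residues + 1) * bond, " A")
    }
  }
  for (attempt in seq_len(max_restarts)) {
    pos <- matrix(NA_real_, n_residues, 3)
    cur <- anchor_start
    ok <- TRUE
    for (i in seq_len(n_residues)) {
      placed <- FALSE
      for (try in 1:40) {
        dir <- rnorm(3)
        if (!is.null(anchor_end)) {
          g <- anchor_end - cur
          glen <- sqrt(sum(g^2))
          m <- n_residues + 1 - i # steps left incl. the virtual closing bond
          alpha <- glen / (m * bond)
          if (alpha >= 1) {
            dir <- g
          } else if (glen > 1e-9) {
            kappa <- 2 * alpha / (1 - alpha)
            dir <- dir / sqrt(sum(dir^2)) + kappa * g / glen
          }
        }
        dir <- dir / sqrt(sum(dir^2))
        cand <- cur + bond * dir
        if (i > 1) {
          d2 <- rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE], 2,
                              cand)^2)
          if (min(d2) < clash^2) next
        }
        pos[i, ] <- cand
        cur <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok && !is.null(anchor_end)) {
      if (sqrt(sum((cur - anchor_end)^2)) > bond + 1e-9) ok <- FALSE
    }
    if (ok) return(pos)
  }
  stop("linker growth failed after ", max_restarts, " restarts")
}

# mobile-module shell path with ~n_beads beads, COM placed at `com`;
# the spiral turn count is chosen to hit the requested bead budget
place_mobile_module <- function(radius, bond, com, n_beads = 190) {
  tt <- sqrt(max(((n_beads * bond / (pi * radius))^2 - 1) / 4, 1))
  shell <- sphere_spiral(radius, bond, turns = tt)
  for (it in 1:6) { # refine the turn count toward the bead budget
    if (abs(nrow(shell) - n_beads) / n_beads < 0.03) break
    tt <- tt * n_beads / nrow(shell)
    shell <- sphere_spiral(radius, bond, turns = tt)
  }
  shell <- sweep(shell, 2, colMeans(shell))
  sweep(shell, 2, com, "+")
}

# deterministic default placement direction for the planted mobile domain
# of chain A (unit vector pointing away from the dimer so the proximal
# module stays the nearest); chain B uses the antiparallel mirror image
planted_directions <- function() {
  u <- c(0, 0.909, 0.417) # lateral: placement does not lengthen the particle
  u / sqrt(sum(u^2))
}

#' Build the full-length dimer with planted mobile-domain displacements
#'
#' Extends [build_dumbbell_dimer()] with, per protomer, a disordered linker
#' (domain "LINKER", flexible) and a compact C-terminal mobile module
#' (domain "PHDBR", rigid) whose centre of mass is placed at the planted
#' distance (template dA, dB) from its proximal terminal module.
#'
#' @param template a [dimer_template()].
#' @param seed RNG seed for the linker conformations.
#' @return a [bead_model()] with ground-truth attributes `dA`, `dB`.
#' @export
build_full_dimer <- function(template, seed = 1) {
  tp <- template
  core <- build_dumbbell_dimer(tp)
  half <- tp$cc_separation / 2
  u <- planted_directions()
  with_seed(seed, {
    parts <- list()
    for (ch in c("A", "B")) {
      idx <- select_beads(core, chain = ch)
      cc_idx <- idx[core$domain[idx] == "CC"]
      cc_end <- core$xyz[cc_idx[length(cc_idx)], ]
      d <- if (ch == "A") tp$dA else tp$dB
      anchor_mod <- if (ch == "A") c(-half, 0, 0) else c(half, 0, 0)
      dir <- if (ch == "A") u else c(-u[1], -u[2], u[3])
      com <- anchor_mod + d * dir
      shell <- place_mobile_module(tp$mobile_radius, tp$bond, com,
                                   tp$n_mobile_beads)
      link <- grow_linker(cc_end, shell[1, ], tp$n_linker, tp$bond)
      parts[[ch]] <- list(link = link, shell = shell)
    }
    xyzA <- rbind(core$xyz[core$chain == "A", ], parts$A$link, parts$A$shell)
    xyzB <- rbind(core$xyz[core$chain == "B", ], parts$B$link, parts$B$shell)
    domA <- c(core$domain[core$chain == "A"],
              rep("LINKER", tp$n_linker), rep("PHDBR", nrow(parts$A$shell)))
    domB <- c(core$domain[core$chain == "B"],
              rep("LINKER", tp$n_linker), rep("PHDBR", nrow(parts$B$shell)))
    m <- bead_model(rbind(xyzA, xyzB),
                    c(rep("A", nrow(xyzA)), rep("B", nrow(xyzB))),
                    c(domA, domB),
                    rigid = c(RB1B2 = TRUE, CC = TRUE, LINKER = FALSE,
                              PHDBR = TRUE))
    attr(m, "dA") <- tp$dA
    attr(m, "dB") <- tp$dB
    attr(m, "seed") <- seed
    m
  })
}

#' Randomise the mobile terminal domains of a full-length model
#'
#' Each mobile module receives an independent uniform random rotation and a
#' random centre-of-mass placement at most `D` from its proximal terminal
#' module; the linkers are regrown to bridge the new placements. Planted
#' displacements can be forced through `planted`.
#'
#' @param model a full-length [bead_model()] (domains PHDBR and LINKER).
#' @param template the [dimer_template()] the model was built from.
#' @param D maximum placement distance in Angstrom (default: template
#'   `max_D`, 140).
#' @param seed RNG seed.
#' @param planted optional c(dA, dB) forcing the displacement magnitudes.
#' @return a new [bead_model()] with attributes `dA`, `dB`, `seed`.
#' @export
randomize_termini <- function(model, template, D = template$max_D,
                              seed = 1, planted = NULL) {
  tp <- template
  if (D < tp$mobile_radius) {
    stop("placement error: D smaller than the mobile-domain radius")
  }
  half <- tp$cc_separation / 2
  xyz <- model$xyz
  dout <- c(NA_real_, NA_real_)
  with_seed(seed, {
    for (k in 1:2) {
      ch <- c("A", "B")[k]
      idx <- select_beads(model, chain = ch)
      cc_idx <- idx[model$domain[idx] == "CC"]
      li_idx <- idx[model$domain[idx] == "LINKER"]
      ph_idx <- idx[model$domain[idx] == "PHDBR"]
      cc_end <- xyz[cc_idx[length(cc_idx)], ]
      anchor_mod <- if (ch == "A") c(-half, 0, 0) else c(half, 0, 0)
      d <- if (is.null(planted)) runif(1, 0, D) else planted[k]
      v <- rnorm(3)
      v <- v / sqrt(sum(v^2))
      com <- anchor_mod + d * v
      # uniform random rotation of the module about its COM
      shell <- model$xyz[ph_idx, , drop = FALSE]
      shell <- sweep(shell, 2, colMeans(shell))
      R <- qr.Q(qr(matrix(rnorm(9), 3)))
      if (det(R) < 0) R[, 1] <- -R[, 1]
      shell <- shell %*% t(R)
      shell <- sweep(shell, 2, com, "+")
      link <- grow_linker(cc_end, shell[1, ], length(li_idx), tp$bond)
      xyz[li_idx, ] <- link
      xyz[ph_idx, ] <- shell
      dout[k] <- d
    }
  })
  out <- set_coords(model, xyz)
  attr(out, "dA") <- dout[1]
  attr(out, "dB") <- dout[2]
  attr(out, "seed") <- seed
  out
}

# ---- noise + simulators ----------------------------------------------

#' Noise specification for the synthetic generators
#'
#' @param saxs_rel SAXS noise scale a in sigma(q) = a sqrt(I(q) I(0))
#'   (relative sigma at I(0); default 0.01).
#' @param trace_sd camera noise standard deviation in dye units
#'   (default 0.2).
#' @param itc_frac ITC heat noise as a fraction of the first-injection heat
#'   (default 0.01).
#' @param seed RNG seed recorded in every output's metadata.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(saxs_rel = 0.01, trace_sd = 0.2, itc_frac = 0.01,
                       seed = 1) {
  stopifnot(saxs_rel >= 0, trace_sd >= 0, itc_frac >= 0)
  structure(list(saxs_rel = saxs_rel, trace_sd = trace_sd,
                 itc_frac = itc_frac, seed = seed), class = "noise_spec")
}

#' Default momentum-transfer grid
#'
#' 0.0025 to 0.6 inverse Angstrom, the synchrotron-beamline range the
#' pipeline is designed around.
#' @param n number of points (default 1000, detector-like sampling).
#' @return numeric vector.
#' @export
default_q_grid <- function(n = 1000) seq(0.0025, 0.6, length.out = n)

#' Simulate a noisy SAXS profile of a model
#'
#' Debye profile plus Gaussian noise with counting-statistics-like
#' sigma(q) = a sqrt(I(q) I(0)).
#'
#' @param model a [bead_model()].
#' @param q_grid ascending q grid within (0, 1].
#' @param noise a [noise_spec()].
#' @param bead_width Debye form-factor width (default 3).
#' @return a [scattering_profile()] with sigma and seed metadata.
#' @export
simulate_saxs <- function(model, q_grid = default_q_grid(),
                          noise = noise_spec(), bead_width = 3) {
  stopifnot(max(q_grid) <= 1)
  truth <- debye_profile(model, q_grid, bead_width)
  I0 <- n_beads(model)^2
  sigma <- noise$saxs_rel * sqrt(pmax(truth$I, 1e-12 * I0) * I0)
  I <- if (noise$saxs_rel > 0) {
    with_seed(noise$seed, truth$I + rnorm(length(sigma), 0, sigma))
  } else truth$I
  if (noise$saxs_rel == 0) {
    return(scattering_profile(q_grid, I, metadata = list(
      source = "simulate_saxs", seed = noise$seed, noiseless = TRUE)))
  }
  scattering_profile(q_grid, I, sigma, metadata = list(
    source = "simulate_saxs", seed = noise$seed))
}

#' Simulate the ensemble-averaged SAXS profile of a planted dimer
#'
#' A scattering measurement averages over the conformational ensemble; a
#' single frozen linker conformation would imprint coil-specific detail a
#' real profile does not carry. This generator averages the Debye profiles
#' of `n_avg` replicas of the planted dimer (same mobile-domain placements,
#' independent linker conformations) and adds counting-statistics-like
#' noise as in [simulate_saxs()].
#'
#' @param template a [dimer_template()] with planted dA, dB.
#' @param q_grid ascending q grid.
#' @param noise a [noise_spec()].
#' @param n_avg number of conformers averaged (default 12).
#' @param bead_width Debye form-factor width.
#' @return a [scattering_profile()] with sigma and metadata.
#' @export
simulate_saxs_ensemble <- function(template, q_grid = default_q_grid(),
                                   noise = noise_spec(), n_avg = 12,
                                   bead_width = 3) {
  reps <- vapply(seq_len(n_avg), function(k) {
    m <- build_full_dimer(template, seed = noise$seed * 1000L + k)
    debye_profile(m, q_grid, bead_width)$I
  }, numeric(length(q_grid)))
  Im <- rowMeans(reps)
  n <- n_beads(build_full_dimer(template, seed = noise$seed * 1000L + 1L))
  I0 <- n^2
  sigma <- noise$saxs_rel * sqrt(pmax(Im, 1e-12 * I0) * I0)
  I <- if (noise$saxs_rel > 0) {
    with_seed(noise$seed, Im + rnorm(length(sigma), 0, sigma))
  } else Im
  scattering_profile(q_grid, I,
                     if (noise$saxs_rel > 0) sigma else NULL,
                     metadata = list(source = "simulate_saxs_ensemble",
                                     seed = noise$seed, n_avg = n_avg))
}

#' Kinetic model for single-molecule binding
#'
#' Double-exponential dissociation (fast/slow residence times with
#' percentage amplitudes) and a bimolecular association rate.
#'
#' @param tau_off1,tau_off2 residence times in seconds (tau_off1 < tau_off2).
#' @param A1_pct,A2_pct percentage amplitudes (must sum to 100).
#' @param k_on association rate constant in 1/(M s).
#' @param concentration fluorescent-ligand concentration in M.
#' @return a `kinetic_model` list.
#' @export
kinetic_model <- function(tau_off1, A1_pct, tau_off2, A2_pct, k_on,
                          concentration) {
  stopifnot(tau_off1 > 0, tau_off2 > 0, k_on > 0, concentration > 0)
  if (abs(A1_pct + A2_pct - 100) > 1e-6) stop("amplitudes must sum to 100")
  structure(list(tau_off1 = tau_off1, A1_pct = A1_pct, tau_off2 = tau_off2,
                 A2_pct = A2_pct, k_on = k_on,
                 concentration = concentration), class = "kinetic_model")
}

#' Reference chromatin-binding kinetics of HP1 alpha at increasing
#' co-factor concentrations
#'
#' Published single-molecule TIRF fit values used as simulation inputs:
#' fast and slow residence times with amplitudes and the association rate,
#' for 3 nM labelled HP1 alpha at 0-400 nM of the KAP1 co-factor.
#'
#' @return data.frame with columns kap1_nM, tau_off1_s, A1_pct, tau_off2_s,
#'   A2_pct, k_on_1e6.
#' @export
hp1_kinetics_reference <- function() {
  data.frame(
    kap1_nM = c(0, 50, 100, 200, 400),
    tau_off1_s = c(0.25, 0.29, 0.28, 0.27, 0.23),
    A1_pct = c(87, 89, 85, 87, 86),
    tau_off2_s = c(2.26, 3.64, 5.79, 5.47, 5.03),
    A2_pct = c(13, 11, 15, 13, 14),
    k_on_1e6 = c(3.64, 1.03, 1.42, 1.43, 0.77))
}

#' Simulate discretised bright dwell times from a kinetic model
#'
#' Continuous double-exponential mixture durations floored to the frame
#' grid; events shorter than one frame are dropped (as in acquisition).
#'
#' @param km a [kinetic_model()].
#' @param n number of recorded dwell times to return.
#' @param frame_rate frames per second (default 20).
#' @param seed RNG seed.
#' @return numeric vector of n durations in seconds (frame multiples).
#' @export
simulate_bright_dwells <- function(km, n, frame_rate = 20, seed = 1) {
  dt <- 1 / frame_rate
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      d <- draw_bright(km, 2 * n)$dur
      fr <- floor(d / dt)
      out <- c(out, fr[fr >= 1] * dt)
    }
    out[seq_len(n)]
  })
}

#' Simulate discretised dark (unbound) intervals
#'
#' Exponential with rate k_on * concentration, floored to the frame grid.
#' @inheritParams simulate_bright_dwells
#' @return numeric vector of n durations in seconds.
#' @export
simulate_dark_dwells <- function(km, n, frame_rate = 20, seed = 1) {
  dt <- 1 / frame_rate
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      d <- rexp(2 * n, km$k_on * km$concentration)
      fr <- floor(d / dt)
      out <- c(out, fr[fr >= 1] * dt)
    }
    out[seq_len(n)]
  })
}

# draw one bright duration from the mixture
draw_bright <- function(km, n) {
  comp <- 1 + (runif(n) * 100 > km$A1_pct)
  tau <- ifelse(comp == 1, km$tau_off1, km$tau_off2)
  list(dur = rexp(n, 1 / tau), comp = comp)
}

#' Simulate single-molecule TIRF fluorescence traces
#'
#' Alternating dark/bright renewal process: dark durations are exponential
#' with rate k_on * concentration; bright durations come from the
#' double-exponential mixture. Each binder is a dimer with probability
#' `dimer_fraction`; dyes are attached independently with probability
#' `label_efficiency` (1 dye possible on a monomer, up to 2 on a dimer) and
#' unlabelled arrivals are invisible (their would-be bright time stays
#' dark). Events are discretised by flooring to the frame grid; events
#' shorter than one frame are dropped.
#'
#' @param km a [kinetic_model()].
#' @param n_traces number of traces.
#' @param frame_rate frames per second (default 20).
#' @param n_frames frames per trace (default 10000).
#' @param label_efficiency dye labelling probability (default 0.6).
#' @param dimer_fraction fraction of binding species that are dimers.
#' @param noise a [noise_spec()] (camera noise sd `trace_sd`).
#' @return list of traces; each trace is a list with `time_s`, `intensity`
#'   and a ground-truth `events` data.frame (t_on_s, duration_s, frames,
#'   n_dyes, component).
#' @export
simulate_smtirf_traces <- function(km, n_traces = 100, frame_rate = 20,
                                   n_frames = 10000, label_efficiency = 0.6,
                                   dimer_fraction = 0, noise = noise_spec()) {
  stopifnot(label_efficiency > 0, label_efficiency <= 1,
            dimer_fraction >= 0, dimer_fraction <= 1)
  dt <- 1 / frame_rate
  if (km$tau_off1 <= dt) {
    warning("fast residence time at or below the frame interval; ",
            "events may be unresolvable")
  }
  k_dark <- km$k_on * km$concentration
  with_seed(noise$seed, lapply(seq_len(n_traces), function(tr) {
    t_total <- n_frames * dt
    sig <- numeric(n_frames)
    ev <- list()
    t <- rexp(1, k_dark)
    while (t < t_total) {
      br <- draw_bright(km, 1)
      is_dimer <- runif(1) < dimer_fraction
      ndyes <- rbinom(1, if (is_dimer) 2 else 1, label_efficiency)
      if (ndyes > 0) {
        f0 <- floor(t / dt)
        nfr <- floor(br$dur / dt)
        if (nfr >= 1 && f0 < n_frames) {
          f1 <- min(f0 + nfr, n_frames)
          sig[(f0 + 1):f1] <- sig[(f0 + 1):f1] + ndyes
          ev[[length(ev) + 1]] <- data.frame(
            t_on_s = f0 * dt, duration_s = br$dur, frames = f1 - f0,
            n_dyes = ndyes, component = br$comp)
        }
      }
      t <- t + br$dur + rexp(1, k_dark)
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(t_on_s = numeric(), duration_s = numeric(),
                 frames = integer(), n_dyes = integer(),
                 component = integer())
    list(time_s = (seq_len(n_frames) - 1) * dt,
         intensity = sig + rnorm(n_frames, 0, noise$trace_sd),
         events = events,
         metadata = list(seed = noise$seed, frame_rate = frame_rate,
                         concentration = km$concentration))
  }))
}

#' Simulate an ITC titration
#'
#' Per-injection heats from the one-set-of-sites model plus Gaussian noise
#' scaled to the first-injection heat.
#'
#' @param design a [titration_experiment()] (heats ignored).
#' @param N sites per monomer.
#' @param Kd dissociation constant (M).
#' @param dH binding enthalpy (cal/mol).
#' @param noise a [noise_spec()].
#' @return the design with `heats_ucal` filled in and ground truth in
#'   metadata.
#' @export
simulate_itc <- function(design, N, Kd, dH, noise = noise_spec()) {
  q <- one_set_of_sites_heat(design, N, Kd, dH)
  if (noise$itc_frac > 0) {
    q <- with_seed(noise$seed,
                   q + rnorm(length(q), 0, noise$itc_frac * abs(q[1])))
  }
  design$heats_ucal <- q
  design$metadata <- list(truth = list(N = N, Kd = Kd, dH = dH),
                          seed = noise$seed)
  design
}
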