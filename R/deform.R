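#' Nonlinear deformation of a model along one normal mode
#'
#' Each block moves by the finite screw motion obtained by integrating its
#' instantaneous mode velocity: a rotation by amplitude * |omega| about the
#' mode axis through the block's screw centre plus the pitch translation.
#' Rigid-block internal geometry is preserved exactly; amplitude 0 is the
#' identity.
#'
#' @param model a [bead_model()].
#' @param modes a `mode_set` from [compute_modes()].
#' @param mode_index which mode to apply.
#' @param amplitude signed amplitude.
#' @return deformed [bead_model()].
#' @export
nonlinear_deform <- function(model, modes, mode_index, amplitude) {
  stopifnot(mode_index >= 1, mode_index <= modes$n_modes)
  screw6 <- t(modes$screws[, , mode_index])
  xyz <- cpp_apply_screw(model$xyz, modes$block, modes$bcom, screw6,
                         amplitude)
  set_coords(model, xyz)
}

#' Linear (infinitesimal) displacement field of one mode
#'
#' Used for Richardson-type checks of the nonlinear extrapolation.
#' @param modes a `mode_set`.
#' @param model the model the modes belong to.
#' @param mode_index which mode.
#' @return n x 3 matrix of per-bead displacement rates.
#' @export
mode_displacement <- function(modes, model, mode_index) {
  s <- modes$screws[, , mode_index]
  n <- n_beads(model)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    b <- modes$block[i]
    tv <- s[1:3, b]
    om <- s[4:6, b]
    r <- model$xyz[i, ] - modes$bcom[b, ]
    out[i, ] <- tv + c(om[2] * r[3] - om[3] * r[2],
                       om[3] * r[1] - om[1] * r[3],
                       om[1] * r[2] - om[2] * r[1])
  }
  out
}

# bonds, pseudo-angles and rigid-domain block ids used by the topology
# restraint; reference geometry comes from the reference model
topology_restraints <- function(reference) {
  b <- bond_list(reference)
  d0 <- sqrt(rowSums((reference$xyz[b[, 1], , drop = FALSE] -
                      reference$xyz[b[, 2], , drop = FALSE])^2))
  n <- n_beads(reference)
  i <- seq_len(n - 2L)
  keep <- reference$chain[i] == reference$chain[i + 2L]
  ai <- i[keep]; aj <- ai + 1L; ak <- ai + 2L
  u <- reference$xyz[ai, , drop = FALSE] - reference$xyz[aj, , drop = FALSE]
  v <- reference$xyz[ak, , drop = FALSE] - reference$xyz[aj, , drop = FALSE]
  c0 <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  # rigid domains move as rigid bodies; linker beads are free (block 0)
  blk <- integer(n)
  nb <- 0L
  dd <- reference$domains
  for (r in seq_len(nrow(dd))) {
    if (!dd$rigid[r]) next
    nb <- nb + 1L
    blk[reference$chain == dd$chain[r] &
        reference$domain == dd$domain[r]] <- nb
  }
  list(bi = b[, 1], bj = b[, 2], bd0 = d0,
       ai = ai, aj = aj, ak = ak, ac0 = c0, block = blk, nblock = nb)
}

#' Restore local topology toward a reference structure
#'
#' Steepest-descent minimisation of harmonic restraints on pseudo-bond
#' lengths and bond angles toward their reference values. Rigid domains move
#' only as rigid bodies (net force and torque); flexible beads move freely.
#' Stops when the maximum bond deviation falls below `tolerance` or after
#' `max_steps` steps (with a warning).
#'
#' @param model the deformed [bead_model()].
#' @param reference the reference [bead_model()] sharing its topology.
#' @param tolerance maximum allowed bond deviation in Angstrom (default 0.1).
#' @param max_steps step cap (default 500).
#' @param kb,ka bond and angle restraint constants.
#' @param gamma descent step size.
#' @return the regularised [bead_model()] with attributes `max_bond_dev`
#'   and `steps`.
#' @export
regularize_topology <- function(model, reference, tolerance = 0.1,
                                max_steps = 500, kb = 1, ka = 0.3,
                                gamma = 0.15) {
  stopifnot(n_beads(model) == n_beads(reference))
  tr <- topology_restraints(reference)
  res <- cpp_regularize(model$xyz, tr$bi, tr$bj, tr$bd0, tr$ai, tr$aj,
                        tr$ak, tr$ac0, tr$block, tr$nblock, kb, ka, gamma,
                        tolerance, max_steps)
  if (res$max_bond_dev >= tolerance) {
    warning(sprintf(
      "topology regularization did not converge: residual %.3f A",
      res$max_bond_dev))
  }
  out <- set_coords(model, res$xyz)
  attr(out, "max_bond_dev") <- res$max_bond_dev
  attr(out, "steps") <- res$steps
  out
}
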