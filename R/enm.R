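#' Elastic-network blocks of a bead model
#'
#' Rigid domains form one block each; flexible (linker) beads are grouped
#' into consecutive segments of `linker_block_size` residues, each treated
#' as one rigid mini-segment in the rotations-translations-of-blocks (RTB)
#' projection. With the default of 5 residues a 200-residue linker keeps 40
#' hinge points, ample for coil geometry, while keeping the reduced
#' eigenproblem small enough to re-solve every fitting iteration.
#'
#' @param model a [bead_model()].
#' @param linker_block_size residues per flexible-segment block (default 5;
#'   1 gives per-residue blocks).
#' @return integer vector of 1-based block ids, one per bead.
#' @export
enm_blocks <- function(model, linker_block_size = 5) {
  n <- n_beads(model)
  blk <- integer(n)
  nb <- 0L
  dd <- model$domains
  for (r in seq_len(nrow(dd))) {
    idx <- which(model$chain == dd$chain[r] & model$domain == dd$domain[r])
    if (dd$rigid[r]) {
      nb <- nb + 1L
      blk[idx] <- nb
    } else {
      grp <- ceiling(seq_along(idx) / linker_block_size)
      blk[idx] <- nb + grp
      nb <- nb + max(grp)
    }
  }
  blk
}

# union-find connectivity of the spring graph
springs_connected <- function(n, sp) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (s in seq_along(sp$i)) {
    a <- find(sp$i[s]); b <- find(sp$j[s])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, 0L)
  table(roots)
}

# TRUE when every bead pair is linked through springs within `cutoff`
enm_connected <- function(xyz, cutoff = 12) {
  cpp_n_components(xyz, cutoff) == 1
}

#' Build an elastic network
#'
#' Springs connect all bead pairs within `cutoff` (default 12 Angstrom) with
#' rest lengths equal to current distances and a uniform spring constant.
#'
#' @param model a [bead_model()].
#' @param cutoff spring cutoff in Angstrom.
#' @param k uniform spring constant (absolute stiffness cancels in mode
#'   directions; default 1).
#' @param linker_block_size passed to [enm_blocks()].
#' @return object of class `elastic_network`.
#' @export
build_enm <- function(model, cutoff = 12, k = 1, linker_block_size = 5) {
  if (!is_topologically_valid(model)) {
    stop("model is not topologically valid (bond > 4.5 A)")
  }
  sp <- cpp_springs(model$xyz, cutoff)
  n <- n_beads(model)
  sizes <- springs_connected(n, sp)
  if (length(sizes) > 1) {
    stop("disconnected elastic network: ", length(sizes),
         " components of sizes ", paste(as.integer(sizes), collapse = ", "))
  }
  structure(list(model = model, springs = sp, cutoff = cutoff, k = k,
                 block = enm_blocks(model, linker_block_size)),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("elastic_network: %d beads, %d springs (cutoff %.1f A), %d blocks\n",
              n_beads(x$model), length(x$springs$i), x$cutoff,
              max(x$block)))
  invisible(x)
}

#' Slowest normal modes of an elastic network (RTB projection)
#'
#' Solves the generalised eigenproblem of the block-projected Hessian and
#' mass matrix. Per-block mass matrices are diagonalised and near-null
#' directions (single-bead or collinear blocks) are removed before the
#' standard symmetric eigensolve, so every block contributes only its
#' physical rigid-body freedoms. The six global rigid-body modes are
#' discarded; the remaining eigenvectors are returned as per-block
#' instantaneous screws (translation, angular velocity) and are
#' mass-orthonormal in bead space.
#'
#' @param network an [build_enm()] result.
#' @param n_modes number of non-rigid modes requested (default 60).
#' @return object of class `mode_set`: values (ascending eigenvalues),
#'   screws (array 6 x nblock x n_modes), block assignment, block COMs,
#'   rigid_values (the near-zero eigenvalues).
#' @export
compute_modes <- function(network, n_modes = 60) {
  model <- network$model
  nb <- max(network$block)
  hm <- cpp_rtb_hessian(model$xyz, network$springs$i, network$springs$j,
                        model$mass, network$block, nb, network$k)
  H <- hm$H; M <- hm$M
  # per-block whitening transform dropping null mass directions
  Tlist <- vector("list", nb)
  dofs <- integer(nb)
  for (b in seq_len(nb)) {
    o <- 6 * (b - 1)
    Mb <- M[o + 1:6, o + 1:6]
    e <- eigen(Mb, symmetric = TRUE)
    keep <- e$values > 1e-9 * max(e$values)
    Tlist[[b]] <- e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep))
    dofs[b] <- sum(keep)
  }
  D <- sum(dofs)
  Tm <- matrix(0, 6 * nb, D)
  off <- 0L
  for (b in seq_len(nb)) {
    o <- 6 * (b - 1)
    Tm[o + 1:6, off + seq_len(dofs[b])] <- Tlist[[b]]
    off <- off + dofs[b]
  }
  Hred <- crossprod(Tm, H %*% Tm)
  Hred <- (Hred + t(Hred)) / 2
  es <- eigen(Hred, symmetric = TRUE)
  vals <- rev(es$values)
  vecs <- es$vectors[, rev(seq_len(D)), drop = FALSE]
  vmax <- max(vals)
  nz <- sum(vals < 1e-8 * vmax)
  if (D < nz + n_modes) n_modes <- D - nz
  if (n_modes < 1) stop("numerical error: no non-rigid modes available")
  sel <- (nz + 1):(nz + n_modes)
  screws <- array(0, c(6, nb, n_modes))
  for (m in seq_along(sel)) {
    v6 <- Tm %*% vecs[, sel[m]]
    screws[, , m] <- matrix(v6, nrow = 6)
  }
  structure(list(values = vals[sel], rigid_values = vals[seq_len(nz)],
                 screws = screws, block = network$block, bcom = hm$com,
                 n_modes = n_modes, all_values = vals),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set: %d non-rigid modes (%d rigid), eigenvalues %.3g .. %.3g\n",
              x$n_modes, length(x$rigid_values),
              min(x$values), max(x$values)))
  invisible(x)
}
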