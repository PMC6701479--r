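#' @useDynLib flexdimer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif coef lm median mad quantile sd setNames
#'   approx dist optimize pnorm var rexp rbinom nls residuals plogis qlogis
#'   dnorm density
#' @importFrom utils read.csv write.csv head tail
NULL

#' Coarse-grained bead model
#'
#' One bead per residue at the C-alpha position. Each bead belongs to exactly
#' one protomer (chain) and one named domain; domains carry a rigid flag
#' (rigid folded domain vs flexible linker). Consecutive beads within a chain
#' are pseudo-bonded (ideal length 3.8 Angstrom).
#'
#' @param xyz numeric matrix (n x 3), coordinates in Angstrom.
#' @param chain character vector of protomer ids (e.g., "A"/"B"), one per bead.
#'   Beads of a chain must be stored contiguously in residue order.
#' @param domain character vector of domain names, one per bead. Beads of a
#'   domain must be contiguous within their chain.
#' @param rigid named logical vector mapping domain name to rigid flag. Names
#'   may be either plain domain names or "domain.chain" combinations.
#' @param mass per-bead masses (default uniform 1).
#' @return an object of class `bead_model`.
#' @export
bead_model <- function(xyz, chain, domain, rigid, mass = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- nrow(xyz)
  stopifnot(ncol(xyz) == 3, length(chain) == n, length(domain) == n)
  if (is.null(mass)) mass <- rep(1, n)
  stopifnot(length(mass) == n, all(mass > 0))
  chain <- as.character(chain)
  domain <- as.character(domain)
  key <- paste(domain, chain, sep = ".")
  rg <- rep(NA, n)
  for (nm in names(rigid)) {
    hit <- if (grepl("\\.", nm)) key == nm else domain == nm
    rg[hit] <- rigid[[nm]]
  }
  if (anyNA(rg)) {
    stop("labeling error: no rigid flag for domain(s): ",
         paste(unique(domain[is.na(rg)]), collapse = ", "))
  }
  m <- structure(list(xyz = xyz, chain = chain, domain = domain,
                      rigid = as.logical(rg), mass = as.numeric(mass)),
                 class = "bead_model")
  dd <- domain_definitions(m) # validates contiguity / partition
  m$domains <- dd
  m
}

#' @export
print.bead_model <- function(x, ...) {
  cat("bead_model:", nrow(x$xyz), "beads,",
      length(unique(x$chain)), "protomer(s),",
      nrow(x$domains), "domain segment(s)\n")
  invisible(x)
}

n_beads <- function(model) nrow(model$xyz)

#' Domain definitions of a bead model
#'
#' Returns the per-chain domain table with 0-based, half-open residue index
#' ranges. Ranges within a chain are disjoint, ordered, and cover all beads.
#'
#' @param model a [bead_model()].
#' @return data.frame with columns chain, domain, start, end, rigid.
#' @export
domain_definitions <- function(model) {
  out <- list()
  for (ch in unique(model$chain)) {
    idx <- which(model$chain == ch)
    if (any(diff(idx) != 1)) {
      stop("format error: beads of chain ", ch, " are not contiguous")
    }
    dom <- model$domain[idx]
    r <- rle(dom)
    if (anyDuplicated(r$values)) {
      stop("labeling error: domain ", r$values[duplicated(r$values)][1],
           " is not contiguous within chain ", ch)
    }
    ends <- cumsum(r$lengths)
    starts <- c(0L, head(ends, -1L))
    out[[ch]] <- data.frame(
      chain = ch, domain = r$values, start = starts, end = ends,
      rigid = model$rigid[idx][ends], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bond list of a bead model
#'
#' Pseudo-bonds between consecutive beads within each chain.
#' @param model a [bead_model()].
#' @return integer matrix (nbond x 2) of 1-based bead indices.
#' @export
bond_list <- function(model) {
  n <- n_beads(model)
  i <- seq_len(n - 1L)
  keep <- model$chain[i] == model$chain[i + 1L]
  cbind(i[keep], i[keep] + 1L)
}

#' Check topological validity
#'
#' A model is topologically valid when every pseudo-bond is shorter than
#' `max_bond` (default 4.5 Angstrom).
#' @param model a [bead_model()].
#' @param max_bond maximum allowed bond length in Angstrom.
#' @return logical.
#' @export
is_topologically_valid <- function(model, max_bond = 4.5) {
  b <- bond_list(model)
  d <- sqrt(rowSums((model$xyz[b[, 1], , drop = FALSE] -
                     model$xyz[b[, 2], , drop = FALSE])^2))
  all(d < max_bond)
}

#' Select beads by domain and/or chain
#'
#' @param model a [bead_model()].
#' @param domain optional domain name(s).
#' @param chain optional chain id(s).
#' @return integer vector of bead indices.
#' @export
select_beads <- function(model, domain = NULL, chain = NULL) {
  keep <- rep(TRUE, n_beads(model))
  if (!is.null(domain)) keep <- keep & model$domain %in% domain
  if (!is.null(chain)) keep <- keep & model$chain %in% chain
  idx <- which(keep)
  if (length(idx) == 0) {
    stop("selection error: no beads match domain=",
         paste(domain, collapse = ","), " chain=",
         paste(chain, collapse = ","))
  }
  idx
}

#' Mass-weighted centre of mass
#'
#' @param model a [bead_model()].
#' @param domain,chain optional selector passed to [select_beads()].
#' @return length-3 numeric vector.
#' @export
center_of_mass <- function(model, domain = NULL, chain = NULL) {
  idx <- select_beads(model, domain, chain)
  m <- model$mass[idx]
  colSums(model$xyz[idx, , drop = FALSE] * m) / sum(m)
}

#' Mass-weighted radius of gyration
#'
#' Root-mean-square mass-weighted distance from the centre of mass.
#' @param model a [bead_model()] or an n x 3 coordinate matrix.
#' @param mass optional masses when `model` is a plain matrix.
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(model, mass = NULL) {
  if (inherits(model, "bead_model")) {
    xyz <- model$xyz
    mass <- model$mass
  } else {
    xyz <- as.matrix(model)
    if (is.null(mass)) mass <- rep(1, nrow(xyz))
  }
  if (nrow(xyz) < 2) stop("radius of gyration needs at least 2 beads")
  com <- colSums(xyz * mass) / sum(mass)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(mass * d2) / sum(mass))
}

#' Maximum intra-model distance
#' @param model a [bead_model()] or coordinate matrix.
#' @return largest pairwise bead distance in Angstrom.
#' @export
max_dimension <- function(model) {
  xyz <- if (inherits(model, "bead_model")) model$xyz else as.matrix(model)
  cpp_max_dist(xyz)
}

#' Replace coordinates of a bead model
#' @param model a [bead_model()].
#' @param xyz replacement n x 3 matrix.
#' @return the model with new coordinates.
#' @export
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == n_beads(model), ncol(xyz) == 3)
  model$xyz <- as.matrix(xyz)
  model
}

# ---- IO ---------------------------------------------------------------

#' Write a bead model as a CA-only PDB plus a domain sidecar table
#'
#' Protomers map to PDB chains; the sidecar is a comma-separated table with
#' columns chain, start, end, domain, rigid using 0-based half-open residue
#' index ranges within each chain.
#'
#' @param model a [bead_model()].
#' @param path PDB output path.
#' @param sidecar_path sidecar CSV output path.
#' @export
write_bead_pdb <- function(model, path, sidecar_path) {
  n <- n_beads(model)
  resid <- integer(n)
  for (ch in unique(model$chain)) {
    idx <- which(model$chain == ch)
    resid[idx] <- seq_along(idx)
  }
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000L, substr(model$chain, 1, 1), resid,
    model$xyz[, 1], model$xyz[, 2], model$xyz[, 3])
  writeLines(c(lines, "END"), path)
  write.csv(domain_definitions(model), sidecar_path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a CA-only bead PDB with its domain sidecar
#'
#' @param path PDB file (CA-only ATOM records).
#' @param sidecar_path CSV with columns chain, start, end, domain, rigid
#'   (0-based half-open residue index ranges per chain).
#' @return a [bead_model()].
#' @export
read_bead_pdb <- function(path, sidecar_path) {
  txt <- readLines(path)
  at <- txt[startsWith(txt, "ATOM")]
  if (length(at) == 0) stop("format error: no ATOM records in ", path)
  chain <- trimws(substr(at, 22, 22))
  resid <- as.integer(substr(at, 23, 26))
  xyz <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
  for (ch in unique(chain)) {
    r <- resid[chain == ch]
    if (any(diff(r) <= 0)) {
      stop("format error: non-monotone residue numbering in chain ", ch)
    }
  }
  sc <- read.csv(sidecar_path, stringsAsFactors = FALSE)
  need <- c("chain", "start", "end", "domain", "rigid")
  if (!all(need %in% names(sc))) {
    stop("format error: sidecar must have columns ",
         paste(need, collapse = ", "))
  }
  n <- length(chain)
  domain <- rep(NA_character_, n)
  rigid_bead <- rep(NA, n)
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    pos0 <- seq_along(idx) - 1L # 0-based index within chain
    rows <- sc[sc$chain == ch, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      hit <- idx[pos0 >= rows$start[r] & pos0 < rows$end[r]]
      domain[hit] <- rows$domain[r]
      rigid_bead[hit] <- as.logical(rows$rigid[r])
    }
  }
  if (anyNA(domain)) {
    stop("labeling error: sidecar ranges do not cover all residues (",
         sum(is.na(domain)), " unlabeled)")
  }
  key <- paste(domain, chain, sep = ".")
  rigid <- tapply(rigid_bead, key, function(v) v[1])
  bead_model(xyz, chain, domain, rigid = as.list(rigid))
}
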