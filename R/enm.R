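#' Heavy-atom type classification
#'
#' Assigns each heavy atom a small integer class used to look up pairwise
#' weights in the interaction matrix.  The default 8-class scheme, shipped as
#' an editable CSV (`system.file("extdata", "atom_classes.csv", package =
#' "cgnma")`), distinguishes: 1 aliphatic C, 2 aromatic C, 3 carbonyl /
#' carboxyl / guanidinium C, 4 amide N, 5 charged or ring N, 6 neutral O,
#' 7 carboxylate O, 8 S.  Lookup falls back from (residue, atom) to
#' (*, atom) to an element default (C=1, N=4, O=6, S=8).
#'
#' @param resid,elety,elesy Parallel vectors of residue names, atom names
#'   and element symbols.
#' @param table Classification table (data frame with columns `residue`,
#'   `atom`, `class`); default is the shipped table.
#' @return Integer vector of atom classes.
#' @export
atom_classes <- function(resid, elety, elesy = element_from_name(elety),
                         table = load_atom_classes()) {
  spec <- match(paste(resid, elety), paste(table$residue, table$atom))
  wild <- match(paste("*", elety), paste(table$residue, table$atom))
  elem <- c(C = 1L, N = 4L, O = 6L, S = 8L)[elesy]
  cls <- ifelse(!is.na(spec), table$class[spec],
                ifelse(!is.na(wild), table$class[wild], elem))
  cls[is.na(cls)] <- 1L
  as.integer(cls)
}

#' @rdname atom_classes
#' @param path Optional path to a user-edited classification CSV.
#' @export
load_atom_classes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "atom_classes.csv", package = "cgnma")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Pairwise interaction matrix over atom classes
#'
#' Symmetric non-negative weight table indexed by atom-class pairs.  The
#' default is all ones (pure surface-contact weighting); users may supply
#' their own, e.g. favouring polar-polar contacts.
#'
#' @param weights Square symmetric numeric matrix, or `NULL` for the
#'   all-ones default over `n_classes` classes.
#' @param n_classes Number of atom classes.
#' @return The validated matrix.
#' @export
interaction_matrix <- function(weights = NULL, n_classes = 8L) {
  if (is.null(weights)) weights <- matrix(1, n_classes, n_classes)
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == ncol(weights),
            all(is.finite(weights)), all(weights >= 0),
            max(abs(weights - t(weights))) < 1e-12)
  weights
}

# van der Waals radii (Angstroms) by element, for the contact ramp
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)

#' Model parameters for the spring network
#'
#' @param model_kind `"encom_like"` (sequence-aware: surface-contact
#'   modulated springs) or `"anm"` (uniform springs within a cutoff,
#'   sequence-agnostic).
#' @param anm_cutoff Distance cutoff in Angstroms for the uniform spring
#'   term (default 18, the customary ANM value).
#' @param base_spring Spring constant (relative energy / A^2) of the uniform
#'   cutoff term.
#' @param covalent_spring Spring constant for sequence-consecutive residues
#'   of the same chain; much stiffer than non-bonded terms.
#' @param contact_scale Multiplier on the surface-contact weighted term.
#' @param im Interaction matrix (see [interaction_matrix()]).
#' @param contact_tol Contact ramp width in Angstroms (water-probe-like).
#' @return A list of class `cg_params`.
#' @export
potential_params <- function(model_kind = c("encom_like", "anm"),
                             anm_cutoff = 18, base_spring = 1,
                             covalent_spring = 100, contact_scale = 1,
                             im = interaction_matrix(), contact_tol = 1.4) {
  model_kind <- match.arg(model_kind)
  stopifnot(anm_cutoff > 0, base_spring >= 0, covalent_spring >= 0,
            contact_scale >= 0, contact_tol > 0)
  structure(list(model_kind = model_kind, anm_cutoff = anm_cutoff,
                 base_spring = base_spring, covalent_spring = covalent_spring,
                 contact_scale = contact_scale, im = interaction_matrix(im),
                 contact_tol = contact_tol),
            class = "cg_params")
}

# Linear surface-contact ramp per heavy-atom pair: 1 at full overlap of
# vdW spheres plus probe, 0 beyond (R_p + R_q + tol).
contact_ramp <- function(d, r_a, r_b, tol = 1.4) {
  pmin(1, pmax(0, (r_a + r_b + tol - d) / tol))
}

#' Surface-contact weight between two residues
#'
#' Sum over heavy-atom pairs of the interaction-matrix weight for the pair's
#' atom classes times a linear contact-surface ramp `s(d) = clamp((R_p + R_q
#' + tol - d)/tol, 0, 1)` with per-element van der Waals radii.  Symmetric in
#' its arguments; zero when every atom pair is beyond contact range.
#'
#' @param atoms_a,atoms_b Data frames of heavy atoms (columns `x`, `y`, `z`,
#'   `class`, `elesy`).
#' @param im Interaction matrix.
#' @param tol Contact ramp width, Angstroms.
#' @return Non-negative scalar weight.
#' @export
contact_weight <- function(atoms_a, atoms_b, im = interaction_matrix(),
                           tol = 1.4) {
  if (nrow(atoms_a) == 0L || nrow(atoms_b) == 0L) return(0)
  pa <- as.matrix(atoms_a[, c("x", "y", "z")])
  pb <- as.matrix(atoms_b[, c("x", "y", "z")])
  d <- sqrt(pmax(0, outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)))
  ra <- VDW_RADII[atoms_a$elesy]; ra[is.na(ra)] <- 1.7
  rb <- VDW_RADII[atoms_b$elesy]; rb[is.na(rb)] <- 1.7
  s <- contact_ramp(d, outer(ra, rep(1, length(rb))),
                    outer(rep(1, length(ra)), rb), tol)
  w <- im[cbind(rep(atoms_a$class, times = length(rb)),
                rep(atoms_b$class, each = length(ra)))]
  sum(s * matrix(w, nrow = length(ra)))
}

#' Build the residue-level spring network
#'
#' ANM mode connects every node pair within `anm_cutoff` with spring
#' constant `base_spring`.  The sequence-aware mode adds, on top of the
#' cutoff term, a stiff spring between sequence-consecutive residues of the
#' same chain and a surface-contact term `contact_scale * w_ij` computed
#' from the residues' heavy atoms, which makes the network depend on the
#' amino-acid sequence.  Springs with zero constant are omitted.
#'
#' @param model A `cg_model`.
#' @param s The preprocessed `cg_structure` the model came from (required
#'   for the sequence-aware contact term; ignored for ANM).
#' @param params A `cg_params` object.
#' @return An object of class `spring_network`: node coordinates plus a
#'   data frame of springs `(i, j, k, d0)`.
#' @export
build_network <- function(model, s = NULL, params = potential_params()) {
  stopifnot(inherits(model, "cg_model"), inherits(params, "cg_params"))
  n <- model$n
  xyz <- model$coords
  d <- as.matrix(stats::dist(xyz))
  pair <- which(upper.tri(d), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  dij <- d[pair]
  k <- params$base_spring * (dij <= params$anm_cutoff)
  if (params$model_kind == "encom_like") {
    consec <- model$chain[i] == model$chain[j] & abs(i - j) == 1L
    k[consec] <- k[consec] + params$covalent_spring
    if (params$contact_scale > 0) {
      if (is.null(s)) stop("sequence-aware mode needs the atomic structure")
      res_atoms <- split_residue_atoms(s, model)
      ext <- vapply(seq_len(n), function(t) {
        a <- res_atoms[[t]]
        max(sqrt((a$x - xyz[t, 1])^2 + (a$y - xyz[t, 2])^2 +
                 (a$z - xyz[t, 3])^2))
      }, 0)
      reach <- ext[i] + ext[j] + 2 * max(VDW_RADII) + params$contact_tol
      cand <- which(dij <= reach)
      for (t in cand) {
        w <- contact_weight(res_atoms[[i[t]]], res_atoms[[j[t]]],
                            params$im, params$contact_tol)
        k[t] <- k[t] + params$contact_scale * w
      }
    }
  }
  keep <- k > 0
  net <- list(node_coords = xyz,
              springs = data.frame(i = i[keep], j = j[keep], k = k[keep],
                                   d0 = dij[keep]),
              n = n)
  class(net) <- "spring_network"
  net
}

# Heavy atoms of each node's residue, with atom classes, in node order.
split_residue_atoms <- function(s, model) {
  at <- s$atom
  at$class <- atom_classes(at$resid, at$elety, at$elesy)
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  node_key <- paste(model$chain, model$resno, model$insert, sep = "|")
  lapply(node_key, function(k) at[key == k, , drop = FALSE])
}

#' @export
print.spring_network <- function(x, ...) {
  cat("spring_network:", x$n, "nodes,", nrow(x$springs), "springs\n")
  invisible(x)
}

#' Harmonic potential energy of a configuration
#'
#' `V = sum over springs of 0.5 * k_ij * (d_ij - d0_ij)^2`; zero at the
#' equilibrium coordinates.
#'
#' @param net A `spring_network`.
#' @param coords Numeric 3N-vector (or N x 3 matrix) of node positions.
#' @return Scalar energy (relative units).
#' @export
potential_energy <- function(net, coords) {
  if (is.matrix(coords)) coords <- as.vector(t(coords))
  if (length(coords) != 3L * net$n)
    stop("coordinate vector has length ", length(coords),
         ", expected ", 3L * net$n)
  p <- matrix(coords, ncol = 3, byrow = TRUE)
  sp <- net$springs
  dv <- p[sp$i, , drop = FALSE] - p[sp$j, , drop = FALSE]
  dij <- sqrt(rowSums(dv^2))
  sum(0.5 * sp$k * (dij - sp$d0)^2)
}

#' Analytic Hessian of the spring network
#'
#' Standard elastic-network Hessian at equilibrium: off-diagonal 3x3 block
#' for spring (i, j) is `-(k/d0^2) (r_i - r_j)(r_i - r_j)^T`; diagonal
#' blocks are minus the sum of the node's off-diagonal blocks, which makes
#' the matrix symmetric, positive semidefinite and translation invariant.
#'
#' @param net A `spring_network`.
#' @return 3N x 3N symmetric matrix (energy / A^2).
#' @export
build_hessian <- function(net) {
  n <- net$n
  H <- matrix(0, 3 * n, 3 * n)
  sp <- net$springs
  for (t in seq_len(nrow(sp))) {
    i <- sp$i[t]; j <- sp$j[t]
    rij <- net$node_coords[i, ] - net$node_coords[j, ]
    blk <- -(sp$k[t] / sp$d0[t]^2) * tcrossprod(rij)
    ii <- 3 * (i - 1) + 1:3; jj <- 3 * (j - 1) + 1:3
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

#' Finite-difference Hessian (test oracle)
#'
#' Central second differences of [potential_energy()] about equilibrium;
#' agrees with [build_hessian()] to O(h^2).  Quadratic cost in N: intended
#' for small fixtures only.
#'
#' @param net A `spring_network`.
#' @param h Step size in Angstroms.
#' @return 3N x 3N matrix.
#' @export
build_hessian_numeric <- function(net, h = 1e-4) {
  stopifnot(h > 0)
  x0 <- as.vector(t(net$node_coords))
  m <- length(x0)
  V <- function(x) potential_energy(net, x)
  H <- matrix(0, m, m)
  for (a in seq_len(m)) {
    ea <- replace(numeric(m), a, h)
    for (b in a:m) {
      eb <- replace(numeric(m), b, h)
      H[a, b] <- (V(x0 + ea + eb) - V(x0 + ea - eb) -
                  V(x0 - ea + eb) + V(x0 - ea - eb)) / (4 * h^2)
      H[b, a] <- H[a, b]
    }
  }
  H
}
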