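#' Sampling parameters for conformational ensembles
#'
#' @param max_rmsd Maximum RMSD distortion from the input structure, A.
#' @param min_rmsd Minimum RMSD between emitted conformations, A.
#' @param cap Hard limit on the number of conformers (default 350); when a
#'   grid exceeds it the minimum RMSD is automatically increased.
#' @return A list of class `sampling_params`.
#' @export
sampling_params <- function(max_rmsd = 2, min_rmsd = 0.5, cap = 350L) {
  stopifnot(min_rmsd > 0, min_rmsd <= max_rmsd, cap >= 1L)
  structure(list(max_rmsd = max_rmsd, min_rmsd = min_rmsd,
                 cap = as.integer(cap)), class = "sampling_params")
}

#' Uniform amplitude grid over selected modes
#'
#' Because eigenvectors are orthonormal, a displacement with per-mode
#' amplitudes `a_k` has RMSD `sqrt(sum(a_k^2) / N)` from the input, so the
#' RMSD constraints translate exactly into amplitude space: each mode gets
#' a 1-D grid `0, +/-delta, +/-2 delta, ...` with `delta = min_rmsd *
#' sqrt(N)` up to `max_rmsd * sqrt(N)`; the Cartesian product over modes is
#' then pruned of combinations whose implied RMSD exceeds `max_rmsd`.  The
#' all-zero tuple (the input structure) is always retained.  Points of the
#' resulting lattice are never closer than `delta`, which guarantees the
#' pairwise minimum-RMSD constraint; a greedy post-filter (keeping
#' lexicographically smaller tuples) enforces it for any non-lattice grid.
#'
#' @param mode_indices Integer vector of 1-based mode indices (> 6).
#' @param params A `sampling_params`.
#' @param n_nodes Node count N.
#' @param min_rmsd Optional override of `params$min_rmsd` (used by the cap
#'   enforcement loop).
#' @return Matrix of amplitude tuples, one row per conformer, columns named
#'   by mode index.
#' @export
amplitude_grid <- function(mode_indices, params, n_nodes,
                           min_rmsd = params$min_rmsd) {
  stopifnot(length(mode_indices) >= 1L, !anyDuplicated(mode_indices))
  delta <- min_rmsd * sqrt(n_nodes)
  A <- params$max_rmsd * sqrt(n_nodes)
  kmax <- floor(A / delta + 1e-9)
  axis <- delta * seq.int(-kmax, kmax)
  grid <- as.matrix(expand.grid(rep(list(axis), length(mode_indices))))
  colnames(grid) <- as.character(mode_indices)
  keep <- sqrt(rowSums(grid^2)) <= A + 1e-9
  grid <- grid[keep, , drop = FALSE]
  # order: input structure first, then by distance from it, then lexicographic
  ord <- order(rowSums(grid^2), apply(grid, 1, paste, collapse = ","))
  grid <- grid[ord, , drop = FALSE]
  # greedy min-distance guard; provably a no-op on a pure delta-lattice
  # (coordinates are integer multiples of delta, so nonzero separations are
  # at least delta), in which case the quadratic scan is skipped
  is_lattice <- all(abs(grid / delta - round(grid / delta)) < 1e-9)
  if (!is_lattice) {
    kept <- logical(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      if (r == 1L) { kept[1] <- TRUE; next }
      prev <- grid[kept, , drop = FALSE]
      d2 <- rowSums(sweep(prev, 2, grid[r, ])^2)
      kept[r] <- all(d2 >= (delta - 1e-9)^2)
    }
    grid <- grid[kept, , drop = FALSE]
  }
  grid
}

#' Enforce the conformer cap by raising the minimum RMSD
#'
#' While the amplitude grid holds more tuples than `params$cap`, the grid
#' spacing is increased geometrically (factor 1.2) and the grid rebuilt,
#' guaranteeing termination and uniform coverage at the final spacing.
#'
#' @inheritParams amplitude_grid
#' @return List with `tuples` (amplitude matrix) and `effective_min_rmsd`.
#' @export
enforce_cap <- function(mode_indices, params, n_nodes) {
  eff <- params$min_rmsd
  repeat {
    grid <- amplitude_grid(mode_indices, params, n_nodes, min_rmsd = eff)
    if (nrow(grid) <= params$cap)
      return(list(tuples = grid, effective_min_rmsd = eff))
    eff <- eff * 1.2
  }
}

#' Displace the structure along modes by given amplitudes
#'
#' Each conformer is the input plus the selected eigenvectors scaled by the
#' tuple's amplitudes.  By orthonormality its RMSD from the input equals
#' `sqrt(sum(a^2)/N)` exactly.
#'
#' @param model A `cg_model`.
#' @param modes A `mode_set` from the model's Hessian.
#' @param tuples Amplitude matrix from [amplitude_grid()] (columns named by
#'   mode index).
#' @return List with `coords` (conformers x 3N matrix), `amplitudes`, and
#'   `rmsd_from_input`.
#' @export
generate_conformers <- function(model, modes, tuples) {
  idx <- as.integer(colnames(tuples))
  stopifnot(all(idx > modes$n_trivial), all(idx <= length(modes$values)))
  x0 <- as.vector(t(model$coords))
  V <- modes$vectors[, idx, drop = FALSE]
  coords <- matrix(rep(x0, each = nrow(tuples)), nrow(tuples)) +
    tuples %*% t(V)
  list(coords = coords, amplitudes = tuples,
       rmsd_from_input = sqrt(rowSums(tuples^2) / model$n))
}

#' RMSD between two conformations in a common frame
#'
#' Plain root-mean-square deviation over nodes with no superposition: all
#' conformers are generated in the input frame and rigid-body modes are
#' excluded, so alignment is unnecessary.
#'
#' @param a,b 3N-vectors (or N x 3 matrices).
#' @return RMSD in Angstroms.
#' @export
rmsd <- function(a, b) {
  if (is.matrix(a)) a <- as.vector(t(a))
  if (is.matrix(b)) b <- as.vector(t(b))
  if (length(a) != length(b)) stop("coordinate vectors differ in length")
  sqrt(sum((a - b)^2) / (length(a) / 3))
}

# All pairwise RMSDs over the rows of a conformers x 3N matrix.
pairwise_rmsd <- function(coords) {
  as.matrix(stats::dist(coords)) / sqrt(ncol(coords) / 3)
}

#' Order conformers into a smooth visualization path
#'
#' Multi-start greedy heuristic for the (NP-hard) problem of ordering
#' conformations to minimize the summed RMSD between consecutive frames:
#' from every possible starting conformer, repeatedly hop to the nearest
#' unvisited one; the start whose completed path has the lowest total is
#' returned.  Ties break to the lower start index, then the lower next
#' index, making the result deterministic.
#'
#' @param D Symmetric pairwise-RMSD matrix with zero diagonal.
#' @return Integer permutation of `seq_len(nrow(D))`.
#' @export
order_trajectory <- function(D) {
  n <- nrow(D)
  stopifnot(n == ncol(D), max(abs(D - t(D))) < 1e-8)
  if (n == 1L) return(1L)
  best_path <- NULL
  best_total <- Inf
  for (s in seq_len(n)) {
    path <- integer(n)
    path[1] <- s
    visited <- logical(n); visited[s] <- TRUE
    total <- 0
    for (step in 2:n) {
      cand <- which(!visited)
      nxt <- cand[which.min(D[path[step - 1L], cand])]
      total <- total + D[path[step - 1L], nxt]
      path[step] <- nxt
      visited[nxt] <- TRUE
      if (total >= best_total) break
    }
    if (all(visited) && total < best_total) {
      best_total <- total
      best_path <- path
    }
  }
  best_path
}

#' Generate a full RMSD-constrained conformational ensemble
#'
#' Pipeline: amplitude grid over the selected modes, automatic cap
#' enforcement, conformer generation, pairwise RMSDs and visualization
#' ordering.
#'
#' @param model A `cg_model`.
#' @param modes Its `mode_set`.
#' @param mode_indices 1-based mode indices (> number of trivial modes).
#' @param params A `sampling_params`.
#' @return An object of class `cg_ensemble`.
#' @export
generate_ensemble <- function(model, modes, mode_indices,
                              params = sampling_params()) {
  stopifnot(all(mode_indices > modes$n_trivial))
  capped <- enforce_cap(mode_indices, params, model$n)
  conf <- generate_conformers(model, modes, capped$tuples)
  D <- pairwise_rmsd(conf$coords)
  structure(list(coords = conf$coords, amplitudes = conf$amplitudes,
                 rmsd_from_input = conf$rmsd_from_input,
                 pairwise_rmsd = D, ordering = order_trajectory(D),
                 effective_min_rmsd = capped$effective_min_rmsd,
                 params = params, mode_indices = mode_indices),
            class = "cg_ensemble")
}

#' @export
print.cg_ensemble <- function(x, ...) {
  cat("cg_ensemble:", nrow(x$coords), "conformers over modes",
      paste(x$mode_indices, collapse = ","),
      "\n  max rmsd", format(max(x$rmsd_from_input), digits = 3),
      "A; effective min rmsd", format(x$effective_min_rmsd, digits = 3),
      "A\n")
  invisible(x)
}

#' Sinusoidal single-mode trajectory
#'
#' Frames displace the structure along one internal mode by `amplitude *
#' sin(2 pi t / n_frames)` for `t = 0 .. n_frames - 1`, giving a loopable
#' oscillation whose maximum excursion has RMSD `amplitude / sqrt(N)`.
#'
#' @param model A `cg_model`.
#' @param modes Its `mode_set`.
#' @param mode_index 1-based mode index, must exceed the trivial count.
#' @param amplitude Peak amplitude (Angstrom * sqrt(N) units).
#' @param n_frames Number of frames.
#' @return Matrix of frames x 3N coordinates.
#' @export
mode_trajectory <- function(model, modes, mode_index, amplitude = NULL,
                            n_frames = 20L) {
  if (mode_index <= modes$n_trivial)
    stop("mode ", mode_index, " is a trivial rigid-body mode")
  if (is.null(amplitude)) amplitude <- 2 * sqrt(model$n)
  x0 <- as.vector(t(model$coords))
  v <- modes$vectors[, mode_index]
  t <- seq_len(n_frames) - 1L
  a <- amplitude * sin(2 * pi * t / n_frames)
  matrix(rep(x0, each = n_frames), n_frames) + outer(a, v)
}

#' Write ensemble outputs to a directory
#'
#' Emits the visualization-ordered multi-model PDB, one PDB per conformer,
#' the pairwise-RMSD table, the per-conformer amplitude table, and
#' sinusoidal trajectories for the first `n_mode_traj` internal modes
#' (default 20, truncated to the modes available).
#'
#' @param ens A `cg_ensemble`.
#' @param model The `cg_model` it was generated from.
#' @param modes The `mode_set`.
#' @param dir Output directory (created if needed).
#' @param n_mode_traj Number of internal-mode trajectories to write.
#' @param per_conformer Also write one PDB per conformer.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ens, model, modes, dir, n_mode_traj = 20L,
                           per_conformer = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_multimodel_pdb(ens$coords[ens$ordering, , drop = FALSE], model,
                       file.path(dir, "ensemble_trajectory.pdb"))
  if (per_conformer)
    for (i in seq_len(nrow(ens$coords)))
      write_multimodel_pdb(ens$coords[i, , drop = FALSE], model,
                           file.path(dir, sprintf("conformer_%03d.pdb", i)))
  utils::write.csv(as.data.frame(ens$amplitudes),
                   file.path(dir, "amplitudes.csv"), row.names = FALSE)
  utils::write.table(round(ens$pairwise_rmsd, 6),
                     file.path(dir, "pairwise_rmsd.txt"),
                     row.names = FALSE, col.names = FALSE)
  n_internal <- length(modes$values) - modes$n_trivial
  for (m in seq_len(min(n_mode_traj, n_internal))) {
    traj <- mode_trajectory(model, modes, modes$n_trivial + m)
    write_multimodel_pdb(traj, model,
                         file.path(dir, sprintf("mode_%02d_trajectory.pdb", m)))
  }
  invisible(dir)
}
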