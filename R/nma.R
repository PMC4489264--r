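#' Diagonalize a Hessian into a normal-mode set
#'
#' Eigendecomposition of the (symmetric) Hessian.  Eigenvalues are returned
#' in ascending order with orthonormal eigenvector columns.  Modes whose
#' eigenvalue falls below `zero_tol * max(eigenvalue)` are counted as
#' trivial; for a connected, non-collinear network these are exactly the six
#' rigid-body translations and rotations, so the first mode representing
#' internal motion is the 7th.  A different trivial count triggers a warning
#' naming the likely cause.
#'
#' @param H 3N x 3N symmetric Hessian matrix.
#' @param zero_tol Relative eigenvalue threshold for trivial modes.
#' @return An object of class `mode_set`: `values` (ascending), `vectors`
#'   (orthonormal columns), `n_trivial`, `zero_tol`, `n_nodes`.
#' @export
diagonalize <- function(H, zero_tol = 1e-8) {
  stopifnot(is.matrix(H), nrow(H) == ncol(H))
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H))))
    stop("Hessian is not symmetric")
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  n_trivial <- sum(values < zero_tol * max(values))
  if (n_trivial != 6L)
    warning("expected 6 trivial (rigid-body) modes but found ", n_trivial,
            "; the network is likely ",
            if (n_trivial > 6L) "disconnected or collinear"
            else "over-constrained or the tolerance too tight")
  structure(list(values = values, vectors = vectors,
                 n_trivial = n_trivial, zero_tol = zero_tol,
                 n_nodes = nrow(H) / 3L),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("mode_set:", length(x$values), "modes (", x$n_trivial, "trivial );",
      "first internal eigenvalue",
      format(x$values[x$n_trivial + 1], digits = 4), "\n")
  invisible(x)
}

#' Vibrational entropy of a mode set
#'
#' `S = -1/2 * sum(log(lambda))` over the non-trivial modes, in relative
#' entropy units (the additive constant from physical prefactors cancels in
#' differences, which is all the stability predictor uses).  Stiffening any
#' mode (raising its eigenvalue) strictly lowers S.
#'
#' @param modes A `mode_set`.
#' @return Scalar relative entropy.
#' @export
vibrational_entropy <- function(modes) {
  lam <- modes$values[-seq_len(modes$n_trivial)]
  if (any(lam <= 0))
    stop("non-trivial eigenvalue <= 0: network is not at a stable minimum")
  -0.5 * sum(log(lam))
}

#' Predicted per-residue b-factors
#'
#' Mean-square fluctuation estimate per node from the inverse-eigenvalue
#' weighted mode amplitudes: `b_i = sum_m |v_m at node i|^2 / lambda_m` over
#' non-trivial modes, in relative units.
#'
#' @param modes A `mode_set`.
#' @return Numeric vector of length N, all positive.
#' @export
predicted_bfactors <- function(modes) {
  idx <- seq.int(modes$n_trivial + 1L, length(modes$values))
  V <- modes$vectors[, idx, drop = FALSE]
  w <- V^2 %*% (1 / modes$values[idx])
  node <- rep(seq_len(modes$n_nodes), each = 3L)
  as.vector(rowsum(as.vector(w), node))
}

#' Squared overlap between a mode and a displacement
#'
#' Squared cosine `(v . d)^2 / (d . d)` between a unit mode vector and a
#' displacement: 1 when the displacement is parallel to the mode, 0 when
#' orthogonal; over a full orthonormal basis the overlaps sum to 1.
#'
#' @param mode_vector Unit 3N-vector (a `mode_set` eigenvector column).
#' @param displacement Nonzero 3N-vector.
#' @return Scalar in [0, 1].
#' @export
squared_overlap <- function(mode_vector, displacement) {
  stopifnot(length(mode_vector) == length(displacement))
  dd <- sum(displacement^2)
  if (dd == 0) stop("displacement vector is zero")
  v <- mode_vector / sqrt(sum(mode_vector^2))
  sum(v * displacement)^2 / dd
}

#' Export eigenvalues and b-factors as CSV
#'
#' @param modes A `mode_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_modes_csv <- function(modes, path) {
  utils::write.csv(data.frame(mode = seq_along(modes$values),
                              eigenvalue = modes$values,
                              trivial = seq_along(modes$values) <=
                                modes$n_trivial),
                   path, row.names = FALSE)
  invisible(path)
}
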