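#' Deterministic synthetic protein structures
#'
#' Generators for small, fully reproducible test structures: an ideal
#' alpha-helix CA trace, a two-domain dumbbell with a soft linker, a
#' collinear chain, and a two-chain dimer.  Side chains are represented by
#' deterministic stubs: the canonical heavy-atom names of each residue type
#' placed at 1.5 Angstrom spacing along a fixed outward direction, the same
#' convention [model_mutant()] uses, so fixtures and modelled mutants are
#' directly comparable.  All output depends only on the arguments, never on
#' the RNG state (except [make_ddg_table()], which seeds locally).
#'
#' @param n,n_per_domain,n_per_chain Residue counts.
#' @param seed Integer controlling the pseudo-random sequence assignment.
#' @param sequence Optional explicit one-letter sequence (overrides `seed`).
#' @param chain Chain identifier.
#' @name fixtures
NULL

# deterministic sequence without touching the RNG stream
pseudo_sequence <- function(n, seed) {
  idx <- (( seq_len(n) - 1L) * 7L + as.integer(seed)) %% 20L + 1L
  STANDARD_AA1[idx]
}

# Assemble a cg_structure from per-residue CA positions, residue types and
# outward stub directions (unit vectors, one per residue).
stub_structure <- function(ca, aa1, out_dir, chain, resno, source_id) {
  n <- nrow(ca)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    aa3 <- aa1to3(aa1[i])
    sc <- SIDECHAIN_ATOMS[[aa3]]
    names_i <- c("CA", sc)
    k <- length(sc)
    pos <- rbind(ca[i, ],
                 if (k) ca[rep(i, k), , drop = FALSE] +
                   outer(1.5 * seq_len(k), out_dir[i, ]))
    rows[[i]] <- data.frame(
      type = "ATOM", eleno = 0L, elety = names_i, resid = aa3,
      chain = chain[i], resno = resno[i], insert = "",
      x = pos[, 1], y = pos[, 2], z = pos[, 3], o = 1,
      elesy = element_from_name(names_i),
      is_hetero = FALSE, stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  at$eleno <- seq_len(nrow(at))
  rownames(at) <- NULL
  structure(list(atom = at, source_id = source_id, preprocessed = TRUE),
            class = "cg_structure")
}

#' @describeIn fixtures Ideal alpha-helix CA trace (rise 1.5 A, 100 degrees
#'   per residue, radius 2.3 A) with radially outward side-chain stubs;
#'   consecutive CA-CA distance is ~3.8 A.
#' @export
make_helix <- function(n, seed = 1, sequence = NULL, chain = "A") {
  stopifnot(n >= 2)
  aa1 <- if (is.null(sequence)) pseudo_sequence(n, seed)
         else strsplit(sequence, "")[[1]]
  stopifnot(length(aa1) == n)
  t <- seq_len(n) - 1L
  ang <- t * 100 * pi / 180
  ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
  # stubs tilt 60 degrees toward the helix axis so they pack against the
  # next turn's residues, as real side chains do; purely radial stubs would
  # leave every side-chain atom outside contact range of its neighbours
  phi <- 60 * pi / 180
  out_dir <- cbind(cos(ang) * cos(phi), sin(ang) * cos(phi),
                   rep(sin(phi), n))
  stub_structure(ca, aa1, out_dir, rep(chain, n), seq_len(n),
                 sprintf("helix_n%d_seed%d", n, seed))
}

#' @describeIn fixtures Two compact mirror-image domains on the arms of a
#'   bent (70 degree) hinge whose zigzag geometry leaves no spurious zero
#'   modes; its slowest internal mode is the hinge-opening motion that
#'   separates the domains.  The residue sequence is palindromic so the two
#'   halves are exact mirror images across the hinge plane.
#' @param linker_len Number of hinge residues including the vertex (odd,
#'   >= 3).
#' @export
make_dumbbell <- function(n_per_domain = 16, linker_len = 9, seed = 1,
                          chain = "A") {
  stopifnot(n_per_domain >= 8, linker_len >= 3, linker_len %% 2 == 1)
  arm <- (linker_len - 1L) %/% 2L
  th <- 35 * pi / 180                       # half-opening angle
  dirB <- c(sin(th), -cos(th), 0)           # right arm direction
  perp <- c(cos(th), sin(th), 0)            # in-plane normal to the arm
  amp <- 3.0                                # zigzag amplitude, Angstroms
  arm_b <- t(vapply(seq_len(arm), function(i)
    dirB * 3.8 * i + amp * ((i %% 2) * 2 - 1) * perp +
      amp * ((((i + 1) %/% 2) %% 2) * 2 - 1) * c(0, 0, 1), numeric(3)))
  m <- ceiling(n_per_domain^(1 / 3))
  g <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m), z = seq_len(m)))
  g <- g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE][seq_len(n_per_domain), ]
  dom_b <- sweep(sweep(g * 3.8, 2, colMeans(g * 3.8)), 2,
                 -dirB * 3.8 * (arm + 2.2))
  right <- rbind(arm_b, dom_b)              # vertex-outward order
  left <- right
  left[, 1] <- -left[, 1]                   # exact mirror across x = 0
  half_n <- nrow(right)
  ca <- rbind(left[rev(seq_len(half_n)), , drop = FALSE],
              matrix(0, 1, 3), right)
  n <- nrow(ca)
  aa_half <- pseudo_sequence(half_n, seed)
  aa1 <- c(rev(aa_half), "G", aa_half)
  # stubs point away from the structure centroid; x-component mirrored
  ctr <- colMeans(ca)
  out_dir <- t(apply(ca, 1, function(p) {
    v <- p - ctr
    if (sum(v^2) < 1e-12) v <- c(0, 1, 0)
    v / sqrt(sum(v^2))
  }))
  stub_structure(ca, aa1, out_dir, rep(chain, n), seq_len(n),
                 sprintf("dumbbell_d%d_l%d_seed%d", n_per_domain, linker_len,
                         seed))
}

#' Inter-domain separation direction of a dumbbell fixture
#'
#' Unit 3N-vector moving the two domains of a [make_dumbbell()] structure
#' apart along the line joining their centroids (hinge residues static);
#' useful as a reference displacement for squared-overlap checks.
#'
#' @param n_per_domain,linker_len As passed to [make_dumbbell()].
#' @return Unit numeric vector of length 3N.
#' @export
dumbbell_separation_vector <- function(n_per_domain = 16, linker_len = 9) {
  n <- 2L * n_per_domain + linker_len
  arm <- (linker_len - 1L) %/% 2L
  d1 <- seq_len(n_per_domain)
  d2 <- seq.int(n - n_per_domain + 1L, n)
  db <- make_dumbbell(n_per_domain, linker_len)
  ca <- db$atom[db$atom$elety == "CA", c("x", "y", "z")]
  u <- colMeans(ca[d2, ]) - colMeans(ca[d1, ])
  u <- u / sqrt(sum(u^2))
  sep <- matrix(0, n, 3)
  sep[d1, ] <- matrix(-u, n_per_domain, 3, byrow = TRUE)
  sep[d2, ] <- matrix(u, n_per_domain, 3, byrow = TRUE)
  as.vector(t(sep)) / sqrt(2 * n_per_domain)
}

#' @describeIn fixtures Collinear glycine chain (no side-chain atoms): a
#'   degenerate geometry whose Hessian has more than six null directions.
#' @export
make_line <- function(n, seed = 1, chain = "A") {
  stopifnot(n >= 2)
  ca <- cbind(3.8 * (seq_len(n) - 1L), 0, 0)
  stub_structure(ca, rep("G", n), matrix(0, n, 3), rep(chain, n),
                 seq_len(n), sprintf("line_n%d", n))
}

#' @describeIn fixtures Two helices as chains A and B, separated by
#'   `separation` Angstroms along x; small separations put the chains in
#'   contact, large ones disconnect the network.
#' @param separation Inter-chain offset in Angstroms.
#' @export
make_dimer <- function(n_per_chain = 10, separation = 8, seed = 1) {
  a <- make_helix(n_per_chain, seed = seed, chain = "A")
  b <- make_helix(n_per_chain, seed = seed + 1, chain = "B")
  b$atom$x <- b$atom$x + separation
  b$atom$chain <- "B"
  at <- rbind(a$atom, b$atom)
  at$eleno <- seq_len(nrow(at))
  structure(list(atom = at,
                 source_id = sprintf("dimer_n%d_sep%g", n_per_chain, separation),
                 preprocessed = TRUE),
            class = "cg_structure")
}

#' @describeIn fixtures Render any fixture (or parsed structure) as PDB text.
#' @param s A `cg_structure`.
#' @export
make_pdb_text <- function(s) structure_to_pdb_text(s)

#' Synthetic calibration table for the stability-combination fit
#'
#' Draws predictor columns and builds `ddG_exp = alpha * ddG_A +
#' beta * ddG_B + noise`, the generating model that [calibrate()] should
#' recover.
#'
#' @param alpha,beta Generating coefficients.
#' @param n Number of mutations (rows).
#' @param sigma Gaussian noise standard deviation, kcal/mol.
#' @param seed RNG seed (restored on exit).
#' @return Data frame with columns `ddG_A`, `ddG_B`, `ddG_exp`.
#' @export
make_ddg_table <- function(alpha = -1, beta = 0.4, n = 300, sigma = 0.1,
                           seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  a <- stats::rnorm(n, 0, 1)
  b <- stats::rnorm(n, 1, 1.5)
  data.frame(ddG_A = a, ddG_B = b,
             ddG_exp = alpha * a + beta * b + stats::rnorm(n, 0, sigma))
}
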