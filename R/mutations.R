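#' Single-point mutation specifications
#'
#' A mutation is addressed by chain, author residue number (plus optional
#' insertion code), wild-type and target amino acid.  [enumerate_mutations()]
#' expands a compact range grammar, `"CHAIN:START[-END]:TARGETS"`, where
#' `TARGETS` is a string of one-letter residue codes or `ALL` for all 19
#' non-wild-type residues at each position.  Positions absent from the
#' structure are skipped with a warning; the wild-type residue itself is
#' never emitted as a target.
#'
#' @param spec_text Character vector of range specifications.
#' @param model A `cg_model` (supplies wild-type identities and numbering).
#' @return Data frame with columns `chain`, `resno`, `insert`, `wt`, `mut`.
#' @examples
#' m <- build_coarse_model(make_helix(12))
#' head(enumerate_mutations("A:3-5:ALL", m))
#' @export
enumerate_mutations <- function(spec_text, model) {
  out <- list()
  for (spec in spec_text) {
    parts <- strsplit(trimws(spec), ":", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop("unparsable mutation spec (expected CHAIN:START[-END]:TARGETS): ",
           spec)
    chain <- parts[1]
    rng <- strsplit(parts[2], "-", fixed = TRUE)[[1]]
    pos <- suppressWarnings(as.integer(rng))
    if (anyNA(pos) || length(pos) > 2L)
      stop("unparsable residue range in mutation spec: ", parts[2])
    pos <- seq(pos[1], pos[length(pos)])
    targets <- if (toupper(parts[3]) == "ALL") STANDARD_AA1
               else strsplit(toupper(parts[3]), "")[[1]]
    bad <- setdiff(targets, STANDARD_AA1)
    if (length(bad))
      stop("unknown target residue type(s): ", paste(bad, collapse = ""))
    for (p in pos) {
      hit <- which(model$chain == chain & model$resno == p)
      if (length(hit) == 0L) {
        warning("position ", chain, ":", p,
                " not found in structure; skipped")
        next
      }
      for (h in hit) {
        wt <- model$aa[h]
        mut <- setdiff(targets, wt)
        if (length(mut))
          out[[length(out) + 1L]] <- data.frame(
            chain = chain, resno = p, insert = model$insert[h],
            wt = wt, mut = mut, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), wt = character(),
                      mut = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Compact mutation identifier, e.g. "KA13Q": wt, chain, resno(+insert), mut.
mutation_string <- function(spec) {
  paste0(spec$wt, spec$chain, spec$resno, spec$insert, spec$mut)
}

#' Build a mutant structure
#'
#' `sequence_swap` mode keeps the backbone and CA fixed and replaces the
#' mutated residue's side-chain heavy atoms with the canonical atom census
#' of the target residue, placed deterministically at 1.5 Angstrom spacing
#' along the CA-to-CB direction (CB built from ideal tetrahedral geometry
#' when absent, or pointing away from the neighbouring-CA midpoint on a bare
#' CA trace).  This changes the surface-contact weights, hence the
#' sequence-aware Hessian, without moving any node.  `external_command` mode
#' runs a user-supplied command template (placeholders `{input}`,
#' `{output}`, `{mutation}`) and parses the PDB it produces; a failing
#' command makes the function return `NULL` with a warning so a batch run
#' can skip that mutation rather than abort.
#'
#' @param s Preprocessed `cg_structure`.
#' @param spec One-row data frame (or list) with `chain`, `resno`, `insert`,
#'   `wt`, `mut`.
#' @param mode `"sequence_swap"` or `"external_command"`.
#' @param external_cmd Command template for `external_command` mode.
#' @return A mutated `cg_structure`, or `NULL` if an external command
#'   failed.
#' @export
model_mutant <- function(s, spec, mode = c("sequence_swap", "external_command"),
                         external_cmd = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "cg_structure"))
  if (spec$wt == spec$mut) stop("mutation target equals wild type")
  if (!spec$mut %in% STANDARD_AA1 || !spec$wt %in% STANDARD_AA1)
    stop("non-standard amino acid in mutation spec")
  at <- s$atom
  sel <- at$chain == spec$chain & at$resno == spec$resno &
    at$insert == (if (is.null(spec$insert)) "" else spec$insert)
  if (!any(sel)) stop("residue ", spec$chain, ":", spec$resno,
                      " not found in structure")
  wt3 <- unique(at$resid[sel])
  if (aa3to1(wt3) != spec$wt)
    stop("wild-type mismatch at ", spec$chain, ":", spec$resno, ": structure has ",
         wt3, ", spec says ", spec$wt)

  if (mode == "external_command") {
    fin <- tempfile(fileext = ".pdb"); fout <- tempfile(fileext = ".pdb")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    writeLines(structure_to_pdb_text(s), fin)
    cmd <- gsub("{input}", fin, external_cmd, fixed = TRUE)
    cmd <- gsub("{output}", fout, cmd, fixed = TRUE)
    cmd <- gsub("{mutation}", mutation_string(spec), cmd, fixed = TRUE)
    status <- try(system(cmd), silent = TRUE)
    if (inherits(status, "try-error") || !identical(status, 0L) ||
        !file.exists(fout)) {
      warning("external mutant builder failed for ", mutation_string(spec),
              "; mutation skipped")
      return(NULL)
    }
    mut <- try(preprocess(read_pdb(fout)), silent = TRUE)
    if (inherits(mut, "try-error")) {
      warning("external mutant output unparsable for ", mutation_string(spec),
              "; mutation skipped")
      return(NULL)
    }
    return(mut)
  }

  res <- at[sel, , drop = FALSE]
  ca <- unlist(res[res$elety == "CA", c("x", "y", "z")])
  u <- sidechain_direction(at, res, ca)
  mut3 <- aa1to3(spec$mut)
  sc <- SIDECHAIN_ATOMS[[mut3]]
  keep_bb <- sel & at$elety %in% BACKBONE_ATOMS
  at_new <- at[!sel | keep_bb, , drop = FALSE]
  at_new$resid[at_new$chain == spec$chain & at_new$resno == spec$resno &
               at_new$insert == res$insert[1]] <- mut3
  if (length(sc)) {
    stub <- data.frame(
      type = "ATOM", eleno = 0L, elety = sc, resid = mut3,
      chain = spec$chain, resno = spec$resno, insert = res$insert[1],
      x = ca[1] + 1.5 * seq_along(sc) * u[1],
      y = ca[2] + 1.5 * seq_along(sc) * u[2],
      z = ca[3] + 1.5 * seq_along(sc) * u[3],
      o = 1, elesy = element_from_name(sc), is_hetero = FALSE,
      stringsAsFactors = FALSE)
    ins_after <- max(which(at_new$chain == spec$chain &
                           at_new$resno == spec$resno &
                           at_new$insert == res$insert[1]))
    at_new <- rbind(at_new[seq_len(ins_after), , drop = FALSE], stub,
                    at_new[-seq_len(ins_after), , drop = FALSE])
  }
  at_new$eleno <- seq_len(nrow(at_new))
  rownames(at_new) <- NULL
  structure(list(atom = at_new,
                 source_id = paste0(s$source_id, "_", mutation_string(spec)),
                 preprocessed = s$preprocessed),
            class = "cg_structure")
}

# Unit vector for stub side-chain placement.  Preference order: existing
# CA->CB; ideal tetrahedral direction from N, CA, C; away from the midpoint
# of the flanking CA atoms; +z.
sidechain_direction <- function(at, res, ca) {
  norm1 <- function(v) {
    nv <- sqrt(sum(v^2)); if (nv < 1e-9) NULL else v / nv
  }
  cb <- res[res$elety == "CB", c("x", "y", "z")]
  if (nrow(cb) == 1L) {
    u <- norm1(unlist(cb) - ca)
    if (!is.null(u)) return(u)
  }
  nn <- res[res$elety == "N", c("x", "y", "z")]
  cc <- res[res$elety == "C", c("x", "y", "z")]
  if (nrow(nn) == 1L && nrow(cc) == 1L) {
    b1 <- norm1(unlist(nn) - ca); b2 <- norm1(unlist(cc) - ca)
    if (!is.null(b1) && !is.null(b2)) {
      bis <- norm1(-(b1 + b2))
      perp <- norm1(c(b1[2] * b2[3] - b1[3] * b2[2],
                      b1[3] * b2[1] - b1[1] * b2[3],
                      b1[1] * b2[2] - b1[2] * b2[1]))
      if (!is.null(bis) && !is.null(perp))
        return(cos(0.9553) * bis + sin(0.9553) * perp)  # ~54.75 deg
    }
  }
  same_chain <- at[at$chain == res$chain[1] & at$elety == "CA", , drop = FALSE]
  pos <- match(res$resno[1], same_chain$resno)
  nb <- same_chain[c(pos - 1, pos + 1), c("x", "y", "z")]
  nb <- nb[stats::complete.cases(nb), , drop = FALSE]
  if (nrow(nb) > 0L) {
    u <- norm1(ca - colMeans(nb))
    if (!is.null(u)) return(u)
  }
  c(0, 0, 1)
}

#' Vibrational entropy difference between two mode sets
#'
#' `S(mutant) - S(wild type)`; negative values mean the mutation rigidifies
#' the structure.  Antisymmetric under argument swap.  Both mode sets must
#' come from networks of the same size with the same trivial-mode count.
#'
#' @param wt_modes,mut_modes `mode_set` objects.
#' @return Scalar entropy difference, relative units.
#' @export
ddS_vib <- function(wt_modes, mut_modes) {
  if (length(wt_modes$values) != length(mut_modes$values))
    stop("mode sets differ in size")
  if (wt_modes$n_trivial != mut_modes$n_trivial)
    stop("mode sets differ in trivial-mode count")
  vibrational_entropy(mut_modes) - vibrational_entropy(wt_modes)
}

#' Linear stability combination model
#'
#' Combines the vibrational-entropy score with an external enthalpic
#' predictor as `ddG = alpha * ddG_A + beta * ddG_B`.  The default
#' coefficients (alpha = -1.12, beta = 0.38) are the published bootstrap
#' medians for the entropy + FoldX pairing.
#'
#' @param alpha Coefficient on the vibrational-entropy term.
#' @param beta Coefficient on the external enthalpic term.
#' @return A list of class `combination_model`.
#' @export
combination_model <- function(alpha = -1.12, beta = 0.38) {
  stopifnot(is.finite(alpha), is.finite(beta))
  structure(list(alpha = alpha, beta = beta), class = "combination_model")
}

#' @rdname combination_model
#' @param ddS Vibrational entropy difference (the `ddG_A` term).
#' @param ddG_B External enthalpic score, kcal/mol; `NA` yields `NA`.
#' @param model A `combination_model`.
#' @export
combine_ddg <- function(ddS, ddG_B, model = combination_model()) {
  if (is.na(ddG_B)) return(NA_real_)
  model$alpha * ddS + model$beta * ddG_B
}

#' Read external enthalpic scores from CSV
#'
#' Two-column CSV (`mutation`, `ddG`) keyed by compact mutation strings
#' such as `"KA13Q"` (wild type, chain, residue number, target).
#'
#' @param path CSV path.
#' @return Named numeric vector.
#' @export
read_ddgb_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}

#' Score a batch of mutations
#'
#' For each mutation: build the mutant with [model_mutant()], assemble the
#' sequence-aware network for wild type and mutant, diagonalize both, and
#' report the vibrational entropy difference, the combined stability score
#' when an external enthalpic value is available, and the per-residue
#' b-factor difference profile (mutant minus wild type).
#'
#' @param s Preprocessed `cg_structure` of the wild type.
#' @param specs Data frame from [enumerate_mutations()].
#' @param params `cg_params` for network construction.
#' @param ddgb Optional named vector of external scores keyed by mutation
#'   string (see [read_ddgb_csv()]).
#' @param cmodel `combination_model` for the linear combination.
#' @param mode Mutant-building mode passed to [model_mutant()].
#' @param external_cmd Command template for external mode.
#' @return A list of class `mutation_scores`: `scores` data frame
#'   (`mutation`, `ddS_vib`, `ddG_B`, `ddG_combined`), `bfactor_delta`
#'   matrix (mutations x residues), `wt_bfactors`, and `skipped`.
#' @export
score_mutations <- function(s, specs, params = potential_params(),
                            ddgb = NULL, cmodel = combination_model(),
                            mode = "sequence_swap", external_cmd = NULL) {
  model <- build_coarse_model(s)
  wt_modes <- diagonalize(build_hessian(build_network(model, s, params)))
  wt_b <- predicted_bfactors(wt_modes)
  n_mut <- nrow(specs)
  scores <- data.frame(mutation = character(n_mut), ddS_vib = NA_real_,
                       ddG_B = NA_real_, ddG_combined = NA_real_,
                       stringsAsFactors = FALSE)
  deltas <- matrix(NA_real_, n_mut, model$n)
  skipped <- character(0)
  for (r in seq_len(n_mut)) {
    spec <- specs[r, ]
    ms <- mutation_string(spec)
    scores$mutation[r] <- ms
    mut_s <- tryCatch(model_mutant(s, spec, mode = mode,
                                   external_cmd = external_cmd),
                      error = function(e) {
                        warning("skipping ", ms, ": ", conditionMessage(e))
                        NULL
                      })
    if (is.null(mut_s)) { skipped <- c(skipped, ms); next }
    mut_model <- build_coarse_model(mut_s)
    mut_modes <- diagonalize(build_hessian(build_network(mut_model, mut_s,
                                                         params)))
    scores$ddS_vib[r] <- ddS_vib(wt_modes, mut_modes)
    if (!is.null(ddgb) && ms %in% names(ddgb))
      scores$ddG_B[r] <- ddgb[[ms]]
    scores$ddG_combined[r] <- combine_ddg(scores$ddS_vib[r], scores$ddG_B[r],
                                          cmodel)
    deltas[r, ] <- bfactor_delta_profile(wt_b, predicted_bfactors(mut_modes))
  }
  rownames(deltas) <- scores$mutation
  structure(list(scores = scores, bfactor_delta = deltas,
                 wt_bfactors = wt_b, specs = specs, skipped = skipped),
            class = "mutation_scores")
}

#' @export
print.mutation_scores <- function(x, ...) {
  cat("mutation_scores:", nrow(x$scores), "mutations (",
      length(x$skipped), "skipped )\n")
  print(utils::head(x$scores))
  invisible(x)
}

#' Per-residue flexibility difference profile
#'
#' @param wt_b,mut_b Predicted b-factor vectors of equal length.
#' @return `mut_b - wt_b`; positive entries mean gained flexibility.
#' @export
bfactor_delta_profile <- function(wt_b, mut_b) {
  if (length(wt_b) != length(mut_b))
    stop("b-factor vectors differ in length")
  mut_b - wt_b
}

#' Job-wide color scale for flexibility differences
#'
#' Scale for mapping b-factor difference profiles onto a blue-white-red
#' gradient: `S = min(max|delta|, 3 * sd(|delta|))` over all mutations and
#' residues of one job.  If the standard deviation degenerates to zero with
#' nonzero differences, the maximum is used.  Colors are only comparable
#' among mutations scaled together in the same job.
#'
#' @param all_deltas Numeric matrix (mutations x residues) of b-factor
#'   differences.
#' @return Non-negative scalar scale.
#' @export
color_scale <- function(all_deltas) {
  d <- abs(as.numeric(all_deltas))
  d <- d[!is.na(d)]
  if (length(d) == 0L) stop("empty delta matrix")
  mx <- max(d)
  if (mx == 0) return(0)
  s3 <- 3 * stats::sd(d)
  if (is.na(s3) || s3 == 0) mx else min(mx, s3)
}

#' PyMOL coloring script for one mutation's flexibility profile
#'
#' Writes b-factor differences, clamped by the job color scale, as per
#' residue `alter` + `spectrum` commands on a blue-white-red ramp.
#'
#' @param delta Per-residue difference vector.
#' @param scale Job color scale from [color_scale()].
#' @param model The `cg_model` giving chain/residue numbering.
#' @param path Output `.pml` path.
#' @return `path`, invisibly.
#' @export
write_pml <- function(delta, scale, model, path) {
  z <- if (scale > 0) pmin(1, pmax(-1, delta / scale)) else delta * 0
  lines <- c("# flexibility difference coloring (blue = rigidified, red = more flexible)",
             sprintf("alter (chain %s and resi %s%s), b = %.6f",
                     model$chain, model$resno, model$insert, z),
             "spectrum b, blue_white_red, minimum=-1, maximum=1")
  writeLines(lines, path)
  invisible(path)
}

#' Stability heatmap grid and top-stabilizing summary
#'
#' Arranges combined stability scores (falling back to the entropy-only
#' score when no external term is present) on a positions x target-residue
#' grid.  The grid is only emitted when more than two positions and more
#' than two target types were scored, mirroring the batch-analysis
#' interface; the summary of the `top_n` most stabilizing mutations (most
#' negative predicted ddG first) is always produced.
#'
#' @param res A `mutation_scores` object.
#' @param top_n Summary length (default 25).
#' @return List with `grid` (matrix or `NULL`) and `top` (data frame).
#' @export
heatmap_matrix <- function(res, top_n = 25L) {
  sc <- res$scores
  val <- ifelse(is.na(sc$ddG_combined), sc$ddS_vib, sc$ddG_combined)
  pos <- paste0(res$specs$chain, res$specs$resno, res$specs$insert)
  typ <- res$specs$mut
  grid <- NULL
  if (length(unique(pos)) > 2L && length(unique(typ)) > 2L) {
    grid <- matrix(NA_real_, length(unique(pos)), length(unique(typ)),
                   dimnames = list(unique(pos), sort(unique(typ))))
    grid[cbind(match(pos, rownames(grid)), match(typ, colnames(grid)))] <- val
  } else {
    message("heatmap skipped: needs more than two positions and two target types")
  }
  ord <- order(val, na.last = NA)
  top <- utils::head(data.frame(mutation = sc$mutation[ord],
                                ddS_vib = sc$ddS_vib[ord],
                                ddG_B = sc$ddG_B[ord],
                                ddG_combined = sc$ddG_combined[ord],
                                predicted_ddG = val[ord],
                                stringsAsFactors = FALSE), top_n)
  list(grid = grid, top = top)
}

#' Bootstrap calibration of the combination coefficients
#'
#' Given a table of per-mutation predictions (`ddG_A`, the entropic score;
#' `ddG_B`, the enthalpic score) and experimental values (`ddG_exp`),
#' repeatedly resamples the rows with replacement and fits the no-intercept
#' least-squares model `ddG_exp ~ alpha * ddG_A + beta * ddG_B` on each
#' sample, minimizing the RMSE.  Reports bootstrap medians of the
#' coefficients and the median +/- SD of the RMSE on all rows and on the
#' stabilizing / destabilizing subsets split at `subset_threshold` kcal/mol.
#' A rank-deficient bootstrap sample is redrawn (the count is reported); if
#' the full table itself is rank deficient the collinear column is dropped
#' and its coefficient reported as `NA`.
#'
#' @param table Data frame with columns `ddG_A`, `ddG_B`, `ddG_exp`.
#' @param n_bootstrap Number of bootstrap samples.
#' @param subset_threshold Stabilizing/destabilizing split, kcal/mol.
#' @return A list of class `calibration_result`.
#' @export
calibrate <- function(table, n_bootstrap = 1000L, subset_threshold = 0.5) {
  stopifnot(nrow(table) >= 3L, n_bootstrap >= 1L,
            all(c("ddG_A", "ddG_B", "ddG_exp") %in% names(table)))
  X_full <- cbind(ddG_A = table$ddG_A, ddG_B = table$ddG_B)
  y <- table$ddG_exp
  use <- qr(X_full)$rank == 2L
  cols <- if (use) 1:2 else which(apply(X_full, 2, function(v) any(v != 0)))[1]
  n <- nrow(table)
  ab <- matrix(NA_real_, n_bootstrap, 2L)
  rmse <- matrix(NA_real_, n_bootstrap, 3L,
                 dimnames = list(NULL, c("all", "stabilizing", "destabilizing")))
  n_resampled <- 0L
  for (b in seq_len(n_bootstrap)) {
    for (attempt in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      X <- X_full[idx, cols, drop = FALSE]
      if (qr(X)$rank == length(cols)) break
      n_resampled <- n_resampled + 1L
    }
    fit <- stats::lm.fit(X, y[idx])
    ab[b, cols] <- fit$coefficients
    pred <- X %*% fit$coefficients
    err <- y[idx] - pred
    rmse[b, "all"] <- sqrt(mean(err^2))
    stab <- y[idx] < subset_threshold
    if (any(stab)) rmse[b, "stabilizing"] <- sqrt(mean(err[stab]^2))
    if (any(!stab)) rmse[b, "destabilizing"] <- sqrt(mean(err[!stab]^2))
  }
  structure(list(
    alpha_median = stats::median(ab[, 1], na.rm = TRUE),
    beta_median = if (use) stats::median(ab[, 2], na.rm = TRUE) else NA_real_,
    rmse = data.frame(
      subset = colnames(rmse),
      median = apply(rmse, 2, stats::median, na.rm = TRUE),
      sd = apply(rmse, 2, stats::sd, na.rm = TRUE),
      row.names = NULL),
    n_bootstrap = n_bootstrap, n_resampled = n_resampled,
    full_rank = use), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration_result over", x$n_bootstrap, "bootstrap samples\n",
      " alpha =", format(x$alpha_median, digits = 4),
      " beta =", format(x$beta_median, digits = 4), "\n")
  print(x$rmse)
  invisible(x)
}
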