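#' Parse PDB-format text into a structure object
#'
#' Reads ATOM/HETATM records from PDB-format text.  Multi-model files are
#' collapsed to the first MODEL; alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by the first altloc label seen).
#'
#' @param text Character scalar or vector of lines in PDB format.
#' @param source_id Free-text identifier stored on the returned object.
#' @return An object of class `cg_structure`: a list with an `atom`
#'   data frame (`type`, `elety`, `resid`, `chain`, `resno`, `insert`,
#'   `x`, `y`, `z`, `o`, `elesy`, `is_hetero`) and `source_id`.
#' @examples
#' s <- parse_pdb(make_pdb_text(make_helix(5)))
#' nrow(s$atom)
#' @export
parse_pdb <- function(text, source_id = "input") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  is_atom_line <- rec == "ATOM  " | rec == "HETATM"
  if (!any(rec == "ATOM  "))
    stop("no ATOM records found: not a parsable PDB structure")
  # validate fixed-width coordinate fields before handing off to the reader
  for (i in which(is_atom_line)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz) || !all(is.finite(xyz)))
      stop("malformed coordinates on line ", i, ": ", trimws(lines[i]))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$elesy[is.na(at$elesy) | at$elesy == ""] <- element_from_name(
    at$elety[is.na(at$elesy) | at$elesy == ""])
  # altloc: keep blank-alt atoms; among alternates of one named atom keep the
  # highest occupancy, first label on ties
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[at$alt != ""])) {
      idx <- which(key == k & at$alt != "")
      if (length(idx) > 1L) {
        best <- idx[which.max(at$o[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    at <- at[keep, , drop = FALSE]
  }
  at <- at[, c("type", "eleno", "elety", "resid", "chain", "resno",
               "insert", "x", "y", "z", "o", "elesy")]
  at$chain[is.na(at$chain)] <- " "
  at$is_hetero <- at$type == "HETATM"
  rownames(at) <- NULL
  structure(list(atom = at, source_id = source_id, preprocessed = FALSE),
            class = "cg_structure")
}

#' Read a PDB file from disk
#'
#' @param path Path to a PDB file.
#' @return A `cg_structure` (see [parse_pdb()]).
#' @export
read_pdb <- function(path) {
  parse_pdb(readLines(path, warn = FALSE), source_id = basename(path))
}

#' @export
print.cg_structure <- function(x, ...) {
  res <- residue_keys(x)
  cat("cg_structure:", x$source_id, "\n ",
      nrow(x$atom), "atoms,", length(unique(res)), "residues, chains:",
      paste(sort(unique(x$atom$chain)), collapse = " "),
      if (x$preprocessed) "(preprocessed)" else "", "\n")
  invisible(x)
}

residue_keys <- function(s) {
  paste(s$atom$chain, s$atom$resno, s$atom$insert, sep = "|")
}

#' Strip heteroatoms and hydrogens, select chains
#'
#' Prepares a parsed structure for coarse-grained modelling: keeps only the
#' requested chains, removes heteroatoms (selenomethionine is retained and
#' mapped to methionine) and hydrogens, drops non-standard residues and any
#' residue lacking a CA after stripping.  Residues of all selected chains are
#' retained together so that inter-chain contacts enter the spring network.
#'
#' @param s A `cg_structure` from [parse_pdb()].
#' @param chains Character vector of chain identifiers; `NULL` keeps all.
#' @return A preprocessed `cg_structure`.
#' @export
preprocess <- function(s, chains = NULL) {
  stopifnot(inherits(s, "cg_structure"))
  at <- s$atom
  avail <- unique(at$chain[!at$is_hetero])
  if (is.null(chains)) chains <- avail
  if (length(chains) == 0L) stop("at least one chain must be selected")
  missing_ch <- setdiff(chains, avail)
  if (length(missing_ch))
    stop("chain(s) ", paste(missing_ch, collapse = ", "),
         " not present; available: ", paste(avail, collapse = ", "))
  at <- at[at$chain %in% chains, , drop = FALSE]
  # selenomethionine comes in as HETATM; fold it back into MET
  is_mse <- at$resid == "MSE"
  if (any(is_mse)) {
    at$resid[is_mse] <- "MET"
    at$elety[is_mse & at$elety == "SE"] <- "SD"
    at$elesy[is_mse & at$elesy == "SE"] <- "S"
    at$is_hetero[is_mse] <- FALSE
    at$type[is_mse] <- "ATOM"
  }
  at <- at[!at$is_hetero, , drop = FALSE]
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  nonstd <- !(at$resid %in% STANDARD_AA3)
  if (any(nonstd)) {
    warning("dropping non-standard residue(s): ",
            paste(unique(at$resid[nonstd]), collapse = ", "))
    at <- at[!nonstd, , drop = FALSE]
  }
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  has_ca <- key %in% key[at$elety == "CA"]
  if (any(!has_ca)) {
    warning("dropping ", length(unique(key[!has_ca])),
            " residue(s) lacking a CA atom")
    at <- at[has_ca, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no residues survive preprocessing")
  rownames(at) <- NULL
  structure(list(atom = at, source_id = s$source_id, preprocessed = TRUE),
            class = "cg_structure")
}

#' Coarse-grain a structure to one node per residue
#'
#' Reduces a preprocessed structure to its CA trace: one point mass per
#' residue at the CA position.  Node order is deterministic: chains in order
#' of first appearance, then author residue number, then insertion code.
#'
#' @param s A preprocessed `cg_structure`.
#' @return An object of class `cg_model` with fields `coords` (N x 3 matrix
#'   of CA positions), `chain`, `resno`, `insert`, `aa` (one-letter codes),
#'   `n`, and `sequence` (one string per chain).
#' @export
build_coarse_model <- function(s) {
  stopifnot(inherits(s, "cg_structure"))
  if (!isTRUE(s$preprocessed))
    s <- preprocess(s)
  ca <- s$atom[s$atom$elety == "CA", , drop = FALSE]
  ord <- order(match(ca$chain, unique(ca$chain)), ca$resno,
               match(ca$insert, c("", LETTERS)))
  ca <- ca[ord, , drop = FALSE]
  if (nrow(ca) < 2L) stop("coarse model needs at least 2 residues")
  aa <- aa3to1(ca$resid)
  m <- list(coords = cbind(x = ca$x, y = ca$y, z = ca$z),
            chain = ca$chain, resno = ca$resno, insert = ca$insert,
            aa = aa, n = nrow(ca),
            sequence = vapply(split(aa, factor(ca$chain, unique(ca$chain))),
                              paste, "", collapse = ""))
  class(m) <- "cg_model"
  m
}

#' @export
print.cg_model <- function(x, ...) {
  cat("cg_model:", x$n, "nodes;",
      paste(names(x$sequence), x$sequence, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Write conformers as a multi-model PDB file
#'
#' Writes a series of CA-trace conformations as consecutive MODEL/ENDMDL
#' blocks, in the order given.  Coordinates survive a round trip through
#' [parse_pdb()] to the three decimals of the fixed-width PDB format.
#'
#' @param conformers A list of N x 3 coordinate matrices (or a single matrix
#'   with 3N columns, one row per conformer), all with the same node count.
#' @param model The `cg_model` supplying residue names and numbering.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(conformers, model, path) {
  if (is.matrix(conformers))
    conformers <- lapply(seq_len(nrow(conformers)),
                         function(i) matrix(conformers[i, ], ncol = 3, byrow = TRUE))
  if (length(conformers) == 0L) stop("no conformers to write")
  sizes <- vapply(conformers, function(cc) length(cc), 0L)
  if (length(unique(sizes)) != 1L || sizes[1] != 3L * model$n)
    stop("conformers disagree in size or do not match the model")
  xyz <- do.call(rbind, lapply(conformers, function(cc) as.vector(t(cc))))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   type = rep("ATOM", model$n),
                   resno = model$resno, resid = aa1to3(model$aa),
                   chain = model$chain, insert = model$insert,
                   elety = rep("CA", model$n), elesy = rep("C", model$n))
  invisible(path)
}

# Serialize a cg_structure back to PDB text (single model).
structure_to_pdb_text <- function(s) {
  at <- s$atom
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  bio3d::write.pdb(pdb = NULL, file = tf,
                   xyz = as.vector(rbind(at$x, at$y, at$z)),
                   type = at$type, resno = at$resno, resid = at$resid,
                   chain = at$chain, insert = at$insert, elety = at$elety,
                   o = at$o, elesy = at$elesy)
  readLines(tf, warn = FALSE)
}
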