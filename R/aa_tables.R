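#' @title Amino-acid reference tables
#' @description Canonical heavy-atom compositions of the 20 standard amino
#'   acids, used by the coarse-grained fixtures and by the deterministic
#'   side-chain stub placement of [model_mutant()].
#' @name aa_tables
#' @keywords internal
NULL

# Backbone heavy atoms common to all residues (OXT only at C-termini).
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Canonical side-chain heavy atoms, in standard PDB naming and branch order.
SIDECHAIN_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

STANDARD_AA3 <- names(SIDECHAIN_ATOMS)
STANDARD_AA1 <- bio3d::aa321(STANDARD_AA3)

aa1to3 <- function(aa1) {
  out <- STANDARD_AA3[match(aa1, STANDARD_AA1)]
  if (anyNA(out)) stop("unknown one-letter amino acid code: ",
                       paste(aa1[is.na(out)], collapse = ", "))
  out
}

aa3to1 <- function(aa3) bio3d::aa321(aa3)

# Chemical element from a PDB heavy-atom name (first non-digit character).
element_from_name <- function(name) {
  substr(gsub("^[0-9 ]+", "", name), 1L, 1L)
}
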