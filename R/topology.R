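## Residue topology: canonical heavy atoms, chi-angle definitions, and a
## Z-matrix (internal-coordinate build order) per residue type with ideal
## covalent geometry. Bond lengths in Angstrom, angles/dihedrals in degrees.
##
## Dihedral references are either one of "chi1".."chi4" or a character of the
## form "chi2+180"/"chi1-122" (offset from a chi), or a fixed number.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

## Canonical number of chi angles per residue type.
N_CHI <- c(ALA = 0L, ARG = 4L, ASN = 2L, ASP = 2L, CYS = 1L, GLN = 3L,
           GLU = 3L, GLY = 0L, HIS = 2L, ILE = 2L, LEU = 2L, LYS = 4L,
           MET = 3L, PHE = 2L, PRO = 2L, SER = 1L, THR = 1L, TRP = 2L,
           TYR = 2L, VAL = 1L)

## Atoms (a, b, c, d) whose torsion defines each chi.
CHI_ATOMS <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

## Z-matrix rows: atom, ref atoms a/b/c (torsion a-b-c-atom), bond, angle, tor.
## CB is placed first from (C, N, CA) with a fixed torsion giving L chirality.
zrow <- function(atom, a, b, c, bond, angle, tor) {
  list(atom = atom, a = a, b = b, c = c,
       bond = bond, angle = angle, tor = tor)
}

## L-amino-acid chirality: torsion C-N-CA-CB is about -122.6 degrees.
cb_row <- function(bond = 1.53) zrow("CB", "C", "N", "CA", bond, 110.4, -122.6)

SIDECHAIN_ZMAT <- list(
  ALA = list(cb_row(1.52)),
  SER = list(cb_row(),
             zrow("OG", "N", "CA", "CB", 1.417, 110.8, "chi1")),
  CYS = list(cb_row(),
             zrow("SG", "N", "CA", "CB", 1.808, 113.8, "chi1")),
  THR = list(cb_row(),
             zrow("OG1", "N", "CA", "CB", 1.433, 109.6, "chi1"),
             zrow("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-120")),
  VAL = list(cb_row(),
             zrow("CG1", "N", "CA", "CB", 1.527, 110.5, "chi1"),
             zrow("CG2", "N", "CA", "CB", 1.527, 110.5, "chi1+122")),
  LEU = list(cb_row(),
             zrow("CG", "N", "CA", "CB", 1.53, 116.3, "chi1"),
             zrow("CD1", "CA", "CB", "CG", 1.521, 110.7, "chi2"),
             zrow("CD2", "CA", "CB", "CG", 1.521, 110.7, "chi2+122")),
  ILE = list(cb_row(),
             zrow("CG1", "N", "CA", "CB", 1.53, 110.4, "chi1"),
             zrow("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-122"),
             zrow("CD1", "CA", "CB", "CG1", 1.513, 113.8, "chi2")),
  MET = list(cb_row(),
             zrow("CG", "N", "CA", "CB", 1.52, 114.1, "chi1"),
             zrow("SD", "CA", "CB", "CG", 1.803, 112.7, "chi2"),
             zrow("CE", "CB", "CG", "SD", 1.791, 100.9, "chi3")),
  PRO = list(cb_row(1.53),
             zrow("CG", "N", "CA", "CB", 1.49, 104.5, "chi1"),
             zrow("CD", "CA", "CB", "CG", 1.51, 106.1, "chi2")),
  ## six-membered rings use exact hexagon geometry so a 180-degree chi2
  ## flip maps the ring onto itself (name-swapped)
  PHE = list(cb_row(),
             zrow("CG", "N", "CA", "CB", 1.50, 113.8, "chi1"),
             zrow("CD1", "CA", "CB", "CG", 1.39, 120.0, "chi2"),
             zrow("CD2", "CA", "CB", "CG", 1.39, 120.0, "chi2+180"),
             zrow("CE1", "CB", "CG", "CD1", 1.39, 120.0, 180),
             zrow("CE2", "CB", "CG", "CD2", 1.39, 120.0, 180),
             zrow("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0)),
  TYR = list(cb_row(),
             zrow("CG", "N", "CA", "CB", 1.51, 113.9, "chi1"),
             zrow("CD1", "CA", "CB", "CG", 1.39, 120.0, "chi2"),
             zrow("CD2", "CA", "CB", "CG", 1.39, 120.0, "chi2+180"),
             zrow("CE1", "CB", "CG", "CD1", 1.39, 120.0, 180),
             zrow("CE2", "CB", "CG", "CD2", 1.39, 120.0, 180),
             zrow("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0),
             zrow("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 180)),
  TRP = list(cb_row(),
             zrow("CG", "N", "CA", "CB", 1.50, 113.6, "chi1"),
             zrow("CD1", "CA", "CB", "CG", 1.365, 126.9, "chi2"),
             zrow("CD2", "CA", "CB", "CG", 1.433, 126.8, "chi2+180"),
             zrow("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
             zrow("CE2", "CB", "CG", "CD2", 1.409, 107.2, 180),
             zrow("CE3", "CD1", "CG", "CD2", 1.40, 133.9, 180),
             zrow("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 180),
             zrow("CZ3", "CE2", "CD2", "CE3", 1.39, 118.6, 0),
             zrow("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0)),
  ASP = list(cb_row(),
             zrow("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
             zrow("OD1", "CA", "CB", "CG", 1.249, 118.4, "chi2"),
             zrow("OD2", "CA", "CB", "CG", 1.249, 118.4, "chi2+180")),
  ASN = list(cb_row(),
             zrow("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
             zrow("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
             zrow("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2+180")),
  GLU = list(cb_row(),
             zrow("CG", "N", "CA", "CB", 1.52, 114.1, "chi1"),
             zrow("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
             zrow("OE1", "CB", "CG", "CD", 1.249, 118.4, "chi3"),
             zrow("OE2", "CB", "CG", "CD", 1.249, 118.4, "chi3+180")),
  GLN = list(cb_row(),
             zrow("CG", "N", "CA", "CB", 1.52, 114.1, "chi1"),
             zrow("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
             zrow("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3"),
             zrow("NE2", "CB", "CG", "CD", 1.328, 116.4, "chi3+180")),
  HIS = list(cb_row(),
             zrow("CG", "N", "CA", "CB", 1.50, 113.8, "chi1"),
             zrow("ND1", "CA", "CB", "CG", 1.378, 122.7, "chi2"),
             zrow("CD2", "CA", "CB", "CG", 1.356, 131.0, "chi2+180"),
             zrow("CE1", "CB", "CG", "ND1", 1.32, 109.2, 180),
             zrow("NE2", "CB", "CG", "CD2", 1.374, 107.2, 180)),
  LYS = list(cb_row(),
             zrow("CG", "N", "CA", "CB", 1.52, 114.1, "chi1"),
             zrow("CD", "CA", "CB", "CG", 1.52, 111.3, "chi2"),
             zrow("CE", "CB", "CG", "CD", 1.52, 111.3, "chi3"),
             zrow("NZ", "CG", "CD", "CE", 1.489, 111.9, "chi4")),
  ARG = list(cb_row(),
             zrow("CG", "N", "CA", "CB", 1.52, 114.1, "chi1"),
             zrow("CD", "CA", "CB", "CG", 1.52, 111.3, "chi2"),
             zrow("NE", "CB", "CG", "CD", 1.46, 112.0, "chi3"),
             zrow("CZ", "CG", "CD", "NE", 1.329, 124.2, "chi4"),
             zrow("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
             zrow("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  GLY = list()
)

## Canonical side-chain heavy atoms per residue type (build order).
sidechain_atoms <- function(restype) {
  z <- SIDECHAIN_ZMAT[[restype]]
  if (is.null(z)) stop("unknown residue type: ", restype)
  vapply(z, function(r) r$atom, character(1))
}

## All canonical heavy atoms (backbone N/CA/C/O + side chain).
residue_atoms <- function(restype) {
  c("N", "CA", "C", "O", sidechain_atoms(restype))
}

## Symmetry-equivalent atom-name swaps (chemically or effectively
## indistinguishable namings) used by RMSD and chi-accuracy.
SYMMETRY_SWAPS <- list(
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2")),
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2")),
  ARG = list(c("NH1", "NH2")),
  LEU = list(c("CD1", "CD2")),
  VAL = list(c("CG1", "CG2"))
)

## Chi angles with a 180-degree naming ambiguity (terminal symmetric group).
CHI_SYMMETRIC <- c(ASP = 2L, PHE = 2L, TYR = 2L, GLU = 3L)

## Element from a PDB heavy-atom name.
element_of <- function(atom_name) {
  substr(gsub("[0-9]", "", atom_name), 1, 1)
}

## van der Waals radii (Angstrom) by element, used by the contact score and
## the direct-contact detector.
VDW_RADII <- c(C = 1.548, O = 1.348, N = 1.400, S = 1.808)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

AA_MAP <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

three2one <- function(restype) names(AA_MAP)[match(restype, AA_MAP)]

one2three <- function(seq1) {
  map <- AA_MAP
  letters1 <- strsplit(toupper(seq1), "")[[1]]
  out <- map[letters1]
  if (anyNA(out)) {
    stop("invalid one-letter residue code(s): ",
         paste(letters1[is.na(out)], collapse = ", "))
  }
  unname(out)
}
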