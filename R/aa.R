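## Amino-acid bookkeeping shared across modules.

AA_1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

## Sidechain pseudo-atoms carried per residue type beyond the backbone
## (N, CA, C, O).  Only atoms that some analysis addresses by name are kept:
## the cysteine S-gamma, the basic nitrogens of Lys/Arg/His, carboxylate
## oxygens of Asp/Glu, aromatic ring atoms, and a CB marking the sidechain.
SIDECHAIN_ATOMS <- list(
  GLY = character(0),
  ALA = "CB", VAL = "CB", LEU = "CB", ILE = "CB", PRO = "CB",
  MET = "CB", SER = "CB", THR = "CB", ASN = "CB", GLN = "CB",
  CYS = c("CB", "SG"),
  LYS = c("CB", "NZ"),
  ARG = c("CB", "NE", "NH1", "NH2"),
  HIS = c("CB", "ND1", "CE1", "NE2"),
  ASP = c("CB", "OD1", "OD2"),
  GLU = c("CB", "OE1", "OE2"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("CB", "CG", "CD1", "NE1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

## six-membered ring used for aromatic centroids (Trp: benzene ring)
RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

ACID_OXYGENS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

ACIDIC_RES <- c("ASP", "GLU")
BASIC_RES <- c("LYS", "ARG", "HIS")
TITRATABLE_RES <- c(ACIDIC_RES, BASIC_RES)

## residues treated as wholly hydrophobic for the minimum-distance contact
## map; amphipathic sidechains (e.g. Lys aliphatic stem) are excluded
HYDROPHOBIC_DEFAULT <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

atom_element <- function(name) {
  e <- substr(name, 1, 1)
  if (!all(e %in% names(ELEMENT_MASS)))
    abort("unknown element for atom name(s): ",
          paste(unique(name[!e %in% names(ELEMENT_MASS)]), collapse = ", "))
  e
}
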