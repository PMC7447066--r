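## Domain types: topology of the two-chain saposin-fold dimer.

#' Native and non-native cysteine pair registries
#'
#' The saposin fold carries three conserved disulfide bonds; in the PSI dimer
#' template these connect Cys6-Cys99, Cys31-Cys71 and Cys37-Cys68 within each
#' monomer. The two spatially adjacent bonds admit two geometrically feasible
#' non-native (interchange) pairings, Cys31-Cys37 and Cys68-Cys71.
#'
#' @return Integer matrix with one row per pair and columns `i`, `j`.
#' @export
native_cys_pairs <- function() {
  m <- rbind(c(6L, 99L), c(31L, 71L), c(37L, 68L))
  dimnames(m) <- list(c("6-99", "31-71", "37-68"), c("i", "j"))
  m
}

#' @rdname native_cys_pairs
#' @export
nonnative_cys_pairs <- function() {
  m <- rbind(c(31L, 37L), c(68L, 71L))
  dimnames(m) <- list(c("31-37", "68-71"), c("i", "j"))
  m
}

default_helix_spans <- function() {
  list(H1 = c(4L, 19L), H2 = c(24L, 39L), H3 = c(64L, 79L), H4 = c(83L, 98L))
}

#' Construct a dimer topology
#'
#' A topology holds the residue and atom roster of a two-chain homodimer
#' together with the registries every analysis consults: the native disulfide
#' pairs, the disordered loop span, helix spans, and the set of residue types
#' treated as wholly hydrophobic.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid` (3-letter
#'   code), `elety` (atom name), `element`, `mass` (amu); one row per atom,
#'   chains ordered A then B with identical rosters.
#' @param cys_pairs Integer matrix of native S-gamma pairs (per chain).
#' @param loop_span Inclusive residue interval of the disordered loop.
#' @param helix_spans Named list of inclusive residue intervals; must not
#'   overlap `loop_span`.
#' @param hydrophobic_set Residue names treated as wholly hydrophobic.
#' @return An object of class `psi_topology`.
#' @export
psi_topology <- function(atoms,
                         cys_pairs = native_cys_pairs(),
                         loop_span = c(40L, 63L),
                         helix_spans = default_helix_spans(),
                         hydrophobic_set = HYDROPHOBIC_DEFAULT) {
  need <- c("chain", "resno", "resid", "elety", "element", "mass")
  if (!all(need %in% names(atoms)))
    abort("atoms must have columns: ", paste(need, collapse = ", "))
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  top <- structure(
    list(atoms = atoms,
         cys_pairs = cys_pairs,
         loop_span = if (!is.null(loop_span)) as.integer(loop_span),
         helix_spans = helix_spans,
         hydrophobic_set = hydrophobic_set),
    class = "psi_topology")
  validate_topology(top)
  top
}

validate_topology <- function(top) {
  atoms <- top$atoms
  chains <- unique(atoms$chain)
  if (!identical(sort(chains), c("A", "B")))
    abort("topology must have exactly chains A and B")
  a <- atoms[atoms$chain == "A", ]
  b <- atoms[atoms$chain == "B", ]
  if (!identical(a[c("resno", "resid", "elety")],
                 structure(b[c("resno", "resid", "elety")],
                           row.names = attr(a, "row.names"))))
    abort("chains A and B must have identical residue/atom rosters (homodimer)")
  seq3 <- residue_table(top, "A")$resid
  if (!all(seq3 %in% AA_1TO3))
    abort("unknown residue name(s): ",
          paste(setdiff(seq3, AA_1TO3), collapse = ", "))
  if (any(residue_table(top, "A")$resno < 1L))
    abort("residue numbering must be 1-based and positive")
  nres <- n_residues(top)
  for (k in seq_len(nrow(top$cys_pairs))) {
    for (r in top$cys_pairs[k, ]) {
      if (r < 1L || r > nres) abort("cysteine pair residue ", r, " out of range")
      if (seq3[r] != "CYS")
        abort("residue ", r, " in cys_pairs is ", seq3[r], ", not CYS")
    }
  }
  ls <- top$loop_span
  if (!is.null(ls)) {
    if (length(ls) != 2L || ls[1] > ls[2] || ls[1] < 1L || ls[2] > nres)
      abort("loop_span must be an inclusive interval within the chain")
    for (nm in names(top$helix_spans)) {
      hs <- top$helix_spans[[nm]]
      if (any(seq.int(hs[1], hs[2]) %in% seq.int(ls[1], ls[2])))
        abort("helix span ", nm, " overlaps the loop span")
    }
  }
  invisible(top)
}

#' @export
print.psi_topology <- function(x, ...) {
  cat("psi_topology:", n_residues(x), "residues/chain,",
      nrow(x$atoms), "atoms total\n")
  cat("  native cys pairs:",
      paste(rownames(x$cys_pairs), collapse = ", "), "\n")
  if (!is.null(x$loop_span))
    cat("  loop span:", x$loop_span[1], "-", x$loop_span[2], "\n")
  invisible(x)
}

#' Residue table of one chain
#'
#' @param top A `psi_topology`.
#' @param chain Chain identifier, `"A"` or `"B"`.
#' @return Data frame with columns `resno`, `resid`.
#' @export
residue_table <- function(top, chain = "A") {
  a <- top$atoms[top$atoms$chain == chain, ]
  out <- unique(a[c("resno", "resid")])
  rownames(out) <- NULL
  out
}

#' @rdname residue_table
#' @export
n_residues <- function(top) nrow(residue_table(top, "A"))

loop_residues <- function(top) {
  if (is.null(top$loop_span)) return(integer(0))
  seq.int(top$loop_span[1], top$loop_span[2])
}

#' Resolve atom indices by selection predicate
#'
#' The selection vocabulary mirrors the analyses: `"backbone"` (N, CA, C, O),
#' `"calpha"`, `"sidechain"`, `"sg"` (cysteine S-gamma), `"heavy"`
#' (non-hydrogen) and `"all"`. The loop can be excluded for the
#' loop-partitioned metrics.
#'
#' @param top A `psi_topology`.
#' @param select One of `"all"`, `"backbone"`, `"calpha"`, `"sidechain"`,
#'   `"sg"`, `"heavy"`.
#' @param chain Optional chain filter (`"A"`/`"B"`).
#' @param residues Optional residue-number filter (applies to both chains
#'   unless `chain` is given).
#' @param exclude_loop If `TRUE`, drop atoms of residues in the loop span.
#' @return Integer vector of atom row indices into `top$atoms`.
#' @export
atom_indices <- function(top, select = "all", chain = NULL, residues = NULL,
                         exclude_loop = FALSE) {
  a <- top$atoms
  keep <- switch(match.arg(select,
                           c("all", "backbone", "calpha", "sidechain",
                             "sg", "heavy")),
                 all = rep(TRUE, nrow(a)),
                 backbone = a$elety %in% BACKBONE_ATOMS,
                 calpha = a$elety == "CA",
                 sidechain = !(a$elety %in% BACKBONE_ATOMS),
                 sg = a$elety == "SG",
                 heavy = a$element != "H")
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(residues)) keep <- keep & a$resno %in% residues
  if (exclude_loop) keep <- keep & !(a$resno %in% loop_residues(top))
  which(keep)
}

## index of the S-gamma atom of one cysteine, with a named error
sg_index <- function(top, chain, resno) {
  i <- which(top$atoms$chain == chain & top$atoms$resno == resno &
               top$atoms$elety == "SG")
  if (length(i) != 1L)
    abort("no S-gamma atom for residue ", resno, " in chain ", chain)
  i
}

## one atom of a residue by name, with a named error
named_atom_index <- function(top, chain, resno, elety) {
  i <- which(top$atoms$chain == chain & top$atoms$resno == resno &
               top$atoms$elety %in% elety)
  if (length(i) == 0L)
    abort("residue ", resno, " (chain ", chain, ") lacks atom(s) ",
          paste(elety, collapse = "/"))
  i
}
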