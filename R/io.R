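## Ensemble and DSSP-series I/O, plus analysis-window selection.

#' Read a coordinate ensemble
#'
#' Two formats are supported: multi-model PDB (coordinates converted from
#' Angstrom to nm) and the package's frame-CSV dialect (one row per atom per
#' frame with columns `frame`, `time_ps`, `chain`, `resid`, `resname`,
#' `atomname`, `x`, `y`, `z`, coordinates already in nm). The atom roster
#' must be constant across frames; a mismatch is rejected naming the
#' offending model/frame.
#'
#' A guard against dimers broken across periodic boundaries rejects frames
#' in which any consecutive intra-chain CA-CA distance exceeds
#' `max_bond_nm`; genuinely broken images jump by box lengths, so the
#' default 0.7 nm separates them cleanly from thermal fluctuation.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"pdb"` or `"csv"`.
#' @param topology Optional `psi_topology` to attach; if `NULL` one is
#'   reconstructed from the file's residue records with the default
#'   registries (dropping registry entries the roster cannot satisfy).
#' @param stride_ps Frame spacing used to synthesise times when the format
#'   carries none (PDB).
#' @param check_whole Apply the broken-image guard.
#' @param max_bond_nm Guard threshold (nm).
#' @return A `psi_trajectory`.
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "csv"),
                          topology = NULL, stride_ps = 1,
                          check_whole = TRUE, max_bond_nm = 0.7) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", csv = "csv",
                     abort("unknown ensemble format for extension '.", ext,
                           "'; use multi-model PDB or frame-CSV"))
  }
  traj <- switch(format,
                 pdb = read_ensemble_pdb(path, topology, stride_ps),
                 csv = read_ensemble_csv(path, topology))
  if (check_whole) check_whole_frames(traj, max_bond_nm)
  traj
}

read_ensemble_pdb <- function(path, topology = NULL, stride_ps = 1) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts)) {
    model_id <- findInterval(which(is_atom), model_starts)
    rosters <- split(substr(lines[is_atom], 13, 27), model_id)
    for (m in seq_along(rosters)[-1]) {
      if (!identical(rosters[[m]], rosters[[1]]))
        abort("atom roster of model ", m, " differs from model 1")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz / 10  # Angstrom -> nm
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (is.null(topology)) {
    at <- pdb$atom
    atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                        elety = at$elety,
                        element = atom_element(at$elety),
                        stringsAsFactors = FALSE)
    atoms$mass <- ELEMENT_MASS[atoms$element]
    topology <- topology_from_atoms(atoms)
  }
  psi_trajectory(topology, xyz, times = (seq_len(nrow(xyz)) - 1L) * stride_ps)
}

read_ensemble_csv <- function(path, topology = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_ps", "chain", "resid", "atomname", "x", "y", "z")
  if (!all(need %in% names(d)))
    abort("frame-CSV must have columns: ", paste(need, collapse = ", "))
  frames <- sort(unique(d$frame))
  d <- d[order(match(d$frame, frames)), ]
  per <- split(d, factor(d$frame, levels = frames))
  key <- function(x) paste(x$chain, x$resid, x$atomname)
  k1 <- key(per[[1]])
  for (m in seq_along(per)[-1]) {
    if (!identical(key(per[[m]]), k1))
      abort("atom roster of frame ", frames[m], " differs from frame ",
            frames[1])
  }
  if (is.null(topology)) {
    if (!"resname" %in% names(d))
      abort("frame-CSV without a resname column needs an explicit topology")
    p1 <- per[[1]]
    atoms <- data.frame(chain = p1$chain, resno = p1$resid,
                        resid = p1$resname, elety = p1$atomname,
                        element = atom_element(p1$atomname),
                        stringsAsFactors = FALSE)
    atoms$mass <- ELEMENT_MASS[atoms$element]
    topology <- topology_from_atoms(atoms)
  }
  if (nrow(per[[1]]) != nrow(topology$atoms))
    abort("frame-CSV atom count does not match the topology")
  xyz <- t(vapply(per, function(p) as.numeric(t(as.matrix(p[c("x", "y", "z")]))),
                  numeric(3L * nrow(per[[1]]))))
  times <- vapply(per, function(p) p$time_ps[1], numeric(1))
  psi_trajectory(topology, xyz, times)
}

## Rebuild a psi_topology from a bare atom table, keeping only the default
## registry entries (cys pairs, loop, helices) the roster can satisfy.
topology_from_atoms <- function(atoms, loop_span = c(40L, 63L),
                                helix_spans = default_helix_spans(),
                                hydrophobic_set = HYDROPHOBIC_DEFAULT) {
  rt <- unique(atoms[atoms$chain == "A", c("resno", "resid")])
  has_sg <- function(r) any(atoms$chain == "A" & atoms$resno == r &
                              atoms$elety == "SG")
  pairs <- native_cys_pairs()
  ok <- apply(pairs, 1, function(p)
    all(p %in% rt$resno) && all(rt$resid[match(p, rt$resno)] == "CYS") &&
      all(vapply(p, has_sg, logical(1))))
  nres <- max(rt$resno)
  if (!is.null(loop_span) && (loop_span[1] < 1L || loop_span[2] > nres))
    loop_span <- NULL  # default registry does not fit this roster
  helix_spans <- Filter(function(h) h[2] <= nres, helix_spans)
  psi_topology(atoms, cys_pairs = pairs[ok, , drop = FALSE],
               loop_span = loop_span, helix_spans = helix_spans,
               hydrophobic_set = hydrophobic_set)
}

check_whole_frames <- function(traj, max_bond_nm = 0.7) {
  top <- traj$topology
  for (ch in c("A", "B")) {
    ca <- atom_indices(top, "calpha", chain = ch)
    if (length(ca) < 2L) next
    cols_a <- xyz_cols(ca[-length(ca)])
    cols_b <- xyz_cols(ca[-1L])
    for (f in seq_len(n_frames(traj))) {
      d <- matrix(traj$xyz[f, cols_b] - traj$xyz[f, cols_a],
                  ncol = 3L, byrow = TRUE)
      if (any(row_norms(d) > max_bond_nm))
        abort("frame ", f, " (chain ", ch, ") has a CA-CA step > ",
              max_bond_nm, " nm; molecule likely broken across periodic ",
              "boundaries")
    }
  }
  invisible(traj)
}

#' Write a coordinate ensemble
#'
#' @param traj A `psi_trajectory`.
#' @param path Output file; extension picks the format unless given.
#' @param format `"auto"`, `"pdb"` (multi-model, Angstrom) or `"csv"`
#'   (frame-CSV dialect, nm).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(traj, path, format = c("auto", "pdb", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), pdb = "pdb", csv = "csv",
                     abort("cannot infer ensemble format for '", path, "'"))
  }
  a <- traj$topology$atoms
  if (format == "pdb") {
    bio3d::write.pdb(file = path, xyz = traj$xyz * 10, type = "ATOM",
                     resno = a$resno, resid = a$resid, elety = a$elety,
                     chain = a$chain)
  } else {
    nf <- n_frames(traj)
    nat <- nrow(a)
    d <- data.frame(
      frame = rep(seq_len(nf) - 1L, each = nat),
      time_ps = rep(traj$times, each = nat),
      chain = rep(a$chain, nf), resid = rep(a$resno, nf),
      resname = rep(a$resid, nf), atomname = rep(a$elety, nf))
    co <- matrix(t(traj$xyz), ncol = 3L, byrow = TRUE)
    d$x <- co[, 1]; d$y <- co[, 2]; d$z <- co[, 3]
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}

## ---- DSSP secondary-structure series ------------------------------------

DSSP_CODES <- c("H", "G", "I", "E", "B", "T", "S", "C", " ", "~")

#' Construct a per-frame DSSP code series
#'
#' @param codes Named list (one element per chain, `A`/`B`) of character
#'   matrices, frames in rows and residues in columns, holding single-letter
#'   DSSP codes.
#' @param times Frame times (ps).
#' @return Object of class `psi_ss_series`.
#' @export
psi_ss_series <- function(codes, times) {
  if (is.null(names(codes)) || !all(nzchar(names(codes))))
    abort("codes must be a named list of per-chain matrices")
  for (ch in names(codes)) {
    m <- codes[[ch]]
    if (!is.matrix(m)) abort("codes for chain ", ch, " must be a matrix")
    if (nrow(m) != length(times))
      abort("chain ", ch, ": frame count does not match times")
    bad <- setdiff(unique(as.vector(m)), DSSP_CODES)
    if (length(bad))
      abort("illegal DSSP code(s) in chain ", ch, ": ",
            paste(sQuote(bad), collapse = ", "))
  }
  nres <- vapply(codes, ncol, integer(1))
  if (length(unique(nres)) != 1L)
    abort("all chains must have the same residue count")
  structure(list(codes = codes, times = as.numeric(times)),
            class = "psi_ss_series")
}

#' @export
print.psi_ss_series <- function(x, ...) {
  cat("psi_ss_series:", length(x$times), "frames,",
      ncol(x$codes[[1]]), "residues, chains",
      paste(names(x$codes), collapse = ","), "\n")
  invisible(x)
}

#' Read/write per-frame DSSP code strings
#'
#' The table format has one row per chain per frame with columns `frame`,
#' `time_ps`, `chain` and `codes` (the DSSP single-letter string for all
#' residues of that chain). Code-string lengths must not drift across
#' frames.
#'
#' @param path CSV file.
#' @return [read_ss_series()] returns a `psi_ss_series`.
#' @export
read_ss_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(codes = "character"))
  need <- c("frame", "time_ps", "chain", "codes")
  if (!all(need %in% names(d)))
    abort("SS table must have columns: ", paste(need, collapse = ", "))
  codes <- list()
  for (ch in unique(d$chain)) {
    dc <- d[d$chain == ch, ]
    dc <- dc[order(dc$frame), ]
    lens <- nchar(dc$codes)
    if (length(unique(lens)) != 1L)
      abort("chain ", ch, ": code-string length drifts across frames (",
            paste(unique(lens), collapse = ", "), ")")
    codes[[ch]] <- do.call(rbind, strsplit(dc$codes, ""))
  }
  times <- sort(unique(d$time_ps))
  psi_ss_series(codes, times)
}

#' @rdname read_ss_series
#' @param ss A `psi_ss_series`.
#' @export
write_ss_series <- function(ss, path) {
  rows <- lapply(names(ss$codes), function(ch) {
    data.frame(frame = seq_along(ss$times) - 1L, time_ps = ss$times,
               chain = ch,
               codes = apply(ss$codes[[ch]], 1, paste, collapse = ""),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

## ---- analysis-window selection ------------------------------------------

window_frame_idx <- function(times, fraction = 0.10, interval = NULL) {
  if (!is.null(interval)) {
    idx <- which(times >= interval[1] & times <= interval[2])
  } else {
    if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
      abort("window fraction must be in (0, 1]")
    cutoff <- times[1] + (1 - fraction) * (times[length(times)] - times[1])
    idx <- which(times >= cutoff - 1e-9)
  }
  if (!length(idx)) abort("analysis window selects no frames")
  idx
}

#' Select the tail analysis window
#'
#' Restricts a trajectory or DSSP series to the last fraction of its time
#' span (default the last 10%), or to an explicit time interval. The time
#' threshold is inclusive, so the final frame is always kept.
#'
#' @param x A `psi_trajectory` or `psi_ss_series`.
#' @param fraction Tail fraction in (0, 1]; `1` is the identity.
#' @param interval Optional explicit `c(t_lo, t_hi)` (ps), overriding
#'   `fraction`.
#' @return Object of the same class restricted to the window.
#' @export
select_window <- function(x, fraction = 0.10, interval = NULL) {
  UseMethod("select_window")
}

#' @export
select_window.psi_trajectory <- function(x, fraction = 0.10, interval = NULL) {
  idx <- window_frame_idx(x$times, fraction, interval)
  psi_trajectory(x$topology, x$xyz[idx, , drop = FALSE], x$times[idx], x$box)
}

#' @export
select_window.psi_ss_series <- function(x, fraction = 0.10, interval = NULL) {
  idx <- window_frame_idx(x$times, fraction, interval)
  psi_ss_series(lapply(x$codes, function(m) m[idx, , drop = FALSE]),
                x$times[idx])
}
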