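## Structure metrics: RMSD with non-loop fitting, RMSF (optionally filtered
## on the first covariance eigenvector), radius of gyration, and
## centre-of-mass separations.

resolve_selection <- function(top, sel, chain = NULL) {
  if (is.numeric(sel)) return(as.integer(sel))
  idx <- switch(sel,
                backbone = atom_indices(top, "backbone", chain = chain),
                backbone_noloop = atom_indices(top, "backbone", chain = chain,
                                               exclude_loop = TRUE),
                all = atom_indices(top, "all", chain = chain),
                all_noloop = atom_indices(top, "all", chain = chain,
                                          exclude_loop = TRUE),
                calpha = atom_indices(top, "calpha", chain = chain),
                abort("unknown selection '", sel, "'"))
  if (!length(idx)) abort("selection '", sel, "' matches no atoms")
  idx
}

#' Per-frame RMSD series
#'
#' Backbone RMSD of every frame against a reference after least-squares
#' superposition. Following the loop-partitioned protocol, only non-loop
#' regions are used for the fitting by default, while the measured set may
#' include or exclude the loop.
#'
#' @param traj A `psi_trajectory`.
#' @param reference Frame index into `traj` (default the first frame) or an
#'   explicit flat xyz vector.
#' @param fit Fit selection: `"backbone_noloop"` (default), `"backbone"`, or
#'   an integer atom-index vector. `NULL` disables fitting.
#' @param measure Measurement selection: `"backbone"` (with loop) or
#'   `"backbone_noloop"`, or an integer vector.
#' @return Data frame with `time_ps`, `value_nm`; attributes `metric`
#'   (`"rmsd"`) and `variant`.
#' @export
rmsd_series <- function(traj, reference = 1L, fit = "backbone_noloop",
                        measure = "backbone") {
  top <- traj$topology
  midx <- resolve_selection(top, measure)
  fidx <- if (is.null(fit)) NULL else resolve_selection(top, fit)
  ref <- if (length(reference) == 1L && is.numeric(reference))
    traj$xyz[reference, ] else as.numeric(reference)
  refm <- matrix(ref, ncol = 3L, byrow = TRUE)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- matrix(traj$xyz[f, ], ncol = 3L, byrow = TRUE)
    if (!is.null(fidx)) fr <- superpose(fr, refm, fidx)$xyz
    rmsd_xyz(fr, refm, midx)
  }, numeric(1))
  structure(data.frame(time_ps = traj$times, value_nm = vals),
            metric = "rmsd",
            variant = if (is.character(measure)) measure else "custom")
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation about the time-average position, per
#' residue, computed separately for each monomer after superposing every
#' frame onto the reference over the (dimer-wide) selection. In
#' `"pc1"` mode the superposed trajectory is first projected onto the first
#' eigenvector of its coordinate covariance (essential-dynamics filtering,
#' the covariance-PCA reading of trajectory eigenvector fitting) and the
#' RMSF is computed on the reconstructed single-mode trajectory; this is
#' never larger than the raw RMSF.
#'
#' @param traj A `psi_trajectory` (at least 2 frames).
#' @param mode `"raw"` or `"pc1"`.
#' @param selection Atom selection the profile is computed over (default
#'   backbone).
#' @param fit Selection used for superposition (default: same as
#'   `selection`); `NULL` disables fitting.
#' @param reference Frame index used as superposition reference.
#' @return Data frame with `chain`, `resno`, `rmsf_nm`; attribute `mode`.
#' @export
rmsf_profile <- function(traj, mode = c("raw", "pc1"), selection = "backbone",
                         fit = selection, reference = 1L) {
  mode <- match.arg(mode)
  if (n_frames(traj) < 2L) abort("RMSF needs at least 2 frames")
  top <- traj$topology
  sel <- resolve_selection(top, selection)
  fidx <- if (is.null(fit)) NULL else resolve_selection(top, fit)
  refm <- matrix(traj$xyz[reference, ], ncol = 3L, byrow = TRUE)
  nf <- n_frames(traj)
  X <- matrix(0, nf, 3L * length(sel))
  cols <- xyz_cols(sel)
  for (f in seq_len(nf)) {
    fr <- matrix(traj$xyz[f, ], ncol = 3L, byrow = TRUE)
    if (!is.null(fidx)) fr <- superpose(fr, refm, fidx)$xyz
    X[f, ] <- as.numeric(t(fr[sel, , drop = FALSE]))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (mode == "pc1") {
    sv <- svd(Xc, nu = 1, nv = 1)
    Xc <- (sv$u * sv$d[1]) %*% t(sv$v)
  }
  fl2 <- colMeans(Xc^2)                       # per-coordinate variance
  atom_fl2 <- rowSums(matrix(fl2, ncol = 3L, byrow = TRUE))  # per selected atom
  key <- paste(top$atoms$chain[sel], top$atoms$resno[sel])
  res_fl2 <- tapply(atom_fl2, key, mean)      # mean square fluct per residue
  parts <- do.call(rbind, strsplit(names(res_fl2), " "))
  out <- data.frame(chain = parts[, 1], resno = as.integer(parts[, 2]),
                    rmsf_nm = sqrt(as.numeric(res_fl2)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  structure(out, mode = mode)
}

#' Pool per-residue profiles across monomers and replicates
#'
#' @param profiles List of data frames with columns `chain`, `resno` and a
#'   value column; every (chain, profile) combination is one pooled series.
#' @param value Name of the value column.
#' @param sd_type Passed to the per-bin spread ( `"sample"` default).
#' @return Data frame `resno`, `mean`, `sd`, `n`.
#' @export
pool_residue_profiles <- function(profiles, value = "rmsf_nm",
                                  sd_type = "sample") {
  long <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(series = paste0(i, ":", p$chain), resno = p$resno,
               value = p[[value]], stringsAsFactors = FALSE)
  }))
  resno <- sort(unique(long$resno))
  wide <- vapply(split(long, long$series),
                 function(s) s$value[match(resno, s$resno)],
                 numeric(length(resno)))
  wide <- matrix(wide, nrow = length(resno))
  data.frame(resno = resno, mean = rowMeans(wide),
             sd = apply(wide, 1, spread_sd, sd_type = sd_type),
             n = ncol(wide))
}

#' Radius of gyration series
#'
#' Mass-weighted radius of gyration per frame,
#' `Rg = sqrt(sum(m_i * |x_i - x_com|^2) / sum(m_i))`, over all atoms or
#' with the loop excluded.
#'
#' @param traj A `psi_trajectory`.
#' @param selection `"all"`, `"all_noloop"`, or an integer atom-index vector.
#' @return Data frame `time_ps`, `value_nm`; attributes `metric` (`"rg"`)
#'   and `variant`.
#' @export
radius_of_gyration <- function(traj, selection = "all") {
  top <- traj$topology
  idx <- resolve_selection(top, selection)
  m <- top$atoms$mass[idx]
  if (sum(m) <= 0) abort("selection has zero total mass")
  cols <- xyz_cols(idx)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- matrix(traj$xyz[f, cols], ncol = 3L, byrow = TRUE)
    com <- colSums(x * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
  }, numeric(1))
  structure(data.frame(time_ps = traj$times, value_nm = vals),
            metric = "rg",
            variant = if (is.character(selection)) selection else "custom")
}

#' Centre-of-mass separation between two atom groups
#'
#' Per-frame distance between the mass-weighted centroids of two groups
#' (e.g. the two monomers, with or without their loops, or two helical
#' elements).
#'
#' @param traj A `psi_trajectory`.
#' @param group_a,group_b Integer atom-index vectors (see [atom_indices()]).
#' @return Data frame `time_ps`, `value_nm`; attribute `metric` (`"com"`).
#' @export
com_separation <- function(traj, group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    abort("both centre-of-mass groups must be non-empty")
  m_a <- traj$topology$atoms$mass[group_a]
  m_b <- traj$topology$atoms$mass[group_b]
  ca <- xyz_cols(group_a); cb <- xyz_cols(group_b)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xa <- matrix(traj$xyz[f, ca], ncol = 3L, byrow = TRUE)
    xb <- matrix(traj$xyz[f, cb], ncol = 3L, byrow = TRUE)
    sqrt(sum((colSums(xa * m_a) / sum(m_a) -
                colSums(xb * m_b) / sum(m_b))^2))
  }, numeric(1))
  structure(data.frame(time_ps = traj$times, value_nm = vals),
            metric = "com")
}

#' Summarise per-frame series across replicates
#'
#' Each replicate's series is reduced to its window mean; the summary is the
#' mean of those replicate means with its standard error (SEM, n =
#' replicates), matching trajectory-level reporting conventions.
#'
#' @param series_list List of data frames with a `value_nm` column, one per
#'   replicate.
#' @return List with `mean`, `sem`, `n`, and the per-replicate means.
#' @export
summarize_replicates <- function(series_list) {
  means <- vapply(series_list, function(s) mean(s$value_nm), numeric(1))
  n <- length(means)
  list(mean = mean(means),
       sem = if (n > 1) stats::sd(means) / sqrt(n) else 0,
       n = n, replicate_means = means)
}
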