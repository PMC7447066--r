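## Hydrogen-bond, hydrophobic, salt-bridge and cation-pi censuses with
## intra-/inter-monomer and loop partitions.

canonical_pairs <- function(chain_i, resno_i, chain_j, resno_j, min_dist,
                            kind) {
  swap <- chain_j < chain_i | (chain_j == chain_i & resno_j < resno_i)
  out <- data.frame(
    kind = kind,
    chain_i = ifelse(swap, chain_j, chain_i),
    resno_i = ifelse(swap, resno_j, resno_i),
    chain_j = ifelse(swap, chain_i, chain_j),
    resno_j = ifelse(swap, resno_i, resno_j),
    min_dist = min_dist, stringsAsFactors = FALSE)
  key <- with(out, paste(chain_i, resno_i, chain_j, resno_j))
  agg <- tapply(out$min_dist, key, min)
  out <- out[!duplicated(key), ]
  out$min_dist <- as.numeric(agg[match(key[!duplicated(key)], names(agg))])
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(kind = character(), chain_i = character(), resno_i = integer(),
             chain_j = character(), resno_j = integer(),
             min_dist = numeric(), stringsAsFactors = FALSE)
}

## residue-pair contacts from an atom-level candidate list
pairs_from_atoms <- function(top, idx_i, idx_j, d, kind) {
  if (!length(idx_i)) return(empty_pairs())
  a <- top$atoms
  canonical_pairs(a$chain[idx_i], a$resno[idx_i],
                  a$chain[idx_j], a$resno[idx_j], d, kind)
}

#' Hydrogen bonds in one frame
#'
#' Donor-acceptor pairs of N/O atoms within 0.35 nm whose
#' hydrogen-donor-acceptor angle is at most 30 degrees (the conventions of
#' standard MD H-bond counting). When the topology carries no hydrogens, an
#' idealised donor hydrogen is assumed along the donor-acceptor axis, so
#' the angle criterion always passes; the result is then flagged with
#' attribute `approx_hydrogens = TRUE`. Pairs closer than `min_seq_sep`
#' residues within a chain are excluded as trivially bonded neighbours.
#' The contact unit is the residue pair: a pair within the criteria counts
#' once per frame regardless of how many atom pairs qualify.
#'
#' @param frame `n_atoms x 3` coordinate matrix (nm) for one frame.
#' @param top A `psi_topology`.
#' @param dist_cutoff Donor-acceptor distance cutoff (nm).
#' @param angle_cutoff H-donor-acceptor angle cutoff (degrees).
#' @param min_seq_sep Minimum intra-chain residue separation.
#' @return Data frame of residue pairs (`kind = "HB"`).
#' @export
hydrogen_bonds <- function(frame, top, dist_cutoff = 0.35, angle_cutoff = 30,
                           min_seq_sep = 2L) {
  a <- top$atoms
  no <- which(a$element %in% c("N", "O"))
  if (length(no) < 2L) return(empty_pairs())
  co <- frame[no, , drop = FALSE]
  D <- as.matrix(stats::dist(co))
  cand <- which(upper.tri(D) & D <= dist_cutoff, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_pairs())
  ai <- no[cand[, 1]]; aj <- no[cand[, 2]]
  keep <- !(a$chain[ai] == a$chain[aj] &
              abs(a$resno[ai] - a$resno[aj]) < min_seq_sep)
  ai <- ai[keep]; aj <- aj[keep]
  if (!length(ai)) return(empty_pairs())
  h_idx <- which(a$element == "H")
  approx_h <- length(h_idx) == 0L
  if (!approx_h) {
    ## attach each hydrogen to its nearest N/O within covalent range
    hco <- frame[h_idx, , drop = FALSE]
    dh <- matrix(0, length(h_idx), length(no))
    for (k in seq_along(no))
      dh[, k] <- sqrt(rowSums(sweep(hco, 2, co[k, ])^2))
    parent <- no[apply(dh, 1, which.min)]
    parent[apply(dh, 1, min) > 0.13] <- NA_integer_
    cosmax <- cos(angle_cutoff * pi / 180)
    ok <- vapply(seq_along(ai), function(k) {
      for (da in list(c(ai[k], aj[k]), c(aj[k], ai[k]))) {
        hs <- h_idx[!is.na(parent) & parent == da[1]]
        if (!length(hs)) next
        v_a <- frame[da[2], ] - frame[da[1], ]
        for (h in hs) {
          v_h <- frame[h, ] - frame[da[1], ]
          cosang <- sum(v_a * v_h) /
            (sqrt(sum(v_a^2)) * max(sqrt(sum(v_h^2)), 1e-12))
          if (cosang >= cosmax) return(TRUE)
        }
      }
      FALSE
    }, logical(1))
    ai <- ai[ok]; aj <- aj[ok]
  }
  d <- sqrt(rowSums((frame[ai, , drop = FALSE] - frame[aj, , drop = FALSE])^2))
  structure(pairs_from_atoms(top, ai, aj, d, "HB"),
            approx_hydrogens = approx_h)
}

#' Hydrophobic contacts in one frame
#'
#' Minimum-distance sidechain contact map restricted to residues of the
#' wholly hydrophobic set: a residue pair is counted when the minimum
#' heavy-atom sidechain-sidechain distance is at most `cutoff` (0.45 nm).
#' Amphipathic sidechains (e.g. the aliphatic stem of lysine) are excluded
#' by construction of the set.
#'
#' @inheritParams hydrogen_bonds
#' @param cutoff Minimum-distance cutoff (nm).
#' @param hydrophobic_set Residue names considered (defaults to the
#'   topology's set).
#' @return Data frame of residue pairs (`kind = "HI"`).
#' @export
hydrophobic_contacts <- function(frame, top, cutoff = 0.45,
                                 hydrophobic_set = NULL, min_seq_sep = 2L) {
  a <- top$atoms
  set <- hydrophobic_set %||% top$hydrophobic_set
  idx <- which(a$resid %in% set & !(a$elety %in% BACKBONE_ATOMS) &
                 a$element != "H")
  if (length(idx) < 2L) return(empty_pairs())
  D <- as.matrix(stats::dist(frame[idx, , drop = FALSE]))
  cand <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_pairs())
  ai <- idx[cand[, 1]]; aj <- idx[cand[, 2]]
  d <- D[cand]
  same_res <- a$chain[ai] == a$chain[aj] & a$resno[ai] == a$resno[aj]
  near <- a$chain[ai] == a$chain[aj] &
    abs(a$resno[ai] - a$resno[aj]) < min_seq_sep
  keep <- !(same_res | near)
  pairs_from_atoms(top, ai[keep], aj[keep], d[keep], "HI")
}

## basic-residue interaction sites: Lys NZ; Arg COM of guanidinium N;
## His COM of the delta/epsilon N and epsilon C carrying the charge
basic_sites <- function(frame, top, protonation) {
  pm <- protonation
  keep <- pm$resid %in% BASIC_RES & pm$state == "charged"
  bs <- pm[keep, , drop = FALSE]
  if (!nrow(bs)) return(NULL)
  pts <- matrix(0, nrow(bs), 3L)
  for (k in seq_len(nrow(bs))) {
    atn <- switch(bs$resid[k],
                  LYS = "NZ",
                  ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2", "CE1"))
    i <- named_atom_index(top, bs$chain[k], bs$resno[k], atn)
    if (length(i) < length(atn))
      abort("residue ", bs$resno[k], " (chain ", bs$chain[k], ") lacks ",
            "expected atom(s) ", paste(atn, collapse = "/"))
    m <- top$atoms$mass[i]
    pts[k, ] <- colSums(frame[i, , drop = FALSE] * m) / sum(m)
  }
  list(res = bs, points = pts)
}

#' Salt bridges in one frame
#'
#' A salt bridge is counted between a deprotonated acidic sidechain and a
#' protonated basic sidechain when the minimum distance between the acidic
#' sidechain oxygens and the basic interaction site is at most `cutoff`
#' (0.45 nm). The basic site is residue-specific: the terminal sidechain
#' nitrogen NZ for lysine, the centre of mass of the three guanidinium
#' nitrogens for arginine, and the centre of mass of the delta/epsilon
#' nitrogens with the epsilon carbon for histidine. Eligibility follows the
#' protonation map: at pH 3.0 the default map neutralises all carboxylates
#' (no salt bridges without overrides), and histidine is excluded entirely
#' at pH 7.4 where it is neutral.
#'
#' @inheritParams hydrophobic_contacts
#' @param protonation A `psi_protonation` map from [assign_protonation()].
#' @return Data frame of residue pairs (`kind = "SB"`).
#' @export
salt_bridges <- function(frame, top, protonation, cutoff = 0.45) {
  pm <- protonation
  ac <- pm[pm$resid %in% ACIDIC_RES & pm$state == "charged", , drop = FALSE]
  bas <- basic_sites(frame, top, pm)
  if (!nrow(ac) || is.null(bas)) return(empty_pairs())
  ci <- character(); ri <- integer(); cj <- character(); rj <- integer()
  dm <- numeric()
  for (k in seq_len(nrow(ac))) {
    oxy <- ACID_OXYGENS[[ac$resid[k]]]
    i <- named_atom_index(top, ac$chain[k], ac$resno[k], oxy)
    ox <- frame[i, , drop = FALSE]
    for (b in seq_len(nrow(bas$res))) {
      d <- min(sqrt(rowSums(sweep(ox, 2, bas$points[b, ])^2)))
      if (d <= cutoff) {
        ci <- c(ci, ac$chain[k]); ri <- c(ri, ac$resno[k])
        cj <- c(cj, bas$res$chain[b]); rj <- c(rj, bas$res$resno[b])
        dm <- c(dm, d)
      }
    }
  }
  if (!length(ci)) return(empty_pairs())
  canonical_pairs(ci, ri, cj, rj, dm, "SB")
}

#' Cation-pi candidate screen in one frame
#'
#' Advisory screen for potential cation-pi interactions: a candidate is
#' reported when a charged basic site (as in [salt_bridges()]) lies within
#' `cutoff` (0.6 nm) of an aromatic ring centroid (Phe/Tyr/Trp six-membered
#' ring). Candidates are reported separately and never merged into the
#' contact census totals.
#'
#' @inheritParams salt_bridges
#' @param cutoff Centroid-cation distance cutoff (nm).
#' @return Data frame of candidate residue pairs (`kind = "CATPI"`).
#' @export
cation_pi_screen <- function(frame, top, protonation, cutoff = 0.6) {
  a <- top$atoms
  bas <- basic_sites(frame, top, protonation)
  arom <- unique(a[a$resid %in% names(RING_ATOMS), c("chain", "resno", "resid")])
  if (is.null(bas) || !nrow(arom)) return(empty_pairs())
  ci <- character(); ri <- integer(); cj <- character(); rj <- integer()
  dm <- numeric()
  for (k in seq_len(nrow(arom))) {
    ring <- named_atom_index(top, arom$chain[k], arom$resno[k],
                             RING_ATOMS[[arom$resid[k]]])
    centroid <- colMeans(frame[ring, , drop = FALSE])
    for (b in seq_len(nrow(bas$res))) {
      d <- sqrt(sum((bas$points[b, ] - centroid)^2))
      if (d <= cutoff &&
          !(arom$chain[k] == bas$res$chain[b] &&
              arom$resno[k] == bas$res$resno[b])) {
        ci <- c(ci, arom$chain[k]); ri <- c(ri, arom$resno[k])
        cj <- c(cj, bas$res$chain[b]); rj <- c(rj, bas$res$resno[b])
        dm <- c(dm, d)
      }
    }
  }
  if (!length(ci)) return(empty_pairs())
  canonical_pairs(ci, ri, cj, rj, dm, "CATPI")
}

#' Label contact pairs by monomer and loop partition
#'
#' Every pair is assigned to exactly one of `intra_A`, `intra_B`, `inter`.
#' In addition, a loop category is attached: `intra_loop` when both
#' residues lie in the loop span of the same chain, `loop_nonloop` when
#' exactly one residue is a loop residue (either chain -- a loop reaching
#' across the interface counts here), and `none` otherwise; the two loop
#' categories are disjoint by construction. `loop_chain` records which
#' monomer's loop is involved.
#'
#' @param pairs Residue-pair data frame from the contact operators.
#' @param top A `psi_topology`.
#' @return The input with columns `partition`, `loop_category`,
#'   `loop_chain` appended.
#' @export
partition_contacts <- function(pairs, top) {
  lr <- loop_residues(top)
  in_i <- pairs$resno_i %in% lr
  in_j <- pairs$resno_j %in% lr
  same <- pairs$chain_i == pairs$chain_j
  pairs$partition <- ifelse(!same, "inter",
                            ifelse(pairs$chain_i == "A", "intra_A", "intra_B"))
  pairs$loop_category <- ifelse(in_i & in_j & same, "intra_loop",
                                ifelse(xor(in_i, in_j), "loop_nonloop",
                                       "none"))
  pairs$loop_chain <- ifelse(pairs$loop_category == "intra_loop",
                             pairs$chain_i,
                             ifelse(pairs$loop_category == "loop_nonloop",
                                    ifelse(in_i, pairs$chain_i, pairs$chain_j),
                                    NA_character_))
  pairs
}

#' Contact census over an analysis window
#'
#' Runs the requested contact operators on every frame of the (optionally
#' windowed) trajectory and returns the partition-labelled pairs together
#' with frame bookkeeping, ready for [summarize_contacts()].
#'
#' @param traj A `psi_trajectory`.
#' @param protonation A `psi_protonation` map.
#' @param window Optional tail fraction passed to [select_window()].
#' @param kinds Subset of `c("HB", "HI", "SB")`.
#' @param hb_dist,hb_angle Hydrogen-bond cutoffs.
#' @param contact_cutoff Hydrophobic / salt-bridge cutoff (nm).
#' @param min_seq_sep Minimum intra-chain residue separation for HB/HI.
#' @param replicate Replicate identifier.
#' @return Object of class `psi_contact_census`: list with `pairs` (labelled
#'   pair data frame with `frame`, `time_ps`), `n_frames`, `times`,
#'   `kinds`, `replicate`.
#' @export
contact_census <- function(traj, protonation, window = NULL,
                           kinds = c("HB", "HI", "SB"),
                           hb_dist = 0.35, hb_angle = 30,
                           contact_cutoff = 0.45, min_seq_sep = 2L,
                           replicate = 1L) {
  if (!is.null(window)) traj <- select_window(traj, window)
  top <- traj$topology
  out <- list()
  for (f in seq_len(n_frames(traj))) {
    fr <- frame_xyz(traj, f)
    pl <- list()
    if ("HB" %in% kinds)
      pl$HB <- hydrogen_bonds(fr, top, hb_dist, hb_angle, min_seq_sep)
    if ("HI" %in% kinds)
      pl$HI <- hydrophobic_contacts(fr, top, contact_cutoff,
                                    min_seq_sep = min_seq_sep)
    if ("SB" %in% kinds)
      pl$SB <- salt_bridges(fr, top, protonation, contact_cutoff)
    p <- do.call(rbind, pl)
    if (!is.null(p) && nrow(p)) {
      p$frame <- f
      p$time_ps <- traj$times[f]
      out[[f]] <- p
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else {
    e <- empty_pairs(); e$frame <- integer(); e$time_ps <- numeric(); e
  }
  if (nrow(pairs)) pairs <- partition_contacts(pairs, top)
  else {
    pairs$partition <- character(); pairs$loop_category <- character()
    pairs$loop_chain <- character()
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n_frames = n_frames(traj),
                 times = traj$times, kinds = kinds, replicate = replicate),
            class = "psi_contact_census")
}

#' @export
print.psi_contact_census <- function(x, ...) {
  cat("psi_contact_census:", x$n_frames, "frames, kinds",
      paste(x$kinds, collapse = ","), "-", nrow(x$pairs), "contact records\n")
  invisible(x)
}

## per-frame counts for one census, one row per frame x kind x category
census_counts <- function(census) {
  p <- census$pairs
  frames <- seq_len(census$n_frames)
  out <- list()
  tally <- function(sub, category, chain) {
    cnt <- tabulate(factor(sub$frame, levels = frames), nbins = length(frames))
    data.frame(frame = frames, time_ps = census$times, category = category,
               chain = chain, count = cnt, stringsAsFactors = FALSE)
  }
  for (k in census$kinds) {
    pk <- p[p$kind == k, , drop = FALSE]
    rows <- rbind(
      tally(pk[pk$partition == "intra_A", ], "intra", "A"),
      tally(pk[pk$partition == "intra_B", ], "intra", "B"),
      tally(pk[pk$partition == "inter", ], "inter", NA_character_),
      tally(pk[pk$loop_category == "intra_loop" & !is.na(pk$loop_chain) &
                 pk$loop_chain == "A", ], "intra_loop", "A"),
      tally(pk[pk$loop_category == "intra_loop" & !is.na(pk$loop_chain) &
                 pk$loop_chain == "B", ], "intra_loop", "B"),
      tally(pk[pk$loop_category == "loop_nonloop" & !is.na(pk$loop_chain) &
                 pk$loop_chain == "A", ], "loop_nonloop", "A"),
      tally(pk[pk$loop_category == "loop_nonloop" & !is.na(pk$loop_chain) &
                 pk$loop_chain == "B", ], "loop_nonloop", "B"))
    rows$kind <- k
    out[[k]] <- rows
  }
  do.call(rbind, out)
}

#' Summarise contact censuses across replicates
#'
#' Per-frame counts are pooled across replicates -- and, for the
#' monomer-resolved categories, across the two monomers -- and the mean and
#' standard deviation of the pooled per-frame counts reported. `n` records
#' the number of pooled series: chains x replicates for `intra` and the
#' loop categories, replicates for `inter`.
#'
#' @param censuses A `psi_contact_census` or list of them (replicates).
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return Data frame with `kind`, `category`, `mean`, `sd`, `n`.
#' @export
summarize_contacts <- function(censuses, sd_type = "sample") {
  if (inherits(censuses, "psi_contact_census")) censuses <- list(censuses)
  counts <- do.call(rbind, lapply(seq_along(censuses), function(r) {
    cc <- census_counts(censuses[[r]])
    cc$replicate <- r
    cc
  }))
  out <- list()
  for (k in unique(counts$kind)) {
    for (cat in c("intra", "inter", "intra_loop", "loop_nonloop")) {
      sub <- counts[counts$kind == k & counts$category == cat, ]
      if (!nrow(sub)) next
      n_series <- if (cat == "inter") length(unique(sub$replicate))
                  else length(unique(paste(sub$replicate, sub$chain)))
      out[[paste(k, cat)]] <- data.frame(
        kind = k, category = cat, mean = mean(sub$count),
        sd = spread_sd(sub$count, sd_type), n = n_series,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
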