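## Synthetic dimer topologies, trajectories and secondary-structure series
## with known ground truth. Not a physical simulator: geometry is plausible
## pseudo-atom scaffolding on which per-residue fluctuation amplitudes,
## S-gamma pair-distance laws, Markov secondary-structure switching and
## planted contacts are imposed exactly.

#' Default 104-residue template sequence
#'
#' A saposin-fold-like template with cysteines at 6/31/37/68/71/99, the
#' loop acidics Asp40/Glu54/Glu56/Glu58 and Glu72, basic and aromatic
#' residues distributed over the helices, and hydrophobic helix faces. It
#' emulates, but does not claim to be, the true PSI sequence.
#'
#' @return Character vector of 104 one-letter codes.
#' @export
default_sequence <- function() {
  strsplit(paste0(
    "GSWLACLVIKALYNLARMAG",
    "SNTALQIVALCAMVFACLAD",
    "GSTNLGSQTNGSTEGESENG",
    "TSGALVACIMCEALKVAIAG",
    "NSALHVAFLKAIVRALMACGKTSG"), "")[[1]]
}

default_sigma_profile <- function(n_res = 104L, loop_span = c(40L, 63L),
                                  helix_spans = default_helix_spans()) {
  sigma <- numeric(n_res)
  helix <- unlist(lapply(helix_spans, function(h) seq.int(h[1], h[2])))
  loop <- seq.int(loop_span[1], loop_span[2])
  other <- setdiff(seq_len(n_res), c(helix, loop))
  ## strictly graded within each class so the profile has no exact ties;
  ## the loop amplitude is tent-shaped (ramping at the junctions) so
  ## neighbouring residues never have wildly mismatched amplitudes
  sigma[sort(helix)] <- seq(0.035, 0.058, length.out = length(helix))
  nl <- length(loop)
  up <- max(2L, round(0.4 * nl))
  sigma[loop] <- c(seq(0.100, 0.145, length.out = up),
                   seq(0.141, 0.104, length.out = nl - up))
  sigma[other] <- seq(0.060, 0.075, length.out = length(other))
  sigma
}

default_switch_profile <- function(n_res = 104L, loop_span = c(40L, 63L),
                                   helix_spans = default_helix_spans()) {
  p <- rep(0.08, n_res)  # linkers / termini: most variable
  for (h in helix_spans) p[seq.int(h[1], h[2])] <- 0.01
  p[seq.int(loop_span[1], loop_span[2])] <- 0.02
  p
}

#' S-gamma distance laws for a condition code
#'
#' Per native pair, the sampling law for the enforced S-gamma separation:
#' intact bonds are pinned at the disulfide bond length 0.2038 nm; reduced
#' bonds draw i.i.d. normal separations whose centres follow the observed
#' behaviour of the system (Cys6-Cys99 near 0.50 nm; Cys31-Cys71 near
#' 0.35 nm; Cys37-Cys68 pH-dependent, 0.40 nm at pH 3.0 vs 0.50 nm at pH
#' 7.4, and broader/looser once its partner bonds are also gone).
#'
#' @param code Condition code (`"AI"`, `"D1"`..`"D6"`, `"AR"`).
#' @param ph 3.0 or 7.4.
#' @return Named list over `"6-99"`, `"31-71"`, `"37-68"`, each
#'   `list(type = "constant", value = )` or
#'   `list(type = "normal", mean = , sd = )`.
#' @export
condition_sg_laws <- function(code = "AI", ph = 7.4) {
  cond <- resolve_condition(code)
  reduced <- rownames(cond$reduced)
  wide <- code %in% c("D6", "AR")  # 37-68 destabilised with partners gone
  laws <- list()
  for (lab in rownames(native_cys_pairs())) {
    if (!lab %in% reduced) {
      laws[[lab]] <- list(type = "constant", value = 0.2038)
    } else if (lab == "6-99") {
      laws[[lab]] <- list(type = "normal", mean = 0.50,
                          sd = if (code == "AR") 0.08 else 0.03)
    } else if (lab == "31-71") {
      laws[[lab]] <- list(type = "normal", mean = if (code == "AR") 0.45 else 0.35,
                          sd = if (code == "AR") 0.08 else 0.03)
    } else {  # 37-68
      laws[[lab]] <- list(
        type = "normal",
        mean = if (wide) 0.55 else if (ph == 3.0) 0.40 else 0.50,
        sd = if (wide) 0.12 else 0.05)
    }
  }
  laws
}

#' Default planted contacts
#'
#' Two true contacts -- an inter-monomer hydrophobic pair held at 0.40 nm
#' and an inter-monomer Glu-Lys salt bridge held at 0.42 nm -- plus two
#' decoys of the same kinds held at 0.54 nm (1.2 x the 0.45 nm cutoff),
#' which must never be detected.
#'
#' @return List of planted-contact descriptors.
#' @export
default_planted_contacts <- function() {
  list(
    list(kind = "HI", chain_i = "A", resno_i = 87L,
         chain_j = "B", resno_j = 87L, dist = 0.40),
    list(kind = "SB", chain_i = "A", resno_i = 72L,
         chain_j = "B", resno_j = 75L, dist = 0.42),
    list(kind = "HI", chain_i = "A", resno_i = 91L,
         chain_j = "B", resno_j = 91L, dist = 0.54),
    list(kind = "SB", chain_i = "A", resno_i = 56L,
         chain_j = "B", resno_j = 90L, dist = 0.54))
}

#' Specification of a synthetic dimer ensemble
#'
#' Bundles everything the generator needs: template sequence, cysteine
#' positions, loop span, the per-residue fluctuation amplitude profile
#' (nm), S-gamma pair-distance laws, per-residue Markov switch
#' probabilities for the secondary-structure series, planted contacts,
#' frame count and spacing, and the seed that makes all outputs
#' reproducible.
#'
#' @param n_res Residues per chain.
#' @param sequence One-letter sequence (length `n_res`).
#' @param cys_positions Cysteine positions (must be Cys in `sequence`).
#' @param loop_span,helix_spans Structural registries.
#' @param sigma_profile Per-residue isotropic fluctuation sigma (nm).
#' @param sigma_smooth Half-width (residues) of the triangular kernel that
#'   correlates neighbouring residues' displacements (keeps bonded
#'   geometry sane without changing per-residue amplitudes).
#' @param sg_laws Named list of distance laws (see [condition_sg_laws()]).
#' @param ss_switch_prob Per-residue Markov switch probability.
#' @param loop_alt_exit Exit probability from the loop's transient
#'   alternate state (3-10 helix), making loop residues
#'   disordered-dominant; `NULL` keeps the loop chains symmetric at their
#'   switch probability.
#' @param planted_contacts List of planted-contact descriptors.
#' @param n_frames,dt_ps Frame count and spacing (ps).
#' @param seed Integer RNG seed.
#' @return List of class `psi_synthetic_spec`.
#' @export
synthetic_spec <- function(n_res = 104L,
                           sequence = default_sequence(),
                           cys_positions = c(6L, 31L, 37L, 68L, 71L, 99L),
                           loop_span = c(40L, 63L),
                           helix_spans = default_helix_spans(),
                           sigma_profile = NULL,
                           sigma_smooth = 3L,
                           sg_laws = condition_sg_laws("AI"),
                           ss_switch_prob = NULL,
                           loop_alt_exit = 0.25,
                           planted_contacts = default_planted_contacts(),
                           n_frames = 1001L,
                           dt_ps = 10,
                           seed = 1L) {
  if (length(sequence) != n_res)
    abort("sequence length (", length(sequence), ") != n_res (", n_res, ")")
  if (anyDuplicated(cys_positions))
    abort("duplicate cysteine positions")
  if (any(cys_positions < 1L | cys_positions > n_res))
    abort("cysteine position out of range 1..", n_res)
  if (!all(sequence[cys_positions] == "C"))
    abort("sequence must have Cys at positions ",
          paste(cys_positions, collapse = ", "))
  sigma_profile <- sigma_profile %||%
    default_sigma_profile(n_res, loop_span, helix_spans)
  ss_switch_prob <- ss_switch_prob %||%
    default_switch_profile(n_res, loop_span, helix_spans)
  if (length(sigma_profile) == 1L) sigma_profile <- rep(sigma_profile, n_res)
  if (length(ss_switch_prob) == 1L) ss_switch_prob <- rep(ss_switch_prob, n_res)
  if (any(sigma_profile < 0)) abort("sigma_profile must be non-negative")
  if (any(ss_switch_prob < 0 | ss_switch_prob > 1))
    abort("ss_switch_prob must be in [0, 1]")
  structure(list(n_res = as.integer(n_res), sequence = sequence,
                 cys_positions = as.integer(cys_positions),
                 loop_span = as.integer(loop_span),
                 helix_spans = helix_spans,
                 sigma_profile = sigma_profile, sigma_smooth = sigma_smooth,
                 sg_laws = sg_laws, ss_switch_prob = ss_switch_prob,
                 loop_alt_exit = loop_alt_exit,
                 planted_contacts = planted_contacts,
                 n_frames = as.integer(n_frames), dt_ps = dt_ps,
                 seed = as.integer(seed)),
            class = "psi_synthetic_spec")
}

#' Build the dimer topology of a synthetic spec
#'
#' Two identical chains of backbone (N, CA, C, O) plus minimal sidechain
#' pseudo-atoms: the cysteine S-gamma, Lys NZ, the Arg guanidinium
#' nitrogens, His/aromatic ring atoms, Asp/Glu carboxylate oxygens, and a
#' CB on every non-Gly residue. Masses are assigned by element.
#'
#' @param spec A `psi_synthetic_spec`.
#' @return A `psi_topology`.
#' @export
make_topology <- function(spec = synthetic_spec()) {
  seq3 <- unname(AA_1TO3[spec$sequence])
  if (anyNA(seq3))
    abort("unknown one-letter code(s): ",
          paste(unique(spec$sequence[is.na(seq3)]), collapse = ", "))
  one_chain <- do.call(rbind, lapply(seq_len(spec$n_res), function(i) {
    atoms <- c(BACKBONE_ATOMS, SIDECHAIN_ATOMS[[seq3[i]]])
    data.frame(resno = i, resid = seq3[i], elety = atoms,
               stringsAsFactors = FALSE)
  }))
  atoms <- rbind(cbind(chain = "A", one_chain), cbind(chain = "B", one_chain))
  atoms$element <- atom_element(atoms$elety)
  atoms$mass <- ELEMENT_MASS[atoms$element]
  cys <- sort(spec$cys_positions)
  pairs <- native_cys_pairs()
  pairs <- pairs[pairs[, 1] %in% cys & pairs[, 2] %in% cys, , drop = FALSE]
  psi_topology(atoms, cys_pairs = pairs, loop_span = spec$loop_span,
               helix_spans = spec$helix_spans)
}

## ---- base geometry -------------------------------------------------------

## ideal alpha-helix parameters used only for plausible scaffolding
HELIX_RISE <- 0.15   # nm per residue
HELIX_TWIST <- 100 * pi / 180
HELIX_RADIUS <- 0.23

## xy positions of the four helix axes; scaled down for short chains so
## bonded geometry stays intact in small fixture systems
helix_axes <- function(spec) {
  s <- min(1, spec$n_res / 104)
  lapply(list(H1 = c(0, 0), H2 = c(1.0, 0.1), H3 = c(1.05, 1.0),
              H4 = c(0.05, 0.95)),
         function(p) p * s)
}

ca_trace <- function(spec) {
  n <- spec$n_res
  ca <- matrix(NA_real_, n, 3L)
  axes <- helix_axes(spec)
  updown <- c(H1 = 1, H2 = -1, H3 = 1, H4 = -1)
  for (nm in names(spec$helix_spans)) {
    h <- spec$helix_spans[[nm]]
    cen <- axes[[nm]] %||% c(0, 0)
    dirz <- updown[[nm]] %||% 1
    z0 <- if (dirz > 0) 0 else HELIX_RISE * (h[2] - h[1])
    for (i in seq.int(h[1], h[2])) {
      th <- (i - h[1]) * HELIX_TWIST
      ca[i, ] <- c(cen[1] + HELIX_RADIUS * cos(th),
                   cen[2] + HELIX_RADIUS * sin(th),
                   z0 + dirz * HELIX_RISE * (i - h[1]))
    }
  }
  ## loop: extended 3D arc between the flanking helices, bulging outward
  ## (-y) with a z meander that keeps non-adjacent loop residues apart
  ls <- spec$loop_span
  if (ls[1] <= 1L || ls[2] >= n)
    abort("the loop span may not touch the chain termini")
  p <- ca[ls[1] - 1L, ]; q <- ca[ls[2] + 1L, ]
  nl <- ls[2] - ls[1] + 1L
  chord <- q - p
  cn <- sqrt(sum(chord^2)); e1 <- chord / cn
  ## bulge away from the dimer interface (+x) and to the outside of the
  ## helix bundle; the z meander keeps non-adjacent loop residues apart.
  ## Amplitudes scale with loop length so short loops stay bonded.
  b1 <- min(2.4, 0.36 * (nl + 1) / 2)
  b2 <- min(1.0, 0.42 * b1)
  w <- c(-1, -1.2, 0); w <- w - sum(w * e1) * e1; w <- w / sqrt(sum(w^2))
  zv <- c(e1[2] * w[3] - e1[3] * w[2], e1[3] * w[1] - e1[1] * w[3],
          e1[1] * w[2] - e1[2] * w[1])
  mid <- (p + q) / 2
  for (k in seq_len(nl)) {
    t <- k / (nl + 1)
    ca[ls[1] + k - 1L, ] <- mid + (cn / 2) * cos(pi * (1 - t)) * e1 +
      b1 * sin(pi * t) * w + b2 * sin(2 * pi * t) * zv
  }
  ## remaining residues: interpolate between, or extrapolate from, anchors
  known <- which(!is.na(ca[, 1]))
  for (i in setdiff(seq_len(n), known)) {
    lo <- suppressWarnings(max(known[known < i]))
    hi <- suppressWarnings(min(known[known > i]))
    if (is.finite(lo) && is.finite(hi)) {
      t <- (i - lo) / (hi - lo)
      ca[i, ] <- ca[lo, ] + (ca[hi, ] - ca[lo, ]) * t
    } else if (is.finite(hi)) {         # N-terminal tail
      d <- ca[hi, ] - ca[hi + 1L, ]
      ca[i, ] <- ca[hi, ] + d / sqrt(sum(d^2)) * 0.36 * (hi - i)
    } else {                            # C-terminal tail
      d <- ca[lo, ] - ca[lo - 1L, ]
      ca[i, ] <- ca[lo, ] + d / sqrt(sum(d^2)) * 0.36 * (i - lo)
    }
  }
  ca
}

sidechain_offsets <- function(resid, o, t) {
  ring6 <- function(center_dist) {
    rbind(o * (center_dist - 0.14),
          o * (center_dist - 0.07) + t * 0.121,
          o * (center_dist - 0.07) - t * 0.121,
          o * (center_dist + 0.07) + t * 0.121,
          o * (center_dist + 0.07) - t * 0.121,
          o * (center_dist + 0.14))
  }
  cb <- o * 0.153
  switch(resid,
         GLY = matrix(numeric(0), 0, 3),
         CYS = rbind(cb, o * 0.28),
         LYS = rbind(cb, o * 0.49),
         ARG = rbind(cb, o * 0.41, o * 0.52 + t * 0.12, o * 0.52 - t * 0.12),
         HIS = rbind(cb, o * 0.32 + t * 0.11, o * 0.42, o * 0.32 - t * 0.11),
         ASP = rbind(cb, o * 0.30 + t * 0.11, o * 0.30 - t * 0.11),
         GLU = rbind(cb, o * 0.42 + t * 0.11, o * 0.42 - t * 0.11),
         PHE = rbind(cb, ring6(0.38)),
         TYR = rbind(cb, ring6(0.38), o * 0.66),
         TRP = rbind(cb, o * 0.25, o * 0.31 + t * 0.12, o * 0.40 + t * 0.14,
                     ring6(0.47)),
         matrix(cb, 1, 3))  # single-CB sidechains
}

build_base_coords <- function(spec, top) {
  ca <- ca_trace(spec)
  n <- spec$n_res
  helix_center <- matrix(NA_real_, n, 2L)
  axes <- helix_axes(spec)
  for (nm in names(spec$helix_spans)) {
    h <- spec$helix_spans[[nm]]
    helix_center[seq.int(h[1], h[2]), ] <-
      matrix(axes[[nm]] %||% c(0, 0), h[2] - h[1] + 1L, 2L, byrow = TRUE)
  }
  loop_idx <- seq.int(spec$loop_span[1], spec$loop_span[2])
  seq3 <- unname(AA_1TO3[spec$sequence])
  one_chain <- function() {
    rows <- list()
    for (i in seq_len(n)) {
      prev <- ca[max(i - 1L, 1L), ]; nxt <- ca[min(i + 1L, n), ]
      d <- nxt - prev
      nd <- sqrt(sum(d^2)); d <- if (nd > 1e-9) d / nd else c(0, 0, 1)
      p <- c(d[2], -d[1], 0)
      np <- sqrt(sum(p^2)); p <- if (np > 1e-9) p / np else c(1, 0, 0)
      q <- c(d[2] * p[3] - d[3] * p[2], d[3] * p[1] - d[1] * p[3],
             d[1] * p[2] - d[2] * p[1])
      o <- if (!is.na(helix_center[i, 1])) {
        v <- c(ca[i, 1] - helix_center[i, 1], ca[i, 2] - helix_center[i, 2], 0)
        v / max(sqrt(sum(v^2)), 1e-9)
      } else if (i %in% loop_idx) c(0, -1, 0) else p
      bb <- rbind(ca[i, ] - 0.125 * d + 0.045 * p,   # N
                  ca[i, ],                            # CA
                  ca[i, ] + 0.125 * d + 0.045 * p,   # C
                  ca[i, ] + 0.125 * d + 0.045 * p + 0.12 * q)  # O
      sc <- sidechain_offsets(seq3[i], o, d)
      if (nrow(sc)) sc <- sweep(sc, 2, ca[i, ], `+`)
      rows[[i]] <- rbind(bb, sc)
    }
    do.call(rbind, rows)
  }
  xa <- one_chain()
  ## chain B: proper rotation about z (180 deg) + translation, preserving
  ## chirality, with the inner helix faces across a ~2 nm interface
  xb <- cbind(4.0 - xa[, 1], 1.1 - xa[, 2], xa[, 3])
  base <- rbind(xa, xb)
  if (nrow(base) != nrow(top$atoms))
    abort("internal error: base geometry atom count mismatch")
  base
}

## ---- trajectory generation ----------------------------------------------

## smoothing matrix: triangular kernel of half-width w, rows rescaled to
## preserve unit marginal variance under truncation at the edges
smoothing_matrix <- function(n, w) {
  if (w <= 0) return(diag(n))
  S <- matrix(0, n, n)
  for (k in -w:w) {
    wt <- (w + 1 - abs(k))
    idx <- seq_len(n)
    j <- idx + k
    ok <- j >= 1 & j <= n
    S[cbind(idx[ok], j[ok])] <- wt
  }
  S / sqrt(rowSums(S^2))
}

draw_law <- function(law, n) {
  switch(law$type,
         constant = rep(law$value, n),
         normal = pmax(stats::rnorm(n, law$mean, law$sd), 0.05),
         abort("unknown distance law type '", law$type, "'"))
}

#' Generate a synthetic trajectory
#'
#' Starting from an ideal-geometry dimer (helical segments for the helix
#' spans, an extended arc for the loop, the two chains across a shared
#' interface), each frame adds per-residue isotropic Gaussian displacements
#' with the spec's sigma profile (spatially smoothed over neighbouring
#' residues so bonded geometry stays sane; marginal per-residue amplitudes
#' are preserved exactly). S-gamma pairs are then moved symmetrically along
#' their separation axis to match draws from the pair's distance law, and
#' planted contacts are enforced at their target distances in every frame.
#' All randomness derives from `spec$seed`; the same seed reproduces the
#' trajectory bit-for-bit.
#'
#' @param spec A `psi_synthetic_spec`.
#' @param topology Optional pre-built topology (else [make_topology()]).
#' @return A `psi_trajectory`.
#' @export
make_trajectory <- function(spec = synthetic_spec(), topology = NULL) {
  top <- topology %||% make_topology(spec)
  base <- build_base_coords(spec, top)
  nf <- spec$n_frames
  n <- spec$n_res
  nat <- nrow(top$atoms)
  ## planted-constraint sanity: one constraint per atom
  anchors <- planted_anchor_atoms(spec, top)
  if (anyDuplicated(anchors$all))
    abort("contradictory constraints: atom(s) appear in more than one ",
          "planted/Sg constraint")
  S <- smoothing_matrix(n, spec$sigma_smooth)
  with_seed(spec$seed, {
    resmap <- top$atoms$resno + ifelse(top$atoms$chain == "B", n, 0L)
    xyz <- matrix(0, nf, 3L * nat)
    for (ax in 1:3) {
      gA <- matrix(stats::rnorm(nf * n), nf, n) %*% t(S)
      gB <- matrix(stats::rnorm(nf * n), nf, n) %*% t(S)
      disp <- cbind(sweep(gA, 2, spec$sigma_profile, `*`),
                    sweep(gB, 2, spec$sigma_profile, `*`))
      xyz[, seq.int(ax, 3L * nat, by = 3L)] <-
        rep(base[, ax], each = nf) + disp[, resmap]
    }
    ## S-gamma pair-distance laws, per chain
    for (lab in names(spec$sg_laws)) {
      pr <- as.integer(strsplit(lab, "-", fixed = TRUE)[[1]])
      for (ch in c("A", "B")) {
        i <- sg_index(top, ch, pr[1]); j <- sg_index(top, ch, pr[2])
        d <- draw_law(spec$sg_laws[[lab]], nf)
        xyz <- enforce_pair_distance(xyz, i, j, d)
      }
    }
    ## planted contacts at fixed distances
    for (pc in spec$planted_contacts) {
      an <- planted_anchor(pc, top)
      xyz <- enforce_pair_distance(xyz, an$i, an$j, rep(pc$dist, nf))
      if (!is.null(an$second_oxygen)) {
        ## keep the residue's other carboxylate oxygen strictly farther
        u <- unit_rows(xyz[, xyz_cols(an$i), drop = FALSE] -
                         xyz[, xyz_cols(an$j), drop = FALSE])
        xyz[, xyz_cols(an$second_oxygen)] <-
          xyz[, xyz_cols(an$i)] + 0.03 * u
      }
    }
    psi_trajectory(top, xyz, times = (seq_len(nf) - 1L) * spec$dt_ps)
  })
}

## move atoms i and j symmetrically about their midpoint to distance d
enforce_pair_distance <- function(xyz, i, j, d) {
  ci <- xyz_cols(i); cj <- xyz_cols(j)
  pi_ <- xyz[, ci, drop = FALSE]; pj <- xyz[, cj, drop = FALSE]
  u <- unit_rows(pj - pi_)
  m <- (pi_ + pj) / 2
  xyz[, ci] <- m - u * (d / 2)
  xyz[, cj] <- m + u * (d / 2)
  xyz
}

planted_anchor <- function(pc, top) {
  anchor_one <- function(chain, resno) {
    resid <- top$atoms$resid[top$atoms$chain == chain &
                               top$atoms$resno == resno][1]
    if (is.na(resid))
      abort("planted contact references nonexistent residue ", resno,
            " (chain ", chain, ")")
    if (pc$kind %in% c("HI", "HI_decoy")) {
      list(atom = named_atom_index(top, chain, resno, "CB")[1], extra = NULL)
    } else if (pc$kind %in% c("SB", "SB_decoy")) {
      if (resid %in% ACIDIC_RES) {
        oxy <- named_atom_index(top, chain, resno, ACID_OXYGENS[[resid]])
        list(atom = oxy[1], extra = oxy[2])
      } else if (resid == "LYS") {
        list(atom = named_atom_index(top, chain, resno, "NZ")[1], extra = NULL)
      } else {
        abort("planted salt bridges support Glu/Asp vs Lys only; residue ",
              resno, " (chain ", chain, ") is ", resid)
      }
    } else abort("unknown planted contact kind '", pc$kind, "'")
  }
  a <- anchor_one(pc$chain_i, pc$resno_i)
  b <- anchor_one(pc$chain_j, pc$resno_j)
  ## keep the acid (the partner owning a second oxygen) as anchor i, so the
  ## spare-oxygen offset below is applied on the correct side
  if (is.null(a$extra) && !is.null(b$extra)) { tmp <- a; a <- b; b <- tmp }
  list(i = a$atom, j = b$atom, second_oxygen = a$extra)
}

planted_anchor_atoms <- function(spec, top) {
  sg_atoms <- integer()
  for (lab in names(spec$sg_laws)) {
    pr <- as.integer(strsplit(lab, "-", fixed = TRUE)[[1]])
    for (ch in c("A", "B"))
      sg_atoms <- c(sg_atoms, sg_index(top, ch, pr[1]),
                    sg_index(top, ch, pr[2]))
  }
  pc_atoms <- integer()
  for (pc in spec$planted_contacts) {
    an <- planted_anchor(pc, top)
    pc_atoms <- c(pc_atoms, an$i, an$j)
  }
  list(sg = sg_atoms, planted = pc_atoms, all = c(sg_atoms, pc_atoms))
}

#' Generate a synthetic secondary-structure series
#'
#' Per residue and chain, an independent two-state Markov chain entered
#' with per-step switch probability from the spec's profile. Helix-span
#' residues alternate between H (alpha helix) and C (coil); loop residues
#' between C and transient G (3-10 helix); all other residues between C
#' and H. Loop residues are kept disordered-dominant by a faster exit
#' probability (`spec$loop_alt_exit`) from the transient state; with a
#' symmetric chain (exit = entry, the case for all non-loop residues) the
#' expected normalised variation of a residue equals its switch
#' probability.
#'
#' @param spec A `psi_synthetic_spec`.
#' @param seed Seed (defaults to `spec$seed + 1` so coordinate and SS
#'   streams differ).
#' @return A `psi_ss_series` with chains A and B.
#' @export
make_ss_series <- function(spec = synthetic_spec(), seed = NULL) {
  n <- spec$n_res; nf <- spec$n_frames
  helix <- unlist(lapply(spec$helix_spans, function(h) seq.int(h[1], h[2])))
  loop <- seq.int(spec$loop_span[1], spec$loop_span[2])
  primary <- rep("C", n); primary[helix] <- "H"
  alternate <- rep("H", n); alternate[helix] <- "C"; alternate[loop] <- "G"
  enter <- spec$ss_switch_prob
  exit <- enter
  if (!is.null(spec$loop_alt_exit))
    exit[loop] <- pmax(enter[loop], spec$loop_alt_exit)
  with_seed(seed %||% (spec$seed + 1L), {
    one_chain <- function() {
      state <- matrix(0L, nf, n)
      u <- matrix(stats::runif((nf - 1L) * n), nf - 1L, n)
      for (f in 2:nf) {
        pr <- ifelse(state[f - 1L, ] == 0L, enter, exit)
        state[f, ] <- (state[f - 1L, ] + (u[f - 1L, ] < pr)) %% 2L
      }
      m <- matrix(primary[col(state)], nf, n)
      m[state == 1L] <- alternate[col(state)[state == 1L]]
      m
    }
    psi_ss_series(list(A = one_chain(), B = one_chain()),
                  times = (seq_len(nf) - 1L) * spec$dt_ps)
  })
}
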