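# Small fixtures and independent brute-force oracles used across tests.
# The oracles deliberately use naive nested loops so they share no code
# path with the vectorised implementations they check.

## a small dimer spec (8 residues/chain, under 50 atoms per chain) with the
## site classes represented: hydrophobic (A, L), acidic (E, D), basic (K),
## and a cysteine pair
small_spec <- function(seed = 1L, n_frames = 5L, sigma = 0.02) {
  synthetic_spec(
    n_res = 8L,
    sequence = strsplit("ACEKLDCA", "")[[1]],
    cys_positions = c(2L, 7L),
    loop_span = c(4L, 5L),
    helix_spans = list(H1 = c(1L, 3L), H2 = c(6L, 8L)),
    sigma_profile = sigma,
    sg_laws = list(),
    ss_switch_prob = 0.1,
    planted_contacts = list(),
    n_frames = n_frames, dt_ps = 1, seed = seed)
}

## random coordinates for a topology, roughly packed so contacts occur
random_frame <- function(top, scale = 1.0, seed = NULL) {
  n <- nrow(top$atoms)
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(3 * n, 0, scale), ncol = 3)
}

as_traj <- function(top, frames, dt = 1) {
  xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f))))
  psi_trajectory(top, xyz, times = (seq_along(frames) - 1) * dt)
}

pair_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$chain_i, df$resno_i, df$chain_j, df$resno_j))
}

## --- brute-force contact oracles -----------------------------------------

oracle_hb <- function(frame, top, cutoff = 0.35, min_seq_sep = 2) {
  a <- top$atoms
  found <- character(0)
  for (i in seq_len(nrow(a) - 1)) {
    for (j in (i + 1):nrow(a)) {
      if (!(a$element[i] %in% c("N", "O"))) next
      if (!(a$element[j] %in% c("N", "O"))) next
      if (a$chain[i] == a$chain[j] &&
          abs(a$resno[i] - a$resno[j]) < min_seq_sep) next
      if (sqrt(sum((frame[i, ] - frame[j, ])^2)) > cutoff) next
      r1 <- c(a$chain[i], a$resno[i]); r2 <- c(a$chain[j], a$resno[j])
      if (r2[1] < r1[1] || (r2[1] == r1[1] &&
                            as.integer(r2[2]) < as.integer(r1[2]))) {
        tmp <- r1; r1 <- r2; r2 <- tmp
      }
      found <- c(found, paste(r1[1], r1[2], r2[1], r2[2]))
    }
  }
  sort(unique(found))
}

oracle_hi <- function(frame, top, cutoff = 0.45, min_seq_sep = 2) {
  a <- top$atoms
  res <- unique(a[c("chain", "resno", "resid")])
  found <- character(0)
  for (i in seq_len(nrow(res) - 1)) {
    for (j in (i + 1):nrow(res)) {
      if (!(res$resid[i] %in% top$hydrophobic_set)) next
      if (!(res$resid[j] %in% top$hydrophobic_set)) next
      if (res$chain[i] == res$chain[j] &&
          abs(res$resno[i] - res$resno[j]) < min_seq_sep) next
      ai <- which(a$chain == res$chain[i] & a$resno == res$resno[i] &
                    !(a$elety %in% c("N", "CA", "C", "O")) & a$element != "H")
      aj <- which(a$chain == res$chain[j] & a$resno == res$resno[j] &
                    !(a$elety %in% c("N", "CA", "C", "O")) & a$element != "H")
      if (!length(ai) || !length(aj)) next
      dmin <- Inf
      for (x in ai) for (y in aj)
        dmin <- min(dmin, sqrt(sum((frame[x, ] - frame[y, ])^2)))
      if (dmin <= cutoff)
        found <- c(found, paste(res$chain[i], res$resno[i],
                                res$chain[j], res$resno[j]))
    }
  }
  sort(unique(found))
}

oracle_sb <- function(frame, top, prot, cutoff = 0.45) {
  a <- top$atoms
  acid_oxy <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  acids <- prot[prot$resid %in% c("ASP", "GLU") & prot$state == "charged", ]
  bases <- prot[prot$resid %in% c("LYS", "ARG", "HIS") &
                  prot$state == "charged", ]
  found <- character(0)
  if (!nrow(acids) || !nrow(bases)) return(found)
  for (i in seq_len(nrow(acids))) {
    oxy <- which(a$chain == acids$chain[i] & a$resno == acids$resno[i] &
                   a$elety %in% acid_oxy[[acids$resid[i]]])
    for (j in seq_len(nrow(bases))) {
      nm <- switch(bases$resid[j], LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                   HIS = c("ND1", "NE2", "CE1"))
      bidx <- which(a$chain == bases$chain[j] & a$resno == bases$resno[j] &
                      a$elety %in% nm)
      w <- a$mass[bidx]
      site <- colSums(frame[bidx, , drop = FALSE] * w) / sum(w)
      dmin <- Inf
      for (x in oxy) dmin <- min(dmin, sqrt(sum((frame[x, ] - site)^2)))
      if (dmin <= cutoff) {
        r1 <- c(acids$chain[i], acids$resno[i])
        r2 <- c(bases$chain[j], bases$resno[j])
        if (r2[1] < r1[1] || (r2[1] == r1[1] &&
                              as.integer(r2[2]) < as.integer(r1[2]))) {
          tmp <- r1; r1 <- r2; r2 <- tmp
        }
        found <- c(found, paste(r1[1], r1[2], r2[1], r2[2]))
      }
    }
  }
  sort(unique(found))
}

## --- change-event oracle ---------------------------------------------------

oracle_changes <- function(class_matrix) {
  out <- integer(ncol(class_matrix))
  for (r in seq_len(ncol(class_matrix))) {
    cnt <- 0L
    for (f in 2:nrow(class_matrix)) {
      if (class_matrix[f, r] != class_matrix[f - 1, r]) cnt <- cnt + 1L
    }
    out[r] <- cnt
  }
  out
}

## rigid motion helper: random proper rotation + translation
random_rigid <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = stats::rnorm(3, sd = 2))
}

apply_rigid <- function(xyz_row, rig) {
  m <- matrix(xyz_row, ncol = 3, byrow = TRUE)
  as.numeric(t(sweep(m %*% t(rig$R), 2, rig$t, `+`)))
}
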