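test_that("DSSP codes collapse onto the three classes", {
  expect_equal(classify_codes(strsplit("HGIEBTSC", "")[[1]]),
               c("helix", "helix", "helix", "beta", "beta",
                 "disordered", "disordered", "disordered"))
  expect_equal(classify_codes("~"), "disordered")
  expect_equal(classify_codes(" "), "disordered")
  expect_equal(unique(as.vector(classify_codes(matrix("H", 3, 4)))), "helix")
  expect_error(classify_codes("X"), "unknown DSSP")
})

test_that("variation index counts class changes, normalised by frames - 1", {
  mk_ss <- function(m) psi_ss_series(list(A = m), seq_len(nrow(m)) - 1)

  # constant series: zero
  v0 <- variation_index(mk_ss(matrix("H", 50, 3)))
  expect_equal(v0$summary$mean, rep(0, 3))
  expect_equal(as.vector(v0$raw), rep(0L, 3), ignore_attr = TRUE)

  # alternation every frame over 1001 frames: raw 1000, normalised 1
  alt <- matrix(rep(c("H", "C"), length.out = 1001), ncol = 1)
  v1 <- variation_index(mk_ss(alt))
  expect_equal(v1$max_theoretical, 1000L)
  expect_equal(as.vector(v1$raw), 1000L, ignore_attr = TRUE)
  expect_equal(v1$summary$mean, 1.0)

  # within-class letter changes (H -> G) are not change events
  hg <- matrix(rep(c("H", "G"), length.out = 100), ncol = 1)
  expect_equal(variation_index(mk_ss(hg))$summary$mean, 0)

  expect_error(variation_index(mk_ss(matrix("H", 1, 3))), "at least 2")
})

test_that("raw change counts equal the brute-force oracle on random series", {
  set.seed(31)
  for (k in 1:25) {
    m <- matrix(sample(c("H", "G", "E", "B", "C", "T", "S", "I", "~"),
                       40 * 6, replace = TRUE), 40, 6)
    ss <- psi_ss_series(list(A = m), times = seq_len(40) - 1)
    v <- variation_index(ss)
    expect_equal(as.vector(v$raw), oracle_changes(classify_codes(m)),
                 ignore_attr = TRUE)
  }
})

test_that("variation is invariant under relabeling of the three classes", {
  set.seed(32)
  m <- matrix(sample(c("H", "E", "C"), 200 * 5, replace = TRUE), 200, 5)
  swap <- c(H = "E", E = "C", C = "H")  # class permutation via letters
  m2 <- matrix(swap[m], nrow(m))
  t0 <- seq_len(nrow(m)) - 1
  v1 <- variation_index(psi_ss_series(list(A = m), t0))
  v2 <- variation_index(psi_ss_series(list(A = m2), t0))
  expect_equal(v1$raw, v2$raw)
})

test_that("Markov switching probability is recovered as mean variation", {
  sp <- synthetic_spec(n_frames = 1001L, seed = 5L, ss_switch_prob = 0.1,
                       loop_alt_exit = NULL)  # symmetric chains everywhere
  v <- variation_index(make_ss_series(sp))
  # binomial concentration across 2 x 104 residues x 1000 transitions
  expect_lt(abs(mean(v$summary$mean) - 0.1),
            3 * sqrt(0.1 * 0.9 / (1000 * 208)))
  # per-series spread also binomial
  expect_true(all(abs(v$per_series - 0.1) < 4 * sqrt(0.1 * 0.9 / 1000)))
})

test_that("per-residue mode follows majority with fixed tie precedence", {
  m <- rbind(matrix("H", 6, 2), matrix("C", 4, 2))       # 60% helix
  tie <- cbind(rep(c("H", "C"), each = 5))               # exact 50/50
  ss <- psi_ss_series(list(A = cbind(m, tie)), times = 0:9)
  md <- ss_mode(ss)
  expect_equal(md$mode, c("helix", "helix", "helix"))    # tie -> helix

  tie_bd <- cbind(rep(c("E", "C"), each = 5))            # beta vs disordered
  md2 <- ss_mode(psi_ss_series(list(A = tie_bd), times = 0:9))
  expect_equal(md2$mode, "beta")

  # loop residues of the default generator stay disordered
  sp <- synthetic_spec(n_frames = 301L, seed = 6L)
  md3 <- ss_mode(make_ss_series(sp))
  loop <- seq(sp$loop_span[1], sp$loop_span[2])
  expect_true(all(md3$mode[loop] == "disordered"))
})

test_that("region summaries divide total variation by interval length", {
  prof <- list(summary = data.frame(resno = 1:104,
                                    mean = rep(0, 104), sd = 0, n = 6))
  prof$summary$mean[60:63] <- c(0.1, 0.1, 0.1, 0.084)   # totals 0.384
  rs <- region_summary(prof, c(60, 63))
  expect_equal(rs$total, 0.384)
  expect_equal(rs$per_residue, 0.096)

  prof$summary$mean[70:78] <- 1.016 / 9                 # nine-residue region
  rs2 <- region_summary(prof, c(70, 78))
  expect_equal(rs2$total, 1.016)
  expect_equal(rs2$per_residue, 1.016 / 9)  # 0.1129, printed 0.112 truncated

  prof$summary$mean[5] <- 0.2
  rs3 <- region_summary(prof, c(5, 5))
  expect_equal(rs3$total, 0.2)
  expect_equal(rs3$per_residue, 0.2)
  expect_error(region_summary(prof, c(50, 200)), "within the sequence")
})

test_that("dimer net variation sums both chains, with per-residue form", {
  zero <- list(summary = data.frame(resno = 1:104, mean = 0, sd = 0, n = 6))
  expect_equal(dimer_net_variation(zero)$total, 0)

  unif <- list(summary = data.frame(resno = 1:104, mean = 0.05, sd = 0, n = 6))
  nv <- dimer_net_variation(unif)
  expect_equal(nv$total, 2 * 104 * 0.05)
  expect_equal(nv$per_residue, 0.05)

  # Markov series at p = 0.05: per-residue net variation ~ 0.05 over 208
  sp <- synthetic_spec(n_frames = 1001L, seed = 7L, ss_switch_prob = 0.05,
                       loop_alt_exit = NULL)
  v <- variation_index(make_ss_series(sp))
  nv2 <- dimer_net_variation(v)
  expect_lt(abs(nv2$per_residue - 0.05), 3 * sqrt(0.05 * 0.95 / (1000 * 208)))
})
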