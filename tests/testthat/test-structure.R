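test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  P <- matrix(rnorm(30), ncol = 3)
  # self-fit: identity transform
  s <- superpose(P, P)
  expect_equal(s$R, diag(3), tolerance = 1e-10)
  expect_lt(s$rmsd_fit, 1e-10)

  # an arbitrarily rotated + translated copy superposes to RMSD ~ 0
  rig <- random_rigid(seed = 2)
  M <- sweep(P %*% t(rig$R), 2, rig$t, `+`)
  s2 <- superpose(M, P)
  expect_lt(s2$rmsd_fit, 1e-6)
  expect_equal(det(s2$R), 1, tolerance = 1e-9)

  # degenerate (collinear) fit sets are rejected
  L <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(L, L + 0.1), "degenerate")
  expect_error(superpose(P[1:2, ], P[1:2, ]), "at least 3")
})

test_that("reflections are never used: proper rotation enforced", {
  set.seed(3)
  P <- matrix(rnorm(24), ncol = 3)
  M <- P %*% diag(c(-1, 1, 1))  # mirror image: only a reflection fits exactly
  s <- superpose(M, P)
  expect_equal(det(s$R), 1, tolerance = 1e-9)
  expect_gt(s$rmsd_fit, 1e-3)
  # brute force over random proper rotations: none beats the Kabsch optimum
  for (k in 1:200) {
    rig <- random_rigid()
    cand <- sweep(M %*% t(rig$R), 2, colMeans(P) - colMeans(M %*% t(rig$R)), `+`)
    expect_gte(sqrt(mean(rowSums((cand - P)^2))), s$rmsd_fit - 1e-9)
  }
})

test_that("superposed RMSD agrees with bio3d's independent fit", {
  set.seed(4)
  P <- matrix(rnorm(45), ncol = 3)
  M <- P + matrix(rnorm(45, sd = 0.1), ncol = 3)
  ours <- superpose(M, P)$rmsd_fit
  fitted <- bio3d::fit.xyz(as.numeric(t(P)), as.numeric(t(M)),
                           fixed.inds = 1:45, mobile.inds = 1:45)
  theirs <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) - P)^2)))
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("RMSD series: static zero, closed-form displacement, n = 3", {
  sp <- small_spec(n_frames = 4L)
  sp$sigma_profile <- rep(0, 8)
  tr <- make_trajectory(sp)
  r <- rmsd_series(tr, fit = "backbone", measure = "backbone")
  expect_equal(r$value_nm, rep(0, 4), tolerance = 1e-10)

  # one atom of an N-atom rigid body displaced by d, fitting disabled:
  # RMSD = d / sqrt(N)
  N <- length(atom_indices(tr$topology, "backbone"))
  d <- 0.3
  tr2 <- tr
  b1 <- atom_indices(tr2$topology, "backbone")[1]
  tr2$xyz[2, psitraj:::xyz_cols(b1)[1]] <-
    tr2$xyz[2, psitraj:::xyz_cols(b1)[1]] + d
  r2 <- rmsd_series(tr2, fit = NULL, measure = "backbone")
  expect_equal(r2$value_nm[2], d / sqrt(N), tolerance = 1e-10)

  # replicate summary reports SEM with n = replicates
  s <- summarize_replicates(list(r, r, r))
  expect_equal(s$n, 3L)
  expect_equal(s$sem, 0)
})

test_that("RMSD and Rg are invariant under global rigid motion", {
  sp <- small_spec(seed = 8L, n_frames = 6L)
  tr <- make_trajectory(sp)
  tr_m <- tr
  for (f in seq_len(n_frames(tr)))
    tr_m$xyz[f, ] <- apply_rigid(tr$xyz[f, ], random_rigid(seed = 100 + f))
  r0 <- rmsd_series(tr, fit = "backbone")$value_nm
  r1 <- rmsd_series(tr_m, fit = "backbone")$value_nm
  expect_equal(r1, r0, tolerance = 1e-6)
  g0 <- radius_of_gyration(tr)$value_nm
  g1 <- radius_of_gyration(tr_m)$value_nm
  expect_equal(g1, g0, tolerance = 1e-6)
})

test_that("RMSF: static zero; isotropic jitter converges to sigma*sqrt(3)", {
  sp <- small_spec(n_frames = 3L)
  sp$sigma_profile <- rep(0, 8)
  tr <- make_trajectory(sp)
  for (m in c("raw", "pc1"))
    expect_equal(rmsf_profile(tr, mode = m)$rmsf_nm, rep(0, 16),
                 tolerance = 1e-10)

  sp2 <- small_spec(seed = 21L, n_frames = 5000L, sigma = 0.02)
  sp2$sigma_smooth <- 0L  # independent residues: pure isotropic jitter
  tr2 <- make_trajectory(sp2)
  pr <- rmsf_profile(tr2, mode = "raw")
  expect_equal(mean(pr$rmsf_nm), 0.02 * sqrt(3), tolerance = 0.1)
})

test_that("PC1-filtered RMSF is bounded by raw RMSF, equal for single-mode", {
  sp <- synthetic_spec(n_frames = 80L, seed = 13L)
  tr <- make_trajectory(sp)
  raw <- rmsf_profile(tr, mode = "raw")
  pc1 <- rmsf_profile(tr, mode = "pc1")
  expect_true(all(pc1$rmsf_nm <= raw$rmsf_nm + 1e-12))

  # motion confined to one collective direction: pc1 equals raw
  sp0 <- small_spec(n_frames = 40L)
  sp0$sigma_profile <- rep(0, 8)
  tr0 <- make_trajectory(sp0)
  amp <- sin(seq(0, 3 * pi, length.out = 40))
  dir <- rep(c(1, 0, 0), nrow(tr0$topology$atoms))
  tr0$xyz <- tr0$xyz + 0.1 * outer(amp, dir)
  r_raw <- rmsf_profile(tr0, mode = "raw", fit = NULL)
  r_pc1 <- rmsf_profile(tr0, mode = "pc1", fit = NULL)
  expect_equal(r_pc1$rmsf_nm, r_raw$rmsf_nm, tolerance = 1e-9)
})

test_that("radius of gyration matches closed forms", {
  # two unit masses at distance d: Rg = d/2
  atoms <- data.frame(chain = rep(c("A", "B"), each = 1),
                      resno = 1L, resid = "GLY", elety = "CA",
                      element = "C", mass = 12.011)
  top <- psi_topology(atoms, cys_pairs = native_cys_pairs()[0, , drop = FALSE],
                      loop_span = c(1L, 1L), helix_spans = list())
  d <- 1.4
  tr <- psi_trajectory(top, matrix(c(0, 0, 0, 0, 0, d), nrow = 1), times = 0)
  expect_equal(radius_of_gyration(tr)$value_nm, d / 2, tolerance = 1e-12)

  # N equal masses uniform on a line of length L: Rg -> L/sqrt(12)
  N <- 1000L; L <- 5
  atoms2 <- data.frame(chain = rep(c("A", "B"), each = N / 2),
                       resno = rep(seq_len(N / 2), 2), resid = "GLY",
                       elety = "CA", element = "C", mass = 12.011)
  top2 <- psi_topology(atoms2,
                       cys_pairs = native_cys_pairs()[0, , drop = FALSE],
                       loop_span = c(1L, 1L), helix_spans = list())
  x <- seq(0, L, length.out = N)
  tr2 <- psi_trajectory(top2, matrix(as.numeric(rbind(x, 0, 0)), nrow = 1),
                        times = 0)
  expect_equal(radius_of_gyration(tr2)$value_nm, L / sqrt(12),
               tolerance = 0.01 * L / sqrt(12))
  expect_error(radius_of_gyration(tr2, selection = integer(0)), "no atoms|mass")
})

test_that("centre-of-mass separations follow centroid arithmetic", {
  sp <- small_spec(n_frames = 2L)
  sp$sigma_profile <- rep(0, 8)
  tr <- make_trajectory(sp)
  a <- atom_indices(tr$topology, chain = "A")
  expect_equal(com_separation(tr, a, a)$value_nm, c(0, 0), tolerance = 1e-12)

  # two equal-mass pairs with centroids 2 nm apart
  atoms <- data.frame(chain = rep(c("A", "B"), each = 2),
                      resno = c(1L, 2L, 1L, 2L), resid = "GLY", elety = "CA",
                      element = "C", mass = 12.011)
  top <- psi_topology(atoms, cys_pairs = native_cys_pairs()[0, , drop = FALSE],
                      loop_span = c(1L, 1L), helix_spans = list())
  xyz <- matrix(c(-1, 0, 0, 1, 0, 0,  -1, 0, 2, 1, 0, 2), nrow = 1)
  tr2 <- psi_trajectory(top, xyz, times = 0)
  expect_equal(com_separation(tr2, 1:2, 3:4)$value_nm, 2, tolerance = 1e-12)
  # two single atoms 1.5 nm apart
  xyz2 <- matrix(c(0, 0, 0, 0, 0, 1.5, 0, 0, 3, 0, 0, 4.5), nrow = 1)
  tr3 <- psi_trajectory(top, xyz2, times = 0)
  expect_equal(com_separation(tr3, 1L, 2L)$value_nm, 1.5, tolerance = 1e-12)
  expect_error(com_separation(tr2, integer(0), 3:4), "non-empty")
})
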