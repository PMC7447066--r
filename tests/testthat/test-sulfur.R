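test_that("S-gamma distances are Euclidean separations in nm", {
  sp <- small_spec(n_frames = 3L)
  sp$sigma_profile <- rep(0, 8)  # static geometry
  sp$sg_laws <- list("2-7" = list(type = "constant", value = 0.2038))
  tr <- make_trajectory(sp)
  d <- sg_distances(tr, pairs = cbind(2L, 7L))
  expect_true(all(abs(d$dist_nm - 0.2038) < 1e-9))
  expect_false(any(d$native))  # 2-7 is not in the native registry

  # missing S-gamma atom is rejected naming the residue
  expect_error(sg_distances(tr, pairs = cbind(1L, 2L)), "residue 1")

  # coincident atoms warn about degeneracy
  i <- psitraj:::sg_index(tr$topology, "A", 2L)
  j <- psitraj:::sg_index(tr$topology, "A", 7L)
  tr$xyz[, psitraj:::xyz_cols(j)] <- tr$xyz[, psitraj:::xyz_cols(i)]
  expect_warning(sg_distances(tr, pairs = cbind(2L, 7L), chains = "A"),
                 "coincident")
})

test_that("series enumeration: pairs x chains x replicates", {
  sp <- synthetic_spec(n_frames = 5L, seed = 11L)
  d <- do.call(rbind, lapply(1:3, function(r) {
    sp$seed <- r
    sg_distances(make_trajectory(sp), replicate = r)
  }))
  series <- unique(d[c("pair", "chain", "replicate")])
  expect_equal(nrow(series), 18L)  # 3 native pairs x 2 chains x 3 replicates
})

test_that("pooled histograms normalise per series and pool mean/SD", {
  mk <- function(vals, chain, rep) {
    data.frame(pair = "31-71", native = TRUE, chain = chain, replicate = rep,
               time_ps = seq_along(vals), dist_nm = vals)
  }
  # two series with per-bin frequencies {0.6, 0.4} and {0.4, 0.6}
  s1 <- mk(c(rep(0.005, 6), rep(0.015, 4)), "A", 1)
  s2 <- mk(c(rep(0.005, 4), rep(0.015, 6)), "B", 1)
  h <- pooled_histogram(rbind(s1, s2))
  expect_equal(h$mean_freq, c(0.5, 0.5))
  expect_equal(h$sd_freq, c(0.1414214, 0.1414214), tolerance = 1e-6)
  expect_equal(unique(h$n), 2L)

  # six identical series: mean equals the series, SD identically zero
  six <- do.call(rbind, lapply(1:3, function(r)
    rbind(mk(c(0.005, 0.015, 0.015, 0.025), "A", r),
          mk(c(0.005, 0.015, 0.015, 0.025), "B", r))))
  h6 <- pooled_histogram(six)
  expect_equal(h6$mean_freq, c(0.25, 0.5, 0.25))
  expect_equal(h6$sd_freq, c(0, 0, 0))
  expect_equal(unique(h6$n), 6L)  # both monomers of three replicates

  expect_error(pooled_histogram(s1[0, ]), "no distance series")
})

test_that("each pooled series' frequencies sum to one on the shared grid", {
  sp <- synthetic_spec(n_frames = 60L, seed = 4L,
                       sg_laws = condition_sg_laws("AR", 3.0))
  d <- sg_distances(make_trajectory(sp))
  h <- pooled_histogram(d)
  sums <- tapply(h$mean_freq, h$pair, sum)
  expect_true(all(abs(sums - 1) < 1e-9))  # mean of unit-sum series is unit-sum
  # grid is uniform at the configured width
  expect_true(all(abs((h$bin_hi - h$bin_lo) - 0.01) < 1e-12))
  # per-bin mean equals a direct average over the per-series frequencies
  one <- h[h$pair == "6-99", ]
  freq <- sapply(split(d[d$pair == "6-99", ],
                       interaction(d$chain[d$pair == "6-99"],
                                   d$replicate[d$pair == "6-99"])),
                 function(s) {
                   b <- pmin(pmax(ceiling(s$dist_nm / 0.01 - 1e-9), 1),
                             nrow(one))
                   tabulate(b, nbins = nrow(one)) / length(s$dist_nm)
                 })
  expect_equal(one$mean_freq, rowMeans(freq), tolerance = 1e-12)
})

test_that("reformability reports the sub-cutoff fraction and a verdict", {
  expect_equal(reformability(rep(0.35, 50))$fraction_below, 1.0)
  expect_equal(reformability(rep(0.35, 50))$verdict, "likely reform")
  expect_equal(reformability(rep(0.50, 50))$fraction_below, 0.0)
  expect_equal(reformability(rep(0.50, 50))$verdict, "unlikely")
  expect_equal(
    reformability(c(rep(0.39, 60), rep(0.41, 40)))$fraction_below, 0.6)

  # monotone non-decreasing in the cutoff
  set.seed(42)
  x <- runif(500, 0.1, 0.9)
  fr <- vapply(seq(0.1, 0.9, by = 0.05),
               function(ct) reformability(x, cutoff = ct)$fraction_below,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_error(reformability(numeric(0)), "empty")
})

test_that("interchange screen covers exactly the two non-native pairs", {
  expect_equal(rownames(nonnative_cys_pairs()), c("31-37", "68-71"))
  sp <- synthetic_spec(n_frames = 10L, seed = 2L)
  d <- interchange_distances(make_trajectory(sp))
  expect_setequal(unique(d$pair), c("31-37", "68-71"))
  expect_true(all(!d$native))

  # a pair held at 0.30 nm is feasible at the 0.4 nm cutoff; 0.80 nm is not
  expect_equal(reformability(rep(0.30, 20))$verdict, "likely reform")
  expect_equal(reformability(rep(0.80, 20))$verdict, "unlikely")
})

test_that("an enforced normal distance law is recovered within MC error", {
  sp <- synthetic_spec(n_frames = 400L, seed = 9L)
  sp$sg_laws <- list("31-71" = list(type = "normal", mean = 0.45, sd = 0.05))
  d <- sg_distances(make_trajectory(sp), pairs = cbind(31L, 71L))
  n <- nrow(d)
  expect_lt(abs(mean(d$dist_nm) - 0.45), 3 * 0.05 / sqrt(n))
})
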