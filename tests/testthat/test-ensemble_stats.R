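test_that("superposed RMSD is zero on rigid copies and matches the SVD closed form", {
  set.seed(4)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(a, a), 0, tolerance = 1e-9)
  R <- random_rotation()
  b <- sweep(a %*% t(R), 2, c(3, -1, 8), "+")
  expect_lt(rmsd(a, b, superpose = TRUE), 1e-6)
  expect_gt(rmsd(a, b, superpose = FALSE), 1)
  # independent closed-form oracle on noisy pairs, including a 3-atom toy
  for (n in c(3, 7, 25)) {
    x <- matrix(rnorm(3 * n), n, 3)
    y <- sweep(x %*% t(random_rotation()), 2, rnorm(3), "+") +
      matrix(rnorm(3 * n, sd = 0.3), n, 3)
    expect_equal(rmsd(x, y, superpose = TRUE), svd_rmsd(x, y),
                 tolerance = 1e-6)
  }
  expect_error(rmsd(a, a[1:5, ]), "congruence")
  # metric properties on random triples
  for (k in 1:5) {
    x <- matrix(rnorm(24), 8, 3); y <- matrix(rnorm(24), 8, 3)
    z <- matrix(rnorm(24), 8, 3)
    expect_equal(rmsd(x, y), rmsd(y, x), tolerance = 1e-6)
    expect_lte(rmsd(x, z), rmsd(x, y) + rmsd(y, z) + 1e-9)
  }
})

test_that("block statistics reproduce the published across-replicate estimate", {
  # the twelve per-replicate mean RMSDs of the stability analysis, fed as
  # degenerate one-block series
  replicate_means <- c(2.69, 2.21, 2.08, 2.11, 2.10, 2.55,
                       2.02, 2.19, 2.65, 2.43, 2.21, 2.08)
  bs <- block_stats(as.list(replicate_means), block_size = 1)
  expect_equal(round(bs$ensemble_mean, 2), 2.28)
  expect_equal(round(bs$ensemble_sem, 2), 0.07)
  # independent one-line recomputation agrees to 1e-12 pre-rounding
  expect_equal(bs$ensemble_sem,
               stats::sd(replicate_means) / sqrt(12), tolerance = 1e-12)
  expect_equal(bs$ensemble_mean, mean(replicate_means), tolerance = 1e-12)
})

test_that("block statistics algebra: degenerate, tiling and truncation cases", {
  const <- block_stats(list(rep(2.5, 100)), block_size = 10)
  expect_equal(const$per_replicate$sem, 0)
  expect_equal(const$per_replicate$mean, 2.5)
  # mean of block means equals the plain mean when blocks tile exactly
  set.seed(8)
  v <- abs(rnorm(500))
  bs <- block_stats(list(v), block_size = 50)
  expect_equal(bs$per_replicate$mean, mean(v), tolerance = 1e-12)
  expect_equal(bs$per_replicate$n_blocks, 10L)
  # trailing partial block dropped and reported
  bs2 <- block_stats(list(v[1:487]), block_size = 50)
  expect_equal(bs2$per_replicate$n_blocks, 9L)
  expect_equal(bs2$per_replicate$dropped_frames, 37L)
  expect_equal(bs2$per_replicate$mean, mean(v[1:450]), tolerance = 1e-12)
  expect_error(block_stats(list(v[1:20]), block_size = 50), "parameter error")
  # per-replicate mean equals the mean of its block means by construction
  many <- block_stats(lapply(1:4, function(i) abs(rnorm(200))), 25)
  expect_equal(many$per_replicate$mean,
               vapply(many$block_means, mean, numeric(1)))
  expect_equal(many$ensemble_mean, mean(many$per_replicate$mean))
})

test_that("rmsd_series fits frames to the reference over the selection", {
  ens <- make_ensemble(small_scenario(seed = 12, noise_sigma = 0.4))
  cx <- attr(ens, "complex")
  sel <- intersect(select_atoms(ens$topology, segment = "H5",
                                map = cx$galpha_map),
                   select_atoms(ens$topology, atom = "CA"))
  series <- rmsd_series(ens, sel, superpose = TRUE)
  expect_length(series, 3)
  expect_true(all(unlist(lapply(series, function(s) s$values)) >= 0))
  # fitted RMSD of a noisy rigid copy concentrates near sigma * sqrt(3)-ish,
  # far below the unfitted positional displacement of the moved basins
  unfitted <- rmsd_series(ens, sel, superpose = FALSE)
  expect_gt(mean(unfitted[[1]]$values), mean(series[[1]]$values))
})

test_that("GROMOS clustering equals the brute-force implementation", {
  for (seed in c(31, 32)) {
    spec <- scenario_spec(seed = seed, n_replicates = 2L,
                          frames_per_replicate = 60L,
                          basins = list(
                            list(fraction = 0.5, displacement = c(0, 0, 0), rotation = 0),
                            list(fraction = 0.3, displacement = c(5, 0, 0), rotation = 15)),
                          noise_sigma = 0.4)
    ens <- make_ensemble(spec)
    cx <- attr(ens, "complex")
    sel <- intersect(select_atoms(ens$topology, segment = "H5",
                                  map = cx$galpha_map),
                     select_atoms(ens$topology, atom = "CA"))
    cl <- cluster_frames(ens, sel, rmsd_cutoff = 1.5)
    X <- gik:::frame_matrix(ens, sel, analyzed_frames(ens))
    ref <- brute_gromos(X, length(sel), 1.5)
    expect_equal(cl$assignments, ref$assignments)
    expect_equal(cl$populations$count, ref$populations$count)
    expect_equal(cl$populations$medoid, ref$populations$medoid)
  }
})

test_that("clustering limits and tie-breaks are deterministic", {
  # infinite cutoff: one cluster holding everything
  ens <- make_ensemble(small_scenario(seed = 44))
  cx <- attr(ens, "complex")
  sel <- intersect(select_atoms(ens$topology, segment = "H5",
                                map = cx$galpha_map),
                   select_atoms(ens$topology, atom = "CA"))
  one <- cluster_frames(ens, sel, rmsd_cutoff = 1e9)
  expect_equal(nrow(one$populations), 1)
  expect_equal(one$populations$fraction, 1)
  expect_equal(one$populations$medoid, 1)  # tie broken to lowest frame index
  # single frame: one cluster of one
  single <- cluster_frames(matrix(rnorm(9), 1, 9))
  expect_equal(single$populations$count, 1L)
  # symmetric equidistant triple: medoid is the lowest index
  eq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  cl3 <- cluster_frames(eq, rmsd_cutoff = 2)
  expect_equal(representative(cl3, 1)$frame_index, 1L)
  expect_error(representative(cl3, 99), "lookup error")
  # fractions over all clusters sum to one
  noisy <- cluster_frames(matrix(rnorm(60), 20, 3), rmsd_cutoff = 0.5)
  expect_equal(sum(noisy$populations$fraction), 1)
  expect_equal(sum(noisy$populations$count), 20L)
})

test_that("zero-noise basins cluster exactly and medoids sit in-basin", {
  spec <- scenario_spec(seed = 5, n_replicates = 2L, frames_per_replicate = 100L,
                        basins = list(
                          list(fraction = 0.6, displacement = c(0, 0, 0), rotation = 0),
                          list(fraction = 0.4, displacement = c(6, 0, 0), rotation = 0)),
                        noise_sigma = 0)
  ens <- make_ensemble(spec)
  cx <- attr(ens, "complex")
  sel <- intersect(select_atoms(ens$topology, segment = "H5",
                                map = cx$galpha_map),
                   select_atoms(ens$topology, atom = "CA"))
  cl <- cluster_frames(ens, sel, rmsd_cutoff = 0.5)
  truth <- attr(ens, "truth")
  expect_equal(nrow(cl$populations), 2)
  expect_equal(cl$populations$fraction,
               sort(truth$empirical_fractions, decreasing = TRUE))
  # within a zero-noise basin every frame is identical: RMSD 0 to the medoid
  med <- representative(cl, 1)
  Xsel <- gik:::frame_matrix(ens, sel, analyzed_frames(ens))
  members <- which(cl$assignments == 1)
  d <- apply(Xsel[members, , drop = FALSE], 1, function(v)
    sqrt(sum((v - Xsel[med$frame_index, ])^2) / length(sel)))
  expect_equal(max(d), 0, tolerance = 1e-9)
})

test_that("population bookkeeping reconstructs fractions from published counts", {
  # a cluster report giving one (count, fraction) pair fixes the frame total
  pops <- population_fractions(c(3525, 1162, 1117),
                               known_count = 1162, known_fraction = 0.155)
  expect_equal(attr(pops, "total"), 7497)
  expect_equal(round(100 * pops$fraction[1], 0), 47)
  expect_equal(round(100 * pops$fraction[3], 1), 14.9)
  expect_error(population_fractions(1:3), "known_count")
})
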