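test_that("seed-point correlation matches a per-pixel Pearson loop oracle", {
  set.seed(5)
  h <- 10; w <- 10; n <- 20
  pats <- array(rnorm(h * w * n), dim = c(h, w, n))
  mask <- matrix(TRUE, h, w)
  pe <- pattern_ensemble(pats, mask, pixel_um = 100)
  seedp <- c(4, 7)
  cf <- correlation_pattern(pe, seedp)
  sv <- vapply(1:n, function(i) pats[seedp[1], seedp[2], i], numeric(1))
  oracle <- matrix(NA_real_, h, w)
  for (r in 1:h) for (c in 1:w)
    oracle[r, c] <- cor(vapply(1:n, function(i) pats[r, c, i], numeric(1)), sv)
  expect_lt(max(abs(cf$values - oracle)), 1e-12)
  expect_equal(cf$values[seedp[1], seedp[2]], 1)
  # symmetry: swapping the roles of x and s gives the same value
  cf2 <- correlation_pattern(pe, c(9, 2))
  expect_equal(cf$values[9, 2], cf2$values[4, 7], tolerance = 1e-12)
})

test_that("two-pattern and degenerate ensembles behave per definition", {
  set.seed(8)
  P <- matrix(rnorm(64), 8, 8)
  P[P == 0] <- 0.1
  pats <- array(c(P, -P), dim = c(8, 8, 2))
  pe <- pattern_ensemble(pats, matrix(TRUE, 8, 8), 100)
  cf <- correlation_pattern(pe, c(3, 3))
  expect_true(all(abs(abs(cf$values) - 1) < 1e-12))
  expect_equal(cf$values, sign(P * P[3, 3]), tolerance = 1e-12)
  # constant seed pixel -> degenerate
  pats2 <- pats
  pats2[5, 5, ] <- 1
  pe2 <- pattern_ensemble(pats2, matrix(TRUE, 8, 8), 100)
  expect_error(correlation_pattern(pe2, c(5, 5)), "degenerate")
  # independent-noise null: |C| < 0.3 almost everywhere for N = 100
  set.seed(12)
  pats3 <- array(rnorm(20 * 20 * 100), dim = c(20, 20, 100))
  pe3 <- pattern_ensemble(pats3, matrix(TRUE, 20, 20), 100)
  cf3 <- correlation_pattern(pe3, c(10, 10))
  far <- abs(cf3$values)
  far[10, 10] <- NA
  expect_gt(mean(far < 0.3, na.rm = TRUE), 0.97)
})

test_that("band-pass follows the difference-of-Gaussians transfer function", {
  p <- synth_params(seed = 1, n_events = 8)
  h <- p$grid_h; w <- p$grid_w
  mask <- matrix(TRUE, h, w)
  lam_um <- 900
  k <- 2 * pi / lam_um
  cols_um <- (col(mask) - 1) * p$pixel_um
  sinp <- sin(k * cols_um)
  pe <- bandpass_filter_patterns(array(sinp, dim = c(h, w, 1)),
                                 s_high_um = 195, s_low_um = 33,
                                 mask = mask, pixel_um = p$pixel_um)
  transfer <- exp(-k^2 * 33^2 / 2) - exp(-k^2 * 195^2 / 2)
  # compare amplitude in the interior (away from mask-edge normalization)
  ctr <- pe$patterns[40:95, 40:120, 1]
  ref <- sinp[40:95, 40:120]
  expect_equal(max(ctr) / max(ref), transfer, tolerance = 0.02)
  expect_equal(sd(ctr) / sd(ref), transfer, tolerance = 0.02)
  # a constant pattern is annihilated (no DC leakage)
  pec <- bandpass_filter_patterns(array(3, dim = c(h, w, 1)),
                                  mask = mask, pixel_um = p$pixel_um)
  expect_lt(max(abs(pec$patterns), na.rm = TRUE), 1e-10)
  # linearity: filtering commutes with scaling
  pe2 <- bandpass_filter_patterns(array(2.5 * sinp, dim = c(h, w, 1)),
                                  s_high_um = 195, s_low_um = 33,
                                  mask = mask, pixel_um = p$pixel_um)
  expect_equal(pe2$patterns, 2.5 * pe$patterns, tolerance = 1e-10)
  expect_error(bandpass_filter_patterns(array(sinp, dim = c(h, w, 1)),
                                        s_high_um = 30, s_low_um = 40,
                                        mask = mask, pixel_um = p$pixel_um),
               "smaller")
})

test_that("downsampling block-averages data and majority-votes the mask", {
  set.seed(3)
  x <- array(rnorm(60 * 60), dim = c(60, 60, 1))
  mask <- matrix(TRUE, 60, 60)
  mask[1:2, ] <- FALSE
  pe <- bandpass_filter_patterns(x, s_high_um = 400, s_low_um = 50,
                                 target_dim = c(15, 15), mask = mask,
                                 pixel_um = 25)
  expect_equal(dim(pe$patterns)[1:2], c(15, 15))
  expect_equal(pe$pixel_um, 100)
  # first row of blocks: 2 of 4 rows masked -> not a majority of in-mask px
  expect_true(all(pe$mask[2:15, ]))
})

test_that("rotation/reflection surrogates are rearrangements of each pattern", {
  p <- small_params()
  ep <- synth_event_patterns(make_modular_basis(p), p)
  pe <- pattern_ensemble(ep$patterns, ep$mask, p$pixel_um)
  ctr_idx <- which(pe$mask, arr.ind = TRUE)
  center <- c(mean(ctr_idx[, 1]), mean(ctr_idx[, 2]))
  # identity transform leaves the pattern untouched
  m0 <- modcortex:::rotation_map(60, 60, 0, FALSE, FALSE, center)
  t0 <- modcortex:::apply_rotation_map(pe$patterns[, , 1], pe$mask, m0)
  expect_equal(t0, pe$patterns[, , 1], tolerance = 1e-12)
  # two 180-degree rotations compose to the identity where defined
  m180 <- modcortex:::rotation_map(60, 60, 180, FALSE, FALSE, center)
  t1 <- modcortex:::apply_rotation_map(pe$patterns[, , 1], pe$mask, m180)
  t2 <- modcortex:::apply_rotation_map(t1, !is.na(t1), m180)
  ok <- !is.na(t2)
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(t2[ok] - pe$patterns[, , 1][ok])), 1e-9)
  # a rotation approximately preserves the value distribution
  m70 <- modcortex:::rotation_map(60, 60, 70, TRUE, FALSE, center)
  t3 <- modcortex:::apply_rotation_map(pe$patterns[, , 1], pe$mask, m70)
  q_src <- quantile(pe$patterns[, , 1][pe$mask], c(0.1, 0.5, 0.9))
  q_rot <- quantile(t3[!is.na(t3)], c(0.1, 0.5, 0.9))
  expect_equal(unname(q_rot), unname(q_src), tolerance = 0.1)
  # draws are seeded
  s1 <- make_surrogate_ensemble(pe, 5, seed = 9)
  s2 <- make_surrogate_ensemble(pe, 5, seed = 9)
  expect_identical(s1$draws, s2$draws)
  expect_identical(surrogate_patterns(s1, 3), surrogate_patterns(s2, 3))
})

test_that("correlation maxima respect the minimum separation", {
  px <- 100  # 100 um per pixel -> 800 um = 8 px suppression radius
  h <- 40; w <- 40
  mask <- matrix(TRUE, h, w)
  two_far <- gauss_bump(h, w, 12, 12, 2, 1) + gauss_bump(h, w, 12, 27, 2, 0.8)
  mx <- find_correlation_maxima(two_far, mask, px, 800)
  expect_equal(nrow(mx), 2)   # 15 px = 1.5 mm apart: both kept
  two_near <- gauss_bump(h, w, 20, 18, 2, 1) + gauss_bump(h, w, 20, 23, 2, 0.8)
  mx2 <- find_correlation_maxima(two_near, mask, px, 800)
  expect_equal(nrow(mx2), 1)  # 0.5 mm apart: higher bump suppresses lower
  expect_equal(unname(unlist(mx2[1, 1:2])), c(20, 18))
  # constant field: no strict maxima
  mx3 <- find_correlation_maxima(matrix(1, h, w), mask, px)
  expect_equal(nrow(mx3), 0)
})

test_that("distance profiles separate structured from unstructured ensembles", {
  # rank-1 ensemble (one global pattern, scaled): r = 1 at all maxima
  p <- synth_params(n_basis = 1, n_events = 30, pattern_noise_sd = 0.02, seed = 17)
  ep <- synth_event_patterns(make_modular_basis(p), p)
  pe <- bandpass_filter_patterns(ep$patterns, mask = ep$mask, pixel_um = p$pixel_um)
  prof <- correlation_vs_distance(pe, n_subsample_events = 30, seed_stride = 10,
                                  seed = 2)
  far <- prof$profile[prof$profile$bin_center_mm > 1, ]
  expect_gt(min(far$median_r), 0.8)
  # independent noise: far maxima carry only the positive selection bias
  # of picking local peaks of an N=100 null field (about 2-3 null SDs),
  # nowhere near the structured ensemble's values
  set.seed(30)
  pats <- array(rnorm(68 * 80 * 100), dim = c(68, 80, 100))
  mask <- matrix(TRUE, 68, 80)
  pen <- bandpass_filter_patterns(pats, mask = mask, pixel_um = 37.5)
  prof2 <- correlation_vs_distance(pen, n_subsample_events = 100,
                                   seed_stride = 10, seed = 2)
  far2 <- prof2$profile[prof2$profile$bin_center_mm > 1, ]
  expect_lt(max(abs(far2$median_r)), 0.4)
  expect_gt(min(far$median_r) - max(far2$median_r), 0.4)
  expect_warning(correlation_vs_distance(pen, n_subsample_events = 150,
                                         seed_stride = 20, seed = 1),
                 "using all")
})

test_that("long-range significance rejects a too-small field of view", {
  set.seed(40)
  pats <- array(rnorm(12 * 12 * 10), dim = c(12, 12, 10))
  pe <- pattern_ensemble(pats, matrix(TRUE, 12, 12), pixel_um = 50)  # 0.6 mm
  surr <- make_surrogate_ensemble(pe, 3, seed = 1)
  expect_error(longrange_significance(pe, surr, band_mm = c(1.8, 2.2)),
               "too small")
})
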