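test_that("neuropil correction is exact elementwise arithmetic", {
  rec <- cell_recording(f_raw = matrix(10, 2, 5), f_neuropil = matrix(5, 2, 5),
                        positions_um = cbind(c(0, 30), c(0, 0)),
                        frame_rate_hz = 15)
  expect_equal(neuropil_correct(rec)[1, 1], 8.0)            # 10 - 0.4 * 5
  expect_equal(neuropil_correct(rec, alpha = 0), rec$f_raw) # identity
  rec2 <- cell_recording(rec$f_raw, rec$f_raw, rec$positions_um, 15)
  expect_equal(neuropil_correct(rec2), 0.6 * rec2$f_raw)
})

test_that("cellular dF/F is robust, smooth, and scale-invariant", {
  fr <- 10
  t_n <- 1200
  flat <- matrix(100, 1, t_n)
  expect_equal(max(abs(cell_dff(flat, fr))), 0)
  # single-frame spike is erased by the 7-frame median smoother
  spiky <- flat
  spiky[1, 600] <- 200
  d <- cell_dff(spiky, fr)
  expect_lt(abs(d[1, 600]), 1e-12)
  # without smoothing the spike survives
  d2 <- cell_dff(spiky, fr, smooth_frames = 1)
  expect_equal(d2[1, 600], 1.0)
  # scaling F leaves dF/F unchanged
  set.seed(3)
  tr <- matrix(100 + cumsum(rnorm(t_n, sd = 0.1)), 1, t_n)
  expect_equal(cell_dff(tr, fr), cell_dff(2 * tr, fr), tolerance = 1e-12)
  expect_error(cell_dff(matrix(0, 1, t_n), fr), "cell")
})

test_that("cell events merge runs and split at active-count minima", {
  n_cells <- 100; t_n <- 40
  # sub-threshold per-cell jitter: a sinusoid never exceeds mean + 2 SD
  set.seed(8)
  phase <- runif(n_cells, 0, 2 * pi)
  dff <- 1e-3 * sin(outer(phase, 2 * pi * (1:t_n) / 13, `+`))
  counts <- c(10, 30, 8, 25, 12)
  for (k in seq_along(counts)) dff[seq_len(counts[k]), 20 + k] <- 10
  ev <- detect_cell_events(dff, cbind(runif(n_cells, 0, 100), runif(n_cells, 0, 100)))
  expect_equal(nrow(ev$events), 2)
  expect_equal(ev$events$start_frame, c(21, 24))
  expect_equal(ev$events$end_frame, c(23, 25))
  # z-scored event frames have mean 0, SD 1 across cells
  expect_lt(max(abs(rowMeans(ev$zscored_matrix))), 1e-12)
  expect_equal(apply(ev$zscored_matrix, 1, sd), rep(1, 2), tolerance = 1e-12)
  # a quiet recording yields no events
  quiet <- 1e-3 * sin(outer(runif(10, 0, 2 * pi), 2 * pi * (1:20) / 7, `+`))
  expect_equal(nrow(detect_cell_events(quiet, cbind(1:10, 1:10))$events), 0)
})

test_that("planted co-activation of 40% of cells forms one event", {
  n_cells <- 50; t_n <- 60
  set.seed(9)
  dff <- 0.01 * sin(outer(runif(n_cells, 0, 2 * pi), 2 * pi * (1:t_n) / 11, `+`))
  dff[1:20, 30:34] <- dff[1:20, 30:34] + 5
  ev <- detect_cell_events(dff, cbind(runif(n_cells), runif(n_cells)))
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$start_frame, 30)
  expect_equal(ev$events$end_frame, 34)
})

test_that("pairwise correlations are symmetric with unit diagonal", {
  n_ev <- 30
  set.seed(12)
  v <- rnorm(n_ev)
  z <- cbind(a = v, b = v, c = -v, d = rnorm(n_ev))
  evset <- structure(list(events = data.frame(start_frame = 1:n_ev,
                                              end_frame = 1:n_ev,
                                              event_frame = 1:n_ev),
                          event_frame_matrix = z, zscored_matrix = z,
                          positions_um = cbind(c(0, 50, 120, 400), c(0, 0, 0, 0))),
                     class = "cell_event_set")
  pc <- pairwise_correlations(evset)
  expect_equal(pc$r[1, 2], 1)
  expect_equal(pc$r[1, 3], -1)
  expect_equal(pc$r, t(pc$r))
  expect_equal(unname(diag(pc$r)), rep(1, 4))
  expect_true(all(abs(pc$r) <= 1 + 1e-12))
  expect_equal(pc$dist_um[1, 2], 50)
})

test_that("within-cell shuffling preserves marginals and is seeded", {
  p <- small_params(n_events = 20, n_cells = 25, event_rate_hz = 0.2,
                    cell_region_mm = 0.6)
  tr <- synth_event_truth(p)
  cr <- synth_cell_recording(p, tr)
  dffc <- cell_dff(neuropil_correct(cr$recording), p$frame_rate_hz)
  ev <- detect_cell_events(dffc, cr$recording$positions_um)
  sh1 <- cell_shuffle_null(ev, n_shuffles = 10, seed = 3, band_um = c(30, 200))
  sh2 <- cell_shuffle_null(ev, n_shuffles = 10, seed = 3, band_um = c(30, 200))
  expect_identical(sh1$null_stats, sh2$null_stats)
  expect_equal(sh1$p_reported, max(sh1$p, 0.1))
  # the shuffle permutes within cells: each column's multiset is intact
  z <- ev$zscored_matrix
  zs <- modcortex:::with_seed(1, apply(z, 2, function(v) v[sample.int(nrow(z))]))
  for (j in seq_len(ncol(z))) expect_setequal(zs[, j], z[, j])
})

test_that("distance bins and LCI summarize the correlation structure", {
  # hand-built correlation matrix: 4 cells on a line
  r <- matrix(c(1, 0.5, 0.5, -0.5,
                0.5, 1, 0.5, -0.5,
                0.5, 0.5, 1, 0.005,
                -0.5, -0.5, 0.005, 1), 4, 4)
  pos <- cbind(c(0, 50, 80, 500), c(0, 0, 0, 0))
  pc <- structure(list(r = r, dist_um = as.matrix(dist(pos)), n_events = 10,
                       undefined_cells = integer(0)),
                  class = "pair_corr_matrix")
  prof <- correlation_by_distance(pc, bin_edges_um = c(30, 100, 300, 600))
  expect_equal(prof$mean_r[1], 0.5)       # pairs 1-2, 1-3, 2-3
  expect_equal(prof$n_pairs[1], 3)
  expect_equal(prof$n_pairs[2], 0)        # nothing between 100 and 300 um
  expect_equal(prof$mean_r[3], mean(c(-0.5, -0.5, 0.005)))
  # single-pair bins have undefined SEM, flagged as NA
  prof1 <- correlation_by_distance(pc, bin_edges_um = c(430, 460))
  expect_equal(prof1$mean_r[1], -0.5)
  expect_true(is.na(prof1$sem_r[1]))
  # co-located cells below the first edge: empty profile with a warning
  pc0 <- structure(list(r = r, dist_um = matrix(0, 4, 4), n_events = 10,
                        undefined_cells = integer(0)),
                   class = "pair_corr_matrix")
  expect_warning(p0 <- correlation_by_distance(pc0), "no cell pairs")
  expect_true(all(p0$n_pairs == 0))
  # LCI: uniform positive correlations give 1 nearby; in the far ring every
  # seed with countable neighbors sees only negative ones (the 0.005 link
  # is excluded), so the FOV mean is -1 with one excluded pair
  lci <- local_coherence_index(pc, annulus_edges_um = c(30, 100, 600))
  expect_equal(lci$lci[1], 1)
  expect_equal(lci$lci[2], -1, tolerance = 1e-12)
  expect_equal(lci$n_excluded_pairs[2], 1)
  # balanced +/- counts cancel
  rb <- matrix(0.5, 5, 5); rb[1, 4:5] <- -0.5; rb[4:5, 1] <- -0.5
  rb[2, 4:5] <- -0.5; rb[4:5, 2] <- -0.5; rb[3, 4:5] <- -0.5; rb[4:5, 3] <- -0.5
  diag(rb) <- 1
  posb <- cbind(seq(0, 200, by = 50), rep(0, 5))
  pcb <- structure(list(r = rb, dist_um = as.matrix(dist(posb)), n_events = 10,
                        undefined_cells = integer(0)),
                   class = "pair_corr_matrix")
  # each seed sees mixed signs; the FOV mean lies strictly between -1 and 1
  lcib <- local_coherence_index(pcb, annulus_edges_um = c(30, 250))
  expect_lt(abs(lcib$lci[1]), 1)
  # zero-crossing interpolation
  profz <- data.frame(lo = c(0, 100, 200), hi = c(100, 200, 300),
                      lci = c(1, 0.5, -0.5))
  expect_equal(profile_zero_crossing(profz), 200)
})
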