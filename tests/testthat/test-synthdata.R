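test_that("parameter validation rejects inconsistent settings", {
  expect_error(synth_params(pixel_um = 200, wavelength_mm = 0.5), "coarse")
  expect_error(synth_params(n_basis = 10, n_events = 5), "exceed")
  expect_error(synth_params(event_rate_hz = 2), "overlap")
  expect_error(synth_params(indicator_rise_s = 1, indicator_decay_s = 0.5),
               "smaller")
})

test_that("generators are bit-identical under the same seed", {
  p <- small_params()
  b1 <- make_modular_basis(p)
  b2 <- make_modular_basis(p)
  expect_identical(b1, b2)
  e1 <- synth_event_patterns(b1, p)
  e2 <- synth_event_patterns(b2, p)
  expect_identical(e1$patterns, e2$patterns)
  m1 <- synth_widefield_movie(p)
  m2 <- synth_widefield_movie(p)
  expect_identical(m1$movie$data, m2$movie$data)
  expect_identical(m1$truth$event_times, m2$truth$event_times)
})

test_that("basis fields are standardized, orthogonal and band-limited", {
  p <- synth_params(n_basis = 4, n_events = 4, seed = 3)
  basis <- make_modular_basis(p)
  mask <- !is.na(basis[[1]])
  V <- vapply(basis, function(f) f[mask], numeric(sum(mask)))
  expect_lt(max(abs(colMeans(V))), 1e-10)
  expect_equal(sqrt(colMeans(V^2)), rep(1, 4), tolerance = 1e-10)
  G <- crossprod(V) / nrow(V)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-10)
  # radially averaged power spectrum peaks within one frequency bin of
  # 1/wavelength (averaged over several independent fields)
  h <- nrow(mask); w <- ncol(mask)
  pixel_mm <- p$pixel_um / 1000
  fy <- modcortex:::fft_freq(h) / pixel_mm
  fx <- modcortex:::fft_freq(w) / pixel_mm
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  df <- 1 / (h * pixel_mm)
  bins <- round(fr / df)
  pw <- numeric(max(bins) + 1)
  for (s in 1:8) {
    ps <- synth_params(n_basis = 1, n_events = 1, seed = 100 + s)
    f <- make_modular_basis(ps)[[1]]
    f[is.na(f)] <- 0
    P2 <- Mod(stats::fft(f))^2
    pw <- pw + as.numeric(tapply(as.numeric(P2), as.numeric(bins), mean))
  }
  pk_freq <- (which.max(pw) - 1) * df
  expect_lt(abs(pk_freq - 1 / p$wavelength_mm), df + 1e-9)
})

test_that("event patterns are rectified mixtures with recorded ground truth", {
  p <- small_params(pattern_noise_sd = 0, pattern_offset_sd = 0)
  basis <- make_modular_basis(p)
  # identity mixing with zero noise and no pedestal reproduces the
  # rectified basis
  coef <- diag(2)[rep(1:2, 2), ]
  ep <- synth_event_patterns(basis, p, coefficients = coef)
  for (i in 1:4) {
    expected <- pmax(basis[[which(coef[i, ] == 1)]], 0)
    expect_equal(ep$patterns[, , i], expected, tolerance = 1e-12)
  }
  # pre-rectification mixtures have rank exactly n_basis when noiseless
  p8 <- synth_params(n_basis = 3, n_events = 12, pattern_noise_sd = 0, seed = 5)
  ep8 <- synth_event_patterns(make_modular_basis(p8), p8)
  sv <- svd(ep8$truth$premix)$d
  expect_equal(sum(sv > 1e-8 * sv[1]), 3)
  # empty ensembles are allowed
  p0 <- small_params(n_events = 0)
  ep0 <- synth_event_patterns(basis, p0)
  expect_equal(dim(ep0$patterns)[3], 0)
})

test_that("a quiet noise-free movie is exactly zero after dF/F", {
  p <- small_params(n_events = 0, pixel_noise_sd = 0, baseline_drift = 0)
  sm <- synth_widefield_movie(p)
  expect_true(all(sm$movie$data == 100))
  dff <- compute_dff(sm$movie, baseline_window_s = 10)
  expect_equal(max(abs(dff$data)), 0)
})

test_that("movie planting matches the ground truth at event peaks", {
  p <- small_params(pixel_noise_sd = 0, baseline_drift = 0)
  sm <- synth_widefield_movie(p)
  i <- 2
  t_peak <- sm$truth$event_times[i]
  frame_dff <- sm$movie$data[, , t_peak] / 100 - 1
  kern_peak <- max(sm$truth$kernel)
  expect_equal(frame_dff,
               p$event_amplitude_dff * kern_peak * sm$truth$event_shapes[, , i],
               tolerance = 1e-12)
  # ROI-mean temporal autocorrelation is 1 at lag zero
  dffm <- compute_dff(sm$movie, baseline_window_s = 10)
  tac <- temporal_autocorrelation(dffm, max_lag_s = 2)
  expect_equal(tac$r[1], 1)
})

test_that("cell recordings sample the field with controllable corruptions", {
  p <- small_params(n_events = 6, n_cells = 12, cell_noise_sd = 0,
                    neuropil_weight = 0, cell_region_mm = 0.6)
  tr <- synth_event_truth(p)
  cr <- synth_cell_recording(p, tr)
  # noiseless, neuropil-free raw trace reconstructs from the truth
  kern <- tr$kernel
  c1 <- 3
  expected <- rep(0, ncol(cr$recording$f_raw))
  for (i in seq_along(tr$event_onsets)) {
    idx <- tr$event_onsets[i] + seq_along(kern) - 1L
    expected[idx] <- expected[idx] +
      p$event_amplitude_dff * cr$truth$cell_field_values[i, c1] * kern
  }
  expect_equal(cr$recording$f_raw[c1, ], 100 * (1 + expected), tolerance = 1e-10)
  # salt-and-pepper permutes positions but leaves traces untouched
  crs <- synth_cell_recording(p, tr, salt_and_pepper = TRUE)
  expect_identical(crs$recording$f_raw, cr$recording$f_raw)
  expect_false(identical(crs$recording$positions_um, cr$recording$positions_um))
  expect_setequal(crs$recording$positions_um[, 1], cr$recording$positions_um[, 1])
})
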