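test_that("active pixels require threshold crossing and contiguous area", {
  h <- 40; w <- 40; px <- 19
  mask <- matrix(TRUE, h, w)
  mu <- matrix(0, h, w); sd <- matrix(1, h, w)
  # frame exactly at the pixel mean: nothing active
  expect_equal(sum(find_active_pixels(mu, mu, sd, mask, px)), 0)
  # 0.12 mm square patch (~7 px at 19 um) at mean + 5 SD: area 0.0144 mm2
  fr <- matrix(0, h, w)
  side <- round(120 / px)
  fr[10:(9 + side), 10:(9 + side)] <- 5
  act <- find_active_pixels(fr, mu, sd, mask, px)
  expect_equal(sum(act), side^2)
  # a single supra-threshold pixel (3.6e-4 mm2) is noise
  fr2 <- matrix(0, h, w); fr2[5, 5] <- 10
  expect_equal(sum(find_active_pixels(fr2, mu, sd, mask, px)), 0)
  # zero-SD pixels warn and stay inactive
  sd0 <- sd; sd0[1, 1] <- 0
  fr3 <- fr; fr3[1, 1] <- 100
  expect_warning(a3 <- find_active_pixels(fr3, mu, sd0, mask, px), "zero-SD")
  expect_false(a3[1, 1])
})

test_that("runs of active frames become events and split at local minima", {
  # bimodal run: ROI means 1,3,2,1.5,4,2 -> split after the interior
  # minimum at run frame 4; the minimum frame ends the earlier event
  frac <- c(0, rep(0.9, 6), 0)
  rmean <- c(0, 1, 3, 2, 1.5, 4, 2, 0)
  ev <- modcortex:::events_from_fractions(frac, rmean, 0.4)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start_frame, c(2, 6))
  expect_equal(ev$end_frame, c(5, 7))
  expect_equal(ev$event_frame, c(3, 6))
  # all-quiescent trace: no events
  ev0 <- modcortex:::events_from_fractions(rep(0.1, 10), rnorm(10), 0.4)
  expect_equal(nrow(ev0), 0)
  # raising the threshold never increases the event count
  set.seed(2)
  frac2 <- pmax(0, sin(seq(0, 12 * pi, length.out = 400))) +
    runif(400, 0, 0.2)
  rmean2 <- frac2 + rnorm(400, sd = 0.01)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9),
                   function(a) nrow(modcortex:::events_from_fractions(frac2, rmean2, a)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detector recovers planted events on a small synthetic movie", {
  p <- small_params(n_events = 4, event_rate_hz = 0.05, seed = 13)
  sm <- synth_widefield_movie(p)
  dff <- compute_dff(sm$movie, baseline_window_s = 10)
  es <- detect_events(dff)
  expect_equal(nrow(es$events), 4)
  expect_true(all(abs(es$events$event_frame - sm$truth$event_times) <= 1))
  # every event frame has the maximal ROI mean within its span
  for (i in seq_len(nrow(es$events))) {
    span <- es$events$start_frame[i]:es$events$end_frame[i]
    expect_equal(es$roi_mean[es$events$event_frame[i]], max(es$roi_mean[span]))
  }
})

test_that("control frames come from the bottom decile outside events", {
  set.seed(6)
  t_n <- 1100
  arr <- array(rnorm(4 * 4 * t_n, mean = 1, sd = 0.01), dim = c(4, 4, t_n))
  dff <- as_dff(arr)
  # plant 12 events of 5 frames each at known spans
  starts <- seq(50, 1050, length.out = 12)
  evd <- data.frame(start_frame = round(starts), end_frame = round(starts) + 4,
                    event_frame = round(starts) + 2)
  es <- structure(list(events = evd, roi_mean = modcortex:::roi_mean_trace(dff)),
                  class = "event_set")
  ctrl <- select_control_frames(dff, es, n_sets = 100, seed = 5)
  n_non_event <- t_n - 12 * 5
  expect_equal(length(ctrl$pool), floor(n_non_event * 0.1))
  expect_equal(lengths(ctrl$sets), rep(12L, 100))
  in_event <- unlist(Map(seq, evd$start_frame, evd$end_frame))
  expect_length(intersect(unlist(ctrl$sets), in_event), 0)
  # pool really is the lowest-activity tail
  expect_true(max(es$roi_mean[ctrl$pool]) <=
                min(es$roi_mean[setdiff(setdiff(1:t_n, in_event), ctrl$pool)]))
  # determinism and the zero-event edge case
  ctrl2 <- select_control_frames(dff, es, n_sets = 100, seed = 5)
  expect_identical(ctrl$sets, ctrl2$sets)
  es0 <- structure(list(events = evd[0, ], roi_mean = es$roi_mean),
                   class = "event_set")
  ctrl0 <- select_control_frames(dff, es0, n_sets = 10, seed = 5)
  expect_true(all(lengths(ctrl0$sets) == 0))
})

test_that("temporal autocorrelation behaves like a Pearson lag profile", {
  t_n <- 10000
  fr <- 15
  # white noise: negligible autocorrelation at all nonzero lags
  set.seed(21)
  v <- rnorm(t_n)
  arr <- array(rep(v, each = 4), dim = c(2, 2, t_n))
  tac <- temporal_autocorrelation(as_dff(arr, frame_rate_hz = fr), max_lag_s = 2)
  expect_equal(tac$r[1], 1)
  expect_lt(max(abs(tac$r[-1])), 0.05)
  # a sine of period P is perfectly correlated at lag P
  P_s <- 2
  v2 <- sin(2 * pi * (1:t_n) / (P_s * fr))
  arr2 <- array(rep(v2, each = 4), dim = c(2, 2, t_n))
  tac2 <- temporal_autocorrelation(as_dff(arr2, frame_rate_hz = fr), max_lag_s = 3)
  expect_gt(tac2$r[tac2$lag_s == P_s], 0.999)
  # constant trace: undefined
  arr3 <- array(1, dim = c(2, 2, 200))
  expect_error(temporal_autocorrelation(as_dff(arr3, frame_rate_hz = fr)),
               "constant")
})
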