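# Spontaneous-event detection in dF/F movies, control frames, and
# temporal autocorrelation.

#' Active pixels of one dF/F frame
#'
#' A pixel is active if its value exceeds its temporal mean by more than
#' `threshold_sd` SDs AND it belongs to an 8-connected active component
#' of area at least `min_region_mm2` (isolated supra-threshold specks are
#' treated as noise).
#'
#' @param dff_frame H x W dF/F values
#' @param pixel_mean,pixel_sd H x W per-pixel temporal mean and SD
#'   (computed over all frames within the ROI)
#' @param mask H x W logical ROI
#' @param pixel_um grid pitch, um
#' @param min_region_mm2 minimum contiguous active area, mm^2
#' @param threshold_sd threshold in per-pixel SDs above the mean
#' @return H x W logical matrix of active pixels
#' @export
find_active_pixels <- function(dff_frame, pixel_mean, pixel_sd, mask, pixel_um,
                               min_region_mm2 = 0.01, threshold_sd = 3) {
  zero_sd <- mask & pixel_sd <= 0
  if (any(zero_sd)) warning(sum(zero_sd), " zero-SD pixel(s) treated as never active")
  act <- mask & pixel_sd > 0 & dff_frame > pixel_mean + threshold_sd * pixel_sd
  if (!any(act)) return(act)
  min_px <- min_region_mm2 * 1e6 / pixel_um^2
  lab <- EBImage::bwlabel(act * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  act & matrix(lab %in% keep, nrow(act), ncol(act))
}

# Per-frame fraction of active ROI pixels for a whole movie. Frames whose
# raw supra-threshold fraction cannot reach `active_fraction` even before
# the region-size filter are skipped (the filter only removes pixels).
active_fraction_trace <- function(dff, min_region_mm2 = 0.01, threshold_sd = 3,
                                  active_fraction_floor = 0) {
  d <- dim(dff$data)
  h <- d[1]; w <- d[2]; t_n <- d[3]
  roi <- which(dff$roi_mask)
  n_roi <- length(roi)
  # pass 1: per-pixel temporal mean/SD and the ROI-mean trace, one frame
  # at a time (avoids copying the whole movie)
  s1 <- numeric(n_roi); s2 <- numeric(n_roi)
  roi_mean <- numeric(t_n)
  for (t in seq_len(t_n)) {
    v <- dff$data[, , t][roi]
    s1 <- s1 + v
    s2 <- s2 + v * v
    roi_mean[t] <- mean(v)
    # long movies shed per-frame temporaries before the heap balloons
    if (t %% 2000L == 0L) gc(FALSE)
  }
  mu <- s1 / t_n
  sd <- sqrt(pmax(s2 / t_n - mu^2, 0))
  thr <- mu + threshold_sd * sd
  # pass 2: raw supra-threshold fraction; region-filtered fraction only
  # where it could exceed the floor (the size filter only removes pixels)
  mu_m <- matrix(0, h, w); mu_m[roi] <- mu
  sd_m <- matrix(0, h, w); sd_m[roi] <- sd
  frac <- numeric(t_n)
  raw_frac <- numeric(t_n)
  for (t in seq_len(t_n)) {
    fr_m <- dff$data[, , t]
    raw_frac[t] <- sum(fr_m[roi] > thr) / n_roi
    if (raw_frac[t] > active_fraction_floor) {
      ap <- suppressWarnings(
        find_active_pixels(fr_m, mu_m, sd_m, dff$roi_mask,
                           dff$pixel_um, min_region_mm2, threshold_sd))
      frac[t] <- sum(ap) / n_roi
    }
    if (t %% 2000L == 0L) gc(FALSE)
  }
  list(fraction = frac, raw_fraction = raw_frac, roi_mean = roi_mean,
       pixel_mean = mu_m, pixel_sd = sd_m)
}

# Turn a per-frame active-fraction trace into events: maximal runs of
# consecutive active frames, split at interior strict local minima of the
# ROI-mean trace (the minimum frame ends the earlier event).
events_from_fractions <- function(fraction, roi_mean, active_fraction = 0.40) {
  active <- fraction > active_fraction
  t_n <- length(active)
  events <- list()
  t <- 1L
  while (t <= t_n) {
    if (!active[t]) { t <- t + 1L; next }
    s <- t
    while (t < t_n && active[t + 1L]) t <- t + 1L
    e <- t
    seg <- roi_mean[s:e]
    cuts <- if (e - s >= 2) local_minima(seg) else integer(0)
    bounds <- c(s - 1L, s - 1L + cuts, e)
    for (b in seq_len(length(bounds) - 1L)) {
      es <- bounds[b] + 1L
      ee <- bounds[b + 1L]
      ef <- es + which.max(roi_mean[es:ee]) - 1L
      events[[length(events) + 1L]] <-
        data.frame(start_frame = es, end_frame = ee, event_frame = ef,
                   mean_activity = roi_mean[ef],
                   at_boundary = es == 1L || ee == t_n)
    }
    t <- t + 1L
  }
  if (length(events) == 0)
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      event_frame = integer(0), mean_activity = numeric(0),
                      at_boundary = logical(0)))
  do.call(rbind, events)
}

#' Detect spontaneous events in a dF/F movie
#'
#' Frames where more than `active_fraction` of ROI pixels are active (see
#' [find_active_pixels()]) are "active frames"; maximal runs of
#' consecutive active frames become events, except that a run containing
#' an interior local minimum of the ROI-mean dF/F trace is split there
#' (the minimum frame ends the earlier event). Each event's "event frame"
#' is its frame of maximal ROI-mean dF/F.
#'
#' @param dff a [dff_movie()]
#' @param active_fraction fraction of active ROI pixels that makes a
#'   frame active (default 0.40, strict inequality)
#' @param min_region_mm2,threshold_sd see [find_active_pixels()]
#' @return an object of class `event_set`: list with `events`
#'   (data.frame: start_frame, end_frame, event_frame, mean_activity,
#'   at_boundary), `peak_patterns` (H x W x n array of event frames),
#'   `active_fraction_trace`, `roi_mean`, calibration fields, and the
#'   detection parameters
#' @export
detect_events <- function(dff, active_fraction = 0.40, min_region_mm2 = 0.01,
                          threshold_sd = 3) {
  stopif(dim(dff$data)[3] < 2, "need at least 2 frames")
  af <- active_fraction_trace(dff, min_region_mm2, threshold_sd,
                              active_fraction_floor = active_fraction)
  rm_trace <- af$roi_mean
  ev <- events_from_fractions(af$fraction, rm_trace, active_fraction)
  n <- nrow(ev)
  d <- dim(dff$data)
  pk <- array(NA_real_, dim = c(d[1], d[2], n))
  for (i in seq_len(n)) pk[, , i] <- dff$data[, , ev$event_frame[i]]
  structure(list(events = ev, peak_patterns = pk,
                 active_fraction_trace = af$fraction, roi_mean = rm_trace,
                 pixel_um = dff$pixel_um, frame_rate_hz = dff$frame_rate_hz,
                 roi_mask = dff$roi_mask,
                 params = list(active_fraction = active_fraction,
                               min_region_mm2 = min_region_mm2,
                               threshold_sd = threshold_sd)),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d events over %d frames (threshold %g SD, >%g%% active)\n",
              nrow(x$events), length(x$roi_mean),
              x$params$threshold_sd, 100 * x$params$active_fraction))
  invisible(x)
}

#' Build an event set from known event frames
#'
#' Constructs an `event_set` directly from a vector of (peak) frame
#' indices — e.g. the planted event times of a synthetic movie — instead
#' of running the detector. Useful for validating downstream stages
#' independently of detection.
#'
#' @param dff a [dff_movie()]
#' @param event_frames frame indices of event peaks
#' @param halfwidth_frames span recorded around each peak (default 1)
#' @return an `event_set`
#' @export
event_set_from_frames <- function(dff, event_frames, halfwidth_frames = 1L) {
  t_n <- dim(dff$data)[3]
  stopif(any(event_frames < 1 | event_frames > t_n), "event frame out of range")
  rm_trace <- roi_mean_trace(dff)
  ev <- data.frame(start_frame = pmax(1L, event_frames - halfwidth_frames),
                   end_frame = pmin(t_n, event_frames + halfwidth_frames),
                   event_frame = as.integer(event_frames),
                   mean_activity = rm_trace[event_frames],
                   at_boundary = FALSE)
  d <- dim(dff$data)
  pk <- array(NA_real_, dim = c(d[1], d[2], nrow(ev)))
  for (i in seq_len(nrow(ev))) pk[, , i] <- dff$data[, , ev$event_frame[i]]
  structure(list(events = ev, peak_patterns = pk,
                 active_fraction_trace = NULL, roi_mean = rm_trace,
                 pixel_um = dff$pixel_um, frame_rate_hz = dff$frame_rate_hz,
                 roi_mask = dff$roi_mask,
                 params = list(source = "ground_truth")),
            class = "event_set")
}

#' Select event-matched sets of low-activity control frames
#'
#' The candidate pool is the bottom decile of non-event frames ranked by
#' ROI-mean dF/F; each control set is an event-count-matched sample drawn
#' without replacement from the pool (with replacement, with a warning,
#' if the pool is smaller than the event count).
#'
#' @param dff a [dff_movie()]
#' @param events an `event_set`
#' @param n_sets number of control sets (default 100)
#' @param seed RNG seed
#' @param pool_fraction fraction of non-event frames forming the pool
#' @return an object of class `control_frame_sets`: list with `sets`
#'   (list of frame-index vectors), `pool`, `seed`
#' @export
select_control_frames <- function(dff, events, n_sets = 100, seed = 1L,
                                  pool_fraction = 0.10) {
  t_n <- dim(dff$data)[3]
  in_event <- rep(FALSE, t_n)
  for (i in seq_len(nrow(events$events)))
    in_event[events$events$start_frame[i]:events$events$end_frame[i]] <- TRUE
  non_event <- which(!in_event)
  n_ev <- nrow(events$events)
  stopif(length(non_event) < max(1, n_ev), "not enough non-event frames")
  rm_trace <- events$roi_mean %||% roi_mean_trace(dff)
  pool_n <- max(1L, floor(length(non_event) * pool_fraction))
  pool <- non_event[order(rm_trace[non_event])][seq_len(pool_n)]
  replace <- pool_n < n_ev
  if (replace) warning("control pool smaller than event count; sampling with replacement")
  sets <- with_seed(derive_seed(seed, "controls"), {
    lapply(seq_len(n_sets), function(s) {
      if (n_ev == 0) integer(0) else sort(sample(pool, n_ev, replace = replace))
    })
  })
  structure(list(sets = sets, pool = pool, n_sets = n_sets, seed = seed),
            class = "control_frame_sets")
}

#' Temporal autocorrelation of the ROI-mean dF/F trace
#'
#' Pearson autocorrelation at integer-frame lags up to `max_lag_s`
#' seconds, computed over all frames (event and non-event).
#'
#' @param dff a [dff_movie()]
#' @param max_lag_s maximum lag, seconds (default 10)
#' @param per_pixel if TRUE, average per-pixel autocorrelations over the
#'   ROI instead of correlating the ROI-mean trace
#' @return data.frame with `lag_s` and `r`
#' @export
temporal_autocorrelation <- function(dff, max_lag_s = 10, per_pixel = FALSE) {
  fr <- dff$frame_rate_hz
  max_lag <- floor(max_lag_s * fr)
  t_n <- dim(dff$data)[3]
  stopif(t_n <= max_lag + 1, "record shorter than the maximum lag")
  lag_r <- function(v) {
    stopif(stats::sd(v) == 0, "autocorrelation undefined for a constant trace")
    vapply(0:max_lag, function(k) {
      if (k == 0) 1 else stats::cor(v[seq_len(t_n - k)], v[seq_len(t_n - k) + k])
    }, numeric(1))
  }
  r <- if (per_pixel) {
    d <- dim(dff$data)
    x <- dff$data
    dim(x) <- c(d[1] * d[2], t_n)
    roi <- which(dff$roi_mask)
    roi <- roi[apply(x[roi, , drop = FALSE], 1, stats::sd) > 0]
    rowMeans(vapply(roi, function(p) lag_r(x[p, ]), numeric(max_lag + 1)))
  } else {
    lag_r(roi_mean_trace(dff))
  }
  data.frame(lag_s = (0:max_lag) / fr, r = r)
}
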