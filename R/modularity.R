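# Modular-structure quantification: radial autocorrelation, wavelength,
# modularity with a control-frame null, and module amplitude.

#' Radially averaged spatial autocorrelation
#'
#' Mask-corrected 2-D spatial autocorrelation of a pattern (correlation
#' sum divided by the overlap pair count at each lag, normalized to 1 at
#' zero lag), averaged over one-pixel-wide annuli.
#'
#' @param pattern H x W field (typically band-pass filtered)
#' @param mask H x W logical ROI
#' @param pixel_um grid pitch, um
#' @param max_r_mm maximum radius (default: largest fully sampled radius)
#' @return an object of class `radial_autocorr`: data.frame with `r_mm`,
#'   `value`, `n_pixels`
#' @export
spatial_autocorr_radial <- function(pattern, mask, pixel_um, max_r_mm = NULL) {
  ac <- masked_autocorr2d(pattern, mask)
  max_r_px <- if (is.null(max_r_mm)) NULL else floor(max_r_mm * 1000 / pixel_um)
  out <- radial_average(ac$acf, ac$center, pixel_um, max_r_px)
  class(out) <- c("radial_autocorr", "data.frame")
  out
}

# First interior local minimum of a radial profile; returns NULL if none.
first_minimum <- function(rad) {
  mins <- local_minima(rad$value)
  if (length(mins) == 0) return(NULL)
  mins[1]
}

#' Wavelength from the radial autocorrelation
#'
#' The pattern wavelength is twice the distance from the origin to the
#' first local minimum of the radially averaged autocorrelation; the
#' minimum's position is refined by a parabolic fit through the three
#' bins around it.
#'
#' @param rad a [spatial_autocorr_radial()] result
#' @return list with `wavelength_mm` (NA if no minimum), `r_min_mm`,
#'   `value_min`, `flag` ("ok" or "no_minimum")
#' @export
estimate_wavelength <- function(rad) {
  i <- first_minimum(rad)
  if (is.null(i))
    return(list(wavelength_mm = NA_real_, r_min_mm = NA_real_,
                value_min = NA_real_, flag = "no_minimum"))
  v <- parabolic_refine(rad$r_mm, rad$value, i)
  list(wavelength_mm = 2 * v[1], r_min_mm = v[1], value_min = v[2], flag = "ok")
}

#' Modularity from the radial autocorrelation
#'
#' Modularity is the absolute difference in amplitude between the first
#' local minimum of the radial autocorrelation and the subsequent
#' maximum. A regular, periodically spaced pattern has a deep first
#' minimum followed by a clear rebound; an irregular pattern's profile
#' decays without structure. The subsequent maximum is taken as the
#' global maximum of the profile beyond the first minimum — for a damped
#' oscillatory profile this is the first rebound peak, and it is immune
#' to the one-bin ripples that radial averaging over sparse annuli
#' produces. If the profile ends at the minimum the event is flagged.
#'
#' @param rad a [spatial_autocorr_radial()] result
#' @return list with `modularity` (NA if undefined), `wavelength_mm`,
#'   `flag`
#' @export
estimate_modularity <- function(rad) {
  wl <- estimate_wavelength(rad)
  if (wl$flag != "ok")
    return(list(modularity = NA_real_, wavelength_mm = NA_real_, flag = wl$flag))
  i <- first_minimum(rad)
  n <- nrow(rad)
  if (i >= n)
    return(list(modularity = NA_real_, wavelength_mm = wl$wavelength_mm,
                flag = "no_maximum"))
  tail_idx <- (i + 1):n
  j <- tail_idx[which.max(rad$value[tail_idx])]
  interior_max <- j > 1 && j < n &&
    rad$value[j] > rad$value[j - 1] && rad$value[j] > rad$value[j + 1]
  vmax <- if (interior_max) parabolic_refine(rad$r_mm, rad$value, j)[2]
          else rad$value[j]
  list(modularity = abs(vmax - wl$value_min),
       wavelength_mm = wl$wavelength_mm, flag = "ok")
}

#' Wavelength and modularity for every pattern of an ensemble
#'
#' @param pe a [pattern_ensemble()] (band-pass filtered patterns)
#' @param max_r_mm radius limit for the radial profile
#' @return data.frame with one row per pattern: `wavelength_mm`,
#'   `modularity`, `flag`
#' @export
pattern_modularity <- function(pe, max_r_mm = NULL) {
  res <- lapply(seq_len(pe$n), function(i) {
    p <- pe$patterns[, , i]
    if (stats::sd(p[pe$mask], na.rm = TRUE) == 0)
      return(data.frame(wavelength_mm = NA_real_, modularity = NA_real_,
                        flag = "constant"))
    rad <- spatial_autocorr_radial(p, pe$mask, pe$pixel_um, max_r_mm)
    m <- estimate_modularity(rad)
    data.frame(wavelength_mm = m$wavelength_mm, modularity = m$modularity,
               flag = m$flag)
  })
  out <- do.call(rbind, res)
  out$event <- seq_len(pe$n)
  out
}

#' Modularity significance against low-activity control frames
#'
#' Compares the median modularity across events with the distribution of
#' median modularities over event-count-matched sets of low-activity
#' control frames. The p-value is the fraction of control-set medians
#' greater than or equal to the real median. Control frames (rather than
#' white noise) form the null because band-pass filtering imprints a
#' spatial scale on any input, including noise; only the recording's own
#' quiet frames share the full measurement pipeline.
#'
#' @param event_modularity numeric vector of per-event modularity values
#'   (NAs excluded)
#' @param pool_modularity modularity of each control-pool frame, named or
#'   indexed by frame
#' @param control_sets a [select_control_frames()] result (its `sets`
#'   index into the pool frames)
#' @return list with `p`, `real_median`, `control_medians`
#' @export
modularity_significance <- function(event_modularity, pool_modularity, control_sets) {
  real <- stats::median(event_modularity, na.rm = TRUE)
  stopif(!is.finite(real), "no defined event modularity values")
  lut <- pool_modularity
  stopif(is.null(names(lut)), "`pool_modularity` must be named by frame index")
  meds <- vapply(control_sets$sets, function(s) {
    stats::median(lut[as.character(s)], na.rm = TRUE)
  }, numeric(1))
  stopif(all(!is.finite(meds)), "control modularities are all undefined")
  list(p = mean(meds >= real, na.rm = TRUE), real_median = real,
       control_medians = meds)
}

#' Module amplitude of an unfiltered event pattern
#'
#' The module amplitude of an event is the mean, over detected activity
#' peaks, of the raw dF/F at the peak divided by the median raw dF/F on
#' the one-pixel-wide annulus at radius wavelength/2 around it (the
#' inter-module background). Peaks are local maxima of a lightly
#' smoothed copy (Gaussian SD = wavelength/8) that exceed the smoothed
#' frame's median by `peak_thresh_mad` MADs (default 1; broad event frames have a large
#' frame-wide MAD, so stricter thresholds can reject every module peak).
#'
#' @param pattern_raw H x W unfiltered dF/F event frame
#' @param mask H x W logical ROI
#' @param pixel_um grid pitch, um
#' @param wavelength_mm the FOV's mean event wavelength, mm
#' @param peak_thresh_mad peak threshold in MADs above the median (default 1)
#' @return list with `amplitude` (NA and flag if no peaks), `peaks`
#'   (data.frame row, col, value, background), `flag`
#' @export
module_amplitude <- function(pattern_raw, mask, pixel_um, wavelength_mm,
                             peak_thresh_mad = 1) {
  stopif(!is.finite(wavelength_mm) || wavelength_mm <= 0,
         "wavelength must be defined and positive")
  sm_sd <- wavelength_mm * 1000 / 8 / pixel_um
  sm <- gaussian_lowpass_masked(pattern_raw, mask, sm_sd)
  med <- stats::median(sm[mask])
  mad <- stats::mad(sm[mask])
  thr <- med + peak_thresh_mad * mad
  pk <- local_maxima_2d(sm, mask)
  if (nrow(pk) > 0) pk <- pk[sm[pk] > thr, , drop = FALSE]
  if (nrow(pk) == 0)
    return(list(amplitude = NA_real_, peaks = NULL, flag = "no_peaks"))
  ring_px <- wavelength_mm * 1000 / 2 / pixel_um
  h <- nrow(pattern_raw); w <- ncol(pattern_raw)
  amps <- numeric(0)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  out_pk <- data.frame(row = integer(0), col = integer(0), value = numeric(0),
                       background = numeric(0))
  for (k in seq_len(nrow(pk))) {
    d_px <- sqrt((rows - pk[k, 1])^2 + (cols - pk[k, 2])^2)
    ring <- abs(d_px - ring_px) <= 0.5 & mask
    if (!any(ring)) next
    bg <- stats::median(pattern_raw[ring], na.rm = TRUE)
    if (!is.finite(bg) || bg <= 0) next
    val <- pattern_raw[pk[k, 1], pk[k, 2]]
    amps <- c(amps, val / bg)
    out_pk <- rbind(out_pk, data.frame(row = pk[k, 1], col = pk[k, 2],
                                       value = val, background = bg))
  }
  if (length(amps) == 0)
    return(list(amplitude = NA_real_, peaks = NULL, flag = "no_background"))
  list(amplitude = mean(amps), peaks = out_pk, flag = "ok")
}
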