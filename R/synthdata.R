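#' Parameters for the synthetic modular-activity generator
#'
#' Bundles and validates every knob of the synthetic data generator. The
#' generator emulates the statistical structure of spontaneous activity in
#' developing cortex: spatially band-limited modular patterns (annular, or
#' "ring", spatial power spectrum), an event ensemble spanned by a small
#' number of basis patterns, calcium-indicator time courses on a slowly
#' drifting baseline, and cellular traces sampled from the same underlying
#' field.
#'
#' @param fov_mm field of view in mm; length 1 (square) or 2 (width,
#'   height). Default 3.0 x 2.53125 mm, which at `pixel_um = 18.75` gives
#'   the 160 x 135 analysis grid used throughout.
#' @param pixel_um pixel pitch in micrometers.
#' @param wavelength_mm target Fourier wavelength of the modular field
#'   (peak of the annular spectrum), mm.
#' @param spectral_bandwidth relative width of the annular spectrum
#'   (SD of the Gaussian radial profile divided by the peak frequency).
#' @param n_basis number of basis patterns spanning the event ensemble.
#' @param n_events number of events.
#' @param frame_rate_hz sampling rate of the movie, Hz.
#' @param event_rate_hz mean event occurrence rate, Hz. Events are laid
#'   out quasi-periodically at spacing `1/event_rate_hz` with small jitter.
#' @param indicator_rise_s,indicator_decay_s calcium kernel time
#'   constants (difference of exponentials), seconds.
#' @param pattern_noise_sd per-event unstructured (fresh ring-spectrum)
#'   noise SD, relative to the SD of the event's mixed pattern.
#' @param pattern_offset_sd pre-rectification offset of each event
#'   pattern, in units of the event's mixture SD (default 1). Real
#'   dF/F events ride on a broad depolarization pedestal (their
#'   peak-to-background ratio is finite), and the offset models it;
#'   numerically it keeps rectification a mild nonlinearity (~16% of
#'   pixels clipped instead of half), so the ensemble's cross-validated
#'   dimensionality tracks `n_basis`. Set to 0 for pure rectified
#'   mixtures.
#' @param pixel_noise_sd per-pixel, per-frame sensor noise SD in dF/F
#'   units.
#' @param event_amplitude_dff peak dF/F of a planted event.
#' @param baseline_drift relative amplitude of the slow multiplicative
#'   baseline drift (0 disables it).
#' @param shape_offset_sd,shape_compress parameters of the display
#'   transform that turns a zero-mean modular pattern into a nonnegative
#'   dF/F event shape: the mixed pattern (in SD units) is shifted by
#'   `shape_offset_sd`, rectified, peak-normalized and raised to the power
#'   `shape_compress`. The offset and compression give events a broad
#'   active pedestal modulated by the modules, as in real dF/F frames.
#' @param n_cells number of cells for cellular recordings.
#' @param cell_region_mm side of the square (centered in the FOV) within
#'   which cell somata are placed, mm.
#' @param cell_noise_sd per-cell trace noise SD, relative to
#'   `event_amplitude_dff`.
#' @param neuropil_weight fraction of the local neuropil signal mixed
#'   into the raw cell trace.
#' @param neuropil_radius_um radius of the window used for the local
#'   neuropil average, micrometers.
#' @param seed integer RNG seed; identical seeds give bit-identical data.
#' @return an object of class `synth_params` (a validated list).
#' @export
synth_params <- function(fov_mm = c(3.0, 2.53125),
                         pixel_um = 18.75,
                         wavelength_mm = 0.9,
                         spectral_bandwidth = 0.1,
                         n_basis = 8,
                         n_events = 100,
                         frame_rate_hz = 15,
                         event_rate_hz = 1 / 30,
                         indicator_rise_s = 0.1,
                         indicator_decay_s = 0.5,
                         pattern_noise_sd = 0.1,
                         pattern_offset_sd = 1.0,
                         pixel_noise_sd = 0.05,
                         event_amplitude_dff = 0.5,
                         baseline_drift = 0.05,
                         shape_offset_sd = 1.0,
                         shape_compress = 0.4,
                         n_cells = 80,
                         cell_region_mm = 1.0,
                         cell_noise_sd = 0.1,
                         neuropil_weight = 0.3,
                         neuropil_radius_um = 20,
                         seed = 1L) {
  if (length(fov_mm) == 1) fov_mm <- c(fov_mm, fov_mm)
  for (nm in c("fov_mm", "pixel_um", "wavelength_mm", "spectral_bandwidth",
               "frame_rate_hz", "event_rate_hz", "indicator_rise_s",
               "indicator_decay_s", "event_amplitude_dff", "cell_region_mm",
               "neuropil_radius_um"))
    check_positive(get(nm), nm)
  for (nm in c("pattern_noise_sd", "pattern_offset_sd", "pixel_noise_sd",
               "baseline_drift", "cell_noise_sd", "neuropil_weight"))
    stopif(get(nm) < 0, paste0("`", nm, "` must be nonnegative"))
  stopif(n_basis < 1 || n_events < 0, "`n_basis` >= 1 and `n_events` >= 0 required")
  stopif(n_events > 0 && n_basis > n_events, "`n_basis` must not exceed `n_events`")
  stopif(pixel_um > 1000 * wavelength_mm / 4,
         "grid too coarse: need at least 4 pixels per wavelength")
  stopif(indicator_rise_s >= indicator_decay_s,
         "`indicator_rise_s` must be smaller than `indicator_decay_s`")
  span_s <- indicator_rise_s + 5 * indicator_decay_s
  stopif(n_events > 0 && 1 / event_rate_hz < span_s,
         "`event_rate_hz` too high: events would overlap the indicator kernel")
  num <- as.numeric
  p <- list(fov_mm = num(fov_mm), pixel_um = num(pixel_um),
            wavelength_mm = num(wavelength_mm),
            spectral_bandwidth = num(spectral_bandwidth),
            n_basis = as.integer(n_basis), n_events = as.integer(n_events),
            frame_rate_hz = num(frame_rate_hz), event_rate_hz = num(event_rate_hz),
            indicator_rise_s = num(indicator_rise_s),
            indicator_decay_s = num(indicator_decay_s),
            pattern_noise_sd = num(pattern_noise_sd),
            pattern_offset_sd = num(pattern_offset_sd),
            pixel_noise_sd = num(pixel_noise_sd),
            event_amplitude_dff = num(event_amplitude_dff),
            baseline_drift = num(baseline_drift),
            shape_offset_sd = num(shape_offset_sd),
            shape_compress = num(shape_compress),
            n_cells = as.integer(n_cells), cell_region_mm = num(cell_region_mm),
            cell_noise_sd = num(cell_noise_sd),
            neuropil_weight = num(neuropil_weight),
            neuropil_radius_um = num(neuropil_radius_um), seed = as.integer(seed))
  p$grid_w <- as.integer(round(p$fov_mm[1] * 1000 / pixel_um))
  p$grid_h <- as.integer(round(p$fov_mm[2] * 1000 / pixel_um))
  stopif(p$grid_w < 8 || p$grid_h < 8, "grid too small")
  class(p) <- "synth_params"
  p
}

# One Gaussian random field with an annular ("ring") power spectrum
# centered at 1/wavelength_mm, standardized to zero mean and unit SD on
# the mask. Consumes RNG state.
grf_ring <- function(h, w, pixel_um, wavelength_mm, bandwidth, mask) {
  noise <- matrix(stats::rnorm(h * w), h, w)
  pixel_mm <- pixel_um / 1000
  fy <- fft_freq(h) / pixel_mm   # cycles per mm
  fx <- fft_freq(w) / pixel_mm
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  f0 <- 1 / wavelength_mm
  amp <- exp(-(fr - f0)^2 / (2 * (bandwidth * f0)^2))
  amp[1, 1] <- 0
  x <- ifft2_re(fft2(noise) * amp)
  mu <- mean(x[mask])
  sd0 <- sqrt(mean((x[mask] - mu)^2))
  x <- (x - mu) / sd0
  x[!mask] <- NA_real_
  x
}

#' Generate modular basis patterns
#'
#' Draws `n_basis` Gaussian random fields whose power spectrum is an
#' annulus centered at spatial frequency `1/wavelength_mm` with relative
#' width `spectral_bandwidth`. Each field is zero-mean, unit-SD on the ROI.
#' The annular spectrum makes the expected radial autocorrelation a Bessel
#' function `J0(2 pi r / wavelength)`, which gives the wavelength
#' estimator an analytic target.
#'
#' @param params a [synth_params()] object
#' @param orthogonalize if TRUE (default), Gram-Schmidt orthogonalize the
#'   fields on the ROI (they remain zero-mean, unit-SD, and band-limited).
#' @param mask optional H x W logical ROI (default: full grid)
#' @return list of H x W basis fields (NA outside the ROI)
#' @export
make_modular_basis <- function(params, orthogonalize = TRUE, mask = NULL) {
  h <- params$grid_h; w <- params$grid_w
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  with_seed(derive_seed(params$seed, "basis"), {
    fields <- lapply(seq_len(params$n_basis), function(i)
      grf_ring(h, w, params$pixel_um, params$wavelength_mm,
               params$spectral_bandwidth, mask))
    if (orthogonalize && params$n_basis > 1) {
      pix <- which(mask)
      V <- vapply(fields, function(f) f[pix], numeric(length(pix)))
      for (j in seq_len(ncol(V))) {
        for (k in seq_len(j - 1)) {
          V[, j] <- V[, j] - sum(V[, k] * V[, j]) / sum(V[, k]^2) * V[, k]
        }
      }
      # re-standardize to unit SD (orthogonality is preserved)
      for (j in seq_len(ncol(V))) {
        V[, j] <- (V[, j] - mean(V[, j])) / sqrt(mean((V[, j] - mean(V[, j]))^2))
      }
      fields <- lapply(seq_len(ncol(V)), function(j) {
        f <- matrix(NA_real_, h, w); f[pix] <- V[, j]; f
      })
    }
    fields
  })
}

# Nonnegative "display" shape of a mixed pattern: shift by offset (in SD
# units), rectify, peak-normalize, compress. Gives events a broad active
# pedestal with modular structure on top, as in real dF/F event frames.
event_shape <- function(mix, offset_sd, compress, mask) {
  v <- mix
  s <- sqrt(mean(v[mask]^2, na.rm = TRUE))
  u <- pmax(v / s + offset_sd, 0)
  mx <- max(u[mask], na.rm = TRUE)
  out <- (u / mx)^compress
  out[!mask] <- NA_real_
  out
}

#' Generate an event-pattern ensemble with ground truth
#'
#' Each raw pattern is the nonnegative rectification of an offset random
#' mixture of the basis fields plus fresh ring-spectrum noise:
#' `A_i = max(sum_j c_ij B_j + mu_i + sigma_i eps_i, 0)`, with
#' half-normal mixing coefficients `c_ij ~ |N(0,1)|`, pedestal
#' `mu_i = pattern_offset_sd` times the mixture SD, and
#' `sigma_i = pattern_noise_sd` times the mixture SD. Nonnegative
#' weights model events as graded activations of the basis patterns,
#' and the pedestal models the broad depolarization real events ride
#' on; together they keep rectification benign (for a single basis the
#' pattern is exactly `c_i` times a fixed field), so the ensemble's
#' effective dimensionality tracks `n_basis`. The coefficients are
#' recorded in the ground truth; `premix` stores the mixtures plus
#' noise without the pedestal.
#'
#' @param basis list of basis fields from [make_modular_basis()]
#' @param params a [synth_params()] object
#' @param coefficients optional n_events x n_basis mixing matrix; by
#'   default coefficients are drawn i.i.d. half-normal |N(0,1)|
#' @return list with `patterns` (H x W x n_events array, NA outside the
#'   ROI), `mask`, and `truth` (basis patterns, mixing coefficients,
#'   per-event noise SDs, and the pre-rectification mixtures `premix`,
#'   one column per event over ROI pixels)
#' @export
synth_event_patterns <- function(basis, params, coefficients = NULL) {
  stopif(length(basis) == 0, "`basis` must be nonempty")
  h <- nrow(basis[[1]]); w <- ncol(basis[[1]])
  mask <- !is.na(basis[[1]])
  n <- params$n_events
  if (n == 0) {
    return(list(patterns = array(numeric(0), dim = c(h, w, 0)), mask = mask,
                truth = list(basis_patterns = basis,
                             event_coefficients = matrix(numeric(0), 0, length(basis)))))
  }
  pix <- which(mask)
  B <- vapply(basis, function(f) f[pix], numeric(length(pix)))
  with_seed(derive_seed(params$seed, "patterns"), {
    coef <- coefficients %||% matrix(abs(stats::rnorm(n * length(basis))), n, length(basis))
    stopif(nrow(coef) != n || ncol(coef) != length(basis),
           "`coefficients` must be n_events x n_basis")
    patterns <- array(NA_real_, dim = c(h, w, n))
    premix <- matrix(NA_real_, length(pix), n)
    noise_sd <- numeric(n)
    for (i in seq_len(n)) {
      mix <- as.numeric(B %*% coef[i, ])
      s_mix <- sqrt(mean(mix^2))
      noise_sd[i] <- params$pattern_noise_sd * s_mix
      if (noise_sd[i] > 0) {
        eps <- grf_ring(h, w, params$pixel_um, params$wavelength_mm,
                        params$spectral_bandwidth, mask)
        mix <- mix + noise_sd[i] * eps[pix]
      }
      premix[, i] <- mix
      f <- matrix(NA_real_, h, w)
      f[pix] <- pmax(mix + params$pattern_offset_sd * s_mix, 0)
      patterns[, , i] <- f
    }
    list(patterns = patterns, mask = mask,
         truth = list(basis_patterns = basis, event_coefficients = coef,
                      noise_sd = noise_sd, premix = premix, premix_pix = pix))
  })
}

# Difference-of-exponentials calcium kernel sampled at the frame rate,
# peak-normalized. Support is truncated where the kernel falls below 1%
# of its peak.
calcium_kernel <- function(rise_s, decay_s, frame_rate_hz) {
  t_end <- decay_s * log(200) + rise_s
  tt <- seq(0, t_end, by = 1 / frame_rate_hz)
  k <- exp(-tt / decay_s) - exp(-tt / rise_s)
  k <- k / max(k)
  k[seq_len(max(which(k > 0.01)))]
}

#' Ground truth for a planted-event study (no movie assembly)
#'
#' Generates basis patterns, event patterns, planted dF/F shapes, event
#' timing and the calcium kernel — everything [synth_widefield_movie()]
#' plants — without materializing the movie. Useful when only event
#' patterns or cellular traces are needed.
#'
#' @param params a [synth_params()] object
#' @return a ground-truth list: basis patterns, mixing coefficients,
#'   rectified `patterns`, planted `event_shapes`, `event_onsets`,
#'   `event_times` (kernel-peak frames), `kernel`, `t_total`, `mask`
#' @export
synth_event_truth <- function(params) {
  h <- params$grid_h; w <- params$grid_w
  mask <- matrix(TRUE, h, w)
  basis <- make_modular_basis(params, mask = mask)
  ep <- synth_event_patterns(basis, params)
  n <- params$n_events
  fr <- params$frame_rate_hz
  tau <- 1 / params$event_rate_hz
  kern <- calcium_kernel(params$indicator_rise_s, params$indicator_decay_s, fr)
  k_peak <- which.max(kern) - 1L
  if (n > 0) {
    jit <- with_seed(derive_seed(params$seed, "timing"),
                     stats::runif(n, -tau / 8, tau / 8))
    onset_s <- tau / 2 + (seq_len(n) - 1) * tau + jit
    onset_f <- as.integer(round(onset_s * fr)) + 1L
    t_total <- as.integer(ceiling((max(onset_s) + tau / 2) * fr))
  } else {
    onset_f <- integer(0)
    t_total <- as.integer(ceiling(20 * fr))
  }
  shapes <- array(NA_real_, dim = c(h, w, n))
  pix <- which(mask)
  for (i in seq_len(n)) {
    mix <- matrix(0, h, w)
    mix[pix] <- ep$truth$premix[, i]
    shapes[, , i] <- event_shape(mix, params$shape_offset_sd,
                                 params$shape_compress, mask)
  }
  truth <- ep$truth
  truth$patterns <- ep$patterns
  truth$event_onsets <- onset_f
  truth$event_times <- onset_f + k_peak
  truth$event_shapes <- shapes
  truth$kernel <- kern
  truth$t_total <- t_total
  truth$mask <- mask
  truth
}

#' Synthesize a widefield movie with planted events
#'
#' Builds a raw-fluorescence movie: a slowly drifting multiplicative
#' baseline, planted modular event patterns convolved with a
#' rise/decay calcium kernel, and per-pixel sensor noise. Event patterns
#' come from [synth_event_patterns()]; each is converted to a nonnegative
#' dF/F shape with peak `event_amplitude_dff` (see [synth_params()]).
#' Events are placed at spacing `1/event_rate_hz` with small jitter, so
#' quiet inter-event frames always exist.
#'
#' @param params a [synth_params()] object
#' @return list with `movie` (a [wf_movie()]) and `truth`; the truth
#'   records onset frames, peak frames (`event_times`), mixing
#'   coefficients, and the planted dF/F shapes.
#' @export
synth_widefield_movie <- function(params) {
  truth <- synth_event_truth(params)
  h <- params$grid_h; w <- params$grid_w
  n <- params$n_events
  fr <- params$frame_rate_hz
  kern <- truth$kernel
  onset_f <- truth$event_onsets
  t_total <- truth$t_total
  mask <- truth$mask

  with_seed(derive_seed(params$seed, "movie"), {
    P <- h * w
    drift <- if (params$baseline_drift > 0)
      1 + params$baseline_drift * sin(2 * pi * seq_len(t_total) / (fr * 300))
    else rep(1, t_total)
    f0 <- 100
    # assemble the raw movie in frame chunks to bound peak memory
    raw <- array(0, dim = c(h, w, t_total))
    dim(raw) <- c(P, t_total)
    klen <- length(kern)
    chunk <- max(1L, min(t_total, as.integer(2e7 / P)))
    for (c0 in seq(1L, t_total, by = chunk)) {
      c1 <- min(t_total, c0 + chunk - 1L)
      len <- c1 - c0 + 1L
      block <- matrix(0, P, len)
      for (i in seq_len(n)) {
        lo <- max(onset_f[i], c0)
        hi <- min(onset_f[i] + klen - 1L, c1)
        if (lo > hi) next
        block[, (lo:hi) - c0 + 1L] <- block[, (lo:hi) - c0 + 1L] +
          params$event_amplitude_dff *
          outer(as.numeric(truth$event_shapes[, , i]), kern[(lo:hi) - onset_f[i] + 1L])
      }
      if (params$pixel_noise_sd > 0)
        block <- block + stats::rnorm(P * len, sd = params$pixel_noise_sd)
      block <- f0 * (1 + block) * rep(drift[c0:c1], each = P)
      raw[, c0:c1] <- block
      rm(block)
      gc(FALSE)
    }
    dim(raw) <- c(h, w, t_total)
    movie <- wf_movie(raw, pixel_um = params$pixel_um, frame_rate_hz = fr,
                      roi_mask = mask, meta = list(source = "synthetic"))
    list(movie = movie, truth = truth)
  })
}

#' Synthesize a cellular recording sampled from the modular field
#'
#' Cell somata are placed uniformly in a square region at the center of
#' the field of view. Each cell's noiseless dF/F trace is the event time
#' course weighted by the field's event shape at the cell position
#' (bilinear interpolation); the raw trace adds `neuropil_weight` times
#' the local neuropil signal (field averaged over a disk of radius
#' `neuropil_radius_um`) and white cell noise. Traces are returned as raw
#' fluorescence on a baseline of 100.
#'
#' With `salt_and_pepper = TRUE` the cell positions are randomly permuted
#' among cells (traces untouched), destroying the spatial arrangement
#' while preserving every trace: the control for locally coherent
#' organization.
#'
#' @param params a [synth_params()] object
#' @param truth ground truth from [synth_widefield_movie()] (or a
#'   compatible list with `event_shapes`, `event_onsets`, `kernel`)
#' @param salt_and_pepper permute cell positions?
#' @return list with `recording` (a [cell_recording()]) and `truth`
#'   (positions and noiseless per-event field values at each cell)
#' @export
synth_cell_recording <- function(params, truth, salt_and_pepper = FALSE) {
  h <- dim(truth$event_shapes)[1]; w <- dim(truth$event_shapes)[2]
  n <- dim(truth$event_shapes)[3]
  px <- params$pixel_um
  side_um <- params$cell_region_mm * 1000
  cx0 <- (w - 1) * px / 2; cy0 <- (h - 1) * px / 2
  stopif(side_um > (w - 3) * px || side_um > (h - 3) * px,
         "cell region larger than the field of view")
  kern <- truth$kernel
  onset <- truth$event_onsets
  t_total <- max(onset) + length(kern) + as.integer(params$frame_rate_hz)

  with_seed(derive_seed(params$seed, "cells"), {
    nc <- params$n_cells
    pos <- cbind(x_um = stats::runif(nc, cx0 - side_um / 2, cx0 + side_um / 2),
                 y_um = stats::runif(nc, cy0 - side_um / 2, cy0 + side_um / 2))
    # bilinear field sample of every event shape at each cell
    sample_at <- function(xy) {
      c0 <- xy[, 1] / px + 1; r0 <- xy[, 2] / px + 1
      ri <- floor(r0); ci <- floor(c0)
      frr <- r0 - ri; fcc <- c0 - ci
      vapply(seq_len(n), function(i) {
        m <- truth$event_shapes[, , i]
        m[cbind(ri, ci)] * (1 - frr) * (1 - fcc) + m[cbind(ri + 1, ci)] * frr * (1 - fcc) +
          m[cbind(ri, ci + 1)] * (1 - frr) * fcc + m[cbind(ri + 1, ci + 1)] * frr * fcc
      }, numeric(nc))   # cells x events
    }
    cell_vals <- sample_at(pos)
    # neuropil: disk average around each cell
    rad <- params$neuropil_radius_um
    offs <- expand.grid(dx = seq(-rad, rad, by = px / 2), dy = seq(-rad, rad, by = px / 2))
    offs <- offs[offs$dx^2 + offs$dy^2 <= rad^2, ]
    np_vals <- matrix(0, nc, n)
    for (k in seq_len(nrow(offs))) {
      shifted <- cbind(pmin(pmax(pos[, 1] + offs$dx[k], 0), (w - 2) * px),
                       pmin(pmax(pos[, 2] + offs$dy[k], 0), (h - 2) * px))
      np_vals <- np_vals + sample_at(shifted)
    }
    np_vals <- np_vals / nrow(offs)

    amp <- params$event_amplitude_dff
    dff_cell <- matrix(0, nc, t_total)
    dff_np <- matrix(0, nc, t_total)
    for (i in seq_len(n)) {
      idx <- onset[i] + seq_along(kern) - 1L
      dff_cell[, idx] <- dff_cell[, idx] + amp * outer(cell_vals[, i], kern)
      dff_np[, idx] <- dff_np[, idx] + amp * outer(np_vals[, i], kern)
    }
    raw_dff <- dff_cell + params$neuropil_weight * dff_np
    if (params$cell_noise_sd > 0)
      raw_dff <- raw_dff + matrix(stats::rnorm(nc * t_total, sd = params$cell_noise_sd * amp),
                                  nc, t_total)
    f0 <- 100
    f_raw <- f0 * (1 + raw_dff)
    f_np <- f0 * (1 + dff_np)
    if (salt_and_pepper) {
      pos <- pos[sample(nc), , drop = FALSE]
    }
    rec <- cell_recording(f_raw = f_raw, f_neuropil = f_np, positions_um = pos,
                          frame_rate_hz = params$frame_rate_hz)
    list(recording = rec,
         truth = list(cell_positions = pos, cell_field_values = t(cell_vals),
                      event_onsets = onset, salt_and_pepper = salt_and_pepper))
  })
}
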