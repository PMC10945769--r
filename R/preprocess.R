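# Movie calibration: rigid registration, running-median baseline, dF/F,
# ROI application.

#' Rigid registration by phase correlation
#'
#' Translates every frame by the integer-pixel shift that maximizes phase
#' correlation with a reference frame. Subpixel refinement is deliberately
#' omitted: downstream statistics are computed on a ~19 um grid and are
#' insensitive to sub-pixel error.
#'
#' @param movie a [wf_movie()]
#' @param reference_frame_index frame used as the common reference
#' @return list with `movie` (registered) and `shifts` (T x 2 matrix of
#'   applied (dy, dx) shifts)
#' @export
register_translation <- function(movie, reference_frame_index = 1L) {
  d <- dim(movie$data)
  h <- d[1]; w <- d[2]; t_n <- d[3]
  stopif(reference_frame_index < 1 || reference_frame_index > t_n,
         "invalid reference frame index")
  if (t_n == 1) return(list(movie = movie, shifts = matrix(0, 1, 2)))
  ref <- movie$data[, , reference_frame_index]
  Fr <- Conj(fft2(ref))
  shifts <- matrix(0L, t_n, 2)
  out <- movie$data
  for (t in seq_len(t_n)) {
    fr <- movie$data[, , t]
    if (all(fr == 0)) {
      warning("all-zero frame ", t, ": shift set to zero")
      next
    }
    X <- fft2(fr) * Fr
    mag <- Mod(X)
    mag[mag < 1e-12] <- 1
    pc <- ifft2_re(X / mag)
    pk <- which.max(pc)
    dy <- (pk - 1L) %% h
    dx <- (pk - 1L) %/% h
    if (dy > h / 2) dy <- dy - h
    if (dx > w / 2) dx <- dx - w
    # frame is displaced by (dy, dx) relative to the reference; shift back
    shifts[t, ] <- c(-dy, -dx)
    if (dy != 0 || dx != 0) {
      shifted <- matrix(NA_real_, h, w)
      src_r <- seq_len(h) + dy
      src_c <- seq_len(w) + dx
      ok_r <- src_r >= 1 & src_r <= h
      ok_c <- src_c >= 1 & src_c <= w
      shifted[ok_r, ok_c] <- fr[src_r[ok_r], src_c[ok_c]]
      # fill uncovered border with the frame median to stay finite
      shifted[is.na(shifted)] <- stats::median(fr)
      out[, , t] <- shifted
    }
  }
  list(movie = wf_movie(out, movie$pixel_um, movie$frame_rate_hz, movie$roi_mask,
                        c(movie$meta, list(registered = TRUE))),
       shifts = shifts)
}

# Running temporal median with reflect padding at both ends; window in
# frames (forced odd).
running_median <- function(v, k) {
  k <- as.integer(k)
  if (k %% 2 == 0) k <- k + 1L
  n <- length(v)
  if (k >= 2 * n) k <- 2 * (n %/% 2) - 1L
  half <- k %/% 2
  vp <- c(v[(half + 1):2], v, v[(n - 1):(n - half)])
  stats::runmed(vp, k)[(half + 1):(half + n)]
}

#' Compute dF/F with a running-median baseline
#'
#' The per-pixel baseline F0 is a running temporal median (reflect-padded
#' at the ends) with a window of `baseline_window_s` seconds; the output
#' is `(F - F0) / F0`.
#'
#' @param movie a [wf_movie()]
#' @param baseline_window_s median window in seconds (default 15;
#'   sessions in this preparation are typically fit well by 10-23 s)
#' @param keep_baseline store the full F0 array? (set FALSE for large
#'   movies; the baseline is then dropped after use)
#' @return a [dff_movie()]
#' @export
compute_dff <- function(movie, baseline_window_s = 15, keep_baseline = TRUE) {
  k <- as.integer(round(baseline_window_s * movie$frame_rate_hz))
  stopif(k < 3, "baseline window must span at least 3 frames")
  d <- dim(movie$data)
  h <- d[1]; w <- d[2]; t_n <- d[3]
  dff <- array(NA_real_, dim = d)
  base <- if (keep_baseline) array(NA_real_, dim = d) else NULL
  bad <- character(0)
  # process one pixel row at a time to bound peak memory on long movies
  for (r in seq_len(h)) {
    cols <- which(movie$roi_mask[r, ])
    if (length(cols) == 0) next
    slab <- movie$data[r, , , drop = TRUE]   # W x T
    out <- matrix(NA_real_, w, t_n)
    bout <- if (keep_baseline) matrix(NA_real_, w, t_n) else NULL
    for (cc in cols) {
      f0 <- running_median(slab[cc, ], k)
      if (any(f0 <= 0)) { bad <- c(bad, paste0(r, ",", cc)); next }
      out[cc, ] <- (slab[cc, ] - f0) / f0
      if (keep_baseline) bout[cc, ] <- f0
    }
    dff[r, , ] <- out
    if (keep_baseline) base[r, , ] <- bout
    if (r %% 32L == 0L) gc(FALSE)
  }
  if (length(bad) > 0) {
    stop("baseline F0 <= 0 at ROI pixel(s): ",
         paste(utils::head(bad, 5), collapse = "; "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  dff_movie(dff, base, movie$pixel_um, movie$frame_rate_hz, movie$roi_mask,
            c(movie$meta, list(baseline_window_s = baseline_window_s)))
}

#' Intersect the ROI with additional exclusion masks
#'
#' Masked-out pixels are invalid for all downstream statistics.
#'
#' @param dff a [dff_movie()]
#' @param extra_masks list of H x W logical matrices (TRUE = keep)
#' @return the [dff_movie()] with the intersected ROI
#' @export
apply_roi <- function(dff, extra_masks) {
  if (is.matrix(extra_masks)) extra_masks <- list(extra_masks)
  m <- dff$roi_mask
  for (em in extra_masks) {
    stopif(!all(dim(em) == dim(m)), "extra mask shape does not match the ROI")
    m <- m & em
  }
  stopif(sum(m) == 0, "mask intersection is empty")
  dff$roi_mask <- m
  removed <- !m
  dff$data[which(rep(removed, dim(dff$data)[3]))] <- NA_real_
  dff
}

# ROI-mean dF/F trace of a movie (vector of length T). Per-frame loop to
# avoid copying the whole movie.
roi_mean_trace <- function(dff) {
  t_n <- dim(dff$data)[3]
  roi <- which(dff$roi_mask)
  out <- numeric(t_n)
  for (t in seq_len(t_n)) {
    out[t] <- mean(dff$data[, , t][roi])
    if (t %% 2000L == 0L) gc(FALSE)
  }
  out
}
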