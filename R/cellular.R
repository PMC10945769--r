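# Cellular-resolution pipeline: neuropil correction, dF/F, event
# detection, pairwise correlations with a shuffle null, distance-binned
# correlation, and the local coherence index (LCI).

#' Neuropil-corrected cell traces
#'
#' `F_cell = F_raw - alpha * F_neuropil`, elementwise.
#'
#' @param rec a [cell_recording()]
#' @param alpha neuropil weight (default: the recording's `alpha`, 0.4)
#' @return cells x T matrix of corrected traces
#' @export
neuropil_correct <- function(rec, alpha = NULL) {
  a <- alpha %||% rec$alpha
  rec$f_raw - a * rec$f_neuropil
}

#' Cellular dF/F with median-filter baseline and smoothing
#'
#' Per-cell baseline F0 is a running temporal median over
#' `baseline_window_s` seconds (reflect-padded); dF/F = (F - F0)/F0 is
#' then median-smoothed over `smooth_frames` frames.
#'
#' @param traces cells x T corrected fluorescence
#' @param frame_rate_hz frame rate, Hz
#' @param baseline_window_s baseline median window, seconds (default 60)
#' @param smooth_frames width of the temporal median smoother (default 7)
#' @return cells x T dF/F matrix
#' @export
cell_dff <- function(traces, frame_rate_hz, baseline_window_s = 60,
                     smooth_frames = 7) {
  t_n <- ncol(traces)
  k <- as.integer(round(baseline_window_s * frame_rate_hz))
  stopif(t_n <= k / 2, "trace shorter than the baseline window")
  out <- matrix(0, nrow(traces), t_n)
  bad <- integer(0)
  for (i in seq_len(nrow(traces))) {
    f0 <- running_median(traces[i, ], k)
    if (any(f0 <= 0)) { bad <- c(bad, i); next }
    v <- (traces[i, ] - f0) / f0
    if (smooth_frames > 1) v <- running_median(v, smooth_frames)
    out[i, ] <- v
  }
  stopif(length(bad) > 0,
         paste("baseline F0 <= 0 for cell(s):",
               paste(utils::head(bad, 10), collapse = ", ")))
  out
}

#' Detect cellular spontaneous events
#'
#' A cell is active on a frame when its dF/F exceeds its temporal mean by
#' `cell_thresh_sd` SDs. Frames with strictly more than `frame_fraction`
#' of cells active are event frames; consecutive runs are merged into
#' events and split at interior local minima of the active-cell count.
#' Each event's frame is the frame with the highest mean dF/F across all
#' cells; the per-event cell activity is z-scored across cells within
#' each event frame.
#'
#' @param dff cells x T dF/F matrix
#' @param positions_um cells x 2 centroid matrix
#' @param cell_thresh_sd per-cell activity threshold, SDs (default 2)
#' @param frame_fraction fraction of active cells defining an event
#'   frame (default 0.05, strict inequality)
#' @return an object of class `cell_event_set`: list with `events`
#'   (data.frame start/end/event_frame), `event_frame_matrix`
#'   (events x cells dF/F), `zscored_matrix`, `positions_um`
#' @export
detect_cell_events <- function(dff, positions_um, cell_thresh_sd = 2,
                               frame_fraction = 0.05) {
  stopif(nrow(dff) < 2 || ncol(dff) < 2, "need at least 2 cells and 2 frames")
  mu <- rowMeans(dff)
  sd <- apply(dff, 1, stats::sd)
  if (any(sd == 0)) warning(sum(sd == 0), " zero-SD cell(s) treated as never active")
  act <- dff > mu + cell_thresh_sd * sd & sd > 0
  n_active <- colSums(act)
  frac <- n_active / nrow(dff)
  mean_sig <- colMeans(dff)
  active_frame <- frac > frame_fraction
  t_n <- ncol(dff)
  events <- list()
  t <- 1L
  while (t <= t_n) {
    if (!active_frame[t]) { t <- t + 1L; next }
    s <- t
    while (t < t_n && active_frame[t + 1L]) t <- t + 1L
    e <- t
    cuts <- if (e - s >= 2) local_minima(n_active[s:e]) else integer(0)
    bounds <- c(s - 1L, s - 1L + cuts, e)
    for (b in seq_len(length(bounds) - 1L)) {
      es <- bounds[b] + 1L
      ee <- bounds[b + 1L]
      ef <- es + which.max(mean_sig[es:ee]) - 1L
      events[[length(events) + 1L]] <-
        data.frame(start_frame = es, end_frame = ee, event_frame = ef)
    }
    t <- t + 1L
  }
  ev <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(start_frame = integer(0), end_frame = integer(0),
               event_frame = integer(0))
  m <- t(dff[, ev$event_frame, drop = FALSE])   # events x cells
  z <- t(apply(m, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(NA_real_, length(v)) else (v - mean(v)) / s
  }))
  if (nrow(ev) == 0) z <- m
  structure(list(events = ev, event_frame_matrix = m, zscored_matrix = z,
                 positions_um = positions_um,
                 params = list(cell_thresh_sd = cell_thresh_sd,
                               frame_fraction = frame_fraction)),
            class = "cell_event_set")
}

#' @export
print.cell_event_set <- function(x, ...) {
  cat(sprintf("<cell_event_set> %d events x %d cells\n",
              nrow(x$events), ncol(x$event_frame_matrix)))
  invisible(x)
}

#' Pairwise cell-cell correlations across event frames
#'
#' Pearson correlation between every pair of cells' z-scored event-frame
#' vectors, with the pairwise inter-cell distances.
#'
#' @param evset a [detect_cell_events()] result
#' @return an object of class `pair_corr_matrix`: list with `r`
#'   (cells x cells), `dist_um`, `n_events`, `undefined_cells` (constant
#'   across events)
#' @export
pairwise_correlations <- function(evset) {
  stopif(nrow(evset$events) < 2, "need at least 2 events")
  z <- evset$zscored_matrix
  sds <- apply(z, 2, stats::sd)
  undef <- which(!is.finite(sds) | sds == 0)
  r <- suppressWarnings(stats::cor(z))
  r[undef, ] <- NA_real_
  r[, undef] <- NA_real_
  diag(r) <- 1
  pos <- evset$positions_um
  dist_um <- as.matrix(stats::dist(pos))
  structure(list(r = r, dist_um = dist_um, n_events = nrow(evset$events),
                 undefined_cells = undef),
            class = "pair_corr_matrix")
}

# Upper-triangle pair table of a pair_corr_matrix.
pair_table <- function(pc) {
  n <- nrow(pc$r)
  ut <- upper.tri(pc$r)
  data.frame(r = pc$r[ut], dist_um = pc$dist_um[ut])
}

#' Shuffle null for cellular correlations
#'
#' Permutes each cell's event-frame values independently across events
#' (destroying inter-cell co-activation while preserving every cell's
#' marginal distribution exactly), recomputes the statistic — the median
#' pairwise correlation among nearby cells — and reports the fraction of
#' shuffles with a statistic greater than or equal to the real one.
#'
#' @param evset a [detect_cell_events()] result
#' @param n_shuffles number of shuffles (default 100)
#' @param seed RNG seed
#' @param band_um distance band defining "nearby" pairs (default 30-100)
#' @return list with `p` (raw counting fraction), `p_reported` (floored
#'   at 1/n_shuffles), `real_stat`, `null_stats`
#' @export
cell_shuffle_null <- function(evset, n_shuffles = 100, seed = 1L,
                              band_um = c(30, 100)) {
  pc <- pairwise_correlations(evset)
  pt <- pair_table(pc)
  sel <- pt$dist_um >= band_um[1] & pt$dist_um <= band_um[2]
  stopif(!any(sel), "no cell pairs in the distance band")
  real <- stats::median(pt$r[sel], na.rm = TRUE)
  z <- evset$zscored_matrix
  n_ev <- nrow(z)
  dist_um <- pc$dist_um
  ut <- upper.tri(dist_um)
  sel_m <- dist_um >= band_um[1] & dist_um <= band_um[2] & ut
  null_stats <- with_seed(derive_seed(seed, "cellshuffle"), {
    vapply(seq_len(n_shuffles), function(s) {
      zs <- apply(z, 2, function(v) v[sample.int(n_ev)])
      rs <- suppressWarnings(stats::cor(zs))
      stats::median(rs[sel_m], na.rm = TRUE)
    }, numeric(1))
  })
  p <- mean(null_stats >= real)
  list(p = p, p_reported = max(p, 1 / n_shuffles), real_stat = real,
       null_stats = null_stats)
}

#' Distance-binned pairwise correlations
#'
#' Mean and SEM of pairwise correlations binned by inter-cell distance.
#' Pairs closer than the first bin edge are excluded.
#'
#' @param pc a [pairwise_correlations()] result
#' @param bin_edges_um ascending bin edges, um (default 30 to 630 in
#'   50-um steps)
#' @return data.frame: bin_lo_um, bin_hi_um, mean_r, sem_r, n_pairs
#' @export
correlation_by_distance <- function(pc, bin_edges_um = seq(30, 630, by = 50)) {
  pt <- pair_table(pc)
  pt <- pt[is.finite(pt$r), ]
  nb <- length(bin_edges_um) - 1L
  out <- data.frame(bin_lo_um = bin_edges_um[-(nb + 1L)],
                    bin_hi_um = bin_edges_um[-1L],
                    mean_r = NA_real_, sem_r = NA_real_, n_pairs = 0L)
  if (nrow(pt) == 0 || !any(pt$dist_um >= bin_edges_um[1])) {
    warning("no cell pairs at or beyond the first distance bin")
    return(out)
  }
  for (b in seq_len(nb)) {
    sel <- pt$dist_um >= bin_edges_um[b] & pt$dist_um < bin_edges_um[b + 1L]
    n <- sum(sel)
    out$n_pairs[b] <- n
    if (n >= 1) out$mean_r[b] <- mean(pt$r[sel])
    if (n >= 2) out$sem_r[b] <- stats::sd(pt$r[sel]) / sqrt(n)
  }
  out
}

#' Local coherence index profile
#'
#' For each seed cell and distance annulus, the LCI is
#' `(N_pos - N_neg) / (N_pos + N_neg)` where N_pos (N_neg) counts
#' positively (negatively) correlated cells in the annulus; cells with
#' |r| < `exclude_r` are excluded. The profile is the mean over seed
#' cells (seeds with an empty annulus are omitted from that annulus's
#' mean). LCI is 1 when all neighbors are positively correlated, -1 when
#' all are negative.
#'
#' @param pc a [pairwise_correlations()] result
#' @param annulus_edges_um ascending annulus edges, um (default 30-630
#'   in 50-um rings)
#' @param exclude_r correlation magnitude below which cells are excluded
#'   (default 0.01)
#' @return data.frame: annulus_lo_um, annulus_hi_um, lci (FOV mean),
#'   n_seeds, n_excluded_pairs
#' @export
local_coherence_index <- function(pc, annulus_edges_um = seq(30, 630, by = 50),
                                  exclude_r = 0.01) {
  n <- nrow(pc$r)
  nb <- length(annulus_edges_um) - 1L
  lci_seed <- matrix(NA_real_, n, nb)
  excl <- integer(nb)
  for (i in seq_len(n)) {
    r <- pc$r[i, -i]
    d <- pc$dist_um[i, -i]
    for (b in seq_len(nb)) {
      sel <- d >= annulus_edges_um[b] & d < annulus_edges_um[b + 1L] & is.finite(r)
      if (!any(sel)) next
      rr <- r[sel]
      keep <- abs(rr) >= exclude_r
      excl[b] <- excl[b] + sum(!keep)
      if (!any(keep)) next
      np <- sum(rr[keep] > 0)
      nn <- sum(rr[keep] < 0)
      lci_seed[i, b] <- (np - nn) / (np + nn)
    }
  }
  data.frame(annulus_lo_um = annulus_edges_um[-(nb + 1L)],
             annulus_hi_um = annulus_edges_um[-1L],
             lci = colMeans(lci_seed, na.rm = TRUE),
             n_seeds = colSums(is.finite(lci_seed)),
             n_excluded_pairs = excl %/% 2L)
}

#' First zero crossing of an LCI (or correlation) profile
#'
#' Linear interpolation between the centers of the first adjacent
#' annulus pair whose values bracket zero.
#'
#' @param profile data.frame with annulus bounds and a `lci` (or
#'   `mean_r`) column
#' @param column which column to scan
#' @return crossing distance in um, or NA if the profile never crosses
#' @export
profile_zero_crossing <- function(profile, column = "lci") {
  ctr <- (profile[[1]] + profile[[2]]) / 2
  v <- profile[[column]]
  ok <- is.finite(v)
  ctr <- ctr[ok]; v <- v[ok]
  if (length(v) < 2) return(NA_real_)
  for (i in seq_len(length(v) - 1L)) {
    if (v[i] > 0 && v[i + 1L] <= 0) {
      return(ctr[i] + (ctr[i + 1L] - ctr[i]) * v[i] / (v[i] - v[i + 1L]))
    }
  }
  NA_real_
}
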