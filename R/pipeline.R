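# End-to-end orchestration: configuration, the widefield and cellular
# runners, report output, and across-group comparison.

#' Pipeline run configuration
#'
#' Collects every stage parameter with its standard default: 3 SD active
#' pixel threshold over 0.01 mm2 regions, >40% active pixels per event
#' frame, Gaussian band-pass 195/33 um, 800 um maximum separation,
#' 1.8-2.2 mm long-range band, 100 surrogates and control sets, neuropil
#' alpha 0.4, 2 SD cell threshold, >5% active cells, and 100 samples of
#' 50 cells x 100 frames for cellular dimensionality.
#'
#' @param synth a [synth_params()] object (used when no movie is given)
#' @param baseline_window_s dF/F median window, s (valid 10-23)
#' @param threshold_sd,min_region_mm2,active_fraction event detection
#' @param events_from "detect" (run the detector) or "truth" (use the
#'   generator's planted event frames)
#' @param s_high_um,s_low_um band-pass SDs, um
#' @param min_separation_um correlation maxima separation, um
#' @param band_mm long-range distance band, mm
#' @param n_surrogates,n_control_sets null ensemble sizes
#' @param n_subsample_events event-count standardization for correlation
#'   analysis
#' @param seed_stride seed grid stride, px
#' @param n_splits cross-validation splits for widefield dimensionality
#' @param alpha,cell_thresh_sd,frame_fraction cellular branch
#' @param n_cells_subset,n_frames_subset,n_samples cellular
#'   dimensionality sampling
#' @param seed global seed; per-stage seeds are derived from it
#' @return an object of class `run_config`
#' @export
run_config <- function(synth = synth_params(),
                       baseline_window_s = 15,
                       threshold_sd = 3, min_region_mm2 = 0.01,
                       active_fraction = 0.40,
                       events_from = c("detect", "truth"),
                       s_high_um = 195, s_low_um = 33,
                       min_separation_um = 800, band_mm = c(1.8, 2.2),
                       n_surrogates = 100, n_control_sets = 100,
                       n_subsample_events = 100, seed_stride = 4,
                       n_splits = 20,
                       alpha = 0.4, cell_thresh_sd = 2, frame_fraction = 0.05,
                       n_cells_subset = 50, n_frames_subset = 100,
                       n_samples = 100,
                       seed = 1L) {
  events_from <- match.arg(events_from)
  stopif(baseline_window_s < 10 || baseline_window_s > 23,
         "`baseline_window_s` must lie in [10, 23] s")
  stopif(s_low_um >= s_high_um, "`s_low_um` must be below `s_high_um`")
  stopif(active_fraction <= 0 || active_fraction >= 1, "invalid `active_fraction`")
  stopif(band_mm[1] >= band_mm[2], "invalid `band_mm`")
  num <- as.numeric
  cfg <- list(synth = synth, baseline_window_s = num(baseline_window_s),
              threshold_sd = num(threshold_sd),
              min_region_mm2 = num(min_region_mm2),
              active_fraction = num(active_fraction), events_from = events_from,
              s_high_um = num(s_high_um), s_low_um = num(s_low_um),
              min_separation_um = num(min_separation_um), band_mm = num(band_mm),
              n_surrogates = as.integer(n_surrogates),
              n_control_sets = as.integer(n_control_sets),
              n_subsample_events = as.integer(n_subsample_events),
              seed_stride = as.integer(seed_stride),
              n_splits = as.integer(n_splits), alpha = num(alpha),
              cell_thresh_sd = num(cell_thresh_sd),
              frame_fraction = num(frame_fraction),
              n_cells_subset = as.integer(n_cells_subset),
              n_frames_subset = as.integer(n_frames_subset),
              n_samples = as.integer(n_samples), seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' The configuration round-trips exactly: `read_run_config(write)` gives
#' back an identical object.
#'
#' @param config a [run_config()]
#' @param path YAML file path
#' @return `path` / the [run_config()]
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$synth <- unclass(x$synth)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sp <- x$synth
  sp$grid_w <- NULL; sp$grid_h <- NULL
  x$synth <- do.call(synth_params, sp)
  x$band_mm <- as.numeric(x$band_mm)
  do.call(run_config, x)
}

#' Run the widefield analysis end to end
#'
#' Synthesizes (or accepts) a movie, converts it to dF/F, detects
#' spontaneous events, builds the band-pass-filtered pattern ensemble,
#' and computes: per-event wavelength and modularity with control-frame
#' significance, module amplitude, long-range correlation significance
#' against rotation/reflection surrogates, cross-validated participation
#' ratio, and the temporal autocorrelation of the ROI-mean trace.
#'
#' @param config a [run_config()]
#' @param movie optional [wf_movie()]; by default a synthetic movie is
#'   generated from `config$synth`
#' @param truth ground truth accompanying `movie` (required for
#'   `events_from = "truth"`); filled automatically for synthetic runs
#' @param out_dir if non-NULL, write `report.json`, `events.csv` and
#'   `config.yaml` there
#' @return an object of class `run_report` (list of summary values and
#'   per-event table)
#' @export
run_widefield <- function(config, movie = NULL, truth = NULL, out_dir = NULL) {
  if (is.null(movie)) {
    sm <- synth_widefield_movie(config$synth)
    movie <- sm$movie
    truth <- sm$truth
  }
  dff <- compute_dff(movie, config$baseline_window_s, keep_baseline = FALSE)
  movie$data <- NULL
  gc(FALSE)

  events <- if (config$events_from == "truth") {
    stopif(is.null(truth), "`events_from = 'truth'` requires ground truth")
    event_set_from_frames(dff, truth$event_times)
  } else {
    detect_events(dff, config$active_fraction, config$min_region_mm2,
                  config$threshold_sd)
  }
  n_ev <- nrow(events$events)
  report <- list(n_events = n_ev, config = config)

  if (n_ev == 0) {
    report$flag <- "no_events"
    report <- as_run_report(report)
    if (!is.null(out_dir)) write_run_report(report, out_dir, config)
    return(report)
  }

  controls <- select_control_frames(dff, events, config$n_control_sets,
                                    seed = derive_seed(config$seed, "ctrl"))
  pe <- bandpass_filter_patterns(events, config$s_high_um, config$s_low_um)

  mod <- pattern_modularity(pe)
  pool_pat <- array(NA_real_, dim = c(dim(dff$data)[1], dim(dff$data)[2],
                                      length(controls$pool)))
  for (i in seq_along(controls$pool))
    pool_pat[, , i] <- dff$data[, , controls$pool[i]]
  pe_pool <- bandpass_filter_patterns(pool_pat, config$s_high_um,
                                      config$s_low_um, mask = dff$roi_mask,
                                      pixel_um = dff$pixel_um)
  pool_mod <- pattern_modularity(pe_pool)$modularity
  names(pool_mod) <- as.character(controls$pool)
  msig <- modularity_significance(mod$modularity, pool_mod, controls)
  rm(pool_pat, pe_pool)
  gc(FALSE)

  wl_mean <- mean(mod$wavelength_mm, na.rm = TRUE)
  amp <- vapply(seq_len(n_ev), function(i) {
    ma <- module_amplitude(events$peak_patterns[, , i], dff$roi_mask,
                           dff$pixel_um, wl_mean)
    ma$amplitude
  }, numeric(1))

  n_corr <- min(n_ev, config$n_subsample_events)
  sub_idx <- with_seed(derive_seed(config$seed, "subsample"),
                       sort(sample(pe$n, n_corr)))
  pe_sub <- pattern_ensemble(pe$patterns[, , sub_idx, drop = FALSE], pe$mask,
                             pe$pixel_um, pe$filter_params)
  long <- if (n_corr >= 2) {
    surr <- make_surrogate_ensemble(pe_sub, config$n_surrogates,
                                    seed = derive_seed(config$seed, "surr"))
    tryCatch(longrange_significance(pe_sub, surr, config$band_mm,
                                    config$seed_stride, config$min_separation_um),
             error = function(e) list(real_median = NA_real_, p = NA_real_,
                                      p_reported = NA_real_, error = conditionMessage(e)))
  } else list(real_median = NA_real_, p = NA_real_, p_reported = NA_real_)

  dim_res <- if (n_ev >= 4)
    widefield_dimensionality(pe, config$n_splits,
                             seed = derive_seed(config$seed, "dim"))
  else list(d_eff = NA_real_, n_variance_75 = NA_real_)

  tac <- tryCatch(temporal_autocorrelation(dff),
                  error = function(e) NULL)

  report$wavelength_mm_median <- stats::median(mod$wavelength_mm, na.rm = TRUE)
  report$modularity_median <- msig$real_median
  report$modularity_p <- msig$p
  report$module_amplitude_mean <- mean(amp, na.rm = TRUE)
  report$longrange_median_r <- long$real_median
  report$longrange_p <- long$p
  report$d_eff <- dim_res$d_eff
  report$n_variance_75 <- dim_res$n_variance_75
  report$n_flagged_no_minimum <- sum(mod$flag != "ok")
  report$events <- cbind(mod[, c("event", "wavelength_mm", "modularity", "flag")],
                         module_amplitude = amp,
                         start_frame = events$events$start_frame,
                         end_frame = events$events$end_frame,
                         event_frame = events$events$event_frame)
  report$temporal_autocorr <- tac
  report <- as_run_report(report)
  if (!is.null(out_dir)) write_run_report(report, out_dir, config)
  report
}

#' Run the cellular analysis end to end
#'
#' Neuropil correction, dF/F with median smoothing, cellular event
#' detection, pairwise correlations with the within-cell shuffle null,
#' distance-binned correlation, LCI profile, and sample-size-controlled
#' cross-validated dimensionality.
#'
#' @param config a [run_config()]
#' @param recording a [cell_recording()]
#' @param out_dir if non-NULL, write `cell_report.json` there
#' @return an object of class `run_report`
#' @export
run_cellular <- function(config, recording, out_dir = NULL) {
  corr <- neuropil_correct(recording, config$alpha)
  dff <- cell_dff(corr, recording$frame_rate_hz)
  evset <- detect_cell_events(dff, recording$positions_um,
                              config$cell_thresh_sd, config$frame_fraction)
  report <- list(n_events = nrow(evset$events), config = config)
  if (nrow(evset$events) < 4) {
    report$flag <- "too_few_events"
    return(as_run_report(report))
  }
  pc <- pairwise_correlations(evset)
  shuf <- cell_shuffle_null(evset, config$n_surrogates,
                            seed = derive_seed(config$seed, "cellshuf"))
  prof <- correlation_by_distance(pc)
  lci <- local_coherence_index(pc)
  cdim <- cellular_dimensionality(evset$event_frame_matrix,
                                  config$n_cells_subset,
                                  config$n_frames_subset, config$n_samples,
                                  seed = derive_seed(config$seed, "celldim"))
  report$nearby_r_mean <- prof$mean_r[1]
  report$nearby_r_median <- shuf$real_stat
  report$shuffle_p <- shuf$p
  report$lci_nearby <- lci$lci[1]
  report$lci_zero_crossing_um <- profile_zero_crossing(lci)
  report$cellular_d_eff <- cdim$d_eff
  report$distance_profile <- prof
  report$lci_profile <- lci
  report <- as_run_report(report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_scalars(report),
                         file.path(out_dir, "cell_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

as_run_report <- function(x) {
  x$package_version <- as.character(utils::packageVersion("modcortex"))
  class(x) <- "run_report"
  x
}

report_scalars <- function(report) {
  keep <- vapply(report, function(v) is.numeric(v) && length(v) == 1, logical(1))
  report[keep]
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  s <- report_scalars(x)
  for (nm in names(s)) cat(sprintf("  %-24s %s\n", nm, format(s[[nm]], digits = 4)))
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes the scalar summary as JSON, the per-event table as CSV, and
#' the configuration as YAML. Output is deterministic: identical reports
#' produce byte-identical files.
#'
#' @param report a `run_report`
#' @param out_dir output directory (created if needed)
#' @param config the [run_config()] used
#' @return `out_dir`, invisibly
#' @export
write_run_report <- function(report, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_scalars(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$events))
    utils::write.csv(report$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Compare a metric across groups (Kruskal-Wallis)
#'
#' Thin wrapper over [stats::kruskal.test()] applied to each numeric
#' column. Post hoc pairwise comparisons are not performed; when a
#' difference is significant, inspect the groups directly.
#'
#' @param values data.frame of per-FOV metrics (numeric columns)
#' @param groups group label per row
#' @return data.frame: metric, H (chi-squared statistic), df, p
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(groups)
  stopif(nlevels(groups) < 2, "need at least 2 groups")
  stopif(min(table(groups)) < 2, "every group needs at least 2 members")
  num <- names(values)[vapply(values, is.numeric, logical(1))]
  out <- lapply(num, function(nm) {
    kt <- stats::kruskal.test(values[[nm]], groups)
    data.frame(metric = nm, H = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value)
  })
  do.call(rbind, out)
}
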