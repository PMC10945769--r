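#' Calibrated widefield movie
#'
#' Container for a raw-fluorescence movie: an H x W x T array with pixel
#' pitch, frame rate, and a logical ROI mask.
#'
#' @param data H x W x T numeric array (fluorescence, arbitrary units)
#' @param pixel_um pixel pitch, micrometers
#' @param frame_rate_hz frame rate, Hz
#' @param roi_mask H x W logical; default all-TRUE
#' @param meta free-form provenance list
#' @return an object of class `wf_movie`
#' @export
wf_movie <- function(data, pixel_um, frame_rate_hz, roi_mask = NULL, meta = list()) {
  stopif(length(dim(data)) != 3, "`data` must be an H x W x T array")
  h <- dim(data)[1]; w <- dim(data)[2]
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, h, w)
  stopif(!is.logical(roi_mask) || !all(dim(roi_mask) == c(h, w)),
         "`roi_mask` must be an H x W logical matrix")
  stopif(sum(roi_mask) < 1, "`roi_mask` must contain at least one pixel")
  check_positive(pixel_um, "pixel_um")
  check_positive(frame_rate_hz, "frame_rate_hz")
  stopif(dim(data)[3] < 1, "movie must have at least one frame")
  structure(list(data = data, pixel_um = pixel_um, frame_rate_hz = frame_rate_hz,
                 roi_mask = roi_mask, meta = meta),
            class = "wf_movie")
}

#' @export
print.wf_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<wf_movie> %d x %d px, %d frames @ %.3g Hz, %.3g um/px, ROI %d px\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$pixel_um, sum(x$roi_mask)))
  invisible(x)
}

#' Baseline-corrected (dF/F) movie
#'
#' @param data H x W x T dF/F array
#' @param baseline the F0 estimate (H x W x T array, or NULL if dropped)
#' @param pixel_um,frame_rate_hz,roi_mask,meta as in [wf_movie()]
#' @return an object of class `dff_movie`
#' @export
dff_movie <- function(data, baseline, pixel_um, frame_rate_hz, roi_mask, meta = list()) {
  m <- wf_movie(data, pixel_um, frame_rate_hz, roi_mask, meta)
  m$baseline <- baseline
  class(m) <- c("dff_movie", "wf_movie")
  m
}

#' @export
print.dff_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dff_movie> %d x %d px, %d frames @ %.3g Hz, %.3g um/px, ROI %d px\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$pixel_um, sum(x$roi_mask)))
  invisible(x)
}

#' Cellular recording (per-cell raw and neuropil traces)
#'
#' @param f_raw cells x T raw fluorescence
#' @param f_neuropil cells x T neuropil fluorescence
#' @param positions_um cells x 2 matrix of (x, y) centroids, micrometers
#' @param frame_rate_hz frame rate, Hz
#' @param alpha neuropil subtraction weight (default 0.4)
#' @param meta provenance list
#' @return an object of class `cell_recording`
#' @export
cell_recording <- function(f_raw, f_neuropil, positions_um, frame_rate_hz,
                           alpha = 0.4, meta = list()) {
  stopif(!is.matrix(f_raw) || !is.matrix(f_neuropil) ||
           !all(dim(f_raw) == dim(f_neuropil)),
         "`f_raw` and `f_neuropil` must be cells x T matrices of equal shape")
  stopif(nrow(positions_um) != nrow(f_raw) || ncol(positions_um) != 2,
         "`positions_um` must be cells x 2")
  stopif(any(!is.finite(positions_um)), "cell positions must be finite")
  check_positive(frame_rate_hz, "frame_rate_hz")
  structure(list(f_raw = f_raw, f_neuropil = f_neuropil,
                 positions_um = as.matrix(positions_um),
                 frame_rate_hz = frame_rate_hz, alpha = alpha, meta = meta),
            class = "cell_recording")
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf("<cell_recording> %d cells, %d frames @ %.3g Hz, alpha = %.2g\n",
              nrow(x$f_raw), ncol(x$f_raw), x$frame_rate_hz, x$alpha))
  invisible(x)
}

#' Read a movie from a TIFF stack
#'
#' Reads a multi-page TIFF into a [wf_movie()]. Calibration is taken from
#' arguments (TIFF tags rarely carry it reliably); the ROI mask can be a
#' logical matrix, a path to a PNG/TIFF image (nonzero = inside), or NULL
#' for all-TRUE.
#'
#' @param path TIFF file; if a `<path>.json` sidecar written by
#'   [write_movie_tiff()] exists, calibration, intensity scale and ROI
#'   are taken from it
#' @param pixel_um,frame_rate_hz calibration (required without a sidecar)
#' @param roi ROI mask (matrix, file path, or NULL)
#' @return a [wf_movie()]
#' @export
read_movie_tiff <- function(path, pixel_um = NULL, frame_rate_hz = NULL, roi = NULL) {
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else NULL
  # sidecar movies are stored as float samples scaled to [0, 1]
  frames <- tiff::readTIFF(path, all = TRUE, as.is = is.null(side))
  if (!is.list(frames)) frames <- list(frames)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  data <- array(0, dim = c(h, w, length(frames)))
  for (i in seq_along(frames)) data[, , i] <- frames[[i]]
  if (!is.null(side)) {
    data <- data * side$scale
    pixel_um <- pixel_um %||% side$pixel_um
    frame_rate_hz <- frame_rate_hz %||% side$frame_rate_hz
    if (is.null(roi) && !is.null(side$roi_mask))
      roi <- matrix(as.numeric(unlist(side$roi_mask)), h, w)
  }
  stopif(is.null(pixel_um) || is.null(frame_rate_hz),
         "`pixel_um` and `frame_rate_hz` are required (no sidecar found)")
  mask <- read_roi_mask(roi, h, w)
  wf_movie(data, pixel_um, frame_rate_hz, mask, meta = list(path = path))
}

#' Write a movie as a TIFF stack with a JSON calibration sidecar
#'
#' @param movie a [wf_movie()]
#' @param path output TIFF path; calibration and ROI go to `<path>.json`
#' @return `path`, invisibly
#' @export
write_movie_tiff <- function(movie, path) {
  d <- dim(movie$data)
  mx <- max(movie$data)
  frames <- lapply(seq_len(d[3]), function(t) movie$data[, , t] / mx)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  side <- list(pixel_um = movie$pixel_um, frame_rate_hz = movie$frame_rate_hz,
               scale = mx, roi_mask = as.integer(movie$roi_mask))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_roi_mask <- function(roi, h, w) {
  if (is.null(roi)) return(matrix(TRUE, h, w))
  if (is.matrix(roi)) {
    stopif(!all(dim(roi) == c(h, w)), "ROI mask shape does not match movie")
    return(roi > 0)
  }
  img <- if (grepl("\\.png$", roi, ignore.case = TRUE)) {
    png::readPNG(roi)
  } else {
    tiff::readTIFF(roi)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  stopif(!all(dim(img) == c(h, w)), "ROI mask shape does not match movie")
  img > 0
}

#' Read a cellular recording from CSV files
#'
#' `traces_csv` holds one row per cell (raw trace); `neuropil_csv` the
#' matching neuropil traces; `positions_csv` columns `cell_id`, `x_um`,
#' `y_um`.
#'
#' @param traces_csv,neuropil_csv,positions_csv file paths
#' @param frame_rate_hz frame rate, Hz
#' @param alpha neuropil weight
#' @return a [cell_recording()]
#' @export
read_cell_recording <- function(traces_csv, neuropil_csv, positions_csv,
                                frame_rate_hz, alpha = 0.4) {
  f_raw <- as.matrix(utils::read.csv(traces_csv, header = FALSE))
  f_np <- as.matrix(utils::read.csv(neuropil_csv, header = FALSE))
  pos <- utils::read.csv(positions_csv)
  cell_recording(unname(f_raw), unname(f_np),
                 as.matrix(pos[, c("x_um", "y_um")]), frame_rate_hz, alpha,
                 meta = list(traces = traces_csv))
}

#' Write a cellular recording to CSV files
#'
#' @param rec a [cell_recording()]
#' @param prefix output path prefix; writes `<prefix>_traces.csv`,
#'   `<prefix>_neuropil.csv`, `<prefix>_positions.csv`
#' @return `prefix`, invisibly
#' @export
write_cell_recording <- function(rec, prefix) {
  utils::write.table(rec$f_raw, paste0(prefix, "_traces.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(rec$f_neuropil, paste0(prefix, "_neuropil.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(cell_id = seq_len(nrow(rec$positions_um)),
                              x_um = rec$positions_um[, 1],
                              y_um = rec$positions_um[, 2]),
                   paste0(prefix, "_positions.csv"), row.names = FALSE)
  invisible(prefix)
}
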