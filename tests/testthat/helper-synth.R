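# Shared small-scale fixtures. Grids are kept small so unit tests run in
# seconds; acceptance tests use the full analysis grid.

small_params <- function(n_basis = 2, n_events = 4, event_rate_hz = 0.2,
                         seed = 7, ...) {
  synth_params(fov_mm = c(1.5, 1.5), pixel_um = 25, wavelength_mm = 0.5,
               n_basis = n_basis, n_events = n_events, frame_rate_hz = 10,
               event_rate_hz = event_rate_hz, seed = seed, ...)
}

# tiny constant-free dff movie wrapper around an H x W x T array
as_dff <- function(arr, pixel_um = 20, frame_rate_hz = 10, mask = NULL) {
  dff_movie(arr, baseline = NULL, pixel_um = pixel_um,
            frame_rate_hz = frame_rate_hz,
            roi_mask = mask %||% matrix(TRUE, dim(arr)[1], dim(arr)[2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian bump centered at (r0, c0) in pixels
gauss_bump <- function(h, w, r0, c0, sigma_px, amp = 1) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  amp * exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * sigma_px^2))
}
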