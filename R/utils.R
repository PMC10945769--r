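# Internal numerical utilities shared across the pipeline.
#
# Grid convention (used everywhere): fields are H x W matrices indexed
# [row, col]; row corresponds to y, col to x. Physical positions are at
# pixel centers, 0-based: x_um = (col - 1) * pixel_um, y_um = (row - 1) *
# pixel_um. Movies are H x W x T arrays.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so generators are pure functions of their seed.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Derive a reproducible sub-seed from a base seed and a stage label.
# Keeps results independent across stages while remaining a pure function
# of (seed, label). Result is a valid 32-bit integer seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stopif <- function(cond, msg) if (cond) stop(msg, call. = FALSE)

check_positive <- function(x, name) {
  stopif(!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x <= 0),
         paste0("`", name, "` must be strictly positive and finite"))
}

# Next size with only small prime factors, for fast FFTs.
next_fast_size <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

fft2 <- function(x) stats::fft(x)
ifft2_re <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

# Frequency grids (cycles per pixel) for an H x W array, fftfreq layout.
fft_freq <- function(n) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq_len(floor(n / 2)) - n %/% 2 - ifelse(n %% 2 == 0, 0L, 1L))
  # simpler explicit construction
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)
  k / n
}

#' Masked Gaussian low-pass filter
#'
#' Gaussian blur with mask-aware normalization: the blur of the masked data
#' is divided by the blur of the mask, so values outside the ROI never leak
#' into the result and ROI edges are not darkened.
#'
#' @param x H x W matrix (values outside `mask` are ignored)
#' @param mask H x W logical ROI
#' @param sigma_px Gaussian SD in pixels
#' @return H x W matrix, NA outside `mask`
#' @keywords internal
gaussian_lowpass_masked <- function(x, mask, sigma_px) {
  h <- nrow(x); w <- ncol(x)
  if (sigma_px <= 0) {
    out <- x
    out[!mask] <- NA_real_
    return(out)
  }
  pad <- ceiling(4 * sigma_px)
  hp <- next_fast_size(h + pad)
  wp <- next_fast_size(w + pad)
  xm <- x
  xm[!mask] <- 0
  xp <- matrix(0, hp, wp); xp[1:h, 1:w] <- xm
  mp <- matrix(0, hp, wp); mp[1:h, 1:w] <- as.numeric(mask)
  fy <- fft_freq(hp); fx <- fft_freq(wp)
  # transfer function of a continuous Gaussian: exp(-k^2 sigma^2 / 2)
  gy <- exp(-2 * pi^2 * sigma_px^2 * fy^2)
  gx <- exp(-2 * pi^2 * sigma_px^2 * fx^2)
  G <- outer(gy, gx)
  num <- ifft2_re(fft2(xp) * G)[1:h, 1:w]
  den <- ifft2_re(fft2(mp) * G)[1:h, 1:w]
  out <- matrix(NA_real_, h, w)
  ok <- mask & den > 1e-12
  out[ok] <- num[ok] / den[ok]
  out
}

#' Mask-corrected 2-D spatial autocorrelation
#'
#' Normalized spatial autocorrelation of a masked field: at each lag the
#' correlation sum is divided by the number of overlapping in-mask pixel
#' pairs, then the whole map is normalized to 1 at zero lag. Computed by
#' FFT with zero padding (no wrap-around across the mask).
#'
#' @param x H x W field
#' @param mask H x W logical ROI
#' @return list with `acf` ((2H-1) x (2W-1), zero lag at center),
#'   `counts` (overlap pair counts), `center` (row, col of zero lag)
#' @keywords internal
masked_autocorr2d <- function(x, mask) {
  h <- nrow(x); w <- ncol(x)
  mu <- mean(x[mask])
  z <- x - mu
  z[!mask] <- 0
  hp <- next_fast_size(2L * h)
  wp <- next_fast_size(2L * w)
  zp <- matrix(0, hp, wp); zp[1:h, 1:w] <- z
  mp <- matrix(0, hp, wp); mp[1:h, 1:w] <- as.numeric(mask)
  Fz <- fft2(zp)
  Fm <- fft2(mp)
  num <- ifft2_re(Conj(Fz) * Fz)
  cnt <- ifft2_re(Conj(Fm) * Fm)
  # reorder lags to -(h-1)..(h-1), -(w-1)..(w-1)
  ridx <- c((hp - h + 2L):hp, 1L:h)
  cidx <- c((wp - w + 2L):wp, 1L:w)
  num <- num[ridx, cidx]
  cnt <- round(cnt[ridx, cidx])
  ac <- matrix(NA_real_, nrow(num), ncol(num))
  ok <- cnt > 0
  ac[ok] <- num[ok] / cnt[ok]
  c0 <- c(h, w)  # zero-lag position after reordering
  v0 <- ac[c0[1], c0[2]]
  stopif(!is.finite(v0) || v0 <= 0, "autocorrelation undefined: pattern is constant on the mask")
  list(acf = ac / v0, counts = cnt, center = c0)
}

#' Radial average of a centered 2-D map
#'
#' Averages a lag map over annuli one pixel wide. Bin k collects lags with
#' rounded radius k pixels.
#'
#' @param a centered 2-D map (e.g. from [masked_autocorr2d()])
#' @param center (row, col) of zero lag
#' @param pixel_um pixel pitch in micrometers
#' @param max_r_px maximum radius in pixels
#' @return data.frame with `r_mm`, `value`, `n_pixels`
#' @keywords internal
radial_average <- function(a, center, pixel_um, max_r_px = NULL) {
  h <- nrow(a); w <- ncol(a)
  r <- sqrt(outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, `+`))
  rb <- as.integer(round(r))
  if (is.null(max_r_px)) max_r_px <- floor(min(center[1] - 1, h - center[1], center[2] - 1, w - center[2]))
  keep <- rb <= max_r_px & is.finite(a)
  sums <- tapply(a[keep], rb[keep], sum)
  ns <- tapply(a[keep], rb[keep], length)
  bins <- as.integer(names(sums))
  o <- order(bins)
  data.frame(r_mm = bins[o] * pixel_um / 1000,
             value = as.numeric(sums[o] / ns[o]),
             n_pixels = as.integer(ns[o]))
}

# Strict interior local minima / maxima of a numeric vector. A point
# qualifies only if strictly below (above) both neighbors; plateaus are
# skipped, which breaks ties toward the earlier index.
local_minima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[v[i] < v[i - 1] & v[i] < v[i + 1]]
}
local_maxima <- function(v) local_minima(-v)

# Parabolic refinement of an extremum at index i of (x, y): vertex of the
# parabola through the three surrounding points. Returns c(x, y) of vertex.
parabolic_refine <- function(x, y, i) {
  if (i <= 1 || i >= length(x)) return(c(x[i], y[i]))
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  d <- y1 - 2 * y2 + y3
  if (abs(d) < 1e-15) return(c(x[i], y[i]))
  delta <- 0.5 * (y1 - y3) / d
  delta <- max(-1, min(1, delta))
  h <- x[i + 1] - x[i]
  c(x[i] + delta * h, y2 - 0.25 * (y1 - y3) * delta)
}

# Strict 2-D local maxima over an 8-neighborhood, restricted to pixels
# where `mask` is TRUE. NA values never qualify and never block neighbors.
local_maxima_2d <- function(x, mask = NULL) {
  h <- nrow(x); w <- ncol(x)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  xp <- matrix(-Inf, h + 2, w + 2)
  xv <- x
  xv[!mask | !is.finite(x)] <- -Inf
  xp[2:(h + 1), 2:(w + 1)] <- xv
  ok <- xv > -Inf
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- xp[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
    ok <- ok & (xv > nb)
    if (!any(ok)) break
  }
  which(ok, arr.ind = TRUE)
}

# Block-average downsampling of a masked field by integer factors.
# Cell value = mean over in-mask source pixels; mask by majority.
block_downsample <- function(x, mask, fr, fc) {
  h <- nrow(x); w <- ncol(x)
  stopif(h %% fr != 0 || w %% fc != 0, "grid size is not a multiple of the downsampling factor")
  h2 <- h %/% fr; w2 <- w %/% fc
  xm <- x; xm[!mask] <- 0
  ri <- rep(seq_len(h2), each = fr)
  ci <- rep(seq_len(w2), each = fc)
  sum_block <- function(m) {
    m1 <- rowsum(m, ri)          # h2 x w
    t(rowsum(t(m1), ci))         # h2 x w2
  }
  s <- sum_block(xm)
  n <- sum_block(matrix(as.numeric(mask), h, w))
  out <- matrix(NA_real_, h2, w2)
  ok <- n > 0
  out[ok] <- s[ok] / n[ok]
  list(x = out, mask = n > (fr * fc) / 2)
}

# Bilinear sampling map for rotation/reflection about a center point.
# Returns source indices (4 per target pixel) and weights; targets whose
# source support is not fully inside `mask` are invalid.
# Cached per (h, w, angle, flip_x, flip_y) since only 36 angles x 4
# reflections occur.
.transform_cache <- new.env(parent = emptyenv())

rotation_map <- function(h, w, angle_deg, flip_x, flip_y, center) {
  key <- paste(h, w, angle_deg, flip_x, flip_y, round(center[1], 3), round(center[2], 3), sep = "_")
  hit <- .transform_cache[[key]]
  if (!is.null(hit)) return(hit)
  th <- -angle_deg * pi / 180  # inverse rotation: target -> source
  rows <- rep(seq_len(h), times = w)
  cols <- rep(seq_len(w), each = h)
  dy <- rows - center[1]
  dx <- cols - center[2]
  sy <- cos(th) * dy - sin(th) * dx
  sx <- sin(th) * dy + cos(th) * dx
  if (flip_y) sy <- -sy  # reflection at the x-axis through the center
  if (flip_x) sx <- -sx  # reflection at the y-axis through the center
  sr <- sy + center[1]
  sc <- sx + center[2]
  inb <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  # clamp the support so sources exactly on the far edge stay valid
  r0 <- pmin(floor(sr), h - 1); c0 <- pmin(floor(sc), w - 1)
  fr <- sr - r0;   fc <- sc - c0
  r0[!inb] <- 1L; c0[!inb] <- 1L
  i00 <- (c0 - 1L) * h + r0
  map <- list(
    i00 = i00, i10 = i00 + 1L, i01 = i00 + h, i11 = i00 + h + 1L,
    w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc),
    w01 = (1 - fr) * fc, w11 = fr * fc,
    inb = inb
  )
  .transform_cache[[key]] <- map
  map
}

# Apply a rotation map to a masked field. Values are NA where the source
# support leaves the mask or the grid.
apply_rotation_map <- function(x, mask, map) {
  v <- as.numeric(x)
  mnum <- as.numeric(mask)
  valid <- map$inb &
    mnum[map$i00] > 0 & mnum[map$i10] > 0 &
    mnum[map$i01] > 0 & mnum[map$i11] > 0
  out <- rep(NA_real_, length(v))
  idx <- which(valid)
  out[idx] <- map$w00[idx] * v[map$i00[idx]] + map$w10[idx] * v[map$i10[idx]] +
    map$w01[idx] * v[map$i01[idx]] + map$w11[idx] * v[map$i11[idx]]
  matrix(out, nrow(x), ncol(x))
}

# Pairwise Euclidean distances (um) between grid pixels given linear
# indices into an H x W grid.
grid_distance_um <- function(idx_a, idx_b, h, pixel_um) {
  ra <- (idx_a - 1L) %% h; ca <- (idx_a - 1L) %/% h
  rb <- (idx_b - 1L) %% h; cb <- (idx_b - 1L) %/% h
  sqrt(outer(ra, rb, `-`)^2 + outer(ca, cb, `-`)^2) * pixel_um
}
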