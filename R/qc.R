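# Image-quality metrics: radially averaged power spectra, frequency-resolved
# SNR with a noise reference, an FFT focus score, and NCC block matching.

# 2-D Hann taper (separable); "none" returns 1
.taper <- function(nr, nc, window = c("hann", "none")) {
  window <- match.arg(window)
  if (window == "none") return(1)
  hy <- 0.5 * (1 - cos(2 * pi * seq_len(nr) / (nr + 1)))
  hx <- 0.5 * (1 - cos(2 * pi * seq_len(nc) / (nc + 1)))
  outer(hy, hx)
}

# radial frequency (cycles/pixel) of each FFT element
.freq_radius <- function(nr, nc) {
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  sqrt(outer(fy^2, fx^2, "+"))
}

#' Radially averaged 2-D power spectrum
#'
#' Subtracts the mean, applies a taper window, takes the 2-D discrete
#' Fourier transform, and averages the squared modulus in radial frequency
#' bins. The DC component is excluded. Bin `b` collects elements with
#' `round(r / 0.5 * n_bins) == b` (clamped to `[1, n_bins]`), `r` the radial
#' frequency in cycles/pixel up to Nyquist (0.5).
#'
#' @param raster Numeric matrix, at least 32 x 32.
#' @param n_bins Number of radial bins; default half the smaller dimension
#'   (integer-radius steps to Nyquist).
#' @param window Taper: `"hann"` (default) or `"none"`.
#' @return An object of class `radial_spectrum`: list with `freq_bins` (bin
#'   centres, cycles/pixel), `power` (mean power per bin), `counts` (bin
#'   occupancy), `total_power` (sum over all non-DC elements), `n_bins`,
#'   `window_id`.
#' @export
radial_power_spectrum <- function(raster, n_bins = NULL,
                                  window = c("hann", "none")) {
  window <- match.arg(window)
  nr <- nrow(raster); nc <- ncol(raster)
  if (nr < 32 || nc < 32)
    stop("raster must be at least 32 x 32", call. = FALSE)
  if (is.null(n_bins)) n_bins <- min(nr, nc) %/% 2L
  m <- (raster - mean(raster)) * .taper(nr, nc, window)
  p <- Mod(stats::fft(m))^2
  r <- .freq_radius(nr, nc)
  bin <- pmin(pmax(as.integer(round(r / 0.5 * n_bins)), 1L), n_bins)
  keep <- !(row(p) == 1L & col(p) == 1L)  # exclude DC
  sums <- rep(0, n_bins); cnts <- rep(0L, n_bins)
  tp <- tapply(p[keep], bin[keep], sum)
  tc <- tapply(rep(1L, sum(keep)), bin[keep], sum)
  ix <- as.integer(names(tp))
  sums[ix] <- tp; cnts[ix] <- tc
  occupied <- cnts > 0L
  structure(list(
    freq_bins = (seq_len(n_bins) / n_bins * 0.5)[occupied],
    power = (sums / pmax(cnts, 1L))[occupied],
    counts = cnts[occupied],
    total_power = sum(p[keep]),
    n_bins = n_bins,
    window_id = window
  ), class = "radial_spectrum")
}

#' Frequency-resolved SNR with a noise-image reference
#'
#' The power spectrum of the image and of one or more pure-noise images
#' (acquired identically but with no signal, e.g. beam blanked) are computed
#' with the same binning and window; per bin,
#' `SNR(f) = max(0, (P_img(f) - Pbar_noise(f)) / Pbar_noise(f))` where
#' `Pbar_noise` is the mean noise spectrum. The scalar spectral-SNR is the
#' trapezoidal integral of `SNR(f)` over the full band. Bins with zero noise
#' power are flagged invalid and excluded from the integral.
#'
#' @param image Numeric matrix.
#' @param noise_images A matrix or list of matrices, same shape as `image`.
#' @param n_bins,window Passed to [radial_power_spectrum()].
#' @return An object of class `ssnr_curve`: list with `freq_bins`, `snr`,
#'   `valid`, `spectral_snr`, `window_id`.
#' @export
ssnr <- function(image, noise_images, n_bins = NULL,
                 window = c("hann", "none")) {
  window <- match.arg(window)
  if (is.matrix(noise_images)) noise_images <- list(noise_images)
  if (length(noise_images) < 1)
    stop("need at least one noise image", call. = FALSE)
  for (n in noise_images)
    if (!all(dim(n) == dim(image)))
      stop("noise images must match the image shape", call. = FALSE)
  ps_img <- radial_power_spectrum(image, n_bins, window)
  ps_noise <- lapply(noise_images, radial_power_spectrum,
                     n_bins = ps_img$n_bins, window = window)
  pbar <- Reduce(`+`, lapply(ps_noise, `[[`, "power")) / length(ps_noise)
  valid <- pbar > 0
  snr <- rep(0, length(pbar))
  snr[valid] <- pmax(0, (ps_img$power[valid] - pbar[valid]) / pbar[valid])
  f <- ps_img$freq_bins
  spectral <- if (sum(valid) >= 2) {
    fv <- f[valid]; sv <- snr[valid]
    sum(diff(fv) * (utils::head(sv, -1) + utils::tail(sv, -1)) / 2)
  } else 0
  structure(list(
    freq_bins = f, snr = snr, valid = valid,
    spectral_snr = spectral, window_id = window
  ), class = "ssnr_curve")
}

#' FFT focus score
#'
#' Fraction of the DC-excluded spectral power lying above
#' `cutoff_frac * Nyquist` in radial frequency. Sharper (better focused)
#' images retain more high-frequency power and score higher.
#'
#' @param raster Numeric matrix.
#' @param cutoff_frac Cutoff as a fraction of Nyquist, in `(0, 1)`.
#' @param window Taper window.
#' @return Scalar in `[0, 1]`; 0 for a constant image.
#' @export
focus_score <- function(raster, cutoff_frac = 0.5,
                        window = c("hann", "none")) {
  if (cutoff_frac <= 0 || cutoff_frac >= 1)
    stop("`cutoff_frac` must be in (0, 1)", call. = FALSE)
  window <- match.arg(window)
  m <- (raster - mean(raster)) * .taper(nrow(raster), ncol(raster), window)
  p <- Mod(stats::fft(m))^2
  r <- .freq_radius(nrow(raster), ncol(raster))
  keep <- !(row(p) == 1L & col(p) == 1L)
  total <- sum(p[keep])
  if (total == 0) return(0)
  sum(p[keep & r > cutoff_frac * 0.5]) / total
}

#' Normalized cross-correlation of two equal-shaped blocks
#'
#' Zero-mean, unit-variance correlation coefficient in `[-1, 1]`.
#'
#' @param block_a,block_b Numeric matrices of identical shape.
#' @return Scalar NCC; `NA` if either block is constant.
#' @export
ncc <- function(block_a, block_b) {
  if (!all(dim(block_a) == dim(block_b)))
    stop("blocks must have identical shape", call. = FALSE)
  a <- block_a - mean(block_a)
  b <- block_b - mean(block_b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

# NCC of template `tpl` against every integer offset of `img` within
# [-search, search]^2 (img must be tpl size + 2*search). Returns the score
# matrix indexed [dy + search + 1, dx + search + 1].
.ncc_search <- function(tpl, img, search) {
  bh <- nrow(tpl); bw <- ncol(tpl)
  ta <- tpl - mean(tpl)
  tnorm <- sqrt(sum(ta^2))
  n <- (2L * search + 1L)
  out <- matrix(NA_real_, n, n)
  if (tnorm == 0) return(out)
  for (dy in -search:search) for (dx in -search:search) {
    sub <- img[dy + search + 1:bh, dx + search + 1:bw]
    sm <- sub - mean(sub)
    den <- tnorm * sqrt(sum(sm^2))
    out[dy + search + 1L, dx + search + 1L] <-
      if (den == 0) NA_real_ else sum(ta * sm) / den
  }
  out
}

# 1-D quadratic subpixel refinement around index i of vector v; returns
# offset in (-0.5, 0.5], ties toward zero
.quad_refine <- function(v, i) {
  if (i <= 1L || i >= length(v) || anyNA(v[(i - 1L):(i + 1L)])) return(0)
  y0 <- v[i - 1L]; y1 <- v[i]; y2 <- v[i + 1L]
  if (y1 >= 1 - 1e-12) return(0)  # exact match: the integer peak is exact
  den <- y0 - 2 * y1 + y2
  if (den >= 0) return(0)  # not a strict local max
  d <- 0.5 * (y0 - y2) / den
  max(-0.5, min(0.5, d))
}

#' Displacement field by NCC block matching
#'
#' Measures local displacements between a reference and a warped image at an
#' evenly spaced grid of points. For each grid point a `block_size` square
#' block from the reference is matched against the warped image over integer
#' offsets within `search_radius`, maximizing normalized cross-correlation;
#' the peak is refined to subpixel precision by a 1-D quadratic fit along
#' each axis. Matches with peak NCC below `min_ncc` are flagged invalid;
#' grid points whose block or search window would leave the image are
#' skipped (flagged, not an error).
#'
#' @param reference,warped Numeric matrices of identical shape.
#' @param grid_spacing Grid point spacing (px).
#' @param block_size Matching block side (px); should be `< 2 * grid_spacing`.
#' @param search_radius Maximum displacement searched (px).
#' @param min_ncc Validity threshold on the peak NCC (default 0.2).
#' @return An object of class `displacement_field`: data frame `points`
#'   (x, y, dx, dy, ncc, valid) plus `stats` (max_mag, rms, mean_dx,
#'   mean_dy over valid points) and the call parameters.
#' @export
displacement_field <- function(reference, warped, grid_spacing = 64,
                               block_size = 32, search_radius = 8,
                               min_ncc = 0.2) {
  if (!all(dim(reference) == dim(warped)))
    stop("images must have identical shape", call. = FALSE)
  h <- nrow(reference); w <- ncol(reference)
  hb <- block_size %/% 2L
  margin <- hb + search_radius + 1L
  gx <- seq(margin, w - margin, by = grid_spacing)
  gy <- seq(margin, h - margin, by = grid_spacing)
  if (length(gx) == 0 || length(gy) == 0)
    stop("image too small for the requested grid/block/search sizes",
         call. = FALSE)
  pts <- expand.grid(x = gx, y = gy)
  n <- nrow(pts)
  dx <- dy <- score <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (k in seq_len(n)) {
    x <- pts$x[k]; y <- pts$y[k]
    ry <- (y - hb):(y - hb + block_size - 1L)
    rx <- (x - hb):(x - hb + block_size - 1L)
    tpl <- reference[ry, rx]
    wy <- (min(ry) - search_radius):(max(ry) + search_radius)
    wx <- (min(rx) - search_radius):(max(rx) + search_radius)
    if (min(wy) < 1L || min(wx) < 1L || max(wy) > h || max(wx) > w) next
    sc <- .ncc_search(tpl, warped[wy, wx], search_radius)
    if (all(is.na(sc))) next
    pk <- which(sc == max(sc, na.rm = TRUE), arr.ind = TRUE)
    # ties broken toward the smaller displacement
    if (nrow(pk) > 1L) {
      ctr <- search_radius + 1L
      d2 <- (pk[, 1] - ctr)^2 + (pk[, 2] - ctr)^2
      pk <- pk[which.min(d2), , drop = FALSE]
    }
    iy <- pk[1, 1]; ix <- pk[1, 2]
    sdy <- .quad_refine(sc[, ix], iy)
    sdx <- .quad_refine(sc[iy, ], ix)
    dy[k] <- iy - (search_radius + 1L) + sdy
    dx[k] <- ix - (search_radius + 1L) + sdx
    score[k] <- sc[iy, ix]
    valid[k] <- is.finite(score[k]) && score[k] >= min_ncc
  }
  pts$dx <- dx; pts$dy <- dy; pts$ncc <- score; pts$valid <- valid
  mags <- sqrt(dx[valid]^2 + dy[valid]^2)
  structure(list(
    points = pts,
    stats = list(
      n = n, n_valid = sum(valid),
      max_mag = if (any(valid)) max(mags) else NA_real_,
      rms = if (any(valid)) sqrt(mean(mags^2)) else NA_real_,
      mean_dx = if (any(valid)) mean(dx[valid]) else NA_real_,
      mean_dy = if (any(valid)) mean(dy[valid]) else NA_real_
    ),
    grid_spacing = grid_spacing, block_size = block_size,
    search_radius = search_radius, min_ncc = min_ncc
  ), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "<displacement_field> %d points (%d valid); max |d| %.2f px, RMS %.2f px\n",
    x$stats$n, x$stats$n_valid, x$stats$max_mag, x$stats$rms))
  invisible(x)
}

#' Export a spectrum or SNR curve as CSV
#'
#' @param x A `radial_spectrum` or `ssnr_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  df <- if (inherits(x, "radial_spectrum"))
    data.frame(freq = x$freq_bins, power = x$power)
  else if (inherits(x, "ssnr_curve"))
    data.frame(freq = x$freq_bins, snr = x$snr, valid = x$valid)
  else stop("unsupported object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render a displacement field as a colour-wheel image
#'
#' Hue encodes direction, intensity encodes magnitude relative to
#' `max_scale_px` (the colour-wheel radius).
#'
#' @param field A [displacement_field()].
#' @param max_scale_px Magnitude mapping to full intensity.
#' @return Matrix of hex colours (one cell per grid point), invisibly usable
#'   with [grDevices::as.raster()].
#' @export
field_colorwheel <- function(field, max_scale_px = 30) {
  p <- field$points
  nx <- length(unique(p$x)); ny <- length(unique(p$y))
  hue <- (atan2(p$dy, p$dx) / (2 * pi)) %% 1
  mag <- pmin(1, sqrt(p$dx^2 + p$dy^2) / max_scale_px)
  col <- ifelse(p$valid & is.finite(hue),
                grDevices::hsv(ifelse(is.finite(hue), hue, 0), 1,
                               ifelse(is.finite(mag), mag, 0)),
                "#000000")
  matrix(col, ny, nx, byrow = TRUE)
}
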