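# Shared fixtures. Scenes are memoized per test run since generation is the
# slowest step at these sizes.

.fixture_env <- new.env(parent = emptyenv())

fixture_scene <- function(w, h, seed) {
  key <- sprintf("scene_%d_%d_%d", w, h, seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_specimen(w, h, seed = seed)
  .fixture_env[[key]]
}

# reference 3 nm / 120 ms operating point
ref_spec <- function() make_supertile_spec(6000, 3, 3, 0.15)
ref_plan <- function() plan_montage(1e6, 1e6, 3.0, ref_spec(), 600)

# small simulation world: 256-px tiles, 30% overlap so pairwise matching has
# a usable (77 px) strip, 2x2 supertiles
small_spec <- function() make_supertile_spec(256, 3, 3, 0.3)
small_plan <- function(n = 2, inter = 100) {
  spec <- small_spec()
  step <- spec$extent_rows_px - inter
  side_nm <- ((n - 1) * step + spec$extent_rows_px) * 3.0
  plan_montage(side_nm, side_nm, 3.0, spec, inter)
}

# exhaustive corner-test oracles for the beam-boundary capacity operations
oracle_fits <- function(i, j, R, tile, pitch) {
  half <- tile / 2
  corners_x <- i * pitch + c(-half, -half, half, half)
  corners_y <- j * pitch + c(-half, half, -half, half)
  all(sqrt(corners_x^2 + corners_y^2) <= R)
}

oracle_cruciform <- function(R, tile, pitch, kmax = 6) {
  cnt <- 0L
  for (i in -kmax:kmax) for (j in -kmax:kmax)
    if (oracle_fits(i, j, R, tile, pitch)) cnt <- cnt + 1L
  cnt
}

oracle_rect <- function(R, tile, pitch, kmax = 6) {
  idx <- -kmax:kmax
  fits <- outer(idx, idx, Vectorize(function(i, j)
    oracle_fits(i, j, R, tile, pitch)))
  best <- 0L
  n <- length(idx)
  for (i0 in 1:n) for (i1 in i0:n) for (j0 in 1:n) for (j1 in j0:n)
    if (all(fits[i0:i1, j0:j1]))
      best <- max(best, (i1 - i0 + 1L) * (j1 - j0 + 1L))
  best
}

# rasterization oracle: count pixels covered by any supertile footprint
raster_unique_pixels <- function(plan) {
  W <- plan$montage_extent_px[["width"]]
  H <- plan$montage_extent_px[["height"]]
  cov <- matrix(FALSE, H, W)
  ex <- plan$spec$extent_cols_px
  ey <- plan$spec$extent_rows_px
  p <- plan$stage_positions
  for (k in seq_len(nrow(p)))
    cov[p$y_px[k] + 1:ey, p$x_px[k] + 1:ex] <- TRUE
  sum(cov)
}
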