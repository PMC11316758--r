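# Synthetic specimen + acquisition simulator.
# In-memory rasters are numeric matrices in intensity units [0, 1], indexed
# [row, col] with 0-based pixel coordinates (x = col, y = row) at the API
# surface. Quantization to 16 bits happens only at TIFF export (write_tile).

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# derive a per-tile seed from (montage seed, supertile index, subtile index);
# stays below 2^31
tile_seed <- function(seed, st_index, sub_index) {
  ((as.numeric(seed) %% 65521) * 65537 +
     st_index * 9973 + sub_index * 97) %% 2147483647
}

# isotropic Gaussian blur via FFT, periodic boundary
.fft_blur <- function(m, sigma) {
  nr <- nrow(m); nc <- ncol(m)
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  h <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, "+"))
  Re(stats::fft(stats::fft(m) * h, inverse = TRUE)) / (nr * nc)
}

#' Default synthetic-specimen texture parameters
#'
#' The generator emulates heavy-metal-stained neural tissue at the texture
#' level only: dark curvilinear ridges stand in for membranes, dark soft
#' disks for vesicles/mitochondria cross-sections, over a band-limited
#' cytoplasmic background. Densities are per megapixel; lengths in pixels.
#'
#' @param membrane_density Membranes per megapixel.
#' @param membrane_thickness_range Ridge full thickness range (px).
#' @param membrane_length_range Curve length range (px).
#' @param membrane_curvature S.d. of the per-step heading increment (rad);
#'   larger values give wigglier, more tortuous membranes.
#' @param blob_density Blobs per megapixel.
#' @param blob_radius_range Blob radius range (px).
#' @param background_level Mean background intensity in `[0, 1]`.
#' @param background_sd Band-limited background fluctuation s.d.
#' @param background_corr_px Background correlation length (blur sigma, px).
#' @return A named list of parameters.
#' @export
specimen_params <- function(membrane_density = 40,
                            membrane_thickness_range = c(2, 6),
                            membrane_length_range = c(150, 900),
                            membrane_curvature = 0.12,
                            blob_density = 350,
                            blob_radius_range = c(3, 14),
                            background_level = 0.55,
                            background_sd = 0.04,
                            background_corr_px = 4) {
  as.list(environment())
}

#' Generate a synthetic specimen scene
#'
#' Deterministic given `(seed, params, size)`. See [specimen_params()] for
#' what the texture emulates.
#'
#' @param width_px,height_px Scene dimensions (x = columns, y = rows).
#' @param seed Integer seed.
#' @param params A [specimen_params()] list.
#' @return Numeric matrix `height_px x width_px` with values in `[0, 1]`,
#'   of class `synthetic_scene` with attributes `seed` and `params`.
#' @export
make_specimen <- function(width_px, height_px, seed = 1,
                          params = specimen_params()) {
  if (width_px < 1 || height_px < 1)
    stop("dimensions must be positive", call. = FALSE)
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  p <- params
  with_seed(seed, {
    mpix <- width_px * height_px / 1e6
    # band-limited background
    bg <- matrix(stats::rnorm(width_px * height_px), height_px, width_px)
    bg <- .fft_blur(bg, p$background_corr_px)
    s <- stats::sd(bg)
    if (s > 0) bg <- bg / s * p$background_sd
    img <- p$background_level + bg

    # dark features accumulate in an occupancy map, subtracted at the end
    dark <- matrix(0, height_px, width_px)
    splat <- function(x, y, w) {
      # accumulate weight w at integer pixel positions (0-based x, y)
      ix <- round(x); iy <- round(y)
      ok <- ix >= 0 & ix < width_px & iy >= 0 & iy < height_px
      if (!any(ok)) return(invisible())
      idx <- iy[ok] + 1L + ix[ok] * height_px  # column-major linear index
      agg <- rowsum(rep(w, sum(ok)), idx)
      dark[as.integer(rownames(agg))] <<-
        dark[as.integer(rownames(agg))] + agg[, 1L]
    }

    n_mem <- stats::rpois(1, p$membrane_density * mpix)
    for (k in seq_len(n_mem)) {
      len <- stats::runif(1, p$membrane_length_range[1],
                          p$membrane_length_range[2])
      th <- stats::runif(1, p$membrane_thickness_range[1],
                         p$membrane_thickness_range[2])
      n_pts <- max(8L, as.integer(len / 0.7))
      # smooth random walk: heading integrates small curvature increments
      ang <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(n_pts - 1L, 0, p$membrane_curvature)))
      cx <- cumsum(c(stats::runif(1, 0, width_px - 1), 0.7 * cos(ang[-1])))
      cy <- cumsum(c(stats::runif(1, 0, height_px - 1), 0.7 * sin(ang[-1])))
      # thicken along the local normal
      nx <- -sin(ang); ny <- cos(ang)
      offs <- seq(-th / 2, th / 2, by = 0.6)
      for (o in offs)
        splat(cx + o * nx, cy + o * ny, 0.35)
    }

    n_blob <- stats::rpois(1, p$blob_density * mpix)
    if (n_blob > 0) {
      bx <- stats::runif(n_blob, 0, width_px - 1)
      by <- stats::runif(n_blob, 0, height_px - 1)
      br <- stats::runif(n_blob, p$blob_radius_range[1], p$blob_radius_range[2])
      bd <- stats::runif(n_blob, 0.15, 0.4)  # darkness
      for (k in seq_len(n_blob)) {
        x0 <- max(0L, floor(bx[k] - br[k] - 2)); x1 <- min(width_px - 1L, ceiling(bx[k] + br[k] + 2))
        y0 <- max(0L, floor(by[k] - br[k] - 2)); y1 <- min(height_px - 1L, ceiling(by[k] + br[k] + 2))
        if (x1 < x0 || y1 < y0) next
        xs <- x0:x1; ys <- y0:y1
        d <- sqrt(outer((ys - by[k])^2, (xs - bx[k])^2, "+"))
        soft <- pmin(1, pmax(0, br[k] - d + 1))  # 1-px soft edge
        dark[ys + 1L, xs + 1L] <- dark[ys + 1L, xs + 1L] + bd[k] * soft
      }
    }

    if (n_mem > 0) dark <- .fft_blur(dark, 0.8)  # soften ridge edges
    img <- img - dark
    img <- pmin(pmax(img, 0), 1)
    structure(img, class = c("synthetic_scene", "matrix", "array"),
              seed = seed, params = p)
  })
}

#' Optics model for the acquisition simulator
#'
#' Degradations grow with the deflection radius `r`, the Euclidean norm of
#' the subtile offset index `(i, j)` (so corner subtiles, `r = sqrt(2)`, are
#' worse than edge subtiles, `r = 1`, matching the observed corner-worst
#' quality ordering).
#'
#' @param boundary_radius_px Circular beam boundary radius from the optic
#'   axis (px); pixels deflected beyond it image nothing. Use `Inf` to
#'   disable.
#' @param distortion_scale Maximum displacement (px) of the per-subtile
#'   smooth distortion field at unit deflection radius.
#' @param snr_falloff Multiplicative contrast attenuation per unit deflection
#'   radius: contrast is scaled by `(1 - snr_falloff)^r`.
#' @param dose_per_ms Expected detected electrons per pixel per ms exposure
#'   at unit intensity. `Inf` disables shot noise (ideal detector).
#' @param read_noise_sd Additive Gaussian read noise s.d., in intensity
#'   units.
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(boundary_radius_px = Inf,
                         distortion_scale = 0,
                         snr_falloff = 0,
                         dose_per_ms = Inf,
                         read_noise_sd = 0) {
  if (boundary_radius_px <= 0 || distortion_scale < 0 || snr_falloff < 0 ||
      snr_falloff >= 1 || dose_per_ms <= 0 || read_noise_sd < 0)
    stop("invalid optics parameter", call. = FALSE)
  structure(as.list(environment()), class = "optics_model")
}

#' Evaluate a subtile distortion field from its coefficient record
#'
#' The simulator's per-subtile distortion is a second-order 2-D polynomial
#' plus a radial (barrel) term, evaluated on normalized coordinates
#' `u, v` in `[-1, 1]` and scaled by `coeffs$amp_scale` so the maximum
#' displacement magnitude equals `distortion_scale * deflection_radius`.
#' Given the coefficient record stored in a truth manifest, this
#' reconstructs the exact field that was applied.
#'
#' @param tile_px Tile side (px).
#' @param coeffs Coefficient record: list with `ax`, `ay` (length-7 numeric)
#'   and `amp_scale`, as stored by the simulator.
#' @return List with `dx`, `dy`: `tile_px x tile_px` displacement matrices
#'   (px).
#' @export
distortion_field <- function(tile_px, coeffs) {
  u <- matrix(rep(seq(-1, 1, length.out = tile_px), each = tile_px),
              tile_px, tile_px)          # varies along columns (x)
  v <- t(u)                              # varies along rows (y)
  r2 <- u^2 + v^2
  poly <- function(a)
    a[1] + a[2] * u + a[3] * v + a[4] * u^2 + a[5] * u * v + a[6] * v^2 +
      a[7] * u * r2
  dx <- poly(coeffs$ax)
  dy <- poly(coeffs$ay)
  list(dx = dx * coeffs$amp_scale, dy = dy * coeffs$amp_scale)
}

# draw distortion coefficients deterministically from a tile seed
draw_distortion_coeffs <- function(seed, amplitude_px) {
  with_seed(seed + 13L, {
    ax <- stats::runif(7, -1, 1)
    ay <- stats::runif(7, -1, 1)
    # normalize on a coarse grid so amp_scale is cheap and reproducible
    n <- 33L
    u <- matrix(rep(seq(-1, 1, length.out = n), each = n), n, n)
    v <- t(u); r2 <- u^2 + v^2
    ev <- function(a)
      a[1] + a[2] * u + a[3] * v + a[4] * u^2 + a[5] * u * v + a[6] * v^2 +
        a[7] * u * r2
    maxmag <- max(sqrt(ev(ax)^2 + ev(ay)^2))
    amp_scale <- if (maxmag > 0) amplitude_px / maxmag else 0
    list(ax = ax, ay = ay, amp_scale = amp_scale)
  })
}

# bilinear sampling of `scene` at 0-based coordinates (x, y), clamped to
# the scene border
.bilinear <- function(scene, x, y) {
  h <- nrow(scene); w <- ncol(scene)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * h; i10 <- y1 + 1 + x0 * h
  i01 <- y0 + 1 + x1 * h; i11 <- y1 + 1 + x1 * h
  s <- scene
  (1 - fx) * ((1 - fy) * s[i00] + fy * s[i10]) +
    fx * ((1 - fy) * s[i01] + fy * s[i11])
}

# subtile offset index (i east+, j north+) -> 0-based (grid_row, grid_col)
.subtile_grid_pos <- function(i, j, spec) {
  cr <- spec$grid_rows %/% 2L
  cc <- spec$grid_cols %/% 2L
  c(row = cr - unname(j), col = cc + unname(i))
}

#' Simulate acquisition of one subtile
#'
#' Extracts the tile window from the scene at its nominal offset, applies the
#' deflection-dependent degradations of the [optics_model()] — a smooth
#' polynomial displacement field with maximum magnitude
#' `distortion_scale * r`, contrast attenuation `(1 - snr_falloff)^r`,
#' Poisson shot noise at `dose_per_ms * exposure_ms * intensity` expected
#' counts plus Gaussian read noise — and masks pixels deflected beyond the
#' circular beam boundary to the background level. The centre subtile
#' (`r = 0`) is undeflected and gets no distortion or attenuation.
#'
#' @param scene A [make_specimen()] scene (or any numeric matrix in
#'   `[0, 1]`).
#' @param stage_origin_px Numeric `(x, y)`: top-left of the supertile in
#'   scene coordinates (0-based, may be fractional if stage jitter is
#'   injected).
#' @param subtile_index Integer `(i, j)` offset index; `(0, 0)` is on-axis.
#' @param spec A [make_supertile_spec()] object.
#' @param optics An [optics_model()] object.
#' @param exposure_s Exposure time (s).
#' @param seed Integer seed for this tile's noise and distortion draw.
#' @return List with `tile` (numeric matrix, intensity units) and `truth`
#'   (nominal offset, applied distortion coefficients, radius, attenuation,
#'   clipped flag, seed, exposure, expected mean counts).
#' @export
acquire_subtile <- function(scene, stage_origin_px, subtile_index, spec,
                            optics, exposure_s = 0.12, seed = 1) {
  stopifnot(inherits(spec, "supertile_spec"), inherits(optics, "optics_model"))
  T <- spec$tile_px
  gp <- .subtile_grid_pos(subtile_index[1], subtile_index[2], spec)
  tl_x <- stage_origin_px[1] + gp[["col"]] * spec$pitch_px
  tl_y <- stage_origin_px[2] + gp[["row"]] * spec$pitch_px
  if (tl_x < -0.5 || tl_y < -0.5 ||
      tl_x + T > ncol(scene) + 0.5 || tl_y + T > nrow(scene) + 0.5)
    stop(sprintf(
      "tile window [%.1f, %.1f] + %d px exceeds scene %d x %d",
      tl_x, tl_y, T, ncol(scene), nrow(scene)), call. = FALSE)

  radius <- sqrt(sum(as.numeric(subtile_index)^2))
  amp <- optics$distortion_scale * radius
  coeffs <- NULL

  # target pixel coordinates in scene space (0-based)
  xs <- matrix(rep(tl_x + 0:(T - 1), each = T), T, T)
  ys <- matrix(rep(tl_y + 0:(T - 1), T), T, T)
  if (amp > 0) {
    coeffs <- draw_distortion_coeffs(seed, amp)
    df <- distortion_field(T, coeffs)
    tile <- .bilinear(scene, xs + df$dx, ys + df$dy)
  } else {
    # integer-aligned fast path preserves exact equality with the crop
    if (abs(tl_x - round(tl_x)) < 1e-9 && abs(tl_y - round(tl_y)) < 1e-9) {
      tile <- scene[round(tl_y) + 1:T, round(tl_x) + 1:T]
    } else {
      tile <- .bilinear(scene, xs, ys)
    }
  }
  tile <- matrix(tile, T, T)

  atten <- (1 - optics$snr_falloff)^radius
  if (atten < 1) {
    m <- mean(tile)
    tile <- m + (tile - m) * atten
  }

  # circular beam boundary: pixel deflection position relative to optic axis
  clipped <- FALSE
  if (is.finite(optics$boundary_radius_px)) {
    cr <- spec$grid_rows %/% 2L; cc <- spec$grid_cols %/% 2L
    # optic axis sits at the centre of the centre subtile
    ax_x <- (cc + 0.5) * spec$pitch_px + (T - spec$pitch_px) / 2
    ax_y <- (cr + 0.5) * spec$pitch_px + (T - spec$pitch_px) / 2
    px <- matrix(rep(gp[["col"]] * spec$pitch_px + 0:(T - 1), each = T), T, T)
    py <- matrix(rep(gp[["row"]] * spec$pitch_px + 0:(T - 1), T), T, T)
    out <- (px - ax_x)^2 + (py - ax_y)^2 > optics$boundary_radius_px^2
    if (any(out)) {
      tile[out] <- mean(tile[!out])
      clipped <- TRUE
    }
  }

  exposure_ms <- exposure_s * 1000
  mean_counts <- NA_real_
  if (is.finite(optics$dose_per_ms)) {
    dose <- optics$dose_per_ms * exposure_ms
    tile <- with_seed(seed, {
      counts <- stats::rpois(length(tile), pmax(0, tile) * dose)
      if (optics$read_noise_sd > 0)
        counts <- counts + stats::rnorm(length(tile),
                                        sd = optics$read_noise_sd * dose)
      matrix(pmax(0, counts) / dose, T, T)
    })
    mean_counts <- mean(tile) * dose
  } else if (optics$read_noise_sd > 0) {
    tile <- with_seed(seed, pmax(0, tile + matrix(
      stats::rnorm(length(tile), sd = optics$read_noise_sd), T, T)))
  }

  list(
    tile = tile,
    truth = list(
      subtile_i = subtile_index[1], subtile_j = subtile_index[2],
      x_px = tl_x, y_px = tl_y,
      radius = radius, attenuation = atten,
      distortion = coeffs, clipped = clipped,
      seed = seed, exposure_ms = exposure_ms,
      dose = optics$dose_per_ms * exposure_ms,
      mean_counts = mean_counts
    )
  )
}

#' Simulate acquisition of a full montage
#'
#' Acquires every tile of the plan — serpentine order over supertiles,
#' spiral order within each supertile — with per-tile seeds derived from
#' `(seed, supertile, subtile)` so any tile is reproducible in isolation.
#' Optional Gaussian stage jitter (one draw per stage position) perturbs the
#' supertile origin; the truth manifest records the jittered offsets.
#'
#' @param plan A [plan_montage()] object (its spec's `tile_px` sets the tile
#'   size).
#' @param scene A scene at least as large as the plan's montage extent, plus
#'   a `ceiling(4 * jitter_sd_px)` margin per side when jitter is injected.
#' @param optics An [optics_model()].
#' @param exposure_s Exposure time (s).
#' @param seed Montage seed.
#' @param jitter_sd_px Stage jitter s.d. in pixels (default 0).
#' @return An object of class `acquisition_result`: list with `tiles` (named
#'   list of matrices, names `s<k>_r<row>c<col>_t<i><j>`), `manifest` (data
#'   frame, one row per tile, true offsets/flags/seeds), `distortions`
#'   (per-tile coefficient records, same order), `plan`, `optics`, `seed`.
#' @export
acquire_montage <- function(plan, scene, optics, exposure_s = 0.12,
                            seed = 1, jitter_sd_px = 0) {
  stopifnot(inherits(plan, "montage_plan"))
  # jitter can push edge tiles outward; reserve a safety margin in the scene
  margin <- ceiling(4 * jitter_sd_px)
  need_w <- plan$montage_extent_px[["width"]] + 2L * margin
  need_h <- plan$montage_extent_px[["height"]] + 2L * margin
  if (ncol(scene) < need_w || nrow(scene) < need_h)
    stop(sprintf(
      "scene %d x %d is smaller than required extent %d x %d (montage extent plus %d px jitter margin per side)",
      ncol(scene), nrow(scene), need_w, need_h, margin), call. = FALSE)
  spec <- plan$spec
  ord <- plan$subtile_order$order
  pos <- plan$stage_positions
  tiles <- list()
  distortions <- list()
  rows <- vector("list", nrow(pos) * nrow(ord))
  k <- 0L
  for (s in seq_len(nrow(pos))) {
    jit <- if (jitter_sd_px > 0)
      with_seed(tile_seed(seed, s, 0L), stats::rnorm(2, 0, jitter_sd_px))
    else c(0, 0)
    origin <- c(pos$x_px[s] + margin + jit[1], pos$y_px[s] + margin + jit[2])
    for (t in seq_len(nrow(ord))) {
      k <- k + 1L
      ts <- tile_seed(seed, s, t)
      acq <- acquire_subtile(scene, origin, ord[t, ], spec, optics,
                             exposure_s, ts)
      nm <- sprintf("s%d_r%dc%d_t%d%d", s, pos$row[s], pos$col[s],
                    ord[t, 1], ord[t, 2])
      tiles[[nm]] <- acq$tile
      distortions[[nm]] <- acq$truth$distortion
      tr <- acq$truth
      rows[[k]] <- data.frame(
        name = nm, supertile = s, st_row = pos$row[s], st_col = pos$col[s],
        subtile_i = tr$subtile_i, subtile_j = tr$subtile_j,
        x_px = tr$x_px, y_px = tr$y_px,
        nominal_x_px = tr$x_px - jit[1], nominal_y_px = tr$y_px - jit[2],
        radius = tr$radius, attenuation = tr$attenuation,
        clipped = tr$clipped, seed = tr$seed,
        exposure_ms = tr$exposure_ms, mean_counts = tr$mean_counts,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(
    tiles = tiles,
    manifest = do.call(rbind, rows),
    distortions = distortions,
    plan = plan, optics = optics, seed = seed,
    jitter_sd_px = jitter_sd_px, exposure_s = exposure_s
  ), class = "acquisition_result")
}

#' Write an acquisition result to disk
#'
#' Tiles as single-channel 16-bit TIFFs plus a JSON manifest carrying the
#' full ground truth (offsets, distortion coefficients, seeds).
#'
#' @param acq An [acquire_montage()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_acquisition <- function(acq, dir) {
  stopifnot(inherits(acq, "acquisition_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(acq$tiles))
    write_tile(acq$tiles[[nm]], file.path(dir, paste0(nm, ".tif")))
  manifest <- list(
    seed = acq$seed, jitter_sd_px = acq$jitter_sd_px,
    exposure_s = acq$exposure_s,
    optics = unclass(acq$optics),
    plan = jsonlite::fromJSON(write_plan_json(acq$plan)),
    tiles = acq$manifest,
    distortions = acq$distortions,
    version = as.character(utils::packageVersion("beamtile"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
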