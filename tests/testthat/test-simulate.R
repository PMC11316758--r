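test_that("specimen generation is deterministic and textured", {
  s1 <- make_specimen(300, 200, seed = 5)
  s2 <- make_specimen(300, 200, seed = 5)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(200L, 300L))
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_gt(sd(s1), 0.01)
  expect_false(identical(s1, make_specimen(300, 200, seed = 6)))
})

test_that("zero feature density leaves a band-limited background", {
  p <- specimen_params(membrane_density = 0, blob_density = 0)
  s <- make_specimen(256, 256, seed = 3, params = p)
  expect_equal(mean(s), p$background_level, tolerance = 0.02)
  expect_equal(sd(s), p$background_sd, tolerance = 0.02)
})

test_that("specimen power spectrum decays with frequency", {
  s <- fixture_scene(512, 512, 21)
  ps <- radial_power_spectrum(s)
  keep <- ps$power > 0 & ps$freq_bins > 0.01
  fit <- stats::lm(log(ps$power[keep]) ~ log(ps$freq_bins[keep]))
  expect_lt(coef(fit)[2], 0)
})

test_that("centre subtile with ideal optics equals the scene crop", {
  sc <- fixture_scene(900, 900, 21)
  spec <- small_spec()
  acq <- acquire_subtile(sc, c(17, 31), c(0, 0), spec, optics_model(),
                         seed = 2)
  crop <- unclass(sc)[31 + spec$pitch_px + 1:256, 17 + spec$pitch_px + 1:256]
  expect_identical(acq$tile, crop)
  expect_equal(acq$truth$radius, 0)
  expect_null(acq$truth$distortion)
  expect_false(acq$truth$clipped)
  expect_error(
    acquire_subtile(sc, c(800, 800), c(1, -1), spec, optics_model()),
    "exceeds scene")
})

test_that("distortion scales with deflection radius and the truth record
           reconstructs the acquired tile exactly", {
  sc <- fixture_scene(900, 900, 21)
  spec <- small_spec()
  opt <- optics_model(distortion_scale = 4)
  # independent bilinear sampler (0-based coords, border clamp)
  sample_bilinear <- function(img, x, y) {
    h <- nrow(img); w <- ncol(img)
    x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
    x0 <- floor(x); y0 <- floor(y)
    x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
    fx <- x - x0; fy <- y - y0
    ix <- function(yy, xx) img[cbind(as.vector(yy) + 1, as.vector(xx) + 1)]
    v00 <- ix(y0, x0); v10 <- ix(y1, x0)
    v01 <- ix(y0, x1); v11 <- ix(y1, x1)
    (1 - as.vector(fx)) * ((1 - as.vector(fy)) * v00 + as.vector(fy) * v10) +
      as.vector(fx) * ((1 - as.vector(fy)) * v01 + as.vector(fy) * v11)
  }
  for (idx in list(c(1, 0), c(1, 1), c(-1, 1))) {
    acq <- acquire_subtile(sc, c(10, 10), idx, spec, opt, seed = 9)
    r <- sqrt(sum(idx^2))
    df <- distortion_field(spec$tile_px, acq$truth$distortion)
    maxmag <- max(sqrt(df$dx^2 + df$dy^2))
    expect_equal(maxmag, 4 * r, tolerance = 0.02)
    # rebuild the tile from the stored coefficients alone
    T <- spec$tile_px
    xg <- matrix(rep(acq$truth$x_px + 0:(T - 1), each = T), T, T)
    yg <- matrix(rep(acq$truth$y_px + 0:(T - 1), T), T, T)
    rebuilt <- matrix(sample_bilinear(unclass(sc), xg + df$dx, yg + df$dy),
                      T, T)
    expect_equal(rebuilt, acq$tile, tolerance = 1e-12)
  }
})

test_that("contrast attenuation follows (1 - falloff)^radius", {
  sc <- fixture_scene(900, 900, 21)
  spec <- small_spec()
  opt <- optics_model(snr_falloff = 0.2)
  ctr <- acquire_subtile(sc, c(5, 5), c(0, 0), spec, opt, seed = 1)$tile
  for (idx in list(c(1, 0), c(1, 1))) {
    t2 <- acquire_subtile(sc, c(5, 5), idx, spec, opt, seed = 1)
    r <- sqrt(sum(idx^2))
    expect_equal(t2$truth$attenuation, 0.8^r)
    # realized contrast matches the recorded attenuation
    crop_sd <- sd(acquire_subtile(sc, c(5, 5), idx, spec, optics_model(),
                                  seed = 1)$tile)
    expect_equal(sd(t2$tile), crop_sd * 0.8^r, tolerance = 1e-10)
  }
})

test_that("tiles deflected past the beam boundary are masked and flagged", {
  sc <- fixture_scene(900, 900, 21)
  spec <- small_spec()
  opt <- optics_model(boundary_radius_px = 250)
  ctr <- acquire_subtile(sc, c(5, 5), c(0, 0), spec, opt, seed = 1)
  expect_false(ctr$truth$clipped)
  corner <- acquire_subtile(sc, c(5, 5), c(1, 1), spec, opt, seed = 1)
  expect_true(corner$truth$clipped)
  ideal <- acquire_subtile(sc, c(5, 5), c(1, 1), spec, optics_model(),
                           seed = 1)
  # masked pixels were replaced by the in-boundary mean
  n_masked <- sum(corner$tile != ideal$tile)
  expect_gte(n_masked / length(corner$tile), 0.5)
})

test_that("counts are linear in exposure with shot + read noise", {
  sc <- fixture_scene(900, 900, 21)
  spec <- small_spec()
  opt <- optics_model(dose_per_ms = 10, read_noise_sd = 0.01)
  exposures <- c(30, 40, 120, 240)
  counts <- vapply(exposures, function(e)
    acquire_subtile(sc, c(5, 5), c(0, 0), spec, opt, exposure_s = e / 1000,
                    seed = 7)$truth$mean_counts, numeric(1))
  fit <- stats::lm(counts ~ 0 + exposures)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum(counts^2)
  expect_gt(1 - ss_res / ss_tot, 0.99)
  expect_equal(counts[3] / counts[2], 3.0, tolerance = 0.02)
})

test_that("montage acquisition is deterministic with exact truth offsets", {
  plan <- small_plan(2)
  sc <- fixture_scene(plan$montage_extent_px[["width"]],
                      plan$montage_extent_px[["height"]], 11)
  a1 <- acquire_montage(plan, sc, optics_model(), seed = 4)
  a2 <- acquire_montage(plan, sc, optics_model(), seed = 4)
  expect_identical(a1$tiles, a2$tiles)
  expect_equal(nrow(a1$manifest), plan$n_tiles)
  expect_equal(anyDuplicated(a1$manifest$name), 0L)

  # identity optics: every tile equals its scene crop
  m <- a1$manifest
  for (k in c(1, 5, 9, 10, nrow(m))) {
    crop <- unclass(sc)[m$y_px[k] + 1:256, m$x_px[k] + 1:256]
    expect_identical(a1$tiles[[m$name[k]]], crop)
  }

  # single-supertile plan: nominal offsets on the pitch grid
  p1 <- small_plan(1)
  sc1 <- fixture_scene(p1$montage_extent_px[["width"]],
                       p1$montage_extent_px[["height"]], 11)
  a <- acquire_montage(p1, sc1, optics_model(), seed = 1)
  expect_equal(nrow(a$manifest), 9L)
  expect_setequal(a$manifest$x_px, c(0, 1, 2) * p1$spec$pitch_px)
  expect_setequal(a$manifest$y_px, c(0, 1, 2) * p1$spec$pitch_px)

  expect_error(acquire_montage(plan, sc[1:100, ], optics_model(), seed = 1),
               "smaller than required")
})

test_that("noise-free overlap strips of adjacent subtiles are identical", {
  p1 <- small_plan(1)
  sc <- fixture_scene(p1$montage_extent_px[["width"]],
                      p1$montage_extent_px[["height"]], 11)
  a <- acquire_montage(p1, sc, optics_model(), seed = 1)
  m <- a$manifest
  ov <- p1$spec$intra_overlap_px
  T <- p1$spec$tile_px
  ctr <- a$tiles[[m$name[m$subtile_i == 0 & m$subtile_j == 0]]]
  east <- a$tiles[[m$name[m$subtile_i == 1 & m$subtile_j == 0]]]
  expect_identical(ctr[, (T - ov + 1):T], east[, 1:ov])
  north <- a$tiles[[m$name[m$subtile_i == 0 & m$subtile_j == 1]]]
  expect_identical(ctr[1:ov, ], north[(T - ov + 1):T, ])
})

test_that("measured spectral SNR decreases with deflection radius", {
  spec <- small_spec()
  opt <- optics_model(dose_per_ms = 3, read_noise_sd = 0.02,
                      snr_falloff = 0.25)
  flat <- matrix(0.5, 900, 900)
  by_radius <- sapply(1:5, function(s) {
    sc <- fixture_scene(900, 900, 30 + s)
    sapply(list(c(0, 0), c(1, 0), c(1, 1)), function(idx) {
      img <- acquire_subtile(sc, c(5, 5), idx, spec, opt, seed = s)$tile
      noise <- lapply(1:2, function(k)
        acquire_subtile(flat, c(5, 5), idx, spec, opt, seed = 100 * s + k)$tile)
      ssnr(img, noise, n_bins = 32)$spectral_snr
    })
  })
  means <- rowMeans(by_radius)
  expect_gte(means[1], means[2])  # centre >= edge
  expect_gte(means[2], means[3])  # edge >= corner
})
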