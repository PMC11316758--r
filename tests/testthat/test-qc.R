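test_that("radial power spectrum: degenerate, sinusoid and Parseval cases", {
  expect_true(all(radial_power_spectrum(matrix(3, 64, 64))$power == 0))

  # pure sinusoid concentrates power in the bin containing f0 (no window so
  # the peak is not smeared)
  n <- 128; f0 <- 0.2
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  ps <- radial_power_spectrum(sin(2 * pi * f0 * x), window = "none")
  near <- abs(ps$freq_bins - f0) < 0.02
  frac <- sum(ps$power[near] * ps$counts[near]) / sum(ps$power * ps$counts)
  expect_gt(frac, 0.9)

  # binned power bookkeeping: sum over bins == total non-DC power
  set.seed(31)
  m <- matrix(rnorm(96 * 96), 96, 96)
  for (w in c("none", "hann")) {
    p2 <- radial_power_spectrum(m, window = w)
    expect_equal(sum(p2$power * p2$counts), p2$total_power)
  }
  expect_error(radial_power_spectrum(matrix(0, 8, 8)), "32 x 32")
})

test_that("radial spectrum is invariant to 90-degree rotation", {
  s <- fixture_scene(256, 256, 40)
  a <- radial_power_spectrum(unclass(s))
  b <- radial_power_spectrum(t(unclass(s))[, 256:1])
  expect_equal(a$power, b$power, tolerance = 1e-8)
})

test_that("ssnr recovers a flat a^2/b^2 ratio and vanishes for pure noise", {
  set.seed(77)
  a <- 0.3; b <- 0.15
  n <- 512
  img <- matrix(rnorm(n^2, sd = a), n, n) + matrix(rnorm(n^2, sd = b), n, n)
  noise <- matrix(rnorm(n^2, sd = b), n, n)
  curve <- ssnr(img, noise, n_bins = 24)
  expect_true(all(abs(curve$snr / (a^2 / b^2) - 1) < 0.2))
  expect_equal(curve$spectral_snr, 0.5 * a^2 / b^2, tolerance = 0.1)

  # image statistically identical to noise: spectral SNR ~ 0 (over 10 draws)
  nulls <- replicate(10, {
    n1 <- matrix(rnorm(128^2), 128, 128)
    n2 <- matrix(rnorm(128^2), 128, 128)
    ssnr(n1, n2, n_bins = 24)$spectral_snr
  })
  expect_lt(mean(nulls), 0.05 * curve$spectral_snr)

  # doubling noise variance at fixed signal decreases spectral SNR
  worse <- sapply(1:5, function(k) {
    sig <- matrix(rnorm(n^2, sd = a), n, n)
    s1 <- ssnr(sig + matrix(rnorm(n^2, sd = b), n, n),
               matrix(rnorm(n^2, sd = b), n, n), n_bins = 24)$spectral_snr
    s2 <- ssnr(sig + matrix(rnorm(n^2, sd = b * sqrt(2)), n, n),
               matrix(rnorm(n^2, sd = b * sqrt(2)), n, n),
               n_bins = 24)$spectral_snr
    s2 < s1
  })
  expect_true(all(worse))
})

test_that("ssnr is invariant to a common positive gain", {
  s <- unclass(fixture_scene(256, 256, 40))
  set.seed(5)
  nz <- matrix(rnorm(256^2, sd = 0.05), 256, 256)
  c1 <- ssnr(s + nz, nz, n_bins = 24)
  c2 <- ssnr(7.3 * (s + nz), 7.3 * nz, n_bins = 24)
  expect_equal(c1$snr, c2$snr, tolerance = 1e-10)
  expect_error(ssnr(s, matrix(0, 10, 10)), "shape")
})

test_that("focus score drops under blur and matches flat-spectrum geometry", {
  s <- unclass(fixture_scene(256, 256, 40))
  blurred <- beamtile:::.fft_blur(s, 2)
  expect_lt(focus_score(blurred), focus_score(s))
  expect_equal(focus_score(matrix(1, 64, 64)), 0)

  # white noise: score ~ fraction of spectral elements above the cutoff
  set.seed(9)
  wn <- matrix(rnorm(256^2), 256, 256)
  r <- beamtile:::.freq_radius(256, 256)
  for (cutoff in c(0.3, 0.5, 0.7)) {
    geom <- mean(r[-1] > cutoff * 0.5)
    expect_equal(focus_score(wn, cutoff, window = "none"), geom,
                 tolerance = 0.05)
  }
  expect_error(focus_score(wn, 1.5), "cutoff")
})

test_that("ncc matches its direct-summation oracle and edge cases", {
  set.seed(12)
  for (k in 1:10) {
    a <- matrix(rnorm(144), 12, 12)
    b <- matrix(rnorm(144), 12, 12)
    oracle <- 0
    am <- mean(a); bm <- mean(b)
    num <- 0; da <- 0; db <- 0
    for (i in 1:12) for (j in 1:12) {
      num <- num + (a[i, j] - am) * (b[i, j] - bm)
      da <- da + (a[i, j] - am)^2
      db <- db + (b[i, j] - bm)^2
    }
    expect_equal(ncc(a, b), num / sqrt(da * db), tolerance = 1e-10)
  }
  a <- matrix(rnorm(64), 8, 8)
  expect_equal(ncc(a, a), 1)
  expect_equal(ncc(a, -a), -1)
  expect_true(is.na(ncc(a, matrix(2, 8, 8))))
  expect_error(ncc(a, matrix(0, 4, 4)), "shape")
})

test_that("displacement field: identity, pure translation, smooth warp", {
  ref <- unclass(fixture_scene(512, 512, 41))

  fd0 <- displacement_field(ref, ref, grid_spacing = 64, block_size = 32,
                            search_radius = 6)
  expect_true(all(fd0$points$valid))
  expect_equal(max(abs(c(fd0$points$dx, fd0$points$dy))), 0)

  # pure translation by (3, -2)
  sh <- matrix(mean(ref), 512, 512)
  sh[1:(512 - 2), 4:512] <- ref[3:512, 1:509]
  fdt <- displacement_field(ref, sh, grid_spacing = 64, block_size = 32,
                            search_radius = 6)
  ok <- fdt$points$valid
  expect_gt(mean(ok), 0.9)
  expect_equal(fdt$points$dx[ok], rep(3, sum(ok)), tolerance = 0.05)
  expect_equal(fdt$points$dy[ok], rep(-2, sum(ok)), tolerance = 0.05)

  # known smooth synthetic field, max 15 px: recovered RMS error < 0.5 px
  coeffs <- list(ax = c(0.2, 0.8, -0.3, 0.4, 0.1, -0.5, 0.3),
                 ay = c(-0.1, 0.3, 0.7, -0.2, 0.5, 0.2, -0.4))
  n <- 33
  u <- matrix(rep(seq(-1, 1, length.out = n), each = n), n, n)
  v <- t(u); r2 <- u^2 + v^2
  ev <- function(a) a[1] + a[2] * u + a[3] * v + a[4] * u^2 + a[5] * u * v +
    a[6] * v^2 + a[7] * u * r2
  coeffs$amp_scale <- 15 / max(sqrt(ev(coeffs$ax)^2 + ev(coeffs$ay)^2))
  df <- distortion_field(512, coeffs)
  expect_equal(max(sqrt(df$dx^2 + df$dy^2)), 15, tolerance = 0.05)
  # pull-back warp: warped(x) = ref(x + d(x))
  xg <- matrix(rep(0:511, each = 512), 512, 512)
  yg <- matrix(rep(0:511, 512), 512, 512)
  warped <- matrix(beamtile:::.bilinear(ref, xg + df$dx, yg + df$dy), 512, 512)
  fdw <- displacement_field(ref, warped, grid_spacing = 48, block_size = 32,
                            search_radius = 17)
  p <- fdw$points[fdw$points$valid, ]
  expect_gt(nrow(p), 40)
  # features move by approximately -d at their location
  idx <- cbind(p$y + 1, p$x + 1)
  errx <- p$dx + df$dx[idx]
  erry <- p$dy + df$dy[idx]
  expect_lt(sqrt(mean(errx^2 + erry^2)), 0.5)
})

test_that("forward and inverse displacement fields compose to ~zero", {
  ref <- unclass(fixture_scene(384, 384, 42))
  coeffs <- list(ax = c(0, 1, 0.5, 0, 0, 0, 0), ay = c(0, -0.3, 1, 0, 0, 0, 0),
                 amp_scale = 4)
  df <- distortion_field(384, coeffs)
  xg <- matrix(rep(0:383, each = 384), 384, 384)
  yg <- matrix(rep(0:383, 384), 384, 384)
  warped <- matrix(beamtile:::.bilinear(ref, xg + df$dx, yg + df$dy), 384, 384)
  fwd <- displacement_field(ref, warped, grid_spacing = 48, block_size = 32,
                            search_radius = 8)
  inv <- displacement_field(warped, ref, grid_spacing = 48, block_size = 32,
                            search_radius = 8)
  pf <- fwd$points; pi_ <- inv$points
  ok <- pf$valid & pi_$valid
  # compose: d_fwd(q) + d_inv(q + d_fwd(q)) ~ 0; fields are smooth enough to
  # look the inverse up at the same grid point
  cx <- pf$dx[ok] + pi_$dx[ok]
  cy <- pf$dy[ok] + pi_$dy[ok]
  expect_lt(sqrt(mean(cx^2 + cy^2)), 0.75)
})

test_that("curve CSV export round-trips", {
  s <- unclass(fixture_scene(256, 256, 40))
  ps <- radial_power_spectrum(s, n_bins = 16)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(ps, path)
  back <- read.csv(path)
  expect_equal(back$freq, ps$freq_bins)
  expect_equal(back$power, ps$power)
})
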