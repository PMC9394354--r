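test_that("generated bundles are reproducible, +Y-monotone and inside the 45-degree cone", {
  shape <- c(40, 80, 40)
  b1 <- generate_bundle(shape, n_filaments = 8, seed = 3)
  b2 <- generate_bundle(shape, n_filaments = 8, seed = 3)
  expect_identical(b1$filaments, b2$filaments)
  expect_length(b1, 8L)
  for (p in b1$filaments) {
    dy <- diff(p[, 2])
    expect_true(all(dy == 1))                       # one voxel per step in Y
    lat <- sqrt(diff(p[, 1])^2 + diff(p[, 3])^2)
    expect_true(all(lat <= dy + 1e-9))              # within 45 degrees of +Y
  }
})

test_that("zero jitter gives perfectly straight filaments", {
  b <- generate_bundle(c(30, 50, 30), n_filaments = 4, jitter = 0, seed = 5)
  for (p in b$filaments) {
    expect_equal(max(abs(diff(p[, 1]))), 0)
    expect_equal(max(abs(diff(p[, 3]))), 0)
  }
})

test_that("rasterization fills straight spans, ignores empty models, and matches a fine-sampling oracle on diagonals", {
  shape <- c(20, 20, 20)
  m <- filament_model(list(rbind(c(10, 5, 10), c(10, 14, 10))))
  occ <- rasterize_model(m, shape)$data
  expect_equal(sum(occ), 10)
  expect_true(all(occ[10, 5:14, 10] == 1))

  expect_true(all(rasterize_model(filament_model(list()), shape)$data == 0))

  # diagonal lines: the voxel set must equal the brute-force nearest-voxel
  # supercover obtained by very dense sampling
  set.seed(8)
  for (rep in 1:5) {
    a <- runif(3, 3, 8); bpt <- runif(3, 12, 17)
    dm <- filament_model(list(rbind(a, bpt)))
    got <- which(rasterize_model(dm, shape)$data > 0, arr.ind = TRUE)
    tt <- seq(0, 1, length.out = 50001)
    fine <- unique(floor(cbind(a[1] + tt * (bpt[1] - a[1]),
                               a[2] + tt * (bpt[2] - a[2]),
                               a[3] + tt * (bpt[3] - a[3])) + 0.5))
    expect_setequal(apply(got, 1, paste, collapse = ","),
                    apply(fine, 1, paste, collapse = ","))
  }
})

test_that("volumization is a unit-sum Gaussian with the requested FWHM and amplification", {
  shape <- c(31, 31, 31)
  occ <- density_grid(array(0, shape), voxel_spacing = 1)
  occ$data[16, 16, 16] <- 1
  v <- volumize(occ, psf_fwhm = 5, amplification = 1.85)
  # impulse response: total mass = amplification, peak at the impulse
  expect_equal(sum(v$data), 1.85, tolerance = 1e-6)
  expect_equal(which.max(v$data), which.max(occ$data))
  # FWHM: response falls to half its max at +-FWHM/2 along an axis
  prof <- v$data[, 16, 16]
  half <- v$data[16, 16, 16] / 2
  xs <- seq_len(31) - 16
  at <- approx(prof[16:23], xs[16:23], xout = half)$y  # monotone flank only
  expect_equal(at, 2.5, tolerance = 0.08)

  # mass scales with the occupied count
  occ$data[10, 10, 10] <- 1
  expect_equal(sum(volumize(occ, 5, 2)$data), 2 * 2, tolerance = 1e-6)
})

test_that("colored noise has the requested spectral slope and is seed-reproducible", {
  shape <- c(64, 64, 64)
  n0 <- colored_noise(shape, noise_exponent = 0, seed = 9)
  expect_equal(mean(n0$data), 0, tolerance = 1e-12)
  expect_equal(sd(n0$data), 1, tolerance = 1e-12)

  radial_psd <- function(x) {
    p <- abs(fft(x))^2 / length(x)
    f <- tomofil:::radial_freq(dim(x))
    bins <- cut(c(f), breaks = seq(0.02, 0.45, by = 0.03))
    tapply(c(p), bins, mean)
  }
  # white limit: flat radial PSD
  psd0 <- radial_psd(n0$data)
  expect_lt(max(abs(log(psd0 / mean(psd0)))), 0.35)

  # alpha = 2: fitted log-log slope ~ -2
  n2 <- colored_noise(shape, noise_exponent = 2, seed = 9)
  f_mid <- seq(0.035, 0.425, by = 0.03)
  psd2 <- radial_psd(n2$data)
  fit <- lm(log(psd2) ~ log(f_mid))
  expect_equal(unname(coef(fit)[2]), -2, tolerance = 0.3)

  expect_identical(colored_noise(shape, 2, seed = 9)$data, n2$data)
  expect_false(identical(colored_noise(shape, 2, seed = 10)$data, n2$data))
})

test_that("missing-wedge masking is identity at angle 0, elongates along Z, and removes power", {
  shape <- c(32, 32, 32)
  set.seed(4)
  g <- density_grid(array(rnorm(prod(shape)), shape))
  same <- apply_missing_wedge(g, 0)
  expect_equal(same$data, g$data, tolerance = 1e-10)

  imp <- density_grid(array(0, shape))
  imp$data[17, 17, 17] <- 1
  w <- apply_missing_wedge(imp, 30)
  # the density (positive) part of the point response is elongated along
  # the beam axis Z; the X side lobes are negative (edge sharpening)
  idx <- seq_len(32) - 17
  px <- pmax(w$data[, 17, 17], 0)
  pz <- pmax(w$data[17, 17, ], 0)
  sig_x <- sqrt(sum(px * idx^2) / sum(px))
  sig_z <- sqrt(sum(pz * idx^2) / sum(pz))
  expect_gt(sig_z / sig_x, 1.15)
  expect_lt(w$data[16, 17, 17], 0)
  expect_gt(w$data[17, 17, 18], 0)

  expect_lt(sum(apply_missing_wedge(g, 30)$data^2), sum(g$data^2))
})

test_that("simulated tomograms are deterministic and correlate with the clean signal in the noiseless limit", {
  shape <- c(32, 64, 32)
  b <- generate_bundle(shape, n_filaments = 4, seed = 6)
  s1 <- simulate_tomogram(b, shape, noise_level = 0.6, seed = 11)
  s2 <- simulate_tomogram(b, shape, noise_level = 0.6, seed = 11)
  expect_identical(s1$map$data, s2$map$data)
  expect_identical(s1$truth$data, s2$truth$data)

  s0 <- simulate_tomogram(b, shape, noise_level = 1e-9, wedge_half_angle = 0,
                          seed = 11)
  clean <- volumize(rasterize_model(b, shape))
  expect_gt(cor(c(s0$map$data), c(clean$data)), 0.9999)
})

test_that("noise level is a pure amplitude scale: SNR goes as 1/level^2 and the truth is uncorrupted", {
  shape <- c(32, 64, 32)
  b <- generate_bundle(shape, n_filaments = 4, seed = 6)
  s04 <- simulate_tomogram(b, shape, noise_level = 0.4, seed = 12)
  s10 <- simulate_tomogram(b, shape, noise_level = 1.0, seed = 12)
  expect_equal(s04$calibration$snr / s10$calibration$snr, (1.0 / 0.4)^2,
               tolerance = 1e-9)
  # ground truth identical across levels and binary
  expect_identical(s04$truth$data, s10$truth$data)
  expect_setequal(unique(c(s04$truth$data)), c(0, 1))
})
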