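test_that("DP path density equals exhaustive path enumeration on random grids", {
  set.seed(101)
  for (trial in 1:12) {
    dm <- sample(5:13, 3, replace = TRUE)
    l <- sample(1:4, 1)
    d <- array(runif(prod(dm)), dm)
    g <- density_grid(d)
    fpd <- path_density(g, l, "forward")$data
    bpd <- path_density(g, l, "backward")$data
    for (rep in 1:3) {
      v <- c(sample(dm[1], 1), sample(dm[2], 1), sample(dm[3], 1))
      expect_equal(fpd[v[1], v[2], v[3]],
                   fpd_enumerate(d, v[1], v[2], v[3], l, 1L), tolerance = 1e-12)
      expect_equal(bpd[v[1], v[2], v[3]],
                   fpd_enumerate(d, v[1], v[2], v[3], l, -1L), tolerance = 1e-12)
    }
  }
})

test_that("FPD on an all-ones grid equals l + 1 and bounds hold generally", {
  one <- density_grid(array(1, c(9, 12, 9)))
  for (l in c(1, 3, 5)) {
    f <- path_density(one, l)$data
    expect_equal(f[5, 2, 5], l + 1)
    expect_true(all(f[, seq_len(12 - l), ] == l + 1))
    expect_true(all(f[, (12 - l + 1):12, ] == 0))    # +Y boundary band
  }
  set.seed(7)
  g <- density_grid(array(runif(9 * 12 * 9), c(9, 12, 9)))
  f <- path_density(g, 4)$data
  expect_true(all(f >= 0 & f <= 5))
})

test_that("BPD is the Y-reflection of FPD", {
  set.seed(11)
  d <- array(runif(8 * 10 * 7), c(8, 10, 7))
  g <- density_grid(d)
  bpd <- path_density(g, 3, "backward")$data
  grev <- density_grid(d[, 10:1, , drop = FALSE])
  ref <- path_density(grev, 3, "forward")$data[, 10:1, , drop = FALSE]
  expect_equal(bpd, ref, tolerance = 1e-12)
})

test_that("path density is monotone in the input densities", {
  set.seed(13)
  d <- array(runif(7 * 9 * 7, 0, 0.8), c(7, 9, 7))
  f0 <- path_density(density_grid(d), 3)$data
  for (rep in 1:5) {
    d2 <- d
    v <- c(sample(7, 1), sample(9, 1), sample(7, 1))
    d2[v[1], v[2], v[3]] <- d2[v[1], v[2], v[3]] + 0.2
    f2 <- path_density(density_grid(d2), 3)$data
    expect_true(all(f2 - f0 >= -1e-12))
  }
})

test_that("path density is Y-translation-equivariant in the grid interior", {
  set.seed(17)
  core <- array(runif(7 * 6 * 7), c(7, 6, 7))
  d1 <- array(0, c(7, 15, 7)); d1[, 4:9, ] <- core
  d2 <- array(0, c(7, 15, 7)); d2[, 7:12, ] <- core
  f1 <- path_density(density_grid(d1), 2)$data
  f2 <- path_density(density_grid(d2), 2)$data
  expect_equal(f1[, 4:7, ], f2[, 7:10, ], tolerance = 1e-12)
})

test_that("straight-line accumulation matches its enumeration oracle and never beats the DP", {
  set.seed(19)
  for (trial in 1:6) {
    dm <- sample(6:12, 3, replace = TRUE)
    l <- sample(2:4, 1)
    d <- array(runif(prod(dm)), dm)
    g <- density_grid(d)
    lf <- path_density(g, l, "forward", method = "line")$data
    df <- path_density(g, l, "forward", method = "dp")$data
    expect_true(all(lf <= df + 1e-12))
    for (rep in 1:3) {
      v <- c(sample(dm[1], 1), sample(dm[2] - l, 1), sample(dm[3], 1))
      expect_equal(lf[v[1], v[2], v[3]],
                   line_fpd_enumerate(d, v[1], v[2], v[3], l), tolerance = 1e-12)
    }
  }
})

test_that("line accumulation equals the DP on a straight unit filament", {
  g <- straight_filament_grid(c(11, 12, 11), 6, 6)
  lf <- path_density(g, 5, method = "line")$data
  expect_equal(lf[6, 3, 6], 6)
})

test_that("blending modes agree when FPD == BPD except the product, which squares", {
  set.seed(23)
  g <- density_grid(array(runif(9 * 14 * 9), c(9, 14, 9)))
  fpd <- path_density(g, 3, "forward")
  s <- blend_path_density(fpd, fpd, "sum")
  geo <- blend_path_density(fpd, fpd, "geometric")
  mn <- blend_path_density(fpd, fpd, "minimum")
  pr <- blend_path_density(fpd, fpd, "product")
  expect_equal(s$data, geo$data, tolerance = 1e-12)
  expect_equal(s$data, mn$data, tolerance = 1e-12)
  # the product is the square of the geometric mean before normalization, a
  # monotone transform: the voxel ranking over the valid region is identical
  valid <- geo$data[, 4:11, ]
  expect_equal(order(c(pr$data[, 4:11, ])), order(c(valid)))
})

test_that("blending is symmetric and conjunctive modes vanish where one input is zero", {
  set.seed(29)
  g <- density_grid(array(runif(8 * 14 * 8), c(8, 14, 8)))
  f <- path_density(g, 3, "forward")
  b <- path_density(g, 3, "backward")
  for (m in c("product", "sum", "geometric", "minimum")) {
    expect_equal(blend_path_density(f, b, m)$data,
                 blend_path_density(b, f, m)$data, tolerance = 1e-12,
                 info = m)
  }
  # zero out the forward map in a region away from the Y boundary: the
  # conjunctive blends must be zero there
  fz <- f
  fz$data[4, 7, 4] <- 0
  for (m in c("product", "geometric", "minimum")) {
    cpd <- blend_path_density(fz, b, m)
    expect_equal(cpd$data[4, 7, 4], 0, info = m)
  }
})

test_that("CPD is normalized to [0, 1] with a zeroed Y-boundary band", {
  set.seed(31)
  g <- density_grid(array(runif(8 * 20 * 8), c(8, 20, 8)))
  f <- path_density(g, 5, "forward")
  b <- path_density(g, 5, "backward")
  cpd <- blend_path_density(f, b, "product")
  expect_equal(range(cpd$data), c(0, 1))
  expect_true(all(cpd$data[, c(1:5, 16:20), ] == 0))
})

test_that("enhancement raises filament contrast on a noisy straight filament", {
  set.seed(37)
  dm <- c(15, 30, 15)
  d <- array(runif(prod(dm), 0, 0.6), dm)
  d[8, , 8] <- 1
  cpd <- enhance_map(density_grid(d), l = 5)
  on_f <- cpd$data[8, 10:20, 8]
  off_f <- cpd$data[3, 10:20, 12]
  raw_contrast <- mean(d[8, 10:20, 8]) / mean(d[3, 10:20, 12])
  cpd_contrast <- mean(on_f) / max(mean(off_f), 1e-9)
  expect_gt(cpd_contrast, raw_contrast)
})

test_that("degenerate path-density inputs are rejected", {
  g <- density_grid(array(0.5, c(4, 6, 4)))
  expect_error(path_density(g, 0), ">= 1")
  expect_error(path_density(g, 6), "Y extent")
  bad <- density_grid(array(2, c(4, 6, 4)))
  expect_error(path_density(bad, 2), "normalized")
  f <- path_density(g, 2)
  b <- path_density(density_grid(array(0.5, c(4, 7, 4))), 2, "backward")
  expect_error(blend_path_density(f, b), "identical shapes")
})
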