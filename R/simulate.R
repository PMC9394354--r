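#' Generate a synthetic ground-truth filament bundle
#'
#' Emulates a loosely organized bundle of curved filaments with mean
#' direction +Y. Each filament is a random walk that advances one voxel per
#' step along Y while its lateral velocity follows a smooth (persistent)
#' perturbation process, bounded so the local direction never deviates more
#' than 45 degrees from the bundle axis. Filament anchor points are scattered
#' over a disc in the X-Z cross-section with a minimum mutual separation, so
#' the bundle occupies a sub-region of the volume (as a real bundle does in a
#' tomogram) and spacing between neighbours is variable.
#'
#' @param shape integer vector `(Ni, Nj, Nk)` of the target volume.
#' @param n_filaments number of filaments.
#' @param mean_length mean filament extent along Y in voxels; default spans
#'   nearly the whole Y range.
#' @param length_sd standard deviation of the filament length in voxels.
#' @param bundle_radius radius (voxels) of the cross-section disc holding the
#'   filament anchors; default 38% of the smaller lateral dimension.
#' @param min_separation minimum anchor separation in voxels; default scales
#'   with the disc area per filament.
#' @param jitter maximum lateral speed in voxels per Y-step (must be < 1 so
#'   the 45-degree constraint holds; 0 gives perfectly straight filaments).
#' @param persistence AR(1) memory of the lateral velocity in `[0, 1)`;
#'   larger values give smoother curves.
#' @param voxel_spacing nm per voxel, carried into the model metadata.
#' @param seed RNG seed; identical seeds give identical bundles.
#' @return a [filament_model].
#' @export
generate_bundle <- function(shape, n_filaments = 40, mean_length = NULL,
                            length_sd = 0, bundle_radius = NULL,
                            min_separation = NULL, jitter = 0.25,
                            persistence = 0.95, voxel_spacing = 0.947,
                            seed = 1) {
  stopifnot(length(shape) == 3, jitter >= 0, jitter < 1,
            persistence >= 0, persistence < 1)
  ni <- shape[1]; nj <- shape[2]; nk <- shape[3]
  if (is.null(mean_length)) mean_length <- nj - 6
  if (is.null(bundle_radius)) bundle_radius <- 0.38 * min(ni, nk)
  if (is.null(min_separation))
    min_separation <- 0.75 * sqrt(pi * bundle_radius^2 / max(1, n_filaments))

  with_seed(seed, {
    cx <- (ni + 1) / 2; cz <- (nk + 1) / 2
    anchors <- matrix(NA_real_, 0, 2)
    tries <- 0L
    sep <- min_separation
    while (nrow(anchors) < n_filaments) {
      r <- bundle_radius * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      p <- c(cx + r * cos(th), cz + r * sin(th))
      ok <- nrow(anchors) == 0 ||
        min(sqrt(rowSums((anchors - matrix(p, nrow(anchors), 2,
                                           byrow = TRUE))^2))) >= sep
      if (ok) anchors <- rbind(anchors, p)
      tries <- tries + 1L
      if (tries %% 2000L == 0L) sep <- sep * 0.8  # relax if packing is tight
    }

    sigma <- 0.15 * jitter
    fils <- vector("list", n_filaments)
    for (f in seq_len(n_filaments)) {
      len <- max(2L, round(stats::rnorm(1, mean_length, length_sd)))
      len <- min(len, nj - 2L)
      y0 <- if (len >= nj - 2L) 2L else
        sample(seq(2L, nj - 1L - len), 1L)
      x <- anchors[f, 1]; z <- anchors[f, 2]
      vx <- stats::runif(1, -jitter / 2, jitter / 2)
      vz <- stats::runif(1, -jitter / 2, jitter / 2)
      if (jitter == 0) { vx <- 0; vz <- 0 }
      pts <- matrix(NA_real_, len + 1L, 3L)
      pts[1L, ] <- c(x, y0, z)
      for (t in seq_len(len)) {
        if (jitter > 0) {
          vx <- persistence * vx + sigma * stats::rnorm(1)
          vz <- persistence * vz + sigma * stats::rnorm(1)
          # steer gently back towards the bundle axis near the disc edge
          dx <- cx - x; dz <- cz - z
          dd <- sqrt(dx^2 + dz^2)
          if (dd > bundle_radius) {
            vx <- vx + 0.05 * dx / dd
            vz <- vz + 0.05 * dz / dd
          }
          sp <- sqrt(vx^2 + vz^2)
          if (sp > jitter) { vx <- vx * jitter / sp; vz <- vz * jitter / sp }
        }
        x <- min(max(x + vx, 2), ni - 1)
        z <- min(max(z + vz, 2), nk - 1)
        pts[t + 1L, ] <- c(x, y0 + t, z)
      }
      fils[[f]] <- pts
    }
    filament_model(fils, voxel_spacing)
  })
}

#' Rasterize a filament model into a binary occupancy grid
#'
#' Polyline segments are traversed exactly: the parameter values where the
#' continuous line crosses a voxel-boundary (half-integer) plane in any axis
#' partition it into intervals, each mapping to the nearest voxel of its
#' midpoint. The occupied set therefore equals the full nearest-voxel
#' supercover of the line and paths are gap-free along their length.
#' Out-of-bounds voxels are clipped.
#'
#' @param model a [filament_model].
#' @param shape target `(Ni, Nj, Nk)`.
#' @return a binary [density_grid] (1 = filament voxel).
#' @export
rasterize_model <- function(model, shape) {
  stopifnot(inherits(model, "filament_model"), length(shape) == 3)
  occ <- array(0, shape)
  for (p in model$filaments) {
    v <- rasterize_polyline(p)
    keep <- v[, 1] >= 1 & v[, 1] <= shape[1] &
            v[, 2] >= 1 & v[, 2] <= shape[2] &
            v[, 3] >= 1 & v[, 3] <= shape[3]
    v <- v[keep, , drop = FALSE]
    if (nrow(v)) occ[v] <- 1
  }
  density_grid(occ, model$voxel_spacing)
}

# exact nearest-voxel supercover of a polyline
rasterize_polyline <- function(p) {
  segs <- lapply(seq_len(nrow(p) - 1L), function(s) {
    a <- p[s, ]; b <- p[s + 1L, ]
    d <- b - a
    tt <- c(0, 1)
    for (ax in 1:3) {
      if (d[ax] != 0) {
        lo <- min(a[ax], b[ax]); hi <- max(a[ax], b[ax])
        from <- floor(lo + 0.5) + 0.5
        if (from <= hi) {
          cross <- seq(from, hi, by = 1)
          cross <- cross[cross > lo & cross < hi]
          if (length(cross)) tt <- c(tt, (cross - a[ax]) / d[ax])
        }
      }
    }
    tt <- sort(unique(tt))
    tm <- (tt[-1] + tt[-length(tt)]) / 2
    tm <- c(0, tm, 1)  # include the exact end points
    floor(cbind(a[1] + tm * d[1], a[2] + tm * d[2], a[3] + tm * d[3]) + 0.5)
  })
  unique(do.call(rbind, segs))
}

# dense piecewise-linear resampling of an n x 3 polyline
interpolate_polyline <- function(p, step = 0.1) {
  if (nrow(p) < 2) return(p)
  out <- vector("list", nrow(p) - 1L)
  for (s in seq_len(nrow(p) - 1L)) {
    a <- p[s, ]; b <- p[s + 1L, ]
    nseg <- max(1L, ceiling(max(abs(b - a)) / step))
    tt <- seq(0, 1, length.out = nseg + 1L)
    if (s < nrow(p) - 1L) tt <- tt[-length(tt)]  # avoid duplicated joints
    out[[s]] <- cbind(a[1] + tt * (b[1] - a[1]),
                      a[2] + tt * (b[2] - a[2]),
                      a[3] + tt * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

#' Volumize an occupancy grid with a Gaussian point-spread
#'
#' Filament voxels are scaled by an amplification factor and convolved with
#' an isotropic Gaussian kernel whose full width at half maximum matches the
#' filament diameter (5 nm for actin). The kernel is truncated at 4 sigma and
#' normalized to unit sum, so total mass equals `amplification` times the
#' occupied voxel count (away from the volume edges).
#'
#' @param occupancy a binary [density_grid].
#' @param psf_fwhm kernel full width at half maximum in nm.
#' @param amplification factor applied to filament voxels before convolution.
#' @return a [density_grid].
#' @export
volumize <- function(occupancy, psf_fwhm = 5, amplification = 1.85) {
  stopifnot(inherits(occupancy, "density_grid"), psf_fwhm > 0)
  sigma <- (psf_fwhm / occupancy$voxel_spacing) / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  out <- cpp_sepconv(amplification * occupancy$data, dim(occupancy$data), kern)
  density_grid(out, occupancy$voxel_spacing, occupancy$origin)
}

#' Colored (power-law) noise volume
#'
#' Zero-mean, unit-variance Gaussian noise whose radially averaged power
#' spectral density follows a `|f|^-alpha` power law. `noise_exponent = 0`
#' gives white noise; larger exponents shift power towards low frequencies,
#' emulating the correlated background of experimental tomograms.
#'
#' @param shape `(Ni, Nj, Nk)`.
#' @param noise_exponent spectral slope alpha of the power law (>= 0).
#' @param seed RNG seed.
#' @param voxel_spacing nm per voxel for the returned grid.
#' @return a [density_grid].
#' @export
colored_noise <- function(shape, noise_exponent = 0.5, seed = 1,
                          voxel_spacing = 0.947) {
  stopifnot(length(shape) == 3, noise_exponent >= 0)
  with_seed(seed, {
    w <- array(stats::rnorm(prod(shape)), shape)
    if (noise_exponent == 0) {
      out <- w
    } else {
      amp <- radial_freq(shape)^(-noise_exponent / 2)
      amp[1, 1, 1] <- 0  # drop DC: keep the field zero-mean
      f <- stats::fft(w) * amp
      out <- Re(stats::fft(f, inverse = TRUE)) / prod(shape)
    }
    out <- (out - mean(out)) / stats::sd(out)
    density_grid(out, voxel_spacing)
  })
}

# |f| on the 3D FFT frequency lattice (cycles per voxel)
radial_freq <- function(shape) {
  f1 <- function(n) {
    f <- (seq_len(n) - 1) / n
    ifelse(f > 0.5, f - 1, f)
  }
  fx <- f1(shape[1]); fy <- f1(shape[2]); fz <- f1(shape[3])
  sqrt(outer(outer(fx^2, fy^2, `+`), fz^2, `+`))
}

#' Apply a missing-wedge Fourier mask
#'
#' Emulates the unsampled wedge of Fourier space caused by the limited tilt
#' range of the specimen holder. With the tilt axis along Y (the filament
#' mean direction) and the beam along Z, all frequency components whose
#' direction in the (fx, fz) plane lies within `wedge_half_angle` of the fz
#' axis are zeroed (the classic double wedge); the fx = fz = 0 line, sampled
#' at every tilt, is kept. Features become elongated along Z.
#'
#' @param grid a [density_grid].
#' @param wedge_half_angle half-angle of the missing wedge in degrees
#'   (`30` corresponds to a +/-60 degree tilt range); `0` disables masking.
#' @return a [density_grid].
#' @export
apply_missing_wedge <- function(grid, wedge_half_angle = 30) {
  stopifnot(inherits(grid, "density_grid"),
            wedge_half_angle >= 0, wedge_half_angle < 90)
  if (wedge_half_angle == 0) return(grid)
  shape <- dim(grid$data)
  f1 <- function(n) {
    f <- (seq_len(n) - 1) / n
    ifelse(f > 0.5, f - 1, f)
  }
  fx <- f1(shape[1]); fz <- f1(shape[3])
  ang <- atan2(abs(outer(fx, rep(1, shape[3]))),
               abs(outer(rep(1, shape[1]), fz)))  # angle from the fz axis
  wedge2d <- ang < wedge_half_angle * pi / 180
  wedge2d[1, 1] <- FALSE                          # keep the fx = fz = 0 line
  keep2d <- !wedge2d
  keep3d <- aperm(array(keep2d, c(shape[1], shape[3], shape[2])), c(1, 3, 2))
  ft <- stats::fft(grid$data) * keep3d
  grid$data <- Re(stats::fft(ft, inverse = TRUE)) / prod(shape)
  grid
}

#' Simulate a tomogram from a filament model
#'
#' Full forward simulation: rasterize the model, amplify and volumize with
#' the Gaussian point-spread, add colored noise at the requested level, mask
#' the missing wedge in Fourier space, and min-max normalize. The noise
#' amplitude is calibrated per run so that at `noise_level = 1` the ratio of
#' volumized-signal variance (over the 2-voxel-dilated filament support) to
#' noise variance equals `target_snr_at_level_1`; the noise level is then a
#' pure amplitude scale, so SNR scales as `1 / noise_level^2` and neither the
#' noise color nor the wedge mask depends on the level.
#'
#' @param model a [filament_model] (ground truth).
#' @param shape `(Ni, Nj, Nk)` of the simulated volume.
#' @param noise_level global noise amplitude scale; the reference study
#'   conditions use 0.4, 0.6, 0.8 and 1.0 (1.0 = worst-case noise, 0.6
#'   closest to a typical experimental map).
#' @param target_snr_at_level_1 signal-to-noise variance ratio defining
#'   noise level 1.0 (see the methods vignette for the calibration).
#' @param psf_fwhm,amplification volumization parameters, see [volumize()].
#' @param noise_exponent spectral slope, see [colored_noise()].
#' @param wedge_half_angle missing-wedge half-angle in degrees.
#' @param seed RNG seed for the noise field.
#' @return a list with elements `map` (normalized [density_grid]), `truth`
#'   (pre-corruption binary occupancy [density_grid]), `model`, and
#'   `calibration` (base noise scale, signal variance, realized SNR).
#' @export
simulate_tomogram <- function(model, shape, noise_level = 0.6,
                              target_snr_at_level_1 = 0.025,
                              psf_fwhm = 5, amplification = 1.85,
                              noise_exponent = 0.5, wedge_half_angle = 30,
                              seed = 1) {
  stopifnot(noise_level > 0)
  occ <- rasterize_model(model, shape)
  sig <- volumize(occ, psf_fwhm, amplification)
  support <- cpp_dilate_cheb(occ$data > 0, dim(occ$data), 2L)
  sig_var <- stats::var(sig$data[support])
  base_scale <- sqrt(sig_var / target_snr_at_level_1)
  noise <- colored_noise(shape, noise_exponent, seed, model$voxel_spacing)
  tom <- sig
  tom$data <- sig$data + noise_level * base_scale * noise$data
  tom <- apply_missing_wedge(tom, wedge_half_angle)
  tom <- normalize01(tom)
  list(map = tom, truth = occ, model = model,
       calibration = list(base_noise_scale = base_scale,
                          signal_variance = sig_var,
                          snr = sig_var / (noise_level * base_scale)^2))
}

# evaluate code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
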