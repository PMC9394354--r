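#' Candidate seed points from spatial subdecomposition
#'
#' Decomposes the map into cubes of a user-defined size and returns the
#' highest-density voxel of each cube as a candidate seed point (CSP).
#' Partial cubes at the volume edges also yield a seed; ties break towards
#' the smallest linear voxel index.
#'
#' @param grid a [density_grid] (typically the CPD-enhanced map).
#' @param cube cube edge in voxels (default 5, equal to the path length `l`,
#'   which gives a natural coarse-graining scale).
#' @return integer matrix `n x 3` of 1-based voxel indices (columns
#'   `i`, `j`, `k`).
#' @export
generate_csps <- function(grid, cube = 5) {
  stopifnot(inherits(grid, "density_grid"), cube >= 1)
  m <- cpp_csp(grid$data, dim(grid$data), as.integer(cube)) + 1L
  colnames(m) <- c("i", "j", "k")
  m
}

#' Trace candidate filament segments from seed points
#'
#' From each seed, traces a path of Y-extent `l` in the forward (+Y)
#' direction and records the candidate filament segment (CFS): the seed, the
#' base target with the maximum accumulated path density, the full voxel
#' path, and the normalized path density NPD = FPD / (l + 1) in `[0, 1]`.
#' Seeds closer than `l` to the +Y boundary are skipped.
#'
#' @param grid a [density_grid] with values in `[0, 1]` (raw normalized map
#'   or CPD-enhanced map).
#' @param seeds integer matrix `n x 3` of 1-based seed voxels, e.g. from
#'   [generate_csps()].
#' @param l segment Y-extent in voxels.
#' @param method `"dp"` (bipyramidal dynamic program) or `"line"`
#'   (straight-line accumulation).
#' @param direction `"forward"` or `"backward"`.
#' @return a `cfs` data frame with columns `is, js, ks, ie, je, ke, npd` and
#'   a list column `path` of `(l+1) x 3` voxel matrices; attribute `l`.
#' @export
trace_cfs <- function(grid, seeds, l = 5, method = c("dp", "line"),
                      direction = c("forward", "backward")) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  check_normalized(grid)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  res <- cpp_trace_seeds(grid$data, dim(grid$data), seeds - 1L,
                         as.integer(l),
                         if (direction == "forward") 1L else -1L,
                         if (method == "dp") 0L else 1L)
  ok <- !is.na(res$fpd)
  if (any(!ok))
    message(sum(!ok), " seed(s) too close to the Y boundary were skipped")
  idx <- which(ok)
  dir <- if (direction == "forward") 1L else -1L
  # a CFS is its endpoint pair; its voxels are the straight chord between
  # them, with X(Y) and Z(Y) linearly interpolated and rounded
  paths <- lapply(idx, function(s)
    chord_voxels(seeds[s, ], res$end[s, ] + 1L, l, dir))
  out <- data.frame(is = seeds[idx, 1], js = seeds[idx, 2],
                    ks = seeds[idx, 3],
                    ie = res$end[idx, 1] + 1L, je = res$end[idx, 2] + 1L,
                    ke = res$end[idx, 3] + 1L,
                    npd = res$fpd[idx] / (l + 1))
  out$path <- paths
  attr(out, "l") <- as.integer(l)
  class(out) <- c("cfs", "data.frame")
  out
}

# rounded first-order interpolation in Y from start to end voxel
chord_voxels <- function(start, end, l, dir = 1L) {
  t <- 0:l
  cbind(start[1] + floor((end[1] - start[1]) * t / l + 0.5),
        start[2] + dir * t,
        start[3] + floor((end[3] - start[3]) * t / l + 0.5))
}

#' Bin candidate filament segments by NPD score
#'
#' Groups CFSs into 10 bins of width 0.1 on the NPD scale: bin
#' `floor(npd * 10) + 1`, with `npd = 1` closed into bin 10 (so bin 10 holds
#' scores in `[0.9, 1]`).
#'
#' @param cfs a `cfs` data frame from [trace_cfs()].
#' @return the same data frame with an integer `bin` column added.
#' @export
bin_cfs <- function(cfs) {
  stopifnot(all(cfs$npd >= 0 - 1e-9), all(cfs$npd <= 1 + 1e-9))
  cfs$bin <- pmax(1L, pmin(10L, as.integer(floor(cfs$npd * 10) + 1)))
  cfs
}

#' Detect the threshold bin from the spatial spread of CFS midpoints
#'
#' High-NPD bins hold mostly true filament segments, which stay localized on
#' the bundle; as bins of decreasing NPD are added, false segments picking up
#' noise appear everywhere. Iterating from bin 10 downward and accumulating
#' midpoints, the first bin at which the segments occupy essentially the
#' whole volume (fewer than `cube_frac` of the coarse cubes still hold fewer
#' than `min_count` midpoints) is reported as the threshold bin: the bin that
#' starts introducing false segments.
#'
#' @param cfs a binned `cfs` data frame (see [bin_cfs()]).
#' @param shape map shape `(Ni, Nj, Nk)`.
#' @param coarse_cube edge of the coarse occupancy cubes in voxels. When the
#'   map is smaller than `coarse_cube` in any axis the cube size auto-scales
#'   to `ceiling(shape / 3)` per axis, keeping the spread-test constants.
#'   The cubes must stay comparable to the bundle cross-section: cells much
#'   smaller than the bundle all intersect it and the spread test loses its
#'   bundle-free reference cells.
#' @param cube_frac fraction of empty-ish cubes that still counts as "not
#'   occupying the full volume".
#' @param min_count midpoint count below which a *full* cube counts as
#'   empty-ish. Partial cubes at the volume faces are held to a
#'   volume-prorated count (at least 1), so a sliver one fifth the size of
#'   a full cube is not required to contain the full-cube quota.
#' @return the threshold bin (integer). If even bin 1 leaves the volume
#'   unfilled, returns 1 with a warning (all bins would be selected).
#' @export
detect_threshold_bin <- function(cfs, shape, coarse_cube = 100,
                                 cube_frac = 0.15, min_count = 10) {
  if (is.null(cfs$bin)) stop("run bin_cfs() first")
  cube <- if (any(shape < coarse_cube)) ceiling(shape / 3)
          else rep(coarse_cube, 3)
  nper <- ceiling(shape / cube)
  ncubes <- prod(nper)
  # per-cube midpoint quota, prorated by the cube's actual voxel volume
  # (edge cubes are partial)
  axis_len <- function(n, cube, full) {
    len <- rep(cube, n)
    if (n * cube > full) len[n] <- full - (n - 1) * cube
    len
  }
  vols <- outer(outer(axis_len(nper[1], cube[1], shape[1]),
                      axis_len(nper[2], cube[2], shape[2])),
                axis_len(nper[3], cube[3], shape[3]))
  quota <- pmax(1, round(min_count * as.vector(vols) / prod(cube)))
  mid <- floor((cbind(cfs$is, cfs$js, cfs$ks) +
                cbind(cfs$ie, cfs$je, cfs$ke)) / 2 + 0.5)
  cid <- 1 + (mid[, 1] - 1) %/% cube[1] +
         nper[1] * ((mid[, 2] - 1) %/% cube[2]) +
         nper[1] * nper[2] * ((mid[, 3] - 1) %/% cube[3])
  for (b in 10:1) {
    counts <- tabulate(cid[cfs$bin >= b], nbins = ncubes)
    n_sparse <- sum(counts < quota)
    if (n_sparse < cube_frac * ncubes) return(b)
  }
  warning("CFSs never spread to the full volume; all bins selected")
  1L
}

#' Screen CFSs by backward retracing
#'
#' A true filament segment traces similarly in both directions: starting a
#' backward trace from the forward end point should come back along the
#' filament. Each CFS end voxel is retraced backward (same accumulation
#' method); the CFS survives iff the angle between its forward displacement
#' and the negated backward displacement is at most `angle_tol` degrees.
#'
#' @param grid the grid the CFSs were traced on.
#' @param cfs a `cfs` data frame.
#' @param angle_tol tolerance angle in degrees (default 30).
#' @param method accumulation method, as in [trace_cfs()].
#' @return the surviving subset of `cfs`.
#' @export
screen_backward <- function(grid, cfs, angle_tol = 30,
                            method = c("dp", "line")) {
  method <- match.arg(method)
  l <- attr(cfs, "l")
  if (nrow(cfs) == 0) return(cfs)
  ends <- cbind(cfs$ie, cfs$je, cfs$ke)
  res <- cpp_trace_seeds(grid$data, dim(grid$data),
                         matrix(as.integer(ends), ncol = 3) - 1L,
                         l, -1L, if (method == "dp") 0L else 1L)
  bend <- res$end + 1L
  fwd <- ends - cbind(cfs$is, cfs$js, cfs$ks)
  back_neg <- ends - bend  # negated backward displacement
  keep <- vec_angle_deg(fwd, back_neg) <= angle_tol + 1e-9
  keep[is.na(keep)] <- FALSE
  subset_cfs(cfs, keep)
}

# rowwise angle between 3D vectors, degrees
vec_angle_deg <- function(a, b) {
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2)) * sqrt(rowSums(b^2))
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}

# subset a cfs data frame preserving attributes
subset_cfs <- function(cfs, keep) {
  out <- cfs[keep, , drop = FALSE]
  attr(out, "l") <- attr(cfs, "l")
  class(out) <- class(cfs)
  rownames(out) <- NULL
  out
}
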