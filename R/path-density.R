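#' Forward / backward path density accumulation
#'
#' The dynamic-programming core of the filament filter. For every voxel, the
#' forward path density `FPD(i,j,k;l)` is the maximum accumulated density
#' over all voxel paths that start at the voxel and advance one Y-slice per
#' step for `l` steps, with lateral moves of at most one voxel per step in X
#' and Z (a 45-degree cone). Equivalently it is the maximum over all
#' `(2l+1)^2` targets at the base of the search pyramid of the best path
#' confined to the bipyramidal accumulation zone between origin and target.
#' For densities normalized to `[0, 1]` the values lie in `[0, l+1]`.
#' The backward path density (`direction = "backward"`) accumulates towards
#' `-Y`. Origins whose pyramid exits the Y range are assigned 0; pyramids
#' exiting the X/Z faces are truncated.
#'
#' @param grid a [density_grid], normalized to `[0, 1]` (see [normalize01()]).
#' @param l path length in Y-slices (default 5, matched to the tomogram
#'   resolution / feature separation).
#' @param direction `"forward"` (+Y) or `"backward"` (-Y).
#' @param method `"dp"` for the bipyramidal dynamic program, `"line"` for
#'   straight-line accumulation (sums along nearest-voxel rounded lines from
#'   the origin to each base target; a strictly weaker score, provided for
#'   comparison).
#' @return a `path_density_grid` (a [density_grid] carrying `l`, `direction`
#'   and `kind` fields).
#' @export
path_density <- function(grid, l = 5, direction = c("forward", "backward"),
                         method = c("dp", "line")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  check_normalized(grid)
  d <- dim(grid$data)
  if (l < 1) stop("`l` must be >= 1")
  if (l >= d[2]) stop("`l` must be smaller than the Y extent of the grid")
  dir <- if (direction == "forward") 1L else -1L
  vals <- if (method == "dp")
    cpp_path_density(grid$data, d, as.integer(l), dir)
  else
    cpp_path_density_line(grid$data, d, as.integer(l), dir)
  structure(list(data = vals, voxel_spacing = grid$voxel_spacing,
                 origin = grid$origin, l = as.integer(l),
                 direction = direction,
                 kind = if (direction == "forward") "FPD" else "BPD"),
            class = c("path_density_grid", "density_grid"))
}

check_normalized <- function(grid, tol = 1e-8) {
  stopifnot(inherits(grid, "density_grid"))
  r <- range(grid$data)
  if (r[1] < -tol || r[2] > 1 + tol)
    stop("grid densities must be normalized to [0, 1]; see normalize01()")
  invisible(grid)
}

#' Blend forward and backward path densities into a combined map
#'
#' A voxel lying on a filament has high path density in both directions, so
#' the blends act as conjunctions that lift filament voxels above the noise.
#' Modes: `"product"` (FPD * BPD, the square of the geometric mean; the
#' strongest conjunction), `"sum"` (arithmetic mean up to scale; closest to a
#' physical density, weakest conjunction), `"geometric"` (sqrt of the
#' product; a density with compressed dynamic range) and `"minimum"`.
#' The blended map is min-max normalized to `[0, 1]` over the valid region;
#' voxels within `l` of either Y boundary (where one of the two directions is
#' undefined) are set to 0 beforehand and excluded from the normalization.
#'
#' @param fpd,bpd forward and backward `path_density_grid`s of the same `l`
#'   and shape (see [path_density()]).
#' @param mode blending function.
#' @return a `path_density_grid` of kind `"CPD"` with values in `[0, 1]`.
#' @export
blend_path_density <- function(fpd, bpd,
                               mode = c("product", "sum", "geometric",
                                        "minimum")) {
  mode <- match.arg(mode)
  if (!identical(dim(fpd$data), dim(bpd$data)))
    stop("FPD and BPD grids must have identical shapes")
  if (!identical(fpd$l, bpd$l))
    stop("FPD and BPD must share the same path length l")
  f <- fpd$data; b <- bpd$data
  v <- switch(mode,
              product   = f * b,
              sum       = f + b,
              geometric = sqrt(f * b),
              minimum   = pmin(f, b))
  d <- dim(v); l <- fpd$l
  bnd <- unique(c(seq_len(min(l, d[2])),
                  seq.int(max(1L, d[2] - l + 1L), d[2])))
  v[, bnd, ] <- 0
  if (l + 1L <= d[2] - l) {
    valid_j <- seq.int(l + 1L, d[2] - l)
    rng <- range(v[, valid_j, ])
    v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
         else array(0, d)
    v[, bnd, ] <- 0
    v[v < 0] <- 0
  } else {
    v <- array(0, d)
  }
  structure(list(data = v, voxel_spacing = fpd$voxel_spacing,
                 origin = fpd$origin, l = l, direction = "both",
                 kind = "CPD"),
            class = c("path_density_grid", "density_grid"))
}

#' Filament pattern enhancement (denoising filter)
#'
#' Convenience wrapper: normalizes the map, accumulates forward and backward
#' path densities with the bipyramidal DP, and blends them into the combined
#' path density (CPD) map. On noisy tomograms this preprocessing lifts the
#' filament densities above the noise and is a prerequisite for reliable
#' tracing at high noise levels.
#'
#' @param grid a [density_grid] (any value range; normalized internally).
#' @param l path length in voxels.
#' @param blend blending mode, see [blend_path_density()].
#' @return a `path_density_grid` of kind `"CPD"`, normalized to `[0, 1]`.
#' @export
enhance_map <- function(grid, l = 5, blend = "product") {
  g <- normalize01(grid)
  fpd <- path_density(g, l, "forward")
  bpd <- path_density(g, l, "backward")
  blend_path_density(fpd, bpd, blend)
}
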