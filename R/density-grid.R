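#' 3D density grid
#'
#' The universal carrier of the package: a 3D scalar voxel map with isotropic
#' spacing metadata. Array dimensions `(Ni, Nj, Nk)` map to the `(X, Y, Z)`
#' axes; the filament mean direction is `+Y` (the second index) by
#' convention. Voxel indices in the R API are 1-based.
#'
#' @param data numeric 3D array.
#' @param voxel_spacing voxel edge length in nm (isotropic). Default 0.947,
#'   the spacing of typical stereocilia actin tomograms.
#' @param origin physical offset of the first voxel in nm, length 3.
#' @return an object of class `density_grid` with elements `data`,
#'   `voxel_spacing`, `origin`.
#' @examples
#' g <- density_grid(array(runif(8 * 8 * 8), c(8, 8, 8)))
#' dim(g$data)
#' @export
density_grid <- function(data, voxel_spacing = 0.947, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all grid dimensions must be >= 1")
  if (!is.numeric(voxel_spacing) || length(voxel_spacing) != 1L ||
      voxel_spacing <= 0)
    stop("`voxel_spacing` must be a single positive number")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_spacing = voxel_spacing,
                 origin = as.numeric(origin)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_grid> %d x %d x %d voxels @ %.4g nm/voxel\n",
              d[1], d[2], d[3], x$voxel_spacing))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.density_grid <- function(x) dim(x$data)

#' Min-max normalization to the unit interval
#'
#' Affine rescaling of the voxel densities so the minimum maps to 0 and the
#' maximum to 1, the form the path-density accumulation expects. A constant
#' grid (no dynamic range) maps to all zeros.
#'
#' @param grid a [density_grid].
#' @return a [density_grid] with values in `[0, 1]`.
#' @export
normalize01 <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  x <- grid$data
  rng <- range(x)
  if (rng[2] > rng[1]) {
    grid$data <- (x - rng[1]) / (rng[2] - rng[1])
  } else {
    grid$data <- array(0, dim(x))
  }
  grid
}

#' Permute grid axes so the filament mean direction is +Y
#'
#' All downstream operations assume the bundle's mean direction lies along
#' the second array index (+Y). If a map was recorded with the bundle axis
#' elsewhere, apply this single axis permutation at load time.
#'
#' @param grid a [density_grid].
#' @param mean_axis which input axis (1 = X, 2 = Y, 3 = Z) carries the
#'   filament mean direction.
#' @return a [density_grid] with the chosen axis moved to position 2.
#' @export
orient_mean_axis <- function(grid, mean_axis = 2L) {
  stopifnot(inherits(grid, "density_grid"), mean_axis %in% 1:3)
  if (mean_axis == 2L) return(grid)
  perm <- if (mean_axis == 1L) c(2L, 1L, 3L) else c(1L, 3L, 2L)
  grid$data <- aperm(grid$data, perm)
  grid$origin <- grid$origin[perm]
  grid
}
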