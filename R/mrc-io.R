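#' Read an MRC/CCP4 density map
#'
#' Reads MRC2014 / CCP4 volumes (modes 0, 1, 2 and 6). The file's axis
#' correspondence (`mapc`/`mapr`/`maps`) is honoured, so the returned array
#' is always indexed `(i, j, k)` = `(X, Y, Z)`. Cell lengths in the header
#' are in angstroms per MRC convention; `voxel_spacing` is returned in nm.
#'
#' @param path path to an MRC/CCP4 file.
#' @return a [density_grid].
#' @seealso [write_mrc()]
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("cannot read MRC file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L)
    stop("malformed MRC file (truncated header): ", path)

  parse_header <- function(endian) {
    ints <- readBin(hdr_raw, "integer", n = 256L, size = 4L, endian = endian)
    flts <- readBin(hdr_raw, "double", n = 256L, size = 4L, endian = endian)
    list(nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
         mx = ints[8], my = ints[9], mz = ints[10],
         xlen = flts[11], ylen = flts[12], zlen = flts[13],
         mapc = ints[17], mapr = ints[18], maps = ints[19],
         nsymbt = ints[24],
         origin = flts[50:52])
  }
  endian <- "little"
  h <- parse_header(endian)
  if (is.na(h$nx) || h$nx <= 0 || h$nx > 100000L || h$mode < 0 || h$mode > 100) {
    endian <- "big"
    h <- parse_header(endian)
  }
  if (is.na(h$nx) || h$nx <= 0 || h$ny <= 0 || h$nz <= 0)
    stop("malformed MRC header in ", path)
  if (!h$mode %in% c(0L, 1L, 2L, 6L))
    stop("unsupported MRC mode ", h$mode, " in ", path)
  if (!all(c(h$mapc, h$mapr, h$maps) %in% 1:3) ||
      anyDuplicated(c(h$mapc, h$mapr, h$maps)))
    stop("malformed MRC axis correspondence in ", path)

  if (h$nsymbt > 0) readBin(con, "raw", n = h$nsymbt)
  nvox <- as.double(h$nx) * h$ny * h$nz
  vals <- switch(as.character(h$mode),
    "0" = readBin(con, "integer", n = nvox, size = 1L, signed = TRUE,
                  endian = endian),
    "1" = readBin(con, "integer", n = nvox, size = 2L, signed = TRUE,
                  endian = endian),
    "2" = readBin(con, "double", n = nvox, size = 4L, endian = endian),
    "6" = readBin(con, "integer", n = nvox, size = 2L, signed = FALSE,
                  endian = endian))
  if (length(vals) < nvox)
    stop("malformed MRC file (truncated data block): ", path)
  a <- array(as.double(vals), c(h$nx, h$ny, h$nz))

  axes <- c(h$mapc, h$mapr, h$maps)   # which XYZ axis each file axis holds
  if (!identical(axes, 1:3)) a <- aperm(a, match(1:3, axes))

  m <- c(h$mx, h$my, h$mz)
  len <- c(h$xlen, h$ylen, h$zlen)
  sp <- ifelse(m > 0 & len > 0, len / m, NA_real_)
  sp <- sp[!is.na(sp)]
  spacing_nm <- if (length(sp)) sp[1] / 10 else 0.947
  if (length(sp) == 3 && (max(sp) - min(sp)) > 1e-3 * max(sp))
    warning("non-isotropic voxel spacing in ", path, "; using the X spacing")

  density_grid(a, voxel_spacing = spacing_nm, origin = h$origin / 10)
}

#' Write a density grid as an MRC2014 map
#'
#' Writes mode 2 (32-bit float) little-endian maps with standard axis order
#' (`mapc,mapr,maps = 1,2,3`) and cell lengths in angstroms.
#'
#' @param grid a [density_grid].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- dim(grid$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  sp_ang <- grid$voxel_spacing * 10
  x <- grid$data
  wi(d)                               # nx ny nz
  wi(2L)                              # mode: float32
  wi(c(0L, 0L, 0L))                   # nxstart
  wi(d)                               # mx my mz
  wf(d * sp_ang)                      # cella
  wf(c(90, 90, 90))                   # cellb
  wi(1:3)                             # mapc mapr maps
  wf(c(min(x), max(x), mean(x)))      # dmin dmax dmean
  wi(c(1L, 0L))                       # ispg, nsymbt
  wi(integer(25))                     # extra
  wf(grid$origin * 10)                # origin (A)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(x))                    # rms
  wi(1L)                              # nlabl
  lab <- charToRaw(formatC("created by tomofil", width = -80))
  writeBin(lab, con)
  writeBin(raw(800 - length(lab)), con)
  writeBin(as.vector(x), con, size = 4L, endian = "little")
  invisible(path)
}
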