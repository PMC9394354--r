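#' Filament model: a set of 3D polylines
#'
#' Ordered point lists in (1-based, real-valued) voxel coordinates. Filament
#' models are both the simulator's ground-truth input and the tracer's
#' output. For bundle-mode models the y coordinate is non-decreasing along
#' each polyline (mean direction +Y).
#'
#' @param filaments list of numeric matrices, each `n x 3` with columns
#'   `(x, y, z)` and `n >= 2`.
#' @param voxel_spacing nm per voxel, carried as metadata.
#' @return an object of class `filament_model`.
#' @export
filament_model <- function(filaments = list(), voxel_spacing = 0.947) {
  filaments <- lapply(filaments, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3L || nrow(p) < 2L)
      stop("each filament must be an n x 3 matrix with n >= 2")
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y", "z")
    p
  })
  structure(list(filaments = filaments, voxel_spacing = voxel_spacing),
            class = "filament_model")
}

#' @export
print.filament_model <- function(x, ...) {
  np <- vapply(x$filaments, nrow, 1L)
  cat(sprintf("<filament_model> %d filaments, %d points total\n",
              length(np), sum(np)))
  invisible(x)
}

#' @export
length.filament_model <- function(x) length(x$filaments)

#' Write / read filament traces as plain-text TSV
#'
#' One point per line, `filament_id x y z` (tab separated), with a comment
#' header recording the voxel spacing. Coordinates are 1-based voxel units;
#' the round-trip is exact.
#'
#' @param model a [filament_model].
#' @param path file path.
#' @return `write_traces()` returns `path` invisibly; `read_traces()` a
#'   [filament_model].
#' @export
write_traces <- function(model, path) {
  stopifnot(inherits(model, "filament_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tomofil traces; voxel_spacing_nm = %.17g",
                     model$voxel_spacing), con)
  writeLines("# filament_id\tx\ty\tz", con)
  for (f in seq_along(model$filaments)) {
    p <- model$filaments[[f]]
    writeLines(sprintf("%d\t%.17g\t%.17g\t%.17g", f, p[, 1], p[, 2], p[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("cannot read trace file: ", path)
  lines <- readLines(path)
  spacing <- 0.947
  m <- regmatches(lines, regexpr("voxel_spacing_nm *= *[0-9.eE+-]+", lines))
  if (length(m) > 0)
    spacing <- as.numeric(sub(".*= *", "", m[[1]]))
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) return(filament_model(list(), spacing))
  parts <- strsplit(trimws(lines[rows]), "[\t ]+")
  bad <- which(vapply(parts, length, 1L) != 4L)
  if (length(bad))
    stop("parse error in ", path, " line ", rows[bad[1]],
         ": expected 4 fields")
  num <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = 4L, byrow = TRUE))
  if (anyNA(num)) {
    bad <- rows[which(rowSums(is.na(num)) > 0)[1]]
    stop("parse error in ", path, " line ", bad, ": non-numeric field")
  }
  ids <- num[, 1]
  fil <- lapply(split(seq_len(nrow(num)), ids),
                function(ix) num[ix, 2:4, drop = FALSE])
  fil <- fil[order(as.numeric(names(fil)))]
  names(fil) <- NULL
  filament_model(fil, spacing)
}

#' Export a filament model as Chimera CMM markers (write-only convenience)
#'
#' Marker coordinates are converted to physical nm using the model's voxel
#' spacing.
#'
#' @param model a [filament_model].
#' @param path output `.cmm` path.
#' @param radius marker radius in nm.
#' @return `path`, invisibly.
#' @export
write_cmm <- function(model, path, radius = 2) {
  stopifnot(inherits(model, "filament_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("<marker_sets>", con)
  sp <- model$voxel_spacing
  id <- 0L
  for (f in seq_along(model$filaments)) {
    writeLines(sprintf("<marker_set name=\"filament_%d\">", f), con)
    p <- (model$filaments[[f]] - 1) * sp
    first <- id + 1L
    for (r in seq_len(nrow(p))) {
      id <- id + 1L
      writeLines(sprintf(
        "<marker id=\"%d\" x=\"%.5g\" y=\"%.5g\" z=\"%.5g\" radius=\"%.3g\"/>",
        id, p[r, 1], p[r, 2], p[r, 3], radius), con)
    }
    if (nrow(p) > 1)
      writeLines(sprintf("<link id1=\"%d\" id2=\"%d\" radius=\"%.3g\"/>",
                         first:(id - 1L), (first + 1L):id, radius / 2), con)
    writeLines("</marker_set>", con)
  }
  writeLines("</marker_sets>", con)
  invisible(path)
}
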