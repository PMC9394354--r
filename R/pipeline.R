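#' Trace filaments in a density map (full pipeline)
#'
#' Runs the complete bottom-up workflow on a tomogram whose filament bundle
#' is oriented along +Y:
#' enhancement (forward/backward path-density blending, optional) ->
#' candidate seed points -> candidate filament segment tracing ->
#' NPD binning with automatic threshold-bin detection -> backward-trace
#' screening -> collinearity merging -> isolated-segment removal ->
#' forward extension -> directional traversal fusion -> redundancy removal.
#'
#' @param grid a [density_grid] (any value range; normalized internally).
#' @param l path length in voxels (Y-extent of traced segments).
#' @param method CFS tracing accumulation: `"dp"` (bipyramidal dynamic
#'   program) or `"line"` (straight-line accumulation).
#' @param blend blending mode for the enhancement filter, see
#'   [blend_path_density()].
#' @param enhance run the path-density enhancement filter before tracing
#'   (recommended; high-noise maps are untraceable without it).
#' @param enhanced_map optionally, a precomputed CPD map (from
#'   [enhance_map()] with the same `l`) to trace on, skipping the
#'   enhancement stage; ignored when `enhance = FALSE`.
#' @param csp_cube seed-point decomposition cube edge, see [generate_csps()].
#' @param coarse_cube,cube_frac,min_count threshold-bin detection controls,
#'   see [detect_threshold_bin()].
#' @param include_threshold_bin keep the threshold bin itself in the
#'   selected set (default `FALSE`: only bins strictly above are selected;
#'   the threshold bin's lower NPD edge still serves as the extension floor).
#' @param angle_tol backward-screening angle tolerance in degrees.
#' @param merge_angle,merge_gap collinearity merge controls, see
#'   [merge_collinear()].
#' @param iso_radius,iso_min_neighbors isolation filter controls, see
#'   [remove_isolated()].
#' @param extend_factor cap on extended segment length in units of `l`.
#' @param overlap_frac redundancy threshold, see [remove_redundant()].
#' @param redundancy_dilate lateral tolerance (voxels) of the redundancy
#'   overlap test, see [remove_redundant()].
#' @param verbose print per-stage segment counts.
#' @return a list of class `tomofil_trace`:
#'   `model` (a [filament_model] of the detected filaments),
#'   `segments` (list of FS voxel matrices), `cfs` (surviving CFS table),
#'   `threshold_bin`, `npd_floor`, and `diagnostics` (per-stage counts).
#' @examples
#' \donttest{
#' shape <- c(48, 96, 48)
#' bundle <- generate_bundle(shape, n_filaments = 6, seed = 7)
#' sim <- simulate_tomogram(bundle, shape, noise_level = 0.4, seed = 7)
#' res <- trace_filaments(sim$map)
#' evaluate_tracing(res$model, bundle, shape)
#' }
#' @export
trace_filaments <- function(grid, l = 5, method = c("dp", "line"),
                            blend = "product", enhance = TRUE,
                            enhanced_map = NULL,
                            csp_cube = 5, coarse_cube = 100,
                            cube_frac = 0.15, min_count = 10,
                            include_threshold_bin = FALSE,
                            angle_tol = 30, merge_angle = 6, merge_gap = 10,
                            iso_radius = 20, iso_min_neighbors = 3,
                            extend_factor = 5, overlap_frac = 0.9,
                            redundancy_dilate = 3, verbose = FALSE) {
  method <- match.arg(method)
  shape <- dim(grid$data)
  say <- function(...) if (verbose) message(...)

  work <- if (!enhance) normalize01(grid)
          else if (!is.null(enhanced_map)) {
            stopifnot(identical(dim(enhanced_map$data), shape))
            enhanced_map
          } else enhance_map(grid, l, blend)
  seeds <- generate_csps(work, csp_cube)
  say("seeds: ", nrow(seeds))
  cfs <- suppressMessages(trace_cfs(work, seeds, l, method))
  cfs <- bin_cfs(cfs)
  n0 <- nrow(cfs)
  tb <- suppressWarnings(
    detect_threshold_bin(cfs, shape, coarse_cube, cube_frac, min_count))
  npd_floor <- (tb - 1) / 10
  sel <- if (include_threshold_bin) cfs$bin >= tb else cfs$bin > tb
  cfs <- subset_cfs(cfs, sel)
  say("threshold bin ", tb, "; selected ", nrow(cfs), " of ", n0, " CFSs")
  n_sel <- nrow(cfs)
  cfs <- screen_backward(work, cfs, angle_tol, method)
  n_screen <- nrow(cfs)
  say("backward screening kept ", n_screen)
  cfs <- merge_collinear(cfs, merge_angle, merge_gap)
  n_merge <- nrow(cfs)
  cfs <- remove_isolated(cfs, iso_radius, iso_min_neighbors)
  n_iso <- nrow(cfs)
  say("after merging/isolation: ", n_iso)
  cfs <- extend_cfs(work, cfs, npd_floor, method, extend_factor,
                    ymax = if (enhance) shape[2] - l else shape[2])

  if (nrow(cfs) > 0) {
    fvs <- unique(do.call(rbind, cfs$path))
    fss <- fuse_traversal(fvs, shape, priority = work$data[fvs])
    fss <- remove_redundant(fss, overlap_frac, redundancy_dilate)
    fss <- partition_segments(fss)
    fss <- consolidate_segments(fss, max_gap = merge_gap)
    fss <- remove_redundant(fss, overlap_frac, redundancy_dilate)
    keep <- vapply(fss, nrow, 1L) >= l + 1
    fss <- structure(fss[keep], shape = shape)
  } else {
    fss <- structure(list(), shape = shape)
  }
  say("final segments: ", length(fss))
  model <- segments_to_model(fss, grid$voxel_spacing)
  structure(list(model = model, segments = fss, cfs = cfs,
                 threshold_bin = tb, npd_floor = npd_floor,
                 diagnostics = list(n_seeds = nrow(seeds), n_cfs = n0,
                                    n_selected = n_sel,
                                    n_screened = n_screen,
                                    n_merged = n_merge, n_isolated = n_iso,
                                    n_segments = length(fss))),
            class = "tomofil_trace")
}

#' @export
print.tomofil_trace <- function(x, ...) {
  cat(sprintf(
    "<tomofil_trace> %d filament segments (threshold bin %d, floor %.1f)\n",
    length(x$segments), x$threshold_bin, x$npd_floor))
  cat("  stages:", paste(names(x$diagnostics), unlist(x$diagnostics),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Pipeline configuration object
#'
#' Collects every tunable pipeline parameter (with the package defaults)
#' into a flat `stage.parameter` named list that serializes losslessly to
#' YAML/JSON; used by the command-line interface, which writes the resolved
#' configuration next to its outputs for reproducibility.
#'
#' @param ... overrides of the default values, by name.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    trace.l = 5L, trace.method = "dp", trace.blend = "product",
    trace.enhance = TRUE, trace.csp_cube = 5L,
    trace.coarse_cube = 100L, trace.cube_frac = 0.15, trace.min_count = 10L,
    trace.include_threshold_bin = FALSE, trace.angle_tol = 30,
    fuse.merge_angle = 6, fuse.merge_gap = 10L,
    fuse.iso_radius = 20, fuse.iso_min_neighbors = 3L,
    fuse.extend_factor = 5, fuse.overlap_frac = 0.9,
    sim.voxel_spacing = 0.947, sim.psf_fwhm = 5, sim.amplification = 1.85,
    sim.noise_exponent = 0.5, sim.wedge_half_angle = 30,
    sim.target_snr_at_level_1 = 0.025, sim.noise_level = 0.6,
    sim.n_filaments = 40L, sim.seed = 1L,
    eval.tol = 3L, eval.dilate = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config parameter(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the tracing pipeline from a configuration object
#'
#' @param grid a [density_grid].
#' @param cfg a [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return a `tomofil_trace`, see [trace_filaments()].
#' @export
run_pipeline <- function(grid, cfg = pipeline_config(), verbose = FALSE) {
  trace_filaments(grid,
                  l = cfg$trace.l, method = cfg$trace.method,
                  blend = cfg$trace.blend, enhance = cfg$trace.enhance,
                  csp_cube = cfg$trace.csp_cube,
                  coarse_cube = cfg$trace.coarse_cube,
                  cube_frac = cfg$trace.cube_frac,
                  min_count = cfg$trace.min_count,
                  include_threshold_bin = cfg$trace.include_threshold_bin,
                  angle_tol = cfg$trace.angle_tol,
                  merge_angle = cfg$fuse.merge_angle,
                  merge_gap = cfg$fuse.merge_gap,
                  iso_radius = cfg$fuse.iso_radius,
                  iso_min_neighbors = cfg$fuse.iso_min_neighbors,
                  extend_factor = cfg$fuse.extend_factor,
                  overlap_frac = cfg$fuse.overlap_frac,
                  verbose = verbose)
}
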