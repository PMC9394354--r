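#' Voxel-level TP/FP/FN classification against a ground truth
#'
#' Both models are rasterized into the map grid. Predicted filament voxels
#' are first dilated by `dilate` voxels (26-neighbourhood, i.e. Chebyshev
#' radius 1 per unit) to balance recall and precision. A (dilated) predicted
#' voxel is a true positive if a true filament voxel exists within `tol`
#' voxels in any direction (Chebyshev distance), otherwise a false positive.
#' A truth voxel with no (dilated) predicted voxel within `tol` voxels is a
#' false negative.
#'
#' @param predicted,truth [filament_model]s (the prediction and the ground
#'   truth).
#' @param shape map shape `(Ni, Nj, Nk)`.
#' @param tol matching tolerance in voxels (Chebyshev).
#' @param dilate dilation radius applied to the prediction.
#' @param count_undilated if `TRUE`, count TP/FP over the raw (undilated)
#'   predicted voxels while still using the dilated set for FN matching.
#' @return list with integer counts `tp`, `fp`, `fn`.
#' @export
classify_voxels <- function(predicted, truth, shape, tol = 3, dilate = 1,
                            count_undilated = FALSE) {
  tr <- rasterize_model(truth, shape)$data > 0
  if (!any(tr)) stop("ground truth contains no filament voxels")
  pr <- rasterize_model(predicted, shape)$data > 0
  prd <- if (dilate > 0) cpp_dilate_cheb(pr, shape, as.integer(dilate)) else pr
  trt <- if (tol > 0) cpp_dilate_cheb(tr, shape, as.integer(tol)) else tr
  pos <- if (count_undilated) pr else prd
  tp <- sum(pos & trt)
  fp <- sum(pos) - tp
  prt <- if (tol > 0) cpp_dilate_cheb(prd, shape, as.integer(tol)) else prd
  fn <- sum(tr & !prt)
  list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

#' Precision, recall and F1 from voxel counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2 P R / (P + R)`.
#' When `TP + FP = 0` (nothing predicted), precision and F1 are undefined
#' and reported as `NA` (rendered "UND" in tables). When P and R are both
#' zero the harmonic mean is taken as 0.
#'
#' @param tp,fp,fn non-negative voxel counts.
#' @param metadata optional named list attached to the report (noise level,
#'   method, blend, ...).
#' @return an `evaluation_report`: list with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `metadata`.
#' @export
score_counts <- function(tp, fp, fn, metadata = list()) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(prec) || is.na(rec)) NA_real_
        else if (prec + rec == 0) 0
        else 2 * prec * rec / (prec + rec)
  structure(list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec,
                 f1 = f1, metadata = metadata),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "UND" else sprintf("%.3f", v)
  cat(sprintf("<evaluation_report> TP=%d FP=%d FN=%d | P=%s R=%s F1=%s\n",
              x$tp, x$fp, x$fn, fmt(x$precision), fmt(x$recall), fmt(x$f1)))
  if (length(x$metadata))
    cat("  ", paste(names(x$metadata), unlist(x$metadata), sep = "=",
                    collapse = " "), "\n")
  invisible(x)
}

#' Evaluate a tracing result against the ground truth
#'
#' Convenience wrapper around [classify_voxels()] and [score_counts()].
#'
#' @inheritParams classify_voxels
#' @param metadata named list recorded in the report.
#' @return an `evaluation_report`.
#' @export
evaluate_tracing <- function(predicted, truth, shape, tol = 3, dilate = 1,
                             metadata = list()) {
  cls <- classify_voxels(predicted, truth, shape, tol, dilate)
  score_counts(cls$tp, cls$fp, cls$fn, metadata)
}

#' Benchmark the pipeline over a grid of conditions
#'
#' For every combination of noise level, tracing method and blending mode:
#' simulate a tomogram from a common synthetic bundle (one noise realization
#' per noise level, so methods are compared on identical maps), run the full
#' pipeline, and evaluate voxel-level precision/recall/F1 against the known
#' truth. A failing cell is recorded with `NA` metrics instead of aborting
#' the grid.
#'
#' @param noise_levels numeric vector of noise levels.
#' @param methods character vector, subset of `c("dp", "line")`.
#' @param blends character vector of blending modes.
#' @param enhance logical vector: run with and/or without the enhancement
#'   filter.
#' @param shape,n_filaments bundle/volume geometry passed to
#'   [generate_bundle()] and [simulate_tomogram()].
#' @param seed master seed; the bundle and each noise level derive fixed
#'   sub-seeds from it.
#' @param l path length.
#' @param ... further arguments passed to [trace_filaments()].
#' @return data frame with one row per cell: condition columns, counts,
#'   `precision`, `recall`, `f1` (NA where undefined) and the detected
#'   threshold bin.
#' @export
run_benchmark <- function(noise_levels = c(0.4, 0.6, 0.8, 1.0),
                          methods = "dp", blends = "product",
                          enhance = TRUE, shape = c(120, 240, 120),
                          n_filaments = 40, seed = 1, l = 5, ...) {
  model <- generate_bundle(shape, n_filaments, seed = seed)
  rows <- list()
  for (ni in seq_along(noise_levels)) {
    nl <- noise_levels[ni]
    sim <- simulate_tomogram(model, shape, noise_level = nl,
                             seed = seed * 131L + ni)
    for (m in methods) for (bl in blends) for (en in enhance) {
      meta <- list(noise = nl, method = m, blend = bl, enhance = en)
      rep <- tryCatch({
        res <- trace_filaments(sim$map, l = l, method = m, blend = bl,
                               enhance = en, ...)
        r <- evaluate_tracing(res$model, model, shape, metadata = meta)
        r$metadata$threshold_bin <- res$threshold_bin
        r
      }, error = function(e) {
        warning("cell failed (noise=", nl, ", method=", m, "): ",
                conditionMessage(e))
        score_counts(0L, 0L, 1L, meta)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        noise = nl, method = m, blend = bl, enhance = en,
        tp = rep$tp, fp = rep$fp, fn = rep$fn,
        precision = rep$precision, recall = rep$recall, f1 = rep$f1,
        threshold_bin = if (is.null(rep$metadata$threshold_bin)) NA_integer_
                        else rep$metadata$threshold_bin)
    }
  }
  do.call(rbind, rows)
}
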