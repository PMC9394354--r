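#' Merge collinear candidate filament segments
#'
#' Pairs of CFSs that are (nearly) collinear -- direction vectors within
#' `max_angle` degrees, the later start at most `max_gap` voxels beyond the
#' earlier end along Y, and the connecting vector aligned with both
#' directions (or laterally adjacent when touching) -- are taken to be
#' fragments of the same filament and merged into one longer CFS, with the
#' gap filled by a rasterized straight line. Merging is applied repeatedly
#' until a fixpoint, so chains of fragments collapse into one segment.
#'
#' @param cfs a `cfs` data frame.
#' @param max_angle collinearity tolerance in degrees.
#' @param max_gap maximum Y gap in voxels between the earlier end and the
#'   later start.
#' @return the merged `cfs` data frame.
#' @export
merge_collinear <- function(cfs, max_angle = 6, max_gap = 10) {
  if (nrow(cfs) < 2) return(cfs)
  cfs <- subset_cfs(cfs, order(cfs$js, cfs$is, cfs$ks))
  repeat {
    merged <- FALSE
    a <- 1L
    while (a <= nrow(cfs)) {
      b <- find_merge_partner(cfs, a, max_angle, max_gap)
      if (is.na(b)) { a <- a + 1L; next }
      cfs <- do_merge(cfs, a, b)
      merged <- TRUE
      # stay on `a`: the merged segment may chain with further fragments
    }
    if (!merged) break
  }
  cfs
}

find_merge_partner <- function(cfs, a, max_angle, max_gap) {
  enda <- c(cfs$ie[a], cfs$je[a], cfs$ke[a])
  dira <- enda - c(cfs$is[a], cfs$js[a], cfs$ks[a])
  gap <- cfs$js - cfs$je[a]
  cand <- which(gap >= 0 & gap <= max_gap & seq_len(nrow(cfs)) != a)
  if (!length(cand)) return(NA_integer_)
  dirb <- cbind(cfs$ie[cand] - cfs$is[cand], cfs$je[cand] - cfs$js[cand],
                cfs$ke[cand] - cfs$ks[cand])
  ok <- vec_angle_deg(matrix(dira, length(cand), 3, byrow = TRUE),
                      dirb) <= max_angle + 1e-9
  conn <- cbind(cfs$is[cand] - enda[1], cfs$js[cand] - enda[2],
                cfs$ks[cand] - enda[3])
  touching <- gap[cand] == 0
  ok[touching] <- ok[touching] &
    pmax(abs(conn[touching, 1]), abs(conn[touching, 3])) <= 1
  if (any(!touching)) {
    ca <- vec_angle_deg(matrix(dira, length(cand), 3, byrow = TRUE), conn)
    ok[!touching] <- ok[!touching] & ca[!touching] <= max_angle + 1e-9
  }
  hit <- cand[ok]
  if (!length(hit)) return(NA_integer_)
  hit[order(gap[hit])][1]   # closest fragment first
}

do_merge <- function(cfs, a, b) {
  pa <- cfs$path[[a]]; pb <- cfs$path[[b]]
  gap_path <- NULL
  if (cfs$js[b] - cfs$je[a] > 0) {
    seg <- rbind(c(cfs$ie[a], cfs$je[a], cfs$ke[a]),
                 c(cfs$is[b], cfs$js[b], cfs$ks[b]))
    gp <- unique(floor(interpolate_polyline(seg, 0.4) + 0.5))
    gp <- gp[gp[, 2] > cfs$je[a] & gp[, 2] < cfs$js[b], , drop = FALSE]
    gap_path <- gp
  }
  la <- cfs$je[a] - cfs$js[a]; lb <- cfs$je[b] - cfs$js[b]
  cfs$ie[a] <- cfs$ie[b]; cfs$je[a] <- cfs$je[b]; cfs$ke[a] <- cfs$ke[b]
  cfs$npd[a] <- (la * cfs$npd[a] + lb * cfs$npd[b]) / (la + lb)
  cfs$path[[a]] <- rbind(pa, gap_path, pb)
  if (!is.null(cfs$bin)) cfs$bin[a] <- max(cfs$bin[a], cfs$bin[b])
  subset_cfs(cfs, setdiff(seq_len(nrow(cfs)), b))
}

#' Remove spatially isolated candidate filament segments
#'
#' False CFSs caused by erratic local noise have no nearby companions,
#' whereas segments on a real filament are surrounded by other segments of
#' the bundle. A CFS is kept iff at least `min_neighbors` other CFS centers
#' lie within Euclidean distance `radius` of its center. Neighbour counts
#' are taken on a single snapshot of the input (removals do not cascade).
#'
#' @param cfs a `cfs` data frame.
#' @param radius neighbourhood radius in voxels.
#' @param min_neighbors minimum number of other CFSs within the radius.
#' @return the surviving subset of `cfs`.
#' @export
remove_isolated <- function(cfs, radius = 20, min_neighbors = 3) {
  n <- nrow(cfs)
  if (n == 0) return(cfs)
  ctr <- (cbind(cfs$is, cfs$js, cfs$ks) + cbind(cfs$ie, cfs$je, cfs$ke)) / 2
  dd <- as.matrix(stats::dist(ctr))
  nb <- rowSums(dd <= radius) - 1L
  subset_cfs(cfs, nb >= min_neighbors)
}

#' Extend surviving CFSs forward through weaker map regions
#'
#' Noise makes real filaments inhomogeneous along their length, so fragments
#' of one filament can fall below the selection threshold. Each surviving
#' CFS is therefore repeatedly extended in the forward direction by a new
#' traced segment of length `l`, as long as the new segment's NPD stays at
#' or above `npd_floor` (the lower NPD edge of the threshold bin), the
#' extension stays inside the volume, and the total Y-extent is below
#' `max_factor * l`.
#'
#' @param grid the grid the CFSs were traced on.
#' @param cfs a `cfs` data frame.
#' @param npd_floor minimum NPD for an extension segment.
#' @param method accumulation method, as in [trace_cfs()].
#' @param max_factor cap on total Y-extent in units of `l`.
#' @param ymax last Y slice an extension may reach (default: the grid's Y
#'   extent). When tracing runs on a CPD map, pass `Nj - l` so extensions do
#'   not run into the zeroed boundary band where the CPD is undefined.
#' @return the extended `cfs` data frame.
#' @export
extend_cfs <- function(grid, cfs, npd_floor, method = c("dp", "line"),
                       max_factor = 5, ymax = NULL) {
  method <- match.arg(method)
  l <- attr(cfs, "l")
  if (nrow(cfs) == 0) return(cfs)
  nj <- dim(grid$data)[2]
  if (is.null(ymax)) ymax <- nj
  ymax <- min(ymax, nj)
  active <- which(cfs$je - cfs$js < max_factor * l & cfs$je + l <= ymax)
  while (length(active)) {
    ends <- cbind(cfs$ie[active], cfs$je[active], cfs$ke[active])
    res <- cpp_trace_seeds(grid$data, dim(grid$data),
                           matrix(as.integer(ends), ncol = 3) - 1L,
                           l, 1L, if (method == "dp") 0L else 1L)
    npd_new <- res$fpd / (l + 1)
    grow <- which(!is.na(npd_new) & npd_new >= npd_floor)
    for (g in grow) {
      a <- active[g]
      newp <- chord_voxels(ends[g, ], res$end[g, ] + 1L, l)
      cfs$path[[a]] <- rbind(cfs$path[[a]], newp[-1, , drop = FALSE])
      cfs$ie[a] <- res$end[g, 1] + 1L
      cfs$je[a] <- res$end[g, 2] + 1L
      cfs$ke[a] <- res$end[g, 3] + 1L
    }
    active <- active[grow]
    active <- active[cfs$je[active] - cfs$js[active] < max_factor * l &
                     cfs$je[active] + l <= ymax]
  }
  cfs
}

#' Fuse filament voxels into filament segments by directional traversal
#'
#' All voxels of the surviving CFSs are labeled filament voxels (FVs). From
#' an unassigned FV (lowest Y first), the traversal repeatedly steps in the
#' +Y direction, allowing lateral movement of at most half the Y movement:
#' it first checks the direct +1 Y neighbour `(0,1,0)`, then the nine
#' offsets at Y+2 with lateral offsets up to one voxel, in the fixed order
#' `(0,2,0), (0,2,1), (0,2,-1), (1,2,1), (1,2,-1), (-1,2,-1), (1,2,0),
#' (-1,2,0), (-1,2,1)`. The first unassigned FV found becomes the next chain
#' voxel; when none is found the segment ends and a new seed is taken. Every
#' FV ends up in exactly one filament segment (FS).
#'
#' @param fvs integer matrix `n x 3` of 1-based FV coordinates (rows unique).
#' @param shape map shape `(Ni, Nj, Nk)`.
#' @param priority optional numeric vector (one value per FV row, e.g. the
#'   enhanced-map density): chains are seeded from high-priority FVs first,
#'   so the strongest filament axes are claimed before weak stray voxels.
#'   Default seeds in ascending `(Y, X, Z)` order.
#' @return list of FS voxel matrices (ordered, Y strictly increasing), with
#'   attribute `shape`. A chain may traverse voxels first reached by an
#'   earlier chain (its recorded path keeps them, so overlap screening sees
#'   the true extent); ownership stays with the first claimant, and fresh
#'   chains are only seeded from unclaimed FVs, so every FV is claimed by
#'   exactly one segment.
#' @export
fuse_traversal <- function(fvs, shape, priority = NULL) {
  fvs0 <- matrix(as.integer(fvs), ncol = 3)
  dup <- duplicated(fvs0)
  fvs <- fvs0[!dup, , drop = FALSE]
  if (!is.null(priority)) priority <- priority[!dup]
  offs <- rbind(c(0, 1, 0),
                c(0, 2, 0), c(0, 2, 1), c(0, 2, -1),
                c(1, 2, 1), c(1, 2, -1), c(-1, 2, -1),
                c(1, 2, 0), c(-1, 2, 0), c(-1, 2, 1))
  ni <- shape[1]; nj <- shape[2]
  lin <- function(v) v[1] + ni * (v[2] - 1 + nj * (v[3] - 1))
  is_fv <- new.env(hash = TRUE, size = nrow(fvs) * 2L)
  for (r in seq_len(nrow(fvs)))
    assign(as.character(lin(fvs[r, ])), r, envir = is_fv)
  claimed <- rep(FALSE, nrow(fvs))
  ord <- if (is.null(priority)) order(fvs[, 2], fvs[, 1], fvs[, 3])
         else order(-priority, fvs[, 2], fvs[, 1], fvs[, 3])
  out <- list()
  for (r in ord) {
    if (claimed[r]) next
    chain <- list(fvs[r, ])
    claimed[r] <- TRUE
    cur <- fvs[r, ]
    repeat {
      nxt <- NULL
      for (o in seq_len(nrow(offs))) {
        cand <- cur + offs[o, ]
        if (cand[1] < 1 || cand[1] > shape[1] || cand[2] > shape[2] ||
            cand[3] < 1 || cand[3] > shape[3]) next
        idx <- get0(as.character(lin(cand)), envir = is_fv)
        if (!is.null(idx)) { nxt <- c(idx, cand); break }
      }
      if (is.null(nxt)) break
      claimed[nxt[1]] <- TRUE
      chain[[length(chain) + 1L]] <- nxt[2:4]
      cur <- nxt[2:4]
    }
    out[[length(out) + 1L]] <- do.call(rbind, chain)
  }
  attr(out, "shape") <- shape
  out
}

#' Join abutting filament segments end-to-start
#'
#' The directional traversal can strand a chain mid-filament (when the
#' filament drifts laterally off the strand the chain is following), leaving
#' one filament split into abutting segments. Two segments are joined when
#' the later one starts within `max_gap` Y-slices of where the earlier one
#' ends, its lateral (X-Z) offset across the gap stays small (Chebyshev
#' offset at most `max(3, ceiling(gap / 2))`, far below the bundle's
#' filament spacing), and its
#' start lies within `lateral_tol` voxels (Chebyshev, in X-Z) of the
#' position predicted by extrapolating the earlier segment's local tangent
#' across the gap. The local tangent is estimated from the last (or first)
#' `tangent_window` voxels, so filament curvature does not block joining.
#' Applied repeatedly until a fixpoint.
#'
#' @param fss list of FS voxel matrices with attribute `shape`.
#' @param max_gap maximum Y gap in voxels.
#' @param lateral_tol lateral tolerance in voxels on the extrapolated
#'   position.
#' @param tangent_window voxels used for the local tangent estimate.
#' @return consolidated list of FS matrices, attribute `shape` preserved.
#' @export
consolidate_segments <- function(fss, max_gap = 10, lateral_tol = 2,
                                 tangent_window = 5) {
  shape <- attr(fss, "shape")
  if (length(fss) < 2) return(fss)
  tangent <- function(m) {
    n <- nrow(m)
    w <- min(tangent_window, n - 1L)
    if (w < 1L) return(c(0, 1, 0))
    d <- m[n, ] - m[n - w, ]
    if (d[2] <= 0) c(0, 1, 0) else d / d[2]   # per unit Y
  }
  fss <- fss[order(vapply(fss, function(m) m[1, 2], 1))]
  repeat {
    joined <- FALSE
    starts <- t(vapply(fss, function(m) m[1, ], numeric(3)))
    ends_y <- vapply(fss, function(m) m[nrow(m), 2], numeric(1))
    a <- 1L
    while (a <= length(fss)) {
      ma <- fss[[a]]
      enda <- ma[nrow(ma), ]
      gap <- starts[, 2] - enda[2]
      lat <- pmax(abs(starts[, 1] - enda[1]), abs(starts[, 3] - enda[3]))
      cand <- which(gap >= -max_gap & gap <= max_gap & ends_y > enda[2] &
                    (gap < 1 | lat <= pmax(3, ceiling(gap / 2))) &
                    seq_along(fss) != a)
      hit <- NA_integer_; hit_gap <- Inf
      for (b in cand[order(abs(gap[cand]))]) {
        g <- gap[b]
        if (abs(g) >= hit_gap) break
        if (g < 1) {
          # segments overlapping by a few Y slices where one chain stranded
          # and its successor restarted behind the strand point: join when
          # the successor's start lies next to this chain's path there
          row <- which(abs(ma[, 2] - starts[b, 2]) <= 1)
          if (!length(row)) next
          near <- min(pmax(abs(ma[row, 1] - starts[b, 1]),
                           abs(ma[row, 3] - starts[b, 3])))
          if (near > 3) next
          hit <- b; hit_gap <- abs(g)
        } else {
          pred <- enda + g * tangent(ma)
          if (max(abs(pred[c(1, 3)] - starts[b, c(1, 3)])) <= lateral_tol) {
            hit <- b; hit_gap <- abs(g)
          }
        }
        if (!is.na(hit)) break
      }
      if (is.na(hit)) { a <- a + 1L; next }
      mb <- fss[[hit]]
      mb <- mb[mb[, 2] > enda[2], , drop = FALSE]   # trim overlapping head
      bridge <- NULL
      if (nrow(mb) && mb[1, 2] - enda[2] > 1) {
        bridge <- unique(floor(interpolate_polyline(
          rbind(enda, mb[1, ]), 0.4) + 0.5))
        bridge <- bridge[bridge[, 2] > enda[2] & bridge[, 2] < mb[1, 2], ,
                         drop = FALSE]
      }
      fss[[a]] <- rbind(ma, bridge, mb)
      fss[[hit]] <- NULL
      joined <- TRUE
      starts <- t(vapply(fss, function(m) m[1, ], numeric(3)))
      ends_y <- vapply(fss, function(m) m[nrow(m), 2], numeric(1))
    }
    if (!joined) break
  }
  attr(fss, "shape") <- shape
  fss
}

#' Reduce surviving filament segments to disjoint voxel chains
#'
#' After redundancy screening, traversal paths of distinct segments can
#' still share short runs where one chain passed through another. Voxels are
#' assigned to the longest containing segment (earlier-created on ties);
#' shorter segments are split into their contiguous runs of still-unclaimed
#' voxels. Runs with fewer than `min_len` voxels are dropped.
#'
#' @param fss list of FS voxel matrices with attribute `shape`.
#' @param min_len minimum surviving run length in voxels.
#' @return list of disjoint FS matrices, attribute `shape` preserved.
#' @export
partition_segments <- function(fss, min_len = 2) {
  shape <- attr(fss, "shape")
  if (length(fss) == 0) return(fss)
  ni <- shape[1]; nj <- shape[2]
  lin <- function(m) m[, 1] + ni * (m[, 2] - 1 + nj * (m[, 3] - 1))
  lens <- vapply(fss, nrow, 1L)
  ord <- order(-lens, seq_along(fss))
  claimed <- new.env(hash = TRUE)
  keep <- vector("list", length(fss))
  for (x in ord) {
    m <- fss[[x]]
    free <- !vapply(as.character(lin(m)), function(k)
      isTRUE(get0(k, envir = claimed)), TRUE)
    if (!any(free)) next
    runs <- rle(free)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    segs <- list()
    for (q in which(runs$values & runs$lengths >= min_len)) {
      seg <- m[starts[q]:ends[q], , drop = FALSE]
      for (k in as.character(lin(seg))) assign(k, TRUE, envir = claimed)
      segs[[length(segs) + 1L]] <- seg
    }
    if (length(segs)) keep[[x]] <- segs
  }
  out <- unlist(keep[!vapply(keep, is.null, TRUE)], recursive = FALSE)
  attr(out, "shape") <- shape
  out
}

#' Discard filament segments redundant with a longer segment
#'
#' Overlapping traces arise from the overlapping extended CFSs. A shorter FS
#' is discarded when more than `overlap_frac` of its voxels coincide with a
#' longer FS, where "coincide" tolerates a lateral offset of `dilate` voxels
#' (the shorter segment's voxels are matched against the Chebyshev dilation
#' of the longer one). Two traces closer than half the point-spread width
#' cannot be distinct filaments, so the default offset tolerance is 3
#' voxels, about half the 5 nm filament FWHM at 0.947 nm spacing (5.3 voxels). Segments
#' are compared in descending length order; equal lengths keep the
#' earlier-created segment.
#'
#' @param fss list of FS voxel matrices with attribute `shape` (from
#'   [fuse_traversal()]).
#' @param overlap_frac overlap fraction above which the shorter FS is
#'   discarded.
#' @param dilate Chebyshev dilation radius (voxels) used for the overlap
#'   test.
#' @return the surviving list of FS matrices (original creation order),
#'   attribute `shape` preserved.
#' @export
remove_redundant <- function(fss, overlap_frac = 0.9, dilate = 3) {
  shape <- attr(fss, "shape")
  if (length(fss) < 2) return(fss)
  fsi <- lapply(fss, function(m) {
    m <- m[, 1:3, drop = FALSE]
    storage.mode(m) <- "integer"
    m
  })
  keep <- cpp_remove_redundant(fsi, as.integer(shape), overlap_frac,
                               as.integer(dilate))
  out <- fss[keep]
  attr(out, "shape") <- shape
  out
}

#' Convert filament segments to a filament model
#'
#' One polyline point per filament voxel; segments with fewer than two
#' voxels cannot form a polyline and are dropped.
#'
#' @param fss list of FS voxel matrices.
#' @param voxel_spacing nm per voxel.
#' @return a [filament_model].
#' @export
segments_to_model <- function(fss, voxel_spacing = 0.947) {
  fss <- fss[vapply(fss, nrow, 1L) >= 2L]
  filament_model(lapply(fss, function(m) {
    m <- m[, 1:3, drop = FALSE]
    colnames(m) <- c("x", "y", "z")
    m
  }), voxel_spacing)
}
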