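# Independent reference implementations used as oracles. They enumerate or
# brute-force the quantities the package computes with dynamic programming /
# compiled kernels, and must stay free of the code paths they check.

# Exhaustive forward path-density at a single origin: enumerate every lateral
# step sequence (m, n) in {-1,0,1}^(2l), sum densities along each monotone
# +Y path (origin included), drop paths leaving the grid, take the maximum.
fpd_enumerate <- function(d, i, j, k, l, dir = 1L) {
  dm <- dim(d)
  if (j + dir * l < 1 || j + dir * l > dm[2]) return(0)
  steps <- as.matrix(expand.grid(rep(list(-1:1), 2 * l)))
  ii <- matrix(i, nrow(steps), l + 1)
  kk <- matrix(k, nrow(steps), l + 1)
  for (t in 1:l) {
    ii[, t + 1] <- ii[, t] + steps[, t]
    kk[, t + 1] <- kk[, t] + steps[, l + t]
  }
  ok <- rowSums(ii < 1 | ii > dm[1] | kk < 1 | kk > dm[3]) == 0
  if (!any(ok)) return(0)
  ii <- ii[ok, , drop = FALSE]; kk <- kk[ok, , drop = FALSE]
  jj <- matrix(j + dir * (0:l), nrow(ii), l + 1, byrow = TRUE)
  sums <- rowSums(matrix(d[cbind(c(ii), c(jj), c(kk))], nrow(ii)))
  max(sums)
}

# As above but also returns the best base target with the package's
# tie-break (lexicographically smallest (i', k')) and the winning value.
trace_enumerate <- function(d, i, j, k, l, dir = 1L) {
  dm <- dim(d)
  steps <- as.matrix(expand.grid(rep(list(-1:1), 2 * l)))
  best <- -Inf; bi <- NA; bk <- NA
  for (di in -l:l) for (dk in -l:l) {
    ti <- i + di; tk <- k + dk
    if (ti < 1 || ti > dm[1] || tk < 1 || tk > dm[3]) next
    ends_i <- rowSums(steps[, 1:l, drop = FALSE])
    ends_k <- rowSums(steps[, (l + 1):(2 * l), drop = FALSE])
    sel <- which(ends_i == di & ends_k == dk)
    val <- -Inf
    for (r in sel) {
      ii <- i; kk <- k; s <- d[i, j, k]; okp <- TRUE
      for (t in 1:l) {
        ii <- ii + steps[r, t]; kk <- kk + steps[r, l + t]
        if (ii < 1 || ii > dm[1] || kk < 1 || kk > dm[3]) { okp <- FALSE; break }
        s <- s + d[ii, j + dir * t, kk]
      }
      if (okp && s > val) val <- s
    }
    if (val > best + 1e-12) { best <- val; bi <- ti; bk <- tk }
  }
  list(fpd = best, end = c(bi, j + dir * l, bk))
}

# Straight-line accumulation at one origin, written independently: for each
# base target, linearly interpolate X(Y) and Z(Y), round to nearest voxel,
# sum densities, take the maximum over targets.
line_fpd_enumerate <- function(d, i, j, k, l, dir = 1L) {
  dm <- dim(d)
  if (j + dir * l < 1 || j + dir * l > dm[2]) return(0)
  best <- -Inf
  for (di in -l:l) for (dk in -l:l) {
    if (i + di < 1 || i + di > dm[1] || k + dk < 1 || k + dk > dm[3]) next
    s <- 0
    for (t in 0:l) {
      ii <- i + floor(di * t / l + 0.5)
      kk <- k + floor(dk * t / l + 0.5)
      s <- s + d[ii, j + dir * t, kk]
    }
    if (s > best) best <- s
  }
  if (best == -Inf) 0 else best
}

# A thin, perfectly straight +Y filament rendered directly into a density
# array (no simulator involvement).
straight_filament_grid <- function(dm, x, z, value = 1) {
  d <- array(0, dm)
  d[x, , z] <- value
  density_grid(d)
}

# minimal CFS table for tracer/fusion unit tests (paths are straight)
make_cfs <- function(starts, ends, npd, l = 5L) {
  n <- nrow(starts)
  paths <- lapply(seq_len(n), function(r) {
    p <- tomofil:::interpolate_polyline(rbind(starts[r, ], ends[r, ]), 0.4)
    unique(floor(p + 0.5))
  })
  out <- data.frame(is = starts[, 1], js = starts[, 2], ks = starts[, 3],
                    ie = ends[, 1], je = ends[, 2], ke = ends[, 3],
                    npd = npd)
  out$path <- paths
  attr(out, "l") <- l
  class(out) <- c("cfs", "data.frame")
  out
}
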