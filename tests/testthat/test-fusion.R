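test_that("collinear CFSs merge across gaps; angled or offset pairs do not", {
  s <- rbind(c(10, 3, 10), c(10, 13, 10))
  e <- rbind(c(10, 8, 10), c(10, 18, 10))
  cfs <- make_cfs(s, e, npd = c(0.9, 0.8))
  m <- merge_collinear(cfs)                      # gap 5, same line
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$is, m$js, m$ks), c(10, 3, 10))
  expect_equal(c(m$ie, m$je, m$ke), c(10, 18, 10))
  expect_equal(sort(unique(m$path[[1]][, 2])), 3:18)  # gap rasterized

  # direction difference ~11 deg > 6 deg: kept apart
  cfs2 <- make_cfs(rbind(c(10, 3, 10), c(10, 13, 10)),
                   rbind(c(10, 8, 10), c(11, 18, 10)), npd = c(0.9, 0.8))
  expect_equal(nrow(merge_collinear(cfs2)), 2L)

  # parallel but laterally offset: the connector is not collinear
  cfs3 <- make_cfs(rbind(c(10, 3, 10), c(14, 13, 10)),
                   rbind(c(10, 8, 10), c(14, 18, 10)), npd = c(0.9, 0.8))
  expect_equal(nrow(merge_collinear(cfs3)), 2L)

  # beyond the 10-voxel gap: kept apart
  cfs4 <- make_cfs(rbind(c(10, 3, 10), c(10, 20, 10)),
                   rbind(c(10, 8, 10), c(10, 25, 10)), npd = c(0.9, 0.8))
  expect_equal(nrow(merge_collinear(cfs4)), 2L)
})

test_that("chains of collinear fragments collapse to one segment at the fixpoint", {
  s <- rbind(c(5, 2, 5), c(5, 10, 5), c(5, 18, 5))
  e <- rbind(c(5, 7, 5), c(5, 15, 5), c(5, 23, 5))
  cfs <- make_cfs(s, e, npd = c(0.9, 0.9, 0.9))
  m <- merge_collinear(cfs)
  expect_equal(nrow(m), 1L)
  expect_equal(m$je - m$js, 21)
  # idempotence at the fixpoint
  m2 <- merge_collinear(m)
  expect_equal(nrow(m2), 1L)
  expect_identical(m2$path[[1]], m$path[[1]])
})

test_that("isolation filtering counts neighbours on a single snapshot", {
  lone <- make_cfs(matrix(c(50, 50, 50), 1), matrix(c(50, 55, 50), 1), 0.9)
  expect_equal(nrow(remove_isolated(lone)), 0L)

  # the central CFS has exactly 3 neighbours at distance 19 and is kept;
  # the outer ones see fewer than 3 within the radius and are removed on
  # the same snapshot
  ctr <- c(30, 30, 30)
  starts <- rbind(ctr, ctr + c(19, 0, 0), ctr + c(-19, 0, 0),
                  ctr + c(0, 0, 19))
  cfs <- make_cfs(starts, starts + matrix(rep(c(0, 5, 0), 4), ncol = 3,
                                          byrow = TRUE),
                  npd = rep(0.9, 4))
  kept19 <- remove_isolated(cfs)
  expect_equal(nrow(kept19), 1L)
  expect_equal(c(kept19$is, kept19$js, kept19$ks), ctr)

  # random scatter: survivors equal the brute-force all-pairs count
  set.seed(59)
  n <- 60
  s <- cbind(sample(1:80, n, TRUE), sample(1:80, n, TRUE),
             sample(1:80, n, TRUE))
  cfs <- make_cfs(s, s + matrix(rep(c(0, 5, 0), n), ncol = 3, byrow = TRUE),
                  npd = runif(n))
  kept <- remove_isolated(cfs, radius = 20, min_neighbors = 3)
  ctr <- s + matrix(rep(c(0, 2.5, 0), n), ncol = 3, byrow = TRUE)
  nb <- sapply(seq_len(n), function(i)
    sum(sqrt(colSums((t(ctr) - ctr[i, ])^2)) <= 20) - 1L)
  expect_equal(nrow(kept), sum(nb >= 3))
  expect_equal(kept$npd, cfs$npd[nb >= 3])
})

test_that("extension grows to the cap on continuous filaments and halts at weak gaps", {
  dm <- c(11, 40, 11)
  g <- straight_filament_grid(dm, 6, 6)
  cfs <- trace_cfs(g, matrix(c(6, 2, 6), 1), 5)
  ext <- extend_cfs(g, cfs, npd_floor = 0.5)
  expect_equal(ext$je - ext$js, 25)              # 5l cap

  # filament ends at y = 17 with void beyond: growth stops there
  g2 <- density_grid({a <- array(0, dm); a[6, 2:17, 6] <- 1; a})
  cfs2 <- trace_cfs(g2, matrix(c(6, 2, 6), 1), 5)
  ext2 <- extend_cfs(g2, cfs2, npd_floor = 0.5)
  expect_equal(ext2$je, 17)

  # a weak stretch below the floor blocks the bridge
  g3 <- density_grid({a <- array(0, dm); a[6, 2:12, 6] <- 1
                      a[6, 13:17, 6] <- 0.2; a[6, 18:30, 6] <- 1; a})
  ext3 <- extend_cfs(g3, trace_cfs(g3, matrix(c(6, 2, 6), 1), 5),
                     npd_floor = 0.5)
  expect_equal(ext3$je, 12)
  # with a permissive floor the same map extends through the weak stretch
  ext3b <- extend_cfs(g3, trace_cfs(g3, matrix(c(6, 2, 6), 1), 5),
                      npd_floor = 0.1)
  expect_equal(ext3b$je - ext3b$js, 25)
})

test_that("directional traversal chains straight runs and respects the connection range", {
  shape <- c(20, 20, 20)
  fvs <- cbind(10, 3:15, 10)
  fss <- fuse_traversal(fvs, shape)
  expect_length(fss, 1L)
  expect_equal(nrow(fss[[1]]), 13L)

  # two parallel filaments 5 voxels apart cannot be bridged
  fvs2 <- rbind(cbind(5, 3:15, 10), cbind(10, 3:15, 10))
  expect_length(fuse_traversal(fvs2, shape), 2L)

  # the offset example: (0,0,0) and (1,2,0) connect when (0,1,0) is absent
  fvs3 <- rbind(c(8, 5, 8), c(9, 7, 8))
  fss3 <- fuse_traversal(fvs3, shape)
  expect_length(fss3, 1L)
  expect_equal(nrow(fss3[[1]]), 2L)

  # every FV claimed by exactly one segment
  set.seed(61)
  fvs4 <- unique(cbind(sample(1:20, 60, TRUE), sample(1:20, 60, TRUE),
                       sample(1:20, 60, TRUE)))
  fss4 <- fuse_traversal(fvs4, shape)
  claimed <- do.call(rbind, fss4)
  expect_true(nrow(unique(claimed)) <= nrow(claimed))  # paths may revisit
  # claims cover all FVs
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_setequal(unique(key(claimed)), key(fvs4))
})

test_that("redundant segments are discarded against longer ones, pairwise in length order", {
  shape <- c(20, 40, 20)
  long <- cbind(10, 3:30, 10)
  contained <- cbind(10, 8:20, 10)       # fully inside
  half <- cbind(10, 25:38, 10)           # ~43% overlap with long
  fss <- structure(list(long, contained, half), shape = shape)
  out <- remove_redundant(fss)
  expect_length(out, 2L)
  expect_equal(sapply(out, nrow), c(28L, 14L))

  # three mutually overlapping segments: survivors match the brute-force
  # descending-length pairwise rule
  a <- cbind(10, 3:30, 10)               # 28
  b <- cbind(10, 5:28, 10)               # 24, inside a -> dropped
  cc <- cbind(11, 4:26, 10)              # 23, within 1 voxel of a -> dropped
  out2 <- remove_redundant(structure(list(cc, b, a), shape = shape))
  expect_length(out2, 1L)
  expect_equal(nrow(out2[[1]]), 28L)

  # 50% overlap survives even laterally adjacent
  d1 <- cbind(10, 3:30, 10)
  d2 <- cbind(11, 20:45, 10)
  out3 <- remove_redundant(structure(list(d1, d2), shape = c(20, 50, 20)))
  expect_length(out3, 2L)
})

test_that("segment consolidation joins stranded chain pieces but not distant filaments", {
  shape <- c(30, 60, 30)
  a <- cbind(10, 3:25, 10)
  b <- cbind(11, 28:50, 10)             # gap 3, lateral offset 1
  fss <- structure(list(a, b), shape = shape)
  out <- consolidate_segments(fss)
  expect_length(out, 1L)
  ys <- out[[1]][, 2]
  expect_equal(min(ys), 3); expect_equal(max(ys), 50)
  expect_true(all(diff(ys) > 0))        # bridge fills the gap monotonically

  # a filament 12 voxels away laterally is never joined
  cpar <- cbind(23, 28:50, 10)
  out2 <- consolidate_segments(structure(list(a, cpar), shape = shape))
  expect_length(out2, 2L)

  # overlapping-by-restart pieces join with the head trimmed
  d1 <- cbind(10, 3:25, 10)
  d2 <- cbind(12, 23:45, 10)            # starts 2 slices before d1 ends
  out3 <- consolidate_segments(structure(list(d1, d2), shape = shape))
  expect_length(out3, 1L)
  expect_true(all(diff(out3[[1]][, 2]) > 0))
})

test_that("partitioning yields disjoint chains and respects the minimum length", {
  shape <- c(20, 40, 20)
  a <- cbind(10, 3:30, 10)
  b <- rbind(cbind(10, 10:20, 10), cbind(11, 21:26, 10))  # shares 11 voxels
  fss <- structure(list(a, b), shape = shape)
  out <- partition_segments(fss, min_len = 3)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  all_keys <- unlist(lapply(out, key))
  expect_equal(anyDuplicated(all_keys), 0L)
  expect_equal(sum(sapply(out, nrow)), 28L + 6L)
  out2 <- partition_segments(fss, min_len = 7)
  expect_equal(sum(sapply(out2, nrow)), 28L)     # the 6-run is dropped
})
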