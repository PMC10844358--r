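test_that("grouping follows bbox overlap with z-gap splitting", {
  # contiguous overlapping stack -> one group of 3
  a <- lapply(2:4, function(z) ellipse_candidate(z, 40, 40, 8, 8))
  expect_length(group_lumens(a), 1)
  expect_length(group_lumens(a)[[1]]$members, 3)
  # overlapping in xy at z = 2,3 and 5,6 with nothing at z = 4 -> two groups
  b <- lapply(c(2, 3, 5, 6), function(z) ellipse_candidate(z, 40, 40, 8, 8))
  expect_length(group_lumens(b, max_gap = 0), 2)
  # two laterally disjoint lumens on the same slices -> two groups
  d <- c(lapply(2:4, function(z) ellipse_candidate(z, 30, 30, 6, 6)),
         lapply(2:4, function(z) ellipse_candidate(z, 80, 80, 6, 6)))
  expect_length(group_lumens(d), 2)
})

test_that("grouping partitions the accepted set and is monotone in max_gap", {
  set.seed(33)
  for (rep in 1:5) {
    cands <- list()
    for (i in 1:12) {
      z <- sample(0:9, 1)
      cy <- sample(15:85, 1); cx <- sample(15:85, 1)
      cands[[i]] <- ellipse_candidate(z, cy, cx, sample(4:9, 1), sample(4:9, 1))
    }
    sizes <- c()
    for (gap in 0:3) {
      gr <- group_lumens(cands, max_gap = gap)
      ids <- unlist(lapply(gr, function(g)
        vapply(g$members, function(m)
          paste(m$z_index, m$bbox[1], m$bbox[2]), character(1))))
      expect_length(ids, length(cands))      # partition: nothing lost
      expect_equal(anyDuplicated(ids), 0L)   # nothing duplicated
      sizes <- c(sizes, length(gr))
    }
    expect_true(all(diff(sizes) <= 0))       # more gap tolerance, fewer groups
  }
})

test_that("point clouds are boundary pixels at physical coordinates", {
  cal <- cal1()
  m <- matrix(FALSE, 20, 20)
  m[5:7, 9:11] <- TRUE  # 3x3 square: 8 boundary + 1 interior
  g <- group_lumens(list(mask_candidate(m, z = 4L)))[[1]]
  pts <- build_point_cloud(g, cal)
  expect_equal(nrow(pts), 8)
  expect_true(all(pts[, "z"] == 4 * 5))
  expect_equal(sort(unique(pts[, "y"])), c(4, 5, 6))  # 0-based * 1 um
  # two members -> union of the per-member clouds
  g2 <- group_lumens(list(mask_candidate(m, z = 4L),
                          ellipse_candidate(5, 10, 10, 4, 4, H = 20, W = 20)))[[1]]
  expect_equal(nrow(build_point_cloud(g2, cal)),
               8 + nrow(build_point_cloud(
                 group_lumens(list(ellipse_candidate(5, 10, 10, 4, 4,
                                                     H = 20, W = 20)))[[1]], cal)))
  # subsampling is deterministic
  gb <- group_lumens(ball_candidates())[[1]]
  s1 <- build_point_cloud(gb, calibration(1, 2), max_points = 100, seed = 3)
  s2 <- build_point_cloud(gb, calibration(1, 2), max_points = 100, seed = 3)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 100)
})

test_that("single-slice lumens use the extrusion convention", {
  cal <- cal1()
  m <- matrix(FALSE, 30, 30)
  m[11:20, 11:20] <- TRUE  # 100 px = 100 um^2, perimeter 40 um
  l <- reconstruct(group_lumens(list(mask_candidate(m, z = 2L)))[[1]], cal)
  expect_equal(l$method, "extrusion")
  expect_equal(l$volume_um3, 100 * 5)
  expect_equal(l$surface_area_um2, 2 * 100 + 40 * 5)
})

test_that("a digitized ball is reconstructed within 10% of 4/3 pi r^3", {
  l <- reconstruct(group_lumens(ball_candidates(r_um = 20, z_step = 2))[[1]],
                   calibration(1, 2))
  expect_equal(l$method, "alpha")
  truth <- 4 / 3 * pi * 20^3
  expect_lt(abs(l$volume_um3 - truth) / truth, 0.10)
  expect_gt(l$surface_area_um2, 0)
})

test_that("a vertical cylinder matches a convex-hull oracle within 15%", {
  cal <- cal1()
  cands <- lapply(0:4, function(z)
    ellipse_candidate(z, 30, 30, 15, 15, H = 60, W = 60))
  g <- group_lumens(cands)[[1]]
  l <- reconstruct(g, cal)
  # oracle: the hulled cloud spans slab faces, and for a straight cylinder
  # its convex hull is (2D hull area) x (z extent)
  pts <- lumenr:::slab_point_cloud(g, cal)
  hull_vol <- hull_area_2d(pts[, "x"], pts[, "y"]) *
    diff(range(pts[, "z"]))
  expect_lt(abs(l$volume_um3 - hull_vol) / hull_vol, 0.15)
})

test_that("hull volume is non-decreasing in alpha and bounded by the convex hull", {
  cal <- cal1()
  cands <- lapply(0:3, function(z)
    ellipse_candidate(z, 30, 30, 10 + 2 * z, 10 + 2 * z, H = 60, W = 60))
  g <- group_lumens(cands)[[1]]
  vols <- vapply(c(4, 6, 9, 13, 18), function(a)
    reconstruct(g, cal, alpha = a)$volume_um3, numeric(1))
  expect_true(all(diff(vols) >= 0))
  pts <- lumenr:::slab_point_cloud(g, cal)
  hull_vol <- hull_area_2d(pts[, "x"], pts[, "y"]) * diff(range(pts[, "z"]))
  # frustum stack is strictly inside the hull of its widest extrusion;
  # allow the half-voxel rasterization skin
  expect_lt(max(vols), hull_vol * 1.05)
})

test_that("volumes scale as s^3 and areas as s^2 under calibration scaling", {
  s <- 2.5
  c1 <- lapply(ball_candidates(r_um = 12, z_step = 3),
               function(m) m)
  g <- group_lumens(c1)[[1]]
  l1 <- reconstruct(g, calibration(1, 3))
  l2 <- reconstruct(g, calibration(1 * s, 3 * s))
  expect_equal(l2$volume_um3, l1$volume_um3 * s^3, tolerance = 1e-10)
  expect_equal(l2$surface_area_um2, l1$surface_area_um2 * s^2,
               tolerance = 1e-10)
})

test_that("summaries count and sum independently of order", {
  cal <- cal1()
  l1 <- reconstruct(group_lumens(list(ellipse_candidate(1, 40, 40, 7, 7)))[[1]], cal)
  l2 <- reconstruct(group_lumens(list(ellipse_candidate(3, 70, 70, 9, 9)))[[1]], cal)
  r <- summarize_lumens("s", list(l1, l2))
  expect_equal(r$lumen_count, 2)
  expect_equal(r$total_volume_um3, l1$volume_um3 + l2$volume_um3)
  r2 <- summarize_lumens("s", list(l2, l1))
  expect_equal(r2$total_volume_um3, r$total_volume_um3)
  r0 <- summarize_lumens("s", list())
  expect_equal(r0$lumen_count, 0)
  expect_equal(r0$total_volume_um3, 0)
})

test_that("mesh export writes a well-formed PLY surface", {
  cal <- cal1()
  cands <- lapply(0:2, function(z)
    ellipse_candidate(z, 20, 20, 6, 6, H = 40, W = 40))
  l <- reconstruct(group_lumens(cands)[[1]], cal, keep_grid = TRUE)
  path <- tempfile(fileext = ".ply")
  export_mesh(l, path)
  txt <- readLines(path)
  expect_equal(txt[1], "ply")
  nv <- as.integer(sub("element vertex ", "", grep("element vertex", txt, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("element face", txt, value = TRUE)))
  expect_gt(nv, 0); expect_gt(nf, 0)
  expect_equal(length(txt), 9 + nv + nf)
})
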