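test_that("read_stack maps pages to channels and slices", {
  tmp <- tempfile(fileext = ".tif")
  pages <- lapply(1:10, function(i) matrix(i / 20, 16, 12))
  tiff::writeTIFF(pages, tmp, bits.per.sample = 16)
  st <- read_stack(tmp, calibration(0.5, 5))
  expect_s3_class(st, "image_stack")
  expect_equal(n_slices(st), 5)
  expect_equal(dim(st$channels$nuclei), c(16, 12, 5))
  # interleaved order: page 1 -> nuclei z0, page 2 -> actin z0, ...
  expect_equal(st$channels$nuclei[1, 1, 1], 1 / 20, tolerance = 1e-3)
  expect_equal(st$channels$actin[1, 1, 3], 6 / 20, tolerance = 1e-3)
  # planar order
  stp <- read_stack(tmp, calibration(0.5, 5), arrangement = "planar")
  expect_equal(stp$channels$actin[1, 1, 1], 6 / 20, tolerance = 1e-3)
  # single-slice two-page file
  tmp1 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.9, 8, 8)), tmp1)
  expect_equal(n_slices(read_stack(tmp1, calibration(1, 5))), 1)
})

test_that("read_stack rejects bad channel structure with descriptive errors", {
  tmp <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:9, function(i) matrix(0.5, 8, 8)), tmp)
  expect_error(read_stack(tmp, calibration(1, 5)), "channel count")
  tmp_rgb <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(array(0.5, c(8, 8, 3)), array(0.5, c(8, 8, 3))), tmp_rgb)
  expect_error(read_stack(tmp_rgb, calibration(1, 5)), "channel count")
  tmp_rag <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 8, 8), matrix(0.5, 10, 8)), tmp_rag)
  expect_error(read_stack(tmp_rag, calibration(1, 5)), "page 2")
})

test_that("fuse_channels normalizes, combines and stays within [0,1]", {
  z0 <- matrix(0, 10, 10)
  st0 <- image_stack(z0, z0, calibration(1, 5))
  expect_true(all(fuse_channels(st0, 0)$raster == 0))
  # constant positive channel normalizes to zero by convention
  stc <- image_stack(matrix(3, 10, 10), z0, calibration(1, 5))
  expect_true(all(fuse_channels(stc, 0)$raster == 0))
  # disjoint bright spots survive a pixelwise max at value 1
  a <- matrix(0, 10, 10); a[2, 2] <- 5
  b <- matrix(0, 10, 10); b[8, 8] <- 7
  f <- fuse_channels(image_stack(a, b, calibration(1, 5)), 0, mode = "max")
  expect_equal(f$raster[2, 2], 1)
  expect_equal(f$raster[8, 8], 1)
  expect_equal(f$raster, pmax(a / 5, b / 7))
  expect_error(fuse_channels(st0, 1), "out of range")
  # property: output in [0,1], shape preserved, for both modes
  set.seed(41)
  for (i in 1:5) {
    n <- matrix(runif(64, 0, 10), 8, 8)
    m <- matrix(runif(64, 0, 3), 8, 8)
    st <- image_stack(n, m, calibration(1, 5))
    for (mode in c("max", "wsum")) {
      r <- fuse_channels(st, 0, mode = mode)$raster
      expect_equal(dim(r), c(8, 8))
      expect_true(min(r) >= 0 && max(r) <= 1)
    }
  }
})

test_that("report CSV round trip preserves all numeric fields and totals", {
  cal <- cal1()
  c1 <- ellipse_candidate(3, 40, 40, 8, 9)
  c1$candidate_id <- "z003_c001"
  g <- group_lumens(list(c1))[[1]]
  l1 <- reconstruct(g, cal)
  c2 <- ellipse_candidate(5, 70, 70, 6, 6)
  c2$candidate_id <- "z005_c001"
  l2 <- reconstruct(group_lumens(list(c2))[[1]], cal)
  rep <- summarize_lumens("stackA", list(l1, l2))
  expect_equal(rep$total_volume_um3, l1$volume_um3 + l2$volume_um3)
  path <- tempfile(fileext = ".csv")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$lumens$volume_um3,
               c(l1$volume_um3, l2$volume_um3))
  expect_equal(back$lumens$surface_area_um2,
               c(l1$surface_area_um2, l2$surface_area_um2))
  expect_equal(back$summary$lumen_count, 2)
  expect_equal(back$summary$total_volume_um3, rep$total_volume_um3)
  expect_equal(back$summary$total_volume_um3,
               sum(back$lumens$volume_um3), tolerance = 1e-6)
  # empty report
  rep0 <- summarize_lumens("empty")
  expect_equal(rep0$lumen_count, 0)
  expect_equal(rep0$total_volume_um3, 0)
  path0 <- tempfile(fileext = ".csv")
  write_report(rep0, path0)
  back0 <- read_report(path0)
  expect_equal(nrow(back0$lumens), 0)
  expect_equal(back0$summary$total_volume_um3, 0)
})

test_that("labeled mask stacks round-trip losslessly", {
  masks <- array(0L, c(12, 9, 3))
  masks[3:5, 2:4, 1] <- 7L
  masks[8:10, 5:8, 2] <- 213L
  masks[1, 1, 3] <- 65535L
  tmp <- tempfile(fileext = ".tif")
  write_mask_stack(masks, tmp)
  expect_identical(read_mask_stack(tmp), masks)
})

test_that("run config files parse from yaml and key=value", {
  ktmp <- tempfile(fileext = ".cfg")
  writeLines(c("pixel_size_xy = 0.65  # um per px", "z_step = 5",
               "fuse_mode = max", "max_gap = 1"), ktmp)
  cfg <- read_run_config(ktmp)
  expect_equal(cfg$pixel_size_xy, 0.65)
  expect_equal(cfg$max_gap, 1)
  ytmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(pixel_size_xy = 0.3, alpha = "auto"), ytmp)
  cfg2 <- read_run_config(ytmp)
  expect_equal(cfg2$pixel_size_xy, 0.3)
  expect_equal(cfg2$alpha, "auto")
})
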