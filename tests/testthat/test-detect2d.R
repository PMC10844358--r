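test_that("iteration_radii is the documented arithmetic schedule", {
  expect_equal(iteration_radii(detection_config()),
               c(6, 11, 16, 21, 26, 31, 36, 41))
  expect_equal(iteration_radii(detection_config(n_iter = 1)), 6)
  expect_equal(iteration_radii(detection_config(r0 = 4, dr = 2, n_iter = 3)),
               c(4, 6, 8))
})

test_that("binarization maximizes between-class variance and handles degenerate input", {
  cfg0 <- detection_config(smooth_sigma = 0)
  expect_false(any(binarize_slice(raw_fused(matrix(0, 20, 20)), cfg0)$mask))
  expect_false(any(binarize_slice(raw_fused(matrix(0.5, 20, 20)), cfg0)$mask))
  # two-valued image: exactly the bright pixels are foreground, matching an
  # exhaustive threshold search
  set.seed(7)
  for (i in 1:4) {
    x <- matrix(0.1, 24, 24)
    bright <- sample(24 * 24, 150)
    x[bright] <- 0.8
    got <- binarize_slice(raw_fused(x), cfg0)$mask
    expect_identical(which(got), sort(bright))
    expect_identical(got, oracle_otsu_mask(x))
  }
  # smoothing on by default; foreground must still be the bright blob core
  x <- matrix(0.1, 32, 32)
  x[8:24, 8:24] <- 0.85
  got <- binarize_slice(raw_fused(x), detection_config())$mask
  expect_true(all(got[10:22, 10:22]))
  expect_false(any(got[1:4, ]))
})

test_that("close_mask is identity at radius 0, extensive and idempotent", {
  cal <- cal1()
  for (s in 1:6) {
    m <- random_mask(100 + s)
    bs <- raw_binary(m)
    expect_identical(close_mask(bs, 0, cal)$mask, m)
    r <- sample(1:6, 1)
    cl <- close_mask(bs, r, cal)
    expect_true(all(cl$mask[m]))                      # extensivity
    expect_identical(close_mask(cl, r, cal)$mask, cl$mask)  # idempotence
  }
})

test_that("close_mask equals the brute-force dilation-then-erosion oracle", {
  cal <- cal1()
  for (s in 1:8) {
    m <- random_mask(200 + s, H = 40, W = 36)
    r <- ((s - 1) %% 4) + 1
    expect_identical(close_mask(raw_binary(m), r, cal)$mask,
                     oracle_close(m, r),
                     info = paste("seed", s, "radius", r))
  }
  # sub-pixel physical radii round to >= 1 px
  m <- random_mask(300, H = 20, W = 20)
  expect_identical(close_mask(raw_binary(m), 0.3, cal)$mask, oracle_close(m, 1))
})

test_that("closing seals a boundary break so the interior becomes enclosed", {
  cal <- cal1()
  ring <- make_annulus(0, H = 48, W = 48, r_out = 18, r_in = 12, cy = 24, cx = 24)
  ring[23:25, 36:48] <- FALSE  # ~3 px break
  # before closing the interior leaks into the background: one big bg comp
  v0 <- extract_voids(raw_binary(ring), detection_config(min_area_um2 = 5), cal)
  expect_length(v0, 0)
  cl <- close_mask(raw_binary(ring), 6, cal)
  v1 <- extract_voids(cl, detection_config(min_area_um2 = 5), cal)
  expect_length(v1, 1)
})

test_that("extract_voids matches a flood-fill oracle and drops the background", {
  cal <- cal1()
  cfg <- detection_config(min_area_um2 = 0)
  # solid disk with one interior hole
  m <- matrix(FALSE, 50, 50)
  m <- (row(m) - 25)^2 + (col(m) - 25)^2 <= 400
  hole <- (row(m) - 25)^2 + (col(m) - 28)^2 <= 36
  got <- extract_voids(raw_binary(m & !hole), cfg, cal)
  expect_length(got, 1)
  expect_identical(got[[1]]$idx, sort(which(hole)))
  expect_equal(got[[1]]$area_um2, sum(hole))
  # two holes -> two candidates, both matching the oracle
  hole2 <- (row(m) - 32)^2 + (col(m) - 18)^2 <= 16
  closed <- m & !hole & !hole2
  got2 <- extract_voids(raw_binary(closed), cfg, cal)
  orc <- oracle_extract(closed)
  expect_length(got2, length(orc))
  expect_identical(lapply(got2, function(x) x$idx), orc)
  # all-foreground slice has no background at all
  expect_length(extract_voids(raw_binary(matrix(TRUE, 10, 10)), cfg, cal), 0)
  # min-area filter suppresses specks (hole2 is 49 px = 49 um^2)
  expect_length(extract_voids(raw_binary(m & !hole2),
                              detection_config(min_area_um2 = 60), cal), 0)
  expect_length(extract_voids(raw_binary(m & !hole2),
                              detection_config(min_area_um2 = 40), cal), 1)
  # border filter drops border-touching voids
  mb <- matrix(TRUE, 20, 20)
  mb[1:5, 8:12] <- FALSE       # touches border
  mb[10:12, 10:12] <- FALSE    # interior
  cfgb <- detection_config(min_area_um2 = 0, border_filter = TRUE)
  # the big background is absent here, so largest = border void is removed
  gotb <- extract_voids(raw_binary(mb), cfgb, cal)
  expect_length(gotb, 1)
  expect_equal(gotb[[1]]$area_px, 9)
})

test_that("superimpose keeps one copy per void, at its largest form", {
  m1 <- matrix(FALSE, 30, 30); m1[5:16, 5:14] <- TRUE    # 120 px
  m2 <- matrix(FALSE, 30, 30); m2[6:16, 6:14] <- TRUE    # 99 px, overlaps
  m3 <- matrix(FALSE, 30, 30); m3[22:25, 22:26] <- TRUE  # disjoint
  c1 <- mask_candidate(m1, first_iter = 1L)
  c2 <- mask_candidate(m2, first_iter = 2L)
  c3 <- mask_candidate(m3, first_iter = 2L)
  out <- superimpose(list(c1, c2, c3))
  expect_length(out, 2)
  areas <- sort(vapply(out, function(x) x$area_px, numeric(1)))
  expect_equal(areas, c(20, 120))
  # masks are inputs verbatim
  expect_true(any(vapply(out, function(x) identical(x$idx, c1$idx), logical(1))))
  expect_length(superimpose(list()), 0)
  # area tie -> earliest iteration wins
  c2b <- mask_candidate(m1, first_iter = 2L)
  rep1 <- superimpose(list(c2b, c1))
  expect_equal(rep1[[1]]$first_iter, 1L)
})

test_that("detect_slice finds a gapped void once and a clean void accurately", {
  cal <- cal1()
  cfg <- detection_config()
  # annulus with an 8 um boundary gap: absent at radius 0, found by the
  # schedule, reported exactly once
  ring <- make_annulus(8)
  f <- raw_fused(ring * 0.9)
  cands <- detect_slice(f, detection_config(smooth_sigma = 0), cal)
  expect_length(cands, 1)
  expect_true(cands[[1]]$first_iter >= 1)
  # blank slice
  expect_length(detect_slice(raw_fused(matrix(0, 64, 64)), cfg, cal), 0)
  # clean (gap-free) void: detected at iteration 1 at its largest form with
  # area close to truth
  ring0 <- make_annulus(0)
  hole_px <- sum(!ring0 & sqrt((row(ring0) - 32)^2 + (col(ring0) - 32)^2) < 18)
  cands0 <- detect_slice(raw_fused(ring0 * 0.9),
                         detection_config(smooth_sigma = 0), cal)
  expect_length(cands0, 1)
  expect_equal(cands0[[1]]$first_iter, 1L)
  expect_lt(abs(cands0[[1]]$area_um2 - hole_px) / hole_px, 0.1)
  # two separate voids -> two candidates with unique ids
  disk <- matrix(FALSE, 64, 64)
  disk <- (row(disk) - 32)^2 + (col(disk) - 32)^2 <= 28^2
  h1 <- (row(disk) - 24)^2 + (col(disk) - 24)^2 <= 49
  h2 <- (row(disk) - 42)^2 + (col(disk) - 40)^2 <= 36
  cands2 <- detect_slice(raw_fused((disk & !h1 & !h2) * 0.8),
                         detection_config(smooth_sigma = 0), cal)
  expect_length(cands2, 2)
  ids <- vapply(cands2, function(x) x$candidate_id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("detected void area is non-increasing across growing disk radii", {
  cal <- cal1()
  cfg <- detection_config(smooth_sigma = 0, min_area_um2 = 5)
  ring <- make_annulus(0)
  bin <- binarize_slice(raw_fused(ring * 0.9), cfg)
  # the void shrinks with the disk radius and eventually closes entirely
  # (disk radius reaches the hole radius); once gone it stays gone
  present <- c(); areas <- c()
  for (r in iteration_radii(cfg)) {
    v <- extract_voids(close_mask(bin, r, cal), cfg, cal)
    present <- c(present, length(v) == 1)
    if (length(v) == 1) areas <- c(areas, v[[1]]$area_px)
  }
  expect_true(present[1])
  expect_true(all(diff(areas) <= 0))
  expect_true(all(diff(present) <= 0))
})

test_that("no candidate is ever the largest background component", {
  cal <- cal1()
  cfg <- detection_config(min_area_um2 = 0)
  for (s in 1:5) {
    m <- random_mask(400 + s, H = 40, W = 40, frac = 0.6)
    closed <- close_mask(raw_binary(m), 3, cal)
    lab <- oracle_label4(!closed$mask)
    if (max(lab) == 0) next
    big <- sort(which(lab == which.max(tabulate(lab))))
    for (cand in extract_voids(closed, cfg, cal))
      expect_false(identical(cand$idx, big))
  }
})
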