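# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

cal1 <- function() calibration(1, 5)

# Candidate from an explicit logical mask.
mask_candidate <- function(mask, z = 0L, pixel_size = 1, id = NA_character_,
                           first_iter = 1L) {
  lumenr:::new_candidate(z, which(mask), dim(mask), pixel_size,
                         first_iter = first_iter, label = 1L,
                         candidate_id = id)
}

# Filled ellipse candidate on an H x W slice.
ellipse_candidate <- function(z, cy, cx, sy, sx, H = 120, W = 120,
                              pixel_size = 1) {
  m <- matrix(FALSE, H, W)
  m <- ((row(m) - cy) / sy)^2 + ((col(m) - cx) / sx)^2 <= 1
  mask_candidate(m, z, pixel_size)
}

# Candidates tracing a digitized ball of radius r_um, 1 um pixels.
ball_candidates <- function(r_um = 20, z_step = 2, H = 52, W = 52,
                            cy = 26, cx = 26) {
  zc <- ceiling(r_um / z_step) * z_step
  out <- list()
  for (k in seq(0, 2 * zc, by = z_step)) {
    rz2 <- r_um^2 - (k - zc)^2
    if (rz2 <= 0) next
    m <- matrix(FALSE, H, W)
    m <- (row(m) - cy)^2 + (col(m) - cx)^2 <= rz2
    if (any(m)) out[[length(out) + 1L]] <- mask_candidate(m, k / z_step)
  }
  out
}

# Small, fast synthetic spec for unit tests (96 px, 16 slices).
small_spec <- function(seed, lumens = NULL, noise_sigma = 0.05, ...) {
  if (is.null(lumens))
    lumens <- list(list(center = c(37.5, 48, 40), radii = c(11, 13, 12)),
                   list(center = c(37.5, 48, 68), radii = c(6, 7, 7),
                        is_true = FALSE))
  synthetic_spec(lumens = lumens, seed = seed, image_size = c(96, 96),
                 n_slices = 16, calibration = calibration(1, 5),
                 spheroid_radius_um = 38, noise_sigma = noise_sigma, ...)
}

# A fused slice directly from a raster matrix.
raw_fused <- function(raster, z = 0L) lumenr:::fused_slice(raster, z)

raw_binary <- function(mask, z = 0L) lumenr:::binary_slice(mask, z)
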