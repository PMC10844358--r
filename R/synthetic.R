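#' Specification of a synthetic spheroid stack
#'
#' Describes a two-channel z-stack of one spherical microtissue containing
#' ellipsoidal voids with known geometry: true lumens (dark voids fully
#' rimmed by bright actin signal, optionally with a boundary gap channel that
#' connects them to the exterior), rimless decoy voids (the surrounding wall
#' signal is suppressed, mimicking enclosed voids that are not lumens), and
#' optional exterior pockets (bright shells outside the spheroid enclosing
#' background). All geometry is in micrometres, coordinates ordered (z, y, x).
#'
#' @param lumens list of voids; each element is a list with \code{center}
#'   (length-3, um, (z, y, x)), \code{radii} (length-3 ellipsoid semi-axes,
#'   um, (z, y, x)), optional \code{gap_um} (width of a boundary-gap channel,
#'   default 0) and optional \code{is_true} (default \code{TRUE};
#'   \code{FALSE} renders a rimless decoy).
#' @param seed mandatory integer seed; all randomness (nuclei speckle,
#'   noise) flows from it.
#' @param image_size (H, W) in pixels.
#' @param n_slices number of z-slices.
#' @param calibration a \code{\link{calibration}}.
#' @param spheroid_radius_um radius of the spherical cell mass, centered in
#'   the volume.
#' @param exterior_pockets list of decoys outside the spheroid; each a list
#'   with \code{center} (z, y, x um) and \code{radius_um} of a bright
#'   spherical shell enclosing background.
#' @param noise_sigma Gaussian intensity noise s.d. (intensity units of the
#'   \[0, 1\] rendering). Default 0.05.
#' @return An object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(lumens, seed, image_size = c(160, 160),
                           n_slices = 30, calibration = NULL,
                           spheroid_radius_um = 65,
                           exterior_pockets = list(), noise_sigma = 0.05) {
  if (is.null(calibration)) calibration <- calibration(1, 5)
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1,
            length(image_size) == 2, all(image_size >= 8),
            n_slices >= 1, inherits(calibration, "calibration"),
            spheroid_radius_um > 0, noise_sigma >= 0)
  center <- c(z = (n_slices - 1) * calibration$z_step / 2,
              y = (image_size[1] - 1) * calibration$pixel_size_xy / 2,
              x = (image_size[2] - 1) * calibration$pixel_size_xy / 2)
  lumens <- lapply(lumens, function(l) {
    stopifnot(length(l$center) == 3, length(l$radii) == 3, all(l$radii > 0))
    if (is.null(l$gap_um)) l$gap_um <- 0
    if (is.null(l$is_true)) l$is_true <- TRUE
    d <- sqrt(sum((l$center - center)^2))
    if (d + max(l$radii) > spheroid_radius_um)
      stop("lumen outside spheroid: center distance ", round(d, 1),
           " + max radius ", max(l$radii), " exceeds spheroid radius ",
           spheroid_radius_um)
    l
  })
  for (p in exterior_pockets) {
    stopifnot(length(p$center) == 3, p$radius_um > 0)
    d <- sqrt(sum((p$center - center)^2))
    if (d - p$radius_um - 3 < spheroid_radius_um)
      stop("exterior pocket overlaps the spheroid")
  }
  structure(list(image_size = as.integer(image_size),
                 n_slices = as.integer(n_slices),
                 calibration = calibration,
                 spheroid_radius_um = spheroid_radius_um,
                 spheroid_center = center,
                 lumens = lumens,
                 exterior_pockets = exterior_pockets,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Intensity constants of the renderer.
.render <- list(actin_cell = 0.8, actin_rimless = 0.15, rim_suppress_um = 4,
                pocket_intensity = 0.7, pocket_shell_um = 2.5,
                nuclei_base = 0.1, nuclei_dot = 0.9, dot_density = 0.004)

#' Render a synthetic spheroid stack with ground truth
#'
#' Renders the spheroid as a bright cell mass in both channels (actin:
#' continuous wall signal; nuclei: seeded speckled dots on a faint base),
#' carves the specified ellipsoidal voids, suppresses the wall around decoy
#' voids, opens boundary-gap channels from gapped lumens to the exterior,
#' draws exterior pocket shells, and adds Gaussian intensity noise. Identical
#' specs (same seed) render bit-identical stacks.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{stack} (an \code{\link{image_stack}}) and
#'   \code{truth} (a \code{"synthetic_ground_truth"}: per-slice labeled void
#'   masks, per-void labels and analytic volumes, expected lumen count and
#'   expected total true-lumen volume \eqn{4/3 \pi abc}).
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]; Z <- spec$n_slices
  px <- spec$calibration$pixel_size_xy; zs <- spec$calibration$z_step
  yy <- (seq_len(H) - 1) * px
  xx <- (seq_len(W) - 1) * px
  ctr <- spec$spheroid_center
  lat2 <- outer((yy - ctr["y"])^2, (xx - ctr["x"])^2, "+")
  nuclei <- array(0, c(H, W, Z))
  actin <- array(0, c(H, W, Z))
  void_masks <- array(0L, c(H, W, Z))
  n_voids <- length(spec$lumens) + length(spec$exterior_pockets)
  labels <- character(n_voids)
  volumes <- numeric(n_voids)
  with_seed(spec$seed, {
    for (k in seq_len(Z)) {
      zp <- (k - 1) * zs
      cell <- lat2 <= spec$spheroid_radius_um^2 - (zp - ctr["z"])^2
      act <- ifelse(cell, .render$actin_cell, 0)
      for (i in seq_along(spec$lumens)) {
        l <- spec$lumens[[i]]
        q <- outer(((yy - l$center[2]) / l$radii[2])^2,
                   ((xx - l$center[3]) / l$radii[3])^2, "+") +
          ((zp - l$center[1]) / l$radii[1])^2
        inside <- q <= 1
        if (any(inside)) {
          act[inside] <- 0
          cell[inside] <- FALSE
          sl <- void_masks[, , k]
          sl[inside] <- i
          void_masks[, , k] <- sl
        }
        if (!l$is_true) {
          # rimless decoy: suppress the wall in a shell around the void
          rs <- .render$rim_suppress_um
          q2 <- outer(((yy - l$center[2]) / (l$radii[2] + rs))^2,
                      ((xx - l$center[3]) / (l$radii[3] + rs))^2, "+") +
            ((zp - l$center[1]) / (l$radii[1] + rs))^2
          shell <- q2 <= 1 & !inside
          act[shell & cell] <- .render$actin_rimless
        }
        if (l$gap_um > 0 && abs(zp - l$center[1]) <= l$gap_um / 2) {
          # boundary-gap channel: dark tube from the void to the exterior
          tube <- outer(abs(yy - l$center[2]) <= l$gap_um / 2,
                        xx >= l$center[3], "&")
          act[tube] <- 0
          cell[tube] <- FALSE
        }
      }
      for (j in seq_along(spec$exterior_pockets)) {
        p <- spec$exterior_pockets[[j]]
        r2 <- outer((yy - p$center[2])^2, (xx - p$center[3])^2, "+") +
          (zp - p$center[1])^2
        shell <- r2 <= (p$radius_um + .render$pocket_shell_um)^2 &
          r2 > p$radius_um^2
        act[shell] <- pmax(act[shell], .render$pocket_intensity)
        inside <- r2 <= p$radius_um^2
        if (any(inside)) {
          sl <- void_masks[, , k]
          sl[inside] <- length(spec$lumens) + j
          void_masks[, , k] <- sl
        }
      }
      nuc <- ifelse(cell, .render$nuclei_base, 0)
      cell_idx <- which(cell)
      ndots <- round(.render$dot_density * length(cell_idx))
      if (ndots > 0) {
        dots <- sample(cell_idx, ndots)
        drow <- ((dots - 1L) %% H) + 1L
        dcol <- ((dots - 1L) %/% H) + 1L
        kern <- exp(-(outer((-2:2)^2, (-2:2)^2, "+")) / 2)
        for (d in seq_along(dots)) {
          r0 <- max(1L, drow[d] - 2L); r1 <- min(H, drow[d] + 2L)
          c0 <- max(1L, dcol[d] - 2L); c1 <- min(W, dcol[d] + 2L)
          kw <- kern[(r0 - drow[d] + 3L):(r1 - drow[d] + 3L),
                     (c0 - dcol[d] + 3L):(c1 - dcol[d] + 3L), drop = FALSE]
          nuc[r0:r1, c0:c1] <- pmax(nuc[r0:r1, c0:c1], .render$nuclei_dot * kw)
        }
        nuc[!cell] <- 0  # nuclear signal stays within cells (no PSF spill)
      }
      if (spec$noise_sigma > 0) {
        nuc <- nuc + rnorm(H * W, 0, spec$noise_sigma)
        act <- act + rnorm(H * W, 0, spec$noise_sigma)
      }
      nuclei[, , k] <- pmax(nuc, 0)
      actin[, , k] <- pmax(act, 0)
    }
  })
  for (i in seq_along(spec$lumens)) {
    l <- spec$lumens[[i]]
    labels[i] <- if (l$is_true) "true_lumen" else "false_lumen"
    volumes[i] <- 4 / 3 * pi * prod(l$radii)
  }
  for (j in seq_along(spec$exterior_pockets)) {
    labels[length(spec$lumens) + j] <- "false_lumen"
    volumes[length(spec$lumens) + j] <-
      4 / 3 * pi * spec$exterior_pockets[[j]]$radius_um^3
  }
  truth <- structure(
    list(void_masks = void_masks, labels = labels,
         analytic_volumes_um3 = volumes,
         expected_lumen_count = sum(labels == "true_lumen"),
         expected_total_volume_um3 = sum(volumes[labels == "true_lumen"]),
         spec = spec),
    class = "synthetic_ground_truth")
  stack <- image_stack(nuclei, actin, spec$calibration,
                       stack_id = sprintf("synthetic_%d", spec$seed))
  list(stack = stack, truth = truth)
}

#' Draw a random synthetic spheroid specification
#'
#' Samples the study conditions used throughout the package's validation:
#' a 160 x 160 px, 30-slice spheroid (1 um pixels, 5 um z-step, radius 65 um)
#' containing 1-4 ellipsoidal true lumens with semi-axes between 10 and 30 um
#' (at most one with a small boundary gap of up to 8 um) and 0-2 rimless decoy
#' voids (semi-axes 6-12 um), all mutually separated, with intensity noise
#' s.d. 0.05. Placement is rejection-sampled; if a void cannot be placed its
#' radius shrinks until it fits, keeping generation total.
#'
#' @param seed integer seed; the spec (and hence the rendered stack) is a
#'   deterministic function of it.
#' @param n_true number of true lumens; default drawn uniformly from 1-4.
#' @param n_decoys number of decoys; default drawn uniformly from 0-2.
#' @return A \code{\link{synthetic_spec}}.
#' @export
random_synthetic_spec <- function(seed, n_true = NULL, n_decoys = NULL) {
  cal <- calibration(1, 5)
  image_size <- c(160L, 160L)
  n_slices <- 30L
  R <- 65
  center <- c(z = (n_slices - 1) * cal$z_step / 2,
              y = (image_size[1] - 1) / 2, x = (image_size[2] - 1) / 2)
  lumens <- with_seed(seed, {
    if (is.null(n_true)) n_true <- sample(1:4, 1)
    if (is.null(n_decoys)) n_decoys <- sample(0:2, 1)
    placed <- list()
    place_void <- function(base_r, is_true, gap_um) {
      clearance <- if (is_true) 6 else 6 + .render$rim_suppress_um
      repeat {
        radii <- pmin(30, pmax(6, base_r * runif(3, 0.85, 1.15)))
        ok <- FALSE
        for (try in seq_len(400)) {
          u <- runif(3, -1, 1)
          if (sum(u^2) > 1) next
          cen <- center + u * (R - max(radii) - clearance)
          ok <- TRUE
          for (p in placed) {
            if (sqrt(sum((cen - p$center)^2)) <
                max(radii) + max(p$radii) + 10) {
              ok <- FALSE
              break
            }
          }
          if (ok) break
        }
        if (ok) {
          return(list(center = cen, radii = radii, gap_um = gap_um,
                      is_true = is_true))
        }
        base_r <- base_r - 2
        if (base_r < 6) stop("could not place synthetic void")
      }
    }
    n_gapped <- 0
    for (i in seq_len(n_true)) {
      gap <- if (n_gapped == 0 && runif(1) < 0.3) runif(1, 4, 8) else 0
      if (gap > 0) n_gapped <- 1
      v <- place_void(runif(1, 10, 26), TRUE, gap)
      placed[[length(placed) + 1]] <- v
    }
    for (i in seq_len(n_decoys))
      placed[[length(placed) + 1]] <- place_void(runif(1, 6, 11), FALSE, 0)
    placed
  })
  synthetic_spec(lumens = lumens, seed = seed, image_size = image_size,
                 n_slices = n_slices, calibration = cal,
                 spheroid_radius_um = R, noise_sigma = 0.05)
}

#' Build a balanced labeled patch set from synthetic stacks
#'
#' Runs phase-I detection on generated stacks and labels every candidate by
#' ground-truth overlap: a candidate with at least half of its pixels inside
#' a true void is a \code{true_lumen}, anything else (decoys, noise
#' components) a \code{false_lumen}. Patches are accumulated until \code{n/2}
#' of each class are available and returned as a balanced set; if the supplied
#' specs cannot reach balance, the maximal balanced subset is returned with a
#' warning.
#'
#' @param specs list of \code{\link{synthetic_spec}}; by default random specs
#'   derived from \code{seed} are generated as needed.
#' @param n target total number of labeled patches (>= 2). Default 200.
#' @param seed integer seed for default spec generation.
#' @param config a \code{\link{detection_config}}.
#' @param margin_um,side patch-preparation parameters (see
#'   \code{\link{prepare_patch}}).
#' @return list of \code{"labeled_patch"} objects, classes balanced.
#' @export
make_patch_training_set <- function(specs = NULL, n = 200, seed = 1,
                                    config = detection_config(),
                                    margin_um = 5, side = 64) {
  stopifnot(n >= 2)
  target <- n %/% 2
  pos <- list(); neg <- list()
  next_spec <- 0L
  get_spec <- function() {
    if (!is.null(specs)) {
      if (next_spec >= length(specs)) return(NULL)
      specs[[next_spec + 1L]]
    } else {
      if (next_spec >= 24L) return(NULL)  # generation cap
      random_synthetic_spec(seed * 1000L + next_spec)
    }
  }
  repeat {
    spec <- get_spec()
    next_spec <- next_spec + 1L
    if (is.null(spec) || (length(pos) >= target && length(neg) >= target))
      break
    gen <- generate_stack(spec)
    cal <- gen$stack$calibration
    for (z in 0:(n_slices(gen$stack) - 1)) {
      fused <- fuse_channels(gen$stack, z)
      for (cand in detect_slice(fused, config, cal)) {
        lab_slice <- gen$truth$void_masks[, , z + 1L]
        ids <- lab_slice[cand$idx]
        frac <- mean(ids > 0 & gen$truth$labels[pmax(ids, 1L)] == "true_lumen")
        patch <- prepare_patch(cand, fused, cal, margin_um, side)
        if (frac >= 0.5) {
          if (length(pos) < target)
            pos[[length(pos) + 1L]] <- labeled_patch(patch, "true_lumen")
        } else if (length(neg) < target) {
          neg[[length(neg) + 1L]] <- labeled_patch(patch, "false_lumen")
        }
      }
    }
  }
  k <- min(length(pos), length(neg))
  if (k < target)
    warning(sprintf(
      "could not reach %d patches per class; returning %d per class",
      target, k))
  c(pos[seq_len(k)], neg[seq_len(k)])
}
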