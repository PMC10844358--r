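#' Phase-I detection configuration
#'
#' Parameters of the per-slice void-detection pipeline: binarization, a
#' schedule of morphological closings with growing disk radii, and
#' connected-component extraction of voids. The defaults follow the published
#' protocol: closing starts at a 6 micrometre disk so small lumens are not
#' swallowed, and is repeated for 8 iterations with 5 micrometre increments so
#' that progressively larger boundary gaps get sealed.
#'
#' @param r0 initial closing disk radius, micrometres (> 0). Default 6.
#' @param dr radius increment per iteration, micrometres (>= 0). Default 5.
#' @param n_iter number of closing iterations (>= 1). Default 8.
#' @param min_area_um2 minimum candidate area in square micrometres; smaller
#'   void components are treated as noise specks. Default 25.
#' @param border_filter if \code{TRUE}, void components touching the slice
#'   border are discarded as well. Off by default: the published rule rejects
#'   only the single largest background component.
#' @param binarize_method \code{"otsu"} (between-class-variance maximizing
#'   threshold, default) or \code{"fixed"}.
#' @param fixed_threshold threshold in \[0, 1\] used when
#'   \code{binarize_method = "fixed"}.
#' @param smooth_sigma Gaussian smoothing sigma in pixels applied before
#'   thresholding. Default 1; set to 0 to disable.
#' @param disk_mode whether the scheduled disk sizes are interpreted as the
#'   structuring-element \code{"radius"} (default, the common convention) or
#'   as its \code{"diameter"}.
#' @return An object of class \code{"detection_config"}.
#' @export
detection_config <- function(r0 = 6, dr = 5, n_iter = 8, min_area_um2 = 25,
                             border_filter = FALSE,
                             binarize_method = c("otsu", "fixed"),
                             fixed_threshold = 0.5, smooth_sigma = 1,
                             disk_mode = c("radius", "diameter")) {
  binarize_method <- match.arg(binarize_method)
  disk_mode <- match.arg(disk_mode)
  stopifnot(r0 > 0, dr >= 0, n_iter >= 1, n_iter == floor(n_iter),
            min_area_um2 >= 0, smooth_sigma >= 0,
            fixed_threshold >= 0, fixed_threshold <= 1,
            is.logical(border_filter), length(border_filter) == 1)
  structure(list(r0 = r0, dr = dr, n_iter = as.integer(n_iter),
                 min_area_um2 = min_area_um2, border_filter = border_filter,
                 binarize_method = binarize_method,
                 fixed_threshold = fixed_threshold,
                 smooth_sigma = smooth_sigma, disk_mode = disk_mode),
            class = "detection_config")
}

#' Closing-disk radius schedule
#'
#' Arithmetic progression of disk sizes used by the iterative closing:
#' \code{r0, r0 + dr, ..., r0 + (n_iter - 1) * dr} micrometres. With the
#' defaults this is 6, 11, 16, 21, 26, 31, 36, 41.
#'
#' @param config a \code{\link{detection_config}}.
#' @return numeric vector of disk sizes in micrometres.
#' @export
iteration_radii <- function(config = detection_config()) {
  stopifnot(inherits(config, "detection_config"))
  config$r0 + (seq_len(config$n_iter) - 1) * config$dr
}

# Scheduled disk size (um) -> structuring-element radius (um), honoring the
# radius/diameter interpretation.
effective_radius_um <- function(size_um, config) {
  if (config$disk_mode == "diameter") size_um / 2 else size_um
}

#' Binarize a fused slice
#'
#' Converts a fused slice to a black-and-white image: foreground (cellular
#' signal) is everything above an automatically chosen threshold that
#' maximizes between-class variance (Otsu), computed after light Gaussian
#' smoothing. Constant (zero-range) slices yield all-background.
#'
#' @param fused a \code{"fused_slice"} with values in \[0, 1\].
#' @param config a \code{\link{detection_config}}.
#' @return A \code{"binary_slice"}: list with logical \code{mask}
#'   (\code{TRUE} = cellular foreground) and \code{z_index}.
#' @export
binarize_slice <- function(fused, config = detection_config()) {
  stopifnot(inherits(fused, "fused_slice"))
  x <- fused$raster
  if (min(x) < 0 || max(x) > 1) stop("fused values must lie in [0, 1]")
  if (config$smooth_sigma > 0)
    x <- EBImage::gblur(x, sigma = config$smooth_sigma)
  x[x < 0] <- 0
  x[x > 1] <- 1
  if (diff(range(x)) <= 0) {
    mask <- matrix(FALSE, nrow(x), ncol(x))
  } else if (config$binarize_method == "otsu") {
    th <- EBImage::otsu(x, range = c(0, 1), levels = 256)
    mask <- x > th
  } else {
    mask <- x > config$fixed_threshold
  }
  binary_slice(mask, fused$z_index)
}

#' Morphological closing of a binary slice with a Euclidean disk
#'
#' Dilation followed by erosion with the disk \eqn{\{(dy,dx): dy^2 + dx^2 \le
#' r^2\}}, where the pixel radius r is \code{round(radius_um /
#' pixel_size_xy)} (minimum 1 px for any positive physical radius). The
#' computation uses exact squared Euclidean distance transforms on a canvas
#' padded by r, which reproduces full-plane closing exactly: the result is a
#' superset of the input (extensive) and applying the same closing twice
#' changes nothing (idempotent). A zero radius is the identity.
#'
#' @param bin a \code{"binary_slice"} (or logical matrix).
#' @param radius_um disk radius in micrometres (>= 0).
#' @param calibration a \code{\link{calibration}}.
#' @return A \code{"binary_slice"} of the same shape.
#' @export
close_mask <- function(bin, radius_um, calibration) {
  if (is.matrix(bin)) bin <- binary_slice(bin, 0L)
  stopifnot(inherits(bin, "binary_slice"), inherits(calibration, "calibration"))
  r <- radius_px(radius_um, calibration)
  if (r == 0L) return(bin)
  m <- bin$mask
  H <- nrow(m); W <- ncol(m)
  p <- r
  canvas <- matrix(FALSE, H + 2L * p, W + 2L * p)
  canvas[(p + 1):(p + H), (p + 1):(p + W)] <- m
  r2 <- as.numeric(r)^2
  dil <- cpp_edt2d_sq(canvas) <= r2        # dilation: within r of foreground
  clo <- cpp_edt2d_sq(!dil) > r2           # erosion of the dilation
  binary_slice(clo[(p + 1):(p + H), (p + 1):(p + W)], bin$z_index)
}

# Internal candidate constructor. Pixels are stored as sorted linear indices
# into the H x W slice; bbox is 0-based half-open (y0, x0, y1, x1).
new_candidate <- function(z_index, idx, dim, pixel_size_xy,
                          first_iter = NA_integer_, label = NA_integer_,
                          candidate_id = NA_character_) {
  idx <- sort(as.integer(idx))
  rows <- ((idx - 1L) %% dim[1]) + 1L
  cols <- ((idx - 1L) %/% dim[1]) + 1L
  structure(list(candidate_id = candidate_id,
                 z_index = as.integer(z_index),
                 idx = idx,
                 dim = as.integer(dim),
                 area_px = length(idx),
                 area_um2 = length(idx) * pixel_size_xy^2,
                 bbox = c(y0 = min(rows) - 1L, x0 = min(cols) - 1L,
                          y1 = max(rows), x1 = max(cols)),
                 first_iter = as.integer(first_iter),
                 label = as.integer(label)),
            class = "candidate_lumen2d")
}

#' Rebuild the logical mask of a 2D candidate
#' @param candidate a \code{"candidate_lumen2d"}.
#' @return logical H x W matrix.
#' @export
candidate_mask <- function(candidate) {
  m <- matrix(FALSE, candidate$dim[1], candidate$dim[2])
  m[candidate$idx] <- TRUE
  m
}

#' Extract candidate void components from a closed binary slice
#'
#' Labels the 4-connected components of the background (void) phase, then
#' discards the single largest component, which represents the image
#' background surrounding the microtissue (area ties are broken toward the
#' smallest, i.e. first-encountered, label). Components smaller than
#' \code{min_area_um2} are dropped as noise; with \code{border_filter},
#' components touching the slice border are dropped too.
#'
#' @param closed a \code{"binary_slice"} (\code{TRUE} = cellular foreground).
#' @param config a \code{\link{detection_config}}.
#' @param calibration a \code{\link{calibration}}.
#' @return List of \code{"candidate_lumen2d"} objects (possibly empty).
#' @export
extract_voids <- function(closed, config, calibration) {
  stopifnot(inherits(closed, "binary_slice"),
            inherits(config, "detection_config"),
            inherits(calibration, "calibration"))
  voids <- !closed$mask
  if (!any(voids)) return(list())
  lab <- cpp_label2d(voids, 4L)
  n <- max(lab)
  sizes <- tabulate(lab, nbins = n)
  background <- which.max(sizes)  # ties -> smallest label
  px2 <- calibration$pixel_size_xy^2
  keep <- setdiff(which(sizes * px2 >= config$min_area_um2), background)
  if (length(keep) == 0) return(list())
  idx_by_label <- split(which(voids), lab[voids])
  H <- nrow(voids); W <- ncol(voids)
  out <- list()
  for (l in keep) {
    idx <- idx_by_label[[as.character(l)]]
    if (config$border_filter) {
      rows <- ((idx - 1L) %% H) + 1L
      cols <- ((idx - 1L) %/% H) + 1L
      if (any(rows == 1L | rows == H | cols == 1L | cols == W)) next
    }
    out[[length(out) + 1L]] <- new_candidate(closed$z_index, idx, c(H, W),
                                             calibration$pixel_size_xy,
                                             label = l)
  }
  out
}

#' Superimpose candidates found at different closing iterations
#'
#' A physical void is typically re-detected at several iterations with
#' non-increasing area (larger disks shrink the same void in place), so
#' candidates from different iterations whose pixel sets overlap are the same
#' potential lumen. Overlap (at least one shared pixel) is closed
#' transitively; each resulting equivalence class is represented once, by its
#' largest-area member (ties broken by earliest iteration, then smallest
#' component label). Output masks are input masks verbatim.
#'
#' @param candidates flat list of \code{"candidate_lumen2d"} for one z-slice,
#'   each with its \code{first_iter} set to the iteration that produced it.
#' @return List of representative candidates.
#' @export
superimpose <- function(candidates) {
  n <- length(candidates)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (candidates[[i]]$first_iter == candidates[[j]]$first_iter) next
      if (any(candidates[[i]]$idx %in% candidates[[j]]$idx)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    areas <- vapply(members, function(i) candidates[[i]]$area_px, numeric(1))
    iters <- vapply(members, function(i) candidates[[i]]$first_iter, integer(1))
    labs <- vapply(members, function(i) candidates[[i]]$label, integer(1))
    ord <- order(-areas, iters, labs)
    out[[length(out) + 1L]] <- candidates[[members[ord[1]]]]
  }
  out
}

#' Detect candidate 2D lumens on one fused slice (phase I)
#'
#' Composition of the per-slice pipeline: binarize, then for every disk size
#' in \code{\link{iteration_radii}} apply \code{\link{close_mask}} and
#' \code{\link{extract_voids}}, and finally \code{\link{superimpose}} the
#' candidates of all iterations so each potential void appears exactly once,
#' at its largest detected form. Candidate ids are unique within the slice
#' and deterministic (ordered by bounding-box position).
#'
#' @param fused a \code{"fused_slice"}.
#' @param config a \code{\link{detection_config}}.
#' @param calibration a \code{\link{calibration}}.
#' @return List of \code{"candidate_lumen2d"} with ids \code{"z<z>_c<k>"}.
#' @export
detect_slice <- function(fused, config = detection_config(), calibration) {
  stopifnot(inherits(fused, "fused_slice"))
  bin <- binarize_slice(fused, config)
  all_cands <- list()
  radii <- iteration_radii(config)
  for (i in seq_along(radii)) {
    closed <- close_mask(bin, effective_radius_um(radii[i], config), calibration)
    cands <- extract_voids(closed, config, calibration)
    for (k in seq_along(cands)) cands[[k]]$first_iter <- i
    all_cands <- c(all_cands, cands)
  }
  reps <- superimpose(all_cands)
  if (length(reps) == 0) return(reps)
  ord <- order(vapply(reps, function(cc) cc$bbox[["y0"]], numeric(1)),
               vapply(reps, function(cc) cc$bbox[["x0"]], numeric(1)),
               -vapply(reps, function(cc) cc$area_px, numeric(1)))
  reps <- reps[ord]
  for (k in seq_along(reps))
    reps[[k]]$candidate_id <- sprintf("z%03d_c%03d", fused$z_index, k)
  reps
}
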