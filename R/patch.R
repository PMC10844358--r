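#' Cut a standardized classifier patch around a candidate lumen
#'
#' The candidate's bounding box is dilated by a physical margin on all sides
#' (so the classifier sees the lumen wall, not just the void), clipped to the
#' image, cut from the fused slice, intensity-rescaled to \[0, 1\]
#' ("remapped"; a constant window becomes all zeros), and resampled to a
#' square of side \code{side} pixels. Aspect ratio is preserved: the longer
#' axis is scaled to \code{side} and the shorter axis is zero-padded,
#' centered.
#'
#' @param candidate a \code{"candidate_lumen2d"}.
#' @param fused the \code{"fused_slice"} of the same z-index.
#' @param calibration a \code{\link{calibration}}.
#' @param margin_um bounding-box dilation margin in micrometres. Default 5.
#' @param side output patch side length in pixels. Default 64.
#' @return A \code{"lumen_patch"}: list with \code{candidate_id},
#'   \code{pixels} (side x side matrix in \[0, 1\]), \code{scale_factor} and
#'   \code{source_bbox} (the expanded, clipped 0-based half-open box).
#' @export
prepare_patch <- function(candidate, fused, calibration,
                          margin_um = 5, side = 64) {
  stopifnot(inherits(candidate, "candidate_lumen2d"),
            inherits(fused, "fused_slice"),
            inherits(calibration, "calibration"),
            side >= 2, margin_um >= 0)
  if (candidate$z_index != fused$z_index)
    stop("candidate and fused slice are from different z-indices")
  H <- nrow(fused$raster); W <- ncol(fused$raster)
  bb <- candidate$bbox
  if (bb[["y1"]] <= bb[["y0"]] || bb[["x1"]] <= bb[["x0"]])
    stop("degenerate candidate bounding box")
  m <- as.integer(round(margin_um / calibration$pixel_size_xy))
  y0 <- max(0L, bb[["y0"]] - m); x0 <- max(0L, bb[["x0"]] - m)
  y1 <- min(H, bb[["y1"]] + m); x1 <- min(W, bb[["x1"]] + m)
  win <- fused$raster[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  win <- normalize01(win)
  h <- nrow(win); w <- ncol(win)
  scale <- side / max(h, w)
  nh <- if (h >= w) side else max(1L, as.integer(round(h * scale)))
  nw <- if (w > h) side else max(1L, as.integer(round(w * scale)))
  resized <- EBImage::resize(win, w = nh, h = nw)  # EBImage dim1 = "w"
  resized[resized < 0] <- 0
  resized[resized > 1] <- 1
  pixels <- matrix(0, side, side)
  oy <- (side - nh) %/% 2L
  ox <- (side - nw) %/% 2L
  pixels[(oy + 1):(oy + nh), (ox + 1):(ox + nw)] <- resized
  structure(list(candidate_id = candidate$candidate_id,
                 pixels = pixels,
                 scale_factor = scale,
                 source_bbox = c(y0 = y0, x0 = x0, y1 = y1, x1 = x1)),
            class = "lumen_patch")
}

#' Bundle a patch with its ground-truth or manual label
#' @param patch a \code{"lumen_patch"}.
#' @param label \code{"true_lumen"} or \code{"false_lumen"}.
#' @return A \code{"labeled_patch"}.
#' @export
labeled_patch <- function(patch, label) {
  stopifnot(inherits(patch, "lumen_patch"),
            label %in% c("true_lumen", "false_lumen"))
  structure(list(patch = patch, label = label), class = "labeled_patch")
}
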