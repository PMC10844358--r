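#' Physical calibration of a z-stack
#'
#' Records the lateral pixel size and the axial step of a stack. All physical
#' quantities in the package are expressed in micrometres (areas in
#' \eqn{\mu m^2}, volumes in \eqn{\mu m^3}). The physical coordinate of voxel
#' \code{(z, y, x)} (0-based indices, pixel centers) is
#' \code{(z * z_step, y * pixel_size_xy, x * pixel_size_xy)}.
#'
#' @param pixel_size_xy lateral pixel size, micrometres per pixel (> 0).
#' @param z_step axial distance between consecutive slices, micrometres
#'   (> 0). Default 5, the acquisition step of the high-content imaging
#'   protocol the package targets.
#' @return An object of class \code{"calibration"}.
#' @examples
#' cal <- calibration(pixel_size_xy = 0.6, z_step = 5)
#' @export
calibration <- function(pixel_size_xy, z_step = 5) {
  stopifnot(is.numeric(pixel_size_xy), length(pixel_size_xy) == 1,
            is.finite(pixel_size_xy), pixel_size_xy > 0,
            is.numeric(z_step), length(z_step) == 1,
            is.finite(z_step), z_step > 0)
  structure(list(pixel_size_xy = as.numeric(pixel_size_xy),
                 z_step = as.numeric(z_step)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %.4g um/px (xy), %.4g um z-step\n",
              x$pixel_size_xy, x$z_step))
  invisible(x)
}

# Physical radius (um) -> structuring-element radius in pixels.
# Rounds to the nearest integer; any strictly positive physical radius maps
# to at least 1 px so that a scheduled closing is never silently skipped.
radius_px <- function(radius_um, calibration) {
  stopifnot(is.numeric(radius_um), length(radius_um) == 1, radius_um >= 0)
  if (radius_um <= 0) return(0L)
  max(1L, as.integer(round(radius_um / calibration$pixel_size_xy)))
}
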