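#' Construct a calibrated two-channel image stack
#'
#' A stack holds the nuclei (Hoechst) and F-actin (phalloidin) channels of one
#' microtissue as \code{H x W x Z} arrays of non-negative finite intensities,
#' ordered by ascending z, together with its physical calibration.
#'
#' @param nuclei,actin \code{H x W x Z} numeric arrays (or \code{H x W}
#'   matrices for a single slice) of non-negative finite intensities.
#' @param calibration a \code{\link{calibration}} object.
#' @param stack_id identifier used in reports.
#' @return An object of class \code{"image_stack"}.
#' @export
image_stack <- function(nuclei, actin, calibration, stack_id = "stack") {
  if (is.matrix(nuclei)) nuclei <- array(nuclei, c(dim(nuclei), 1L))
  if (is.matrix(actin)) actin <- array(actin, c(dim(actin), 1L))
  stopifnot(is.array(nuclei), length(dim(nuclei)) == 3,
            is.array(actin), identical(dim(nuclei), dim(actin)),
            inherits(calibration, "calibration"),
            is.character(stack_id), length(stack_id) == 1)
  if (dim(nuclei)[3] < 1) stop("stack must contain at least one slice")
  if (!all(is.finite(nuclei)) || !all(is.finite(actin)))
    stop("stack intensities must be finite")
  if (min(nuclei) < 0 || min(actin) < 0)
    stop("stack intensities must be non-negative")
  structure(list(channels = list(nuclei = nuclei, actin = actin),
                 calibration = calibration,
                 stack_id = stack_id),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels$nuclei)
  cat(sprintf("image_stack '%s': %d x %d px, %d slice(s), 2 channels\n",
              x$stack_id, d[1], d[2], d[3]))
  print(x$calibration)
  invisible(x)
}

#' Number of z-slices in a stack
#' @param stack an \code{\link{image_stack}}.
#' @return integer slice count.
#' @export
n_slices <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  dim(stack$channels$nuclei)[3]
}

fused_slice <- function(raster, z_index) {
  structure(list(raster = raster, z_index = as.integer(z_index)),
            class = "fused_slice")
}

binary_slice <- function(mask, z_index) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(list(mask = mask, z_index = as.integer(z_index)),
            class = "binary_slice")
}

#' Fuse the two channels of one z-slice
#'
#' Each channel slice is min-max normalized to \[0, 1\] (a constant channel
#' normalizes to all zeros), then combined pixelwise: \code{"max"} takes the
#' maximum of the two normalized channels, \code{"wsum"} takes a weighted sum
#' re-normalized to \[0, 1\]. The fused image is what downstream binarization,
#' patch cutting and classification operate on: nuclei supply the "cells"
#' signal and actin the "walls" signal, so their fusion outlines the cellular
#' region around each void.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param z 0-based slice index.
#' @param mode \code{"max"} (default) or \code{"wsum"}.
#' @param weights length-2 non-negative weights (nuclei, actin) for
#'   \code{mode = "wsum"}.
#' @return A \code{"fused_slice"}: list with \code{raster} (H x W matrix in
#'   \[0, 1\]) and \code{z_index}.
#' @export
fuse_channels <- function(stack, z, mode = c("max", "wsum"),
                          weights = c(0.5, 0.5)) {
  stopifnot(inherits(stack, "image_stack"))
  mode <- match.arg(mode)
  Z <- n_slices(stack)
  if (!(is.numeric(z) && length(z) == 1 && z == floor(z) && z >= 0 && z < Z))
    stop(sprintf("slice index z = %s out of range [0, %d]", format(z), Z - 1))
  k <- as.integer(z) + 1L
  nuc <- normalize01(stack$channels$nuclei[, , k])
  act <- normalize01(stack$channels$actin[, , k])
  raster <- switch(mode,
    max = pmax(nuc, act),
    wsum = {
      stopifnot(length(weights) == 2, all(weights >= 0), sum(weights) > 0)
      normalize01(weights[1] * nuc + weights[2] * act)
    })
  fused_slice(raster, z)
}
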