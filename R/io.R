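#' Read a calibrated two-channel z-stack from a multi-page TIFF
#'
#' Pages are mapped to (channel, z) either through an explicit
#' \code{channel_map} (a list with one integer vector of 1-based page numbers
#' per channel, one page per z-slice) or through a standard arrangement:
#' \code{"interleaved"} (channel 1 of z1, channel 2 of z1, channel 1 of z2,
#' ...) or \code{"planar"} (all pages of channel 1, then all of channel 2).
#' Physical calibration always comes from the \code{calibration} argument,
#' which overrides any file metadata.
#'
#' @param path a multi-page TIFF / OME-TIFF file.
#' @param calibration a \code{\link{calibration}}.
#' @param channels channel names in page order; must name exactly the nuclei
#'   and actin channels. Default \code{c("nuclei", "actin")}.
#' @param arrangement \code{"interleaved"} (default) or \code{"planar"},
#'   ignored when \code{channel_map} is given.
#' @param channel_map optional named list of page-index vectors.
#' @param stack_id identifier; defaults to the file name without extension.
#' @return An \code{\link{image_stack}}.
#' @export
read_stack <- function(path, calibration, channels = c("nuclei", "actin"),
                       arrangement = c("interleaved", "planar"),
                       channel_map = NULL, stack_id = NULL) {
  arrangement <- match.arg(arrangement)
  stopifnot(file.exists(path), inherits(calibration, "calibration"))
  if (length(channels) != 2 || !setequal(channels, c("nuclei", "actin")))
    stop("channel count: exactly the two channels 'nuclei' and 'actin' ",
         "must be mapped")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  for (i in seq_len(np)) {
    if (length(dim(pages[[i]])) == 3)
      stop(sprintf(
        "channel count: page %d carries %d samples per pixel; expected single-sample grayscale pages",
        i, dim(pages[[i]])[3]))
    if (!identical(dim(pages[[i]]), dim(pages[[1]])))
      stop(sprintf("ragged slice shapes: page %d is %dx%d but page 1 is %dx%d",
                   i, dim(pages[[i]])[1], dim(pages[[i]])[2],
                   dim(pages[[1]])[1], dim(pages[[1]])[2]))
  }
  if (is.null(channel_map)) {
    if (np %% 2 != 0)
      stop(sprintf(
        "channel count: %d pages cannot hold 2 channels per z-slice", np))
    nz <- np %/% 2
    channel_map <- if (arrangement == "interleaved") {
      stats::setNames(list(seq(1, np, by = 2), seq(2, np, by = 2)), channels)
    } else {
      stats::setNames(list(seq_len(nz), nz + seq_len(nz)), channels)
    }
  }
  if (!setequal(names(channel_map), c("nuclei", "actin")) ||
      length(channel_map$nuclei) != length(channel_map$actin))
    stop("channel count: channel_map must map both channels to one page per z")
  bad <- setdiff(unlist(channel_map), seq_len(np))
  if (length(bad))
    stop("channel_map references missing page(s): ",
         paste(bad, collapse = ", "))
  nz <- length(channel_map$nuclei)
  d <- dim(pages[[1]])
  nuclei <- array(0, c(d, nz))
  actin <- array(0, c(d, nz))
  for (k in seq_len(nz)) {
    nuclei[, , k] <- pages[[channel_map$nuclei[k]]]
    actin[, , k] <- pages[[channel_map$actin[k]]]
  }
  if (is.null(stack_id))
    stack_id <- sub("\\.[^.]*$", "", basename(path))
  image_stack(nuclei, actin, calibration, stack_id)
}

#' Write a two-channel stack as an interleaved multi-page 16-bit TIFF
#'
#' Intensities are clipped to \[0, 1\] and quantized to 16 bits. The page
#' order matches \code{read_stack(arrangement = "interleaved")}.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param path output file path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  Z <- n_slices(stack)
  pages <- vector("list", 2L * Z)
  for (k in seq_len(Z)) {
    pages[[2L * k - 1L]] <- pmin(pmax(stack$channels$nuclei[, , k], 0), 1)
    pages[[2L * k]] <- pmin(pmax(stack$channels$actin[, , k], 0), 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write / read a 16-bit labeled mask stack
#'
#' One TIFF page per slice; pixel value = integer label (0 = background,
#' otherwise lumen id). The round trip is lossless for labels up to 65535.
#'
#' @param masks integer H x W x Z array of labels.
#' @param path TIFF path.
#' @export
write_mask_stack <- function(masks, path) {
  stopifnot(is.array(masks), length(dim(masks)) == 3,
            min(masks) >= 0, max(masks) <= 65535)
  pages <- lapply(seq_len(dim(masks)[3]),
                  function(k) masks[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_mask_stack
#' @return \code{read_mask_stack} returns the integer label array.
#' @export
read_mask_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages))
    out[, , k] <- as.integer(round(pages[[k]] * 65535))
  out
}

#' Write a microtissue report to CSV
#'
#' Writes two RFC-4180 CSV files: a per-lumen table (\code{stack_id,
#' lumen_id, n_slices, z_min, z_max, volume_um3, surface_area_um2}) at
#' \code{path}, and a one-row summary (\code{stack_id, lumen_count,
#' total_volume_um3}) at \code{summary_path} (default: \code{path} with a
#' \code{_summary} suffix). Volumes are in cubic micrometres.
#'
#' @param report a \code{"microtissue_report"}.
#' @param path per-lumen CSV path.
#' @param summary_path summary CSV path.
#' @export
write_report <- function(report, path, summary_path = NULL) {
  stopifnot(inherits(report, "microtissue_report"))
  if (is.null(summary_path))
    summary_path <- sub("(\\.[^.]*)?$", "_summary\\1", path)
  write.csv(report_table(report), path, row.names = FALSE)
  write.csv(data.frame(stack_id = report$stack_id,
                       lumen_count = report$lumen_count,
                       total_volume_um3 = report$total_volume_um3,
                       stringsAsFactors = FALSE),
            summary_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @return \code{read_report} returns a list with data.frames \code{lumens}
#'   and \code{summary}.
#' @export
read_report <- function(path, summary_path = NULL) {
  if (is.null(summary_path))
    summary_path <- sub("(\\.[^.]*)?$", "_summary\\1", path)
  list(lumens = read.csv(path, stringsAsFactors = FALSE),
       summary = read.csv(summary_path, stringsAsFactors = FALSE))
}

#' Candidate table for QC export
#' @param candidates list of \code{"candidate_lumen2d"}.
#' @return data.frame with one row per candidate (z, id, area, bbox,
#'   first detection iteration).
#' @export
candidate_table <- function(candidates) {
  if (length(candidates) == 0) {
    return(data.frame(z = integer(), candidate_id = character(),
                      area_um2 = numeric(), y0 = integer(), x0 = integer(),
                      y1 = integer(), x1 = integer(), first_iter = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(candidates, function(cc) {
    data.frame(z = cc$z_index, candidate_id = cc$candidate_id,
               area_um2 = cc$area_um2,
               y0 = cc$bbox[["y0"]], x0 = cc$bbox[["x0"]],
               y1 = cc$bbox[["y1"]], x1 = cc$bbox[["x1"]],
               first_iter = cc$first_iter, stringsAsFactors = FALSE)
  }))
}

#' Export patches as a labeling archive
#'
#' Writes one grayscale PNG per patch plus an \code{index.csv}
#' (\code{candidate_id, file}) so external tools can attach labels for
#' \code{\link{train_classifier}}.
#'
#' @param patches list of \code{"lumen_patch"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the index data.frame.
#' @export
export_patches <- function(patches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(candidate_id = character(), file = character(),
                    stringsAsFactors = FALSE)
  for (p in patches) {
    stopifnot(inherits(p, "lumen_patch"))
    f <- file.path(dir, paste0(p$candidate_id, ".png"))
    png::writePNG(p$pixels, f)
    idx <- rbind(idx, data.frame(candidate_id = p$candidate_id,
                                 file = basename(f), stringsAsFactors = FALSE))
  }
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' Read a run-configuration file
#'
#' Accepts YAML (\code{.yml}/\code{.yaml}) or plain \code{key = value} lines
#' (\code{#} comments allowed). Values are type-converted. Keys mirror
#' \code{\link{run_config}} arguments, e.g. \code{pixel_size_xy},
#' \code{z_step}, \code{fuse_mode}, \code{max_gap}, \code{alpha},
#' \code{classifier}, \code{seed}.
#'
#' @param path config file path.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    return(yaml::read_yaml(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("cannot parse config line: ", ln)
    key <- trimws(kv[2])
    out[[key]] <- utils::type.convert(trimws(kv[3]), as.is = TRUE)
  }
  out
}
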