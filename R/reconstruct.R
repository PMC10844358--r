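#' Group accepted 2D lumens into provisional 3D lumens
#'
#' Two accepted 2D lumens belong to the same 3D lumen when their xy bounding
#' boxes intersect (seen from a vertical view) and their z-indices are within
#' \code{max_gap + 1} slices of each other; grouping is the transitive
#' closure of this relation. Any group whose member z-levels leave a run of
#' more than \code{max_gap} empty slices is then split at those gaps, since
#' such a stack most probably represents several vertically stacked lumens.
#'
#' @param accepted list of \code{"candidate_lumen2d"} accepted by the
#'   classifier, from all slices of one stack.
#' @param max_gap largest tolerated run of empty z-levels inside one group.
#'   Default 0: any missing slice splits the group.
#' @return List of \code{"lumen_group"} objects, each with deterministic
#'   \code{group_id} and members sorted by z. Every accepted lumen belongs to
#'   exactly one group.
#' @export
group_lumens <- function(accepted, max_gap = 0) {
  stopifnot(max_gap >= 0, max_gap == floor(max_gap))
  n <- length(accepted)
  if (n == 0) return(list())
  z <- vapply(accepted, function(a) a$z_index, integer(1))
  bb <- t(vapply(accepted, function(a) as.numeric(a$bbox), numeric(4)))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        dz <- abs(z[i] - z[j])
        if (dz == 0 || dz > max_gap + 1) next
        if (bb[i, 1] < bb[j, 3] && bb[j, 1] < bb[i, 3] &&
            bb[i, 2] < bb[j, 4] && bb[j, 2] < bb[i, 4]) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    members <- members[order(z[members], bb[members, 1], bb[members, 2])]
    zs <- z[members]
    # split at z-gaps wider than max_gap
    brk <- cumsum(c(0, diff(zs) > max_gap + 1))
    for (piece in split(members, brk))
      groups[[length(groups) + 1L]] <- accepted[piece]
  }
  key <- vapply(groups, function(g)
    c(g[[1]]$z_index, g[[1]]$bbox[["y0"]], g[[1]]$bbox[["x0"]]), numeric(3))
  ord <- order(key[1, ], key[2, ], key[3, ])
  out <- vector("list", length(groups))
  for (k in seq_along(ord)) {
    out[[k]] <- structure(list(group_id = sprintf("g%03d", k),
                               members = groups[[ord[k]]]),
                          class = "lumen_group")
  }
  out
}

# Linear indices of mask pixels with a 4-neighbour outside the mask (or on
# the image border): the boundary used for point-cloud building.
boundary_indices <- function(candidate) {
  m <- candidate_mask(candidate)
  H <- nrow(m); W <- ncol(m)
  inner <- matrix(TRUE, H, W)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, m[-H, , drop = FALSE])
  left <- cbind(m[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, m[, -W, drop = FALSE])
  which(m & !(up & down & left & right))
}

#' Physical-coordinate boundary point cloud of a lumen group
#'
#' Maps the boundary pixels of every member mask to micrometre coordinates
#' (pixel centers; columns \code{x}, \code{y}, \code{z}). Point clouds larger
#' than \code{max_points} are uniformly subsampled with a fixed seed so the
#' result is deterministic.
#'
#' @param group a \code{"lumen_group"}.
#' @param calibration a \code{\link{calibration}}.
#' @param max_points subsampling cap. Default 20000.
#' @param seed seed for the (rarely needed) subsampling step.
#' @return numeric matrix with columns \code{x}, \code{y}, \code{z} (um).
#' @export
build_point_cloud <- function(group, calibration, max_points = 20000,
                              seed = 1) {
  stopifnot(inherits(group, "lumen_group"), length(group$members) >= 1)
  px <- calibration$pixel_size_xy
  pts <- do.call(rbind, lapply(group$members, function(m) {
    idx <- boundary_indices(m)
    H <- m$dim[1]
    rows <- ((idx - 1L) %% H)
    cols <- ((idx - 1L) %/% H)
    cbind(x = cols * px, y = rows * px, z = m$z_index * calibration$z_step)
  }))
  if (nrow(pts) > max_points) {
    keep <- with_seed(seed, sample(nrow(pts), max_points))
    pts <- pts[sort(keep), , drop = FALSE]
  }
  pts
}

# Point cloud actually used for hull reconstruction. Each 2D lumen is a
# z_step-thick optical slab, not an infinitely thin contour: its boundary
# points are placed on both slab faces (z +/- z_step/2), which makes
# multi-slice volumes consistent with the single-slice extrusion convention
# (a one-slab stack gets area x z_step either way) and removes the half-slab
# truncation at the top and bottom of every lumen. The outermost faces (the
# bottom of the lowest members and the top of the highest) are genuine
# surfaces of the sampled solid and are sampled filled, not just at their
# rings, so the alpha ball cannot dive through the open end caps.
slab_point_cloud <- function(group, calibration, max_points = 20000,
                             seed = 1) {
  px <- calibration$pixel_size_xy
  half <- calibration$z_step / 2
  zm <- vapply(group$members, function(m) m$z_index, integer(1))
  zmin <- min(zm); zmax <- max(zm)
  pieces <- list()
  for (m in group$members) {
    H <- m$dim[1]
    zc <- m$z_index * calibration$z_step
    bidx <- boundary_indices(m)
    bxy <- cbind(x = ((bidx - 1L) %/% H) * px, y = ((bidx - 1L) %% H) * px)
    pieces[[length(pieces) + 1L]] <- cbind(bxy, z = zc - half)
    pieces[[length(pieces) + 1L]] <- cbind(bxy, z = zc + half)
    fxy <- cbind(x = ((m$idx - 1L) %/% H) * px, y = ((m$idx - 1L) %% H) * px)
    if (m$z_index == zmin)
      pieces[[length(pieces) + 1L]] <- cbind(fxy, z = zc - half)
    if (m$z_index == zmax)
      pieces[[length(pieces) + 1L]] <- cbind(fxy, z = zc + half)
  }
  pts <- do.call(rbind, pieces)
  if (nrow(pts) > 2 * max_points) {
    keep <- with_seed(seed, sample(nrow(pts), 2 * max_points))
    pts <- pts[sort(keep), , drop = FALSE]
  }
  pts
}

# Perimeter (um) of a candidate mask: count of exposed 4-edges times pixel
# size.
candidate_perimeter_um <- function(candidate, calibration) {
  m <- candidate_mask(candidate)
  H <- nrow(m); W <- ncol(m)
  vert <- sum(m[-H, , drop = FALSE] & m[-1, , drop = FALSE])
  horiz <- sum(m[, -W, drop = FALSE] & m[, -1, drop = FALSE])
  (4 * sum(m) - 2 * (vert + horiz)) * calibration$pixel_size_xy
}

extrusion_lumen <- function(group, calibration) {
  zs <- calibration$z_step
  area <- sum(vapply(group$members, function(m) m$area_um2, numeric(1)))
  perim <- sum(vapply(group$members, candidate_perimeter_um, numeric(1),
                      calibration = calibration))
  list(volume = area * zs, surface = 2 * area + perim * zs)
}

# Voxelized alpha hull of a point cloud. The alpha hull (complement of the
# union of all open alpha-balls avoiding the points) equals the morphological
# closing of the point set by a ball of radius alpha; on an isotropic voxel
# grid both steps are exact Euclidean distance thresholds.
alpha_hull_grid <- function(pts, h, alpha_max) {
  lo <- apply(pts, 2, min)
  pad <- as.integer(ceiling((alpha_max + 2 * h) / h))
  ijk <- sweep(pts, 2, lo, "-") / h
  ijk <- round(ijk) + pad  # 0-based voxel indices
  dims <- apply(ijk, 2, max) + pad + 1
  mask <- array(FALSE, dim = c(dims[2], dims[1], dims[3]))  # (y, x, z)
  mask[cbind(ijk[, 2], ijk[, 1], ijk[, 3]) + 1L] <- TRUE
  list(mask = mask, origin = lo - pad * h, h = h,
       d2p = array(cpp_edt3d_sq(mask, dim(mask)), dim(mask)))
}

alpha_close <- function(grid, alpha) {
  a2 <- (alpha / grid$h)^2
  D <- grid$d2p <= a2
  ero <- cpp_edt3d_sq(!D, dim(D)) > a2
  array(ero, dim(D))
}

# TRUE when the closed region is a single connected solid that encloses the
# point cloud: one 6-connected foreground component, a connected complement
# (no internal cavity), and the cloud centroid inside. The centroid condition
# rejects thin shells whose cavity leaks out through unsealed gaps, which are
# connected and cavity-free yet enclose nothing.
is_enclosing <- function(closed, centroid_vox) {
  if (!closed[centroid_vox[1], centroid_vox[2], centroid_vox[3]])
    return(FALSE)
  lab_fg <- cpp_label3d6(closed, dim(closed))
  if (max(lab_fg) != 1L) return(FALSE)
  lab_bg <- cpp_label3d6(!closed, dim(closed))
  max(lab_bg) == 1L
}

# Surface area by the coarea formula: smooth the voxel indicator with a small
# Gaussian and integrate the gradient magnitude.
grid_surface_area <- function(closed, h) {
  k <- exp(-((-2:2)^2) / 2)
  k <- k / sum(k)
  f <- array(cpp_sepconv3d(as.numeric(closed), dim(closed), k), dim(closed))
  d <- dim(f)
  gy <- array(0, d); gx <- array(0, d); gz <- array(0, d)
  gy[2:(d[1] - 1), , ] <- (f[3:d[1], , ] - f[1:(d[1] - 2), , ]) / (2 * h)
  gx[, 2:(d[2] - 1), ] <- (f[, 3:d[2], ] - f[, 1:(d[2] - 2), ]) / (2 * h)
  gz[, , 2:(d[3] - 1)] <- (f[, , 3:d[3]] - f[, , 1:(d[3] - 2)]) / (2 * h)
  sum(sqrt(gy^2 + gx^2 + gz^2)) * h^3
}

#' Reconstruct a 3D lumen and measure its volume and surface area
#'
#' Groups spanning at least two z-levels are reconstructed as the alpha hull
#' of their boundary point cloud, computed on an isotropic voxel grid as the
#' morphological closing of the rasterized points by a ball of radius alpha
#' (exact Euclidean distance transforms). \code{alpha = "auto"} selects, by
#' bisection, the smallest alpha for which the hull is a single connected
#' region without internal cavities; a fixed alpha in micrometres can be given
#' instead. Volume is the voxel count times the voxel volume; surface area is
#' estimated from the smoothed-indicator gradient (coarea formula).
#' Single-slice groups use the extrusion convention: volume = area x z_step,
#' surface = 2 x area + perimeter x z_step. Multi-slice groups with fewer
#' than 4 points fall back to extrusion with a warning.
#'
#' @param group a \code{"lumen_group"}.
#' @param calibration a \code{\link{calibration}}.
#' @param alpha \code{"auto"} (default) or a fixed radius in micrometres.
#' @param grid_max cap on reconstruction-grid side length, voxels; the voxel
#'   size grows beyond \code{pixel_size_xy} if needed. Default 128.
#' @param max_points point-cloud subsampling cap (see
#'   \code{\link{build_point_cloud}}).
#' @param seed seed for point-cloud subsampling.
#' @param keep_grid if \code{TRUE}, the voxel grid is retained in the result
#'   (needed by \code{\link{export_mesh}}).
#' @return A \code{"lumen3d"}: list with \code{group}, \code{point_cloud},
#'   \code{volume_um3}, \code{surface_area_um2}, \code{alpha_um},
#'   \code{method} ("alpha" or "extrusion"), \code{n_slices}, \code{z_min},
#'   \code{z_max}.
#' @export
reconstruct <- function(group, calibration, alpha = "auto", grid_max = 128,
                        max_points = 20000, seed = 1, keep_grid = FALSE) {
  stopifnot(inherits(group, "lumen_group"), length(group$members) >= 1,
            inherits(calibration, "calibration"))
  zs <- vapply(group$members, function(m) m$z_index, integer(1))
  res <- list(group = group, n_slices = length(unique(zs)),
              z_min = min(zs), z_max = max(zs))
  pts <- build_point_cloud(group, calibration, max_points, seed)
  res$point_cloud <- pts
  if (length(unique(zs)) == 1L || nrow(pts) < 4) {
    if (length(unique(zs)) > 1L)
      warning("fewer than 4 points in a multi-slice group; ",
              "falling back to the extrusion convention")
    ext <- extrusion_lumen(group, calibration)
    res$volume_um3 <- ext$volume
    res$surface_area_um2 <- ext$surface
    res$alpha_um <- NA_real_
    res$method <- "extrusion"
    return(structure(res, class = "lumen3d"))
  }
  hull_pts <- slab_point_cloud(group, calibration, max_points, seed)
  spans <- apply(hull_pts, 2, function(v) diff(range(v)))
  alpha_max <- max(spans) / 2 + calibration$z_step +
    2 * calibration$pixel_size_xy
  h <- calibration$pixel_size_xy
  need <- max(spans) / h + 2 * ceiling((alpha_max + 2 * h) / h) + 1
  if (need > grid_max)
    h <- (max(spans) + 2 * (alpha_max + 2 * h)) / (grid_max - 1)
  grid <- alpha_hull_grid(hull_pts, h, alpha_max)
  cen <- colMeans(hull_pts)
  cen_vox <- round((cen - grid$origin) / h) + 1L
  cen_vox <- c(cen_vox[2], cen_vox[1], cen_vox[3])  # grid is (y, x, z)
  if (identical(alpha, "auto")) {
    if (is_enclosing(alpha_close(grid, alpha_max), cen_vox)) {
      lo <- h; hi <- alpha_max
      while (hi - lo > h / 2) {
        mid <- (lo + hi) / 2
        if (is_enclosing(alpha_close(grid, mid), cen_vox)) hi <- mid else lo <- mid
      }
      alpha_um <- hi
    } else {
      alpha_um <- alpha_max
    }
  } else {
    stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
    alpha_um <- alpha
  }
  closed <- alpha_close(grid, alpha_um)
  res$volume_um3 <- sum(closed) * h^3
  res$surface_area_um2 <- grid_surface_area(closed, h)
  res$alpha_um <- alpha_um
  res$method <- "alpha"
  if (keep_grid)
    res$grid <- list(mask = closed, h = h, origin = grid$origin)
  structure(res, class = "lumen3d")
}

#' @export
print.lumen3d <- function(x, ...) {
  cat(sprintf(
    "lumen3d %s: %d slice(s) z[%d..%d], volume %.1f um^3, surface %.1f um^2 (%s)\n",
    x$group$group_id, x$n_slices, x$z_min, x$z_max,
    x$volume_um3, x$surface_area_um2, x$method))
  invisible(x)
}

#' Per-microtissue summary of reconstructed lumens
#'
#' @param stack_id stack identifier.
#' @param lumens list of \code{"lumen3d"} (may be empty: microtissues with no
#'   detected lumen are a meaningful outcome).
#' @return A \code{"microtissue_report"}: list with \code{stack_id},
#'   \code{lumens}, \code{lumen_count} and \code{total_volume_um3}.
#' @export
summarize_lumens <- function(stack_id, lumens = list()) {
  stopifnot(is.character(stack_id), length(stack_id) == 1)
  vols <- vapply(lumens, function(l) l$volume_um3, numeric(1))
  structure(list(stack_id = stack_id, lumens = lumens,
                 lumen_count = length(lumens),
                 total_volume_um3 = if (length(vols)) sum(vols) else 0),
            class = "microtissue_report")
}

#' @export
print.microtissue_report <- function(x, ...) {
  cat(sprintf("microtissue_report '%s': %d lumen(s), total volume %.1f um^3\n",
              x$stack_id, x$lumen_count, x$total_volume_um3))
  invisible(x)
}

#' Per-lumen table of a report
#' @param report a \code{"microtissue_report"}.
#' @return data.frame with one row per lumen.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "microtissue_report"))
  if (report$lumen_count == 0) {
    return(data.frame(stack_id = character(), lumen_id = character(),
                      n_slices = integer(), z_min = integer(),
                      z_max = integer(), volume_um3 = numeric(),
                      surface_area_um2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(report$lumens, function(l) {
    data.frame(stack_id = report$stack_id, lumen_id = l$group$group_id,
               n_slices = l$n_slices, z_min = l$z_min, z_max = l$z_max,
               volume_um3 = l$volume_um3,
               surface_area_um2 = l$surface_area_um2,
               stringsAsFactors = FALSE)
  }))
}

#' Export a reconstructed lumen surface as a PLY or OBJ mesh
#'
#' Writes the exposed voxel faces of the reconstruction grid as a triangle
#' mesh for external viewers. The lumen must have been reconstructed with
#' \code{keep_grid = TRUE}.
#'
#' @param lumen a \code{"lumen3d"} with a retained grid.
#' @param path output file path.
#' @param format \code{"ply"} or \code{"obj"} (default from file extension).
#' @export
export_mesh <- function(lumen, path, format = c("auto", "ply", "obj")) {
  stopifnot(inherits(lumen, "lumen3d"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  if (is.null(lumen$grid))
    stop("reconstruct() must be called with keep_grid = TRUE for mesh export")
  g <- lumen$grid
  m <- g$mask
  d <- dim(m)
  verts <- matrix(numeric(0), 0, 3)
  faces <- matrix(integer(0), 0, 3)
  vkey <- new.env(hash = TRUE)
  vid <- function(y, x, z) {
    key <- paste(y, x, z, sep = ",")
    id <- vkey[[key]]
    if (is.null(id)) {
      verts <<- rbind(verts, g$origin + (c(x, y, z) - 1) * g$h - g$h / 2)
      id <- nrow(verts)
      vkey[[key]] <- id
    }
    id
  }
  emit <- function(q) {
    faces <<- rbind(faces, q[c(1, 2, 3)], q[c(1, 3, 4)])
  }
  idx <- which(m, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    y <- idx[r, 1]; x <- idx[r, 2]; z <- idx[r, 3]
    nb <- list(c(y - 1, x, z), c(y + 1, x, z), c(y, x - 1, z),
               c(y, x + 1, z), c(y, x, z - 1), c(y, x, z + 1))
    for (f in seq_along(nb)) {
      p <- nb[[f]]
      inside <- all(p >= 1) && p[1] <= d[1] && p[2] <= d[2] && p[3] <= d[3] &&
        m[p[1], p[2], p[3]]
      if (inside) next
      corners <- switch(f,
        list(c(y, x, z), c(y, x + 1, z), c(y, x + 1, z + 1), c(y, x, z + 1)),
        list(c(y + 1, x, z), c(y + 1, x, z + 1), c(y + 1, x + 1, z + 1),
             c(y + 1, x + 1, z)),
        list(c(y, x, z), c(y, x, z + 1), c(y + 1, x, z + 1), c(y + 1, x, z)),
        list(c(y, x + 1, z), c(y + 1, x + 1, z), c(y + 1, x + 1, z + 1),
             c(y, x + 1, z + 1)),
        list(c(y, x, z), c(y + 1, x, z), c(y + 1, x + 1, z), c(y, x + 1, z)),
        list(c(y, x, z + 1), c(y, x + 1, z + 1), c(y + 1, x + 1, z + 1),
             c(y + 1, x, z + 1)))
      emit(vapply(corners, function(cc) vid(cc[1], cc[2], cc[3]), integer(1)))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(verts)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%g %g %g", verts[, 1], verts[, 2], verts[, 3]), con)
    writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                       faces[, 3] - 1L), con)
  } else {
    writeLines(sprintf("v %g %g %g", verts[, 1], verts[, 2], verts[, 3]), con)
    writeLines(sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  }
  invisible(path)
}
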