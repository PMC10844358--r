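# Independent brute-force oracles. These deliberately share no code with the
# package: closing is computed by explicit offset loops, components by a
# hand-written flood fill, thresholds by exhaustive search.

# Euclidean disk offsets: all (dy, dx) with dy^2 + dx^2 <= r^2.
disk_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

shift_mat <- function(m, dy, dx, fill = FALSE) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  if (length(ys) && length(xs))
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

oracle_dilate <- function(m, offs) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_mat(m, offs$dy[i], offs$dx[i])
  out
}

oracle_erode <- function(m, offs, outside = FALSE) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs)))
    out <- out & shift_mat(m, offs$dy[i], offs$dx[i], fill = outside)
  out
}

# Full-plane closing: dilation then erosion on a canvas padded by r with
# background outside, cropped back.
oracle_close <- function(m, r_px) {
  if (r_px <= 0) return(m)
  H <- nrow(m); W <- ncol(m)
  canvas <- matrix(FALSE, H + 2 * r_px, W + 2 * r_px)
  canvas[(r_px + 1):(r_px + H), (r_px + 1):(r_px + W)] <- m
  offs <- disk_offsets(r_px)
  clo <- oracle_erode(oracle_dilate(canvas, offs), offs)
  clo[(r_px + 1):(r_px + H), (r_px + 1):(r_px + W)]
}

# Flood-fill 4-connected labeling of TRUE cells, labels in column-major
# first-encounter order.
oracle_label4 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (x in seq_len(W)) for (y in seq_len(H)) {
    if (!m[y, x] || lab[y, x]) next
    nxt <- nxt + 1L
    queue <- list(c(y, x))
    lab[y, x] <- nxt
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] < 1 || q[1] > H || q[2] < 1 || q[2] > W) next
        if (m[q[1], q[2]] && !lab[q[1], q[2]]) {
          lab[q[1], q[2]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Void extraction oracle: 4-connected components of the background phase,
# largest removed (ties -> smallest label), then an area floor. Returns a
# list of sorted pixel-index vectors, ordered by label.
oracle_extract <- function(closed_mask, min_area_px = 0) {
  lab <- oracle_label4(!closed_mask)
  if (max(lab) == 0) return(list())
  sizes <- tabulate(lab)
  biggest <- which.max(sizes)
  keep <- setdiff(which(sizes >= min_area_px), biggest)
  lapply(keep, function(l) sort(which(lab == l)))
}

# Exhaustive between-class-variance threshold over the 256-level grid on
# [0, 1]; returns the binarized mask (foreground = above threshold).
oracle_otsu_mask <- function(x) {
  breaks <- seq(0, 1, length.out = 257)
  h <- hist(x, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-257]) / 2
  n <- sum(h)
  best <- -Inf; best_t <- 0
  for (k in 1:255) {
    w0 <- sum(h[1:k]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * mids[1:k]) / w0
    mu1 <- sum(h[(k + 1):256] * mids[(k + 1):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) {
      best <- v
      best_t <- breaks[k + 1]
    }
  }
  x > best_t
}

# Random blobby binary mask (smoothed noise thresholded), deterministic.
random_mask <- function(seed, H = 48, W = 48, frac = 0.5) {
  set.seed(seed)
  z <- matrix(rnorm(H * W), H, W)
  k <- matrix(1 / 25, 5, 5)
  zp <- matrix(0, H + 4, W + 4)
  zp[3:(H + 2), 3:(W + 2)] <- z
  sm <- matrix(0, H, W)
  for (dy in -2:2) for (dx in -2:2)
    sm <- sm + zp[(3 + dy):(H + 2 + dy), (3 + dx):(W + 2 + dx)] / 25
  sm > quantile(sm, 1 - frac)
}

# Annulus (cell ring) with a boundary gap of the given width cut on the +x
# side; TRUE = foreground.
make_annulus <- function(gap_um, H = 64, W = 64, r_out = 26, r_in = 18,
                         cy = 32, cx = 32) {
  d <- sqrt((row(matrix(0, H, W)) - cy)^2 + (col(matrix(0, H, W)) - cx)^2)
  ring <- d <= r_out & d >= r_in
  if (gap_um > 0)
    ring[abs(row(ring) - cy) <= gap_um / 2 & col(ring) > cx] <- FALSE
  ring
}

# Shoelace polygon area of the 2D convex hull of (x, y) points.
hull_area_2d <- function(x, y) {
  hp <- chull(x, y)
  xs <- x[hp]; ys <- y[hp]
  n <- length(hp)
  j <- c(n, seq_len(n - 1))
  abs(sum(xs[j] * ys - xs * ys[j])) / 2
}
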