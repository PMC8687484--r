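# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own code paths: explicit loops,
# all-pairs distances, grid rasterization.

# Direct (loop-based) separable Gaussian smoothing with replicate edges.
oracle_smooth3 <- function(a, sigma) {
  d <- dim(a)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- exp(-((-r:r)^2) / (2 * sigma[ax]^2)); k <- k / sum(k)
    out <- array(0, d)
    for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3]) {
      acc <- 0
      for (t in -r:r) {
        ii <- i; jj <- j; ll <- l
        if (ax == 1) ii <- min(max(i + t, 1), d[1])
        if (ax == 2) jj <- min(max(j + t, 1), d[2])
        if (ax == 3) ll <- min(max(l + t, 1), d[3])
        acc <- acc + k[t + r + 1] * a[ii, jj, ll]
      }
      out[i, j, l] <- acc
    }
    a <- out
  }
  a
}

# Loop-based discrete Laplacian with replicate edges.
oracle_laplacian3 <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  cl <- function(v, n) min(max(v, 1), n)
  for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3]) {
    out[i, j, l] <-
      a[cl(i - 1, d[1]), j, l] + a[cl(i + 1, d[1]), j, l] +
      a[i, cl(j - 1, d[2]), l] + a[i, cl(j + 1, d[2]), l] +
      a[i, j, cl(l - 1, d[3])] + a[i, j, cl(l + 1, d[3])] - 6 * a[i, j, l]
  }
  out
}

# All-pairs shell counts: per punctum, the min distance from its containing
# voxel center to every reference voxel center.
oracle_shell_counts <- function(ref_mask, centers, vx, vz, shell_width, max_distance) {
  d <- dim(ref_mask)
  ridx <- which(ref_mask)
  rijk <- arrayInd(ridx, d)
  rpts <- cbind((rijk[, 1] - 0.5) * vx, (rijk[, 2] - 0.5) * vx, (rijk[, 3] - 0.5) * vz)
  n_shell <- ceiling(max_distance / shell_width)
  counts <- integer(n_shell)
  for (p in seq_len(nrow(centers))) {
    i <- floor(centers[p, 1] / vx) + 1; j <- floor(centers[p, 2] / vx) + 1
    k <- floor(centers[p, 3] / vz) + 1
    if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3]) next
    q <- c((i - 0.5) * vx, (j - 0.5) * vx, (k - 0.5) * vz)
    dmin <- Inf
    for (r in seq_len(nrow(rpts))) {
      dmin <- min(dmin, sqrt(sum((q - rpts[r, ])^2)))
    }
    if (dmin < max_distance) {
      s <- floor(dmin / shell_width) + 1
      counts[s] <- counts[s] + 1L
    }
  }
  counts
}

# Rasterized area of a triangulated region at grid step `step` nm, using
# sp's point-in-polygon on each triangle.
oracle_raster_area <- function(region, step = 2) {
  pts <- region$coords
  lo <- apply(pts, 2, min) - step
  hi <- apply(pts, 2, max) + step
  gx <- seq(lo[1], hi[1], by = step)
  gy <- seq(lo[2], hi[2], by = step)
  g <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- rep(FALSE, nrow(g))
  for (r in seq_len(nrow(region$triangles))) {
    tri <- pts[region$triangles[r, ], , drop = FALSE]
    hit <- sp::point.in.polygon(g[, 1], g[, 2], tri[, 1], tri[, 2]) > 0
    inside <- inside | hit
  }
  sum(inside) * step^2
}

# All-pairs count of neighbours within radius (self-inclusive).
oracle_count_within <- function(coords, radius) {
  n <- nrow(coords)
  counts <- integer(n)
  for (i in seq_len(n)) {
    c_i <- 0L
    for (j in seq_len(n)) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= radius + 1e-9) c_i <- c_i + 1L
    }
    counts[i] <- c_i
  }
  counts
}

# Shoelace area of the convex hull of a point set.
oracle_chull_area <- function(pts) {
  h <- chull(pts)
  p <- pts[h, , drop = FALSE]
  n <- nrow(p)
  abs(sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])) / 2
}

# Random rigid transform (rotation + translation) of planar coordinates.
rigid_transform2 <- function(coords, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(coords %*% t(R), 2, shift, "+")
}

# 3D rotation about an arbitrary axis + translation.
rigid_transform3 <- function(coords, theta, axis, shift) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  sweep(coords %*% t(R), 2, shift, "+")
}
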