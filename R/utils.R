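#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so simulations are reproducible without side effects.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Shift a 3D array along one axis by `off` voxels, replicating edges.
#' @noRd
shift3 <- function(a, off, axis) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

## Separable convolution of a 3D array with a symmetric kernel along `axis`,
## replicate padding at the edges.
#' @noRd
conv_axis3 <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (t in seq_along(kernel)) {
    out <- out + kernel[t] * shift3(a, t - r - 1L, axis)
  }
  out
}

#' @noRd
gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

## Anisotropic Gaussian smoothing of a 3D array (sigma in voxels per axis;
## sigma = 0 skips an axis).
#' @noRd
gauss_smooth3 <- function(a, sigma) {
  for (ax in 1:3) {
    if (sigma[ax] > 0) a <- conv_axis3(a, gaussian_kernel1d(sigma[ax]), ax)
  }
  a
}

## Discrete Laplacian (sum of second central differences, pixel units).
#' @noRd
laplacian3 <- function(a) {
  out <- -6 * a
  for (ax in 1:3) out <- out + shift3(a, 1L, ax) + shift3(a, -1L, ax)
  out
}

## Count, for every row of `coords`, the number of rows (self included) within
## `radius`. Blocked squared-distance computation through BLAS.
#' @noRd
count_within_radius <- function(coords, radius) {
  n <- nrow(coords)
  sq <- rowSums(coords^2)
  counts <- integer(n)
  block <- 1024L
  r2 <- radius^2 + 1e-9 * radius^2  # guard exact-distance ties against fp error
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(coords[s:e, , drop = FALSE], coords)
    counts[s:e] <- rowSums(d2 <= r2)
  }
  counts
}

## Voxel index (1-based) containing a physical position along one axis.
## Voxel i covers [(i-1)*step, i*step) nm; its center is (i-0.5)*step.
#' @noRd
pos_to_voxel <- function(pos_nm, step_nm) floor(pos_nm / step_nm) + 1L

#' @noRd
voxel_center <- function(i, step_nm) (i - 0.5) * step_nm

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
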