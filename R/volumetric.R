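#' Enhance punctate objects in a 3D channel
#'
#' Applies a negated anisotropic Laplacian-of-Gaussian (LoG) filter so that
#' diffraction-limited blobs become positive peaks, the standard blob-enhancing
#' step before histogram thresholding. The kernel is separable Gaussian
#' smoothing (sigma in pixels, anisotropic: `sigma_xy` in x/y, `sigma_z` in z)
#' followed by a discrete Laplacian; the response is negated and clipped at 0.
#' A plain Gaussian mode is available for comparison.
#'
#' @param image a [volumetric_image()].
#' @param channel channel name to enhance.
#' @param sigma_xy,sigma_z Gaussian sigma in pixels (default 2 and 1).
#' @param method `"log"` (default) or `"gaussian"` (smoothing only).
#' @return a `volumetric_image` with a single channel (same name) holding the
#'   enhancement response.
#' @export
enhance_puncta <- function(image, channel, sigma_xy = 2, sigma_z = 1,
                           method = c("log", "gaussian")) {
  method <- match.arg(method)
  if (sigma_xy <= 0 || sigma_z <= 0) stop("sigma must be > 0")
  a <- get_channel(image, channel)
  sm <- gauss_smooth3(a, c(sigma_xy, sigma_xy, sigma_z))
  resp <- if (method == "log") pmax(-laplacian3(sm), 0) else sm
  ch <- list(resp)
  names(ch) <- channel
  volumetric_image(ch, image$voxel_size_xy, image$voxel_size_z)
}

#' Two-level histogram threshold (three-class Otsu)
#'
#' Finds the two cut points that minimize total within-class intensity
#' variance over three classes, i.e. multi-level Otsu on a 256-bin histogram.
#' The higher threshold is the one used to build puncta masks; the thresholds
#' scale with the intensities, so masking is intensity-scale equivariant.
#'
#' @param image a [volumetric_image()].
#' @param channel channel name.
#' @param n_bins number of histogram bins (default 256).
#' @return numeric `c(low, high)` intensity cut points, `low < high`.
#' @export
two_level_threshold <- function(image, channel, n_bins = 256L) {
  v <- as.vector(get_channel(image, channel))
  if (length(unique(v)) < 3L) {
    stop("degenerate histogram: fewer than 3 distinct intensity values")
  }
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins)
  h <- tabulate(bin, nbins = n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  W <- cumsum(h)
  S <- cumsum(h * centers)
  n <- W[n_bins]
  best <- -Inf; best_ij <- c(1L, 2L)
  # between-class variance, maximized over all cut pairs (i < j)
  for (i in seq_len(n_bins - 2L)) {
    w1 <- W[i]; s1 <- S[i]
    if (w1 == 0) next
    j <- (i + 1L):(n_bins - 1L)
    w2 <- W[j] - w1; s2 <- S[j] - s1
    w3 <- n - W[j]; s3 <- S[n_bins] - S[j]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    bc <- rep(-Inf, length(j))
    bc[ok] <- s1^2 / w1 + s2[ok]^2 / w2[ok] + s3[ok]^2 / w3[ok]
    m <- which.max(bc)
    if (bc[m] > best) { best <- bc[m]; best_ij <- c(i, j[m]) }
  }
  c(low = edges[best_ij[1] + 1L], high = edges[best_ij[2] + 1L])
}

#' Split touching puncta with a per-slice watershed
#'
#' Closely spaced puncta merge under thresholding. Following the
#' frame-by-frame convention of puncta-segmentation toolboxes, each z-slice of
#' the Gaussian-smoothed intensity is treated as a topographic surface,
#' catchment basins are grown from its regional maxima, and the watershed
#' lines between basins are subtracted from the mask, cutting merged objects
#' apart. The basin-merge tolerance is a fraction of the slice intensity
#' range, keeping the operation intensity-scale equivariant.
#'
#' @param image a [volumetric_image()] (the original intensity channel).
#' @param channel channel name.
#' @param mask logical 3D array, same shape as the channel.
#' @param smoothing_sigma_xy Gaussian sigma (pixels) applied per slice before
#'   watershed (default 1).
#' @param tolerance_frac minimum basin depth, as a fraction of the slice
#'   intensity range, below which adjacent maxima are merged (default 0.05).
#' @return logical 3D array: `mask` minus watershed-line voxels (always a
#'   subset of `mask`).
#' @export
watershed_split <- function(image, channel, mask, smoothing_sigma_xy = 1,
                            tolerance_frac = 0.05) {
  a <- get_channel(image, channel)
  if (!identical(dim(a), dim(mask))) stop("mask shape must match the image")
  mode(mask) <- "logical"
  out <- mask
  k <- gaussian_kernel1d(smoothing_sigma_xy)
  for (z in seq_len(dim(a)[3])) {
    if (!any(mask[, , z])) next
    sl <- a[, , z]
    # separable 2D smoothing with replicate edges
    sl <- apply(sl, 2, function(col) conv1_replicate(col, k))
    sl <- t(apply(sl, 1, function(row) conv1_replicate(row, k)))
    rng <- diff(range(sl))
    if (rng == 0) next
    lab <- EBImage::imageData(EBImage::watershed(sl, tolerance = tolerance_frac * rng, ext = 1))
    nr <- nrow(lab); nc <- ncol(lab)
    line <- matrix(FALSE, nr, nc)
    line[-1, ] <- lab[-1, ] != lab[-nr, ]
    line[, -1] <- line[, -1] | (lab[, -1] != lab[, -nc])
    out[, , z] <- mask[, , z] & !line
  }
  out
}

#' @noRd
conv1_replicate <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1], r), x, rep(x[n], r))
  stats::convolve(xp, rev(k), type = "filter")
}

#' Label connected objects and measure them
#'
#' Connected-component labeling of a binary volume (26-neighborhood by
#' default) with per-object voxel counts, integrated intensities and
#' (optionally intensity-weighted) centers of mass reported in physical nm
#' using the voxel-center convention.
#'
#' @param mask logical 3D array.
#' @param image optional [volumetric_image()] supplying intensities.
#' @param channel channel of `image` to measure (required when `image` given).
#' @param voxel_size_xy,voxel_size_z voxel sizes in nm (taken from `image`
#'   when provided).
#' @param connectivity 26 (default) or 6.
#' @param weighted logical; intensity-weighted centers of mass (default TRUE;
#'   ignored when no image is supplied).
#' @return an [object_label_map()].
#' @export
label_objects <- function(mask, image = NULL, channel = NULL,
                          voxel_size_xy = NULL, voxel_size_z = NULL,
                          connectivity = 26L, weighted = TRUE) {
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  if (!is.null(image)) {
    if (is.null(channel)) stop("`channel` is required when `image` is given")
    intens <- get_channel(image, channel)
    if (!identical(dim(intens), dim(mask))) stop("mask shape must match the image")
    voxel_size_xy <- image$voxel_size_xy
    voxel_size_z <- image$voxel_size_z
  } else {
    intens <- NULL
    if (is.null(voxel_size_xy) || is.null(voxel_size_z)) {
      stop("voxel sizes are required when no image is supplied")
    }
  }
  d <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, d)
  if (length(idx) == 0L) {
    objects <- data.frame(id = integer(), x_nm = numeric(), y_nm = numeric(),
                          z_nm = numeric(), voxel_count = integer(),
                          integrated_intensity = numeric())
    return(object_label_map(labels, objects, voxel_size_xy, voxel_size_z))
  }
  ijk <- arrayInd(idx, d)
  comp <- connected_voxel_components(ijk, d, connectivity)
  labels[idx] <- comp
  w <- if (!is.null(intens) && weighted) as.numeric(intens[idx]) else rep(1, length(idx))
  if (any(w <= 0)) w <- w - min(w, 0) + 1e-12  # CoM weights must be positive
  sw <- rowsum(w, comp)
  x_nm <- rowsum(w * voxel_center(ijk[, 1], voxel_size_xy), comp) / sw
  y_nm <- rowsum(w * voxel_center(ijk[, 2], voxel_size_xy), comp) / sw
  z_nm <- rowsum(w * voxel_center(ijk[, 3], voxel_size_z), comp) / sw
  cnt <- as.integer(rowsum(rep(1L, length(idx)), comp))
  ii <- if (!is.null(intens)) as.numeric(rowsum(as.numeric(intens[idx]), comp)) else as.numeric(cnt)
  objects <- data.frame(id = seq_along(cnt), x_nm = as.numeric(x_nm),
                        y_nm = as.numeric(y_nm), z_nm = as.numeric(z_nm),
                        voxel_count = cnt, integrated_intensity = ii)
  object_label_map(labels, objects, voxel_size_xy, voxel_size_z)
}

## Connected components over a sparse voxel set; returns contiguous 1..N ids
## ordered by first occurrence.
#' @noRd
connected_voxel_components <- function(ijk, d, connectivity) {
  m <- nrow(ijk)
  key <- (ijk[, 1] - 1) + d[1] * ((ijk[, 2] - 1) + d[2] * (ijk[, 3] - 1))
  ord <- order(key)
  skey <- key[ord]
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  if (connectivity == 6L) offs <- offs[abs(offs$di) + abs(offs$dj) + abs(offs$dk) == 1, ]
  # keep one direction per neighbor pair (undirected edges)
  offs <- offs[offs$dk > 0 | (offs$dk == 0 & (offs$dj > 0 | (offs$dj == 0 & offs$di > 0))), ]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    ni <- ijk[, 1] + offs$di[r]; nj <- ijk[, 2] + offs$dj[r]; nk <- ijk[, 3] + offs$dk[r]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    nk_key <- (ni - 1) + d[1] * ((nj - 1) + d[2] * (nk - 1))
    pos <- rep(NA_integer_, m)
    pos[ok] <- findInterval(nk_key[ok], skey)
    hit <- ok & pos > 0 & !is.na(pos) & skey[pmax(pos, 1L)] == nk_key
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(which(hit), ord[pos[hit]])
  }
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  # relabel to contiguous ids in order of first occurrence
  as.integer(match(comp, unique(comp)))
}
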