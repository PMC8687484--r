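## SMLM localization-table handling: CSV dialect, quality filtering,
## bead-based channel registration, redundant cross-correlation drift
## correction.

.loc_aliases <- list(
  frame = c("frame", "frame_idx"),
  x = c("x", "x_nm", "x [nm]"),
  y = c("y", "y_nm", "y [nm]"),
  sigma = c("sigma", "sigma_nm", "sigma [nm]", "sigma1 [nm]"),
  uncertainty = c("uncertainty", "uncertainty_nm", "uncertainty [nm]",
                  "uncertainty_xy [nm]"),
  photons = c("photons", "intensity [photon]"),
  channel = c("channel")
)

#' Read a localization table from CSV
#'
#' Accepts the canonical dialect (`frame, x_nm, y_nm, sigma_nm,
#' uncertainty_nm, photons, channel`) as well as ThunderSTORM-style headers
#' (`"x [nm]"`, `"uncertainty [nm]"`, ...) and plain names. Coordinates and
#' precision attributes are in nm.
#'
#' @param path CSV file path.
#' @return data.frame with columns `frame`, `x`, `y`, `sigma`,
#'   `uncertainty`, `photons`, `channel` (missing optional columns are NA).
#' @export
read_localizations <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  found <- names(raw)
  out <- list()
  for (canon in names(.loc_aliases)) {
    hit <- intersect(.loc_aliases[[canon]], found)
    out[[canon]] <- if (length(hit)) raw[[hit[1]]] else NA
  }
  required <- c("frame", "x", "y")
  missing <- required[vapply(out[required], function(v) all(is.na(v)) && length(v) == 1L, TRUE)]
  if (length(missing)) {
    stop(sprintf("missing mandatory columns: %s; found headers: %s",
                 paste(missing, collapse = ", "), paste(found, collapse = ", ")))
  }
  n <- length(out$frame)
  for (canon in names(out)) if (length(out[[canon]]) == 1L) out[[canon]] <- rep(out[[canon]], n)
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  df$channel <- as.character(df$channel)
  df
}

#' Write a localization table to CSV
#'
#' Writes the canonical dialect with full double precision so that
#' write-then-read round-trips bit-exactly.
#'
#' @param table localization data.frame (columns as in
#'   [read_localizations()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  fmt_num <- function(v) {
    s <- vapply(v, function(x) if (is.na(x)) "NA" else sprintf("%.17g", x), "")
    s
  }
  cols <- c(frame = "frame", x = "x_nm", y = "y_nm", sigma = "sigma_nm",
            uncertainty = "uncertainty_nm", photons = "photons",
            channel = "channel")
  n <- nrow(table)
  body <- character(0)
  if (n > 0) {
    fields <- lapply(names(cols), function(cn) {
      v <- table[[cn]]
      if (is.null(v)) rep("NA", n)
      else if (cn == "channel") as.character(v)
      else fmt_num(as.numeric(v))
    })
    body <- do.call(paste, c(fields, sep = ","))
  }
  writeLines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' Quality-filter localizations
#'
#' Keeps records whose localization uncertainty is below `uncertainty_max`
#' (strict, matching the "< 20 nm" convention) and whose fitted PSF sigma
#' lies inside the closed per-channel range (e.g. 100-200 nm for CF568 and
#' 90-190 nm for Alexa Fluor 647). Record order is preserved; the filter is
#' idempotent.
#'
#' @param table localization data.frame.
#' @param uncertainty_max uncertainty cutoff in nm (default 20).
#' @param sigma_range named list mapping channel -> `c(lo, hi)` in nm, or
#'   NULL to skip the sigma filter. Channels without an entry are filtered on
#'   uncertainty only; naming a channel absent from the table is an error.
#' @return the filtered data.frame.
#' @export
filter_localizations <- function(table, uncertainty_max = 20, sigma_range = NULL) {
  keep <- table$uncertainty < uncertainty_max
  keep[is.na(keep)] <- FALSE
  if (!is.null(sigma_range)) {
    unknown <- setdiff(names(sigma_range), unique(table$channel))
    if (length(unknown)) {
      stop(sprintf("sigma_range names channels not present in the table: %s",
                   paste(unknown, collapse = ", ")))
    }
    for (ch in names(sigma_range)) {
      rng <- sigma_range[[ch]]
      if (rng[1] >= rng[2]) stop("sigma_range lo must be < hi")
      sel <- table$channel == ch
      keep[sel] <- keep[sel] & !is.na(table$sigma[sel]) &
        table$sigma[sel] >= rng[1] & table$sigma[sel] <= rng[2]
    }
  }
  table[keep, , drop = FALSE]
}

#' Fit a two-channel calibration from matched bead positions
#'
#' Models the per-axis displacement (moving minus reference) across the field
#' of view, either as a bivariate polynomial of position (least squares) or
#' as a Gaussian-kernel locally weighted average of the control
#' displacements. Applying the model to the moving channel aligns it to the
#' reference channel.
#'
#' @param ref_points,moving_points matched n x 2 position matrices in nm.
#' @param model_kind `"polynomial"` (default) or `"locally_weighted"`.
#' @param degree polynomial degree (default 2).
#' @param bandwidth Gaussian kernel bandwidth in nm (required for
#'   `locally_weighted`).
#' @return object of class `channel_calibration` with `control_rms` (nm, RMS
#'   residual at the control points) and `n_control_points`.
#' @export
fit_channel_calibration <- function(ref_points, moving_points,
                                    model_kind = c("polynomial", "locally_weighted"),
                                    degree = 2L, bandwidth = NULL) {
  model_kind <- match.arg(model_kind)
  ref_points <- as.matrix(ref_points); moving_points <- as.matrix(moving_points)
  if (nrow(ref_points) != nrow(moving_points)) stop("point sets must be matched")
  n <- nrow(ref_points)
  disp <- moving_points - ref_points
  center <- colMeans(moving_points)
  scale <- max(apply(moving_points, 2, function(v) diff(range(v))), 1)
  cal <- list(model_kind = model_kind, center = center, scale = scale,
              n_control_points = n)
  if (model_kind == "polynomial") {
    n_terms <- (degree + 1) * (degree + 2) / 2
    if (n < n_terms) {
      stop(sprintf("under-determined fit: degree %d needs at least %d matched pairs",
                   degree, n_terms))
    }
    X <- .cal_design(moving_points, center, scale, degree)
    fx <- stats::lm.fit(X, disp[, 1])
    fy <- stats::lm.fit(X, disp[, 2])
    cal$degree <- degree
    cal$coef_x <- fx$coefficients
    cal$coef_y <- fy$coefficients
    cal$coef_x[is.na(cal$coef_x)] <- 0
    cal$coef_y[is.na(cal$coef_y)] <- 0
    res2 <- fx$residuals^2 + fy$residuals^2
  } else {
    if (is.null(bandwidth) || bandwidth <= 0) {
      stop("`bandwidth` (nm, > 0) is required for locally weighted calibration")
    }
    cal$bandwidth <- bandwidth
    cal$control_points <- moving_points
    cal$control_disp <- disp
    pred <- .lw_predict(cal, moving_points)
    res2 <- rowSums((disp - pred)^2)
  }
  cal$control_rms <- sqrt(mean(res2))
  class(cal) <- "channel_calibration"
  cal
}

#' @noRd
.cal_design <- function(xy, center, scale, degree) {
  u <- (xy[, 1] - center[1]) / scale
  v <- (xy[, 2] - center[2]) / scale
  cols <- list()
  for (i in 0:degree) for (j in 0:(degree - i)) {
    cols[[length(cols) + 1L]] <- u^i * v^j
  }
  do.call(cbind, cols)
}

#' @noRd
.lw_predict <- function(cal, xy) {
  cp <- cal$control_points
  out <- matrix(0, nrow(xy), 2)
  bw2 <- 2 * cal$bandwidth^2
  for (q in seq_len(nrow(xy))) {
    d2 <- (cp[, 1] - xy[q, 1])^2 + (cp[, 2] - xy[q, 2])^2
    w <- exp(-d2 / bw2)
    w <- w / sum(w)
    out[q, ] <- colSums(cal$control_disp * w)
  }
  out
}

#' Predict the modeled displacement at positions
#'
#' @param calibration a `channel_calibration`.
#' @param xy n x 2 positions in nm.
#' @return n x 2 displacement matrix in nm.
#' @export
predict_displacement <- function(calibration, xy) {
  xy <- matrix(xy, ncol = 2)
  if (calibration$model_kind == "polynomial") {
    X <- .cal_design(xy, calibration$center, calibration$scale, calibration$degree)
    cbind(X %*% calibration$coef_x, X %*% calibration$coef_y)
  } else {
    .lw_predict(calibration, xy)
  }
}

#' Apply a channel calibration to a localization table
#'
#' Shifts the (moving-channel) coordinates by the modeled displacement so
#' they align with the reference channel; all other fields are untouched.
#'
#' @param table localization data.frame.
#' @param calibration a `channel_calibration`.
#' @return the corrected data.frame.
#' @export
apply_calibration <- function(table, calibration) {
  d <- predict_displacement(calibration, cbind(table$x, table$y))
  table$x <- table$x - d[, 1]
  table$y <- table$y - d[, 2]
  table
}

#' Redundant cross-correlation drift correction
#'
#' Splits the movie into segments of `segment_len` frames, renders each
#' segment as a 2D localization histogram at `bin_size`, estimates all
#' pairwise segment offsets from the cross-correlation peak (sub-bin accuracy
#' by intensity centroid over the 3 x 3 peak neighborhood), solves the
#' redundant offset set by least squares with the first segment as reference,
#' discards pairwise measurements whose residual exceeds
#' `error_threshold * pixel_size` and re-solves once, interpolates the
#' per-segment drift to every frame and subtracts it from the coordinates.
#'
#' @param table localization data.frame.
#' @param segment_len frames per segment (default 500).
#' @param bin_size correlation histogram bin in nm (default 10).
#' @param error_threshold residual rejection threshold in camera pixels
#'   (default 5).
#' @param pixel_size camera pixel size in nm (default 100), so the default
#'   rejection radius is 500 nm.
#' @return list with `table` (drift-corrected) and `drift` (class
#'   `drift_trace`: `segment_edges`, `segment_frames`, `displacement` k x 2
#'   with the first segment at (0, 0), `per_frame` data.frame).
#' @export
drift_correct <- function(table, segment_len = 500L, bin_size = 10,
                          error_threshold = 5, pixel_size = 100) {
  f0 <- min(table$frame)
  f1 <- max(table$frame)
  n_frames <- f1 - f0 + 1L
  n_seg <- n_frames %/% segment_len
  if (n_seg < 2L) stop("fewer than 2 full segments: need n_frames >= 2 * segment_len")
  seg <- pmin((table$frame - f0) %/% segment_len + 1L, n_seg)
  xr <- range(table$x); yr <- range(table$y)
  nx <- ceiling(diff(xr) / bin_size) + 1L
  ny <- ceiling(diff(yr) / bin_size) + 1L
  P <- 2^ceiling(log2(2L * max(nx, ny)))
  hists <- lapply(seq_len(n_seg), function(s) {
    sel <- seg == s
    ix <- floor((table$x[sel] - xr[1]) / bin_size) + 1L
    iy <- floor((table$y[sel] - yr[1]) / bin_size) + 1L
    h <- matrix(0, P, P)
    for (r in seq_along(ix)) h[ix[r], iy[r]] <- h[ix[r], iy[r]] + 1
    h
  })
  ffts <- lapply(hists, stats::fft)
  pairs <- utils::combn(n_seg, 2L)
  meas <- matrix(0, ncol(pairs), 2)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    cc <- Re(stats::fft(ffts[[j]] * Conj(ffts[[i]]), inverse = TRUE))
    meas[p, ] <- .cc_peak_shift(cc, P) * bin_size
  }
  solve_drift <- function(use) {
    A <- matrix(0, sum(use), n_seg - 1L)
    rows <- which(use)
    for (r in seq_along(rows)) {
      i <- pairs[1, rows[r]]; j <- pairs[2, rows[r]]
      if (j > 1L) A[r, j - 1L] <- 1
      if (i > 1L) A[r, i - 1L] <- A[r, i - 1L] - 1
    }
    dx <- stats::lm.fit(A, meas[use, 1])
    dy <- stats::lm.fit(A, meas[use, 2])
    list(d = cbind(c(0, dx$coefficients), c(0, dy$coefficients)),
         res = sqrt(dx$residuals^2 + dy$residuals^2))
  }
  use <- rep(TRUE, ncol(pairs))
  fit <- solve_drift(use)
  bad <- fit$res > error_threshold * pixel_size
  if (any(bad)) {
    use[use][bad] <- FALSE
    if (!any(use)) {
      stop(sprintf("all segment pairs rejected (residuals %s nm)",
                   paste(signif(fit$res, 3), collapse = ", ")))
    }
    fit <- solve_drift(use)
  }
  d <- fit$d
  seg_frames <- f0 + (seq_len(n_seg) - 0.5) * segment_len
  per_frame <- data.frame(
    frame = f0:f1,
    dx = stats::approx(seg_frames, d[, 1], xout = f0:f1, rule = 2)$y,
    dy = stats::approx(seg_frames, d[, 2], xout = f0:f1, rule = 2)$y)
  idx <- match(table$frame, per_frame$frame)
  table$x <- table$x - per_frame$dx[idx]
  table$y <- table$y - per_frame$dy[idx]
  drift <- structure(
    list(segment_edges = f0 + (0:n_seg) * segment_len,
         segment_frames = seg_frames, displacement = d,
         per_frame = per_frame, n_pairs_used = sum(use)),
    class = "drift_trace")
  list(table = table, drift = drift)
}

## Cross-correlation peak location as a signed shift in bins, with sub-bin
## refinement by the 3 x 3 intensity centroid around the peak.
#' @noRd
.cc_peak_shift <- function(cc, P) {
  pk <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i) ((i - 1L) %% P) + 1L
  ii <- wrap(pk[1] + (-1:1)); jj <- wrap(pk[2] + (-1:1))
  w <- cc[ii, jj]
  w <- w - min(w)
  tot <- sum(w)
  off <- if (tot > 0) {
    c(sum((-1:1) * rowSums(w)), sum((-1:1) * colSums(w))) / tot
  } else c(0, 0)
  shift <- pk - 1L
  shift <- ifelse(shift > P / 2, shift - P, shift)
  shift + off
}
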