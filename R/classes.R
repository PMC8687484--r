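#' Multichannel volumetric image
#'
#' The substrate of 3D segmentation and enrichment analysis: one or more
#' channels of identical dimensions with physical voxel sizes in nm.
#' Physical coordinates follow the voxel-center convention: voxel
#' \eqn{(i, j, k)} (1-based) has its center at
#' \eqn{((i-0.5) p_{xy}, (j-0.5) p_{xy}, (k-0.5) p_z)} nm.
#'
#' @param channels named list of non-negative 3D numeric arrays sharing
#'   dimensions. Axis 3 is the optical (z) axis.
#' @param voxel_size_xy,voxel_size_z physical voxel sizes in nm (> 0).
#' @return an object of class `volumetric_image`.
#' @export
volumetric_image <- function(channels, voxel_size_xy, voxel_size_z) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stop("`channels` must be a non-empty named list of 3D arrays")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) stop("all channels must be 3D arrays")
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("all channels must share dimensions")
  }
  if (!is.numeric(voxel_size_xy) || voxel_size_xy <= 0 ||
      !is.numeric(voxel_size_z) || voxel_size_z <= 0) {
    stop("voxel sizes must be positive (nm)")
  }
  structure(
    list(channels = channels,
         voxel_size_xy = as.numeric(voxel_size_xy),
         voxel_size_z = as.numeric(voxel_size_z)),
    class = "volumetric_image")
}

#' @export
print.volumetric_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<volumetric_image> %d x %d x %d voxels (%.4g x %.4g nm), channels: %s\n",
              d[1], d[2], d[3], x$voxel_size_xy, x$voxel_size_z,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @noRd
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "volumetric_image"))
  if (!channel %in% names(image$channels)) {
    stop(sprintf("channel '%s' not found; available channels: %s",
                 channel, paste(names(image$channels), collapse = ", ")),
         call. = FALSE)
  }
  image$channels[[channel]]
}

#' Labeled objects in a volumetric image
#'
#' Connected puncta/objects with per-object statistics. Created by
#' [label_objects()].
#'
#' @param labels 3D integer array, 0 = background, object ids 1..N contiguous.
#' @param objects data.frame with columns `id`, `x_nm`, `y_nm`, `z_nm`
#'   (center of mass in physical nm), `voxel_count`, `integrated_intensity`.
#' @param voxel_size_xy,voxel_size_z voxel sizes in nm.
#' @return an object of class `object_label_map`.
#' @export
object_label_map <- function(labels, objects, voxel_size_xy, voxel_size_z) {
  structure(
    list(labels = labels, objects = objects,
         voxel_size_xy = voxel_size_xy, voxel_size_z = voxel_size_z),
    class = "object_label_map")
}

#' @export
print.object_label_map <- function(x, ...) {
  cat(sprintf("<object_label_map> %d objects in %s-voxel volume\n",
              nrow(x$objects), paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Extract object centers as a matrix in nm
#'
#' @param x an `object_label_map`.
#' @return an n x 3 matrix of center-of-mass positions (nm).
#' @export
object_centers <- function(x) {
  stopifnot(inherits(x, "object_label_map"))
  as.matrix(x$objects[, c("x_nm", "y_nm", "z_nm")])
}

#' Intensity trace over time
#'
#' @param time_s strictly increasing times in seconds.
#' @param value intensity values (raw integrated density or normalized F/F0).
#' @param compartment one of "synaptic", "extrasynaptic", "roi".
#' @param normalized logical; TRUE when values are F/F0.
#' @param normalization_range index range used for F0 (or NULL).
#' @return data.frame of class `intensity_trace` with columns `time_s`, `value`.
#' @export
intensity_trace <- function(time_s, value, compartment = "roi",
                            normalized = FALSE, normalization_range = NULL) {
  if (length(time_s) != length(value)) stop("time and value lengths differ")
  if (any(diff(time_s) <= 0)) stop("`time_s` must be strictly increasing")
  out <- data.frame(time_s = as.numeric(time_s), value = as.numeric(value))
  attr(out, "compartment") <- compartment
  attr(out, "normalized") <- isTRUE(normalized)
  attr(out, "normalization_range") <- normalization_range
  class(out) <- c("intensity_trace", "data.frame")
  out
}
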