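## File interfaces: TIFF stacks, ROI JSON, enrichment-profile CSV.

#' Read a multichannel volumetric image from TIFF stacks
#'
#' @param paths named character vector of TIFF paths, one per channel; each
#'   file holds one z-page per slice.
#' @param voxel_size_xy,voxel_size_z voxel sizes in nm.
#' @return a [volumetric_image()].
#' @export
read_volumetric_tiff <- function(paths, voxel_size_xy, voxel_size_z) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    stop("`paths` must be named by channel")
  }
  channels <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
    arr * read_tiff_scale(p)
  })
  volumetric_image(channels, voxel_size_xy, voxel_size_z)
}

#' Write a volumetric image as one 32-bit TIFF stack per channel
#'
#' Intensities are stored as 32-bit float scaled to \[0, 1\] by the channel
#' maximum; the scale factor is recorded in the TIFF description so
#' [read_volumetric_tiff()] can restore the original values.
#'
#' @param image a [volumetric_image()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_volumetric_tiff <- function(image, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ch in names(image$channels)) {
    a <- image$channels[[ch]]
    mx <- max(a, 1e-12)
    pages <- lapply(seq_len(dim(a)[3]), function(z) a[, , z] / mx)
    p <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(pages, p, bits.per.sample = 32L)
    # record the restore scale alongside (plain-text sidecar)
    writeLines(sprintf("%.17g", mx), paste0(p, ".scale"))
    paths[ch] <- p
  }
  invisible(paths)
}

#' @noRd
read_tiff_scale <- function(path) {
  sp <- paste0(path, ".scale")
  if (file.exists(sp)) as.numeric(readLines(sp)[1]) else 1
}

#' Read named rectangular ROIs from JSON
#'
#' The JSON maps ROI names to objects with `x`, `y`, `width`, `height`
#' (nm). Each ROI becomes a rectangular region usable with
#' [fraction_in_region()] and [classify_overlap()].
#'
#' @param path JSON file path.
#' @return named list of `synaptic_region` rectangles.
#' @export
read_roi_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(spec, function(r) {
    region_from_polygon(rbind(
      c(r$x, r$y), c(r$x + r$width, r$y),
      c(r$x + r$width, r$y + r$height), c(r$x, r$y + r$height)))
  })
  out
}

#' Write an enrichment profile to CSV
#'
#' @param profile an `enrichment_profile`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
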