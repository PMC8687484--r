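#' Coordinate-by-coordinate local density
#'
#' For every localization, the number of localizations (itself included)
#' within `radius`, divided by the disk area \eqn{\pi R^2}. Densities are
#' invariant under rigid motion of the coordinate set.
#'
#' @param coords n x 2 matrix of planar coordinates in nm (n >= 1).
#' @param radius counting radius in nm (default 30, commensurate with
#'   nanocluster scale and typical localization precision).
#' @return object of class `density_locs`: list with `coords`, `density`
#'   (per nm^2), `radius`.
#' @export
local_density <- function(coords, radius = 30) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("need at least one coordinate")
  if (radius <= 0) stop("`radius` must be > 0")
  counts <- count_within_radius(coords, radius)
  structure(list(coords = coords, density = counts / (pi * radius^2),
                 radius = radius),
            class = "density_locs")
}

#' Segment synaptic regions from density-annotated localizations
#'
#' Thresholds localizations on local density — by default at the lower 10%
#' of the density *range* (`d_min + q (d_max - d_min)`); localizations below
#' are considered outside synaptic structures — and groups the survivors
#' into connected alpha-complex components at `alpha`. Components whose
#' alpha-shape area falls below `min_area` are discarded. When all densities
#' are identical the range is zero and every localization is retained.
#'
#' @param annotated a [local_density()] result.
#' @param range_quantile proportion of the density range (default 0.10).
#' @param alpha alpha radius in nm for the region boundary (default 100).
#' @param min_area minimum region area in nm^2 (default 1.5e3).
#' @param threshold_mode `"range"` (default; fraction of the density range)
#'   or `"percentile"` (quantile of the density distribution).
#' @return list of `synaptic_region` objects, largest first (possibly empty).
#' @export
segment_synaptic_region <- function(annotated, range_quantile = 0.10,
                                    alpha = 100, min_area = 1.5e3,
                                    threshold_mode = c("range", "percentile")) {
  stopifnot(inherits(annotated, "density_locs"))
  threshold_mode <- match.arg(threshold_mode)
  d <- annotated$density
  thr <- switch(threshold_mode,
                range = min(d) + range_quantile * (max(d) - min(d)),
                percentile = as.numeric(stats::quantile(d, range_quantile)))
  keep <- which(d >= thr)
  if (length(keep) < 3L) return(list())
  pts <- annotated$coords[keep, , drop = FALSE]
  comps <- alpha_components(pts, alpha)
  regions <- lapply(comps, function(cc) {
    make_region(pts[cc$point_idx, , drop = FALSE],
                remap_triangles(cc$triangles, cc$point_idx),
                cc$area,
                remap_triangles(cc$boundary_edges, cc$point_idx),
                alpha)
  })
  regions <- Filter(function(r) r$area >= min_area, regions)
  regions[order(vapply(regions, `[[`, 1, "area"), decreasing = TRUE)]
}

#' @noRd
remap_triangles <- function(mat, point_idx) {
  out <- matrix(match(as.vector(mat), point_idx), nrow(mat), ncol(mat))
  storage.mode(out) <- "integer"
  out
}

#' Fraction of localizations inside a region
#'
#' The proportion of coordinates strictly inside or on the boundary of the
#' region (e.g. the percentage of ligand or receptor localizations that fall
#' within the PSD boundary).
#'
#' @param coords n x 2 matrix in nm.
#' @param region a `synaptic_region`.
#' @return a proportion in \[0, 1\]; `NA` with a warning for empty input.
#' @export
fraction_in_region <- function(coords, region) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) {
    warning("empty coordinate set: fraction undefined")
    return(NA_real_)
  }
  mean(point_in_region(coords, region))
}

#' Detect nanoclusters against a uniform randomization null
#'
#' Within a synaptic region, the local-density threshold separating clustered
#' from dispersed localizations is set empirically: the same number of points
#' is drawn uniformly across the region in each of `n_randomizations`
#' randomizations, their local densities are pooled, and the threshold is the
#' pooled mean plus 2 SD. Experimental localizations above threshold are
#' grouped into connected alpha-complex components at `alpha`; components
#' with at least `min_members` members become nanoclusters with an area,
#' boundary and weighted center (mean of member coordinates).
#'
#' @param annotated a [local_density()] result (full coordinate set).
#' @param region the `synaptic_region` to analyze (must contain >= 3
#'   coordinates with nonzero area).
#' @param n_randomizations number of uniform randomizations (default 20;
#'   1 reproduces a single-randomization cutoff).
#' @param alpha nanocluster alpha radius in nm (default 11).
#' @param min_members minimum localizations per cluster (default 3, the
#'   smallest set that bounds an alpha-complex triangle).
#' @param seed integer seed for the randomizations.
#' @return list of `nanocluster` objects (fields of `synaptic_region` plus
#'   `weighted_center`, `density_threshold`; classification fields are filled
#'   by [classify_overlap()]).
#' @export
detect_nanoclusters <- function(annotated, region, n_randomizations = 20L,
                                alpha = 11, min_members = 3L, seed = 1L) {
  stopifnot(inherits(annotated, "density_locs"))
  if (region$area <= 0) stop("region has zero area")
  inside <- point_in_region(annotated$coords, region)
  coords_in <- annotated$coords[inside, , drop = FALSE]
  n <- nrow(coords_in)
  if (n < 3L) stop("region must contain at least 3 coordinates")
  radius <- annotated$radius
  dens_in <- count_within_radius(coords_in, radius) / (pi * radius^2)
  pooled <- with_seed(seed, {
    unlist(lapply(seq_len(n_randomizations), function(s) {
      pts <- sample_in_region(region, n)
      count_within_radius(pts, radius) / (pi * radius^2)
    }))
  })
  thr <- mean(pooled) + 2 * stats::sd(pooled)
  hot <- which(dens_in > thr)
  if (length(hot) < min_members) return(list())
  pts <- coords_in[hot, , drop = FALSE]
  comps <- alpha_components(pts, alpha)
  out <- lapply(comps, function(cc) {
    if (length(cc$point_idx) < min_members) return(NULL)
    members <- pts[cc$point_idx, , drop = FALSE]
    cl <- make_region(members, remap_triangles(cc$triangles, cc$point_idx),
                      cc$area, remap_triangles(cc$boundary_edges, cc$point_idx),
                      alpha, class = c("nanocluster", "synaptic_region"))
    cl$weighted_center <- colMeans(members)
    cl$density_threshold <- thr
    cl$overlap_fraction <- NA_real_
    cl$classification <- NA_character_
    cl$center_to_psd_edge <- NA_real_
    cl
  })
  Filter(Negate(is.null), out)
}

## Uniform samples inside a region polygon by seeded rejection from its
## bounding box.
#' @noRd
sample_in_region <- function(region, n) {
  lo <- apply(region$coords, 2, min)
  hi <- apply(region$coords, 2, max)
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, lo[1], hi[1]), stats::runif(m, lo[2], hi[2]))
    out <- rbind(out, cand[point_in_region(cand, region), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Classify a nanocluster's overlap with the PSD
#'
#' Computes the fraction of the nanocluster's alpha-shape area that lies
#' inside the PSD region (exact polygon clipping). Clusters whose overlap
#' fraction is at least `overlap_threshold` are classified `overlapping` and
#' assigned a center-to-PSD-edge distance of zero; otherwise the Euclidean
#' distance from the cluster's weighted center to the nearest point of the
#' PSD boundary is reported.
#'
#' @param cluster a `nanocluster` (or any triangulated region with a
#'   `weighted_center`).
#' @param psd the PSD `synaptic_region`.
#' @param overlap_threshold minimum area fraction counted as overlapping
#'   (default 0.23; the boundary value itself classifies as overlapping).
#' @return the cluster with `overlap_fraction`, `classification`
#'   (`"overlapping"` / `"non_overlapping"`) and `center_to_psd_edge` filled.
#' @export
classify_overlap <- function(cluster, psd, overlap_threshold = 0.23) {
  if (is.null(cluster$area) || cluster$area <= 0) stop("cluster has zero area")
  ov <- region_overlap_area(cluster, psd)
  frac <- min(max(ov / cluster$area, 0), 1)
  cluster$overlap_fraction <- frac
  if (is.null(cluster$weighted_center)) {
    cluster$weighted_center <- colMeans(cluster$coords)
  }
  # the >= rule holds at the printed threshold precision; the 1e-9 guard
  # absorbs rounding from the scaled-integer polygon clipping
  if (frac >= overlap_threshold - 1e-9) {
    cluster$classification <- "overlapping"
    cluster$center_to_psd_edge <- 0
  } else {
    cluster$classification <- "non_overlapping"
    cluster$center_to_psd_edge <- distance_to_boundary(cluster$weighted_center, psd)
  }
  cluster
}

#' Summarize nanoclusters of one synapse
#'
#' Convenience wrapper running [detect_nanoclusters()] and
#' [classify_overlap()] and returning a per-cluster table.
#'
#' @inheritParams detect_nanoclusters
#' @param psd PSD region used for overlap classification.
#' @param overlap_threshold see [classify_overlap()].
#' @return data.frame with one row per nanocluster: `area_nm2`,
#'   `member_count`, `overlap_fraction`, `classification`,
#'   `center_to_psd_edge_nm`.
#' @export
nanocluster_table <- function(annotated, region, psd,
                              n_randomizations = 20L, alpha = 11,
                              overlap_threshold = 0.23, seed = 1L) {
  cl <- detect_nanoclusters(annotated, region, n_randomizations, alpha,
                            seed = seed)
  cl <- lapply(cl, classify_overlap, psd = psd,
               overlap_threshold = overlap_threshold)
  data.frame(
    area_nm2 = vapply(cl, `[[`, 1, "area"),
    member_count = vapply(cl, `[[`, 1L, "member_count"),
    overlap_fraction = vapply(cl, `[[`, 1, "overlap_fraction"),
    classification = vapply(cl, `[[`, "", "classification"),
    center_to_psd_edge_nm = vapply(cl, `[[`, 1, "center_to_psd_edge"))
}
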