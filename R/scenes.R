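## Synthetic-scene generators. Every generator is driven by a single seed,
## returns the generated data plus a ground-truth object, and emulates the
## statistical structure the corresponding analysis assumes.

## Render isotropic-in-nm 3D Gaussian spots (truncated at 3 sigma) into an array.
#' @noRd
render_spots <- function(d, vx, vz, centers, amplitude, sigma_nm) {
  a <- array(0, d)
  if (is.null(centers) || nrow(centers) == 0L) return(a)
  for (p in seq_len(nrow(centers))) {
    cx <- centers[p, 1]; cy <- centers[p, 2]; cz <- centers[p, 3]
    i0 <- max(1L, pos_to_voxel(cx - 3 * sigma_nm, vx)); i1 <- min(d[1], pos_to_voxel(cx + 3 * sigma_nm, vx))
    j0 <- max(1L, pos_to_voxel(cy - 3 * sigma_nm, vx)); j1 <- min(d[2], pos_to_voxel(cy + 3 * sigma_nm, vx))
    k0 <- max(1L, pos_to_voxel(cz - 3 * sigma_nm, vz)); k1 <- min(d[3], pos_to_voxel(cz + 3 * sigma_nm, vz))
    if (i0 > i1 || j0 > j1 || k0 > k1) next
    gx <- exp(-(voxel_center(i0:i1, vx) - cx)^2 / (2 * sigma_nm^2))
    gy <- exp(-(voxel_center(j0:j1, vx) - cy)^2 / (2 * sigma_nm^2))
    gz <- exp(-(voxel_center(k0:k1, vz) - cz)^2 / (2 * sigma_nm^2))
    patch <- amplitude * outer(outer(gx, gy), gz)
    a[i0:i1, j0:j1, k0:k1] <- a[i0:i1, j0:j1, k0:k1] + patch
  }
  a
}

#' Generate a 3D two-channel scene with tunable perisynaptic enrichment
#'
#' Emulates a volumetric image of punctate synaptic-marker objects plus a
#' ligand channel whose puncta are partly enriched around the markers:
#' a fraction `enriched_fraction` of ligand puncta is placed uniformly at
#' random on voxel centers within `enrichment_radius` of a marker center —
#' the same voxel-grid sampler the analysis null uses — and the remainder
#' uniformly over the volume. Marker centers are snapped to voxel centers so
#' that placement distances are exact. Puncta are rendered as isotropic-in-nm
#' 3D Gaussians truncated at 3 sigma, with additive Gaussian noise clipped
#' at 0.
#'
#' @param shape voxel dimensions `c(nx, ny, nz)`.
#' @param voxel_size_xy,voxel_size_z voxel sizes in nm.
#' @param n_markers,n_ab numbers of marker and ligand puncta.
#' @param enriched_fraction proportion of ligand puncta placed within
#'   `enrichment_radius` of a marker (in \[0, 1\]).
#' @param enrichment_radius placement radius in nm (default 642).
#' @param psf_sigma Gaussian sigma of rendered puncta in nm.
#' @param amplitude peak intensity of a punctum.
#' @param noise_sd additive Gaussian noise sigma (intensity units).
#' @param placement `"centers"` (default): enriched puncta are placed on
#'   voxel centers within `enrichment_radius` of a marker *center*, so the
#'   truth is verifiable by a brute-force center-to-center distance check.
#'   `"reference_field"`: the marker channel is rendered and segmented first
#'   and enriched puncta are drawn uniformly from the voxels within
#'   `enrichment_radius` of the segmented marker *mask* — exactly the
#'   candidate set the analysis null samples from, which is the right
#'   construction for null self-consistency experiments.
#' @param min_separation optional minimum pairwise distance (nm) between
#'   ligand puncta, enforced by thinning; use to build well-separated scenes
#'   for segmentation-recovery tests.
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @return list with `image` (a [volumetric_image()] with channels `marker`
#'   and `ab`) and `truth` (class `scene_truth`: `marker_centers`,
#'   `ab_centers` in nm, `ab_enriched` logical, `enrichment_radius`,
#'   `enriched_fraction`, `seed`).
#' @export
gen_sim_scene <- function(shape = c(128L, 128L, 8L), voxel_size_xy = 32.1,
                          voxel_size_z = 200, n_markers = 20L, n_ab = 200L,
                          enriched_fraction = 1, enrichment_radius = 642,
                          psf_sigma = 64, amplitude = 100, noise_sd = 10,
                          placement = c("centers", "reference_field"),
                          min_separation = 0, seed = 1L) {
  placement <- match.arg(placement)
  if (n_markers <= 0L || n_ab <= 0L) stop("counts must be > 0")
  if (voxel_size_xy <= 0 || voxel_size_z <= 0) stop("voxel sizes must be > 0")
  if (enriched_fraction < 0 || enriched_fraction > 1) {
    stop("`enriched_fraction` must be in [0, 1]")
  }
  d <- as.integer(shape)
  nvox <- prod(d)
  if ((n_markers + n_ab) > nvox / 64) {
    stop("shape too small to hold the requested puncta without excessive overlap")
  }
  with_seed(seed, {
    vx <- voxel_size_xy; vz <- voxel_size_z
    marker_idx <- sample.int(nvox, n_markers)
    mijk <- arrayInd(marker_idx, d)
    marker_centers <- cbind(voxel_center(mijk[, 1], vx),
                            voxel_center(mijk[, 2], vx),
                            voxel_center(mijk[, 3], vz))
    marker_ch <- render_spots(d, vx, vz, marker_centers, amplitude, psf_sigma)
    if (noise_sd > 0) {
      marker_ch <- marker_ch + array(stats::rnorm(nvox, 0, noise_sd), d)
    }
    marker_ch <- pmax(marker_ch, 0)
    if (placement == "centers") {
      grid <- cbind(
        voxel_center(rep.int(seq_len(d[1]), d[2] * d[3]), vx),
        voxel_center(rep.int(rep(seq_len(d[2]), each = d[1]), d[3]), vx),
        voxel_center(rep(seq_len(d[3]), each = d[1] * d[2]), vz))
      dist_ref <- RANN::nn2(marker_centers, grid, k = 1L)$nn.dists[, 1]
    } else {
      # distances measured from the segmented marker mask, as the null does
      mimg <- volumetric_image(list(marker = marker_ch), vx, vz)
      ref_olm <- segment_channel(mimg, "marker", watershed = FALSE)
      dist_ref <- as.vector(distance_transform(ref_olm)$distances)
    }
    cand <- which(dist_ref <= enrichment_radius)
    n_enr <- round(enriched_fraction * n_ab)
    if (n_enr > length(cand)) {
      stop("not enough candidate voxels within the enrichment radius")
    }
    pick_thinned <- function(pool, n_pick, taken_ijk) {
      # draw voxels one batch at a time, dropping candidates closer than
      # `min_separation` (nm) to any accepted punctum
      acc <- integer(0)
      pool <- pool[sample.int(length(pool))]
      to_nm <- function(idx) {
        ij <- arrayInd(idx, d)
        cbind(voxel_center(ij[, 1], vx), voxel_center(ij[, 2], vx),
              voxel_center(ij[, 3], vz))
      }
      taken <- taken_ijk
      for (ix in pool) {
        if (length(acc) == n_pick) break
        p <- to_nm(ix)
        if (min_separation > 0 && nrow(taken) > 0) {
          if (min(sqrt(rowSums(sweep(taken, 2, p)^2))) < min_separation) next
        }
        acc <- c(acc, ix)
        taken <- rbind(taken, p)
      }
      if (length(acc) < n_pick) {
        stop("could not place the requested puncta at the given minimum separation")
      }
      acc
    }
    if (min_separation > 0) {
      enr_idx <- if (n_enr > 0L) {
        pick_thinned(cand, n_enr, matrix(numeric(0), 0, 3))
      } else integer()
      pool <- setdiff(seq_len(nvox), c(marker_idx, enr_idx))
      unif_idx <- if (n_ab - n_enr > 0L) {
        ij <- arrayInd(enr_idx, d)
        taken <- cbind(voxel_center(ij[, 1], vx), voxel_center(ij[, 2], vx),
                       voxel_center(ij[, 3], vz))
        pick_thinned(pool, n_ab - n_enr, taken)
      } else integer()
    } else {
      enr_idx <- if (n_enr > 0L) cand[sample.int(length(cand), n_enr)] else integer()
      pool <- setdiff(seq_len(nvox), c(marker_idx, enr_idx))
      unif_idx <- if (n_ab - n_enr > 0L) pool[sample.int(length(pool), n_ab - n_enr)] else integer()
    }
    ab_idx <- c(enr_idx, unif_idx)
    aijk <- arrayInd(ab_idx, d)
    ab_centers <- cbind(voxel_center(aijk[, 1], vx),
                        voxel_center(aijk[, 2], vx),
                        voxel_center(aijk[, 3], vz))
    ab_ch <- render_spots(d, vx, vz, ab_centers, amplitude, psf_sigma)
    if (noise_sd > 0) {
      ab_ch <- ab_ch + array(stats::rnorm(nvox, 0, noise_sd), d)
    }
    image <- volumetric_image(list(marker = marker_ch, ab = pmax(ab_ch, 0)),
                              vx, vz)
    truth <- structure(
      list(marker_centers = marker_centers, ab_centers = ab_centers,
           ab_enriched = c(rep(TRUE, n_enr), rep(FALSE, n_ab - n_enr)),
           enrichment_radius = enrichment_radius,
           enriched_fraction = enriched_fraction, seed = seed),
      class = "scene_truth")
    list(image = image, truth = truth)
  })
}

## Regular polygon approximating a disk (used as the PSD boundary).
#' @noRd
disk_polygon <- function(center, radius, n_vertices = 64L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

#' Generate a 2D SMLM localization scene with a dense PSD and planted clusters
#'
#' Builds a localization table from three populations: points uniform in a
#' central PSD disk, planted circular nanoclusters, and uniform background
#' over the field; every point is jittered by Gaussian localization noise.
#' The truth records cluster memberships and the realized in-PSD fraction
#' (evaluated on the jittered coordinates against the PSD polygon with the
#' same point-in-region test the analysis uses).
#'
#' @param field field extent in nm, scalar or `c(width, height)`.
#' @param psd_radius radius of the central PSD disk in nm.
#' @param n_psd number of PSD points; may be omitted when `in_psd_target`
#'   is given.
#' @param n_background number of uniform background points.
#' @param clusters list of planted clusters, each
#'   `list(center = c(x, y), radius, n)`.
#' @param in_psd_target optional target in-PSD fraction; when supplied,
#'   `n_psd` is solved for in expectation.
#' @param loc_precision Gaussian localization jitter sigma in nm (> 0).
#' @param seed integer seed.
#' @return list with `table` (localization data.frame: `frame`, `x`, `y`,
#'   `sigma`, `uncertainty`, `photons`, `channel`) and `truth` (class
#'   `smlm_truth`: `psd_polygon`, `cluster_memberships` (0 = background/PSD),
#'   `in_psd_fraction` realized, `seed`).
#' @export
gen_smlm_scene <- function(field = c(1000, 1000), psd_radius = 150,
                           n_psd = NULL, n_background = 100, clusters = list(),
                           in_psd_target = NULL, loc_precision = 10, seed = 1L) {
  if (loc_precision <= 0) stop("`loc_precision` must be > 0")
  field <- rep(as.numeric(field), length.out = 2L)
  ctr <- field / 2
  for (cl in clusters) {
    if (cl$radius <= 0) stop("cluster radii must be > 0")
    if (any(cl$center < 0) || any(cl$center > field)) {
      stop("cluster centered outside the field")
    }
  }
  n_cl <- if (length(clusters)) sum(vapply(clusters, `[[`, 1, "n")) else 0
  if (!is.null(in_psd_target)) {
    f <- in_psd_target
    disk_frac <- pi * psd_radius^2 / prod(field)
    bg_in <- n_background * disk_frac
    cl_in <- 0
    for (cl in clusters) {
      if (sqrt(sum((cl$center - ctr)^2)) <= psd_radius) cl_in <- cl_in + cl$n
    }
    if (f >= 1) {
      if (n_background > 0 || n_cl > cl_in) {
        stop("in_psd_target = 1 requires no background and no outside clusters")
      }
      n_psd <- n_psd %||% 500L
    } else if (f <= 0) {
      n_psd <- 0L
    } else {
      n_psd <- max(0L, round((f * (n_background + n_cl) - bg_in - cl_in) / (1 - f)))
    }
  }
  if (is.null(n_psd)) stop("supply `n_psd` or `in_psd_target`")
  with_seed(seed, {
    pts <- matrix(numeric(0), 0, 2)
    member <- integer(0)
    psd_poly <- disk_polygon(ctr, psd_radius)
    if (n_psd > 0L) {
      # uniform inside the PSD polygon (rejection from the circumscribed disk)
      acc <- matrix(numeric(0), 0, 2)
      while (nrow(acc) < n_psd) {
        m <- 2L * (n_psd - nrow(acc)) + 8L
        r <- psd_radius * sqrt(stats::runif(m))
        th <- stats::runif(m, 0, 2 * pi)
        cand <- cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
        acc <- rbind(acc, cand[point_in_polygon(cand, psd_poly), , drop = FALSE])
      }
      pts <- rbind(pts, acc[seq_len(n_psd), , drop = FALSE])
      member <- c(member, rep(0L, n_psd))
    }
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      r <- cl$radius * sqrt(stats::runif(cl$n))
      th <- stats::runif(cl$n, 0, 2 * pi)
      pts <- rbind(pts, cbind(cl$center[1] + r * cos(th), cl$center[2] + r * sin(th)))
      member <- c(member, rep(ci, cl$n))
    }
    if (n_background > 0L) {
      bgp <- cbind(stats::runif(n_background, 0, field[1]),
                   stats::runif(n_background, 0, field[2]))
      if (!is.null(in_psd_target) && in_psd_target <= 0) {
        # a zero-fraction scene has no background inside the PSD either
        while (any(hit <- point_in_polygon(bgp, psd_poly))) {
          bgp[hit, ] <- cbind(stats::runif(sum(hit), 0, field[1]),
                              stats::runif(sum(hit), 0, field[2]))
        }
      }
      pts <- rbind(pts, bgp)
      member <- c(member, rep(0L, n_background))
    }
    n <- nrow(pts)
    if (n == 0L) stop("scene has no localizations")
    pts <- pts + matrix(stats::rnorm(2L * n, 0, loc_precision), n, 2)
    inside <- point_in_polygon(pts, psd_poly)
    table <- data.frame(
      frame = seq_len(n) %% 1000L,
      x = pts[, 1], y = pts[, 2],
      sigma = stats::runif(n, 120, 180),
      uncertainty = rep(loc_precision, n),
      photons = round(stats::rlnorm(n, log(1000), 0.3)),
      channel = "ab", stringsAsFactors = FALSE)
    truth <- structure(
      list(psd_polygon = psd_poly, cluster_memberships = member,
           in_psd_fraction = mean(inside), drift_trace = NULL,
           distortion_field = NULL, seed = seed),
      class = "smlm_truth")
    list(table = table, truth = truth)
  })
}

## Bivariate polynomial design matrix on centered, field-normalized coords.
#' @noRd
poly2d_design <- function(xy, field, degree) {
  u <- xy[, 1] / field[1] - 0.5
  v <- xy[, 2] / field[2] - 0.5
  cols <- list()
  for (i in 0:degree) for (j in 0:(degree - i)) {
    cols[[length(cols) + 1L]] <- u^i * v^j
  }
  do.call(cbind, cols)
}

#' Generate a matched two-channel bead field with smooth distortion
#'
#' Channel-1 bead positions are uniform over the field; channel-2 positions
#' add a smooth bivariate-polynomial displacement whose maximum magnitude
#' over the field equals `distortion_amplitude` (emulating the up-to-100 nm
#' inter-channel shift and distortion of dual-color SMLM optics), plus
#' independent Gaussian localization noise in each channel.
#'
#' @param n_beads number of beads.
#' @param field field extent in nm, scalar or `c(width, height)`.
#' @param distortion_amplitude maximum displacement magnitude in nm (>= 0).
#' @param polynomial_degree degree of the distortion polynomial (default 2).
#' @param noise_sd per-channel localization noise sigma in nm.
#' @param coefficients optional list with numeric vectors `dx`, `dy`: explicit
#'   polynomial coefficients (terms `u^i v^j`, `i + j <= degree`, on centered
#'   field-normalized coordinates). Overrides the random distortion; useful
#'   for planting exact translations.
#' @param seed integer seed.
#' @return list with `ref` and `moving` localization tables (row-matched) and
#'   `truth` (class `smlm_truth`-like list: `displacement` n x 2 true
#'   displacement at each bead, `coefficients`, `amplitude`, `seed`).
#' @export
gen_bead_field <- function(n_beads = 200L, field = 25000, distortion_amplitude = 100,
                           polynomial_degree = 2L, noise_sd = 5, coefficients = NULL,
                           seed = 1L) {
  if (distortion_amplitude < 0) stop("`distortion_amplitude` must be >= 0")
  field <- rep(as.numeric(field), length.out = 2L)
  with_seed(seed, {
    ref <- cbind(stats::runif(n_beads, 0, field[1]), stats::runif(n_beads, 0, field[2]))
    n_terms <- (polynomial_degree + 1) * (polynomial_degree + 2) / 2
    if (is.null(coefficients)) {
      cx <- stats::rnorm(n_terms); cy <- stats::rnorm(n_terms)
      if (distortion_amplitude == 0) { cx[] <- 0; cy[] <- 0 }
      # scale so the max displacement magnitude over the field is the amplitude
      gs <- seq(0, 1, length.out = 60L)
      gxy <- cbind(rep(gs * field[1], each = 60L), rep(gs * field[2], 60L))
      Dg <- poly2d_design(gxy, field, polynomial_degree)
      mags <- sqrt((Dg %*% cx)^2 + (Dg %*% cy)^2)
      mx <- max(mags)
      if (mx > 0) { cx <- cx * distortion_amplitude / mx; cy <- cy * distortion_amplitude / mx }
    } else {
      cx <- coefficients$dx; cy <- coefficients$dy
      if (length(cx) != n_terms || length(cy) != n_terms) {
        stop(sprintf("coefficient vectors must have %d terms for degree %d",
                     n_terms, polynomial_degree))
      }
    }
    D <- poly2d_design(ref, field, polynomial_degree)
    disp <- cbind(D %*% cx, D %*% cy)
    mov <- ref + disp
    if (noise_sd > 0) {
      ref_obs <- ref + matrix(stats::rnorm(2L * n_beads, 0, noise_sd), n_beads, 2)
      mov_obs <- mov + matrix(stats::rnorm(2L * n_beads, 0, noise_sd), n_beads, 2)
    } else {
      ref_obs <- ref; mov_obs <- mov
    }
    mk_tab <- function(xy, channel) data.frame(
      frame = seq_len(n_beads), x = xy[, 1], y = xy[, 2],
      sigma = 150, uncertainty = max(noise_sd, 1e-3), photons = 5000,
      channel = channel, stringsAsFactors = FALSE)
    truth <- structure(
      list(displacement = disp, coefficients = list(dx = cx, dy = cy),
           amplitude = distortion_amplitude, field = field,
           degree = polynomial_degree, seed = seed),
      class = "smlm_truth")
    list(ref = mk_tab(ref_obs, "ref"), moving = mk_tab(mov_obs, "moving"),
         truth = truth)
  })
}

#' Generate a drifting localization stream
#'
#' Fixed emitters are observed over a movie; each frame's localizations are
#' offset by the frame's true drift plus Gaussian localization noise. Each
#' emitter is detected independently per frame with probability `p_on`.
#'
#' @param n_frames number of frames.
#' @param emitters either an m x 2 matrix of emitter positions in nm or a
#'   count (positions then drawn uniformly over `field`).
#' @param drift_model `"linear"` (drift grows linearly from 0 to `magnitude`)
#'   or `"step"` (0 for the first half, `magnitude` after the midpoint).
#' @param magnitude total drift in nm: scalar (applied along x) or `c(dx, dy)`.
#' @param loc_precision localization noise sigma in nm.
#' @param p_on per-frame detection probability of each emitter.
#' @param field field extent in nm used when `emitters` is a count.
#' @param seed integer seed.
#' @return list with `table` (localization data.frame) and `truth`
#'   (`drift_trace`: n_frames x 2 true drift; `emitters`; `seed`).
#' @export
gen_drift_series <- function(n_frames = 2000L, emitters = 40L,
                             drift_model = c("linear", "step"), magnitude = 100,
                             loc_precision = 10, p_on = 0.5, field = 2000,
                             seed = 1L) {
  drift_model <- match.arg(drift_model)
  if (n_frames < 2L) stop("need at least 2 frames")
  mag <- if (length(magnitude) == 1L) c(magnitude, 0) else as.numeric(magnitude)
  with_seed(seed, {
    if (is.matrix(emitters)) {
      pos <- emitters
    } else {
      pos <- cbind(stats::runif(emitters, 0, field), stats::runif(emitters, 0, field))
    }
    m <- nrow(pos)
    frac <- switch(drift_model,
                   linear = (seq_len(n_frames) - 1) / (n_frames - 1),
                   step = as.numeric(seq_len(n_frames) > n_frames / 2))
    drift <- cbind(frac * mag[1], frac * mag[2])
    rows <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      on <- which(stats::runif(m) < p_on)
      if (!length(on)) next
      k <- length(on)
      rows[[f]] <- data.frame(
        frame = f,
        x = pos[on, 1] + drift[f, 1] + stats::rnorm(k, 0, loc_precision),
        y = pos[on, 2] + drift[f, 2] + stats::rnorm(k, 0, loc_precision),
        sigma = 150, uncertainty = loc_precision, photons = 1000,
        channel = "ab", stringsAsFactors = FALSE)
    }
    table <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    rownames(table) <- NULL
    truth <- structure(list(drift_trace = drift, emitters = pos, seed = seed),
                       class = "smlm_truth")
    list(table = table, truth = truth)
  })
}

#' Generate a three-channel expansion-microscopy synapse scene
#'
#' Renders separated presynaptic and postsynaptic marker puncta plus ligand
#' puncta placed at stated cylindrical coordinates relative to the
#' postsynaptic-to-presynaptic axis (origin at the midpoint; positive axial
#' offsets toward the presynaptic side). Radial directions are drawn at
#' random in the plane perpendicular to the axis.
#'
#' @param pre_center,post_center 3D positions in nm (must differ).
#' @param n_ab number of ligand puncta.
#' @param axial_offsets,radial_offsets cylindrical coordinates in nm,
#'   recycled to `n_ab`; radial offsets must be >= 0.
#' @param psf_sigma rendered Gaussian sigma in nm.
#' @param shape,voxel_size_xy,voxel_size_z image geometry.
#' @param amplitude,noise_sd rendering intensity and additive noise.
#' @param seed integer seed.
#' @return list with `image` (channels `pre`, `post`, `ab`) and `truth`
#'   (`marker_centers` 2 x 3 matrix rows pre/post, `ab_centers`,
#'   `axial_offsets`, `radial_offsets`, `seed`).
#' @export
gen_exm_scene <- function(pre_center, post_center, n_ab = 10L,
                          axial_offsets = 0, radial_offsets = 0,
                          psf_sigma = 80, shape = c(128L, 128L, 16L),
                          voxel_size_xy = 50, voxel_size_z = 100,
                          amplitude = 100, noise_sd = 5, seed = 1L) {
  pre_center <- as.numeric(pre_center); post_center <- as.numeric(post_center)
  if (all(pre_center == post_center)) stop("pre and post centers must differ")
  d <- as.integer(shape)
  axial <- rep(as.numeric(axial_offsets), length.out = n_ab)
  radial <- rep(as.numeric(radial_offsets), length.out = n_ab)
  if (any(radial < 0)) stop("radial offsets must be >= 0")
  axis_vec <- pre_center - post_center           # post -> pre
  L <- sqrt(sum(axis_vec^2))
  u <- axis_vec / L
  origin <- (pre_center + post_center) / 2
  with_seed(seed, {
    # orthonormal basis of the plane perpendicular to the axis
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v1 <- a - sum(a * u) * u; v1 <- v1 / sqrt(sum(v1^2))
    v2 <- c(u[2] * v1[3] - u[3] * v1[2],
            u[3] * v1[1] - u[1] * v1[3],
            u[1] * v1[2] - u[2] * v1[1])
    th <- stats::runif(n_ab, 0, 2 * pi)
    ab_centers <- t(vapply(seq_len(n_ab), function(p) {
      origin + axial[p] * u + radial[p] * (cos(th[p]) * v1 + sin(th[p]) * v2)
    }, numeric(3)))
    ext <- c(d[1] * voxel_size_xy, d[2] * voxel_size_xy, d[3] * voxel_size_z)
    all_pts <- rbind(ab_centers, pre_center, post_center)
    if (any(all_pts < 0) || any(all_pts > rep(ext, each = nrow(all_pts)))) {
      stop("requested offsets place puncta outside the image bounds")
    }
    mk <- function(centers) {
      ch <- render_spots(d, voxel_size_xy, voxel_size_z, centers, amplitude, psf_sigma)
      if (noise_sd > 0) ch <- ch + array(stats::rnorm(prod(d), 0, noise_sd), d)
      pmax(ch, 0)
    }
    image <- volumetric_image(
      list(pre = mk(matrix(pre_center, 1)), post = mk(matrix(post_center, 1)),
           ab = mk(ab_centers)),
      voxel_size_xy, voxel_size_z)
    truth <- structure(
      list(marker_centers = rbind(pre = pre_center, post = post_center),
           ab_centers = ab_centers, axial_offsets = axial,
           radial_offsets = radial, seed = seed),
      class = "scene_truth")
    list(image = image, truth = truth)
  })
}

#' Generate noisy exponential kinetics traces
#'
#' Closed-form single-exponential traces for ligand binding (association),
#' washout, and FRAP, with additive Gaussian noise:
#' association `F(t) = baseline + (plateau - baseline)(1 - exp(-t/tau))`;
#' washout `F(t) = plateau + (1 - plateau) exp(-t/tau)` (decay toward the
#' stable fraction `plateau`); FRAP: prebleach baseline at 1, bleach dip to
#' `bleach_depth`, recovery
#' `F(t) = Fb + mobile_fraction (1 - Fb)(1 - exp(-rate t))`.
#' Times are in seconds; `tau` is in minutes and `rate` in 1/min.
#'
#' @param kind `"association"`, `"washout"` or `"frap"`.
#' @param truth list of kinetic parameters: `tau` (min), `plateau` (F/F0),
#'   `mobile_fraction` in \[0, 1\], `rate` (1/min), `noise_sd`, and optionally
#'   `baseline` (association start level, default 0) and `bleach_depth`
#'   (default 0.3).
#' @param n_points number of postbaseline points (>= 5).
#' @param dt sampling interval in seconds.
#' @param prebleach_points FRAP only: number of prebleach frames (default 12).
#' @param seed integer seed for the noise.
#' @return an [intensity_trace()]; for FRAP the bleach frame index is
#'   attached as attribute `bleach_frame`.
#' @export
gen_traces <- function(kind = c("association", "washout", "frap"), truth,
                       n_points = 60L, dt = 10, prebleach_points = 12L, seed = 1L) {
  kind <- match.arg(kind)
  if (n_points < 5L) stop("`n_points` must be >= 5")
  noise_sd <- truth$noise_sd %||% 0
  if (!is.null(truth$tau) && truth$tau <= 0) stop("tau must be > 0")
  if (!is.null(truth$mobile_fraction) &&
      (truth$mobile_fraction < 0 || truth$mobile_fraction > 1)) {
    stop("mobile_fraction must be in [0, 1]")
  }
  with_seed(seed, {
    if (kind == "association") {
      t_s <- (seq_len(n_points) - 1) * dt
      base <- truth$baseline %||% 0
      f <- base + (truth$plateau - base) * (1 - exp(-(t_s / 60) / truth$tau))
      bleach_frame <- NULL
    } else if (kind == "washout") {
      t_s <- (seq_len(n_points) - 1) * dt
      f <- truth$plateau + (1 - truth$plateau) * exp(-(t_s / 60) / truth$tau)
      bleach_frame <- NULL
    } else {
      t_s <- (seq_len(prebleach_points + n_points) - 1) * dt
      fb <- truth$bleach_depth %||% 0.3
      t_post <- (t_s[(prebleach_points + 1):length(t_s)] - t_s[prebleach_points + 1]) / 60
      rec <- fb + truth$mobile_fraction * (1 - fb) * (1 - exp(-truth$rate * t_post))
      f <- c(rep(1, prebleach_points), rec)
      bleach_frame <- prebleach_points + 1L
    }
    if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
    out <- intensity_trace(t_s, f, compartment = "roi", normalized = TRUE)
    if (!is.null(bleach_frame)) attr(out, "bleach_frame") <- bleach_frame
    out
  })
}
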