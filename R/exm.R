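#' Pair presynaptic and postsynaptic objects into synapses
#'
#' Candidate synapses are mutually nearest presynaptic/postsynaptic object
#' pairs. A pair is retained when (1) both objects exist, (2) at least one
#' ligand punctum lies within the Chebyshev window (`xy_window` pixels in
#' X-Y, `z_window` pixels in Z, converted to nm) of the pair midpoint, and
#' (3) the pre/post separation is at least `min_separation_factor` times the
#' mean marker-object radius — an automatic stand-in for manual selection of
#' synapses whose axis is well resolved in the imaging plane.
#'
#' @param pre,post,ab [object_label_map()]s sharing geometry.
#' @param xy_window,z_window window half-widths in pixels (defaults 20 and 3).
#' @param xy_window_nm,z_window_nm physical overrides in nm (useful when the
#'   effective pixel size depends on the expansion factor).
#' @param min_separation_factor required pre/post separation in units of the
#'   mean marker radius (default 2; set 0 to disable).
#' @return list of `synapse_pair` objects; each carries `pre_center`,
#'   `post_center`, `axis_vector` (post to pre), `axis_length`, `origin`
#'   (midpoint) and the indices `ab_ids` of in-window puncta.
#' @export
pair_synapses <- function(pre, post, ab, xy_window = 20, z_window = 3,
                          xy_window_nm = NULL, z_window_nm = NULL,
                          min_separation_factor = 2) {
  stopifnot(inherits(pre, "object_label_map"), inherits(post, "object_label_map"),
            inherits(ab, "object_label_map"))
  vx <- pre$voxel_size_xy; vz <- pre$voxel_size_z
  wxy <- xy_window_nm %||% (xy_window * vx)
  wz <- z_window_nm %||% (z_window * vz)
  pc <- object_centers(pre); qc <- object_centers(post); ac <- object_centers(ab)
  if (nrow(pc) == 0L || nrow(qc) == 0L) return(list())
  nn_pq <- RANN::nn2(qc, pc, k = 1L)   # nearest post for each pre
  nn_qp <- RANN::nn2(pc, qc, k = 1L)   # nearest pre for each post
  pairs <- list()
  for (i in seq_len(nrow(pc))) {
    j <- nn_pq$nn.idx[i, 1]
    if (nn_qp$nn.idx[j, 1] != i) next  # not mutual
    pre_ctr <- pc[i, ]; post_ctr <- qc[j, ]
    L <- sqrt(sum((pre_ctr - post_ctr)^2))
    if (L == 0) next
    if (min_separation_factor > 0) {
      vol_nm3 <- vx^2 * vz
      r_mean <- mean((3 * c(pre$objects$voxel_count[i], post$objects$voxel_count[j]) *
                        vol_nm3 / (4 * pi))^(1 / 3))
      if (L < min_separation_factor * r_mean) next
    }
    mid <- (pre_ctr + post_ctr) / 2
    hit <- integer(0)
    if (nrow(ac) > 0L) {
      hit <- which(abs(ac[, 1] - mid[1]) <= wxy &
                   abs(ac[, 2] - mid[2]) <= wxy &
                   abs(ac[, 3] - mid[3]) <= wz)
    }
    if (!length(hit)) next
    pairs[[length(pairs) + 1L]] <- structure(
      list(pre_center = pre_ctr, post_center = post_ctr,
           axis_vector = pre_ctr - post_ctr, axis_length = L,
           origin = mid, pre_id = i, post_id = j, ab_ids = hit),
      class = "synapse_pair")
  }
  pairs
}

#' Construct a synapse pair from known centers
#'
#' @param pre_center,post_center 3D positions in nm (must differ).
#' @return a `synapse_pair`.
#' @export
synapse_pair <- function(pre_center, post_center) {
  pre_center <- as.numeric(pre_center); post_center <- as.numeric(post_center)
  L <- sqrt(sum((pre_center - post_center)^2))
  if (L == 0) stop("degenerate pair: coincident pre/post centers")
  structure(
    list(pre_center = pre_center, post_center = post_center,
         axis_vector = pre_center - post_center, axis_length = L,
         origin = (pre_center + post_center) / 2),
    class = "synapse_pair")
}

#' Map puncta into the cylindrical synaptic-axis frame
#'
#' Projects each punctum onto the longitudinal axis defined by the vector
#' from the postsynaptic to the presynaptic center with origin at the
#' midpoint: `z` is the signed axial position in nm (positive toward the
#' presynaptic side, negative postsynaptic) and `r` the radial distance from
#' the axis. Both are invariant under rigid motion applied to the pair and
#' puncta together.
#'
#' @param pair a `synapse_pair`.
#' @param puncta n x 3 matrix of positions in nm.
#' @param expansion_factor divide reported distances by this factor to
#'   express pre-expansion units (default 1 = post-expansion nm).
#' @return data.frame of class `axial_positions` with columns `punctum_id`,
#'   `z_nm`, `r_nm`.
#' @export
map_to_axis <- function(pair, puncta, expansion_factor = 1) {
  stopifnot(inherits(pair, "synapse_pair"))
  if (pair$axis_length <= 0) stop("degenerate pair: zero axis length")
  puncta <- matrix(puncta, ncol = 3)
  u <- pair$axis_vector / pair$axis_length
  rel <- sweep(puncta, 2, pair$origin)
  z <- as.numeric(rel %*% u)
  perp <- rel - outer(z, u)
  r <- sqrt(rowSums(perp^2))
  out <- data.frame(punctum_id = seq_len(nrow(puncta)),
                    z_nm = z / expansion_factor, r_nm = r / expansion_factor)
  class(out) <- c("axial_positions", "data.frame")
  out
}

#' Histogram of axial puncta positions
#'
#' Counts puncta with radial distance `r <= r_max` into half-open axial bins
#' centered on zero (the synapse midpoint): the central bin spans
#' `[-bin_width/2, bin_width/2)`.
#'
#' @param positions an `axial_positions` data.frame from [map_to_axis()],
#'   possibly pooled over synapses.
#' @param bin_width axial bin width in nm (> 0).
#' @param r_max maximum radial distance in nm for inclusion.
#' @return data.frame with columns `z_lo`, `z_hi`, `z_mid`, `count`.
#' @export
axial_histogram <- function(positions, bin_width, r_max) {
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  z <- positions$z_nm[positions$r_nm <= r_max]
  if (!length(z)) {
    return(data.frame(z_lo = numeric(), z_hi = numeric(), z_mid = numeric(),
                      count = integer()))
  }
  k <- floor((z + bin_width / 2) / bin_width)
  kr <- min(k):max(k)
  data.frame(z_lo = kr * bin_width - bin_width / 2,
             z_hi = kr * bin_width + bin_width / 2,
             z_mid = kr * bin_width,
             count = as.integer(tabulate(k - min(k) + 1L, nbins = length(kr))))
}
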