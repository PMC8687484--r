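## Planar geometry shared by the coordinate-based (SMLM) analyses.
## Alpha shapes follow the alpha-radius convention: the alpha complex is the
## union of Delaunay triangles whose circumradius is <= alpha; the shape
## boundary is the set of edges used by exactly one kept triangle.

#' @noRd
delaunay_triangles <- function(points) {
  if (nrow(points) < 3L) return(matrix(integer(0), 0, 3))
  dd <- suppressMessages(deldir::deldir(points[, 1], points[, 2], suppressMsge = TRUE))
  tm <- deldir::triMat(dd)
  if (is.null(tm) || nrow(tm) == 0L) return(matrix(integer(0), 0, 3))
  tm
}

#' @noRd
triangle_circumradius <- function(points, tri) {
  p1 <- points[tri[, 1], , drop = FALSE]
  p2 <- points[tri[, 2], , drop = FALSE]
  p3 <- points[tri[, 3], , drop = FALSE]
  a <- sqrt(rowSums((p2 - p3)^2))
  b <- sqrt(rowSums((p1 - p3)^2))
  c <- sqrt(rowSums((p1 - p2)^2))
  ar <- triangle_area(points, tri)
  r <- a * b * c / (4 * ar)
  r[ar <= 0] <- Inf  # degenerate (collinear) triangles never enter the complex
  r
}

#' @noRd
triangle_area <- function(points, tri) {
  p1 <- points[tri[, 1], , drop = FALSE]
  p2 <- points[tri[, 2], , drop = FALSE]
  p3 <- points[tri[, 3], , drop = FALSE]
  abs((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
}

## Union-find over n items given an edge list (2-column matrix).
#' @noRd
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

## Decompose a point set into connected alpha-complex components.
## Returns a list of components, each: point indices (into `points`),
## triangle matrix (indices into `points`), area, boundary edge matrix.
#' @noRd
alpha_components <- function(points, alpha) {
  tri <- delaunay_triangles(points)
  if (nrow(tri) == 0L) return(list())
  keep <- triangle_circumradius(points, tri) <= alpha
  tri <- tri[keep, , drop = FALSE]
  if (nrow(tri) == 0L) return(list())
  n_tri <- nrow(tri)
  edge_key <- function(i, j) pmin(i, j) * (nrow(points) + 1) + pmax(i, j)
  keys <- cbind(edge_key(tri[, 1], tri[, 2]),
                edge_key(tri[, 2], tri[, 3]),
                edge_key(tri[, 1], tri[, 3]))
  # triangles sharing an edge belong to one component
  ek <- as.vector(keys)
  ti <- rep(seq_len(n_tri), 3L)
  ord <- order(ek)
  ek <- ek[ord]; ti <- ti[ord]
  same <- which(ek[-1] == ek[-length(ek)])
  edges <- cbind(ti[same], ti[same + 1L])
  comp <- union_find_components(n_tri, edges)
  lapply(seq_len(max(comp)), function(ci) {
    tci <- tri[comp == ci, , drop = FALSE]
    kci <- keys[comp == ci, , drop = FALSE]
    tab <- table(as.vector(kci))
    bkeys <- as.numeric(names(tab)[tab == 1L])
    all_e <- rbind(tci[, c(1, 2)], tci[, c(2, 3)], tci[, c(1, 3)])
    bsel <- edge_key(all_e[, 1], all_e[, 2]) %in% bkeys
    list(point_idx = sort(unique(as.vector(tci))),
         triangles = tci,
         area = sum(triangle_area(points, tci)),
         boundary_edges = unique(all_e[bsel, , drop = FALSE]))
  })
}

#' Region bounded by an alpha shape
#'
#' Internal constructor shared by synaptic regions and nanoclusters: stores
#' the member coordinates, the alpha-complex triangles (indices into
#' `coords`), the total area and the boundary edges.
#'
#' @noRd
make_region <- function(coords, triangles, area, boundary_edges, alpha,
                        class = "synaptic_region") {
  structure(
    list(coords = coords, triangles = triangles, area = area,
         boundary_edges = boundary_edges, alpha = alpha,
         member_count = nrow(coords)),
    class = class)
}

#' @export
print.synaptic_region <- function(x, ...) {
  cat(sprintf("<%s> %d members, area %.4g nm^2 (alpha = %g nm)\n",
              class(x)[1], x$member_count, x$area, x$alpha))
  invisible(x)
}

#' Build a region from an explicit polygon
#'
#' Constructs a `synaptic_region` from a known simple polygon (e.g. a
#' rectangular ROI or a geometric reference shape) by fan triangulation.
#' The polygon must be convex (or star-shaped from its first vertex).
#'
#' @param polygon n x 2 matrix of vertices in nm, in order, not closed.
#' @return a `synaptic_region`.
#' @export
region_from_polygon <- function(polygon) {
  polygon <- as.matrix(polygon)
  n <- nrow(polygon)
  if (n < 3L) stop("polygon needs at least 3 vertices")
  tri <- cbind(1L, 2:(n - 1L), 3:n)
  make_region(polygon, tri, sum(triangle_area(polygon, tri)),
              rbind(cbind(1:(n - 1L), 2:n), c(n, 1L)), alpha = Inf)
}

## Point-in-region test: a point belongs to the region iff it lies inside or
## on the edge of any alpha-complex triangle. Handles holes and
## multi-part shapes exactly.
#' @noRd
point_in_region <- function(xy, region) {
  xy <- matrix(xy, ncol = 2)
  inside <- rep(FALSE, nrow(xy))
  tri <- region$triangles
  pts <- region$coords
  scale <- max(abs(pts)) + 1
  tol <- 1e-9 * scale^2
  for (r in seq_len(nrow(tri))) {
    rem <- which(!inside)
    if (!length(rem)) break
    p1 <- pts[tri[r, 1], ]; p2 <- pts[tri[r, 2], ]; p3 <- pts[tri[r, 3], ]
    q <- xy[rem, , drop = FALSE]
    s1 <- (p2[1] - p1[1]) * (q[, 2] - p1[2]) - (p2[2] - p1[2]) * (q[, 1] - p1[1])
    s2 <- (p3[1] - p2[1]) * (q[, 2] - p2[2]) - (p3[2] - p2[2]) * (q[, 1] - p2[1])
    s3 <- (p1[1] - p3[1]) * (q[, 2] - p3[2]) - (p1[2] - p3[2]) * (q[, 1] - p3[1])
    ok <- (s1 >= -tol & s2 >= -tol & s3 >= -tol) |
          (s1 <= tol & s2 <= tol & s3 <= tol)
    inside[rem[ok]] <- TRUE
  }
  inside
}

## Point-in-polygon (ray casting, boundary-inclusive). Used where the region
## is a plain polygon rather than a triangulated alpha shape.
#' @noRd
point_in_polygon <- function(xy, polygon) {
  xy <- matrix(xy, ncol = 2)
  n <- nrow(polygon)
  px <- polygon[, 1]; py <- polygon[, 2]
  nx <- px[c(2:n, 1)]; ny <- py[c(2:n, 1)]
  out <- logical(nrow(xy))
  for (q in seq_len(nrow(xy))) {
    x <- xy[q, 1]; y <- xy[q, 2]
    crosses <- ((py > y) != (ny > y)) &
      (x < (nx - px) * (y - py) / (ny - py) + px)
    out[q] <- (sum(crosses) %% 2L) == 1L
    if (!out[q]) {
      # boundary-inclusive: on-segment check
      d <- point_segment_distance(c(x, y), cbind(px, py), cbind(nx, ny))
      if (min(d) <= 1e-9 * (max(abs(polygon)) + 1)) out[q] <- TRUE
    }
  }
  out
}

## Distance from one point to each segment (a, b).
#' @noRd
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  len2 <- rowSums(ab^2)
  t <- ifelse(len2 > 0, pmin(pmax(rowSums(ap * ab) / len2, 0), 1), 0)
  proj <- a + ab * t
  sqrt((p[1] - proj[, 1])^2 + (p[2] - proj[, 2])^2)
}

## Convert a region's triangles into a polyclip polygon list (CCW rings).
#' @noRd
region_to_rings <- function(region) {
  pts <- region$coords
  lapply(seq_len(nrow(region$triangles)), function(r) {
    tri <- region$triangles[r, ]
    p <- pts[tri, , drop = FALSE]
    signed <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
              (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])
    if (signed < 0) p <- p[c(1, 3, 2), ]
    list(x = p[, 1], y = p[, 2])
  })
}

## Exact intersection area of two triangulated regions via polygon clipping.
#' @noRd
region_overlap_area <- function(a, b) {
  # fixed fine resolution (fm on the nm scale) keeps clipped areas exact to
  # ~1e-12 relative for coordinates up to ~10^5 nm
  sc <- max(abs(a$coords), abs(b$coords), 1)
  inter <- polyclip::polyclip(region_to_rings(a), region_to_rings(b),
                              op = "intersection",
                              fillA = "nonzero", fillB = "nonzero",
                              x0 = 0, eps = sc * 1e-12)
  if (!length(inter)) return(0)
  sum(vapply(inter, function(ring) {
    x <- ring$x; y <- ring$y
    n <- length(x)
    sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
  }, numeric(1)))
}

## Minimum distance from a point to a region's boundary edges.
#' @noRd
distance_to_boundary <- function(p, region) {
  be <- region$boundary_edges
  if (is.null(be) || nrow(be) == 0L) return(NA_real_)
  a <- region$coords[be[, 1], , drop = FALSE]
  b <- region$coords[be[, 2], , drop = FALSE]
  min(point_segment_distance(p, a, b))
}
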