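# Coordinate-based nanocluster analysis: local densities, alpha-shape
# regions, in-region fractions, randomization-thresholded clusters, overlap
# classification.

test_that("local density counts match an all-pairs oracle and the self-count limit", {
  # a single coordinate counts only itself
  one <- local_density(matrix(c(10, 20), 1), radius = 30)
  expect_equal(one$density, 1 / (pi * 30^2))

  # square grid with spacing d and d < R < sqrt(2) d: interior points count
  # 5 (self + 4 orthogonal neighbours; diagonals at sqrt(2) d are outside)
  d <- 20; R <- 1.2 * d
  g <- as.matrix(expand.grid(x = seq(0, 100, d), y = seq(0, 100, d)))
  ld <- local_density(g, radius = R)
  interior <- g[, 1] > 0 & g[, 1] < 100 & g[, 2] > 0 & g[, 2] < 100
  expect_equal(round(ld$density[interior] * pi * R^2), rep(5, sum(interior)))

  # random set: counts equal the brute-force double loop
  set.seed(31)
  pts <- cbind(runif(80, 0, 500), runif(80, 0, 500))
  ld2 <- local_density(pts, radius = 40)
  expect_equal(round(ld2$density * pi * 40^2), oracle_count_within(pts, 40))
})

test_that("mean local density of uniform points approaches n over area", {
  set.seed(32)
  n <- 3000; R <- 100; L <- 2000
  est <- replicate(6, {
    pts <- cbind(runif(n, 0, L), runif(n, 0, L))
    ld <- local_density(pts, radius = R)
    interior <- pts[, 1] > R & pts[, 1] < L - R & pts[, 2] > R & pts[, 2] < L - R
    mean(ld$density[interior])
  })
  # interior mean density = n/A plus the 1/(pi R^2) self-count term
  target <- n / L^2 + 1 / (pi * R^2)
  expect_lt(abs(mean(est) - target) / target, 0.05)
})

test_that("density-range segmentation recovers a dense disk and applies the area filter", {
  set.seed(33)
  # dense 150 nm disk of 500 points over sparse far-away background
  r <- 150 * sqrt(runif(500)); th <- runif(500, 0, 2 * pi)
  disk <- cbind(1000 + r * cos(th), 1000 + r * sin(th))
  bg <- cbind(runif(40, 2500, 4000), runif(40, 2500, 4000))
  ann <- local_density(rbind(disk, bg), radius = 30)
  regs <- segment_synaptic_region(ann)
  expect_equal(length(regs), 1L)
  expect_lt(abs(regs[[1]]$area - pi * 150^2) / (pi * 150^2), 0.15)
  expect_lt(abs(regs[[1]]$area - oracle_raster_area(regs[[1]])) / regs[[1]]$area, 0.15)
  # every member lies inside its own boundary
  expect_true(all(perisynmap:::point_in_region(regs[[1]]$coords, regs[[1]])))

  # a region with area below 1.5e3 nm^2 is discarded
  small <- as.matrix(expand.grid(x = seq(0, 30, 5), y = seq(0, 40, 5)))  # 1200 nm^2 hull
  ann2 <- local_density(small, radius = 30)
  expect_equal(length(segment_synaptic_region(ann2)), 0L)
  expect_gt(length(segment_synaptic_region(ann2, min_area = 1000)), 0L)
})

test_that("zero density range retains every localization (degenerate threshold rule)", {
  # four well-separated points: all have identical (self-only) density
  pts <- rbind(c(0, 0), c(500, 0), c(0, 500), c(500, 500))
  ann <- local_density(pts, radius = 30)
  expect_equal(length(unique(ann$density)), 1L)
  regs <- segment_synaptic_region(ann, alpha = 1e4, min_area = 0)
  expect_equal(sum(vapply(regs, `[[`, 1L, "member_count")), 4L)
})

test_that("in-region fractions are exact for planted membership", {
  rect <- region_from_polygon(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
  set.seed(34)
  inside <- cbind(runif(60, 1, 99), runif(60, 1, 99))
  outside <- cbind(runif(40, 150, 300), runif(40, 150, 300))
  expect_equal(fraction_in_region(rbind(inside, outside), rect), 0.60)
  expect_equal(fraction_in_region(inside, rect), 1.0)
  expect_equal(fraction_in_region(outside, rect), 0.0)
  expect_warning(f <- fraction_in_region(matrix(numeric(0), 0, 2), rect), "undefined")
  expect_true(is.na(f))
})

test_that("planted nanoclusters are detected with high recall and a stable threshold", {
  recalls <- vapply(1:5, function(s) {
    set.seed(700 + s)
    reg <- region_from_polygon(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)))
    n_bg <- 400
    bg <- cbind(runif(n_bg, 0, 1000), runif(n_bg, 0, 1000))
    # cluster at 10x the background point density within its disk
    r <- 30 * sqrt(runif(100)); th <- runif(100, 0, 2 * pi)
    cl <- cbind(500 + r * cos(th), 500 + r * sin(th))
    coords <- rbind(bg, cl)
    ann <- local_density(coords, radius = 30)
    found <- detect_nanoclusters(ann, reg, n_randomizations = 10, seed = 800 + s)
    if (!length(found)) return(0)
    # recall: planted members appearing in any detected cluster
    members <- do.call(rbind, lapply(found, `[[`, "coords"))
    hit <- RANN::nn2(members, cl, k = 1)$nn.dists[, 1] < 1e-9
    mean(hit)
  }, numeric(1))
  expect_gte(mean(recalls), 0.9)
})

test_that("uniform scenes yield few false-positive cluster assignments", {
  fp <- vapply(1:5, function(s) {
    set.seed(900 + s)
    reg <- region_from_polygon(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)))
    coords <- cbind(runif(400, 0, 1000), runif(400, 0, 1000))
    ann <- local_density(coords, radius = 30)
    found <- detect_nanoclusters(ann, reg, n_randomizations = 10, seed = 950 + s)
    if (!length(found)) return(0)
    sum(vapply(found, `[[`, 1L, "member_count")) / 400
  }, numeric(1))
  expect_lte(mean(fp), 0.10)
})

test_that("nanocluster detection is deterministic under a fixed seed", {
  set.seed(41)
  reg <- region_from_polygon(rbind(c(0, 0), c(600, 0), c(600, 600), c(0, 600)))
  r <- 25 * sqrt(runif(80)); th <- runif(80, 0, 2 * pi)
  coords <- rbind(cbind(runif(150, 0, 600), runif(150, 0, 600)),
                  cbind(300 + r * cos(th), 300 + r * sin(th)))
  ann <- local_density(coords, radius = 30)
  a <- detect_nanoclusters(ann, reg, n_randomizations = 5, seed = 77)
  b <- detect_nanoclusters(ann, reg, n_randomizations = 5, seed = 77)
  expect_identical(a, b)
})

test_that("overlap classification matches exact rectangle arithmetic and boundary rules", {
  sq <- function(x0, y0, w, h) region_from_polygon(
    rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h)))

  # wholly inside: fraction 1, overlapping, distance 0
  inside <- classify_overlap(sq(10, 10, 20, 20), sq(0, 0, 100, 100))
  expect_equal(inside$overlap_fraction, 1)
  expect_equal(inside$classification, "overlapping")
  expect_equal(inside$center_to_psd_edge, 0)

  # 100x100 cluster with a 30 nm strip inside the PSD: fraction 0.30
  strip <- classify_overlap(sq(0, 0, 100, 100), sq(70, -50, 300, 200))
  expect_equal(strip$overlap_fraction, 0.30, tolerance = 1e-9)
  expect_equal(strip$classification, "overlapping")

  # overlap of exactly 0.23 classifies as overlapping (>= rule)
  edge <- classify_overlap(sq(0, 0, 100, 100), sq(77, -50, 300, 200))
  expect_equal(edge$overlap_fraction, 0.23, tolerance = 1e-9)
  expect_equal(edge$classification, "overlapping")
  just_below <- classify_overlap(sq(0, 0, 100, 100), sq(77.5, -50, 300, 200))
  expect_equal(just_below$classification, "non_overlapping")

  # disjoint cluster whose center sits 50 nm from the PSD edge
  far <- sq(0, 0, 10, 10); far$weighted_center <- c(5, 5)
  cls <- classify_overlap(far, sq(55, -100, 200, 200))
  expect_equal(cls$overlap_fraction, 0)
  expect_equal(cls$classification, "non_overlapping")
  expect_equal(cls$center_to_psd_edge, 50)

  bad <- sq(0, 0, 10, 10); bad$area <- 0
  expect_error(classify_overlap(bad, sq(0, 0, 50, 50)), "zero area")
})

test_that("alpha shapes reach the convex hull for large alpha", {
  set.seed(35)
  pts <- cbind(runif(60, 0, 300), runif(60, 0, 300))
  ann <- local_density(pts, radius = 1e4)  # all densities equal -> all retained
  regs <- segment_synaptic_region(ann, alpha = 1e6, min_area = 0)
  expect_equal(length(regs), 1L)
  expect_equal(regs[[1]]$area, oracle_chull_area(pts), tolerance = 1e-9)
})

test_that("densities, areas, fractions and classifications are rigid-motion invariant", {
  set.seed(36)
  r <- 25 * sqrt(runif(90)); th <- runif(90, 0, 2 * pi)
  coords <- rbind(cbind(runif(200, 0, 800), runif(200, 0, 800)),
                  cbind(400 + r * cos(th), 400 + r * sin(th)))
  moved <- rigid_transform2(coords, theta = 0.83, shift = c(1234.5, -987.6))

  ld1 <- local_density(coords, 30); ld2 <- local_density(moved, 30)
  expect_equal(ld1$density, ld2$density, tolerance = 1e-9)

  r1 <- segment_synaptic_region(ld1, min_area = 0)
  r2 <- segment_synaptic_region(ld2, min_area = 0)
  a1 <- sort(vapply(r1, `[[`, 1, "area"))
  a2 <- sort(vapply(r2, `[[`, 1, "area"))
  expect_equal(a1, a2, tolerance = 1e-9)

  rect <- rbind(c(300, 300), c(500, 300), c(500, 500), c(300, 500))
  f1 <- fraction_in_region(coords, region_from_polygon(rect))
  f2 <- fraction_in_region(moved, region_from_polygon(rigid_transform2(rect, 0.83, c(1234.5, -987.6))))
  expect_equal(f1, f2)
})
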