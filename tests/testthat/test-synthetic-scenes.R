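# Ground-truth consistency and determinism of the scene generators.

test_that("identical seeds give bit-identical outputs across all generators", {
  a <- gen_sim_scene(shape = c(32, 32, 4), n_markers = 3, n_ab = 12, seed = 5)
  b <- gen_sim_scene(shape = c(32, 32, 4), n_markers = 3, n_ab = 12, seed = 5)
  expect_identical(a, b)

  c1 <- gen_smlm_scene(n_psd = 50, n_background = 20, seed = 8)
  c2 <- gen_smlm_scene(n_psd = 50, n_background = 20, seed = 8)
  expect_identical(c1, c2)

  d1 <- gen_bead_field(n_beads = 30, seed = 2)
  d2 <- gen_bead_field(n_beads = 30, seed = 2)
  expect_identical(d1, d2)

  e1 <- gen_drift_series(n_frames = 100, emitters = 5, seed = 3)
  e2 <- gen_drift_series(n_frames = 100, emitters = 5, seed = 3)
  expect_identical(e1, e2)

  f1 <- gen_traces("association", list(tau = 3, plateau = 2, noise_sd = 0.1), seed = 4)
  f2 <- gen_traces("association", list(tau = 3, plateau = 2, noise_sd = 0.1), seed = 4)
  expect_identical(f1, f2)
})

test_that("fully enriched ligand puncta all lie within the radius of a marker (brute force)", {
  sc <- gen_sim_scene(shape = c(64, 64, 6), n_markers = 5, n_ab = 50,
                      enriched_fraction = 1, enrichment_radius = 642, seed = 11)
  tr <- sc$truth
  for (p in seq_len(nrow(tr$ab_centers))) {
    dmin <- min(sqrt(rowSums(sweep(tr$marker_centers, 2, tr$ab_centers[p, ])^2)))
    expect_lte(dmin, 642)
  }
  expect_true(all(tr$ab_enriched))
})

test_that("an unenriched scene marks no punctum as enriched and a too-small scene is refused", {
  sc <- gen_sim_scene(shape = c(32, 32, 4), n_markers = 3, n_ab = 20,
                      enriched_fraction = 0, seed = 2)
  expect_false(any(sc$truth$ab_enriched))
  expect_error(gen_sim_scene(shape = c(8, 8, 2), n_markers = 4, n_ab = 40, seed = 1),
               "too small")
})

test_that("SMLM truth records the realized in-PSD fraction and plants detectable density", {
  # all points in the PSD disk with negligible jitter -> fraction exactly 1
  sc <- gen_smlm_scene(field = c(1000, 1000), psd_radius = 200, n_psd = 200,
                       n_background = 0, loc_precision = 1e-4, seed = 6)
  expect_equal(sc$truth$in_psd_fraction, 1.0)

  # planted cluster: local density at its center > 5x the background mean
  sc2 <- gen_smlm_scene(field = c(2000, 2000), psd_radius = 150, n_psd = 0,
                        n_background = 300,
                        clusters = list(list(center = c(400, 400), radius = 30, n = 100)),
                        loc_precision = 5, seed = 7)
  xy <- cbind(sc2$table$x, sc2$table$y)
  R <- 30
  cnt <- sum(sqrt((xy[, 1] - 400)^2 + (xy[, 2] - 400)^2) <= R)
  dens_center <- cnt / (pi * R^2)
  dens_bg <- 300 / (2000 * 2000)
  expect_gt(dens_center, 5 * dens_bg)

  expect_error(gen_smlm_scene(clusters = list(list(center = c(5000, 0), radius = 10, n = 5)),
                              n_psd = 10, seed = 1),
               "outside the field")
})

test_that("bead fields honor translation, amplitude bound, and the no-distortion limit", {
  # amplitude 0, noise 0 -> identical channels
  b0 <- gen_bead_field(n_beads = 40, distortion_amplitude = 0, noise_sd = 0, seed = 3)
  expect_equal(b0$ref$x, b0$moving$x)
  expect_equal(b0$ref$y, b0$moving$y)

  # explicit pure translation (+50, -30): every pairwise displacement matches
  nt <- 6  # degree-2 term count
  bt <- gen_bead_field(n_beads = 25, noise_sd = 0,
                       coefficients = list(dx = c(50, rep(0, nt - 1)),
                                           dy = c(-30, rep(0, nt - 1))),
                       seed = 4)
  expect_equal(bt$moving$x - bt$ref$x, rep(50, 25))
  expect_equal(bt$moving$y - bt$ref$y, rep(-30, 25))

  # degree-2 distortion: max realized displacement <= the 100 nm amplitude
  b1 <- gen_bead_field(n_beads = 300, distortion_amplitude = 100,
                       polynomial_degree = 2, noise_sd = 0, seed = 5)
  mags <- sqrt(rowSums(b1$truth$displacement^2))
  expect_lte(max(mags), 100 + 1e-9)
  expect_gt(max(mags), 50)  # the distortion is actually exercised
})

test_that("drift truth traces are exact by construction", {
  # zero drift: truth trace identically zero, per-frame means stationary
  z <- gen_drift_series(n_frames = 200, emitters = 30, magnitude = 0,
                        loc_precision = 5, seed = 6)
  expect_true(all(z$truth$drift_trace == 0))
  # track one emitter: its localizations stay put within localization noise
  e1 <- z$truth$emitters[1, ]
  sel <- abs(z$table$x - e1[1]) < 25 & abs(z$table$y - e1[2]) < 25
  m1 <- mean(z$table$x[sel & z$table$frame <= 100])
  m2 <- mean(z$table$x[sel & z$table$frame > 100])
  expect_lt(abs(m1 - m2), 5 * 5 / sqrt(sum(sel) / 2))

  # linear drift: last-frame minus first-frame truth offset is the magnitude
  l <- gen_drift_series(n_frames = 500, emitters = 10, drift_model = "linear",
                        magnitude = 100, seed = 7)
  expect_equal(l$truth$drift_trace[500, ] - l$truth$drift_trace[1, ], c(100, 0))

  # step drift: piecewise constant with exactly one jump
  s <- gen_drift_series(n_frames = 400, emitters = 10, drift_model = "step",
                        magnitude = 80, seed = 8)
  jumps <- diff(s$truth$drift_trace[, 1])
  expect_equal(sum(jumps != 0), 1L)
  expect_equal(max(s$truth$drift_trace[, 1]), 80)
})

test_that("ExM puncta land at their stated cylindrical coordinates", {
  pre <- c(3500, 3200, 800); post <- c(2900, 3200, 800)
  L <- sqrt(sum((pre - post)^2))
  sc <- gen_exm_scene(pre, post, n_ab = 3,
                      axial_offsets = c(0, L / 2, -120),
                      radial_offsets = c(0, 0, 90), seed = 5)
  tr <- sc$truth
  expect_equal(tr$ab_centers[1, ], (pre + post) / 2)   # origin
  expect_equal(tr$ab_centers[2, ], pre)                # +L/2 -> presynaptic center
  # arbitrary (z, r): brute-force vector projection
  u <- (pre - post) / L
  rel <- tr$ab_centers[3, ] - (pre + post) / 2
  z <- sum(rel * u)
  r <- sqrt(sum((rel - z * u)^2))
  expect_equal(z, -120, tolerance = 1e-9)
  expect_equal(r, 90, tolerance = 1e-9)

  expect_error(gen_exm_scene(c(100, 100, 100), c(100, 100, 100), seed = 1),
               "must differ")
  expect_error(gen_exm_scene(pre, post, n_ab = 1, axial_offsets = 1e6,
                             radial_offsets = 0, seed = 1),
               "outside the image bounds")
})

test_that("kinetics traces follow their closed forms", {
  # association, noiseless: value at t = tau is plateau (1 - 1/e); end ~ plateau
  tr <- gen_traces("association", list(tau = 3.5, plateau = 2.0, noise_sd = 0),
                   n_points = 200, dt = 10)
  at_tau <- tr$value[tr$time_s == 3.5 * 60]
  expect_equal(at_tau, 2.0 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(tr$value[200], 2.0, tolerance = 1e-3)

  # FRAP with zero mobile fraction: flat postbleach trace at the bleach depth
  fr <- gen_traces("frap", list(mobile_fraction = 0, rate = 0.2, noise_sd = 0,
                                bleach_depth = 0.4), n_points = 10, dt = 60)
  bf <- attr(fr, "bleach_frame")
  expect_true(all(fr$value[bf:nrow(fr)] == 0.4))
  expect_true(all(fr$value[1:(bf - 1)] == 1))

  # washout decays toward the stable fraction
  w <- gen_traces("washout", list(tau = 5, plateau = 0.8, noise_sd = 0),
                  n_points = 300, dt = 30)
  expect_equal(w$value[1], 1)
  expect_equal(w$value[300], 0.8, tolerance = 1e-3)
  expect_true(all(diff(w$value) < 0))
})
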