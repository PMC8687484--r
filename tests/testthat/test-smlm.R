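# Localization-table IO, quality filtering, bead registration, drift
# correction.

test_that("localization CSV round-trips bit-exactly, including empty tables", {
  tab <- data.frame(frame = c(1L, 2L, 7L),
                    x = c(1 / 3, 1234.56789012345, 2e4),
                    y = c(sqrt(2), -0.125, 999.999999999999),
                    sigma = c(150, 160.5, 170),
                    uncertainty = c(8.25, 19.9999999, 5),
                    photons = c(1000, 2500, 333),
                    channel = c("ab", "ab", "psd"),
                    stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".csv")
  write_localizations(tab, p)
  back <- read_localizations(p)
  expect_identical(back$x, tab$x)
  expect_identical(back$y, tab$y)
  expect_identical(back$uncertainty, tab$uncertainty)
  expect_identical(back$channel, tab$channel)

  empty <- tab[0, ]
  write_localizations(empty, p)
  expect_equal(nrow(read_localizations(p)), 0L)
})

test_that("ThunderSTORM-style and plain headers parse to the same table", {
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  writeLines(c('frame,"x [nm]","y [nm]","sigma [nm]","uncertainty [nm]","intensity [photon]"',
               "1,100.5,200.25,150,10,1200",
               "2,300,400,160,12,800"), p1)
  writeLines(c("frame,x,y,sigma,uncertainty,photons",
               "1,100.5,200.25,150,10,1200",
               "2,300,400,160,12,800"), p2)
  t1 <- read_localizations(p1)
  t2 <- read_localizations(p2)
  expect_identical(t1[c("frame", "x", "y", "sigma", "uncertainty", "photons")],
                   t2[c("frame", "x", "y", "sigma", "uncertainty", "photons")])

  p3 <- tempfile(fileext = ".csv")
  writeLines(c("frame,sigma", "1,150"), p3)
  expect_error(read_localizations(p3), "missing mandatory columns: x, y")
})

test_that("quality filtering applies the uncertainty and per-channel sigma rules", {
  tab <- data.frame(
    frame = 1:5,
    x = 1:5, y = 1:5,
    sigma = c(150, 150, 250, 95, 180),
    uncertainty = c(10, 25, 10, 10, 19.99),
    photons = 1000,
    channel = c("cf568", "cf568", "cf568", "af647", "af647"),
    stringsAsFactors = FALSE)
  rng <- list(cf568 = c(100, 200), af647 = c(90, 190))
  out <- filter_localizations(tab, uncertainty_max = 20, sigma_range = rng)
  # row 1: kept; row 2: uncertainty 25 removed; row 3: sigma 250 removed;
  # rows 4, 5: inside the closed af647 range
  expect_equal(out$frame, c(1L, 4L, 5L))
  # idempotence and monotonicity
  expect_identical(filter_localizations(out, 20, rng), out)
  expect_lte(nrow(out), nrow(tab))
  # boundary values are kept (closed sigma range)
  tabb <- data.frame(frame = 1, x = 0, y = 0, sigma = 100, uncertainty = 1,
                     photons = 1, channel = "cf568", stringsAsFactors = FALSE)
  expect_equal(nrow(filter_localizations(tabb, sigma_range = list(cf568 = c(100, 200)))), 1L)

  expect_error(filter_localizations(tab, sigma_range = list(nosuch = c(1, 2))),
               "not present")
  expect_equal(nrow(filter_localizations(tab[0, ], 20, NULL)), 0L)
})

test_that("channel calibration recovers exact models and composes to identity", {
  set.seed(10)
  ref <- cbind(runif(50, 0, 20000), runif(50, 0, 20000))
  # identical point sets -> zero model
  cal0 <- fit_channel_calibration(ref, ref)
  expect_equal(cal0$control_rms, 0, tolerance = 1e-9)
  expect_equal(max(abs(predict_displacement(cal0, ref))), 0, tolerance = 1e-9)

  # pure translation, no noise: displacement recovered everywhere
  mov <- sweep(ref, 2, c(50, -30), "+")
  calt <- fit_channel_calibration(ref, mov)
  pred <- predict_displacement(calt, cbind(runif(10, 0, 20000), runif(10, 0, 20000)))
  expect_equal(pred[, 1], rep(50, 10), tolerance = 1e-9)
  expect_equal(pred[, 2], rep(-30, 10), tolerance = 1e-9)
  expect_lt(calt$control_rms, 1e-9)

  # quadratic distortion (a function of the observed moving position, the
  # model's predictor), no noise, degree 2: exact recovery at new points
  qd <- function(xy) cbind(20 + 1e-3 * xy[, 1] + 3e-8 * xy[, 1] * xy[, 2],
                           -10 + 2e-3 * xy[, 2] - 2e-8 * xy[, 1]^2)
  mov2 <- cbind(runif(50, 0, 20000), runif(50, 0, 20000))
  ref2 <- mov2 - qd(mov2)
  cal2 <- fit_channel_calibration(ref2, mov2)
  mtest <- cbind(runif(20, 0, 20000), runif(20, 0, 20000))
  expect_equal(predict_displacement(cal2, mtest), qd(mtest), tolerance = 1e-7)
  corr <- apply_calibration(data.frame(x = mtest[, 1], y = mtest[, 2]), cal2)
  expect_equal(cbind(corr$x, corr$y), mtest - qd(mtest), tolerance = 1e-7)

  # under-determined polynomial fit is refused with the minimum count
  expect_error(fit_channel_calibration(ref[1:4, ], mov[1:4, ], degree = 2),
               "at least 6")

  # forward and reverse fits compose to identity within 2x control RMS
  bf <- gen_bead_field(n_beads = 120, distortion_amplitude = 80, noise_sd = 3, seed = 9)
  A <- cbind(bf$ref$x, bf$ref$y); B <- cbind(bf$moving$x, bf$moving$y)
  fwd <- fit_channel_calibration(A, B)
  rev <- fit_channel_calibration(B, A)
  corrB <- B - predict_displacement(fwd, B)
  round_trip <- corrB - predict_displacement(rev, corrB)
  err <- sqrt(rowSums((round_trip - B)^2))
  expect_lt(sqrt(mean(err^2)), 2 * (fwd$control_rms + rev$control_rms))
})

test_that("locally weighted calibration reproduces smooth displacement fields", {
  set.seed(12)
  ref <- cbind(runif(150, 0, 10000), runif(150, 0, 10000))
  disp <- cbind(40 * sin(ref[, 1] / 4000), 30 * cos(ref[, 2] / 4000))
  mov <- ref + disp
  cal <- fit_channel_calibration(ref, mov, model_kind = "locally_weighted",
                                 bandwidth = 1500)
  expect_lt(cal$control_rms, 10)
  expect_error(fit_channel_calibration(ref, mov, model_kind = "locally_weighted"),
               "bandwidth")
})

test_that("drift correction recovers planted drift within one correlation bin", {
  # stationary stream: estimated drift within one bin of zero
  z <- gen_drift_series(n_frames = 2000, emitters = 60, magnitude = 0,
                        loc_precision = 10, p_on = 0.6, seed = 21)
  dz <- drift_correct(z$table)
  expect_lt(max(abs(dz$drift$displacement)), 10)
  expect_equal(dz$drift$displacement[1, ], c(0, 0))

  # linear drift 100 nm over the movie, dense emitters
  l <- gen_drift_series(n_frames = 2000, emitters = 60, drift_model = "linear",
                        magnitude = 100, loc_precision = 10, p_on = 0.6, seed = 22)
  dl <- drift_correct(l$table)
  truth_seg <- approx(seq_len(2000), l$truth$drift_trace[, 1],
                      xout = dl$drift$segment_frames)$y
  truth_seg <- truth_seg - truth_seg[1]
  expect_true(all(abs(dl$drift$displacement[, 1] - truth_seg) <= 10))

  # post-correction spread of a fixed emitter ~ localization precision
  e1 <- l$truth$emitters[1, ]
  raw_sel <- abs(l$table$x - e1[1]) < 120 & abs(l$table$y - e1[2]) < 60
  raw_sd <- sd(l$table$x[raw_sel])
  cor_sel <- abs(dl$table$x - e1[1]) < 60 & abs(dl$table$y - e1[2]) < 60
  cor_sd <- sd(dl$table$x[cor_sel])
  expect_gt(raw_sd, 15)           # drift inflates the raw spread
  expect_lt(cor_sd, 13)           # corrected spread ~ 10 nm precision

  expect_error(drift_correct(z$table[z$table$frame <= 600, ]), "fewer than 2")
})

test_that("drift estimates are equivariant under a constant coordinate offset", {
  l <- gen_drift_series(n_frames = 1200, emitters = 50, drift_model = "linear",
                        magnitude = 60, loc_precision = 8, p_on = 0.6, seed = 23)
  d1 <- drift_correct(l$table, segment_len = 400)
  shifted <- l$table
  shifted$x <- shifted$x + 5000
  d2 <- drift_correct(shifted, segment_len = 400)
  expect_true(all(abs(d1$drift$displacement - d2$drift$displacement) <= 10))
})
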