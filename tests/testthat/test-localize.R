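test_that("Thompson precision has the right limits and scaling", {
  # zero background, vanishing pixels: sigma -> s / sqrt(N)
  expect_equal(thompson_precision(400, 100, 1e-4, 0), 100 / sqrt(400),
               tolerance = 1e-6)
  # doubling N with b = 0 halves the variance exactly
  s1 <- thompson_precision(200, 102, 160, 0)
  s2 <- thompson_precision(400, 102, 160, 0)
  expect_equal(s2^2, s1^2 / 2, tolerance = 1e-12)
  # calibrated fixture value
  expect_equal(thompson_precision(350, 102, 160, calibrate_background()),
               32, tolerance = 1e-6)
  expect_error(thompson_precision(0, 102, 160, 1), "positive")
})

test_that("spot detection finds isolated emitters and nothing in noise-free darkness", {
  cam <- camera_model(background_rate = 10, sensor_px = c(64, 64))
  expect_equal(nrow(detect_spots(matrix(0, 64, 64), cam, threshold = 10)), 0)
  set.seed(21)
  # high SNR: one emitter -> exactly one candidate within 1 px
  mu <- expected_frame(5000, 5000, 2000, cam)
  hits <- replicate(50, {
    fr <- matrix(rpois(length(mu), mu), 64, 64)
    d <- detect_spots(fr, cam, threshold = 200)
    nrow(d) == 1 &&
      abs(d$j_px * 160 + 80 - 5000) <= 160 && abs(d$i_px * 160 + 80 - 5000) <= 160
  })
  expect_true(all(hits))
  # two emitters >= 4 psf sigma apart -> two candidates
  mu2 <- expected_frame(c(4700, 5600), c(5000, 5000), c(2000, 2000), cam)
  two <- replicate(50, {
    fr <- matrix(rpois(length(mu2), mu2), 64, 64)
    nrow(detect_spots(fr, cam, threshold = 200))
  })
  expect_true(all(two == 2))
})

test_that("noiseless fits recover the exact model", {
  cam <- camera_model(background_rate = 2, sensor_px = c(13, 13))
  mu <- expected_frame(6.3 * 160, 6.7 * 160, 1000, cam)
  f <- fit_spot(mu, cam)
  expect_lt(abs(f$x_nm - 6.3 * 160), 0.5)
  expect_lt(abs(f$y_nm - 6.7 * 160), 0.5)
  expect_lt(abs(f$photons - 1000) / 1000, 0.01)
  expect_true(f$converged)
})

test_that("empirical precision is consistent with the Thompson estimate", {
  for (N in c(100, 350, 1000)) {
    f <- repeated_fits(N, 500, seed = 42)
    keep <- f$converged & sqrt(f$err_x^2 + f$err_y^2) < 240
    th <- thompson_precision(N, 102, 160, calibrate_background())
    scatter <- mad(f$err_x[keep])
    expect_gt(scatter / th, 0.75)
    expect_lt(scatter / th, 1.3)
    # unbiasedness: mean deviation below sigma_loc / 5
    expect_lt(abs(mean(f$err_x[keep])), th / 5)
  }
})

test_that("mean reported precision at the fixture equals the printed 32 nm", {
  f <- repeated_fits(350, 400, seed = 43)
  keep <- f$converged & sqrt(f$err_x^2 + f$err_y^2) < 240
  expect_lt(abs(mean(f$precision_nm[keep]) - 32), 4)
  expect_lt(abs(mean(f$photons[keep]) - 350) / 350, 0.1)
})

test_that("fitted photons are linear in true photons without background", {
  cam <- camera_model(background_rate = 0.01, sensor_px = c(13, 13))
  set.seed(44)
  Ns <- c(200, 500, 1000, 2000)
  est <- sapply(Ns, function(N) {
    mean(repeated_fits(N, 60, camera = cam, seed = N)$photons)
  })
  slope <- coef(lm(est ~ Ns))[2]
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})

test_that("localization filtering matches a brute-force row scan", {
  tab <- dense_loc_table(n = 10)
  tab$photons <- c(50, 150, 80, 200, 120, 90, 300, 60, 110, 130)
  out <- filter_localizations(tab, min_photons = 100)
  expect_equal(out$photons, tab$photons[tab$photons >= 100])
  expect_equal(attr(out, "n_removed"), sum(tab$photons < 100))
  # empty criteria are the identity
  same <- filter_localizations(tab)
  expect_equal(nrow(same), nrow(tab))
  # threshold above the maximum empties the table
  none <- filter_localizations(tab, min_photons = 1e6)
  expect_equal(nrow(none), 0)
})
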