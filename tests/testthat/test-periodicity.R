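one_loc_table <- function(x, y, prec) {
  tab <- data.frame(frame = seq_along(x), x_nm = x, y_nm = y, photons = 350,
                    background = 33.7, sigma_nm = 102, precision_nm = prec,
                    quality = 1, converged = TRUE)
  class(tab) <- c("localization_table", "data.frame")
  tab
}

test_that("Thompson rendering conserves unit mass and is linear", {
  t1 <- one_loc_table(500, 500, 20)
  img1 <- render_thompson(t1, render_pixel = 5)
  expect_equal(sum(img1$intensity), 1, tolerance = 1e-6)
  t2 <- one_loc_table(c(500, 500), c(500, 500), c(20, 20))
  img2 <- render_thompson(t2, render_pixel = 5)
  expect_equal(sum(img2$intensity), 2, tolerance = 1e-6)
  expect_equal(max(img2$intensity), 2 * max(img1$intensity), tolerance = 1e-9)
})

test_that("the rendered width equals the localization precision", {
  img <- render_thompson(one_loc_table(600, 600, 25), render_pixel = 2)
  # second-moment width of the rendered spot
  ny <- nrow(img$intensity); nx <- ncol(img$intensity)
  xs <- img$origin_nm[1] + (seq_len(nx) - 0.5) * img$render_pixel
  w <- colSums(img$intensity)
  mu <- sum(w * xs) / sum(w)
  sig <- sqrt(sum(w * (xs - mu)^2) / sum(w) - img$render_pixel^2 / 12)
  expect_lt(abs(sig - 25) / 25, 0.02)
})

test_that("profiles reproduce constant and periodic test images", {
  flat <- structure(list(intensity = matrix(3, 100, 100), render_pixel = 5,
                         origin_nm = c(0, 0)), class = "rendered_image")
  path <- data.frame(x_nm = c(60, 400), y_nm = c(250, 250))
  pr <- extract_profile(flat, path, width = 40, step = 5)
  expect_true(all(abs(pr$intensity - 3) < 1e-9))
  # 1D cosine grating of period 60 nm sampled along a straight path
  xs <- (seq_len(200) - 0.5) * 5
  grating <- structure(list(
    intensity = matrix(rep(1 + cos(2 * pi * xs / 60), each = 100), 100, 200),
    render_pixel = 5, origin_nm = c(0, 0)), class = "rendered_image")
  path2 <- data.frame(x_nm = c(50, 950), y_nm = c(250, 250))
  pr2 <- extract_profile(grating, path2, width = 20, step = 2)
  est <- first_peak_spacing(autocorrelate(pr2))
  expect_equal(est$spacing_nm, 60, tolerance = 2)
  expect_error(extract_profile(flat, data.frame(x_nm = c(-50, 900),
                                                y_nm = c(250, 250)), width = 0),
               "outside")
})

test_that("rolling-ball background correction meets its oracles", {
  mk <- function(v, step = 2) {
    p <- data.frame(arc_nm = (seq_along(v) - 1) * step, intensity = v)
    attr(p, "step") <- step
    class(p) <- c("intensity_profile", "data.frame")
    p
  }
  # flat profile -> all zeros
  out <- rolling_ball_1d(mk(rep(5, 300)), 40)
  expect_true(all(abs(out$intensity) < 1e-9))
  # narrow peak on a flat baseline is preserved within 5%
  v <- rep(2, 400); v[200] <- 12
  out2 <- rolling_ball_1d(mk(v), 40)
  expect_lt(abs(out2$intensity[200] - 10) / 10, 0.05)
  # fast oscillation on a slow ramp: ramp removed, oscillation retained
  x <- (0:999) * 2
  v3 <- 0.01 * x + sin(2 * pi * x / 30)
  out3 <- rolling_ball_1d(mk(v3), 120)
  trend <- coef(lm(out3$intensity ~ x))[2]
  expect_lt(abs(trend) / 0.01, 0.05)
  amp <- diff(range(out3$intensity[300:700]))
  expect_gt(amp, 1.5)
  expect_error(rolling_ball_1d(mk(rep(1, 50)), 1), "exceed")
})

test_that("autocorrelation is normalized and finds harmonic structure", {
  x <- (0:599) * 2
  ac <- autocorrelate(1 + cos(2 * pi * x / 30), step = 2)
  expect_equal(ac$acf[1], 1, tolerance = 1e-12)
  # maxima at multiples of the period
  pk <- first_peak_spacing(ac)
  expect_equal(pk$spacing_nm, 30, tolerance = 1)
  near60 <- ac$acf[abs(ac$lag_nm - 60) <= 2]
  expect_gt(max(near60), 0.9)
  # white noise stays within the statistical bound
  set.seed(5)
  acn <- autocorrelate(rnorm(2000), step = 1)
  expect_lt(max(abs(acn$acf[-1])), 3 / sqrt(2000) * 1.6)
  expect_true(is.na(first_peak_spacing(acn, significance = 3 / sqrt(2000))$spacing_nm) ||
              !first_peak_spacing(acn, significance = 3 / sqrt(2000))$found)
  expect_error(autocorrelate(c(1, 2, 3), step = 1), "at least 4")
})

test_that("hexagonal pattern rendering obeys the Gaussian identity", {
  p <- hex_pattern_params(pitch_nm = 200, grid_n = 6,
                          localization_accuracy_nm = 12, jitter_sd_nm = 0)
  img <- simulate_hex_pattern(p, render_pixel = 2)
  expect_equal(sum(img$intensity), 36, tolerance = 1e-3)
  # effective width: sigma_tot^2 = sigma_fwhm^2 + sigma_loc^2
  s_expect <- sqrt((30 / 2.3548)^2 + 12^2)
  # isolate the central node by local moments
  nodes <- rumpalm:::.hex_nodes(p, seed = 1)
  ctr <- nodes[which.min(rowSums(nodes^2)), ]
  px <- img$render_pixel
  jx <- round((ctr[1] - img$origin_nm[1]) / px)
  iy <- round((ctr[2] - img$origin_nm[2]) / px)
  win <- (-35:35)
  # restrict to the central node's neighbourhood in both axes
  sub <- img$intensity[iy + win, jx + win, drop = FALSE]
  w <- colSums(sub)
  xs <- win * px
  mu <- sum(w * xs) / sum(w)
  sig <- sqrt(sum(w * (xs - mu)^2) / sum(w))
  # neighbours bias the tails; require agreement at the 15% level
  expect_lt(abs(sig - s_expect) / s_expect, 0.05)
})

test_that("delta-limit pattern concentrates mass on the lattice nodes", {
  p <- hex_pattern_params(grid_n = 6, fwhm_nm = 0.5,
                          localization_accuracy_nm = 0, jitter_sd_nm = 0)
  img <- simulate_hex_pattern(p, render_pixel = 1)
  nodes <- rumpalm:::.hex_nodes(p, seed = 1)
  # nearest-neighbour same-row spacing equals the pitch
  d <- as.matrix(dist(nodes)); diag(d) <- Inf
  expect_equal(min(d), 30, tolerance = 1e-9)
  expect_gt(max(img$intensity) / mean(img$intensity[img$intensity > 0]), 5)
})

test_that("axis-aligned rotation analysis returns the exact pitch", {
  p <- hex_pattern_params(localization_accuracy_nm = 0, jitter_sd_nm = 0,
                          rotation_range_deg = c(0, 5), rotation_step_deg = 5)
  est <- rotated_projection_analysis(p, seed = 1, n_bands = 1)
  expect_equal(est$spacing_nm, 30, tolerance = 0.5)
})

test_that("rotation-average recovery is unbiased across pitches", {
  for (pitch in c(24, 30, 39)) {
    p <- hex_pattern_params(pitch_nm = pitch,
                            localization_accuracy_nm = pitch / 6,
                            jitter_sd_nm = pitch / 10)
    est <- rotated_projection_analysis(p, seed = 2)
    expect_lt(abs(est$spacing_nm - pitch) / pitch, 0.1)
  }
})

test_that("doubling the pitch doubles the recovered spacing", {
  e30 <- rotated_projection_analysis(hex_pattern_params(), seed = 3)
  e60 <- rotated_projection_analysis(hex_pattern_params(pitch_nm = 60), seed = 3)
  expect_equal(e60$spacing_nm / e30$spacing_nm, 2, tolerance = 0.15)
})
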