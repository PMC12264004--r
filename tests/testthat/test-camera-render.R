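test_that("background calibration reproduces the target Thompson precision", {
  b <- calibrate_background(350, 102, 160, 32)
  expect_equal(thompson_precision(350, 102, 160, b), 32, tolerance = 1e-9)
  cam <- camera_model()
  expect_equal(cam$background_rate, b^2, tolerance = 1e-9)
})

test_that("expected photon image conserves photons", {
  cam <- camera_model(background_rate = 3, sensor_px = c(40, 40))
  mu <- expected_frame(c(3000, 3500), c(3200, 3300), c(350, 500), cam)
  expect_equal(sum(mu), 350 + 500 + 3 * 40 * 40, tolerance = 1e-6 * 850)
  # null case: no emitters, no background, no noise
  cam0 <- camera_model(background_rate = 0, sensor_px = c(16, 16))
  expect_true(all(expected_frame(numeric(0), numeric(0), numeric(0), cam0) == 0))
})

test_that("rendered counts average the expected image", {
  cam <- camera_model(background_rate = 0, sensor_px = c(16, 16))
  g <- rumposome_geometry()
  em <- build_rumposome_lattice(g, 1)
  em$x_nm <- 8 * 160; em$y_nm <- 8 * 160
  tr <- list(on = data.frame(frame = 1:300, molecule_id = 1L, photons = 350L),
             n_frames = 300L,
             params = photophysics_params(n_frames = 300))
  class(tr) <- "state_trajectory"
  stack <- render_frames(em, tr, cam, seed = 2)
  tot <- apply(stack$frames, 3, sum)
  expect_lt(abs(mean(tot) - 350), 3 * sqrt(350 / 300))
})

test_that("rendering is reproducible under a seed and clips outside emitters", {
  sim <- tiny_sim(seed = 2, n_frames = 50)
  s1 <- render_frames(sim$emitters, sim$trajectory, sim$camera, seed = 5)
  s2 <- render_frames(sim$emitters, sim$trajectory, sim$camera, seed = 5)
  expect_identical(s1$frames, s2$frames)
  # an emitter far outside the sensor contributes nothing and raises nothing
  em <- sim$emitters
  em$x_nm <- em$x_nm + 1e6
  s3 <- render_frames(em, sim$trajectory, sim$camera, seed = 5)
  mu_bg <- sim$camera$background_rate
  expect_lt(abs(mean(s3$frames) - mu_bg) / mu_bg, 0.01)
})

test_that("drift model produces the prescribed trajectories", {
  # zero model is the identity
  tab <- dense_loc_table(n = 500, n_frames = 100)
  out <- apply_drift(tab, drift_model())
  expect_equal(out$table$x_nm, tab$x_nm)
  # linear drift: 0.05 nm/frame over 10,000 frames ends at 500 nm
  d <- simulate_drift(drift_model(c(0.05, 0)), 10000)
  expect_equal(d$dx_nm[10000], 500, tolerance = 1e-9)
  expect_equal(d$dy_nm[10000], 0)
  # random walk: mean-squared displacement grows linearly with lag
  set.seed(3)
  msd_lag <- function(v, lag) mean(diff(v, lag = lag)^2)
  sds <- replicate(40, {
    dd <- simulate_drift(drift_model(rw_sd_nm = 2), 2000)
    c(msd_lag(dd$dx_nm, 10), msd_lag(dd$dx_nm, 40))
  })
  expect_equal(mean(sds[1, ]), 4 * 10, tolerance = 0.15 * 40)
  expect_equal(mean(sds[2, ]), 4 * 40, tolerance = 0.15 * 160)
})

test_that("EM gain and read noise enter the camera model", {
  cam <- camera_model(em_gain = 30, read_noise = 2, background_rate = 5,
                     sensor_px = c(12, 12))
  g <- rumposome_geometry()
  em <- build_rumposome_lattice(g, 1)
  em$x_nm <- 6 * 160; em$y_nm <- 6 * 160
  tr <- list(on = data.frame(frame = 1L, molecule_id = 1L, photons = 300L),
             n_frames = 1L, params = photophysics_params(n_frames = 1))
  class(tr) <- "state_trajectory"
  set.seed(1)
  stack <- render_frames(em, tr, cam)
  # counts are amplified roughly by the gain
  expect_gt(sum(stack$frames), 0.5 * 30 * (300 + 5 * 144))
})
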