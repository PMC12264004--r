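test_that("standard curves calibrate and invert peak areas", {
  conc <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5)
  areas <- 1000 * conc + 50
  sc <- standard_curve(conc, areas)
  expect_equal(sc$slope, 1000, tolerance = 1e-9)
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)
  # area equal to the 1 mM standard reads back 1 mM
  expect_equal(as.numeric(quantify_nucleotide(areas[5], sc)), 1,
               tolerance = 1e-9)
  # area-ratio mode
  expect_equal(as.numeric(quantify_nucleotide(25, mode = "area_ratio",
                                              total_area = 100, total_mM = 2)),
               0.5)
  # below-blank areas clamp to zero with a flag
  out <- quantify_nucleotide(0, sc)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "flagged"))
})

test_that("a synthetic linear detector round-trips concentrations", {
  set.seed(14)
  conc <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5)
  sc <- standard_curve(conc, 1000 * conc + rnorm(7, 0, 10))
  truth <- runif(20, 0.1, 4)
  meas <- 1000 * truth + rnorm(20, 0, 10)
  rec <- as.numeric(quantify_nucleotide(meas, sc))
  expect_lt(max(abs(rec - truth)), 2 * 10 / 1000 * 3)
})

test_that("linear turnover slopes come from least squares on timepoint means", {
  f <- linear_turnover(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$slope_mM_per_min, 1, tolerance = 1e-12)
  expect_equal(linear_turnover(c(0, 5, 10), c(2, 2, 2))$slope_mM_per_min, 0,
               tolerance = 1e-12)
  expect_error(linear_turnover(5, 1), "timepoints")
  set.seed(15)
  t <- rep(c(0, 2, 4), each = 3)
  y <- 0.3 * t + rnorm(9, 0, 0.02)
  f2 <- linear_turnover(t, y)
  expect_lt(abs(f2$slope_mM_per_min - 0.3), 3 * max(f2$se, 0.01))
})

test_that("noiseless saturation data are fitted exactly", {
  d <- generate_kinetics(list(Vmax = 1, K_M = 0.5, h = 1), noise_cv = 0)
  f <- fit_hill(d)
  expect_lt(abs(f$Vmax - 1), 1e-4)
  expect_lt(abs(f$K_M - 0.5), 1e-4)
  expect_lt(abs(f$h - 1), 1e-4)
  # half-saturation identity on the fitted model
  expect_equal(predict(f, f$K_M), f$Vmax / 2, tolerance = 1e-9)
})

test_that("fixing h = 1 reproduces a direct Michaelis-Menten fit", {
  d <- generate_kinetics(list(Vmax = 0.8, K_M = 1.2, h = 1), seed = 3)
  f <- fit_hill(d, fix_h = 1)
  mm <- minpack.lm::nlsLM(v ~ Vmax * S_mM / (K + S_mM), data = d,
                          start = list(Vmax = 0.8, K = 1.2))
  expect_lt(max(abs(f$residuals - resid(mm))), 1e-8)
  expect_true(f$h_fixed)
})

test_that("half-saturation constants are recovered from noisy data", {
  d <- generate_kinetics(list(Vmax = 1, K_M = 0.55, h = 1), seed = 2)
  f <- fit_hill(d, fix_h = 1, weighting = "relative")
  expect_lt(abs(f$K_M - 0.55) / 0.55, 0.1)
})

test_that("fluorescence normalization rescales and preserves fold changes", {
  act <- c(10, 20, 30)
  expect_equal(normalize_by_fluorescence(act, c(2, 2, 2)), act)
  expect_equal(normalize_by_fluorescence(c(10, 10), c(1, 2))[2], 5)
  n1 <- normalize_by_fluorescence(act, c(1, 2, 4))
  n2 <- normalize_by_fluorescence(act, c(10, 20, 40))
  expect_equal(n1[2] / n1[1], n2[2] / n2[1], tolerance = 1e-12)
  expect_error(normalize_by_fluorescence(act, c(1, 0, 2)), "positive")
})

test_that("the kinetics generator matches its model in expectation", {
  d0 <- generate_kinetics(list(Vmax = 2, K_M = 1, h = 1.5), noise_cv = 0)
  v_model <- 2 * d0$S_mM^1.5 / (1 + d0$S_mM^1.5)
  expect_equal(d0$v, v_model, tolerance = 1e-12)
  # default grid is the standard concentration row
  expect_equal(sort(unique(d0$S_mM)), c(0.05, 0.1, 0.2, 0.5, 1, 2, 5))
  d <- generate_kinetics(list(Vmax = 1, K_M = 0.5, h = 1), S_mM = 1,
                         noise_cv = 0.05, n_reps = 1000, seed = 6)
  expect_lt(abs(mean(d$v) - 1 / 1.5), 3 * 0.05 * (1 / 1.5) / sqrt(1000))
})
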