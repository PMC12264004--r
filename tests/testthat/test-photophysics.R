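test_that("absorbing limit gives single-frame bursts and no re-appearance", {
  g <- rumposome_geometry()
  em <- build_rumposome_lattice(g, 50)
  p <- photophysics_params(p_off = 0, p_bleach = 1, n_frames = 300)
  tr <- simulate_states(em, p, reactivation_controller(target_rate = 2), seed = 4)
  sp <- on_spells(tr)
  expect_true(all(sp$n_frames == 1))
  expect_false(any(duplicated(sp$molecule_id)))
})

test_that("BLEACHED is absorbing: no ON frames after the bleach event", {
  sim <- tiny_sim(seed = 5)
  tr <- sim$trajectory
  on <- tr$on
  for (m in which(!is.na(tr$bleach_frame))) {
    expect_true(all(on$frame[on$molecule_id == m] <= tr$bleach_frame[m]))
  }
})

test_that("constant reactivation matches the closed-form expectation", {
  g <- rumposome_geometry()
  em <- build_rumposome_lattice(g, 2000)
  # no bleaching: the dark pool is stationary, activations/frame ~ target
  p <- photophysics_params(p_off = 0.5, p_bleach = 0, n_frames = 4000)
  ctrl <- reactivation_controller(target_rate = 0.5, gain = 0.05)
  tr <- simulate_states(em, p, ctrl, seed = 6)
  total <- sum(tr$activations)
  expected <- 0.5 * 4000
  expect_lt(abs(total - expected), 3 * sqrt(expected))
})

test_that("controller keeps the activation rate stationary", {
  sim <- simulate_zoospore(simulation_config(sensor_px = 48, seed = 3,
                                             n_frames = 4000))
  act <- sim$trajectory$activations
  win <- colSums(matrix(act[1:4000], nrow = 100))
  expect_lt(sd(win) / mean(win), 0.5)
})

test_that("state simulation is bit-identical under a fixed seed", {
  g <- rumposome_geometry()
  em <- build_rumposome_lattice(g, 100)
  p <- photophysics_params(n_frames = 500)
  a <- simulate_states(em, p, seed = 11)
  b <- simulate_states(em, p, seed = 11)
  expect_identical(a$on, b$on)
  expect_identical(a$bleach_frame, b$bleach_frame)
})

test_that("photons per ON frame follow the requested model", {
  g <- rumposome_geometry()
  em <- build_rumposome_lattice(g, 500)
  for (mod in c("poisson", "geometric", "constant")) {
    p <- photophysics_params(photon_model = mod, n_frames = 1500)
    tr <- suppressWarnings(
      simulate_states(em, p, reactivation_controller(target_rate = 1),
                      seed = 8))
    ph <- tr$on$photons
    expect_true(all(ph >= 1))
    expect_lt(abs(mean(ph) - 350) / 350, 0.1)
    if (mod == "constant") expect_true(all(ph == 350))
    if (mod == "geometric") expect_gt(sd(ph), 250)  # heavy-tailed
    if (mod == "poisson") expect_lt(sd(ph), 40)
  }
})

test_that("bulk two-state conversion follows first-order kinetics", {
  expect_equal(bulk_switch_fraction(0, 100), 0)
  k <- 0.01
  expect_equal(bulk_switch_fraction(k, log(2) / k), 0.5)
  expect_error(bulk_switch_fraction(-1, 1), "non-negative")
  # far-red photoconversion regime: >85% converted within a 60 min dose
  expect_gt(bulk_switch_fraction(6e-4, 3600), 0.85)
})
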