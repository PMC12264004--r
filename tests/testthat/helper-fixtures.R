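# shared fixtures, built in code

# small camera with the calibrated fixture background
fixture_camera <- function(sensor = 13) {
  camera_model(sensor_px = c(sensor, sensor))
}

# localization table drawn from the band lattice at given precision;
# emulates a well-sampled acquisition for drift tests
dense_loc_table <- function(n = 40000, precision = 32, seed = 9,
                            n_frames = 10000) {
  set.seed(seed)
  g <- rumposome_geometry(center = c(4000, 4000))
  em <- build_rumposome_lattice(g, 3417)
  id <- sample(nrow(em), n, replace = TRUE)
  tab <- data.frame(frame = sort(sample.int(n_frames, n, replace = TRUE)),
                    x_nm = em$x_nm[id] + stats::rnorm(n, 0, precision),
                    y_nm = em$y_nm[id] + stats::rnorm(n, 0, precision),
                    photons = 350, background = 33.75, sigma_nm = 102,
                    precision_nm = precision, quality = 1, converged = TRUE)
  class(tab) <- c("localization_table", "data.frame")
  tab
}

# batched repeated fits of one emitter rendered at the fixture background
repeated_fits <- function(N, n_rep, camera = fixture_camera(), seed = 42,
                          fit_sigma = FALSE, x_px = 6.5, y_px = 6.5) {
  set.seed(seed)
  a <- camera$pixel_size_nm
  mu <- expected_frame(x_px * a, y_px * a, N, camera)
  roi <- camera$sensor_px[1]
  arr <- array(stats::rpois(length(mu) * n_rep, mu), c(roi, roi, n_rep))
  cand <- data.frame(frame = seq_len(n_rep),
                     i_px = (roi - 1) %/% 2, j_px = (roi - 1) %/% 2,
                     amp_photons = N, chunk_k = seq_len(n_rep))
  f <- rumpalm:::.fit_candidates(arr, cand, camera, roi_size = roi,
                                 fit_sigma = fit_sigma)
  f$err_x <- f$x_nm - x_px * a
  f$err_y <- f$y_nm - y_px * a
  f
}

# one-cell simulation small enough for unit tests
tiny_sim <- function(seed = 1, n_frames = 400, n_molecules = 150) {
  simulate_zoospore(simulation_config(
    n_molecules = n_molecules, seed = seed, sensor_px = 48,
    n_frames = n_frames, target_rate = 1.5))
}
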