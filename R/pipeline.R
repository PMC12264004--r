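#' Simulation configuration for a synthetic zoospore acquisition
#'
#' Collects every tunable parameter of the forward simulation in one
#' flat, YAML-serializable list. Defaults reproduce the fixture
#' acquisition: a ~4 um zoospore with ~3417 lattice emitters at 30 nm
#' pitch, 10,000 frames of 35 ms, ~350 detected photons per ON frame,
#' background calibrated to a 32 nm mean localization precision, and a
#' slow linear stage drift.
#'
#' @param n_molecules emitters placed on the rumposome lattice
#' @param seed simulation seed
#' @param sensor_px sensor side (pixels; square sensor)
#' @param pixel_size_nm,psf_sigma_nm,background_rate,em_gain,read_noise
#'   see [camera_model()]
#' @param cell_diameter_um,band_arc_radius_um,band_arc_span_deg,band_width_nm,lattice_pitch_nm,lattice_orientation_deg
#'   see [rumposome_geometry()]
#' @param p_off,p_bleach,photons_mean,photon_model,frame_time_s,n_frames
#'   see [photophysics_params()]
#' @param target_rate,controller_window,controller_gain see
#'   [reactivation_controller()]
#' @param drift_velocity_x,drift_velocity_y,drift_rw_sd linear drift
#'   (nm/frame) and random-walk step SD (nm)
#' @param jitter_sd_nm lattice jitter (nm)
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_molecules = 3417, seed = 1,
                              sensor_px = 128,
                              pixel_size_nm = 160, psf_sigma_nm = 102,
                              background_rate = NULL, em_gain = 1,
                              read_noise = 0,
                              cell_diameter_um = 4,
                              band_arc_radius_um = 1.4,
                              band_arc_span_deg = 150,
                              band_width_nm = 760,
                              lattice_pitch_nm = 30,
                              lattice_orientation_deg = 0,
                              p_off = 0.012, p_bleach = 0.238,
                              photons_mean = 350, photon_model = "poisson",
                              frame_time_s = 0.035, n_frames = 10000,
                              target_rate = 0.4, controller_window = 200,
                              controller_gain = 0.005,
                              drift_velocity_x = 0.05,
                              drift_velocity_y = -0.035,
                              drift_rw_sd = 0,
                              jitter_sd_nm = 0,
                              placement = "compact") {
  structure(as.list(environment()), class = "simulation_config")
}

#' Structure-acquisition fixture configuration
#'
#' The counting fixture ([simulation_config()] defaults) images a cell in
#' the post-bleach low-dose regime, where each molecule yields about one
#' short blink event (best for molecule counting). Resolving the 30 nm
#' lattice instead requires many photons per molecule, so the structure
#' fixture images long-lived emissions: the thermally stable far-red
#' state under weak off-switching stays ON for ~40 frames (~1.4 s),
#' re-blinks, and is activated sparsely (~0.1 activations/frame) so
#' concurrently active molecules rarely overlap. The band's lattice
#' sites are partially occupied (random placement), which keeps the
#' active density low while every molecule is revisited across the
#' movie - that revisiting also anchors the drift estimation.
#'
#' @param ... overrides passed to [simulation_config()]
#' @return a `simulation_config`
#' @export
structure_config <- function(...) {
  defaults <- list(n_molecules = 800, p_off = 0.015, p_bleach = 0.0017,
                   target_rate = 0.03, placement = "random",
                   lattice_orientation_deg = 90)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

#' Simulate a synthetic zoospore PALM acquisition
#'
#' Builds the rumposome lattice (centred on the sensor), simulates
#' photoswitching states under the ramped-reactivation controller and a
#' ground-truth drift trajectory. Rendering/localization is done
#' separately ([localize_movie()] or [render_frames()]), so the same
#' ground truth can be imaged repeatedly.
#'
#' @param config a [simulation_config()]
#' @return list with `emitters`, `trajectory`, `drift`, `camera`,
#'   `geometry`, `config`
#' @export
simulate_zoospore <- function(config = simulation_config()) {
  camera <- camera_model(pixel_size_nm = config$pixel_size_nm,
                         psf_sigma_nm = config$psf_sigma_nm,
                         background_rate = config$background_rate,
                         em_gain = config$em_gain,
                         read_noise = config$read_noise,
                         sensor_px = rep(config$sensor_px, 2))
  geometry <- rumposome_geometry(
    cell_diameter_um = config$cell_diameter_um,
    band_arc_radius_um = config$band_arc_radius_um,
    band_arc_span_deg = config$band_arc_span_deg,
    band_width_nm = config$band_width_nm,
    lattice_pitch_nm = config$lattice_pitch_nm,
    lattice_orientation_deg = config$lattice_orientation_deg,
    center = sensor_center_nm(camera))
  emitters <- build_rumposome_lattice(geometry, config$n_molecules,
                                      seed = config$seed,
                                      jitter_sd_nm = config$jitter_sd_nm,
                                      placement = config$placement)
  params <- photophysics_params(p_off = config$p_off,
                                p_bleach = config$p_bleach,
                                photons_mean = config$photons_mean,
                                photon_model = config$photon_model,
                                frame_time_s = config$frame_time_s,
                                n_frames = config$n_frames)
  controller <- reactivation_controller(target_rate = config$target_rate,
                                        window = config$controller_window,
                                        gain = config$controller_gain)
  trajectory <- simulate_states(emitters, params, controller,
                                seed = config$seed)
  drift <- simulate_drift(drift_model(c(config$drift_velocity_x,
                                        config$drift_velocity_y),
                                      config$drift_rw_sd),
                          config$n_frames, seed = config$seed + 1)
  list(emitters = emitters, trajectory = trajectory, drift = drift,
       camera = camera, geometry = geometry, config = config)
}

#' Run the structural-imaging pipeline on a simulated acquisition
#'
#' Localizes a structure-fixture movie (small fit ROI and permissive
#' detection threshold suited to long-lived emissions), removes drift,
#' merges localizations into long blink events, renders the grouped
#' reconstruction by Thompson blurring and estimates the lattice spacing
#' along the band with [band_spacing()].
#'
#' @param sim result of [simulate_zoospore()] (typically from
#'   [structure_config()])
#' @param k_sigma,roi_size detection threshold multiplier and fit ROI
#' @param radius,max_dark_frames blink-linkage parameters
#' @param min_locs minimum localizations per rendered event
#' @param render_pixel rendering grid (nm)
#' @param chunk_size frames per rendering chunk
#' @return list with `locs`, `drift_est`, `locs_dc`, `events`,
#'   `event_table`, `image`, `spacing`
#' @export
analyze_structure <- function(sim, k_sigma = 3.5, roi_size = 7L,
                              radius = 100, max_dark_frames = 8,
                              min_locs = 8, render_pixel = 5,
                              chunk_size = 250L) {
  locs <- localize_movie(sim$emitters, sim$trajectory, sim$camera,
                         drift = sim$drift, seed = sim$config$seed + 2,
                         chunk_size = chunk_size, k_sigma = k_sigma,
                         roi_size = roi_size, fit_sigma = FALSE)
  locs <- filter_localizations(locs, converged_only = TRUE)
  pre <- crop_to_band(locs, sim$geometry, margin = 700)
  drift_est <- estimate_drift(pre, n_frames = sim$trajectory$n_frames)
  locs_dc <- correct_drift(locs, drift_est)
  locs_dc <- crop_to_band(locs_dc, sim$geometry)
  events <- merge_into_events(locs_dc, radius = radius,
                              max_dark_frames = max_dark_frames)
  event_table <- events_to_table(events, locs_dc, min_locs = min_locs)
  image <- render_thompson(event_table, render_pixel = render_pixel)
  spacing <- band_spacing(image, sim$geometry)
  list(locs = locs, drift_est = drift_est, locs_dc = locs_dc,
       events = events, event_table = event_table, image = image,
       spacing = spacing)
}

#' Run the full analysis pipeline on a simulated acquisition
#'
#' Localizes the movie chunk-wise, estimates and removes lateral drift,
#' crops to the organelle band, merges blink events and counts
#' molecules. Returns every intermediate product.
#'
#' @param sim result of [simulate_zoospore()]
#' @param n_blocks temporal blocks for drift estimation
#' @param radius,max_dark_frames blink-linkage parameters. The default
#'   radius is 96 nm = 3 x the fixture's nominal 32 nm precision; the
#'   table's mean reported precision underestimates the true per-frame
#'   scatter at this background (detection selects upward photon
#'   fluctuations), so a data-driven radius would fragment bursts
#' @param chunk_size frames per rendering chunk
#' @param ... further arguments to [localize_stack()]
#' @return list with `locs` (raw), `drift_est`, `locs_dc`
#'   (drift-corrected, band-cropped), `events`, `count`
#' @export
analyze_zoospore <- function(sim, n_blocks = 10, radius = 96,
                             max_dark_frames = 2, chunk_size = 250L, ...) {
  locs <- localize_movie(sim$emitters, sim$trajectory, sim$camera,
                         drift = sim$drift, seed = sim$config$seed + 2,
                         chunk_size = chunk_size, ...)
  locs <- filter_localizations(locs, converged_only = TRUE)
  # block-level accuracy suffices for event linkage: events span a few
  # frames, so only the crop and rendering see residual drift
  drift_est <- estimate_drift(locs, n_blocks = n_blocks, fine = FALSE,
                              n_frames = sim$trajectory$n_frames)
  locs_dc <- correct_drift(locs, drift_est)
  locs_dc <- crop_to_band(locs_dc, sim$geometry)
  events <- merge_into_events(locs_dc, radius = radius,
                              max_dark_frames = max_dark_frames)
  list(locs = locs, drift_est = drift_est, locs_dc = locs_dc,
       events = events,
       count = count_molecules(events))
}
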