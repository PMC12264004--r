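#' Write a localization table to CSV
#'
#' Fixed schema `frame,x_nm,y_nm,photons,background,sigma_nm,precision_nm,quality`,
#' floats at 3 decimals, UTF-8, comma-separated.
#'
#' @param table a `localization_table`
#' @param path output file
#' @export
write_localizations <- function(table, path) {
  cols <- c("frame", "x_nm", "y_nm", "photons", "background",
            "sigma_nm", "precision_nm", "quality")
  df <- table[cols]
  for (c in cols[-1]) df[[c]] <- round(df[[c]], 3)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Read a localization table CSV
#' @param path CSV written by [write_localizations()]
#' @return a `localization_table`
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  class(df) <- c("localization_table", "data.frame")
  df
}

#' Write blink events to CSV
#'
#' Schema `event_id,x_nm,y_nm,first_frame,last_frame,n_locs,total_photons`.
#'
#' @param events a `blink_events`
#' @param path output file
#' @export
write_events <- function(events, path) {
  df <- events$events[c("event_id", "x_nm", "y_nm", "first_frame",
                        "last_frame", "n_locs", "total_photons")]
  df$x_nm <- round(df$x_nm, 3); df$y_nm <- round(df$y_nm, 3)
  df$total_photons <- round(df$total_photons, 3)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write a drift trajectory to CSV (`frame,dx_nm,dy_nm`)
#' @param trajectory a `drift_trajectory`
#' @param path output file
#' @export
write_drift <- function(trajectory, path) {
  df <- data.frame(frame = trajectory$frame,
                   dx_nm = round(trajectory$dx_nm, 3),
                   dy_nm = round(trajectory$dy_nm, 3))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write a cohort summary to JSON
#' @param summary a `cell_count_summary`
#' @param path output file
#' @export
write_count_summary <- function(summary, path) {
  jsonlite::write_json(list(mean = summary$mean, sd = summary$sd,
                            n = summary$n, counts = summary$counts),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Write a frame stack as a multi-page 16-bit grayscale TIFF
#'
#' Counts are clamped to the 16-bit range. Acquisition metadata (pixel
#' size, frame time) is not stored in the TIFF; keep the YAML config
#' alongside.
#'
#' @param stack a `frame_stack`
#' @param path output TIFF
#' @export
write_framestack <- function(stack, path) {
  arr <- stack$frames
  pages <- lapply(seq_len(dim(arr)[3]), function(k)
    pmin(arr[, , k], 65535L) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
}

#' Read a multi-page TIFF as a frame stack
#' @param path TIFF file
#' @param camera the [camera_model()] of the acquisition
#' @param frame_time_s frame integration time (s)
#' @return a `frame_stack`
#' @export
read_framestack <- function(path, camera, frame_time_s = 0.035) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages))
    arr[, , k] <- as.integer(round(pages[[k]] * 65535))
  structure(list(frames = arr, frame_index = seq_along(pages),
                 camera = camera, frame_time_s = frame_time_s),
            class = "frame_stack")
}

#' Write ground-truth emitters to CSV (`molecule_id,x_nm,y_nm,label`)
#' @param emitters an `emitter_field`
#' @param path output file
#' @export
write_emitters <- function(emitters, path) {
  df <- data.frame(molecule_id = emitters$molecule_id,
                   x_nm = round(emitters$x_nm, 3),
                   y_nm = round(emitters$y_nm, 3),
                   label = emitters$label)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write per-frame ON states to CSV (`frame,molecule_id,photons`)
#' @param trajectory a `state_trajectory`
#' @param path output file
#' @export
write_states <- function(trajectory, path) {
  utils::write.csv(trajectory$on, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write an intensity profile to CSV (`arc_nm,intensity`)
#' @param profile an `intensity_profile`
#' @param path output file
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(data.frame(arc_nm = round(profile$arc_nm, 3),
                              intensity = round(profile$intensity, 6)),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write an autocorrelation curve to CSV (`lag_nm,acf`)
#' @param acf an `acf_curve`
#' @param path output file
#' @export
write_acf <- function(acf, path) {
  utils::write.csv(data.frame(lag_nm = round(acf$lag_nm, 3),
                              acf = round(acf$acf, 6)),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Read a path polyline CSV (`x_nm,y_nm`)
#' @param path CSV file
#' @return data.frame with `x_nm`, `y_nm`
#' @export
read_path <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  stopifnot(all(c("x_nm", "y_nm") %in% names(df)))
  df
}

#' Read a simulation configuration from YAML
#'
#' Expects a top-level `simulate:` block whose keys override the
#' defaults of [simulation_config()]; unknown keys raise an error.
#'
#' @param path YAML file
#' @return a `simulation_config` list
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$simulate)) stop("config must contain a 'simulate:' block")
  do.call(simulation_config, y$simulate)
}

#' Write a simulation configuration to YAML
#' @param config a `simulation_config`
#' @param path output file
#' @export
write_simulation_config <- function(config, path) {
  yaml::write_yaml(list(simulate = unclass(config)), path)
}
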