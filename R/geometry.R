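#' Rumposome geometry description
#'
#' Describes the crescent-shaped rumposome band inside a zoospore cell body:
#' an annular arc of given mid-line radius, angular span and radial width,
#' carrying a hexagonal lattice of photoreceptor positions. All coordinates
#' are in nm in the sample plane; the cell is centred at `center`.
#'
#' Defaults emulate a ~4 um zoospore with a ~1 um lipid globule and a band
#' dimensioned so that a 30 nm-pitch hexagonal lattice hosts ~3500 molecules.
#'
#' @param cell_diameter_um cell body diameter (um)
#' @param globule_diameter_um lipid globule diameter (um)
#' @param band_arc_radius_um radius of the band mid-line from the cell centre (um)
#' @param band_arc_span_deg angular span of the crescent (degrees)
#' @param band_width_nm radial width of the band (nm)
#' @param lattice_pitch_nm in-row (horizontal) centre-to-centre lattice distance (nm)
#' @param lattice_orientation_deg global lattice row direction (degrees)
#' @param center cell centre (x, y) in nm; defaults to the origin
#' @return an object of class `rumposome_geometry`
#' @export
rumposome_geometry <- function(cell_diameter_um = 4,
                               globule_diameter_um = 1,
                               band_arc_radius_um = 1.4,
                               band_arc_span_deg = 150,
                               band_width_nm = 760,
                               lattice_pitch_nm = 30,
                               lattice_orientation_deg = 0,
                               center = c(0, 0)) {
  stopifnot(cell_diameter_um > 0, globule_diameter_um > 0,
            band_arc_radius_um > 0, band_arc_span_deg > 0,
            band_width_nm > 0, lattice_pitch_nm > 0)
  r_out <- band_arc_radius_um * 1000 + band_width_nm / 2
  if (r_out > cell_diameter_um * 1000 / 2)
    stop("band does not fit inside the cell circle")
  structure(list(
    cell_diameter_um = cell_diameter_um,
    globule_diameter_um = globule_diameter_um,
    band_arc_radius_um = band_arc_radius_um,
    band_arc_span_deg = band_arc_span_deg,
    band_width_nm = band_width_nm,
    lattice_pitch_nm = lattice_pitch_nm,
    lattice_orientation_deg = lattice_orientation_deg,
    center = as.numeric(center)
  ), class = "rumposome_geometry")
}

#' @export
print.rumposome_geometry <- function(x, ...) {
  cat("Rumposome geometry\n")
  cat(sprintf("  cell %g um, globule %g um\n",
              x$cell_diameter_um, x$globule_diameter_um))
  cat(sprintf("  band: radius %g um, span %g deg, width %g nm\n",
              x$band_arc_radius_um, x$band_arc_span_deg, x$band_width_nm))
  cat(sprintf("  lattice: pitch %g nm, orientation %g deg\n",
              x$lattice_pitch_nm, x$lattice_orientation_deg))
  cat(sprintf("  capacity: %d lattice sites\n", band_capacity(x)))
  invisible(x)
}

# midpoint of the band arc (on the mid-line, at the central angle), nm
band_midpoint <- function(geometry) {
  r <- geometry$band_arc_radius_um * 1000
  geometry$center + c(r, 0)  # central angle is 0 by convention
}

# all hexagonal lattice sites falling inside the annular band sector;
# lattice is anchored so that the band midpoint is a lattice node
band_lattice_sites <- function(geometry) {
  p <- geometry$lattice_pitch_nm
  rowsep <- p * sqrt(3) / 2
  r0 <- geometry$band_arc_radius_um * 1000
  hw <- geometry$band_width_nm / 2
  half_span <- geometry$band_arc_span_deg / 2 * pi / 180
  # generous bounding radius around the band midpoint
  mid <- band_midpoint(geometry)
  r_max <- sqrt((r0 * half_span)^2 + (r0 * (1 - cos(half_span)) + hw)^2) + p
  ni <- ceiling(r_max / p) + 1
  nj <- ceiling(r_max / rowsep) + 1
  j <- seq(-nj, nj)
  grid <- do.call(rbind, lapply(j, function(jj) {
    xs <- seq(-ni, ni) * p + (jj %% 2) * p / 2
    cbind(xs, jj * rowsep)
  }))
  th <- geometry$lattice_orientation_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- grid %*% t(rot)
  pts[, 1] <- pts[, 1] + mid[1]
  pts[, 2] <- pts[, 2] + mid[2]
  # keep sites inside the annular sector
  dx <- pts[, 1] - geometry$center[1]
  dy <- pts[, 2] - geometry$center[2]
  rad <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  keep <- abs(rad - r0) <= hw & abs(ang) <= half_span
  pts[keep, , drop = FALSE]
}

#' Number of lattice sites the band can host
#'
#' @param geometry a [rumposome_geometry()]
#' @return integer site count
#' @export
band_capacity <- function(geometry) nrow(band_lattice_sites(geometry))

#' Place emitters on the rumposome hexagonal lattice
#'
#' Generates ground-truth emitter positions on hexagonal lattice nodes
#' (in-row spacing = `lattice_pitch_nm`, rows offset by pitch * sqrt(3)/2)
#' restricted to the crescent band. When fewer molecules than lattice sites
#' are requested, the sites nearest the band midpoint are used, so the
#' occupied patch stays contiguous and the selection is deterministic.
#' Optional positional jitter perturbs nodes isotropically.
#'
#' @param geometry a [rumposome_geometry()]
#' @param n_molecules number of emitters to place
#' @param seed RNG seed (placement = "random" and jitter)
#' @param jitter_sd_nm isotropic Gaussian jitter of node positions (nm)
#' @param placement `"compact"` fills the sites nearest the band midpoint
#'   (deterministic, contiguous patch); `"random"` occupies a random
#'   subset of sites across the whole band (partial lattice occupancy)
#' @return an `emitter_field`: data.frame with `molecule_id`, `x_nm`, `y_nm`,
#'   `label`, with the geometry attached as an attribute
#' @export
build_rumposome_lattice <- function(geometry, n_molecules, seed = 1,
                                    jitter_sd_nm = 0,
                                    placement = c("compact", "random")) {
  placement <- match.arg(placement)
  stopifnot(n_molecules > 0)
  sites <- band_lattice_sites(geometry)
  if (nrow(sites) < n_molecules)
    stop(sprintf(
      "band capacity exceeded: %d lattice sites at pitch %g nm, %d molecules requested",
      nrow(sites), geometry$lattice_pitch_nm, n_molecules))
  if (placement == "random") {
    set.seed(seed)
    sel <- sites[sample(nrow(sites), n_molecules), , drop = FALSE]
  } else {
    mid <- band_midpoint(geometry)
    d2 <- (sites[, 1] - mid[1])^2 + (sites[, 2] - mid[2])^2
    sel <- sites[order(d2)[seq_len(n_molecules)], , drop = FALSE]
  }
  if (jitter_sd_nm > 0) {
    set.seed(seed)
    sel <- sel + matrix(stats::rnorm(2 * nrow(sel), 0, jitter_sd_nm), ncol = 2)
  }
  out <- data.frame(molecule_id = seq_len(n_molecules),
                    x_nm = sel[, 1], y_nm = sel[, 2],
                    label = "lattice", stringsAsFactors = FALSE)
  stopifnot(all(is.finite(out$x_nm)), all(is.finite(out$y_nm)))
  attr(out, "geometry") <- geometry
  class(out) <- c("emitter_field", "data.frame")
  out
}

#' Polyline along the band mid-line
#'
#' Arc-length sampled path along the rumposome band mid-line, for intensity
#' profile extraction.
#'
#' @param geometry a [rumposome_geometry()]
#' @param step_nm spacing of polyline vertices along the arc (nm)
#' @param trim_deg degrees trimmed from both arc ends (avoids band-end falloff)
#' @param radial_offset_nm radial offset from the band mid-line (nm);
#'   positive moves the path outward
#' @return data.frame with `x_nm`, `y_nm`
#' @export
band_path <- function(geometry, step_nm = 10, trim_deg = 5,
                      radial_offset_nm = 0) {
  r <- geometry$band_arc_radius_um * 1000 + radial_offset_nm
  half <- (geometry$band_arc_span_deg / 2 - trim_deg) * pi / 180
  stopifnot(half > 0)
  dth <- step_nm / r
  th <- seq(-half, half, by = dth)
  data.frame(x_nm = geometry$center[1] + r * cos(th),
             y_nm = geometry$center[2] + r * sin(th))
}
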