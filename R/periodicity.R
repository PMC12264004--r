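#' Thompson-blur reconstruction of a localization table
#'
#' Renders each localization as a unit-mass 2D Gaussian whose sigma is its
#' localization precision, on a grid of `render_pixel` nm. The total image
#' intensity equals the number of rendered localizations.
#'
#' @param table a `localization_table` with a `precision_nm` column
#' @param render_pixel grid pixel (nm)
#' @param sigma_nm optional fixed rendering sigma overriding the per-row
#'   precision
#' @param pad_nm margin added around the localization bounding box
#' @return object of class `rendered_image`: list with `intensity`
#'   (matrix, rows = y), `render_pixel`, `origin_nm` (x, y of the image's
#'   top-left corner)
#' @export
render_thompson <- function(table, render_pixel = 5, sigma_nm = NULL,
                            pad_nm = NULL) {
  stopifnot(nrow(table) >= 1)
  sig <- if (is.null(sigma_nm)) table$precision_nm else rep(sigma_nm, nrow(table))
  stopifnot(all(is.finite(sig)), all(sig > 0))
  if (is.null(pad_nm)) pad_nm <- 4 * max(sig)
  x0 <- min(table$x_nm) - pad_nm; y0 <- min(table$y_nm) - pad_nm
  nx <- ceiling((max(table$x_nm) + pad_nm - x0) / render_pixel)
  ny <- ceiling((max(table$y_nm) + pad_nm - y0) / render_pixel)
  img <- matrix(0, ny, nx)
  for (k in seq_len(nrow(table))) {
    s <- sig[k]
    hw <- 5 * s
    jlo <- max(0L, floor((table$x_nm[k] - hw - x0) / render_pixel))
    jhi <- min(nx - 1L, ceiling((table$x_nm[k] + hw - x0) / render_pixel))
    ilo <- max(0L, floor((table$y_nm[k] - hw - y0) / render_pixel))
    ihi <- min(ny - 1L, ceiling((table$y_nm[k] + hw - y0) / render_pixel))
    if (jlo > jhi || ilo > ihi) next
    ex <- diff(stats::pnorm(seq(jlo, jhi + 1L) * render_pixel + x0,
                            mean = table$x_nm[k], sd = s))
    ey <- diff(stats::pnorm(seq(ilo, ihi + 1L) * render_pixel + y0,
                            mean = table$y_nm[k], sd = s))
    stamp <- outer(ey, ex)
    img[(ilo + 1L):(ihi + 1L), (jlo + 1L):(jhi + 1L)] <-
      img[(ilo + 1L):(ihi + 1L), (jlo + 1L):(jhi + 1L)] +
      stamp / sum(stamp)  # exact unit mass despite stamp truncation
  }
  structure(list(intensity = img, render_pixel = render_pixel,
                 origin_nm = c(x0, y0)),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("Rendered image: %dx%d px at %g nm/px, total intensity %.2f\n",
              ncol(x$intensity), nrow(x$intensity), x$render_pixel,
              sum(x$intensity)))
  invisible(x)
}

# bilinear interpolation of image intensity at (x, y) nm (vectors)
.bilinear <- function(image, x_nm, y_nm) {
  px <- (x_nm - image$origin_nm[1]) / image$render_pixel - 0.5
  py <- (y_nm - image$origin_nm[2]) / image$render_pixel - 0.5
  ny <- nrow(image$intensity); nx <- ncol(image$intensity)
  if (any(px < 0 | px > nx - 1 | py < 0 | py > ny - 1))
    stop("sampling point outside image bounds")
  j0 <- pmin(floor(px), nx - 2); i0 <- pmin(floor(py), ny - 2)
  fx <- px - j0; fy <- py - i0
  I <- image$intensity
  v00 <- I[cbind(i0 + 1, j0 + 1)]; v01 <- I[cbind(i0 + 1, j0 + 2)]
  v10 <- I[cbind(i0 + 2, j0 + 1)]; v11 <- I[cbind(i0 + 2, j0 + 2)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Extract an intensity profile along a path
#'
#' Resamples the polyline at uniform arc-length steps; at each step the
#' mean intensity over a segment perpendicular to the path of the given
#' width is taken (bilinear interpolation).
#'
#' @param image a `rendered_image`
#' @param path data.frame with `x_nm`, `y_nm` polyline vertices
#' @param width transverse averaging width (nm); 0 samples the line itself
#' @param step arc-length sampling step (nm)
#' @param n_transverse samples across the width
#' @return object of class `intensity_profile`: data.frame `arc_nm`,
#'   `intensity`, with `step`, `width` and the path attached
#' @export
extract_profile <- function(image, path, width = 60, step = 5,
                            n_transverse = NULL) {
  stopifnot(width >= 0, step > 0, nrow(path) >= 2)
  seg <- sqrt(diff(path$x_nm)^2 + diff(path$y_nm)^2)
  arc <- c(0, cumsum(seg))
  s <- seq(0, arc[length(arc)], by = step)
  fx <- stats::approxfun(arc, path$x_nm); fy <- stats::approxfun(arc, path$y_nm)
  xs <- fx(s); ys <- fy(s)
  # tangent by central differences, normal perpendicular to it
  tx <- c(xs[2] - xs[1], diff(xs, lag = 2) / 2, xs[length(xs)] - xs[length(xs) - 1])
  ty <- c(ys[2] - ys[1], diff(ys, lag = 2) / 2, ys[length(ys)] - ys[length(ys) - 1])
  nrm <- sqrt(tx^2 + ty^2); nx <- -ty / nrm; ny <- tx / nrm
  if (width == 0) {
    val <- .bilinear(image, xs, ys)
  } else {
    if (is.null(n_transverse))
      n_transverse <- max(3L, ceiling(width / image$render_pixel) + 1L)
    off <- seq(-width / 2, width / 2, length.out = n_transverse)
    acc <- 0
    for (o in off) acc <- acc + .bilinear(image, xs + o * nx, ys + o * ny)
    val <- acc / n_transverse
  }
  out <- data.frame(arc_nm = s, intensity = val)
  attr(out, "step") <- step
  attr(out, "width") <- width
  attr(out, "path") <- path
  class(out) <- c("intensity_profile", "data.frame")
  out
}

#' Rolling-ball background correction of a 1D profile
#'
#' Morphological opening with a disk-arc structuring element of the given
#' radius: the baseline is the upper envelope of a ball rolled under the
#' signal, and is subtracted. The ball's curvature in the intensity
#' direction is set by `intensity_scale` (intensity units per nm);
#' the default scales the signal range to the ball radius. The result is
#' zero at all opened minima and never negative where the ball touches.
#'
#' @param profile an `intensity_profile`
#' @param ball_radius ball radius in arc-length units (nm); must exceed
#'   the sampling step
#' @param intensity_scale intensity units per nm of ball height;
#'   `NULL` uses `diff(range(intensity)) / ball_radius`
#' @return background-corrected `intensity_profile` (attribute
#'   `background` holds the subtracted baseline)
#' @export
rolling_ball_1d <- function(profile, ball_radius = 120, intensity_scale = NULL) {
  step <- attr(profile, "step")
  if (is.null(step)) step <- stats::median(diff(profile$arc_nm))
  if (ball_radius <= step)
    stop("ball_radius must exceed the profile sampling step")
  v <- profile$intensity
  n <- length(v)
  m <- floor(ball_radius / step)
  u <- seq(-m, m) * step
  scale <- if (is.null(intensity_scale)) diff(range(v)) / ball_radius else intensity_scale
  se <- scale * (sqrt(pmax(ball_radius^2 - u^2, 0)) - ball_radius)  # <= 0, 0 at centre
  erode <- function(f) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      k <- max(1, i - m):min(n, i + m)
      out[i] <- min(f[k] - se[k - i + m + 1])
    }
    out
  }
  dilate <- function(f) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      k <- max(1, i - m):min(n, i + m)
      out[i] <- max(f[k] + se[k - i + m + 1])
    }
    out
  }
  background <- dilate(erode(v))
  out <- profile
  out$intensity <- v - background
  attr(out, "background") <- background
  out
}

#' Normalized spatial autocorrelation of a profile
#'
#' Mean-subtracted, biased-normalized autocorrelation with value 1 at lag
#' zero; lags run to half the profile length.
#'
#' @param profile an `intensity_profile` (or numeric vector with `step`)
#' @param step sampling step (nm) when `profile` is a bare vector
#' @return object of class `acf_curve`: data.frame `lag_nm`, `acf`
#' @export
autocorrelate <- function(profile, step = NULL) {
  if (is.data.frame(profile)) {
    v <- profile$intensity
    if (is.null(step)) step <- attr(profile, "step")
    if (is.null(step)) step <- stats::median(diff(profile$arc_nm))
  } else v <- as.numeric(profile)
  n <- length(v)
  if (n < 4) stop("profile must have at least 4 points")
  z <- v - mean(v)
  denom <- sum(z^2)
  if (denom == 0) denom <- 1
  max_lag <- floor(n / 2)
  # biased-normalized ACF via zero-padded FFT
  np <- stats::nextn(2L * n, 2)
  zf <- stats::fft(c(z, numeric(np - n)))
  ac <- Re(stats::fft(zf * Conj(zf), inverse = TRUE))[1:(max_lag + 1)] / np / denom
  out <- data.frame(lag_nm = (0:max_lag) * step, acf = ac)
  attr(out, "n") <- n
  class(out) <- c("acf_curve", "data.frame")
  out
}

#' Spacing from the first autocorrelation peak
#'
#' Locates the first local maximum beyond the central lobe (i.e. after
#' the first local minimum), refines it with a 3-point parabolic fit and
#' reports the refined lag as the spacing. Peaks smaller than
#' `significance` (default, the white-noise bound `3/sqrt(n)`) are
#' ignored; if no significant peak exists, a no-period result is
#' returned.
#'
#' @param acf an `acf_curve`
#' @param significance minimum ACF value for an acceptable peak
#' @param min_lag_nm ignore peaks below this lag (0 = no constraint)
#' @param window_nm half-width of the window over which a candidate must
#'   be the running extremum; suppresses single-bin noise wiggles on the
#'   flanks of broader features
#' @return object of class `spacing_estimate`: list with `spacing_nm`
#'   (NA when no period found), `peak_acf`, `found`, and the curve
#' @export
first_peak_spacing <- function(acf, significance = NULL, min_lag_nm = 0,
                               window_nm = 6) {
  v <- acf$acf; lags <- acf$lag_nm
  n_src <- attr(acf, "n")
  if (is.null(significance))
    significance <- if (!is.null(n_src)) 3 / sqrt(n_src) else 0
  n <- length(v)
  step <- lags[2] - lags[1]
  w <- max(1L, round(window_nm / step))
  win <- function(i) max(1L, i - w):min(n, i + w)
  # first windowed local minimum marks the end of the central lobe
  i_min <- NA
  for (i in 2:(n - 1)) if (v[i] <= min(v[win(i)])) { i_min <- i; break }
  found <- FALSE; sp <- NA_real_; pk <- NA_real_
  if (!is.na(i_min)) {
    for (i in (i_min + 1):(n - 1)) {
      if (lags[i] < min_lag_nm) next
      if (v[i] >= max(v[win(i)]) && v[i] >= significance) {
        den <- v[i - 1] - 2 * v[i] + v[i + 1]
        frac <- if (den < 0) 0.5 * (v[i - 1] - v[i + 1]) / den else 0
        frac <- min(max(frac, -1), 1)
        sp <- lags[i] + frac * step
        pk <- v[i]
        found <- TRUE
        break
      }
    }
  }
  structure(list(spacing_nm = sp, peak_acf = pk, found = found, curve = acf),
            class = "spacing_estimate")
}

#' @export
print.spacing_estimate <- function(x, ...) {
  if (x$found)
    cat(sprintf("Spacing estimate: %.1f nm (ACF peak %.3f)\n",
                x$spacing_nm, x$peak_acf))
  else cat("Spacing estimate: no significant period found\n")
  invisible(x)
}

#' Lattice spacing along the rumposome band of a reconstruction
#'
#' Extracts intensity profiles along several parallel arc paths spanning
#' the band (the curved path sweeps the lattice orientations, so the
#' per-strip autocorrelations average over projections like the rotation
#' analysis), applies rolling-ball background correction to each,
#' autocorrelates, averages the curves on a common lag grid and fits the
#' first non-zero-lag peak.
#'
#' @param image a `rendered_image` of the (drift-corrected) band
#' @param geometry the [rumposome_geometry()] of the cell
#' @param offsets_nm radial strip offsets from the band mid-line
#' @param width_nm transverse width of each strip
#' @param step_nm profile sampling step
#' @param ball_radius_nm rolling-ball radius
#' @return a `spacing_estimate`
#' @export
band_spacing <- function(image, geometry,
                         offsets_nm = seq(-360, 360, by = 20),
                         width_nm = 20, step_nm = 2,
                         ball_radius_nm = 120) {
  acc <- NULL; ncur <- 0L; nmin <- Inf
  curves <- list()
  for (o in offsets_nm) {
    path <- band_path(geometry, radial_offset_nm = o)
    pr <- tryCatch(extract_profile(image, path, width = width_nm,
                                   step = step_nm),
                   error = function(e) NULL)
    if (is.null(pr) || nrow(pr) < 8) next
    pr <- rolling_ball_1d(pr, ball_radius_nm)
    ncur <- ncur + 1L
    curves[[ncur]] <- autocorrelate(pr)
  }
  if (!ncur) stop("no strip lies inside the rendered image")
  nlag <- min(vapply(curves, nrow, integer(1)))
  acf_mean <- rowMeans(vapply(curves, function(cv) cv$acf[seq_len(nlag)],
                              numeric(nlag)))
  out <- data.frame(lag_nm = curves[[1]]$lag_nm[seq_len(nlag)], acf = acf_mean)
  attr(out, "n") <- sum(vapply(curves, function(cv) attr(cv, "n"), numeric(1)))
  class(out) <- c("acf_curve", "data.frame")
  est <- first_peak_spacing(out)
  est$n_strips <- ncur
  est
}

#' Parameters of the hexagonal-pattern forward simulation
#'
#' A grid of `grid_n` x `grid_n` Gaussian distributions on a hexagonal
#' lattice of given horizontal pitch, each of the given FWHM, convolved
#' with a localization-accuracy Gaussian, optionally with random membrane
#' jitter of the node positions.
#'
#' @param pitch_nm horizontal (in-row) pitch
#' @param fwhm_nm full width at half maximum of each distribution
#' @param grid_n distributions per side
#' @param localization_accuracy_nm sigma of the accuracy convolution
#' @param jitter_sd_nm random node displacement SD (membrane disorder)
#' @param rotation_step_deg,rotation_range_deg rotation scheme of the
#'   projection analysis
#' @return object of class `hex_pattern_params`
#' @export
hex_pattern_params <- function(pitch_nm = 30, fwhm_nm = 30, grid_n = 200,
                               localization_accuracy_nm = 5,
                               jitter_sd_nm = 3,
                               rotation_step_deg = 5,
                               rotation_range_deg = c(0, 360)) {
  stopifnot(pitch_nm > 0, fwhm_nm > 0, grid_n >= 2,
            localization_accuracy_nm >= 0, jitter_sd_nm >= 0,
            rotation_step_deg > 0)
  span <- diff(rotation_range_deg)
  if (abs(span / rotation_step_deg - round(span / rotation_step_deg)) > 1e-9)
    stop("rotation_step_deg must divide the rotation range")
  structure(list(pitch_nm = pitch_nm, fwhm_nm = fwhm_nm,
                 grid_n = as.integer(grid_n),
                 localization_accuracy_nm = localization_accuracy_nm,
                 jitter_sd_nm = jitter_sd_nm,
                 rotation_step_deg = rotation_step_deg,
                 rotation_range_deg = rotation_range_deg),
            class = "hex_pattern_params")
}

# hexagonal node coordinates, optional jitter; anchored so that one row
# lies on y = 0 with a node at the origin
.hex_nodes <- function(params, seed = 1) {
  n <- params$grid_n; p <- params$pitch_nm
  rowsep <- p * sqrt(3) / 2
  c0 <- ceiling(n / 2)
  j <- seq_len(n) - c0
  nodes <- do.call(rbind, lapply(seq_len(n), function(r) {
    y <- (r - c0) * rowsep
    cbind(j * p + ((r - c0) %% 2) * p / 2, y)
  }))
  if (params$jitter_sd_nm > 0) {
    set.seed(seed)
    nodes <- nodes + matrix(stats::rnorm(length(nodes), 0, params$jitter_sd_nm),
                            ncol = 2)
  }
  nodes
}

#' Render the simulated hexagonal pattern
#'
#' Unit-mass Gaussians (sigma = FWHM / 2.355) at hexagonal lattice nodes,
#' convolved with the localization-accuracy Gaussian (Gaussian identity:
#' effective sigma^2 = sigma_fwhm^2 + sigma_loc^2).
#'
#' @param params a [hex_pattern_params()]
#' @param seed RNG seed for node jitter
#' @param render_pixel grid pixel (nm)
#' @return a `rendered_image`
#' @export
simulate_hex_pattern <- function(params, seed = 1, render_pixel = 5) {
  nodes <- .hex_nodes(params, seed)
  s_tot <- sqrt((params$fwhm_nm / (2 * sqrt(2 * log(2))))^2 +
                params$localization_accuracy_nm^2)
  tab <- data.frame(x_nm = nodes[, 1], y_nm = nodes[, 2],
                    precision_nm = s_tot)
  render_thompson(tab, render_pixel = render_pixel, sigma_nm = s_tot)
}

#' Rotation-averaged projection analysis of the hexagonal pattern
#'
#' For each rotation angle the node pattern is rotated, a horizontal
#' line-band profile through the pattern centre is extracted,
#' mean-subtracted and autocorrelated; the autocorrelations are averaged
#' over all angles and the first non-zero-lag peak is fitted. Because the
#' nearest-neighbour shell of a hexagonal lattice has a single length
#' (the pitch), the projected spacings of a narrow band pile up at the
#' pitch across rotations, producing the averaged central peak.
#'
#' Two profile modes are available. `"positions"` (default) profiles the
#' simulated molecule positions themselves (fine-binned position
#' histogram; localization accuracy enters as a random displacement of
#' each position). `"intensity"` profiles the Gaussian-blurred pattern
#' (transverse Gaussian mass of each node inside the band); note that at
#' a 30 nm pitch the FWHM-sized blur of the distributions largely washes
#' out the periodicity of an intensity profile, which is why the
#' position-based analysis is the default.
#'
#' @param params a [hex_pattern_params()]
#' @param seed RNG seed for node jitter and accuracy displacement
#' @param band_width_nm full transverse width of each line band
#' @param n_bands number of parallel bands averaged per rotation
#'   (centred on the pattern middle, stacked contiguously)
#' @param step_nm profile sampling step
#' @param profile_of `"positions"` or `"intensity"`
#' @return a `spacing_estimate`; the averaged curve is in `$curve`
#' @export
rotated_projection_analysis <- function(params, seed = 1,
                                        band_width_nm = 10, n_bands = 15,
                                        step_nm = 2,
                                        profile_of = c("positions", "intensity")) {
  profile_of <- match.arg(profile_of)
  nodes <- .hex_nodes(params, seed)
  s_blur <- params$fwhm_nm / (2 * sqrt(2 * log(2)))
  if (profile_of == "positions" && params$localization_accuracy_nm > 0) {
    # localization accuracy as a per-molecule position error
    set.seed(seed + 1)
    nodes <- nodes + matrix(stats::rnorm(length(nodes), 0,
                                         params$localization_accuracy_nm),
                            ncol = 2)
  }
  s_tot <- sqrt(s_blur^2 + params$localization_accuracy_nm^2)
  angles <- seq(params$rotation_range_deg[1], params$rotation_range_deg[2],
                by = params$rotation_step_deg)
  angles <- angles[angles < params$rotation_range_deg[2] | length(angles) == 1]
  # profile support: inscribed circle of the square pattern keeps the band
  # fully inside the pattern at every rotation
  half_extent <- 0.45 * (params$grid_n - 1) * min(1, sqrt(3) / 2) * params$pitch_nm
  grid <- seq(-half_extent, half_extent, by = step_nm)
  hb <- band_width_nm / 2
  offs <- (seq_len(n_bands) - (n_bands + 1) / 2) * band_width_nm
  acc <- NULL
  n_curves <- 0L
  for (th in angles * pi / 180) {
    xr <- nodes[, 1] * cos(th) - nodes[, 2] * sin(th)
    yr <- nodes[, 1] * sin(th) + nodes[, 2] * cos(th)
    for (o in offs) {
      if (profile_of == "positions") {
        sel <- abs(yr - o) <= hb & abs(xr) < half_extent
        prof <- tabulate(floor((xr[sel] + half_extent) / step_nm) + 1L,
                         nbins = length(grid))
      } else {
        w <- stats::pnorm(o + hb, mean = yr, sd = s_tot) -
             stats::pnorm(o - hb, mean = yr, sd = s_tot)
        sel <- which(w > 1e-6 & abs(xr) < half_extent + 6 * s_tot)
        prof <- numeric(length(grid))
        for (i in sel) {
          jlo <- max(1L, ceiling((xr[i] - 6 * s_tot + half_extent) / step_nm))
          jhi <- min(length(grid), floor((xr[i] + 6 * s_tot + half_extent) / step_nm))
          if (jlo > jhi) next
          j <- jlo:jhi
          prof[j] <- prof[j] + w[i] * stats::dnorm(grid[j], mean = xr[i], sd = s_tot)
        }
      }
      if (sum(prof) == 0) next
      ac <- autocorrelate(prof, step = step_nm)
      n_curves <- n_curves + 1L
      if (is.null(acc)) acc <- ac else acc$acf <- acc$acf + ac$acf
    }
  }
  acc$acf <- acc$acf / n_curves
  # effective sample size of the averaged curve (bands/angles treated as
  # near-independent realizations for the white-noise significance bound)
  attr(acc, "n") <- length(grid) * n_curves
  class(acc) <- c("acf_curve", "data.frame")
  est <- first_peak_spacing(acc)
  est$n_angles <- length(angles)
  est
}
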