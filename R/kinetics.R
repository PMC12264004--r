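#' Nucleotide standard curve
#'
#' Linear calibration of chromatogram peak area against known nucleotide
#' concentrations. The default concentration series matches a typical
#' cGMP standard dilution row (0.05-5 mM).
#'
#' @param concentrations_mM known standard concentrations (strictly increasing)
#' @param areas measured peak areas (a.u.)
#' @return object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `fit` and the data
#' @export
standard_curve <- function(concentrations_mM = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5),
                           areas) {
  stopifnot(length(concentrations_mM) == length(areas),
            all(diff(concentrations_mM) > 0))
  fit <- stats::lm(areas ~ concentrations_mM)
  structure(list(concentrations_mM = concentrations_mM, areas = areas,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared, fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: area = %.3g * mM + %.3g (R2 = %.4f, %d standards)\n",
              x$slope, x$intercept, x$r_squared, length(x$areas)))
  invisible(x)
}

#' Quantify a nucleotide from a chromatogram peak area
#'
#' Either linear inverse prediction against a fitted standard curve, or
#' the area-ratio mode in which the analyte's fraction of the total
#' nucleotide peak area is multiplied by a known total nucleotide
#' concentration. Areas at or below blank give 0 with a `flagged`
#' attribute.
#'
#' @param peak_area measured peak area(s)
#' @param curve a [standard_curve()] (standard_curve mode)
#' @param mode `"standard_curve"` or `"area_ratio"`
#' @param total_area total nucleotide peak area (area_ratio mode)
#' @param total_mM known total nucleotide concentration (area_ratio mode)
#' @return concentration(s) in mM, with attribute `flagged` marking
#'   non-positive results clamped to 0
#' @export
quantify_nucleotide <- function(peak_area, curve = NULL,
                                mode = c("standard_curve", "area_ratio"),
                                total_area = NULL, total_mM = NULL) {
  mode <- match.arg(mode)
  if (mode == "standard_curve") {
    stopifnot(inherits(curve, "standard_curve"))
    conc <- (peak_area - curve$intercept) / curve$slope
  } else {
    stopifnot(!is.null(total_area), total_area > 0, !is.null(total_mM))
    conc <- peak_area / total_area * total_mM
  }
  flagged <- conc < 0
  conc[flagged] <- 0
  attr(conc, "flagged") <- flagged
  conc
}

#' Turnover rate from a linear time course
#'
#' Ordinary least squares on the mean product concentration per timepoint
#' (replicates are averaged first), as used for 2-3 timepoints inside the
#' enzyme's linear activity range. A single timepoint is only accepted
#' with `anchor_origin = TRUE`, which forces the line through (0, 0).
#'
#' @param t_min timepoints (min)
#' @param conc_mM product concentrations (mM), same length as `t_min`
#'   (replicates appear as repeated timepoints)
#' @param anchor_origin force the fit through the origin
#' @return list with `slope_mM_per_min`, `se`, `fit`
#' @export
linear_turnover <- function(t_min, conc_mM, anchor_origin = FALSE) {
  stopifnot(length(t_min) == length(conc_mM))
  mt <- tapply(conc_mM, t_min, mean)
  tt <- as.numeric(names(mt)); mm <- as.numeric(mt)
  if (length(tt) < 2 && !anchor_origin)
    stop("need >= 2 timepoints, or a single timepoint with anchor_origin = TRUE")
  fit <- if (anchor_origin) stats::lm(mm ~ tt + 0) else stats::lm(mm ~ tt)
  co <- summary(fit)$coefficients
  slope_row <- if (anchor_origin) "tt" else "tt"
  list(slope_mM_per_min = unname(co[slope_row, "Estimate"]),
       se = unname(co[slope_row, "Std. Error"]), fit = fit)
}

#' Fit the Hill equation to substrate-saturation data
#'
#' Nonlinear least squares of
#' \deqn{v(S) = V_{max} S^h / (K_M^h + S^h)}
#' by Levenberg-Marquardt, initialized at `Vmax0 = max(v)`, `K_M0 = S` at
#' half-max (interpolated) and `h0 = 1`. With `fix_h = 1` the model
#' reduces to Michaelis-Menten. Standard errors come from the fit's
#' variance-covariance matrix; `h` is always reported.
#'
#' @param data data.frame with columns `S_mM` and `v` (>= 3 distinct
#'   substrate levels)
#' @param fix_h optional fixed Hill coefficient
#' @param weighting `"none"` (ordinary least squares, default) or
#'   `"relative"` (weights `1/v^2`; the efficient choice when the
#'   measurement error is proportional to the rate)
#' @return object of class `hill_fit`: list with `Vmax`, `K_M`, `h`,
#'   `se` (named vector), `h_fixed`, `fitted`, `residuals`, `fit`
#' @export
fit_hill <- function(data, fix_h = NULL, weighting = c("none", "relative")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("S_mM", "v") %in% names(data)))
  S <- data$S_mM; v <- data$v
  stopifnot(all(S >= 0), length(unique(S)) >= 3)
  if (all(v == 0)) stop("all rates are zero; nothing to fit")
  wts <- if (weighting == "relative") 1 / pmax(abs(v), 1e-9)^2 else rep(1, length(v))
  vm0 <- max(v)
  mS <- tapply(v, S, mean); uS <- as.numeric(names(mS))
  k0 <- tryCatch(stats::approx(as.numeric(mS), uS, xout = vm0 / 2,
                               ties = mean)$y,
                 error = function(e) NA)
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(S[S > 0])
  df <- data.frame(S = S, v = v)
  if (is.null(fix_h)) {
    fit <- minpack.lm::nlsLM(v ~ Vmax * S^h / (K^h + S^h), data = df,
                             start = list(Vmax = vm0, K = k0, h = 1),
                             lower = c(1e-12, 1e-12, 1e-3), weights = wts,
                             control = minpack.lm::nls.lm.control(maxiter = 500,
                                                                  ftol = 1e-12))
    co <- summary(fit)$coefficients
    out <- list(Vmax = co["Vmax", 1], K_M = co["K", 1], h = co["h", 1],
                se = c(Vmax = co["Vmax", 2], K_M = co["K", 2], h = co["h", 2]),
                h_fixed = FALSE)
  } else {
    stopifnot(fix_h > 0)
    hh <- fix_h
    fit <- minpack.lm::nlsLM(v ~ Vmax * S^hh / (K^hh + S^hh), data = df,
                             start = list(Vmax = vm0, K = k0),
                             lower = c(1e-12, 1e-12), weights = wts,
                             control = minpack.lm::nls.lm.control(maxiter = 500,
                                                                  ftol = 1e-12))
    co <- summary(fit)$coefficients
    out <- list(Vmax = co["Vmax", 1], K_M = co["K", 1], h = hh,
                se = c(Vmax = co["Vmax", 2], K_M = co["K", 2], h = NA),
                h_fixed = TRUE)
  }
  out$fitted <- stats::fitted(fit)
  out$residuals <- stats::residuals(fit)
  out$fit <- fit
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: Vmax = %.4g +/- %.2g, K_M = %.4g +/- %.2g mM, h = %.3g%s\n",
              x$Vmax, x$se["Vmax"], x$K_M, x$se["K_M"], x$h,
              if (x$h_fixed) " (fixed)" else sprintf(" +/- %.2g", x$se["h"])))
  invisible(x)
}

#' Predict rates from a Hill fit
#' @param object a `hill_fit`
#' @param S_mM substrate concentrations
#' @param ... ignored
#' @return predicted rates
#' @export
predict.hill_fit <- function(object, S_mM, ...) {
  object$Vmax * S_mM^object$h / (object$K_M^object$h + S_mM^object$h)
}

#' Normalize activities by intrinsic fluorescence
#'
#' Rescales each activity by `reference / fluorescence`, correcting for
#' differing amounts of expressed photoreceptor; the first sample's
#' fluorescence is the default reference. Fold changes between samples
#' are invariant to a global fluorescence rescaling.
#'
#' @param activities activity measurements
#' @param fluorescence matching intrinsic fluorescence readouts (> 0)
#' @param reference reference fluorescence (default: first sample)
#' @return normalized activities
#' @export
normalize_by_fluorescence <- function(activities, fluorescence,
                                      reference = fluorescence[1]) {
  stopifnot(length(activities) == length(fluorescence))
  if (any(fluorescence <= 0)) stop("fluorescence readouts must be positive")
  activities * reference / fluorescence
}

#' Generate synthetic saturation kinetics data
#'
#' Rates from a Hill-model truth with multiplicative Gaussian noise:
#' `v = model(S) * (1 + N(0, noise_cv))`, per replicate, seeded. The
#' default substrate grid is the standard-curve concentration series.
#'
#' @param truth list with `Vmax`, `K_M`, `h`
#' @param S_mM substrate grid (mM)
#' @param noise_cv coefficient of variation of the multiplicative noise
#' @param n_reps replicates per substrate level
#' @param seed RNG seed
#' @param condition condition label
#' @return a `kinetics_dataset` data.frame: `condition`, `S_mM`,
#'   `replicate`, `v`
#' @export
generate_kinetics <- function(truth, S_mM = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5),
                              noise_cv = 0.05, n_reps = 3, seed = 1,
                              condition = "sim") {
  stopifnot(all(c("Vmax", "K_M") %in% names(truth)),
            truth$Vmax > 0, truth$K_M > 0)
  h <- if (is.null(truth$h)) 1 else truth$h
  set.seed(seed)
  S <- rep(S_mM, each = n_reps)
  v0 <- truth$Vmax * S^h / (truth$K_M^h + S^h)
  v <- v0 * (1 + stats::rnorm(length(S), 0, noise_cv))
  out <- data.frame(condition = condition, S_mM = S,
                    replicate = rep(seq_len(n_reps), times = length(S_mM)),
                    v = v)
  class(out) <- c("kinetics_dataset", "data.frame")
  out
}

#' Substrate grid spanning a kinetic constant
#'
#' Convenience grid `K_M * c(0.1, 0.2, 0.5, 1, 2, 3, 4)` covering 0.1x to
#' 4x the half-saturation constant, for parameter-recovery simulations of
#' enzymes whose `K_M` exceeds the standard concentration row.
#'
#' @param K_M half-saturation constant (mM)
#' @return numeric substrate grid (mM)
#' @export
hill_grid <- function(K_M) K_M * c(0.1, 0.2, 0.5, 1, 2, 3, 4)
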