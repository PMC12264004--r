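#' Thompson localization precision
#'
#' Precision of a single-molecule position estimate from photon count,
#' PSF width, pixelation and background:
#' \deqn{\sigma_{loc}^2 = \frac{s^2 + a^2/12}{N} + \frac{8\pi s^4 b^2}{a^2 N^2}}
#' where `b` is the background noise RMS in photons/pixel (for Poisson
#' background of rate lambda, `b = sqrt(lambda)`).
#'
#' @param N photons in the localization
#' @param s PSF sigma (nm)
#' @param a pixel size (nm)
#' @param b background noise RMS (photons/pixel)
#' @return precision sigma_loc (nm); arguments recycle
#' @export
thompson_precision <- function(N, s, a, b) {
  if (any(N <= 0)) stop("photon count N must be positive")
  sqrt((s^2 + a^2 / 12) / N + 8 * pi * s^4 * b^2 / (a^2 * N^2))
}

# --- detection -------------------------------------------------------------

# 1D Gaussian kernel integrated over unit pixels, radius 4 sigma
.gauss_kernel <- function(sigma_px) {
  m <- max(1L, ceiling(4 * sigma_px))
  k <- diff(stats::pnorm(seq(-m - 0.5, m + 0.5), sd = sigma_px))
  k / sum(k)
}

# band matrix applying 1D kernel along a dimension of length n
.band_matrix <- function(n, kernel) {
  m <- (length(kernel) - 1L) / 2L
  B <- matrix(0, n, n)
  for (d in seq(-m, m)) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1 & j <= n
    B[cbind(i[ok], j[ok])] <- kernel[d + m + 1L]
  }
  B
}

# detection setup shared across frames: DoG band matrices, response of a
# unit-photon centred PSF, and the kernel l2 norm for noise propagation.
# sigma2_factor sets the broad (background-estimating) scale; a wide second
# Gaussian approaches a matched filter with local-DC removal, which matters
# at the shot-noise-limited SNR of this acquisition.
.detect_setup <- function(camera, sigma2_factor = 5) {
  s_px <- camera$psf_sigma_nm / camera$pixel_size_nm
  k1 <- .gauss_kernel(s_px)
  k2 <- .gauss_kernel(sigma2_factor * s_px)
  nx <- camera$sensor_px[1]; ny <- camera$sensor_px[2]
  # PSF centred on a pixel, in 1D pixel-integral form (support covers both kernels)
  m <- max(3L, ceiling(5 * s_px), (length(k2) - 1L) %/% 2L)
  p <- diff(stats::pnorm(seq(-m - 0.5, m + 0.5), sd = s_px))
  conv_center <- function(k) {
    r <- (length(k) - 1L) / 2L
    sum(k * p[(m + 1L - r):(m + 1L + r)])
  }
  resp <- conv_center(k1)^2 - conv_center(k2)^2
  # l2 norm of the 2D DoG kernel (for white-noise propagation)
  pad <- function(k, len) { r <- (length(k) - 1L) / 2L
    v <- numeric(2 * len + 1); v[(len + 1 - r):(len + 1 + r)] <- k; v }
  L <- max((length(k1) - 1L) / 2L, (length(k2) - 1L) / 2L)
  d1 <- pad(k1, L); d2 <- pad(k2, L)
  dog2d <- outer(d1, d1) - outer(d2, d2)
  list(By1 = .band_matrix(ny, k1), Bx1 = .band_matrix(nx, k1),
       By2 = .band_matrix(ny, k2), Bx2 = .band_matrix(nx, k2),
       resp = resp, dog_l2 = sqrt(sum(dog2d^2)))
}

#' Detect candidate molecules in one frame
#'
#' Band-pass filters the frame with a difference of Gaussians at the PSF
#' scale (which cancels uniform background exactly), converts the response
#' to an equivalent photon amplitude, finds local maxima above threshold
#' and suppresses non-maxima closer than `min_separation`. Candidates
#' within `border` pixels of the sensor edge are dropped (they cannot be
#' fitted with a full ROI).
#'
#' @param frame integer/numeric matrix of photon counts
#' @param camera a [camera_model()]
#' @param threshold detection threshold in photon units; `NULL` uses
#'   `k_sigma` times the shot-noise RMS of the filtered background
#' @param min_separation minimum candidate separation (px)
#' @param k_sigma auto-threshold multiplier
#' @param border border margin (px); default half the 13-px fit ROI
#' @param setup optional precomputed [.detect_setup] result (internal reuse)
#' @return data.frame `i_px`, `j_px` (0-based row/column), `amp_photons`
#' @export
detect_spots <- function(frame, camera, threshold = NULL, min_separation = 2,
                         k_sigma = 4, border = 6L, setup = NULL) {
  stopifnot(all(frame >= 0))
  if (is.null(setup)) setup <- .detect_setup(camera)
  dog <- setup$By1 %*% frame %*% setup$Bx1 - setup$By2 %*% frame %*% setup$Bx2
  amp <- dog / setup$resp
  if (is.null(threshold)) {
    bg <- stats::median(frame)
    threshold <- k_sigma * sqrt(max(bg, 1)) * setup$dog_l2 / setup$resp
  }
  ny <- nrow(frame); nx <- ncol(frame)
  ci <- (border + 1L):(ny - border); cj <- (border + 1L):(nx - border)
  A <- amp[ci, cj]
  ismax <- A > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & A > amp[ci + di, cj + dj]
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(i_px = integer(), j_px = integer(),
                      amp_photons = numeric()))
  cand <- data.frame(i_px = idx[, 1] + border - 1L,   # back to 0-based full-frame
                     j_px = idx[, 2] + border - 1L,
                     amp_photons = A[idx])
  cand <- cand[order(-cand$amp_photons), ]
  keep <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!keep[k]) next
    d2 <- (cand$i_px - cand$i_px[k])^2 + (cand$j_px - cand$j_px[k])^2
    close <- d2 > 0 & d2 < min_separation^2
    keep[close & seq_len(nrow(cand)) > k] <- FALSE
  }
  cand <- cand[keep, ]
  rownames(cand) <- NULL
  cand
}

# --- batched Poisson MLE fitting ------------------------------------------

# Fit integrated-Gaussian PSF models to a batch of square ROIs by Fisher
# scoring on the Poisson likelihood. rois: n x (roi*roi) count matrix
# (column-major: pixel (iy, jx) at index (jx-1)*roi + iy). Returns a list
# of per-spot parameter vectors in ROI pixel units.
.fit_rois <- function(rois, camera, init, roi = 13L, fit_sigma = TRUE,
                      max_iter = 40L, tol = 1e-6, wts = NULL) {
  n <- nrow(rois)
  if (is.null(wts)) wts <- matrix(1, n, roi * roi)
  a <- camera$pixel_size_nm
  s_nom <- camera$psf_sigma_nm / a
  s_lo <- 0.5 * s_nom; s_hi <- 2 * s_nom
  np <- if (fit_sigma) 5L else 4L

  jx <- rep(seq_len(roi), each = roi)   # column index per flattened pixel
  iy <- rep(seq_len(roi), times = roi)  # row index
  edges <- 0:roi

  x <- init$x; y <- init$y
  nu <- log(pmax(init$N, 10)); be <- log(pmax(init$b, 0.05))
  u <- rep(0, n)  # logistic sigma param; 0 -> s = (s_lo+s_hi)/2... map so 0 -> s_nom
  u <- rep(stats::qlogis((s_nom - s_lo) / (s_hi - s_lo)), n)

  model <- function(x, y, nu, be, u) {
    s <- s_lo + (s_hi - s_lo) * stats::plogis(u)
    N <- exp(nu); b <- exp(be)
    hx <- (matrix(edges[-1], n, roi, byrow = TRUE) - x) / s
    lx <- (matrix(edges[-(roi + 1)], n, roi, byrow = TRUE) - x) / s
    hy <- (matrix(edges[-1], n, roi, byrow = TRUE) - y) / s
    ly <- (matrix(edges[-(roi + 1)], n, roi, byrow = TRUE) - y) / s
    ex <- stats::pnorm(hx) - stats::pnorm(lx)
    ey <- stats::pnorm(hy) - stats::pnorm(ly)
    phx <- stats::dnorm(hx); plx <- stats::dnorm(lx)
    phy <- stats::dnorm(hy); ply <- stats::dnorm(ly)
    list(s = s, N = N, b = b, ex = ex, ey = ey,
         dex_dx = -(phx - plx) / s, dey_dy = -(phy - ply) / s,
         dex_ds = -(hx * phx - lx * plx) / s,
         dey_ds = -(hy * phy - ly * ply) / s)
  }

  nll_of <- function(m) {
    mu <- m$b + m$N * m$ex[, jx, drop = FALSE] * m$ey[, iy, drop = FALSE]
    mu <- pmax(mu, 1e-9)
    rowSums(wts * (mu - rois * log(mu)))
  }

  m <- model(x, y, nu, be, u)
  nll <- nll_of(m)
  lambda <- rep(1e-3, n)
  active <- rep(TRUE, n)
  converged <- rep(FALSE, n)
  iters <- rep(0L, n)

  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    exj <- m$ex[, jx, drop = FALSE]; eyi <- m$ey[, iy, drop = FALSE]
    spot <- m$N * exj * eyi
    mu <- pmax(m$b + spot, 1e-9)
    r <- rois / mu - 1
    g <- vector("list", np)
    g[[1]] <- m$N * m$dex_dx[, jx, drop = FALSE] * eyi
    g[[2]] <- m$N * exj * m$dey_dy[, iy, drop = FALSE]
    g[[3]] <- spot            # d mu / d log N
    g[[4]] <- matrix(m$b, n, roi * roi)
    if (fit_sigma) {
      dsdu <- (s_hi - s_lo) * stats::plogis(u) * (1 - stats::plogis(u))
      g[[5]] <- m$N * (m$dex_ds[, jx, drop = FALSE] * eyi +
                       exj * m$dey_ds[, iy, drop = FALSE]) * dsdu
    }
    score <- do.call(cbind, lapply(g, function(gp) rowSums(wts * r * gp)))
    FI <- array(0, c(n, np, np))
    for (p in seq_len(np)) for (q in p:np) {
      v <- rowSums(wts * g[[p]] * g[[q]] / mu)
      FI[, p, q] <- v; FI[, q, p] <- v
    }
    idx_active <- which(active)
    prop <- matrix(0, n, np)
    ok <- rep(FALSE, n)
    for (k in idx_active) {
      Ik <- FI[k, , ] + diag(lambda[k] * pmax(diag(FI[k, , ]), 1e-8), np)
      d <- tryCatch(solve(Ik, score[k, ]), error = function(e) NULL)
      if (!is.null(d) && all(is.finite(d))) {
        d <- pmin(pmax(d, -2), 2)  # trust region in px / log units
        prop[k, ] <- d; ok[k] <- TRUE
      }
    }
    x2 <- x; y2 <- y; nu2 <- nu; be2 <- be; u2 <- u
    x2[ok] <- pmin(pmax(x[ok] + prop[ok, 1], 0.5), roi - 0.5)
    y2[ok] <- pmin(pmax(y[ok] + prop[ok, 2], 0.5), roi - 0.5)
    nu2[ok] <- pmin(pmax(nu[ok] + prop[ok, 3], 0), 12)
    be2[ok] <- pmin(pmax(be[ok] + prop[ok, 4], -7), 12)
    if (fit_sigma) u2[ok] <- pmin(pmax(u[ok] + prop[ok, 5], -8), 8)
    m2 <- model(x2, y2, nu2, be2, u2)
    nll2 <- nll_of(m2)
    better <- ok & active & (nll2 < nll)
    worse <- active & !better
    x[better] <- x2[better]; y[better] <- y2[better]
    nu[better] <- nu2[better]; be[better] <- be2[better]
    u[better] <- u2[better]
    improved <- nll[better] - nll2[better]
    conv_now <- better
    conv_now[better] <- improved < tol
    converged[conv_now] <- TRUE
    active[conv_now] <- FALSE
    nll[better] <- nll2[better]
    lambda[better] <- pmax(lambda[better] / 3, 1e-7)
    lambda[worse] <- pmin(lambda[worse] * 8, 1e6)
    # repeated rejection at maximum damping: converged to a stationary point
    stuck <- worse & lambda >= 1e6
    converged[stuck] <- TRUE
    active[stuck] <- FALSE
    iters[active] <- it
    m <- model(x, y, nu, be, u)
  }
  s <- s_lo + (s_hi - s_lo) * stats::plogis(u)
  # deviance-based fit quality per degree of freedom
  mu <- pmax(m$b + m$N * m$ex[, jx, drop = FALSE] * m$ey[, iy, drop = FALSE], 1e-9)
  kk <- rois
  devterm <- ifelse(kk > 0, kk * log(kk / mu), 0) - (kk - mu)
  quality <- 2 * rowSums(wts * devterm) / pmax(rowSums(wts) - np, 1)
  list(x_px = x, y_px = y, photons = exp(nu), b_rate = exp(be),
       sigma_px = s, quality = quality,
       converged = converged, iterations = iters)
}

#' Fit a single spot ROI
#'
#' Maximum-likelihood fit of one integrated-Gaussian spot under Poisson
#' noise. Positions are returned in nm relative to the top-left corner of
#' the ROI; the PSF width is fitted freely within [0.5, 2] times the
#' nominal width unless `fit_sigma = FALSE`.
#'
#' @param roi square count matrix (rows = y) containing one candidate
#' @param camera a [camera_model()]
#' @param init optional list with starting values `x_px`, `y_px` (ROI
#'   pixel units), `N`, `b`
#' @param fit_sigma fit the PSF width (default) or fix it at nominal
#' @return one-row data.frame: `x_nm`, `y_nm`, `photons`, `background`
#'   (RMS photons/pixel), `sigma_nm`, `precision_nm`, `quality`, `converged`
#' @export
fit_spot <- function(roi, camera, init = NULL, fit_sigma = TRUE) {
  roi <- as.matrix(roi)
  stopifnot(nrow(roi) == ncol(roi))
  rs <- nrow(roi)
  if (rs < ceiling(6 * camera$psf_sigma_nm / camera$pixel_size_nm))
    stop("ROI smaller than 2 x 3 psf_sigma")
  if (is.null(init)) {
    b0 <- stats::median(roi)
    init <- list(x = rs / 2, y = rs / 2,
                 N = max(sum(roi) - b0 * rs * rs, 30), b = max(b0, 0.05))
  } else {
    init <- list(x = init$x_px, y = init$y_px, N = init$N, b = init$b)
  }
  f <- .fit_rois(matrix(as.numeric(roi), nrow = 1), camera,
                 lapply(init, as.numeric), roi = rs, fit_sigma = fit_sigma)
  a <- camera$pixel_size_nm
  data.frame(x_nm = f$x_px * a, y_nm = f$y_px * a, photons = f$photons,
             background = sqrt(f$b_rate), sigma_nm = f$sigma_px * a,
             precision_nm = thompson_precision(f$photons, f$sigma_px * a, a,
                                               sqrt(f$b_rate)),
             quality = f$quality, converged = f$converged)
}

# fit all candidates of a chunk of frames; frames is ny x nx x k array,
# cand has columns frame (index into 3rd dim), i_px, j_px, amp_photons.
# mask: optional data.frame (chunk_k, i_px, j_px) of emitter positions
# whose surrounding pixels (mask_radius_px) are excluded from other
# spots' likelihoods, suppressing neighbour contamination in dense frames
.fit_candidates <- function(frames, cand, camera, roi_size = 13L,
                            fit_sigma = TRUE, batch = 4000L,
                            mask = NULL, mask_radius_px = 2) {
  if (!nrow(cand))
    return(data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                      photons = numeric(), background = numeric(),
                      sigma_nm = numeric(), precision_nm = numeric(),
                      quality = numeric(), converged = logical()))
  half <- (roi_size - 1L) %/% 2L
  a <- camera$pixel_size_nm
  out <- vector("list", ceiling(nrow(cand) / batch))
  for (bi in seq_along(out)) {
    rows <- ((bi - 1L) * batch + 1L):min(bi * batch, nrow(cand))
    cb <- cand[rows, ]
    n <- nrow(cb)
    rois <- matrix(0, n, roi_size * roi_size)
    for (k in seq_len(n)) {
      i0 <- cb$i_px[k] + 1L; j0 <- cb$j_px[k] + 1L
      rois[k, ] <- as.numeric(frames[(i0 - half):(i0 + half),
                                     (j0 - half):(j0 + half), cb$chunk_k[k]])
    }
    wts <- NULL
    if (!is.null(mask) && nrow(mask)) {
      mask_by_k <- split(mask[c("i_px", "j_px")], mask$chunk_k)
      wts <- matrix(1, n, roi_size * roi_size)
      mjx <- rep(seq_len(roi_size), each = roi_size)
      miy <- rep(seq_len(roi_size), times = roi_size)
      for (k in seq_len(n)) {
        mm <- mask_by_k[[as.character(cb$chunk_k[k])]]
        if (is.null(mm) || !nrow(mm)) next
        # other emitters only: keep anything close to this candidate
        dd <- sqrt((mm$i_px - cb$i_px[k])^2 + (mm$j_px - cb$j_px[k])^2)
        mm <- mm[dd > 2.5 & dd < roi_size, , drop = FALSE]
        if (!nrow(mm)) next
        # ROI-local (1-based) coordinates of the maskers
        ri <- mm$i_px - cb$i_px[k] + half + 1L
        rj <- mm$j_px - cb$j_px[k] + half + 1L
        w <- wts[k, ]
        for (q in seq_len(nrow(mm)))
          w[(mjx - rj[q])^2 + (miy - ri[q])^2 <= mask_radius_px^2] <- 0
        wts[k, ] <- w
      }
    }
    b0 <- apply(rois, 1, stats::median)
    init <- list(x = rep(half + 0.5, n), y = rep(half + 0.5, n),
                 N = pmax(cb$amp_photons, 30), b = pmax(b0, 0.05))
    f <- .fit_rois(rois, camera, init, roi = roi_size, fit_sigma = fit_sigma,
                   wts = wts)
    out[[bi]] <- data.frame(
      frame = cb$frame,
      x_nm = (cb$j_px - half + f$x_px) * a,
      y_nm = (cb$i_px - half + f$y_px) * a,
      photons = f$photons, background = sqrt(f$b_rate),
      sigma_nm = f$sigma_px * a,
      precision_nm = thompson_precision(f$photons, f$sigma_px * a, a,
                                        sqrt(f$b_rate)),
      quality = f$quality, converged = f$converged)
  }
  do.call(rbind, out)
}

.empty_loc_table <- function() {
  data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
             photons = numeric(), background = numeric(),
             sigma_nm = numeric(), precision_nm = numeric(),
             quality = numeric(), converged = logical())
}

.as_loc_table <- function(df, camera) {
  df <- df[order(df$frame), ]
  rownames(df) <- NULL
  attr(df, "camera") <- camera
  class(df) <- c("localization_table", "data.frame")
  df
}

#' Localize an in-memory frame stack
#'
#' Runs spot detection and Poisson-MLE fitting on every frame of a
#' [render_frames()] stack. Images acquired with EM gain are first
#' converted back to photon units by dividing by the gain.
#'
#' @param stack a `frame_stack`
#' @param threshold,min_separation,k_sigma see [detect_spots()]
#' @param roi_size fit ROI side (px, odd)
#' @param fit_sigma fit the PSF width freely (bounded) or fix it
#' @param mask_k_sigma threshold multiplier of a second, more permissive
#'   detection pass whose candidates are masked out of other spots'
#'   fit likelihoods (suppresses neighbour contamination in crowded
#'   frames); `NULL` disables masking
#' @return a `localization_table` data.frame with columns `frame`, `x_nm`,
#'   `y_nm`, `photons`, `background`, `sigma_nm`, `precision_nm`,
#'   `quality`, `converged`, `crowded`
#' @export
localize_stack <- function(stack, threshold = NULL, min_separation = 2,
                           k_sigma = 4, roi_size = 13L, fit_sigma = TRUE,
                           mask_k_sigma = 3) {
  camera <- stack$camera
  arr <- stack$frames
  if (camera$em_gain > 1) arr <- arr / camera$em_gain
  setup <- .detect_setup(camera)
  half <- (roi_size - 1L) %/% 2L
  ny <- dim(arr)[1]; nx <- dim(arr)[2]
  # one permissive detection pass; candidates above the fit threshold are
  # fitted, the rest only mask pixels in other spots' likelihoods
  k_detect <- if (is.null(mask_k_sigma)) k_sigma else min(k_sigma, mask_k_sigma)
  cands <- vector("list", dim(arr)[3])
  masks <- vector("list", dim(arr)[3])
  for (k in seq_len(dim(arr)[3])) {
    cd <- detect_spots(arr[, , k], camera, threshold, min_separation,
                       k_detect, border = 1L, setup = setup)
    if (!nrow(cd)) next
    if (!is.null(mask_k_sigma)) {
      cd$chunk_k <- k
      masks[[k]] <- cd
    }
    if (is.null(threshold)) {
      bg <- stats::median(arr[, , k])
      thr_fit <- k_sigma * sqrt(max(bg, 1)) * setup$dog_l2 / setup$resp
    } else thr_fit <- threshold
    keep <- cd$amp_photons >= thr_fit &
      cd$i_px >= half & cd$i_px < ny - half &
      cd$j_px >= half & cd$j_px < nx - half
    cd <- cd[keep, , drop = FALSE]
    if (nrow(cd)) {
      cd$frame <- stack$frame_index[k]
      cd$chunk_k <- k
      cands[[k]] <- cd
    }
  }
  cand <- do.call(rbind, cands)
  mask <- do.call(rbind, masks)
  if (is.null(cand)) return(.as_loc_table(.empty_loc_table(), camera))
  # flag candidates with a same-frame neighbour close enough to leak into
  # the fit ROI; downstream robust centroids can exclude them
  cand$crowded <- FALSE
  for (f in unique(cand$frame)) {
    i <- which(cand$frame == f)
    if (length(i) < 2) next
    d <- as.matrix(stats::dist(cand[i, c("i_px", "j_px")]))
    diag(d) <- Inf
    cand$crowded[i] <- apply(d, 1, min) < roi_size
  }
  out <- .fit_candidates(arr, cand, camera, roi_size, fit_sigma, mask = mask)
  out$crowded <- cand$crowded
  .as_loc_table(out, camera)
}

#' Simulate and localize a movie in chunks
#'
#' Renders the movie of a state trajectory chunk by chunk (never holding
#' the whole stack in memory), detecting and fitting spots as it goes.
#' Equivalent to [render_frames()] followed by [localize_stack()] but
#' scales to 10,000-frame acquisitions.
#'
#' @param emitters an `emitter_field`
#' @param trajectory a `state_trajectory`
#' @param camera a [camera_model()]
#' @param drift optional `drift_trajectory` applied to the ground truth
#' @param seed RNG seed for the rendering noise
#' @param chunk_size frames rendered per chunk
#' @param ... passed to [localize_stack()]
#' @return a `localization_table`
#' @export
localize_movie <- function(emitters, trajectory, camera, drift = NULL,
                           seed = 1, chunk_size = 250L, ...) {
  set.seed(seed)
  n <- trajectory$n_frames
  starts <- seq(1L, n, by = chunk_size)
  parts <- vector("list", length(starts))
  for (ci in seq_along(starts)) {
    fr <- starts[ci]:min(starts[ci] + chunk_size - 1L, n)
    stack <- render_frames(emitters, trajectory, camera, frames = fr,
                           drift = drift, seed = NULL)
    parts[[ci]] <- localize_stack(stack, ...)
  }
  .as_loc_table(do.call(rbind, parts), camera)
}

#' Filter a localization table
#'
#' Row subset preserving order; the number of removed rows is recorded in
#' the `n_removed` attribute. Empty criteria return the table unchanged.
#'
#' @param table a `localization_table`
#' @param min_photons keep rows with at least this many photons
#' @param max_precision keep rows with precision at most this (nm)
#' @param max_quality keep rows with fit quality (deviance/df) at most this
#' @param converged_only drop localizations whose fit did not converge
#' @return filtered `localization_table`
#' @export
filter_localizations <- function(table, min_photons = NULL,
                                 max_precision = NULL, max_quality = NULL,
                                 converged_only = FALSE) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(min_photons)) keep <- keep & table$photons >= min_photons
  if (!is.null(max_precision)) keep <- keep & table$precision_nm <= max_precision
  if (!is.null(max_quality)) keep <- keep & table$quality <= max_quality
  if (converged_only && "converged" %in% names(table))
    keep <- keep & table$converged
  out <- table[keep, ]
  rownames(out) <- NULL
  attr(out, "camera") <- attr(table, "camera")
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- class(table)
  out
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("Localization table: %d localizations over %d frames\n",
              nrow(x), length(unique(x$frame))))
  if (nrow(x))
    cat(sprintf("  mean photons %.0f, mean precision %.1f nm\n",
                mean(x$photons), mean(x$precision_nm)))
  NextMethod()
}
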