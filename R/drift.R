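#' Estimate lateral drift by temporal-block cross-correlation
#'
#' Splits the localizations into `n_blocks` contiguous temporal blocks
#' rendered as 2D histograms at `render_pixel` nm and estimates a per-block
#' offset, interpolated to per-frame drift with a monotone
#' (Fritsch-Carlson) cubic. The first block is anchored at (0, 0).
#'
#' Three correlation modes are available:
#' \describe{
#'   \item{`reference` (default)}{each block image is cross-correlated
#'     against the pooled, leave-block-out image of all other blocks.
#'     Estimation is iterated (`n_iter` passes), rebuilding the
#'     reference from drift-corrected positions, so the reference
#'     sharpens as the drift estimate improves. This mode is much more
#'     precise than pairwise correlation at low per-block counts,
#'     because every block is registered against nearly the whole
#'     data set instead of one other sparse block.}
#'   \item{`consecutive`}{classic chained cross-correlation of
#'     consecutive block images.}
#'   \item{`to_first`}{every block correlated against the first.}
#' }
#' All modes locate peaks with subpixel 3-point parabolic interpolation.
#'
#' @param table a `localization_table`
#' @param n_blocks number of temporal blocks (>= 2)
#' @param render_pixel histogram bin size (nm)
#' @param mode correlation mode, see Details
#' @param min_per_block minimum localizations required per block
#' @param max_shift_frac peak search radius as a fraction of image size
#' @param smooth_nm Gaussian sigma of the block/reference smoothing (nm)
#' @param n_iter reference-mode refinement passes
#' @param fine logical; optionally refine each
#'   block on a finer grid with the peak search restricted to less than
#'   half the expected structure period (`fine_max_shift_nm`), so that
#'   registration cannot snap to a neighbouring lattice alignment on
#'   periodic specimens
#' @param fine_render,fine_smooth,fine_iter,fine_max_shift_nm fine-stage
#'   grid pixel, smoothing, passes and search radius (nm)
#' @param n_frames number of frames the returned trajectory must cover
#'   (default: the table's last frame)
#' @return a `drift_trajectory` data.frame (`frame`, `dx_nm`, `dy_nm`)
#'   covering frames 1..n_frames, with block anchors attached as the
#'   `anchors` attribute
#' @export
estimate_drift <- function(table, n_blocks = 10, render_pixel = 25,
                           mode = c("reference", "consecutive", "to_first"),
                           min_per_block = 50, max_shift_frac = 0.25,
                           smooth_nm = 40, n_iter = 3,
                           fine = FALSE, fine_render = 8, fine_smooth = 10,
                           fine_iter = 3, fine_max_shift_nm = 18,
                           n_frames = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_blocks >= 2)
  if (is.null(n_frames)) n_frames <- max(table$frame)
  breaks <- round(seq(0, max(table$frame), length.out = n_blocks + 1))
  block <- cut(table$frame, breaks, labels = FALSE)
  counts <- tabulate(block, n_blocks)
  if (any(counts < min_per_block))
    stop(sprintf("each temporal block needs >= %d localizations (worst block has %d)",
                 min_per_block, min(counts)))

  bx <- split(table$x_nm, block); by <- split(table$y_nm, block)
  bf <- split(table$frame, block)
  anchors <- (breaks[-1] + breaks[-(n_blocks + 1)] + 1) / 2
  off <- matrix(0, n_blocks, 2)

  # machinery for one grid resolution: histogram, smoothing, CC peak
  make_stage <- function(render_px, smooth, rmax_px = NULL) {
    pad <- max(20 * render_px, 800)
    x0 <- min(table$x_nm) - pad; y0 <- min(table$y_nm) - pad
    nxb <- ceiling((max(table$x_nm) + pad - x0) / render_px)
    nyb <- ceiling((max(table$y_nm) + pad - y0) / render_px)
    if (is.null(rmax_px)) rmax_px <- max_shift_frac * min(nyb, nxb)
    ks <- .gauss_kernel(smooth / render_px)
    By <- .band_matrix(nyb, ks); Bx <- .band_matrix(nxb, ks)
    hist2d <- function(x, y) {
      jx <- pmin(pmax(floor((x - x0) / render_px) + 1L, 1L), nxb)
      iy <- pmin(pmax(floor((y - y0) / render_px) + 1L, 1L), nyb)
      h <- matrix(0, nyb, nxb)
      tb <- table(factor(iy, levels = seq_len(nyb)),
                  factor(jx, levels = seq_len(nxb)))
      h + as.numeric(tb)
    }
    xcorr_shift <- function(A, B, center = TRUE) {
      ny <- 2L * nyb; nx <- 2L * nxb
      pa <- matrix(0, ny, nx); pb <- matrix(0, ny, nx)
      pa[seq_len(nyb), seq_len(nxb)] <- if (center) A - mean(A) else A
      pb[seq_len(nyb), seq_len(nxb)] <- if (center) B - mean(B) else B
      cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb), inverse = TRUE))
      sy <- c(0:(ny / 2 - 1), -(ny / 2):-1)
      sx <- c(0:(nx / 2 - 1), -(nx / 2):-1)
      ok <- outer(abs(sy) <= rmax_px, abs(sx) <= rmax_px)
      cc[!ok] <- -Inf
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      para <- function(cm, c0, cp) {
        den <- cm - 2 * c0 + cp
        if (!is.finite(cm) || !is.finite(cp) || !is.finite(den) || den >= 0) 0
        else min(max(0.5 * (cm - cp) / den, -0.5), 0.5)
      }
      wrap <- function(i, n) ((i - 1) %% n) + 1
      iy <- pk[1]; jx <- pk[2]
      dy <- sy[iy] + para(cc[wrap(iy - 1, ny), jx], cc[iy, jx], cc[wrap(iy + 1, ny), jx])
      dx <- sx[jx] + para(cc[iy, wrap(jx - 1, nx)], cc[iy, jx], cc[iy, wrap(jx + 1, nx)])
      c(dx, dy) * render_px
    }
    list(hist2d = hist2d, smooth = function(h) By %*% h %*% Bx,
         xcorr_shift = xcorr_shift)
  }

  # per-localization correction from the interpolated block offsets, so
  # intra-block drift smear shrinks as the iterations converge; linear
  # extrapolation beyond the end anchors keeps the end blocks unskewed
  interp_at <- function(v, f) {
    fn <- stats::splinefun(anchors, v, method = "monoH.FC")
    out <- fn(f)
    s1 <- (v[2] - v[1]) / (anchors[2] - anchors[1])
    s2 <- (v[n_blocks] - v[n_blocks - 1]) / (anchors[n_blocks] - anchors[n_blocks - 1])
    lo <- f < anchors[1]; hi <- f > anchors[n_blocks]
    out[lo] <- v[1] + s1 * (f[lo] - anchors[1])
    out[hi] <- v[n_blocks] + s2 * (f[hi] - anchors[n_blocks])
    out
  }
  reference_passes <- function(stage, iters, off) {
    for (iter in seq_len(iters)) {
      kde <- vector("list", n_blocks)
      for (b in seq_len(n_blocks))
        kde[[b]] <- stage$smooth(stage$hist2d(
          bx[[b]] - interp_at(off[, 1], bf[[b]]),
          by[[b]] - interp_at(off[, 2], bf[[b]])))
      pooled <- Reduce(`+`, kde)
      for (b in seq_len(n_blocks)) {
        ref <- pooled - kde[[b]]
        off[b, ] <- off[b, ] + stage$xcorr_shift(ref, kde[[b]])
      }
    }
    off
  }

  if (mode == "reference") {
    off <- reference_passes(make_stage(render_pixel, smooth_nm), n_iter, off)
    if (fine)
      off <- reference_passes(
        make_stage(fine_render, fine_smooth, fine_max_shift_nm / fine_render),
        fine_iter, off)
    off[, 1] <- off[, 1] - off[1, 1]
    off[, 2] <- off[, 2] - off[1, 2]
  } else {
    stage <- make_stage(render_pixel, smooth_nm)
    H <- lapply(seq_len(n_blocks), function(b) stage$smooth(stage$hist2d(bx[[b]], by[[b]])))
    if (mode == "consecutive") {
      for (b in 2:n_blocks)
        off[b, ] <- off[b - 1, ] + stage$xcorr_shift(H[[b - 1]], H[[b]])
    } else {
      for (b in 2:n_blocks)
        off[b, ] <- stage$xcorr_shift(H[[1]], H[[b]])
    }
  }

  fr <- seq_len(n_frames)
  interp <- function(v) {
    f <- stats::splinefun(anchors, v, method = "monoH.FC")
    out <- f(fr)
    # linear extrapolation beyond the end anchors with the boundary slopes
    s1 <- (v[2] - v[1]) / (anchors[2] - anchors[1])
    s2 <- (v[n_blocks] - v[n_blocks - 1]) / (anchors[n_blocks] - anchors[n_blocks - 1])
    lo <- fr < anchors[1]; hi <- fr > anchors[n_blocks]
    out[lo] <- v[1] + s1 * (fr[lo] - anchors[1])
    out[hi] <- v[n_blocks] + s2 * (fr[hi] - anchors[n_blocks])
    out
  }
  out <- data.frame(frame = fr, dx_nm = interp(off[, 1]), dy_nm = interp(off[, 2]))
  attr(out, "anchors") <- data.frame(frame = anchors,
                                     dx_nm = off[, 1], dy_nm = off[, 2])
  attr(out, "mode") <- mode
  class(out) <- c("drift_trajectory", "data.frame")
  out
}

#' Remove drift from a localization table
#'
#' Subtracts the per-frame interpolated drift from every localization.
#' A zero trajectory is the identity.
#'
#' @param table a `localization_table`
#' @param trajectory a `drift_trajectory` covering the table's frame range
#' @return corrected `localization_table` (attribute `drift_corrected` set)
#' @export
correct_drift <- function(table, trajectory) {
  if (any(table$frame < min(trajectory$frame)) ||
      any(table$frame > max(trajectory$frame)))
    stop("trajectory does not cover the table's frame range")
  i <- match(table$frame, trajectory$frame)
  table$x_nm <- table$x_nm - trajectory$dx_nm[i]
  table$y_nm <- table$y_nm - trajectory$dy_nm[i]
  attr(table, "drift_corrected") <- TRUE
  table
}
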