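#' Merge localizations into blink events
#'
#' Greedy temporal linkage: localizations are scanned in frame order; a
#' localization joins an open event when it lies within `radius` of the
#' event centroid and within `max_dark_frames` dark frames of the event's
#' last frame; otherwise it opens a new event. Ties are broken by nearest
#' centroid. Events are closed once stale. The result is deterministic
#' given the input order.
#'
#' @param table a drift-corrected `localization_table`
#' @param radius linkage radius (nm); `NULL` uses 3 x the table's mean
#'   localization precision
#' @param max_dark_frames maximum dark (gap) frames inside one event
#' @return object of class `blink_events`: list with `events` (data.frame
#'   `event_id`, `x_nm`, `y_nm`, `first_frame`, `last_frame`, `n_locs`,
#'   `total_photons`, `precision_nm`), `members` (list of row indices into
#'   `table`), `radius`, `max_dark_frames`
#' @export
merge_into_events <- function(table, radius = NULL, max_dark_frames = 2) {
  if (max_dark_frames < 0) stop("max_dark_frames must be >= 0")
  if (is.null(radius)) radius <- 3 * mean(table$precision_nm)
  if (radius < 0) stop("radius must be >= 0")
  ord <- order(table$frame)
  x <- table$x_nm[ord]; y <- table$y_nm[ord]; fr <- table$frame[ord]
  w <- if ("precision_nm" %in% names(table))
    1 / pmax(table$precision_nm[ord], 1e-3)^2 else rep(1, length(ord))
  n <- length(x)
  ev_of <- integer(n)
  # open-event registers (grown geometrically)
  cap <- 256L
  cx <- numeric(cap); cy <- numeric(cap); cw <- numeric(cap)
  last <- integer(cap); first <- integer(cap); nl <- integer(cap)
  open <- integer(0)
  n_ev <- 0L
  for (k in seq_len(n)) {
    f <- fr[k]
    if (length(open)) {
      stale <- f - last[open] > max_dark_frames + 1L
      open <- open[!stale]
    }
    hit <- 0L
    if (length(open)) {
      d2 <- (cx[open] - x[k])^2 + (cy[open] - y[k])^2
      j <- which.min(d2)
      if (d2[j] <= radius^2) hit <- open[j]
    }
    if (hit) {
      cw[hit] <- cw[hit] + w[k]
      cx[hit] <- cx[hit] + (x[k] - cx[hit]) * w[k] / cw[hit]
      cy[hit] <- cy[hit] + (y[k] - cy[hit]) * w[k] / cw[hit]
      last[hit] <- f; nl[hit] <- nl[hit] + 1L
      ev_of[k] <- hit
    } else {
      n_ev <- n_ev + 1L
      if (n_ev > cap) {
        cap <- cap * 2L
        length(cx) <- cap; length(cy) <- cap; length(cw) <- cap
        length(last) <- cap; length(first) <- cap; length(nl) <- cap
      }
      cx[n_ev] <- x[k]; cy[n_ev] <- y[k]; cw[n_ev] <- w[k]
      first[n_ev] <- f; last[n_ev] <- f; nl[n_ev] <- 1L
      open <- c(open, n_ev)
      ev_of[k] <- n_ev
    }
  }
  members <- split(ord, ev_of)
  members <- members[order(as.integer(names(members)))]
  ids <- seq_len(n_ev)
  photons <- vapply(members, function(m) sum(table$photons[m]), numeric(1))
  prec <- vapply(members, function(m) {
    if ("precision_nm" %in% names(table))
      sqrt(1 / sum(1 / pmax(table$precision_nm[m], 1e-3)^2))
    else NA_real_
  }, numeric(1))
  events <- data.frame(event_id = ids, x_nm = cx[ids], y_nm = cy[ids],
                       first_frame = first[ids], last_frame = last[ids],
                       n_locs = nl[ids], total_photons = photons,
                       precision_nm = prec)
  structure(list(events = events, members = unname(members),
                 radius = radius, max_dark_frames = max_dark_frames),
            class = "blink_events")
}

#' @export
print.blink_events <- function(x, ...) {
  cat(sprintf("Blink events: %d events (radius %.0f nm, max dark frames %d)\n",
              nrow(x$events), x$radius, x$max_dark_frames))
  invisible(x)
}

#' Blink events as a localization-style table
#'
#' One row per event with the inverse-variance-weighted centroid, summed
#' photons and the combined (grouped) precision, suitable for
#' [render_thompson()] of a grouped reconstruction.
#'
#' With `table` supplied, robust (median) centroids are recomputed from
#' the member localizations, preferring members that were not flagged as
#' crowded (another candidate near the fit ROI in the same frame) —
#' crowding biases all of a neighbour-overlapped spell's fits in the same
#' direction, which a weighted mean cannot remove.
#'
#' @param events a `blink_events`
#' @param table the localization table the events were merged from
#'   (enables robust centroids)
#' @param min_locs keep only events with at least this many localizations
#' @param min_clean minimum uncrowded members required before restricting
#'   the robust centroid to them
#' @return a `localization_table`-like data.frame
#' @export
events_to_table <- function(events, table = NULL, min_locs = 1,
                            min_clean = 5) {
  keep <- events$events$n_locs >= min_locs
  ev <- events$events[keep, ]
  x <- ev$x_nm; y <- ev$y_nm
  prec <- ev$precision_nm
  if (!is.null(table)) {
    members <- events$members[keep]
    has_crowd <- "crowded" %in% names(table)
    for (i in seq_along(members)) {
      m <- members[[i]]
      if (has_crowd) {
        clean <- m[!table$crowded[m]]
        if (length(clean) >= min_clean) m <- clean
      }
      x[i] <- stats::median(table$x_nm[m])
      y[i] <- stats::median(table$y_nm[m])
      # median efficiency relative to the mean
      prec[i] <- sqrt(pi / 2) * sqrt(1 / sum(1 / pmax(table$precision_nm[m], 1e-3)^2))
    }
  }
  out <- data.frame(frame = ev$first_frame, x_nm = x, y_nm = y,
                    photons = ev$total_photons, background = NA_real_,
                    sigma_nm = NA_real_, precision_nm = prec,
                    quality = NA_real_, converged = TRUE)
  class(out) <- c("localization_table", "data.frame")
  out
}

#' Estimate the number of molecules from blink events
#'
#' In the post-bleach, low-dose reactivation regime each blink event is
#' attributed to one molecule (`events_as_molecules`); when the mean
#' number of reactivation events per molecule is known, the count can be
#' corrected for recurrence.
#'
#' @param events a `blink_events`
#' @param mode counting mode
#' @param recurrence_mean mean events per molecule (>= 1), used by
#'   `recurrence_corrected`
#' @return integer molecule count estimate
#' @export
count_molecules <- function(events,
                            mode = c("events_as_molecules", "recurrence_corrected"),
                            recurrence_mean = 1) {
  mode <- match.arg(mode)
  n_ev <- nrow(events$events)
  if (n_ev == 0) {
    warning("empty event set: molecule count is 0")
    return(0L)
  }
  if (mode == "events_as_molecules") return(n_ev)
  if (recurrence_mean < 1) stop("recurrence_mean must be >= 1")
  as.integer(round(n_ev / recurrence_mean))
}

#' Summarize per-cell molecule counts across a cohort
#'
#' @param counts integer vector of per-cell molecule counts
#' @return object of class `cell_count_summary`: list with `counts`,
#'   `mean`, `sd` (sample SD, n-1 denominator; 0 with `sd_defined = FALSE`
#'   for a single cell) and `n`
#' @export
summarize_cohort <- function(counts) {
  stopifnot(length(counts) >= 1, all(counts >= 0))
  n <- length(counts)
  s <- if (n > 1) stats::sd(counts) else 0
  structure(list(counts = counts, mean = mean(counts), sd = s,
                 sd_defined = n > 1, n = n),
            class = "cell_count_summary")
}

#' @export
print.cell_count_summary <- function(x, ...) {
  cat(sprintf("Cohort: %.0f +/- %.0f molecules per cell (n = %d%s)\n",
              x$mean, x$sd, x$n,
              if (!x$sd_defined) ", SD undefined for n = 1" else ""))
  invisible(x)
}

#' Crop a localization table to the rumposome band region
#'
#' The analysis treats one table as one cell; this performs the upstream
#' cropping to the fluorescent organelle: localizations within `margin`
#' of the band's annular sector are kept.
#'
#' @param table a `localization_table`
#' @param geometry the [rumposome_geometry()] of the cell
#' @param margin extra distance around the band (nm)
#' @return cropped `localization_table`
#' @export
crop_to_band <- function(table, geometry, margin = 300) {
  dx <- table$x_nm - geometry$center[1]
  dy <- table$y_nm - geometry$center[2]
  r0 <- geometry$band_arc_radius_um * 1000
  hw <- geometry$band_width_nm / 2 + margin
  half_span <- geometry$band_arc_span_deg / 2 * pi / 180
  rad <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  extra_ang <- margin / r0
  keep <- abs(rad - r0) <= hw & abs(ang) <= half_span + extra_ang
  out <- table[keep, ]
  rownames(out) <- NULL
  attr(out, "camera") <- attr(table, "camera")
  class(out) <- class(table)
  out
}
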