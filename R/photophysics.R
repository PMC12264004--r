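#' Photophysics parameters for photoswitching simulation
#'
#' Discrete-frame two-step photoswitching model: molecules start DARK
#' (post-bleach regime), are reactivated (DARK -> ON) at a controller-set
#' per-frame probability emulating the ramped 405 nm laser, and while ON
#' either stay ON, return to DARK (readout-driven off-switching,
#' `p_off`) or photobleach irreversibly (`p_bleach`) at the end of each
#' frame. ON spells therefore last at least one frame, with geometric
#' duration of mean `1 / (p_off + p_bleach)` frames.
#'
#' Photons emitted per ON frame follow `photon_model`: `"poisson"`
#' (default; photon count of a constant-rate emitter integrated over a
#' fixed frame time), `"geometric"` (heavy-tailed burst-total style
#' emission) or `"constant"`.
#'
#' Fixture defaults give a mean ON spell of ~4 frames (140 ms) and ~1.05
#' activation spells per molecule, emulating a counting-friendly
#' post-bleach low-dose reactivation regime.
#'
#' @param p_off per-frame ON -> DARK probability
#' @param p_bleach per-frame ON -> BLEACHED probability
#' @param photons_mean mean detected photons per ON frame
#' @param photon_model one of `"poisson"`, `"geometric"`, `"constant"`
#' @param frame_time_s camera integration time per frame (s)
#' @param n_frames number of frames in the movie
#' @return object of class `photophysics_params`
#' @export
photophysics_params <- function(p_off = 0.012, p_bleach = 0.238,
                                photons_mean = 350,
                                photon_model = c("poisson", "geometric", "constant"),
                                frame_time_s = 0.035, n_frames = 10000) {
  photon_model <- match.arg(photon_model)
  stopifnot(p_off >= 0, p_off <= 1, p_bleach >= 0, p_bleach <= 1,
            p_off + p_bleach <= 1, photons_mean > 0,
            frame_time_s > 0, n_frames >= 1)
  structure(list(p_off = p_off, p_bleach = p_bleach,
                 photons_mean = photons_mean, photon_model = photon_model,
                 frame_time_s = frame_time_s, n_frames = as.integer(n_frames)),
            class = "photophysics_params")
}

#' Reactivation controller emulating the ramped 405 nm laser
#'
#' Proportional feedback on the activation count in a trailing window:
#' the per-molecule activation probability `q` is scaled up or down each
#' frame so that the expected number of activations per frame stays at
#' `target_rate` while the unbleached pool shrinks. `q` saturates at
#' `q_max`; a saturated controller that still undershoots the target is
#' reported in the trajectory (`controller_saturated`).
#'
#' @param target_rate target expected activations per frame
#' @param window trailing window length (frames) for the measured rate
#' @param gain proportional gain on the relative rate error
#' @param q_max maximum per-molecule per-frame activation probability
#' @return object of class `reactivation_controller`
#' @export
reactivation_controller <- function(target_rate = 0.4, window = 200,
                                    gain = 0.005, q_max = 0.05) {
  stopifnot(target_rate >= 0, window >= 1, gain > 0, q_max > 0, q_max <= 1)
  structure(list(target_rate = target_rate, window = as.integer(window),
                 gain = gain, q_max = q_max),
            class = "reactivation_controller")
}

#' Simulate photoswitching state trajectories
#'
#' Runs the discrete-frame Markov model for every emitter. All molecules
#' start DARK; BLEACHED is absorbing. The result stores only ON
#' (frame, molecule, photons) triples, which is sparse for realistic
#' activation rates.
#'
#' @param emitters an `emitter_field` from [build_rumposome_lattice()]
#' @param params a [photophysics_params()]
#' @param controller a [reactivation_controller()]
#' @param seed RNG seed
#' @return object of class `state_trajectory`: list with `on`
#'   (data.frame `frame`, `molecule_id`, `photons`), `bleach_frame`
#'   (NA when never bleached), `activations` per frame, `q` per frame,
#'   `controller_saturated`, `n_frames`, `params`
#' @export
simulate_states <- function(emitters, params, controller = reactivation_controller(),
                            seed = 1) {
  stopifnot(inherits(params, "photophysics_params"),
            inherits(controller, "reactivation_controller"))
  set.seed(seed)
  n_mol <- nrow(emitters)
  n_frames <- params$n_frames
  DARK <- 0L; ON <- 1L; BLEACHED <- 2L
  state <- rep(DARK, n_mol)
  bleach_frame <- rep(NA_integer_, n_mol)

  q <- min(controller$target_rate / max(n_mol, 1), controller$q_max)
  q_hist <- numeric(n_frames)
  act_hist <- integer(n_frames)
  saturated <- FALSE

  draw_photons <- switch(params$photon_model,
    poisson  = function(n) stats::rpois(n, params$photons_mean),
    geometric = function(n) stats::rgeom(n, 1 / (params$photons_mean + 1)),
    constant = function(n) rep(round(params$photons_mean), n))

  frames_l <- vector("list", n_frames)
  ids_l <- vector("list", n_frames)
  phot_l <- vector("list", n_frames)

  for (t in seq_len(n_frames)) {
    dark <- which(state == DARK)
    if (length(dark)) {
      act <- dark[stats::runif(length(dark)) < q]
      state[act] <- ON
      act_hist[t] <- length(act)
    }
    on <- which(state == ON)
    if (length(on)) {
      ph <- draw_photons(length(on))
      ph[ph < 1L] <- 1L  # an ON frame emits at least one photon
      frames_l[[t]] <- rep.int(t, length(on))
      ids_l[[t]] <- on
      phot_l[[t]] <- ph
      # end-of-frame transitions
      u <- stats::runif(length(on))
      bl <- u < params$p_bleach
      off <- !bl & u < params$p_bleach + params$p_off
      state[on[bl]] <- BLEACHED
      bleach_frame[on[bl]] <- t
      state[on[off]] <- DARK
    }
    q_hist[t] <- q
    # proportional feedback on the trailing-window activation rate
    w <- controller$window
    lo <- max(1L, t - w + 1L)
    rate <- sum(act_hist[lo:t]) / (t - lo + 1L)
    err <- (controller$target_rate - rate) / max(controller$target_rate, 1e-12)
    q <- q * exp(controller$gain * err)
    if (q >= controller$q_max) {
      q <- controller$q_max
      if (rate < 0.5 * controller$target_rate && t > w) saturated <- TRUE
    }
    q <- max(q, 1e-8)
  }
  if (saturated)
    warning("reactivation controller saturated: target activation rate exceeds remaining unbleached molecules")

  on_df <- data.frame(frame = unlist(frames_l), molecule_id = unlist(ids_l),
                      photons = unlist(phot_l))
  structure(list(on = on_df, bleach_frame = bleach_frame,
                 activations = act_hist, q = q_hist,
                 controller_saturated = saturated,
                 n_frames = n_frames, params = params),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat("Photoswitching state trajectory\n")
  cat(sprintf("  %d molecules, %d frames, %d ON-frame records\n",
              length(x$bleach_frame), x$n_frames, nrow(x$on)))
  cat(sprintf("  activations: %d total (%.3f / frame); bleached: %d\n",
              sum(x$activations), mean(x$activations),
              sum(!is.na(x$bleach_frame))))
  invisible(x)
}

#' ON-spells (ground-truth blink events) of a state trajectory
#'
#' Contiguous runs of ON frames per molecule; the reference against which
#' blink-event merging is validated.
#'
#' @param trajectory a `state_trajectory`
#' @return data.frame `molecule_id`, `first_frame`, `last_frame`, `n_frames`
#' @export
on_spells <- function(trajectory) {
  on <- trajectory$on[order(trajectory$on$molecule_id, trajectory$on$frame), ]
  if (!nrow(on))
    return(data.frame(molecule_id = integer(), first_frame = integer(),
                      last_frame = integer(), n_frames = integer()))
  new_spell <- c(TRUE, diff(on$frame) != 1L | diff(on$molecule_id) != 0L)
  gid <- cumsum(new_spell)
  data.frame(molecule_id = tapply(on$molecule_id, gid, `[`, 1L),
             first_frame = tapply(on$frame, gid, min),
             last_frame = tapply(on$frame, gid, max),
             n_frames = as.integer(table(gid)),
             row.names = NULL)
}

#' Bulk two-state photoswitch conversion fraction
#'
#' Fraction of an ensemble converted after time `t` under first-order
#' kinetics with rate constant `k`: `1 - exp(-k * t)`. Used to emulate
#' ensemble photobleach/recovery curves of the bistable photoreceptor.
#'
#' @param k rate constant (1/s)
#' @param t time (s); `k` and `t` recycle
#' @return converted fraction in `[0, 1]`
#' @export
bulk_switch_fraction <- function(k, t) {
  if (any(k < 0) || any(t < 0)) stop("k and t must be non-negative")
  1 - exp(-k * t)
}
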