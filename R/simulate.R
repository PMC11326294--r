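#' Parameters of the generative walker model
#'
#' The walker is a biased-random-walk navigator in a static odor gradient.
#' It crawls forward at `forward_speed` with a sinusoidal head swing of period
#' `head_cycle_period`; reorientation events (reversal + turn) are drawn from
#' a per-frame hazard `base_reorientation_rate / 60 * (1 - bearing_rate_gain *
#' cos(theta)) * dt`, where `theta` is the signed direction to the odor.  Each
#' event draws a turn magnitude `|dtheta| = amplitude_gain * |theta_start| +
#' N(0, amplitude_noise_sd)` and turns in the error-correcting direction
#' (sign of `theta_start`) with probability `p_correct_dv`.  After an event,
#' a follow-up event within the pirouette window may be scheduled with
#' probability `pirouette_reentry_prob(bearing_at_event_end)`.
#'
#' With `bearing_rate_gain = 0`, `amplitude_gain = 0`, `p_correct_dv = 0.5`
#' and a bearing-independent reentry probability the walker is a pure
#' unbiased random walk (the null configuration, [null_walker_params()]).
#'
#' @param frame_rate sampling rate, Hz.
#' @param forward_speed crawling speed, mm/s.
#' @param head_cycle_period head-swing cycle period, s.
#' @param base_reorientation_rate baseline event rate, events/min.
#' @param bearing_rate_gain dimensionless slope of the hazard vs cos(theta);
#'   positive values make events more likely when heading away from the odor.
#' @param amplitude_gain degrees of |dtheta| per degree of |theta_start|.
#' @param amplitude_noise_sd Gaussian sd of the turn magnitude, degrees.
#' @param amplitude_floor minimum turn magnitude, degrees.
#' @param p_correct_dv probability that the turn sign corrects the heading
#'   error, in [0, 1]; 0.5 is unbiased.
#' @param pirouette_reentry_prob function of the bearing (cos theta) at event
#'   end returning the probability of a follow-up event within the pirouette
#'   window; the default is bearing-independent.
#' @param reversal_duration_mean mean of the (truncated) exponential reversal
#'   duration, s.
#' @param reversal_duration_range admissible reversal durations, s; draws are
#'   clamped into this range so spike pairing stays within its gap window.
#' @param turn_duration duration over which the turn heading change is
#'   executed, s.
#' @param head_curvature_amp head-curvature oscillation amplitude
#'   (arbitrary units, dorsal-positive).
#' @param wiggle_amp amplitude (deg) of the sinusoidal deviation of the step
#'   direction from the heading (crawling sinuosity).
#' @param odor_position odor source (mm, mm).
#' @param arena_radius plate radius, mm; heading reflects at the boundary.
#' @param handedness "left" (dorsal = counterclockwise), "right", or
#'   "random" (drawn per animal).
#' @param seed integer seed.
#' @return a list of class `walker_params`.
#' @export
walker_params <- function(frame_rate = 3,
                          forward_speed = 0.15,
                          head_cycle_period = 4.8,
                          base_reorientation_rate = 1.5,
                          bearing_rate_gain = 0.5,
                          amplitude_gain = 0.5,
                          amplitude_noise_sd = 25,
                          amplitude_floor = 15,
                          p_correct_dv = 0.6,
                          pirouette_reentry_prob = function(bearing) 0.25,
                          reversal_duration_mean = 2.5,
                          reversal_duration_range = c(1, 7.5),
                          turn_duration = 1,
                          head_curvature_amp = 30,
                          wiggle_amp = 6,
                          odor_position = c(30, 0),
                          arena_radius = 45,
                          handedness = "left",
                          seed = 1L) {
  .assert_scalar(frame_rate, "frame_rate", lo = 1e-6)
  .assert_scalar(forward_speed, "forward_speed", lo = 0)
  .assert_scalar(head_cycle_period, "head_cycle_period", lo = 1e-6)
  .assert_scalar(base_reorientation_rate, "base_reorientation_rate", lo = 0)
  .assert_scalar(bearing_rate_gain, "bearing_rate_gain")
  .assert_scalar(amplitude_gain, "amplitude_gain", lo = 0)
  .assert_scalar(amplitude_noise_sd, "amplitude_noise_sd", lo = 0)
  .assert_scalar(amplitude_floor, "amplitude_floor", lo = 0, hi = 180)
  .assert_scalar(p_correct_dv, "p_correct_dv", lo = 0, hi = 1)
  if (!is.function(pirouette_reentry_prob))
    stop("parameter 'pirouette_reentry_prob' must be a function of bearing")
  .assert_scalar(reversal_duration_mean, "reversal_duration_mean", lo = 1e-6)
  .assert_scalar(turn_duration, "turn_duration", lo = 0)
  .assert_scalar(head_curvature_amp, "head_curvature_amp", lo = 0)
  .assert_scalar(wiggle_amp, "wiggle_amp", lo = 0)
  .assert_scalar(arena_radius, "arena_radius", lo = 1e-6)
  if (!is.numeric(odor_position) || length(odor_position) != 2L ||
      !all(is.finite(odor_position)))
    stop("parameter 'odor_position' must be a finite (x, y) pair")
  if (!handedness %in% c("left", "right", "random"))
    stop("parameter 'handedness' must be 'left', 'right' or 'random'")
  if (length(reversal_duration_range) != 2L ||
      reversal_duration_range[1] <= 0 || diff(reversal_duration_range) < 0)
    stop("parameter 'reversal_duration_range' must be an increasing positive pair")
  structure(as.list(environment()), class = "walker_params")
}

#' Null (unbiased) walker configuration
#'
#' All gradient couplings are zeroed: flat reorientation hazard, turn
#' magnitude independent of the heading error, unbiased turn sign, and a
#' bearing-independent pirouette reentry probability.
#'
#' @param ... overrides passed on to [walker_params()].
#' @return a `walker_params` object.
#' @export
null_walker_params <- function(...) {
  args <- list(bearing_rate_gain = 0, amplitude_gain = 0, p_correct_dv = 0.5,
               amplitude_noise_sd = 45,
               pirouette_reentry_prob = function(bearing) 0.25)
  args[names(list(...))] <- list(...)
  do.call(walker_params, args)
}

#' Simulate navigating walkers with ground truth
#'
#' Runs `n_animals` independent walkers for `duration` seconds each and
#' returns their trajectories together with a ground-truth record: the exact
#' reorientation event table (frame indices, true turn angles, true
#' dorsal/ventral signs, pirouette membership) and the per-frame movement
#' state ("forward", "reverse", "turn") of every animal.
#'
#' @param params a [walker_params()] object.
#' @param n_animals number of animals.
#' @param duration recording duration per animal, s; must be at least ten
#'   head-swing cycles.
#' @return a list with elements `trajectories` (list of `worm_trajectory`),
#'   and `truth` (list with `events`, a data.frame, and `states`, a list of
#'   per-frame state vectors).
#' @export
simulate_walkers <- function(params, n_animals, duration) {
  stopifnot(inherits(params, "walker_params"))
  if (duration < 10 * params$head_cycle_period)
    stop("duration must be at least 10 head-swing cycles")
  set.seed(params$seed)
  trajectories <- vector("list", n_animals)
  states <- vector("list", n_animals)
  ev_list <- vector("list", n_animals)
  for (a in seq_len(n_animals)) {
    sim <- .simulate_one_walker(params, duration, animal = a)
    trajectories[[a]] <- sim$trajectory
    states[[a]] <- sim$state
    ev_list[[a]] <- sim$events
  }
  events <- do.call(rbind, ev_list)
  rownames(events) <- NULL
  if (nrow(events)) {
    events$pirouette_id <- .true_pirouette_ids(events, params$frame_rate)
  }
  list(trajectories = trajectories,
       truth = list(events = events, states = states))
}

# gap (s) from end of one event to the start of the next, per animal;
# groups under the strict < 13 s rule used throughout the package
.true_pirouette_ids <- function(events, fs, max_gap = 13) {
  ids <- rep(NA_integer_, nrow(events))
  nxt <- 1L
  for (a in unique(events$animal)) {
    idx <- which(events$animal == a)
    if (length(idx) < 2L) next
    gaps <- (events$reversal_start[idx[-1L]] -
               events$turn_end[idx[-length(idx)]]) / fs
    grp <- cumsum(c(0, gaps >= max_gap))
    for (g in unique(grp)) {
      members <- idx[grp == g]
      if (length(members) >= 2L) {
        ids[members] <- nxt
        nxt <- nxt + 1L
      }
    }
  }
  ids
}

.simulate_one_walker <- function(p, duration, animal) {
  fs <- p$frame_rate
  dt <- 1 / fs
  n <- floor(duration * fs) + 1L
  hand <- if (p$handedness == "random")
    sample(c("left", "right"), 1L) else p$handedness
  # dorsal bend = CCW(+) for left-handed animals, CW(-) for right-handed
  dorsal_ccw <- if (hand == "left") 1 else -1

  x <- numeric(n); y <- numeric(n)
  curv <- numeric(n); ecc <- numeric(n)
  state <- character(n)

  r0 <- sqrt(stats::runif(1)) * p$arena_radius * 0.5
  a0 <- stats::runif(1, -pi, pi)
  pos <- c(r0 * cos(a0), r0 * sin(a0))
  heading <- stats::runif(1, -180, 180)
  phase <- stats::runif(1, 0, 2 * pi)
  dphase <- 2 * pi / (p$head_cycle_period * fs)

  st <- "forward"
  frames_left <- 0L
  turn_step <- 0
  ecc_target <- NA_real_
  cur_event <- NULL
  scheduled <- NA_integer_   # frame of a scheduled pirouette reentry
  events <- list()

  odor <- p$odor_position
  hazard_base <- p$base_reorientation_rate / 60 * dt

  for (i in seq_len(n)) {
    x[i] <- pos[1]; y[i] <- pos[2]
    state[i] <- st
    if (st == "turn") {
      curv[i] <- cur_event$dv_num * 1.5 * p$head_curvature_amp
      ecc[i] <- ecc_target
    } else {
      curv[i] <- p$head_curvature_amp * sin(phase)
      ecc[i] <- 0.92
    }

    # --- kinematics for this frame
    theta_odor <- atan2(odor[2] - pos[2], odor[1] - pos[1]) * 180 / pi
    if (st == "forward") {
      step_dir <- heading + p$wiggle_amp * sin(phase)
      speed <- p$forward_speed
    } else if (st == "reverse") {
      step_dir <- heading + 180 + p$wiggle_amp * sin(phase)
      speed <- p$forward_speed
    } else { # turn: heading rotates by turn_step each frame
      heading <- wrap_deg(heading + turn_step)
      step_dir <- heading
      speed <- 0.4 * p$forward_speed
    }
    step <- speed * dt * c(cos(step_dir * pi / 180), sin(step_dir * pi / 180))
    cand <- pos + step
    if (sqrt(sum(cand^2)) > p$arena_radius) {
      # reflect the velocity about the local tangent; keeps the walker inside
      nrm <- cand / sqrt(sum(cand^2))
      v <- step - 2 * sum(step * nrm) * nrm
      heading <- atan2(v[2], v[1]) * 180 / pi
      if (st == "reverse") heading <- wrap_deg(heading + 180)
      cand <- pos + v
    }
    pos <- cand
    phase <- phase + dphase

    # --- state transitions (take effect from the next frame)
    if (st == "forward") {
      theta <- wrap_deg(theta_odor - heading)
      start_now <- FALSE
      if (!is.na(scheduled) && i >= scheduled) {
        start_now <- TRUE
        scheduled <- NA_integer_
      } else {
        haz <- hazard_base * (1 - p$bearing_rate_gain * cos(theta * pi / 180))
        if (haz > 0 && stats::runif(1) < haz) start_now <- TRUE
      }
      if (start_now && i < n - 4L) {
        dur <- stats::rexp(1, 1 / p$reversal_duration_mean)
        dur <- min(max(dur, p$reversal_duration_range[1]),
                   p$reversal_duration_range[2])
        amp <- p$amplitude_gain * abs(theta) +
          stats::rnorm(1, 0, p$amplitude_noise_sd)
        amp <- min(max(amp, p$amplitude_floor), 180)
        sgn <- if (theta == 0) sample(c(-1, 1), 1L) else sign(theta)
        if (stats::runif(1) >= p$p_correct_dv) sgn <- -sgn
        delta <- sgn * amp
        cur_event <- list(
          reversal_start = i + 1L,
          theta_start = theta,
          delta = delta,
          dv_num = sign(delta) * dorsal_ccw,  # +1 dorsal, -1 ventral
          correct = (sign(delta) == sign(theta)))
        st <- "reverse"
        frames_left <- max(2L, round(dur * fs))
      }
    } else if (st == "reverse") {
      frames_left <- frames_left - 1L
      if (frames_left <= 0L) {
        cur_event$reversal_end <- i
        nturn <- max(2L, round(p$turn_duration * fs))
        turn_step <- cur_event$delta / nturn
        ecc_target <- if (abs(cur_event$delta) > 135) 0.45
                      else if (abs(cur_event$delta) > 40) 0.65 else 0.88
        st <- "turn"
        frames_left <- nturn
      }
    } else { # turn
      frames_left <- frames_left - 1L
      if (frames_left <= 0L) {
        cur_event$turn_end <- i
        theta_end <- wrap_deg(cur_event$theta_start - cur_event$delta)
        cur_event$theta_end <- theta_end
        events[[length(events) + 1L]] <- cur_event
        # possibly schedule a pirouette reentry while the bearing is what it is
        pr <- p$pirouette_reentry_prob(cos(theta_end * pi / 180))
        if (is.finite(pr) && pr > 0 && stats::runif(1) < pr) {
          scheduled <- i + as.integer(round(stats::runif(1, 2, 9) * fs))
        }
        cur_event <- NULL
        turn_step <- 0
        st <- "forward"
      }
    }
  }

  ev <- if (length(events)) {
    data.frame(
      animal = animal,
      reversal_start = vapply(events, `[[`, 1L, "reversal_start"),
      reversal_end = vapply(events, function(e) e$reversal_end %||% NA_integer_,
                            1L),
      turn_end = vapply(events, function(e) e$turn_end %||% NA_integer_, 1L),
      theta_start = vapply(events, `[[`, 1, "theta_start"),
      theta_end = vapply(events, function(e) e$theta_end %||% NA_real_, 1),
      delta_theta = vapply(events, `[[`, 1, "delta"),
      dv_sign = ifelse(vapply(events, `[[`, 1, "dv_num") > 0,
                       "dorsal", "ventral"),
      correct_direction = vapply(events, `[[`, TRUE, "correct"))
  } else {
    data.frame(animal = integer(), reversal_start = integer(),
               reversal_end = integer(), turn_end = integer(),
               theta_start = numeric(), theta_end = numeric(),
               delta_theta = numeric(), dv_sign = character(),
               correct_direction = logical())
  }
  # drop an event still in progress at the recording edge
  ev <- ev[!is.na(ev$turn_end), , drop = FALSE]

  traj <- worm_trajectory(time = (seq_len(n) - 1L) / fs, x = x, y = y,
                          odor_position = odor, head_curvature = curv,
                          eccentricity = ecc, handedness = hand)
  list(trajectory = traj, state = state, events = ev)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
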