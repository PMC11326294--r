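#' Per-frame angular speed of the centroid path
#'
#' The rate of change of the movement-direction angle of the (optionally
#' smoothed) centroid path, in deg/s.  Angle differences are wrapped to
#' (-180, 180], so an instantaneous reversal of direction registers as
#' 180 deg over one frame interval.  Frames whose displacement falls below
#' `min_disp` have no defined direction and propagate NA rather than a
#' spurious value.
#'
#' @param trajectory a `worm_trajectory`.
#' @param smooth_window centered running-mean window (s) applied to the
#'   coordinates before differencing; 0 disables smoothing.
#' @param min_disp minimum per-frame displacement (mm) for a defined
#'   direction.
#' @return numeric vector, one value per frame (NA at the two edge frames
#'   and at stationary frames).
#' @export
compute_angular_speed <- function(trajectory, smooth_window = 0,
                                  min_disp = 1e-6) {
  stopifnot(inherits(trajectory, "worm_trajectory"))
  n <- nrow(trajectory)
  if (n < 3L) stop("need at least 3 frames")
  fs <- attr(trajectory, "frame_rate")
  k <- max(1L, as.integer(round(smooth_window * fs)))
  if (k %% 2L == 0L) k <- k + 1L
  xs <- .runmean(trajectory$x, k)
  ys <- .runmean(trajectory$y, k)
  dir <- .displacement_dir(diff(xs), diff(ys), min_disp)  # length n-1
  dd <- abs(ang_diff(dir[-1], dir[-(n - 1L)])) * fs        # length n-2
  c(NA_real_, dd, NA_real_)
}

#' Detect reversals from angular-speed spikes
#'
#' A reversal produces two spikes of supra-threshold angular speed: one when
#' the animal flips from forward to backward movement and one when it flips
#' back.  Contiguous supra-threshold runs ("spikes") closer together than
#' `pair_gap` are paired left-to-right into one reversal spanning from the
#' first frame of the first spike to the last supra-threshold frame of the
#' second.  Unpaired spikes are dropped.
#'
#' @param angular_speed per-frame angular speed (deg/s), NA allowed.
#' @param frame_rate sampling rate, Hz.
#' @param spike_thresh spike threshold, deg/s.
#' @param pair_gap maximum spike separation (s) for pairing (strict `<`).
#' @return data.frame with columns `reversal_start`, `reversal_end`
#'   (frame indices).
#' @export
detect_reversals <- function(angular_speed, frame_rate, spike_thresh = 75,
                             pair_gap = 8.8) {
  empty <- data.frame(reversal_start = integer(), reversal_end = integer())
  if (length(angular_speed) == 0L) return(empty)
  supra <- !is.na(angular_speed) & angular_speed > spike_thresh
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spike_start <- starts[r$values]
  spike_end <- ends[r$values]
  if (length(spike_start) < 2L) return(empty)
  out_start <- integer(); out_end <- integer()
  i <- 1L
  while (i < length(spike_start)) {
    gap_s <- (spike_start[i + 1L] - spike_end[i]) / frame_rate
    if (gap_s < pair_gap) {
      out_start <- c(out_start, spike_start[i])
      out_end <- c(out_end, spike_end[i + 1L])
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  data.frame(reversal_start = out_start, reversal_end = out_end)
}

#' Movement direction to the odor source
#'
#' The signed angle (deg, CCW-positive) between the animal's smoothed
#' movement direction and the animal-to-odor vector: 0 means moving straight
#' at the odor, 180 straight away, positive values mean the odor lies
#' counterclockwise of the movement direction.
#'
#' @param trajectory a `worm_trajectory`.
#' @param frame frame index at which to evaluate.
#' @param window displacement window (s) used for the movement direction.
#' @param mode "forward" uses displacement over [t, t + window] (the
#'   default, matching run-time bearing); "backward" uses
#'   [t - window, t], the direction the animal was moving *before* frame
#'   `t` (used at reorientation starts).
#' @param min_disp minimum displacement (mm); below it theta is NA.
#' @return theta in (-180, 180], NA if undefined.
#' @export
direction_to_odor <- function(trajectory, frame, window = 2,
                              mode = c("forward", "backward"),
                              min_disp = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(trajectory, "worm_trajectory"))
  fs <- attr(trajectory, "frame_rate")
  n <- nrow(trajectory)
  w <- max(1L, as.integer(round(window * fs)))
  i0 <- if (mode == "forward") frame else frame - w
  i1 <- i0 + w
  out <- rep(NA_real_, length(frame))
  ok <- i0 >= 1L & i1 <= n
  if (!any(ok)) return(out)
  dir <- .displacement_dir(trajectory$x[i1[ok]] - trajectory$x[i0[ok]],
                           trajectory$y[i1[ok]] - trajectory$y[i0[ok]],
                           min_disp)
  odor <- attr(trajectory, "odor_position")
  beta <- atan2(odor[2] - trajectory$y[frame[ok]],
                odor[1] - trajectory$x[frame[ok]]) * 180 / pi
  out[ok] <- wrap_deg(beta - dir)
  out
}

#' Bearing to odor
#'
#' @param theta direction to odor, degrees.
#' @return cos(theta) in [-1, 1]; +1 toward the odor, -1 away.  NA
#'   propagates.
#' @export
bearing <- function(theta) cospi(theta / 180)

#' Signed reorientation angle
#'
#' The wrapped difference between the movement direction in the 1 s window
#' before the reversal start and the 1 s window after the turn end,
#' CCW-positive.  Events too close to the recording edge return NA.
#'
#' @param trajectory a `worm_trajectory`.
#' @param reversal_start,turn_end frame indices (vectors allowed).
#' @param window direction window, s.
#' @return signed delta-theta in (-180, 180].
#' @export
reorientation_angle <- function(trajectory, reversal_start, turn_end,
                                window = 1) {
  fs <- attr(trajectory, "frame_rate")
  n <- nrow(trajectory)
  w <- max(1L, as.integer(round(window * fs)))
  pre0 <- reversal_start - w
  post1 <- turn_end + w
  out <- rep(NA_real_, length(reversal_start))
  ok <- pre0 >= 1L & post1 <= n
  if (!any(ok)) return(out)
  dir_pre <- .displacement_dir(
    trajectory$x[reversal_start[ok]] - trajectory$x[pre0[ok]],
    trajectory$y[reversal_start[ok]] - trajectory$y[pre0[ok]])
  dir_post <- .displacement_dir(
    trajectory$x[post1[ok]] - trajectory$x[turn_end[ok]],
    trajectory$y[post1[ok]] - trajectory$y[turn_end[ok]])
  out[ok] <- ang_diff(dir_post, dir_pre)
  out
}

#' Classify the post-reversal turn
#'
#' Turn type from the magnitude of the direction change and the body posture:
#' omega turns exceed 135 deg and require the coiled posture (eccentricity
#' dipping below `omega_ecc`); mid-angle turns are in (40, 135] deg and
#' require a milder eccentricity drop (below `mid_ecc`); anything at or below
#' 40 deg is low (essentially a pure reversal).  Boundary values go to the
#' lower class.  For omega/mid calls the turn end is the first post-reversal
#' frame where eccentricity recovers above the class threshold; low turns end
#' at the reversal end.  Without eccentricity the call degrades to angle-only
#' and is flagged.
#'
#' @param trajectory a `worm_trajectory`.
#' @param reversal_start,reversal_end frame indices of one reversal.
#' @param omega_ecc,mid_ecc eccentricity thresholds (configurable; tracker
#'   calibration dependent).
#' @param attach_window turn must begin within this many seconds of the
#'   reversal end.
#' @return list with `turn_type` ("omega", "mid", "low"), `turn_end`
#'   (frame), `delta_theta`, and `flag` (TRUE if angle-only).
#' @export
classify_turn <- function(trajectory, reversal_start, reversal_end,
                          omega_ecc = 0.55, mid_ecc = 0.75,
                          attach_window = 1.5) {
  fs <- attr(trajectory, "frame_rate")
  n <- nrow(trajectory)
  have_ecc <- !is.null(trajectory$eccentricity)
  turn_end <- reversal_end
  flag <- !have_ecc
  if (!have_ecc)
    warning("no eccentricity column: angle-only turn classification")

  # provisional angle using a short post-reversal window
  probe_end <- min(n - 1L, reversal_end + as.integer(round(attach_window * fs)))
  dth <- reorientation_angle(trajectory, reversal_start, probe_end)
  mag <- abs(dth)
  if (is.na(mag)) {
    return(list(turn_type = NA_character_, turn_end = reversal_end,
                delta_theta = NA_real_, flag = TRUE))
  }
  type <- if (mag > 135) "omega" else if (mag > 40) "mid" else "low"
  if (type != "low" && have_ecc) {
    thresh <- if (type == "omega") omega_ecc else mid_ecc
    # the coiled posture can fall on either side of the detected reversal
    # end (high-angle turns keep angular speed supra-threshold into the
    # turn), so search a window straddling it
    wlen <- as.integer(round(attach_window * fs))
    win <- max(reversal_start, reversal_end - wlen):min(n, reversal_end + wlen)
    dip <- which(trajectory$eccentricity[win] < thresh)
    if (!length(dip)) {
      flag <- TRUE          # angle says turn, posture does not confirm
    } else {
      after <- (win[dip[1]]):n
      rec <- which(trajectory$eccentricity[after] >= thresh)
      turn_end <- if (length(rec)) after[rec[1]] else n
    }
  }
  dth_final <- reorientation_angle(trajectory, reversal_start, turn_end)
  if (is.na(dth_final)) dth_final <- dth
  list(turn_type = type, turn_end = turn_end, delta_theta = dth_final,
       flag = flag)
}

#' Group reorientations into pirouettes
#'
#' Consecutive events whose end-to-next-start gap is strictly less than
#' `max_gap` seconds form one pirouette; singletons are labeled isolated
#' (NA id).
#'
#' @param events data.frame with `reversal_start` and `turn_end` frame
#'   columns, sorted by time (within one animal/plate).
#' @param frame_rate Hz.
#' @param max_gap pirouette gap, s (strict `<`).
#' @return integer vector of pirouette ids, NA for isolated events.
#' @export
group_pirouettes <- function(events, frame_rate, max_gap = 13) {
  n <- nrow(events)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(NA_integer_)
  if (is.unsorted(events$reversal_start))
    stop("events must be sorted by time")
  gaps <- (events$reversal_start[-1L] - events$turn_end[-n]) / frame_rate
  grp <- cumsum(c(0L, as.integer(gaps >= max_gap))) + 1L
  sizes <- table(grp)
  ids <- rep(NA_integer_, n)
  keep <- names(sizes)[sizes >= 2L]
  ids[grp %in% as.integer(keep)] <- match(grp[grp %in% as.integer(keep)],
                                          as.integer(keep))
  ids
}

#' Towards/away classification of a reorientation
#'
#' A reorientation turns the animal towards the odor iff the magnitude of
#' its direction to the odor strictly decreases: `|theta_start| >
#' |theta_end|`.
#'
#' @param theta_start,theta_end directions to odor, degrees.
#' @return logical; NA where either angle is undefined.
#' @export
classify_towards_away <- function(theta_start, theta_end) {
  abs(theta_start) > abs(theta_end)
}

#' Correct-direction classification of a reorientation
#'
#' The turn is "correct" iff the signed heading error and the executed turn
#' share a sign, i.e. the animal turned in the error-correcting
#' (dorsal/ventral or cw/ccw) direction.  Events with `theta_start == 0`
#' have no defined correct side and return NA.
#'
#' @param theta_start signed direction to odor at event start, degrees.
#' @param delta_theta signed reorientation angle, degrees.
#' @return logical; NA for degenerate or undefined inputs.
#' @export
classify_correct_direction <- function(theta_start, delta_theta) {
  out <- sign(theta_start) == sign(delta_theta)
  out[!is.na(theta_start) & theta_start == 0] <- NA
  out[!is.na(delta_theta) & delta_theta == 0] <- NA
  out
}

#' Weathervaning profile: curving rate vs direction to odor
#'
#' During the first seconds of forward runs, the curving rate is the change
#' in movement direction divided by the displacement over the next second
#' (deg/mm), binned by the current direction to the odor.  Pause frames
#' (speed below `min_speed`) are excluded.  A profile resembling -sin(theta)
#' indicates runs bending toward the odor.
#'
#' @param trajectory a `worm_trajectory`.
#' @param runs data.frame with `start`, `end` frame columns of forward runs.
#' @param run_head seconds of each run to use (from run start).
#' @param min_speed pause threshold, mm/s.
#' @param bin_width theta bin width, degrees.
#' @return data.frame with `theta_mid`, `curving_rate`, `lo`, `hi`, `n`.
#' @export
weathervane_profile <- function(trajectory, runs, run_head = 10,
                                min_speed = 0.04, bin_width = 30) {
  fs <- attr(trajectory, "frame_rate")
  n <- nrow(trajectory)
  w <- as.integer(round(fs))  # 1-s lookahead
  frames <- integer(0)
  for (r in seq_len(nrow(runs))) {
    hi <- min(runs$end[r], runs$start[r] + as.integer(round(run_head * fs)))
    frames <- c(frames, runs$start[r]:hi)
  }
  frames <- frames[frames + w <= n - w & frames > w]
  if (!length(frames)) {
    return(data.frame(theta_mid = numeric(), curving_rate = numeric(),
                      lo = numeric(), hi = numeric(), n = integer()))
  }
  disp <- sqrt((trajectory$x[frames + w] - trajectory$x[frames])^2 +
               (trajectory$y[frames + w] - trajectory$y[frames])^2)
  speed <- disp * fs / w
  keep <- speed >= min_speed
  frames <- frames[keep]; disp <- disp[keep]
  if (!length(frames)) {
    breaks <- seq(-180, 180, by = bin_width)
    mids <- breaks[-1] - bin_width / 2
    return(data.frame(theta_mid = mids, curving_rate = NA_real_,
                      lo = NA_real_, hi = NA_real_, n = 0L))
  }
  dir_now <- .displacement_dir(trajectory$x[frames + 1L] - trajectory$x[frames],
                               trajectory$y[frames + 1L] - trajectory$y[frames])
  dir_next <- .displacement_dir(
    trajectory$x[frames + w + 1L] - trajectory$x[frames + w],
    trajectory$y[frames + w + 1L] - trajectory$y[frames + w])
  curve <- ang_diff(dir_next, dir_now) / disp
  theta <- direction_to_odor(trajectory, frames, window = 2)
  breaks <- seq(-180, 180, by = bin_width)
  bin <- cut(theta, breaks, include.lowest = TRUE)
  agg <- tapply(curve, bin, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(c(NA, NA, NA, 0))
    se <- stats::sd(v) / sqrt(length(v))
    c(mean(v), mean(v) - 1.96 * se, mean(v) + 1.96 * se, length(v))
  })
  mids <- breaks[-1] - bin_width / 2
  res <- do.call(rbind, lapply(agg, function(z) if (is.null(z)) rep(NA, 4) else z))
  data.frame(theta_mid = mids, curving_rate = res[, 1], lo = res[, 2],
             hi = res[, 3], n = as.integer(ifelse(is.na(res[, 4]), 0, res[, 4])))
}

#' Reorientation rate as a function of bearing
#'
#' Counts reorientation starts per bearing bin and divides by the total time
#' the animal spent at that bearing; bins with zero occupancy are undefined
#' (NA), not zero.
#'
#' @param events event table with `theta_start`.
#' @param trajectory a `worm_trajectory` (occupancy source).
#' @param bin_width bearing (cos theta) bin width.
#' @param exclude_frames optional frames (e.g. within reversals) dropped
#'   from the occupancy; NULL keeps all frames.
#' @return data.frame with `bearing_mid`, `rate` (events/min), `n_events`,
#'   `occupancy_s`.
#' @export
reorientation_rate_by_bearing <- function(events, trajectory, bin_width = 0.1,
                                          exclude_frames = NULL) {
  fs <- attr(trajectory, "frame_rate")
  frames <- seq_len(nrow(trajectory))
  if (!is.null(exclude_frames)) frames <- setdiff(frames, exclude_frames)
  th <- direction_to_odor(trajectory, frames, window = 2)
  occ_bearing <- bearing(th)
  breaks <- seq(-1, 1, by = bin_width)
  occ <- table(cut(occ_bearing, breaks, include.lowest = TRUE)) / fs
  cnt <- table(cut(bearing(events$theta_start), breaks, include.lowest = TRUE))
  rate <- ifelse(occ > 0, as.numeric(cnt) / as.numeric(occ) * 60, NA_real_)
  data.frame(bearing_mid = breaks[-1] - bin_width / 2,
             rate = rate, n_events = as.integer(cnt),
             occupancy_s = as.numeric(occ))
}

#' Chemotaxis index
#'
#' (number at odor - number at control) / total animals.
#'
#' @param n_odor,n_control,n_total animal counts.
#' @return index in [-1, 1].
#' @export
chemotaxis_index <- function(n_odor, n_control, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  (n_odor - n_control) / n_total
}
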