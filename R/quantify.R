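#' Quantify navigation events in a trajectory
#'
#' The full behavioral pipeline for one animal: angular speed, reversal
#' detection by paired supra-threshold spikes, turn classification, the
#' paper-style navigation metrics per event (theta at start/end, signed
#' reorientation angle, towards/away, correct-direction), and pirouette
#' grouping.  Without anatomical handedness the turn sign is reported as
#' cw/ccw; with handedness known it is relabeled dorsal/ventral.
#'
#' @param trajectory a `worm_trajectory`.
#' @param plate plate/recording identifier stored with each event.
#' @param animal animal identifier.
#' @param smooth_window smoothing for angular speed, s.
#' @param spike_thresh,pair_gap see [detect_reversals()].
#' @param ... further arguments to [classify_turn()].
#' @return a data.frame of class `reorientation_events`, one row per event:
#'   `plate, animal, reversal_start, reversal_end, turn_end, turn_type,
#'   theta_start, theta_end, delta_theta, dv_sign, towards_odor,
#'   correct_direction, pirouette_id, flag`.
#' @export
quantify_navigation <- function(trajectory, plate = 1L, animal = 1L,
                                smooth_window = 0, spike_thresh = 75,
                                pair_gap = 8.8, ...) {
  stopifnot(inherits(trajectory, "worm_trajectory"))
  fs <- attr(trajectory, "frame_rate")
  ang <- compute_angular_speed(trajectory, smooth_window)
  rev <- detect_reversals(ang, fs, spike_thresh, pair_gap)
  n_ev <- nrow(rev)
  ev <- data.frame(
    plate = rep(plate, n_ev), animal = rep(animal, n_ev),
    reversal_start = rev$reversal_start, reversal_end = rev$reversal_end,
    turn_end = rev$reversal_end, turn_type = rep(NA_character_, n_ev),
    theta_start = rep(NA_real_, n_ev), theta_end = rep(NA_real_, n_ev),
    delta_theta = rep(NA_real_, n_ev), dv_sign = rep(NA_character_, n_ev),
    towards_odor = rep(NA, n_ev), correct_direction = rep(NA, n_ev),
    pirouette_id = rep(NA_integer_, n_ev), flag = rep(FALSE, n_ev))
  if (n_ev == 0L) {
    class(ev) <- c("reorientation_events", "data.frame")
    return(ev)
  }
  hand <- attr(trajectory, "handedness")
  suppress <- is.null(trajectory$eccentricity)
  for (e in seq_len(n_ev)) {
    ct <- if (suppress) {
      suppressWarnings(classify_turn(trajectory, rev$reversal_start[e],
                                     rev$reversal_end[e], ...))
    } else {
      classify_turn(trajectory, rev$reversal_start[e], rev$reversal_end[e], ...)
    }
    ev$turn_type[e] <- ct$turn_type
    ev$turn_end[e] <- ct$turn_end
    ev$delta_theta[e] <- ct$delta_theta
    ev$flag[e] <- ct$flag
  }
  # bearing at start uses the pre-event movement direction
  ev$theta_start <- direction_to_odor(trajectory, ev$reversal_start,
                                      window = 1, mode = "backward")
  ev$theta_end <- direction_to_odor(trajectory, ev$turn_end,
                                    window = 1, mode = "forward")
  ev$towards_odor <- classify_towards_away(ev$theta_start, ev$theta_end)
  ev$correct_direction <- classify_correct_direction(ev$theta_start,
                                                     ev$delta_theta)
  ccw <- ev$delta_theta > 0
  ev$dv_sign <- ifelse(is.na(ccw), NA_character_, ifelse(ccw, "ccw", "cw"))
  if (hand %in% c("left", "right")) {
    dorsal <- if (hand == "left") ccw else !ccw
    ev$dv_sign <- ifelse(is.na(dorsal), NA_character_,
                         ifelse(dorsal, "dorsal", "ventral"))
  }
  ev$pirouette_id <- group_pirouettes(ev, fs)
  class(ev) <- c("reorientation_events", "data.frame")
  ev
}

#' @export
print.reorientation_events <- function(x, ...) {
  cat(sprintf("<reorientation_events> %d events", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(" | types: %s | fraction correct: %.3f",
                paste(names(table(x$turn_type)), table(x$turn_type),
                      sep = ":", collapse = " "),
                mean(x$correct_direction, na.rm = TRUE)))
  }
  cat("\n")
  invisible(as.data.frame(x))
}

#' Forward-run intervals between reorientation events
#'
#' @param events a `reorientation_events` table for one animal.
#' @param n_frames total frames in the trajectory.
#' @return data.frame with `start`, `end` frame columns of inter-event
#'   forward periods.
#' @export
forward_runs <- function(events, n_frames) {
  if (nrow(events) == 0L)
    return(data.frame(start = 1L, end = n_frames))
  bounds <- rbind(c(0L, events$reversal_start[1] - 1L),
                  cbind(events$turn_end[-nrow(events)],
                        events$reversal_start[-1L] - 1L),
                  c(events$turn_end[nrow(events)], n_frames))
  starts <- bounds[, 1] + 1L
  ends <- bounds[, 2]
  keep <- ends - starts >= 1L
  data.frame(start = starts[keep], end = ends[keep])
}

#' Per-plate summary of navigation metrics
#'
#' @param events a `reorientation_events` table (possibly several plates).
#' @return data.frame, one row per plate: event count, fraction towards,
#'   fraction correct, pirouette count.
#' @export
summarize_plates <- function(events) {
  sp <- split(as.data.frame(events), events$plate)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(plate = d$plate[1], n_events = nrow(d),
               fraction_towards = mean(d$towards_odor, na.rm = TRUE),
               fraction_correct = mean(d$correct_direction, na.rm = TRUE),
               n_pirouettes = length(unique(stats::na.omit(d$pirouette_id))))
  }))
  rownames(out) <- NULL
  out
}

#' Read / write event tables
#' @param events a `reorientation_events` data.frame.
#' @param file path.
#' @param sep field separator.
#' @return the path ([write_events()]) or the events table
#'   ([read_events()]).
#' @export
write_events <- function(events, file, sep = ",") {
  utils::write.table(as.data.frame(events), file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_events
#' @export
read_events <- function(file, sep = ",") {
  ev <- utils::read.table(file, header = TRUE, sep = sep)
  class(ev) <- c("reorientation_events", "data.frame")
  ev
}
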