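#' Construct a worm trajectory object
#'
#' A trajectory is a per-frame record of a single animal's centroid path on a
#' chemotaxis plate, on a uniform time grid, together with the odor-source
#' location.  Optional per-frame columns carry signed head curvature
#' (dorsal-positive), body eccentricity (in [0, 1]) and the animal's
#' handedness (which image-plane rotation sense corresponds to a dorsal bend).
#'
#' @param time numeric vector of times (s), strictly increasing, constant step.
#' @param x,y centroid coordinates (mm).
#' @param odor_position length-2 numeric, odor source (mm, mm).
#' @param head_curvature optional signed head curvature, dorsal-positive.
#' @param eccentricity optional body eccentricity in [0, 1].
#' @param handedness one of "left", "right", "unknown": whether a dorsal bend
#'   corresponds to counterclockwise ("left") or clockwise ("right") rotation
#'   in image coordinates.
#' @return an object of class `worm_trajectory` (a data.frame with
#'   attributes `odor_position`, `frame_rate`, `handedness`).
#' @export
worm_trajectory <- function(time, x, y, odor_position,
                            head_curvature = NULL, eccentricity = NULL,
                            handedness = c("unknown", "left", "right")) {
  handedness <- match.arg(handedness)
  n <- length(time)
  if (n < 2L) stop("trajectory needs at least 2 frames")
  if (length(x) != n || length(y) != n)
    stop("time, x, y must have equal length")
  if (!all(is.finite(time)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("time and coordinates must be finite")
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop("time must be strictly increasing with constant step")
  if (!is.numeric(odor_position) || length(odor_position) != 2L ||
      !all(is.finite(odor_position)))
    stop("odor_position must be a finite (x, y) pair")
  df <- data.frame(time = time, x = x, y = y)
  if (!is.null(head_curvature)) {
    stopifnot(length(head_curvature) == n)
    df$head_curvature <- head_curvature
  }
  if (!is.null(eccentricity)) {
    stopifnot(length(eccentricity) == n)
    df$eccentricity <- eccentricity
  }
  structure(df,
            odor_position = as.numeric(odor_position),
            frame_rate = 1 / mean(dt),
            handedness = handedness,
            class = c("worm_trajectory", "data.frame"))
}

#' @export
print.worm_trajectory <- function(x, ...) {
  cat(sprintf(
    "<worm_trajectory> %d frames at %.3g Hz (%.1f s), odor at (%.1f, %.1f) mm\n",
    nrow(x), attr(x, "frame_rate"),
    nrow(x) / attr(x, "frame_rate"),
    attr(x, "odor_position")[1], attr(x, "odor_position")[2]))
  cat(sprintf("  columns: %s; handedness: %s\n",
              paste(names(x), collapse = ", "), attr(x, "handedness")))
  invisible(x)
}

#' Frame rate of a trajectory or trace object
#' @param x a `worm_trajectory` or `neural_traces` object.
#' @return sampling rate in Hz.
#' @export
frame_rate <- function(x) attr(x, "frame_rate")

#' Read / write trajectories as tidy delimited tables
#'
#' One row per frame, columns `time, x, y` plus optional `head_curvature`,
#' `eccentricity`.  The odor position travels in the call, not the file.
#'
#' @param file path to a delimited text file.
#' @param odor_position length-2 numeric (mm, mm).
#' @param handedness see [worm_trajectory()].
#' @param sep field separator.
#' @return [read_trajectory()] returns a `worm_trajectory`;
#'   [write_trajectory()] returns the path, invisibly.
#' @export
read_trajectory <- function(file, odor_position, handedness = "unknown",
                            sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep)
  worm_trajectory(df$time, df$x, df$y, odor_position,
                  head_curvature = df$head_curvature,
                  eccentricity = df$eccentricity,
                  handedness = handedness)
}

#' @rdname read_trajectory
#' @param trajectory a `worm_trajectory`.
#' @export
write_trajectory <- function(trajectory, file, sep = ",") {
  utils::write.table(as.data.frame(trajectory), file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
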