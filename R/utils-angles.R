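#' Wrap angles into (-180, 180]
#'
#' All angular arithmetic in the package runs through this helper so that the
#' seam at +/-180 degrees is handled once, consistently.
#'
#' @param a numeric vector of angles in degrees.
#' @return angles wrapped into (-180, 180].
#' @export
wrap_deg <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

#' Signed angular difference a - b, wrapped
#' @param a,b angles in degrees.
#' @return wrapped difference in (-180, 180].
#' @export
ang_diff <- function(a, b) wrap_deg(a - b)

# Direction (deg, CCW-positive from +x) of the displacement between two
# points; NA where the displacement is below `min_disp` (stationary frames
# must be flagged, not given spurious directions).
.displacement_dir <- function(dx, dy, min_disp = 1e-6) {
  d <- sqrt(dx^2 + dy^2)
  out <- atan2(dy, dx) * 180 / pi
  out[!is.finite(d) | d < min_disp] <- NA_real_
  out
}

# centered running mean, window in samples (odd); NA-safe at edges
.runmean <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.assert_scalar <- function(x, field, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("parameter '%s' must be a finite numeric scalar", field),
         call. = FALSE)
  if (x < lo || x > hi)
    stop(sprintf("parameter '%s' out of range [%g, %g]", field, lo, hi),
         call. = FALSE)
  invisible(x)
}
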