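#' Shuffle null for directed turning
#'
#' Tests whether reorientations improve the bearing more often than expected
#' from the marginal distributions of initial errors and turn angles alone.
#' Within each plate, the signed turn angles are permuted across events; for
#' each permutation the simulated final error is `wrap(theta_start -
#' delta_theta)` and an event counts as improved when `|theta_end| <
#' |theta_start|`.  The per-plate real fractions are compared against the
#' per-plate shuffled fractions.
#'
#' Two p-values are reported: `p_permutation`, the one-sided add-one
#' empirical probability that the mean shuffled fraction is at least the
#' mean real fraction, and `p_ranksum`, a Wilcoxon rank-sum test of the
#' per-plate real fractions against the per-plate mean shuffled fractions.
#'
#' @param events event table with `plate`, `theta_start`, `delta_theta`.
#' @param n_shuffles number of within-plate permutations.
#' @param seed integer seed.
#' @param replace if TRUE, sample turn angles with replacement instead of
#'   permuting.
#' @return an object of class `shuffle_result`.
#' @export
shuffle_turn_null <- function(events, n_shuffles = 1000, seed = 1L,
                              replace = FALSE) {
  ev <- as.data.frame(events)
  ev <- ev[is.finite(ev$theta_start) & is.finite(ev$delta_theta), ]
  plates <- split(ev, ev$plate)
  small <- vapply(plates, nrow, 1L) < 2L
  if (any(small)) {
    warning(sum(small), " plate(s) with < 2 events skipped")
    plates <- plates[!small]
  }
  if (!length(plates)) stop("no plate with at least 2 events")
  set.seed(seed)
  improved <- function(th, dth) abs(wrap_deg(th - dth)) < abs(th)
  real <- vapply(plates, function(d)
    mean(improved(d$theta_start, d$delta_theta)), 1)
  shuffled <- matrix(NA_real_, length(plates), n_shuffles,
                     dimnames = list(names(plates), NULL))
  for (p in seq_along(plates)) {
    d <- plates[[p]]
    m <- nrow(d)
    for (s in seq_len(n_shuffles)) {
      dth <- if (replace) sample(d$delta_theta, m, replace = TRUE)
             else sample(d$delta_theta, m)
      shuffled[p, s] <- mean(improved(d$theta_start, dth))
    }
  }
  shuf_means <- colMeans(shuffled)
  p_perm <- (1 + sum(shuf_means >= mean(real))) / (n_shuffles + 1)
  p_rs <- tryCatch(
    stats::wilcox.test(real, rowMeans(shuffled), exact = FALSE)$p.value,
    error = function(e) NA_real_)
  structure(list(real_fraction_improved = real,
                 shuffled_fraction_improved = shuffled,
                 p_permutation = p_perm, p_ranksum = p_rs,
                 n_shuffles = n_shuffles, seed = seed),
            class = "shuffle_result")
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(sprintf(
    "<shuffle_result> %d plates, %d shuffles\n  real fraction improved: %.3f (mean across plates)\n  shuffled: %.3f\n  p (permutation, one-sided): %.4g | p (rank-sum): %.4g\n",
    length(x$real_fraction_improved), x$n_shuffles,
    mean(x$real_fraction_improved), mean(x$shuffled_fraction_improved),
    x$p_permutation, x$p_ranksum))
  invisible(x)
}

#' Event-triggered average of the bearing
#'
#' Average bearing (cos theta) around reorientation onsets.  Frames inside
#' any reversal interval are masked out (bearing is unreliable during
#' backward movement) and never contribute to any time bin.
#'
#' @param trajectory a `worm_trajectory`.
#' @param events event table with `reversal_start`, `reversal_end` for this
#'   trajectory.
#' @param window half-window, s.
#' @return data.frame with `t` (s relative to onset), `mean_bearing`, `lo`,
#'   `hi`, `n`.
#' @export
bearing_triggered_average <- function(trajectory, events, window = 30) {
  fs <- attr(trajectory, "frame_rate")
  n <- nrow(trajectory)
  th <- direction_to_odor(trajectory, seq_len(n), window = 2)
  b <- bearing(th)
  mask <- rep(FALSE, n)
  for (e in seq_len(nrow(events)))
    mask[events$reversal_start[e]:events$reversal_end[e]] <- TRUE
  b[mask] <- NA_real_
  w <- as.integer(round(window * fs))
  offs <- -w:w
  acc <- matrix(NA_real_, nrow(events), length(offs))
  for (e in seq_len(nrow(events))) {
    idx <- events$reversal_start[e] + offs
    ok <- idx >= 1L & idx <= n
    acc[e, ok] <- b[idx[ok]]
  }
  mn <- colMeans(acc, na.rm = TRUE)
  nn <- colSums(!is.na(acc))
  se <- apply(acc, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nn, 1L))
  data.frame(t = offs / fs, mean_bearing = mn,
             lo = mn - 1.96 * se, hi = mn + 1.96 * se, n = nn)
}

#' Turn-amplitude distributions split by initial heading error
#'
#' Compares |delta-theta| between events that began with a small heading
#' error (|theta| in the `small` bin) and a large one (|theta| in the
#' `large` bin).  Optionally normalizes the binned densities by a no-odor
#' control event set.
#'
#' @param events event table with `theta_start`, `delta_theta`.
#' @param small,large inclusive |theta_start| ranges (deg) of the two bins.
#' @param normalizer optional control event table; densities are divided by
#'   the control's densities on shared breaks.
#' @param breaks histogram breaks for |delta_theta| (deg) used when
#'   normalizing.
#' @return list with per-bin amplitude vectors, medians, the rank-sum
#'   p-value, and (when `normalizer` given) normalized densities.
#' @export
amplitude_by_error <- function(events, small = c(0, 45), large = c(135, 180),
                               normalizer = NULL,
                               breaks = seq(0, 180, by = 20)) {
  ev <- as.data.frame(events)
  pick <- function(d, rng) {
    a <- abs(d$theta_start)
    abs(d$delta_theta[!is.na(a) & a >= rng[1] & a <= rng[2] &
                        is.finite(d$delta_theta)])
  }
  amp_small <- pick(ev, small)
  amp_large <- pick(ev, large)
  p <- if (length(amp_small) && length(amp_large))
    stats::wilcox.test(amp_large, amp_small, exact = FALSE)$p.value
  else NA_real_
  out <- list(small = amp_small, large = amp_large,
              median_small = stats::median(amp_small),
              median_large = stats::median(amp_large),
              p_ranksum = p)
  if (!is.null(normalizer)) {
    ctl <- as.data.frame(normalizer)
    dens <- function(a) {
      h <- graphics::hist(pmin(a, max(breaks)), breaks = breaks, plot = FALSE)
      h$density
    }
    ctl_small <- dens(pick(ctl, small)); ctl_large <- dens(pick(ctl, large))
    out$normalized_small <- dens(amp_small) / ifelse(ctl_small > 0,
                                                     ctl_small, NA)
    out$normalized_large <- dens(amp_large) / ifelse(ctl_large > 0,
                                                     ctl_large, NA)
    out$breaks <- breaks
  }
  out
}

#' Bearing at the ends of isolated vs pirouette reorientations
#'
#' Group means (with dispersion) of the final bearing `cos(theta_end)` for
#' isolated events, the first event of each pirouette, and the last event of
#' each pirouette.
#'
#' @param events event table with `theta_end` and `pirouette_id` (NA =
#'   isolated).
#' @return data.frame with one row per group: `group`, `mean_bearing`,
#'   `sem`, `n`.
#' @export
pirouette_end_bearing <- function(events) {
  ev <- as.data.frame(events)
  ev <- ev[is.finite(ev$theta_end), ]
  b <- bearing(ev$theta_end)
  iso <- is.na(ev$pirouette_id)
  first <- last <- rep(FALSE, nrow(ev))
  for (id in unique(stats::na.omit(ev$pirouette_id))) {
    idx <- which(!is.na(ev$pirouette_id) & ev$pirouette_id == id)
    first[idx[which.min(ev$reversal_start[idx])]] <- TRUE
    last[idx[which.max(ev$reversal_start[idx])]] <- TRUE
  }
  one <- function(sel, gname) {
    v <- b[sel]
    data.frame(group = gname,
               mean_bearing = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               n = length(v))
  }
  rbind(one(iso, "isolated"), one(first, "pirouette_first"),
        one(last, "pirouette_last"))
}
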