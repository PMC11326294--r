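#' Zero crossings of head curvature
#'
#' Finds the times at which the (dorsal-positive) head curvature crosses
#' zero, with linear sub-frame interpolation, and labels each crossing
#' "dv" (dorsal to ventral, positive to negative) or "vd".  Labels strictly
#' alternate; segments without a sign change yield no crossings.  Frames with
#' exactly zero curvature inherit the preceding sign so a touch-and-return
#' does not register as two crossings.
#'
#' @param head_curvature numeric vector, dorsal-positive.
#' @param frame_rate sampling rate, Hz.
#' @param time optional explicit time vector (overrides `frame_rate`).
#' @return data.frame with `time` (s), `index` (fractional frame) and
#'   `direction` ("dv" or "vd").
#' @export
detect_crossings <- function(head_curvature, frame_rate = NULL, time = NULL) {
  n <- length(head_curvature)
  if (is.null(time)) {
    if (is.null(frame_rate)) stop("give either frame_rate or time")
    time <- (seq_len(n) - 1L) / frame_rate
  }
  s <- sign(head_curvature)
  for (i in seq_len(n)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  ch <- which(s[-1L] != s[-n] & s[-n] != 0 & s[-1L] != 0)
  if (!length(ch)) {
    return(data.frame(time = numeric(), index = numeric(),
                      direction = character()))
  }
  y0 <- head_curvature[ch]; y1 <- head_curvature[ch + 1L]
  frac <- ifelse(y0 == y1, 0.5, y0 / (y0 - y1))
  data.frame(time = time[ch] + frac * (time[ch + 1L] - time[ch]),
             index = ch + frac,
             direction = ifelse(s[ch] > 0, "dv", "vd"))
}

# exact integral of the linear interpolant of (t, y) over [u, v]
.interp_integral <- function(t, y, u, v) {
  F <- c(0, cumsum(diff(t) * (y[-1L] + y[-length(y)]) / 2))
  evalF <- function(q) {
    i <- findInterval(q, t, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(t) - 1L)
    fq <- y[i] + (y[i + 1L] - y[i]) * (q - t[i]) / (t[i + 1L] - t[i])
    F[i] + (q - t[i]) * (y[i] + fq) / 2
  }
  evalF(v) - evalF(u)
}

#' Warp a trace onto uniform head-swing cycles
#'
#' Each half-cycle of head curvature (between consecutive zero crossings) is
#' resampled onto a fixed grid of `points_per_half` points, i.e. uniformly
#' stretched or compressed to the target cycle period.  The default method
#' ("cell") assigns each grid point the exact average of the linearly
#' interpolated signal over its phase bin, which preserves the per-half-cycle
#' mean exactly; method "point" samples the interpolant at the bin centers.
#'
#' @param values numeric vector (one neuron's activity, or head curvature).
#' @param time time vector (s), same length.
#' @param crossings output of [detect_crossings()].
#' @param target_period uniform cycle period, s.
#' @param points_per_half grid points per half-cycle.
#' @param method "cell" (phase-bin average) or "point" (interpolation at bin
#'   centers).
#' @param states optional per-frame movement state; each segment is labeled
#'   with its majority state.
#' @param min_frames half-cycles spanning fewer frames are skipped; the
#'   count of skipped half-cycles is reported in attribute `n_skipped`.
#' @return an object of class `warped_segments`: list with `values`
#'   (segments x points matrix), `direction`, `t_start`, `t_end`, `state`,
#'   `points_per_half`, `target_period`.
#' @export
warp_to_uniform_cycles <- function(values, time, crossings,
                                   target_period = 4.8, points_per_half = 12,
                                   method = c("cell", "point"),
                                   states = NULL, min_frames = 2L) {
  method <- match.arg(method)
  if (nrow(crossings) < 2L) stop("need at least one complete half-cycle")
  m <- points_per_half
  nseg <- nrow(crossings) - 1L
  out <- matrix(NA_real_, nseg, m)
  segstate <- rep(NA_character_, nseg)
  keep <- rep(TRUE, nseg)
  fs <- 1 / mean(diff(time))
  nT <- length(time)
  for (k in seq_len(nseg)) {
    u <- crossings$time[k]; v <- crossings$time[k + 1L]
    if ((v - u) * fs < min_frames) { keep[k] <- FALSE; next }
    edges <- u + (v - u) * (0:m) / m
    # work on the local slice of the signal only
    i0 <- max(1L, findInterval(u, time))
    i1 <- min(nT, findInterval(v, time) + 2L)
    tt <- time[i0:i1]; yy <- values[i0:i1]
    if (method == "cell") {
      out[k, ] <- .interp_integral(tt, yy, edges[-(m + 1L)],
                                   edges[-1L]) / ((v - u) / m)
    } else {
      ctr <- (edges[-(m + 1L)] + edges[-1L]) / 2
      out[k, ] <- stats::approx(tt, yy, xout = ctr, rule = 2)$y
    }
    if (!is.null(states)) {
      idx <- i0:i1
      idx <- idx[time[idx] >= u & time[idx] <= v]
      if (length(idx))
        segstate[k] <- names(which.max(table(states[idx])))
    }
  }
  structure(list(values = out[keep, , drop = FALSE],
                 direction = crossings$direction[seq_len(nseg)][keep],
                 t_start = crossings$time[seq_len(nseg)][keep],
                 t_end = crossings$time[-1L][keep],
                 state = segstate[keep],
                 points_per_half = m, target_period = target_period),
            n_skipped = sum(!keep), class = "warped_segments")
}

#' @export
print.warped_segments <- function(x, ...) {
  cat(sprintf(
    "<warped_segments> %d half-cycles x %d points (target period %.1f s, %d skipped)\n",
    nrow(x$values), x$points_per_half, x$target_period,
    attr(x, "n_skipped")))
  invisible(x)
}

# stack `span` consecutive half-cycles (contiguous in time, first one a
# "dv" crossing) into windows; returns row indices matrix (windows x span)
.cycle_windows <- function(seg, span, anchor = "dv") {
  nseg <- nrow(seg$values)
  if (nseg < span) return(matrix(integer(), 0, span))
  starts <- which(seg$direction == anchor)
  starts <- starts[starts + span - 1L <= nseg]
  ok <- vapply(starts, function(s) {
    idx <- s:(s + span - 1L)
    all(abs(seg$t_start[idx[-1L]] - seg$t_end[idx[-length(idx)]]) < 1e-6)
  }, TRUE)
  if (!any(ok)) return(matrix(integer(), 0, span))
  t(vapply(starts[ok], function(s) s:(s + span - 1L), integer(span)))
}

.boot_ci <- function(mat, n_boot = 200, conf = 0.95) {
  nr <- nrow(mat)
  if (nr < 2L) {
    return(list(lo = rep(NA_real_, ncol(mat)), hi = rep(NA_real_, ncol(mat))))
  }
  bm <- matrix(NA_real_, n_boot, ncol(mat))
  for (b in seq_len(n_boot))
    bm[b, ] <- colMeans(mat[sample.int(nr, nr, replace = TRUE), ,
                            drop = FALSE], na.rm = TRUE)
  a <- (1 - conf) / 2
  list(lo = apply(bm, 2, stats::quantile, a, na.rm = TRUE),
       hi = apply(bm, 2, stats::quantile, 1 - a, na.rm = TRUE))
}

#' Head-swing-aligned average activity
#'
#' Mean activity over two full head-swing cycles (four consecutive
#' half-cycles anchored at a dorsal-to-ventral crossing), restricted to
#' windows whose half-cycles all carry the requested movement state.
#' Confidence band by percentile bootstrap across windows.
#'
#' @param segments a `warped_segments` object built with `states`.
#' @param state movement state to average ("forward" or "reverse"), or NULL
#'   for all windows.
#' @param n_boot bootstrap replicates for the CI.
#' @param seed seed for the bootstrap.
#' @return a `warped_average`: data.frame with `phase` (cycles), `mean`,
#'   `lo`, `hi`, `n`; zero rows if no window qualifies.
#' @export
headswing_average <- function(segments, state = NULL, n_boot = 200,
                              seed = 1L) {
  win <- .cycle_windows(segments, span = 4L)
  if (!is.null(state) && nrow(win)) {
    ok <- apply(win, 1, function(idx)
      all(!is.na(segments$state[idx]) & segments$state[idx] == state))
    win <- win[ok, , drop = FALSE]
  }
  m <- segments$points_per_half
  phase <- (seq_len(4L * m) - 0.5) / (2L * m)
  if (!nrow(win)) {
    res <- data.frame(phase = phase, mean = NA_real_, lo = NA_real_,
                      hi = NA_real_, n = 0L)[0, ]
    class(res) <- c("warped_average", "data.frame")
    return(res)
  }
  mat <- t(apply(win, 1, function(idx) as.vector(t(segments$values[idx, ,
                                                                   drop = FALSE]))))
  set.seed(seed)
  ci <- .boot_ci(mat, n_boot)
  res <- data.frame(phase = phase, mean = colMeans(mat, na.rm = TRUE),
                    lo = ci$lo, hi = ci$hi, n = nrow(mat))
  class(res) <- c("warped_average", "data.frame")
  res
}

#' Dorsal/ventral label of a post-reversal turn
#'
#' Sign of the mean head curvature over the first one to two frames after
#' the reversal end: positive means dorsal, negative ventral, exactly zero
#' is excluded (NA).
#'
#' @param head_curvature per-frame signed curvature.
#' @param reversal_end frame index (vectorized).
#' @param frames_post which post-reversal frames to average (default 1:2).
#' @return character vector "dorsal"/"ventral", NA when undefined.
#' @export
turn_dv_label <- function(head_curvature, reversal_end, frames_post = 1:2) {
  n <- length(head_curvature)
  vapply(reversal_end, function(e) {
    idx <- e + frames_post
    idx <- idx[idx >= 1L & idx <= n]
    if (!length(idx)) return(NA_character_)
    mu <- mean(head_curvature[idx])
    if (mu > 0) "dorsal" else if (mu < 0) "ventral" else NA_character_
  }, "")
}

#' Cumulative post-reversal turn amplitude
#'
#' The absolute cumulative change in movement direction over the
#' `window`-second stretch after the reversal end (12 frames at the
#' whole-brain rate).  Events whose window is truncated by the recording
#' edge return NA.
#'
#' @param trajectory a `worm_trajectory`.
#' @param reversal_end frame index (vectorized).
#' @param window post-reversal window, s.
#' @return |cumulative direction change| in degrees.
#' @export
turn_amplitude <- function(trajectory, reversal_end, window = 7.2) {
  fs <- attr(trajectory, "frame_rate")
  n <- nrow(trajectory)
  w <- as.integer(round(window * fs))
  vapply(reversal_end, function(e) {
    if (e + w + 2L > n || e < 1L) return(NA_real_)
    # start one frame after the reversal end so the backward-to-forward
    # flip at the boundary itself is not counted as turning
    idx <- (e + 1L):(e + 1L + w)
    dir <- .displacement_dir(diff(trajectory$x[c(idx, e + w + 2L)]),
                             diff(trajectory$y[c(idx, e + w + 2L)]))
    dd <- ang_diff(dir[-1L], dir[-length(dir)])
    abs(sum(dd, na.rm = TRUE))
  }, 1)
}

#' Reversal-end-aligned group averages on the uniform phase grid
#'
#' Event-triggered averages of warped activity around reversal endings,
#' split into groups (e.g. dorsal vs ventral upcoming turn, or small vs
#' large turn amplitude).  Each event contributes the `n_half` half-cycles
#' before and after the crossing closest to its reversal end.  The group
#' statistic compares, across events, the mean activity within one head
#' swing (one full cycle) before -- and separately after -- the reversal end
#' (Wilcoxon rank-sum).
#'
#' @param segments a `warped_segments` object for the activity trace.
#' @param event_times reversal-end times (s), one per event.
#' @param groups factor/character of group labels, one per event; NA events
#'   are dropped.
#' @param n_half half-cycles kept on each side (4 = two full cycles).
#' @param n_boot bootstrap replicates for the CI.
#' @param seed seed for the bootstrap.
#' @return list with `averages` (one `warped_average` per group, phase 0 at
#'   reversal end), `p_pre`, `p_post` (rank-sum p of the first two listed
#'   groups), and `event_stats` (per-event pre/post means).
#' @export
reversal_end_aligned <- function(segments, event_times, groups, n_half = 4L,
                                 n_boot = 200, seed = 1L) {
  keep <- !is.na(groups)
  event_times <- event_times[keep]
  groups <- as.character(groups[keep])
  m <- segments$points_per_half
  nseg <- nrow(segments$values)
  rows <- list(); glab <- character(); pre <- numeric(); post <- numeric()
  for (e in seq_along(event_times)) {
    k <- which(segments$t_start >= event_times[e])[1]
    if (is.na(k) || k - n_half < 1L || k + n_half - 1L > nseg) next
    idx <- (k - n_half):(k + n_half - 1L)
    if (any(abs(segments$t_start[idx[-1L]] -
                segments$t_end[idx[-length(idx)]]) > 1e-6)) next
    rows[[length(rows) + 1L]] <-
      as.vector(t(segments$values[idx, , drop = FALSE]))
    glab <- c(glab, groups[e])
    one_pre <- segments$values[(k - 2L):(k - 1L), , drop = FALSE]
    one_post <- segments$values[k:(k + 1L), , drop = FALSE]
    pre <- c(pre, mean(one_pre, na.rm = TRUE))
    post <- c(post, mean(one_post, na.rm = TRUE))
  }
  if (!length(rows)) stop("no event with enough aligned half-cycles")
  mat <- do.call(rbind, rows)
  phase <- ((seq_len(2L * n_half * m) - 0.5) / (2 * m)) - n_half / 2
  set.seed(seed)
  avgs <- lapply(split(seq_along(glab), glab), function(ii) {
    sub <- mat[ii, , drop = FALSE]
    ci <- .boot_ci(sub, n_boot)
    res <- data.frame(phase = phase, mean = colMeans(sub, na.rm = TRUE),
                      lo = ci$lo, hi = ci$hi, n = length(ii))
    class(res) <- c("warped_average", "data.frame")
    res
  })
  gl <- names(avgs)
  p_pre <- p_post <- NA_real_
  if (length(gl) >= 2L) {
    a <- glab == gl[1]; b <- glab == gl[2]
    if (sum(a) > 1 && sum(b) > 1) {
      p_pre <- stats::wilcox.test(pre[a], pre[b], exact = FALSE)$p.value
      p_post <- stats::wilcox.test(post[a], post[b], exact = FALSE)$p.value
    }
  }
  list(averages = avgs, p_pre = p_pre, p_post = p_post,
       event_stats = data.frame(group = glab, pre_mean = pre,
                                post_mean = post))
}

#' Run-stretched average activity
#'
#' Selects forward runs whose duration lies in `select` seconds, linearly
#' resamples each onto a common fictitious `target`-second grid, and
#' averages.
#'
#' @param values activity vector.
#' @param time time vector, s.
#' @param runs data.frame with `start`, `end` frame indices of runs.
#' @param select admissible run duration range, s.
#' @param target fictitious duration all selected runs are stretched to, s.
#' @param n_points grid points of the stretched run.
#' @param n_boot,seed bootstrap CI parameters.
#' @return list with `grid` (data.frame: `t`, `mean`, `lo`, `hi`, `n`) and
#'   `matrix` (runs x points); zero-row grid if no run qualifies.
#' @export
stretch_runs <- function(values, time, runs, select = c(10, 20), target = 15,
                         n_points = 46, n_boot = 200, seed = 1L) {
  dur <- (runs$end - runs$start) / (1 / mean(diff(time)))
  sel <- which(dur >= select[1] & dur <= select[2])
  tgrid <- seq(0, target, length.out = n_points)
  if (!length(sel)) {
    return(list(grid = data.frame(t = numeric(), mean = numeric(),
                                  lo = numeric(), hi = numeric(),
                                  n = integer()),
                matrix = matrix(NA_real_, 0, n_points)))
  }
  mat <- t(vapply(sel, function(r) {
    idx <- runs$start[r]:runs$end[r]
    stats::approx(seq(0, target, length.out = length(idx)), values[idx],
                  xout = tgrid)$y
  }, numeric(n_points)))
  set.seed(seed)
  ci <- .boot_ci(mat, n_boot)
  list(grid = data.frame(t = tgrid, mean = colMeans(mat), lo = ci$lo,
                         hi = ci$hi, n = nrow(mat)),
       matrix = mat)
}

#' Odor-encounter vs spontaneous activity contrast
#'
#' Compares head-swing-aligned activity while the animal moves forward onto
#' the odor boundary against matched spontaneous forward movement,
#' separately by the side (dorsal/ventral) of the first head swing at the
#' encounter.
#'
#' @param segments a `warped_segments` object (built with `states` so
#'   forward half-cycles are identifiable).
#' @param encounters data.frame with `t_start`, `t_end`, `side`
#'   ("dorsal"/"ventral") windows of approach onto the odor.
#' @param spontaneous data.frame with `t_start`, `t_end` windows of
#'   spontaneous forward movement.
#' @return data.frame, one row per side: mean encounter activity, mean
#'   spontaneous activity, `contrast`, rank-sum `p`, segment counts.  If
#'   there are no encounters the spontaneous average alone is returned (side
#'   NA).
#' @export
encounter_comparison <- function(segments, encounters, spontaneous) {
  seg_in <- function(win) {
    hits <- rep(FALSE, nrow(segments$values))
    for (w in seq_len(nrow(win))) {
      hits <- hits | (segments$t_start >= win$t_start[w] &
                        segments$t_end <= win$t_end[w])
    }
    hits
  }
  spont <- seg_in(spontaneous)
  spont_vals <- rowMeans(segments$values[spont, , drop = FALSE], na.rm = TRUE)
  if (is.null(encounters) || nrow(encounters) == 0L) {
    return(data.frame(side = NA_character_,
                      encounter_mean = NA_real_,
                      spontaneous_mean = mean(spont_vals),
                      contrast = NA_real_, p = NA_real_,
                      n_encounter = 0L, n_spontaneous = sum(spont)))
  }
  out <- lapply(unique(encounters$side), function(sd) {
    enc <- seg_in(encounters[encounters$side == sd, , drop = FALSE])
    enc_vals <- rowMeans(segments$values[enc, , drop = FALSE], na.rm = TRUE)
    p <- if (length(enc_vals) > 1 && length(spont_vals) > 1)
      stats::wilcox.test(enc_vals, spont_vals, exact = FALSE)$p.value
    else NA_real_
    data.frame(side = sd, encounter_mean = mean(enc_vals),
               spontaneous_mean = mean(spont_vals),
               contrast = mean(enc_vals) - mean(spont_vals), p = p,
               n_encounter = sum(enc), n_spontaneous = sum(spont))
  })
  do.call(rbind, out)
}
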