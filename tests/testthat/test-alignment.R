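# analytic curvature signals on a fine clock
sine_curv <- function(duration = 120, fs = 10, period = 4.8, phase = 0) {
  t <- seq(0, duration, by = 1 / fs)
  list(t = t, k = sin(2 * pi * t / period + phase), fs = fs)
}

test_that("crossings of a pure sinusoid alternate every half period", {
  s <- sine_curv()
  cr <- detect_crossings(s$k, frame_rate = s$fs)
  expect_equal(diff(cr$time), rep(2.4, nrow(cr) - 1), tolerance = 1e-3)
  expect_true(all(cr$direction == rep(c("dv", "vd"),
                                      length.out = nrow(cr))))
  # constant-positive curvature has no crossings
  expect_identical(nrow(detect_crossings(rep(1, 50), frame_rate = 3)), 0L)
})

test_that("chirp half-cycle durations match the analytic half-periods", {
  # period sweeps 3 -> 6 s via linear instantaneous frequency
  fs <- 20; dur <- 60
  t <- seq(0, dur, by = 1 / fs)
  f0 <- 1 / 3; f1 <- 1 / 6
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * dur))
  k <- sin(phase)
  cr <- detect_crossings(k, frame_rate = fs)
  # analytic zero times: phase = j * pi
  jmax <- floor(max(phase) / pi)
  roots <- vapply(1:jmax, function(j)
    stats::uniroot(function(x) 2 * pi * (f0 * x + (f1 - f0) * x^2 /
                                           (2 * dur)) - j * pi,
                   c(0, dur))$root, 1)
  expect_equal(length(cr$time), length(roots))
  expect_lt(max(abs(diff(cr$time) - diff(roots))), 1 / fs)
})

test_that("warping preserves constants and per-half-cycle means", {
  s <- sine_curv(duration = 60)
  cr <- detect_crossings(s$k, frame_rate = s$fs)
  # constant activity warps to the same constant
  wc <- warp_to_uniform_cycles(rep(3.7, length(s$t)), s$t, cr)
  expect_true(all(abs(wc$values - 3.7) < 1e-9))
  # mass preservation: warped per-half-cycle mean equals the exact mean of
  # the interpolated signal over the same interval
  set.seed(8)
  v <- cumsum(rnorm(length(s$t)))
  wv <- warp_to_uniform_cycles(v, s$t, cr)
  for (k in seq_len(nrow(wv$values))) {
    exact <- wormnav:::.interp_integral(s$t, v, wv$t_start[k], wv$t_end[k]) /
      (wv$t_end[k] - wv$t_start[k])
    expect_lt(abs(mean(wv$values[k, ]) - exact), 1e-6)
  }
})

test_that("variable-frequency curvature warps onto the fixed template", {
  fs <- 20; dur <- 240
  t <- seq(0, dur, by = 1 / fs)
  f0 <- 1 / 3; f1 <- 1 / 6
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * dur))
  k <- sin(phase)
  cr <- detect_crossings(k, frame_rate = fs)
  w <- warp_to_uniform_cycles(k, t, cr, points_per_half = 12)
  avg <- headswing_average(w, state = NULL, n_boot = 50)
  template <- sin(2 * pi * avg$phase)  # dv-anchored: starts falling... sign
  # the dv anchor starts at a + -> - crossing, i.e. -sin(phase * 2pi)
  expect_gt(abs(stats::cor(avg$mean, template)), 0.99)
})

test_that("a 90-degree phase-shifted signal peaks a quarter cycle later", {
  fs <- 20
  s <- sine_curv(duration = 240, fs = fs)
  cr <- detect_crossings(s$k, frame_rate = fs)
  lag <- sin(2 * pi * s$t / 4.8 - pi / 2)   # lags curvature by 90 degrees
  wk <- warp_to_uniform_cycles(s$k, s$t, cr)
  wl <- warp_to_uniform_cycles(lag, s$t, cr)
  ak <- headswing_average(wk, NULL, n_boot = 10)
  al <- headswing_average(wl, NULL, n_boot = 10)
  # circular cross-correlation: the lagged signal should be the template
  # delayed by a quarter cycle (one quarter of 2*points_per_half bins)
  nb <- length(ak$mean)
  cc <- vapply(0:(nb - 1), function(s)
    stats::cor(al$mean, ak$mean[((seq_len(nb) - 1 - s) %% nb) + 1]), 1)
  best_shift_cycles <- (which.max(cc) - 1) / 24  # bins per cycle = 2 * 12
  expect_equal(best_shift_cycles %% 1, 0.25, tolerance = 0.021)
})

test_that("point-method warping is idempotent on an already-uniform signal", {
  # frame grid aligned with the 4.8 s cycle: crossings fall on frames and
  # the warp grid reproduces the original samples
  fs <- 10; m <- 24   # 2.4 s half-cycle = 24 frames
  t <- seq(0, 96, by = 1 / fs)
  k <- sin(2 * pi * t / 4.8)
  cr <- detect_crossings(k, frame_rate = fs)
  w <- warp_to_uniform_cycles(k, t, cr, points_per_half = m,
                              method = "point")
  for (kk in seq_len(nrow(w$values))) {
    orig <- stats::approx(t, k, xout = w$t_start[kk] +
                            (w$t_end[kk] - w$t_start[kk]) *
                            (seq_len(m) - 0.5) / m)$y
    expect_lt(sqrt(mean((w$values[kk, ] - orig)^2)), 1e-6)
  }
})

test_that("state-gated averages scale with the state gains and recombine", {
  sim <- simulate_walkers(walker_params(seed = 141, reversal_duration_mean = 12,
                                        reversal_duration_range = c(10, 20)), 1, 900)
  tr <- sim$trajectories[[1]]
  truth <- list(events = sim$truth$events[sim$truth$events$animal == 1, ],
                state = sim$truth$states[[1]])
  spec <- neuron_spec("S", state_gains = c(forward = 1, reverse = 3),
                      noise_sd = 0)
  tra <- simulate_neural_traces(tr, truth, list(spec), seed = 1)
  cr <- detect_crossings(tr$head_curvature, frame_rate = 3)
  w <- warp_to_uniform_cycles(tra$values[, 1], tr$time, cr,
                              states = truth$state)
  af <- headswing_average(w, "forward", n_boot = 20)
  ar <- headswing_average(w, "reverse", n_boot = 20)
  skip_if(nrow(af) == 0 || nrow(ar) == 0)
  ratio <- max(abs(ar$mean)) / max(abs(af$mean))
  expect_gt(ratio, 2); expect_lt(ratio, 4)
  # a state with zero segments returns an empty result, not an error
  expect_identical(nrow(headswing_average(w, "no-such-state")), 0L)

  # group-split averages recombine into the unsplit average
  win <- wormnav:::.cycle_windows(w, 4L)
  skip_if(nrow(win) < 4)
  mat <- t(apply(win, 1, function(idx) as.vector(t(w$values[idx, ]))))
  grp <- rep_len(c("a", "b"), nrow(mat))
  unsplit <- colMeans(mat)
  recomb <- (colSums(mat[grp == "a", , drop = FALSE]) +
               colSums(mat[grp == "b", , drop = FALSE])) / nrow(mat)
  expect_equal(recomb, unsplit, tolerance = 1e-12)
})

test_that("phase-inverted states anti-correlate", {
  sim <- simulate_walkers(walker_params(seed = 151, reversal_duration_mean = 12,
                                        reversal_duration_range = c(10, 20)), 1, 900)
  tr <- sim$trajectories[[1]]
  truth <- list(events = sim$truth$events[sim$truth$events$animal == 1, ],
                state = sim$truth$states[[1]])
  spec <- neuron_spec("S", state_gains = c(forward = 1, reverse = 1),
                      state_phases = c(forward = 0, reverse = pi),
                      noise_sd = 0)
  tra <- simulate_neural_traces(tr, truth, list(spec), seed = 1)
  cr <- detect_crossings(tr$head_curvature, frame_rate = 3)
  w <- warp_to_uniform_cycles(tra$values[, 1], tr$time, cr,
                              states = truth$state)
  af <- headswing_average(w, "forward", n_boot = 10)
  ar <- headswing_average(w, "reverse", n_boot = 10)
  skip_if(nrow(af) == 0 || nrow(ar) == 0)
  expect_lt(stats::cor(af$mean, ar$mean), -0.8)
})

test_that("turn labels and amplitudes recover the generated turn properties", {
  sim <- simulate_walkers(walker_params(seed = 161), 5, 900)
  amps <- trues <- numeric(0)
  for (a in 1:5) {
    tr <- sim$trajectories[[a]]
    ev <- sim$truth$events[sim$truth$events$animal == a, ]
    if (!nrow(ev)) next
    lab <- turn_dv_label(tr$head_curvature, ev$reversal_end)
    expect_identical(lab, ev$dv_sign)
    amp <- turn_amplitude(tr, ev$reversal_end)
    # events whose post window contains another reorientation measure that
    # pirouette, not this turn: restrict to temporally isolated events
    iso <- (c(ev$reversal_start[-1], Inf) - ev$turn_end) / 3 > 8
    ok <- !is.na(amp) & iso
    amps <- c(amps, amp[ok]); trues <- c(trues, abs(ev$delta_theta[ok]))
  }
  # cumulative |direction change| tracks the true turn magnitude
  # monotonically (the boundary frame truncates a fixed fraction of the
  # rotation, so the mapping is proportional rather than identity)
  expect_gt(stats::cor(amps, trues), 0.6)
  expect_gt(stats::median(amps[trues > 75]),
            stats::median(amps[trues < 40]))
  # degenerate inputs
  expect_identical(turn_dv_label(c(0, 0, 0, 0), 1), NA_character_)
  st <- straight_trajectory(30)
  expect_true(is.na(turn_amplitude(st, 25)))  # truncated window
})

test_that("predictive offsets separate dorsal and ventral pre-end activity", {
  sim <- simulate_walkers(walker_params(seed = 171,
                                        reversal_duration_mean = 6,
                                        reversal_duration_range = c(3, 7.5)),
                          4, 900)
  pre_d <- pre_v <- numeric(0)
  for (a in 1:4) {
    tr <- sim$trajectories[[a]]
    truth <- list(events = sim$truth$events[sim$truth$events$animal == a, ],
                  state = sim$truth$states[[a]])
    if (nrow(truth$events) < 6) next
    spec <- neuron_spec("P", predictive_offset = 1, noise_sd = 0.05)
    tra <- simulate_neural_traces(tr, truth, list(spec), seed = a)
    cr <- detect_crossings(tr$head_curvature, frame_rate = 3)
    w <- warp_to_uniform_cycles(tra$values[, 1], tr$time, cr)
    ends <- (truth$events$reversal_end - 1) / 3
    res <- tryCatch(
      reversal_end_aligned(w, ends, truth$events$dv_sign, n_boot = 20),
      error = function(e) NULL)
    if (is.null(res)) next
    es <- res$event_stats
    pre_d <- c(pre_d, es$pre_mean[es$group == "dorsal"])
    pre_v <- c(pre_v, es$pre_mean[es$group == "ventral"])
  }
  skip_if(length(pre_d) < 5 || length(pre_v) < 5)
  expect_gt(mean(pre_v) - mean(pre_d), 0.5)
  # label exchange destroys the difference
  allv <- c(pre_d, pre_v)
  set.seed(9)
  null_diffs <- replicate(200, {
    sh <- sample(allv)
    mean(sh[seq_along(pre_v)]) - mean(sh[-seq_along(pre_v)])
  })
  expect_gt(mean(pre_v) - mean(pre_d), stats::quantile(null_diffs, 0.99))
})

test_that("run stretching is affine-invariant and preserves ramp shape", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  # ramp within each run regardless of run length
  runs <- data.frame(start = c(1000, 3000), end = c(1000 + 12 * fs,
                                                    3000 + 18 * fs))
  v <- numeric(length(t))
  for (r in 1:2) {
    idx <- runs$start[r]:runs$end[r]
    v[idx] <- seq(0, 1, length.out = length(idx))
  }
  sr <- stretch_runs(v, t, runs, select = c(10, 20), target = 15)
  expect_identical(nrow(sr$matrix), 2L)
  # both runs stretch to the same normalized ramp
  expect_lt(max(abs(sr$matrix[1, ] - sr$matrix[2, ])), 1e-6)
  expect_true(all(diff(sr$grid$mean) > 0))
  # no runs in the window -> empty output
  none <- stretch_runs(v, t, data.frame(start = 1, end = 50))
  expect_identical(nrow(none$grid), 0L)
})

test_that("encounter contrasts reflect side-dependent sensory gain", {
  sim <- simulate_walkers(walker_params(seed = 181), 1, 900)
  tr <- sim$trajectories[[1]]
  truth <- list(events = sim$truth$events[sim$truth$events$animal == 1, ],
                state = sim$truth$states[[1]])
  # dorsal-gated sensory neuron with a strong response
  spec <- neuron_spec("E", sensory_gain = 2, sensory_side = "dorsal",
                      noise_sd = 0.01)
  tra <- simulate_neural_traces(tr, truth, list(spec), seed = 2)
  cr <- detect_crossings(tr$head_curvature, frame_rate = 3)
  w <- warp_to_uniform_cycles(tra$values[, 1], tr$time, cr,
                              states = truth$state)
  tmax <- max(tr$time)
  enc <- data.frame(t_start = c(100, 300), t_end = c(140, 340),
                    side = c("dorsal", "ventral"))
  spont <- data.frame(t_start = 500, t_end = 700)
  res <- encounter_comparison(w, enc, spont)
  expect_identical(sort(res$side), c("dorsal", "ventral"))
  # zero sensory gain: contrast vanishes
  spec0 <- neuron_spec("Z", noise_sd = 0.01)
  tra0 <- simulate_neural_traces(tr, truth, list(spec0), seed = 3)
  w0 <- warp_to_uniform_cycles(tra0$values[, 1], tr$time, cr)
  res0 <- encounter_comparison(w0, enc, spont)
  expect_true(all(abs(res0$contrast) < 0.05))
  # no encounters: spontaneous average only
  resn <- encounter_comparison(w0, enc[0, ], spont)
  expect_true(is.na(resn$side))
  expect_identical(resn$n_encounter, 0L)
})
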