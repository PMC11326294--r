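test_that("angular speed: straight path, direction flip, analytic circle", {
  tr <- straight_trajectory(60)
  ang <- compute_angular_speed(tr)
  expect_true(all(abs(ang[2:59]) < 1e-8))

  # instantaneous 180-degree flip at 3 Hz peaks at 540 deg/s
  fl <- flip_trajectory(30, fs = 3, flip_at = 15)
  expect_equal(max(compute_angular_speed(fl), na.rm = TRUE), 540)

  # circle of period 36 s turns at 10 deg/s (finite-difference oracle)
  circ <- circle_trajectory(n = 300, period = 36)
  dirs <- atan2(diff(circ$y), diff(circ$x)) * 180 / pi
  oracle <- abs(wormnav::ang_diff(dirs[-1], dirs[-length(dirs)])) * 3
  got <- compute_angular_speed(circ)
  expect_equal(got[2:299], oracle, tolerance = 1e-8)
  expect_equal(mean(got, na.rm = TRUE), 10, tolerance = 1e-6)
})

test_that("stationary segments yield flagged NA, not spurious speeds", {
  t <- (0:29) / 3
  x <- c(seq(0, 0.7, length.out = 15), rep(0.7, 15))
  tr <- worm_trajectory(t, x, rep(0, 30), c(30, 0))
  ang <- compute_angular_speed(tr)
  expect_true(all(is.na(ang[17:29])))
})

test_that("reversal detection pairs spikes left-to-right within the gap", {
  fs <- 3
  mk <- function(spike_frames) {
    v <- rep(10, 120)
    v[spike_frames] <- 400
    v
  }
  # two spikes 5 s apart -> one reversal spanning them
  r <- detect_reversals(mk(c(30, 45)), fs)
  expect_identical(nrow(r), 1L)
  expect_identical(r$reversal_start, 30L)
  expect_identical(r$reversal_end, 45L)
  # a single isolated spike is not a reversal
  expect_identical(nrow(detect_reversals(mk(60), fs)), 0L)
  # 10 s apart exceeds the 8.8 s pairing gap
  expect_identical(nrow(detect_reversals(mk(c(30, 60)), fs)), 0L)
  # three spikes: the first two pair, the third is left over
  r3 <- detect_reversals(mk(c(30, 45, 60)), fs)
  expect_identical(nrow(r3), 1L)
  expect_identical(r3$reversal_end, 45L)
  expect_identical(nrow(detect_reversals(numeric(0), fs)), 0L)
})

test_that("reversal detection recovers ground-truth events on walkers", {
  sim <- simulate_walkers(walker_params(seed = 61), 15, 1200)
  tp <- fp <- fn <- 0
  for (a in 1:15) {
    tr <- sim$trajectories[[a]]
    det <- detect_reversals(compute_angular_speed(tr),
                            attr(tr, "frame_rate"))
    tru <- sim$truth$events[sim$truth$events$animal == a, ]
    if (!nrow(tru)) next
    hit <- vapply(seq_len(nrow(det)), function(i)
      any(det$reversal_start[i] <= tru$turn_end &
            det$reversal_end[i] >= tru$reversal_start), TRUE)
    hitT <- vapply(seq_len(nrow(tru)), function(i)
      any(tru$reversal_start[i] <= det$reversal_end &
            tru$turn_end[i] >= det$reversal_start), TRUE)
    tp <- tp + sum(hit); fp <- fp + sum(!hit); fn <- fn + sum(!hitT)
  }
  expect_gte(tp / (tp + fp), 0.95)  # precision
  expect_gte(tp / (tp + fn), 0.95)  # recall
})

test_that("direction to odor and bearing follow the sign convention", {
  # moving straight at the odor
  expect_equal(direction_to_odor(straight_trajectory(30), 10), 0,
               tolerance = 1e-8)
  # moving directly away
  expect_equal(abs(direction_to_odor(straight_trajectory(30, angle = 180,
                                                         x0 = -5), 10)),
               180, tolerance = 1e-8)
  # odor due east, movement due north: odor is clockwise of movement
  th <- direction_to_odor(straight_trajectory(30, angle = 90), 1)
  expect_equal(th, -90, tolerance = 1e-6)
  expect_equal(bearing(c(0, 180, 60)), c(1, -1, 0.5))
  expect_true(is.na(bearing(NA_real_)))
})

test_that("reorientation angle recovers trivial and generated turns", {
  # identical pre/post directions
  tr <- straight_trajectory(60)
  expect_equal(reorientation_angle(tr, 20, 25), 0, tolerance = 1e-8)
  # north then east is a -90 (clockwise) change
  t <- (0:39) / 3
  x <- c(rep(0, 20), seq(0, by = 0.05, length.out = 20))
  y <- c(seq(0, by = 0.05, length.out = 20), rep(0.05 * 19, 20))
  tr2 <- worm_trajectory(t, x, y, c(30, 0))
  expect_equal(abs(reorientation_angle(tr2, 20, 20)), 90, tolerance = 1)
  # generated turns recovered within +/- 10 degrees
  sim <- simulate_walkers(walker_params(seed = 71), 10, 900)
  errs <- unlist(lapply(1:10, function(a) {
    tru <- sim$truth$events[sim$truth$events$animal == a, ]
    got <- reorientation_angle(sim$trajectories[[a]], tru$reversal_start,
                               tru$turn_end)
    wormnav::ang_diff(got, tru$delta_theta)
  }))
  expect_lt(stats::median(abs(errs), na.rm = TRUE), 10)
  expect_gt(mean(abs(errs) <= 10, na.rm = TRUE), 0.6)
})

test_that("turn classification thresholds and posture requirement", {
  sim <- simulate_walkers(walker_params(seed = 81, amplitude_noise_sd = 60),
                          10, 900)
  ev <- quantify_all(sim)
  tru <- sim$truth$events
  m <- match(ev$reversal_start, tru$reversal_start)
  ok <- !is.na(m)
  truemag <- abs(tru$delta_theta[m[ok]])
  # class assignment tracks the true magnitude through the 40/135 table
  tab <- table(factor(ev$turn_type[ok], levels = c("low", "mid", "omega")),
               cut(truemag, c(0, 40, 135, 180)))
  expect_gt(tab["low", 1] / sum(tab[, 1]), 0.7)
  expect_gt(tab["mid", 2] / sum(tab[, 2]), 0.7)
  if (sum(tab[, 3]) > 5) expect_gt(tab["omega", 3] / sum(tab[, 3]), 0.5)

  # missing eccentricity degrades to a flagged angle-only call
  tr <- sim$trajectories[[1]]
  tr2 <- worm_trajectory(tr$time, tr$x, tr$y, attr(tr, "odor_position"))
  r1 <- sim$truth$events[sim$truth$events$animal == 1, ][1, ]
  expect_warning(ct <- classify_turn(tr2, r1$reversal_start, r1$reversal_end),
                 "eccentricity")
  expect_true(ct$flag)
})

test_that("pirouette grouping uses a strict 13 s end-to-start rule", {
  fs <- 3
  mk <- function(starts, ends) data.frame(reversal_start = starts,
                                          turn_end = ends)
  # gaps of 10 s and 10 s: one pirouette of three
  ev <- mk(c(100, 160, 220), c(130, 190, 250))
  expect_identical(group_pirouettes(ev, fs), c(1L, 1L, 1L))
  # a 20 s gap separates groups
  ev2 <- mk(c(100, 160, 320), c(130, 190, 350))
  expect_identical(group_pirouettes(ev2, fs), c(1L, 1L, NA_integer_))
  # a gap of exactly 13.0 s separates (strict inequality)
  ev3 <- mk(c(100, 130 + 13 * fs), c(130, 160 + 13 * fs))
  expect_identical(group_pirouettes(ev3, fs), c(NA_integer_, NA_integer_))
  # just under 13 s joins
  ev4 <- mk(c(100, 130 + 13 * fs - 1), c(130, 160))
  expect_identical(group_pirouettes(ev4, fs), c(1L, 1L))
  expect_identical(group_pirouettes(mk(integer(0), integer(0)), fs),
                   integer(0))
})

test_that("towards/away and correct-direction classifications", {
  expect_true(classify_towards_away(120, 40))
  expect_false(classify_towards_away(40, 120))
  expect_false(classify_towards_away(90, 90))   # strict inequality
  expect_false(classify_towards_away(90, -90))
  expect_true(classify_correct_direction(60, 30))
  expect_false(classify_correct_direction(-60, 30))
  expect_true(is.na(classify_correct_direction(0, 30)))
})

test_that("weathervaning profile recovers an injected -sin(theta) bend", {
  # many short runs, each launched at a random direction to a far-east odor
  # and bending at a constant curving rate of -50*sin(theta) deg/mm
  fs <- 3; speed <- 0.15; run_len <- 30L; n_runs <- 300
  set.seed(5)
  x <- y <- t <- numeric(0)
  runs <- data.frame(start = integer(), end = integer())
  for (r in seq_len(n_runs)) {
    theta0 <- runif(1, -180, 180)
    heading0 <- -theta0               # odor due east: theta = -heading
    dh <- -50 * sinpi(theta0 / 180) * speed / fs   # deg per frame
    h <- heading0 + dh * (0:(run_len - 1))
    xs <- cumsum(c(0, speed / fs * cos(h[-run_len] * pi / 180)))
    ys <- cumsum(c(0, speed / fs * sin(h[-run_len] * pi / 180)))
    runs <- rbind(runs, data.frame(start = length(x) + 1L,
                                   end = length(x) + run_len))
    x <- c(x, xs); y <- c(y, ys)
  }
  tr <- worm_trajectory((seq_along(x) - 1) / fs, x, y, c(1e6, 0))
  prof <- weathervane_profile(tr, runs, run_head = 5)
  ok <- is.finite(prof$curving_rate) & prof$n > 10
  expect_gt(stats::cor(prof$curving_rate[ok],
                       -50 * sinpi(prof$theta_mid[ok] / 180)), 0.9)
  # straight runs give a flat profile
  st <- straight_trajectory(600)
  prof0 <- weathervane_profile(st, data.frame(start = 1, end = 580))
  expect_true(all(abs(prof0$curving_rate[prof0$n > 0]) < 1e-6))
})

test_that("pause frames are excluded from weathervaning", {
  st <- straight_trajectory(300, speed = 0.02)  # below the 0.04 mm/s cutoff
  prof <- weathervane_profile(st, data.frame(start = 1, end = 280))
  expect_true(all(prof$n == 0))
})

test_that("reorientation rate by bearing: flat under null, biased with gain", {
  sim0 <- simulate_walkers(null_walker_params(seed = 91), 10, 900)
  ev0 <- sim0$truth$events
  prof0 <- do.call(rbind, lapply(1:10, function(a)
    reorientation_rate_by_bearing(ev0[ev0$animal == a, ],
                                  sim0$trajectories[[a]],
                                  bin_width = 0.5)))
  agg0 <- stats::aggregate(cbind(n_events, occupancy_s) ~ bearing_mid,
                           prof0, sum)
  rates0 <- agg0$n_events / agg0$occupancy_s * 60
  expect_lt(diff(range(rates0)) / mean(rates0), 0.5)

  sim1 <- simulate_walkers(walker_params(bearing_rate_gain = 0.7, seed = 92),
                           10, 900)
  ev1 <- sim1$truth$events
  prof1 <- do.call(rbind, lapply(1:10, function(a)
    reorientation_rate_by_bearing(ev1[ev1$animal == a, ],
                                  sim1$trajectories[[a]],
                                  bin_width = 0.5)))
  agg1 <- stats::aggregate(cbind(n_events, occupancy_s) ~ bearing_mid,
                           prof1, sum)
  rates1 <- agg1$n_events / agg1$occupancy_s * 60
  expect_gt(rates1[1], rates1[length(rates1)])  # away > towards

  # zero-occupancy bins are NA, not zero
  st <- straight_trajectory(100)
  pr <- reorientation_rate_by_bearing(
    data.frame(theta_start = numeric(0)), st)
  expect_true(all(is.na(pr$rate[pr$occupancy_s == 0])))
})

test_that("chemotaxis index follows the counting formula", {
  expect_equal(chemotaxis_index(80, 20, 100), 0.6)
  expect_equal(chemotaxis_index(0, 0, 50), 0)
  expect_equal(chemotaxis_index(50, 0, 50), 1)
  expect_error(chemotaxis_index(1, 1, 0), "positive")
})

test_that("metrics are equivariant under rotation and reflect under mirroring", {
  sim <- simulate_walkers(walker_params(seed = 101), 2, 600)
  tr <- sim$trajectories[[1]]
  ev <- as.data.frame(quantify_navigation(tr))
  skip_if(nrow(ev) < 3)
  rot <- function(x, y, a) list(x = x * cos(a) - y * sin(a),
                                x2 = x * sin(a) + y * cos(a))
  a <- 0.83
  odor <- attr(tr, "odor_position")
  ro <- rot(odor[1], odor[2], a)
  rp <- rot(tr$x, tr$y, a)
  trR <- worm_trajectory(tr$time, rp$x, rp$x2, c(ro$x, ro$x2),
                         head_curvature = tr$head_curvature,
                         eccentricity = tr$eccentricity,
                         handedness = attr(tr, "handedness"))
  evR <- as.data.frame(quantify_navigation(trR))
  expect_equal(evR$theta_start, ev$theta_start, tolerance = 1e-6)
  expect_equal(evR$delta_theta, ev$delta_theta, tolerance = 1e-6)
  expect_identical(evR$correct_direction, ev$correct_direction)

  # mirror: y -> -y flips signed angles, leaves scalar classifications
  trM <- worm_trajectory(tr$time, tr$x, -tr$y, c(odor[1], -odor[2]),
                         head_curvature = tr$head_curvature,
                         eccentricity = tr$eccentricity,
                         handedness = attr(tr, "handedness"))
  evM <- as.data.frame(quantify_navigation(trM))
  # compare as angles (the +/-180 seam maps to itself under mirroring)
  expect_equal(max(abs(ang_diff(evM$theta_start, -ev$theta_start))), 0,
               tolerance = 1e-6)
  expect_equal(max(abs(ang_diff(evM$delta_theta, -ev$delta_theta))), 0,
               tolerance = 1e-6)
  expect_identical(evM$towards_odor, ev$towards_odor)
  expect_identical(evM$correct_direction, ev$correct_direction)
})
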