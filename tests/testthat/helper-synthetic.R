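# Shared fixture builders: everything is generated in code at test time.

# straight constant-velocity trajectory moving at `angle` deg
straight_trajectory <- function(n = 100, fs = 3, speed = 0.15, angle = 0,
                                odor = c(30, 0), x0 = 0, y0 = 0, ...) {
  t <- (seq_len(n) - 1) / fs
  worm_trajectory(t,
                  x0 + speed * t * cos(angle * pi / 180),
                  y0 + speed * t * sin(angle * pi / 180),
                  odor, ...)
}

# circular path with given period (s); radius set by speed
circle_trajectory <- function(n = 200, fs = 3, period = 36, speed = 0.15,
                              odor = c(30, 0)) {
  t <- (seq_len(n) - 1) / fs
  omega <- 2 * pi / period
  r <- speed / omega
  worm_trajectory(t, r * cos(omega * t), r * sin(omega * t), odor)
}

# a path that flips direction 180 degrees at frame `flip_at`
flip_trajectory <- function(n = 30, fs = 3, flip_at = 15, speed = 0.15) {
  t <- (seq_len(n) - 1) / fs
  x <- speed / fs * c(seq(0, flip_at - 1),
                      seq(flip_at - 2, by = -1, length.out = n - flip_at))
  worm_trajectory(t, x, rep(0, n), c(30, 0))
}

# whole-brain style decoder dataset: long reversals, SAAV-like neuron with a
# predictive offset before ventral turns
gen_decoder_data <- function(seed, offset = 0.5, noise = 0.3,
                             n_animals = 10, duration = 1200) {
  p <- walker_params(frame_rate = 1.667, reversal_duration_mean = 10,
                     reversal_duration_range = c(6, 18),
                     base_reorientation_rate = 2.5,
                     pirouette_reentry_prob = function(b) 0, seed = seed)
  sim <- simulate_walkers(p, n_animals, duration)
  recs <- list()
  for (a in seq_along(sim$trajectories)) {
    tr <- sim$trajectories[[a]]
    truth <- list(events = sim$truth$events[sim$truth$events$animal == a, ],
                  state = sim$truth$states[[a]])
    spec <- neuron_spec("SAAV",
                        state_gains = c(forward = 0.2, reverse = 0.3,
                                        turn = 0.2),
                        predictive_offset = offset, noise_sd = noise)
    tra <- simulate_neural_traces(tr, truth, list(spec),
                                  seed = seed * 1000 + a)
    ds <- build_decoder_dataset(tra$values[, 1], tr$head_curvature, tr$time,
                                truth$events)
    recs <- c(recs, unclass(ds))
  }
  structure(recs, class = "decoder_dataset")
}

# quantify all animals of a simulation into one events table
quantify_all <- function(sim, animals_per_plate = 10) {
  do.call(rbind, lapply(seq_along(sim$trajectories), function(a)
    as.data.frame(quantify_navigation(sim$trajectories[[a]],
                                      plate = ceiling(a / animals_per_plate),
                                      animal = a))))
}
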