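#' Specification of a synthetic neuron's activity motifs
#'
#' Each motif mirrors a qualitative activity feature of the head-steering
#' circuit: head-swing-locked oscillation whose amplitude and phase depend on
#' the movement state, within-state activity ramps, turn-kinematics scaling,
#' a predictive offset during reversals that precede ventral turns, and a
#' (possibly side-gated) odor-concentration response.  A spec with all gains
#' zero yields pure Gaussian noise.
#'
#' @param label neuron-class name (must be unique within a trace set).
#' @param state_gains named numeric: oscillation amplitude per movement state
#'   (`forward`, `reverse`, `turn`).
#' @param state_phases named numeric: phase offset (rad) of the oscillation
#'   relative to head curvature, per state; positive lags the curvature.
#' @param ramp_slope activity/s added cumulatively within each bout of
#'   `ramp_state`.
#' @param ramp_state state in which the ramp runs.
#' @param turn_kinematics_gain activity added during turn frames per 90
#'   degrees of turn magnitude.
#' @param kinematics_ventral_only if TRUE the kinematics term applies to
#'   ventral turns only.
#' @param predictive_offset activity added throughout reversals that precede
#'   ventral (vs dorsal) turns.
#' @param sensory_gain activity per unit odor concentration.
#' @param sensory_side "both", "dorsal" or "ventral": gate the sensory term
#'   on the sign of the instantaneous head curvature.
#' @param noise_sd Gaussian noise sd (activity units).
#' @return an object of class `neuron_spec`.
#' @export
neuron_spec <- function(label,
                        state_gains = c(forward = 0, reverse = 0, turn = 0),
                        state_phases = c(forward = 0, reverse = 0, turn = 0),
                        ramp_slope = 0, ramp_state = "reverse",
                        turn_kinematics_gain = 0,
                        kinematics_ventral_only = FALSE,
                        predictive_offset = 0,
                        sensory_gain = 0,
                        sensory_side = c("both", "dorsal", "ventral"),
                        noise_sd = 0.05) {
  sensory_side <- match.arg(sensory_side)
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("label must be a non-empty string")
  .assert_scalar(noise_sd, "noise_sd", lo = 0)
  gains <- c(forward = 0, reverse = 0, turn = 0)
  gains[names(state_gains)] <- state_gains
  phases <- c(forward = 0, reverse = 0, turn = 0)
  phases[names(state_phases)] <- state_phases
  structure(list(label = label, state_gains = gains, state_phases = phases,
                 ramp_slope = ramp_slope, ramp_state = ramp_state,
                 turn_kinematics_gain = turn_kinematics_gain,
                 kinematics_ventral_only = kinematics_ventral_only,
                 predictive_offset = predictive_offset,
                 sensory_gain = sensory_gain, sensory_side = sensory_side,
                 noise_sd = noise_sd),
            class = "neuron_spec")
}

#' Simulate neural activity traces coupled to a trajectory
#'
#' Builds one activity trace per [neuron_spec()] on the trajectory's own
#' clock: state-gated oscillation phase-locked to head curvature, plus ramps,
#' event-locked kinematics and predictive terms, a sensory term driven by an
#' exponentially decaying odor field, and Gaussian noise.
#'
#' @param trajectory a `worm_trajectory` with head curvature.
#' @param truth ground truth for this animal: a list with `events` (the
#'   event table restricted to this animal) and `state` (per-frame movement
#'   state vector), as produced by [simulate_walkers()].
#' @param specs list of `neuron_spec` objects with distinct labels.
#' @param seed integer seed.
#' @param odor_length_scale decay length (mm) of the odor concentration
#'   field `exp(-distance / odor_length_scale)`.
#' @return an object of class `neural_traces`: list with `time`, `values`
#'   (frames x neurons matrix), `frame_rate`.
#' @export
simulate_neural_traces <- function(trajectory, truth, specs, seed = 1L,
                                   odor_length_scale = 10) {
  stopifnot(inherits(trajectory, "worm_trajectory"))
  if (is.null(trajectory$head_curvature))
    stop("trajectory must carry per-frame head curvature")
  if (inherits(specs, "neuron_spec")) specs <- list(specs)
  labels <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate neuron labels: ", paste(unique(labels[duplicated(labels)]),
                                            collapse = ", "))
  state <- truth$state
  events <- truth$events
  n <- nrow(trajectory)
  if (length(state) != n)
    stop("truth$state must have one entry per trajectory frame")
  set.seed(seed)
  fs <- attr(trajectory, "frame_rate")
  curv <- trajectory$head_curvature

  # normalized curvature and its quadrature (derivative) component, so a
  # phase offset p yields an oscillation lagging the curvature by p
  amp <- sqrt(2) * stats::sd(curv)
  if (amp < 1e-12) amp <- 1
  k <- curv / amp
  dk <- c(0, diff(curv)) * fs
  period <- .dominant_half_period(curv, fs) * 2
  kd <- dk / (2 * pi / period * amp)

  conc <- exp(-sqrt((trajectory$x - attr(trajectory, "odor_position")[1])^2 +
                    (trajectory$y - attr(trajectory, "odor_position")[2])^2) /
              odor_length_scale)
  tvec <- trajectory$time

  values <- matrix(0, n, length(specs), dimnames = list(NULL, labels))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    v <- numeric(n)
    for (stn in c("forward", "reverse", "turn")) {
      g <- sp$state_gains[[stn]]
      if (g != 0) {
        p <- sp$state_phases[[stn]]
        idx <- state == stn
        v[idx] <- v[idx] + g * (cos(p) * k[idx] - sin(p) * kd[idx])
      }
    }
    if (sp$ramp_slope != 0) {
      in_state <- state == sp$ramp_state
      r <- rle(in_state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (b in which(r$values)) {
        idx <- starts[b]:ends[b]
        v[idx] <- v[idx] + sp$ramp_slope * (tvec[idx] - tvec[idx[1]])
      }
    }
    if (nrow(events)) {
      for (e in seq_len(nrow(events))) {
        ventral <- events$dv_sign[e] == "ventral"
        if (sp$predictive_offset != 0 && ventral) {
          idx <- events$reversal_start[e]:events$reversal_end[e]
          v[idx] <- v[idx] + sp$predictive_offset
        }
        if (sp$turn_kinematics_gain != 0 &&
            (!sp$kinematics_ventral_only || ventral) &&
            events$turn_end[e] > events$reversal_end[e]) {
          idx <- (events$reversal_end[e] + 1L):events$turn_end[e]
          v[idx] <- v[idx] +
            sp$turn_kinematics_gain * abs(events$delta_theta[e]) / 90
        }
      }
    }
    if (sp$sensory_gain != 0) {
      gate <- switch(sp$sensory_side,
                     both = rep(TRUE, n),
                     dorsal = curv > 0,
                     ventral = curv < 0)
      v[gate] <- v[gate] + sp$sensory_gain * conc[gate]
    }
    if (sp$noise_sd > 0) v <- v + stats::rnorm(n, 0, sp$noise_sd)
    values[, j] <- v
  }
  structure(list(time = tvec, values = values, frame_rate = fs),
            class = "neural_traces")
}

#' @export
print.neural_traces <- function(x, ...) {
  cat(sprintf("<neural_traces> %d neurons x %d frames at %.3g Hz: %s\n",
              ncol(x$values), nrow(x$values), x$frame_rate,
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}

# mean half-period (s) from zero crossings; falls back to 2.4 s if the
# signal never changes sign
.dominant_half_period <- function(x, fs) {
  s <- sign(x)
  ch <- which(s[-1] != s[-length(s)] & s[-1] != 0)
  if (length(ch) < 2L) return(2.4)
  mean(diff(ch)) / fs
}

#' Simulate a neuron x receptor expression table (TPM)
#'
#' Generates a sparse non-negative TPM matrix.  Under the null, entries are
#' i.i.d.; with `enriched_set`, the named neurons' rows are scaled up by
#' `enrich_factor`, creating genuine set-level enrichment for the permutation
#' test to detect.
#'
#' @param n_neurons,n_receptors table dimensions.
#' @param null if TRUE the table is i.i.d. (ignores `enriched_set`).
#' @param enriched_set character vector of neuron labels to enrich.
#' @param enrich_factor multiplicative enrichment.
#' @param expressed_prob probability an entry is nonzero.
#' @param seed integer seed.
#' @return numeric matrix with neuron rownames and receptor colnames.
#' @export
simulate_expression <- function(n_neurons, n_receptors, null = TRUE,
                                enriched_set = NULL, enrich_factor = 5,
                                expressed_prob = 0.7, seed = 1L) {
  if (n_receptors < 1L) stop("n_receptors must be at least 1")
  if (n_neurons < 1L) stop("n_neurons must be at least 1")
  set.seed(seed)
  neurons <- sprintf("N%03d", seq_len(n_neurons))
  receptors <- sprintf("rec%d", seq_len(n_receptors))
  tpm <- matrix(stats::rbinom(n_neurons * n_receptors, 1L, expressed_prob) *
                  stats::rgamma(n_neurons * n_receptors, shape = 1.2,
                                scale = 250),
                n_neurons, n_receptors,
                dimnames = list(neurons, receptors))
  # every receptor must be expressed somewhere for max-normalization
  for (jcol in which(colSums(tpm) == 0)) {
    tpm[sample.int(n_neurons, 1L), jcol] <-
      stats::rgamma(1, shape = 1.2, scale = 250)
  }
  if (!null && !is.null(enriched_set)) {
    if (!all(enriched_set %in% neurons))
      stop("enriched_set must be a subset of the neuron labels")
    rows <- match(enriched_set, neurons)
    tpm[rows, ] <- tpm[rows, , drop = FALSE] * enrich_factor
  }
  tpm
}
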