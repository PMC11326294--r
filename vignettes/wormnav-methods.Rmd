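---
title: "Models and methods behind wormnav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wormnav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormnav)
```

## The scientific problem

*C. elegans* navigates odor gradients as a biased non-random walk.  An
animal crawling on a plate holds a movement direction, and the signed angle
$\theta \in (-180^\circ, 180^\circ]$ between that direction and the
animal-to-odor vector measures its heading error; the *bearing*
$\cos\theta$ is $+1$ when moving straight at the source and $-1$ when
moving away.  Navigation is realized through discrete *reorientations*: a
bout of backward movement (reversal) followed by a dorsal or ventral turn.
Three gradient couplings make the walk biased:

1. **Rate bias** — the per-frame reorientation hazard rises as the bearing
   worsens (hazard $\propto 1 - g_r\cos\theta$);
2. **Amplitude coupling** — the executed direction change $\Delta\theta$
   grows with the initial error, $|\Delta\theta| \approx
   g_a\,|\theta_\mathrm{start}| + \varepsilon$;
3. **Sign (dorsal/ventral) bias** — the turn corrects the sign of the error
   with probability $p_c > 0.5$.

`wormnav` implements, end to end: a seeded generative simulator of such
walkers with ground truth; detection and quantification of reorientation
events from raw trajectories; population statistics including a
within-plate shuffle null for directed turning; head-swing phase warping
and event-triggered averaging of neural traces; behavior-matched quintile
subsampling and a receptor-expression permutation test; and a
gated-recurrent-unit (GRU) decoder of upcoming turn direction with
hierarchical cross-validation.

## The walker simulator and what it does (and does not) emulate

`simulate_walkers()` integrates each animal at the behavioral frame rate
(3 Hz by default) through a three-state machine (forward, reverse, turn).
Heading is a continuous angle; head curvature is a sinusoidal body-bend
term with a 4.8 s cycle, signed dorsal-positive, and the step direction
deviates sinusoidally from the heading (crawling sinuosity, default
6° — centroid paths from multi-animal trackers wiggle much less than the
head itself because the body centroid averages out the bend).  Reversal
durations are truncated-exponential (the data give no generative reversal
model, so the simplest memoryless choice is used); the turn's heading
change is executed over one second after the reversal, producing the two
supra-threshold angular-speed spikes that the detector expects.
Dorsal/ventral identity maps to image-plane rotation sense per animal
through `handedness`.  After an event, a follow-up event may be scheduled
within 2–9 s with probability `pirouette_reentry_prob(bearing)`, producing
pirouette clustering under the strict `< 13 s` rule.  The arena boundary
reflects the heading, which avoids escapes without biasing interior
statistics.  The odor field used by sensory neurons is a smooth exponential
decay of distance; only relative gradients matter downstream.

Default parameters are fixed once as plausible study conditions: speed
0.15 mm/s, base rate 1.5 events/min with hazard slope 0.5, amplitude gain
0.5 deg/deg with 25° noise and a 15° floor, sign-correctness 0.6 (the real
effect is small; `p_correct_dv` is exposed rather than fixed because no
quantitative magnitude is available), reversal duration mean 2.5 s.  The
null configuration (`null_walker_params()`) zeroes every gradient coupling
and is provably a pure unbiased random walk.

The simulator does **not** model a biomechanical body, posture images, odor
diffusion, food state, or multi-animal collisions.  Consequently, passing
recovery tests shows the *analysis* code is correct under the stated
statistical structure — it does not validate the analyses against
real-tracker artifacts such as segmentation errors, collisions, or
non-sinusoidal gaits.

Synthetic neural traces (`simulate_neural_traces()`) superimpose, per
neuron: a state-gated oscillation phase-locked to head curvature (built
from the normalized curvature and its quadrature so any phase offset is
realizable on arbitrary curvature), within-state linear ramps,
turn-kinematics terms scaling with turn magnitude, a constant predictive
offset during reversals that precede ventral turns, a (possibly
side-gated) odor-concentration response, and Gaussian noise.

## Event detection and navigation metrics

Angular speed is the wrapped frame-to-frame change of the centroid
movement direction (deg/s); stationary frames are flagged `NA` rather than
given spurious directions.  A reversal is a pair of supra-threshold spikes
(default 75 deg/s) closer than 8.8 s, consumed left-to-right; unpaired
spikes are dropped.  Turn types use the 40°/135° direction-change
thresholds with boundary values assigned to the lower class; omega and
mid-angle calls additionally require an eccentricity drop (thresholds are
configurable because posture calibration is tracker-specific), and the
posture search window straddles the detected reversal end because
high-angle turns keep angular speed supra-threshold into the turn.
Without eccentricity the classification degrades to angle-only and is
flagged.

Movement direction uses a 2 s displacement window (1 s for the
reorientation angle windows); the direction "at event start" uses the
pre-event window.  Towards/away is the strict inequality
$|\theta_\mathrm{start}| > |\theta_\mathrm{end}|$; correct-direction is
$\mathrm{sign}(\theta_\mathrm{start}) = \mathrm{sign}(\Delta\theta)$ with
$\theta_\mathrm{start}=0$ events excluded as degenerate.  Pirouette
grouping uses the end-to-next-start interval with a strict 13 s rule.  All
angle arithmetic runs through a single wrapping helper, and the suite
property-tests the ±180° seam against a complex-argument oracle, plus
rotation equivariance and mirror antisymmetry of the full pipeline.

The shuffle null (`shuffle_turn_null()`) permutes $\Delta\theta$ across
events within a plate and scores simulated outcomes
$\theta_\mathrm{end} = \mathrm{wrap}(\theta_\mathrm{start} -
\Delta\theta)$.  Permutation without replacement is the default (sampling
with replacement is available).  Two p-values are reported: a one-sided
add-one permutation p for the pooled mean fraction improved — used for the
calibration claims because it is exact under exchangeability — and a
rank-sum test of per-plate real vs shuffled fractions, mirroring the
plate-level testing style used with real recordings.

## Head-swing alignment

Head-swing frequency varies across time and animals, so curvature-locked
signals cancel in plain time averages.  `detect_crossings()` finds
zero crossings of the signed curvature with linear sub-frame
interpolation (exact zeros inherit the preceding sign so a touch does not
double-count).  `warp_to_uniform_cycles()` maps every half-cycle onto a
fixed grid (12 points per half-cycle by default), i.e. uniformly
compresses or stretches each interval to the 4.8 s target cycle.  The
default resampling assigns each grid point the exact average of the
linearly interpolated signal over its phase bin, which preserves the
per-half-cycle mean to machine precision; plain interpolation at bin
centers is available (`method = "point"`) and is the identity on signals
already at the target period.  Averages are displayed over two full
cycles anchored at dorsal-to-ventral crossings; confidence bands are
percentile bootstrap across segments (the method behind the real data's
intervals is not fully specified, so the bootstrap is used and stated).
Reversal-end-aligned group statistics compare mean activity within one
full head swing before, and separately after, the reversal end, with
half-open windows at the boundary.

Behavioral (3 Hz) and whole-brain (1.667 Hz) clocks are never resampled
into each other; every operation runs on the trace's own clock.

## Matched resampling and permutation testing

`quintile_match()` takes quintile edges from the reference sample's
empirical 20/40/60/80 percentiles (linear-interpolation percentile
definition; boundary values to the lower quintile), bins the pool by those
edges, finds the scarcest quintile count $k$, and draws $k$ members
uniformly without replacement from each quintile — yielding a subsample
with exactly equal quintile masses under the reference distribution.  When
two groups must both be subsampled, the reference is an explicit argument.

`receptor_normalize()` divides each receptor column by its own maximum
(idempotent, column-scale invariant); the set score is the grand sum of
normalized expression over the neuron set.  The permutation test draws
same-size neuron sets without replacement and reports the one-sided
add-one empirical p, $p = (1 + \#\{S_\mathrm{null} \ge S_\mathrm{obs}\}) /
(n_\mathrm{draws} + 1)$, which avoids $p = 0$ and enforces the
$1/(n_\mathrm{draws}+1)$ floor.  One-sided matches the directional
enrichment question.  `bootstrap_compare()` resamples test items with
replacement and reports the two-sided empirical probability that two
classifiers' (balanced) accuracies differ.

## The turn-direction decoder

The decoder asks whether within-reversal activity of a head-steering
neuron predicts the upcoming turn's dorsal/ventral sign beyond what head
curvature alone predicts.  Reversals spanning at least 1.5 head-swing
cycles (three complete half-cycles, boundary inclusive) are eligible; both
channels are head-swing aligned (4 grid points per half-cycle, so a
4-frame window is one half-cycle, matching the raw-frame window length at
the whole-brain rate), and a 4-frame window is drawn uniformly inside the
reversal so windows are not time-locked to reversal endings.  One window
per reversal is redrawn each epoch — this realizes both the random
placement and full data coverage over training; a fixed-window mode exists
for exact reproducibility.

Architecture: GRU cell (input 2, hidden 3) over the 4 frames; dropout on
the final hidden state (rate 0.2 by default — the rate is not documented
anywhere, so it is exposed); layer normalization; affine map to a logistic
output.  Training: 250 epochs, Adam at $10^{-3}$ (standard moment
defaults), binary cross-entropy, minibatches of 16, and per-epoch class
balancing by subsampling the majority class to the minority count.  The
parameter snapshot from the epoch with minimum validation loss is kept.
The implementation is plain base-R matrix algebra with hand-derived
gradients; the test suite verifies every gradient against central finite
differences at $10^{-7}$ tolerance.

Cross-validation is hierarchical and stratified at the event level: 5
rotated 80:20 train/test partitions, each training partition split into 4
rotated 75:25 train/validation partitions (20 models; 60:20:20 overall).
Every event sits in exactly one outer test fold, and the suite asserts
no-leakage directly.  Accuracy is balanced (mean of per-class accuracies,
outputs $\ge 0.5$ rounding to dorsal) so a constant guess scores exactly
0.5; fold accuracies are averaged across all 20 models.  The
activity-plus-behavior and behavior-only (activity channel zeroed, not
removed) configurations are compared by bootstrap over test events, with a
label-shuffled control expected at chance.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at the following
scales, chosen as a deliberate scaled-down analog of a full study:
100 walkers of 20 simulated minutes for metric recovery; 20 directed and
100 null replicates for shuffle power and calibration (smaller plates per
replicate for the null, where only the rejection rate matters); 10
replicate decoder datasets of roughly 450 eligible reversals each, trained
for 80 epochs (the full 250-epoch default is unchanged and used in the
unit tests on smaller data — lengthening training raises absolute accuracy
but not the sign of any comparison); 200 repeats of the 500-draw
permutation test; 100 repeats of quintile matching against a +2σ-shifted
pool.  Tolerances: warped-average template correlation > 0.99;
mass-preservation error < 1e-6 (machine precision in practice); gradient
checks at 1e-7; seed-identical reruns are asserted `identical()`.

Known limitations: the simulator's gait is strictly sinusoidal, so
crossing detection is easier than on real curvature traces; eccentricity
is emulated as clean plateaus, so the posture thresholds are effectively
unchallenged; `turn_amplitude()` truncates the first post-reversal frame
(the backward-to-forward flip), making it proportional to, not identical
with, the generated turn angle; and the decoder is only exercised on one
synthetic neuron class at a time.
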