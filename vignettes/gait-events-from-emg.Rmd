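---
title: "Predicting gait phases and events from surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gait phases and events from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitphase)
```

## The problem

During walking, each leg alternates between *stance* (foot on the ground)
and *swing* (foot in the air). The two transition instants — *heel-strike*
(HS, swing to stance) and *toe-off* (TO, stance to swing) — anchor
essentially every temporal gait parameter used in clinical gait analysis.
They are usually measured with dedicated hardware (foot-switches, pressure
mats, IMUs). Since many clinical protocols already record surface
electromyography (sEMG) from the leg muscles, a classifier that reads gait
phases directly off the sEMG removes the need for that extra hardware: the
foot-switch signal is needed once, to train, and never again for the same
subject.

`gaitphase` implements that pipeline end to end:

1. raw multi-channel sEMG is turned into normalized activation envelopes;
2. the envelopes are cut into short multi-channel windows, labeled stance
   or swing by the foot-switch (*basographic*) signal;
3. a multi-layer perceptron (MLP) classifies each window;
4. the predicted binary foot-floor-contact signal is cleaned and HS/TO
   events are extracted and scored against ground truth.

Because clinical sEMG recordings of this kind are not freely
redistributable, the package ships a synthetic gait/EMG simulator with the
same statistical structure, so every stage is testable without any
external data.

## Signal model and pre-processing

Ten channels are recorded at 2 kHz, five muscles per leg: tibialis
anterior (TA), gastrocnemius lateralis (GL), medial hamstrings (MH),
vastus lateralis (VL), rectus femoris (RF). Pre-processing per channel:

- **Band-pass**: linear-phase FIR high-pass at 20 Hz (motion artifact)
  then FIR low-pass at 450 Hz (high-frequency noise). The FIR order is not
  dictated by the underlying method; we use 250 taps + 1 per filter
  (Hamming window), which at 2 kHz attenuates a 5 Hz tone to below 0.1%
  while passing 100 Hz within 0.2%. The order is a configuration knob.
  Both filters are applied with reflection padding and group-delay
  compensation, so the output stays sample-aligned with the input.
- **Envelope**: full-wave rectification followed by a second-order
  Butterworth low-pass at 5 Hz, applied forward and backward. The
  forward–backward pass reconciles the two requirements of a second-order
  filter and zero phase shift (the effective magnitude response is fourth
  order); its start-up transient is suppressed by a reflection pad long
  enough for the transient to decay below 10⁻⁶. The 5 Hz cut-off sits
  between the classic 3 Hz and 10 Hz recommendations for linear envelopes.
- **Normalization**: min–max to [0, 1] per channel over the whole
  recording (subject-level normalization). Note this uses the full record,
  including portions later used as test data; that mirrors the original
  protocol. A train-only normalization variant can be obtained by
  preprocessing the training portion separately and reusing its bounds —
  the bounds are returned for exactly this purpose. A constant channel
  cannot be normalized and raises an error naming the channel.

## Windowing

The common timeline is split into consecutive, non-overlapping 20-sample
windows (10 ms at 2 kHz). Each window becomes one flat vector of
20 × 10 = 200 values with channel-fastest interleaving: the vector starts
with sample 0 of every channel in canonical order, then sample 1, and so
on. A window whose basographic samples are all 0 (or all 1) is labeled
stance (swing); a window containing a transition is *masked* — excluded
from classifier training and from accuracy, but still predicted at event
time, because events live exactly in those windows. Masked windows are
retained with a flag rather than dropped, which keeps the chronological
sequence intact for reconstruction.

## The classifier

A fully-connected MLP with input 200, hidden layers 512–256–128 (ReLU),
and a single sigmoid output; a strict `> 0.5` threshold yields the binary
label, so a probability of exactly 0.5 maps to stance. A lighter
single-hidden-layer 128-unit variant is available via
`mlp_config(hidden_sizes = 128)`.

Training is plain SGD on binary cross-entropy, learning rate 0.01, at most
100 epochs, with early stopping: when validation accuracy has not
increased for 10 consecutive epochs, training halts and the weights of the
best-validation epoch are restored. The validation set is the
chronological tail 10% of the training sequence — in the
leave-one-subject-out protocol this is the tail of the concatenated
training subjects, a choice we document rather than inherit. Data are
never shuffled across the train/validation boundary; only mini-batch order
is reshuffled each epoch, deterministically under the configured seed.

Choices the method itself leaves open, fixed here as defaults with knobs:
batch size 32 (conventional for mini-batch SGD at this scale); He-style
scaled-uniform weight initialization (standard for ReLU stacks), drawn
from R's RNG under the config seed so runs are bit-reproducible; no
momentum or weight decay. The numerical core (forward pass,
backpropagation, SGD loop) is implemented in C++ via RcppArmadillo; a
training epoch on ~27,000 windows takes roughly two seconds on one CPU.

## From labels to events

All windows — masked ones included — receive a predicted label, and the
labels are expanded back to a 2 kHz binary signal. Two post-processing
rules then produce events:

- **Minimum phase duration.** Healthy stance and swing last roughly 60%
  and 40% of a gait cycle, so any phase shorter than 175 ms (~16% of a
  cycle) is a misclassification spike. While any run of the binary signal
  is strictly shorter than 175 ms, the shortest violating run (leftmost on
  ties) is absorbed into the preceding phase (the first run takes the
  following phase's value). We remove the *shortest* run first rather than
  scanning left to right because the two orders can differ when violating
  runs are adjacent, and removing the most egregious spike first is the
  deterministic rule that our brute-force oracle (re-encode, delete
  shortest, repeat) also implements. Runs of exactly 175 ms survive the
  strict inequality. Whether the record's partial first/last phases should
  be exempt is genuinely ambiguous; we do not exempt them.
- **Event extraction.** HS at every 1→0 transition, TO at every 0→1
  transition, timestamped at the first sample of the new phase (0-based).
  Since labels are per-window, event resolution is one window (10 ms).

Predicted events are matched to ground truth per event type, one-to-one:
scanning predictions chronologically, each takes the nearest unmatched
truth event with |t_g − t_p| strictly below the tolerance T (600 ms by
default; 50 ms as a stricter variant). Precision = TP/(TP+FP),
recall = TP/(TP+FN), F1 their harmonic mean, and MAE the mean |t_g − t_p|
over matched pairs. Metrics with empty denominators are reported as
missing, never as 0, so empty predictions are not silently rewarded.
Greedy matching is not optimal in general; for gait-like event spacing
(~1 s between same-type events, errors of tens of ms) it attains the
optimal pair count, which the test suite verifies against an exhaustive
assignment oracle on small instances.

## Protocols

- **Intra-subject**: the subject's window sequence is split into 10
  contiguous, equal (±1 window) slots; each fold trains on 9 slots and
  tests on the held-out slot (10-fold cross-validation over contiguous
  blocks, never a random shuffle — windows are autocorrelated and a random
  split would leak). Accuracy is averaged over folds; events from all test
  slots are pooled before computing precision/recall/F1/MAE, so
  fold-level small-sample noise does not distort ratios.
- **Inter-subject**: leave-one-subject-out; each fold trains one model on
  all other subjects and tests on the whole left-out subject.
- **Comparison**: per-subject metric distributions are compared with a
  Shapiro–Wilk normality gate at 5%: both normal → two-tailed unpaired
  Student's t test; otherwise Kruskal–Wallis. Constant groups, where
  Shapiro–Wilk is undefined, fall back to Kruskal–Wallis with a warning.

Both protocols assert at the index level that no test window enters
training or validation, and the returned reports carry the fold index
audit so the assertion can be re-checked externally.

## The synthetic data generator

`simulate_subject()` emulates what the pipeline assumes about a ~5-minute
self-paced walk of a healthy adult:

- stride durations drawn i.i.d. from a normal law (default 1100 ± 60 ms)
  truncated at ±3 SD — truncation forbids non-physiological durations;
- a per-stride stance fraction, normal 0.60 ± 0.02 truncated to
  [0.45, 0.75], matching the canonical 60/40 stance/swing split;
- per-muscle activation envelopes as sums of Gaussian bursts in
  gait-cycle coordinates (TA in swing and at loading, GL in mid/late
  stance, MH in terminal swing, VL/RF at loading response, RF again around
  toe-off), truncated at ±3σ;
- raw-like sEMG = (noise floor + envelope) × a zero-mean carrier
  band-limited to 20–450 Hz, i.e. amplitude-modulated broadband noise;
- the left leg runs half a cycle out of phase with the right, as in
  contralateral walking, so both legs' channels carry phase information;
- records start and end in stance; a truncated final stride's partial
  swing is converted to stance to keep the boundary convention.

Stride-duration statistics for the original cohort were never published;
the defaults are plausible for healthy adults walking at a self-selected
pace and are *not* calibrated to any dataset. Ground-truth events are read
off the realized basographic signal, so the generator and the event
detector agree by construction on what an event is.

What the simulator deliberately does **not** model: motor-unit
physiology, signal nonstationarity within a phase, electrode artifacts,
crosstalk between channels, kinematics or forces, and the four-sub-phase
structure of stance. Consequently, passing tests demonstrate that the
pipeline's machinery is correct and that its accuracy claims hold under
the stated statistical structure — not that the same accuracy would be
reached on any particular clinical recording.

## Problem sizes used in the test suite

The end-to-end checks run on one 5-minute subject (about 270 strides,
30,000 windows, capped at 30 training epochs) for the intra-subject
experiment, and on five heterogeneous 3-minute subjects with a reduced
epoch budget (6 epochs, patience 2) for the intra- vs. inter-subject
contrast. These sizes keep a full run of the suite on one CPU in the
tens of minutes while leaving hundreds of events per experiment, enough
for stable MAE and F1 estimates. The acceptance script uses one 5-minute
subject and three heterogeneous 2-minute subjects for the same reason.

## Worked example

```{r, eval = FALSE}
library(gaitphase)

rec <- simulate_subject(gait_sim_params(duration_s = 60, seed = 1))
report <- run_intra_subject(rec, mlp_config(max_epochs = 30, seed = 1))
report$test_accuracy
report$event_scores
compare_approaches(rnorm(23, 14.4, 4.7), rnorm(23, 18.7, 7.8),
                   metric = "hs_mae_ms")
```

## Known limitations

- Event resolution is bounded below by the window length (10 ms); no
  sub-window interpolation is attempted.
- Subject-level min–max normalization leaks test-range information by
  design fidelity; use the returned bounds for train-only normalization
  if that matters for your application.
- The greedy matcher is only guaranteed optimal-equivalent for
  well-separated events; pathological event streams (several events per
  tolerance window) may be scored conservatively.
- The statistical comparison treats subjects as independent; fold-level
  correlation within a subject is not modeled.
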