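# gaitphase

Classify gait phases and predict gait-event timing from surface EMG.

During walking each leg alternates between **stance** (foot on the ground)
and **swing** (foot in the air); the transition instants — **heel-strike**
(HS) and **toe-off** (TO) — anchor every temporal gait parameter used in
clinical gait analysis. `gaitphase` predicts both the phase and the event
times from ten channels of surface electromyography (sEMG) alone, using
the foot–floor-contact ("basographic") signal from foot-switches only as
training ground truth. Once a model is trained for a subject, follow-up
sessions need no contact sensors at all.

## The method

Per channel, at 2 kHz: linear-phase FIR band-pass (20–450 Hz), full-wave
rectification, zero-phase 2nd-order Butterworth low-pass at 5 Hz, and
subject-level min–max normalization to [0, 1]. The ten envelopes are cut
into non-overlapping 20-sample windows (10 ms) and interleaved
channel-fastest into 200-value vectors `x`, labeled by the basographic
signal `b` (0 = stance, 1 = swing) when the window is phase-pure.

A multi-layer perceptron `200 → 512 → 256 → 128 → 1` (ReLU, sigmoid
output, label 1 iff p > 0.5) is trained with SGD on binary cross-entropy
(lr = 0.01, ≤ 100 epochs), early-stopped when validation accuracy — on the
chronological tail 10% of the training sequence — has not increased for 10
epochs, restoring the best-epoch weights.

The predicted labels are expanded back to a binary signal; phases shorter
than 175 ms are rejected as spikes; HS = each 1→0 transition, TO = each
0→1. Predicted events match ground truth one-to-one when
|t_g − t_p| < T (T = 600 ms, or 50 ms for strict timing studies), and are
scored with

    Precision = TP / (TP + FP)
    Recall    = TP / (TP + FN)
    F1        = 2 · Precision · Recall / (Precision + Recall)
    MAE       = mean |t_g − t_p| over matched pairs

Two protocols: **intra-subject** (10-fold over contiguous slots of one
recording) and **inter-subject** (leave-one-subject-out across a
population), compared per metric with a Shapiro–Wilk-gated Student's
t test / Kruskal–Wallis at α = 5%.

A synthetic gait/EMG simulator (truncated-normal stride timing, 60/40
stance/swing split, Gaussian activation bursts per muscle modulating
band-limited noise) generates subjects with the statistical structure the
pipeline assumes, so the whole package is testable without clinical data.

## Worked example

```r
library(gaitphase)

rec <- simulate_subject(gait_sim_params(duration_s = 60, seed = 1))
report <- run_intra_subject(rec, mlp_config(max_epochs = 30, seed = 1))
report
#> <gait_subject_report> S1 (intra, leg L): test accuracy 0.9761 +/- 0.0119 over 10 folds
#> # A tibble: 2 × 8
#>   type     tp    fp    fn precision recall    f1 mae_ms
#>   <chr> <int> <int> <int>     <dbl>  <dbl> <dbl>  <dbl>
#> 1 HS       51     0     4         1  0.927 0.962   8.16
#> 2 TO       51     0     4         1  0.927 0.962  25.3
```

Read: on a one-minute synthetic walk (~55 strides), the fold-averaged
stance/swing accuracy on held-out slots is 97.6%; heel-strikes are
predicted with a mean timing error of ~8 ms and toe-offs — the harder
event, arriving while extensor activity decays — with ~25 ms. The few
false negatives are events at test-slot boundaries of this short record;
they fade with recording length (a 5-minute walk recovers essentially
all events, see the acceptance run).

`run_intra_study()` / `run_inter_subject()` lift this to a population and
`compare_approaches()` tests whether the intra-subject approach beats the
inter-subject one on any per-subject metric. `autoplot()` methods cover
envelopes and training histories; `tidy()`/`glance()` return per-subject
and population summaries.

A thin CLI wraps the same functions:

```sh
inst/cli/gaitphase simulate --subjects 5 --duration-s 300 \
    --heterogeneity 0.5 --seed 1 --out data/
inst/cli/gaitphase run-intra --data data/ --out intra.json
```

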