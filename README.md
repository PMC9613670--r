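# nmmap — quantitative intraoperative neuro-motor mapping

During awake deep brain stimulation (DBS) surgery for Parkinson's disease,
clinicians localize motor-responsive subthalamic tissue by judging — by ear
and eye, in real time — whether multi-unit activity (MUA) from a
microelectrode is modulated by passive or active limb movement. `nmmap`
implements an automated, reproducible version of that judgment for
post-hoc analysis:

1. **Kinematics**: markerless-tracking keypoint tables (60 Hz, 21 hand
   landmarks) are reduced to the mean frame-to-frame Euclidean displacement
   of the five fingertips, artifact-repaired (mean + 4.5 SD flagging with
   local interpolation), smoothed (333 ms moving average), resampled to
   1200 Hz, and min–max normalized to [0, 1].
2. **MUA**: 44 kHz voltage is zero-phase bandpass filtered (2nd-order
   Butterworth, 100–4000 Hz), thresholded at an adaptive multiple
   k ∈ [2.5, 6.5] of the robust noise estimate
   SD_bn = median(|v|)/0.6745 (k starts at 4.5 and walks until the
   crossing rate lies strictly in 80–400 Hz), downsampled to the 1200 Hz
   grid, converted to an instantaneous firing rate (reciprocal inter-spike
   interval), and normalized to [0, 1].
3. **Similarity**: the two signals are compared with dynamic time warping
   constrained to a ±200 ms Sakoe–Chiba band (local cost |aᵢ − bⱼ|, sum
   along the optimal monotone path). The observed distance is ranked
   within a bootstrap null of B comparisons against random MUA segments
   from a pooled database; percentile < 5 ⇒ `quant_plus`.
4. **Evaluation**: quantitative percentiles are compared with clinician
   case-note labels (clin+/clin−) via rank-sum/t tests behind a Lilliefors
   normality gate, a Harrell–Davis shift function, and ROC-like
   threshold-separation curves with a shuffled-label baseline, Fisher
   exact p, and cross-product odds ratio.

Because the underlying patient recordings are not public, the package
includes a first-class synthetic-session generator (movement-modulated
Poisson spiking over bandlimited noise, quasi-periodic active clenches and
stochastic passive flexion bouts, tracking dropouts) so that every stage
and every statistic is testable end to end.

## Worked example

```r
library(nmmap)

cfg <- session_config(n_epochs = 12, epoch_duration_s = 5, seed = 7,
                      label_error_rate = 0.1)
ses <- gen_labeled_session(cfg)             # epochs + synthetic clin labels
db  <- gen_null_database(cfg, n_recordings = 8)
out <- run_session(ses$epochs, db, run_config(seed = 7, B = 200),
                   n_shuffle = 200, n_boot = 200)

print(out$results[[1]])
#> <nm_similarity> epoch ep001
#>   DTW distance : 2106.1 a.u. (window 200 ms, n = 5980)
#>   percentile   : 0.0 of 200 null comparisons
#>   label        : quant_plus (threshold 5)
```

The DTW distance is the summed sample-to-sample cost along the optimal
warping path (arbitrary units; only its rank within the epoch's null
matters). Percentile 0.0 means the observed comparison was more similar
than every one of the 200 null comparisons, hence `quant_plus`:
movement-locked activity. Epoch ep001 is in fact a coupled epoch whose
synthetic clinician label was flipped by the 10 % label-noise setting —
exactly the clin−/quant+ discordance structure the evaluation module is
built to quantify.

```r
print(out$evaluation)
#> == active movements (n = 8) ==
#>   central tendency: wilcoxon, p = 0.76
#> <threshold_analysis> active movements (n+ = 3, n- = 5)
#>   best threshold : percentile 30.5 (group difference 0.40)
#>   ruled in       : 100% of clin+, 60% of clin-
#>   Fisher exact   : p = 0.464, odds ratio = 5.00
```

(A 12-epoch toy session; group statistics become meaningful at realistic
session sizes.) `plot(out$results[[1]])` overlays the two normalized
signals and marks the observed distance in the null distribution;
`plot(out$evaluation$active$thresholds)` draws the rule-in curves with
the shuffled baseline.

A command-line front end over the same functions lives at
`inst/cli/nmmap.R` (`synth`, `run`, `evaluate` subcommands).

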