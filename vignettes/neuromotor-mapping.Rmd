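---
title: "Quantifying neuro-motor similarity during intraoperative motor mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuro-motor similarity during intraoperative motor mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 5)
library(nmmap)
```

## The problem

During awake deep brain stimulation (DBS) surgery for Parkinson's disease,
clinicians localize motor-responsive tissue in the subthalamic nucleus (STN)
by listening to audio-converted multi-unit activity (MUA) from a
microelectrode while moving the patient's limb (passive testing) or asking
the patient to move (active testing, e.g. hand clenches). Judging by ear and
eye whether neural activity is movement-locked is subjective and discards
most of the information in both signals.

`nmmap` implements an automated alternative: hand kinematics extracted by
markerless video tracking are reduced to a single normalized movement
signal, the microelectrode voltage is reduced to a normalized
instantaneous-firing-rate signal, and the two are compared with banded
dynamic time warping (DTW). The strength of a comparison is expressed as a
percentile within a bootstrap null distribution of comparisons against
unrelated MUA segments, and epochs below the 5th percentile are classified
`quant_plus` (movement-related activity present).

## The processing model

**Kinematics (60 Hz video).** For each of the five fingertip landmarks of a
21-point hand model, the frame-to-frame Euclidean displacement
$d_t = \sqrt{(x_t - x_{t-1})^2 + (y_t - y_{t-1})^2}$ is computed in pixel
space from one camera's view. Detections with tracking likelihood below
0.6 are treated as absent. Within each epoch, samples above
$\mathrm{mean} + 4.5\,\mathrm{SD}$ of the epoch's own displacement series,
and all absent samples, are flagged and linearly interpolated (edge runs
take the nearest value); epochs with more than half their samples flagged
are excluded rather than repaired. The five fingertip series are averaged,
smoothed with a centered 333 ms moving average, resampled to 1200 Hz with
polyphase FIR (anti-aliased) resampling, and min–max normalized to
$[0, 1]$.

**MUA (44 kHz voltage).** The voltage is zero-phase filtered with a 2nd
order Butterworth bandpass between 100 and 4000 Hz (edges normalized to the
Nyquist frequency; the forward–backward pass doubles the effective order).
Background-noise SD is estimated robustly as
$\mathrm{SD}_{bn} = \mathrm{median}(|v|)/0.6745$, which high firing rates
do not inflate. Spikes are rising threshold crossings of $|v|$ above
$k \cdot \mathrm{SD}_{bn}$ with no refractory period; $k$ starts at 4.5 and
walks in 0.1 steps within $[2.5, 6.5]$ until the mean crossing rate lies
strictly inside (80, 400) Hz — the range expected for 1–3 STN units firing
at 80–125 Hz — or a limit is reached. Timestamps are divided by
$44/1.2$ and rounded (duplicates collapsed) to move to the 1200 Hz grid,
where the instantaneous rate at each sample is the reciprocal of the
surrounding inter-spike interval, held constant beyond the first and last
spike. The rate is then min–max normalized like the kinematics.

**Comparison.** The two equal-length 1200 Hz signals are compared with
classical DTW constrained to a Sakoe–Chiba band of ±200 ms (240 samples):
local cost $|a_i - b_j|$, steps (1,0), (0,1), (1,1), monotone index
mapping, no path-length normalization. Signal lengths are never warped
onto each other; only point-to-point timing may shift within the band,
a deliberately liberal allowance for pathologically extended neuro-motor
latency. The observed distance is ranked (midrank convention) within a
null distribution of `B` distances between the same kinematic signal and
random equal-length MUA segments drawn from a database pooled across
subjects and depths; the epoch's own time window is never eligible.
Because the kinematic signal is held fixed across all null comparisons,
the percentile is well calibrated per epoch. Percentile < 5 is
`quant_plus`; exactly 5 is `quant_minus` (both published inequalities are
strict).

**Evaluation.** Group comparisons between clinician labels use a
Lilliefors normality gate (t-test when both groups pass, Wilcoxon rank-sum
otherwise, both two-tailed), a Harrell–Davis shift function with
percentile-bootstrap confidence intervals (Hochberg-adjusted across the
nine deciles), and a threshold-separation analysis: rule-in proportion
curves per label, a shuffled-label baseline (the pointwise average over
label permutations, which converges to the pooled empirical CDF), the
threshold maximizing the clin+ − clin− difference (ties to the smallest
threshold), and at that threshold a two-tailed Fisher exact test with the
cross-product odds ratio (Haldane 0.5 correction only when a cell is
zero).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window_s` | 0.2 | s | DTW band half-width; latencies beyond it cannot be absorbed |
| `B` | 1000 | — | null size; percentile resolution is 100/B |
| `threshold_pct` | 5 | percentile | quant+/− boundary (strict `<`) |
| `smoothing_window_s` | 0.333 | s | kinematic moving average; results are insensitive over a broad range |
| `artifact_sd` | 4.5 | SD | tracking-artifact flag threshold |
| `likelihood_min` | 0.6 | — | tracking-likelihood gate; below it a detection is absent |
| `band_hz` | 100–4000 | Hz | MUA passband |
| `start_k`, `k_range` | 4.5, 2.5–6.5 | SD_bn | adaptive detection threshold |
| `rate_bounds_hz` | 80–400 | Hz | acceptable multi-unit crossing rate (strict) |
| `fs_common` | 1200 | Hz | common grid; comfortably above 3 units × 125 Hz |

## The synthetic-data generator

No public recordings exist for this setting, so the package ships a
generator that emulates the study conditions end to end and makes every
stage testable:

* **Kinematics** — a fixed 21-landmark rest layout moves toward the palm
  center under a movement drive: active epochs are quasi-periodic clench
  cycles at a nominal 0.5–2 Hz whose individual cycle durations are drawn
  with lognormal jitter (σ = 0.18 in log-period) and whose amplitude
  drifts slowly, because human repetitions are not phase-stable; passive
  epochs are irregular clinician-paced flexion bouts (0.8–1.6 s
  half-cosine pulses with exponential gaps, lower amplitude). Tracking
  noise is 0.5 px; occlusions are short global dropout runs at a
  configurable rate.
* **Voltage** — inhomogeneous Poisson spiking at
  $r(t) = r_0 (1 + g\,e(t - \ell))$, with base rate $r_0$ (default
  100 Hz), coupling gain $g \in [0,1]$, latency $\ell$, and $e$ the
  normalized movement-speed envelope; spikes are 1 ms biphasic waveforms
  (sharp main lobe at `spike_amplitude_snr` × noise SD, 15% opposite
  rebound) on Gaussian noise bandlimited to 100–4000 Hz.
* **Null database** — independent uncoupled recordings (≥ 35 s),
  processed once through the standard MUA path.
* **Sessions** — mixtures of coupled and uncoupled epochs with synthetic
  clinician labels derived from the true coupling and an optional flip
  probability.

Everything is a pure function of (config, seed).

What the generator does *not* emulate: tremor and other pathological
kinematic signatures, bursting or oscillatory (e.g. beta-band) spike
statistics, electrode drift, cross-channel artifacts, and camera
perspective effects. Passing tests on synthetic sessions therefore
demonstrate the pipeline's statistical behavior under the stated
generative model, not clinical performance on patient data.

```{r example, eval = FALSE}
cfg <- session_config(n_epochs = 20, seed = 7)
ses <- gen_labeled_session(cfg)
db <- gen_null_database(cfg, n_recordings = 12)
out <- run_session(ses$epochs, db, run_config(seed = 7, B = 1000),
                   out_dir = "nmmap_out")
print(out$evaluation)
plot(out$results[[1]])
```

## Numerical choices

* **Resampling and filtering edges.** Both the polyphase resampler and the
  zero-phase bandpass see the input extended by odd reflection at the
  ends, so FIR/IIR startup transients stay out of the epoch. Without this,
  a constant input does not resample to a constant and a DC offset leaks
  filter ringing into the first tens of milliseconds.
* **Crossing polarity.** The detector thresholds $|v|$ (both spike
  polarities carry multi-unit energy); negative-only crossing is available
  via `polarity = "negative"`.
* **Degenerate inputs.** Min–max normalization of a constant series, and
  epochs with fewer than two detected spikes, are explicit degenerate
  cases: the epoch is excluded with a recorded reason, never silently
  dropped or zero-filled.
* **Percentile ties** use midranks; a percentile exactly at the threshold
  is `quant_minus` — both inequalities in the classification rule are
  strict.
* **RNG discipline.** All library randomness runs under locally scoped
  seeds; per-epoch null seeds are derived from the run seed and the epoch
  id, so epoch processing order cannot change any epoch's result.
* **Shift-function multiplicity.** Bootstrap p-values per decile are
  Hochberg-adjusted; each decile's interval is reported at its Hochberg
  step level. The decile estimator, bootstrap count, and adjustment are
  exposed as parameters.
* **Fisher exact** is enumerated from the hypergeometric pmf (the sum of
  table probabilities not exceeding the observed one), which agrees with
  `stats::fisher.test`; the reported odds ratio is the descriptive
  cross-product, not the conditional MLE.

## Design choices where the method was genuinely open

* **DTW, not greedy matching.** "Match each point with the most similar
  point in a window" could be read as greedy nearest-point pairing, but
  greedy pairing violates monotone index mapping; the package implements
  the standard banded DTW recurrence.
* **Artifact rule before averaging.** The 4.5 SD artifact rule is applied
  per fingertip, before averaging, so a dropout in one digit cannot
  contaminate the mean; whether to apply it before or after averaging is
  not dictated by the method description.
* **Adaptive-threshold schedule.** Only the start (4.5), range (2.5–6.5),
  and target rate band are fixed by the method; the 0.1 step and
  walk-direction rule (down when too slow, up when too fast, stop at the
  first acceptable k or at a limit) are this package's schedule.
* **Null eligibility.** By default only the epoch's own time window is
  excluded from the segment database; same-depth or same-subject
  exclusion is available (`policy` argument). Null segments are min–max
  normalized exactly like an epoch's own MUA.
* **Time alignment** between video and neural clocks is taken as given via
  an explicit per-session offset (`t_offset_s`, default 0); inferring
  synchronization from the data is out of scope.

## Identifiability limit for periodic movements

A latency larger than the DTW band cannot be absorbed, which is the
mechanism that demotes consistently-lagged epochs to `quant_minus`. That
statement has a domain of validity: if the movement-speed envelope is
(quasi-)periodic with period shorter than the latency, the band can
re-align the comparison to the *next* cycle and the latency aliases away.
Active clenches at 1.25 Hz and above have speed-envelope periods under
400 ms, so a 400 ms latency is genuinely unidentifiable for them — which
mirrors the clinical observation that rhythmic active movements can
produce happenstance similarity, and why passive testing with
stochastically initiated movements is the sensitive probe of neuro-motor
latency. The latency-recovery checks in this package therefore use
passive epochs; active epochs are still used everywhere latency is inside
the band.

A softer version of the same limit applies to passive movements: the band
absorbs 200 ms of a 400 ms latency, and the residual 200 ms misalignment
is small relative to the width of a typical flexion bout's speed envelope
(roughly 400–800 ms for 0.8–1.6 s bouts). A minority of well-coupled
epochs therefore remain significantly more similar than fully unrelated
null segments even at latencies twice the band width — partially
overlapping structure is genuine similarity, and the percentile endpoint
reports it as such. Latency exclusion by the band is sharp only for
movement features briefer than the residual misalignment; the acceptance
script measures both the in-window recovery rate and this out-of-window
leak rate.

## Problem sizes used by the test suite and acceptance script

Simulation-based checks are scaled to stay responsive: synthetic epochs of
5 s (calibration) and 10 s (latency recovery; the generator's clinical
default is 10 s, with 10–30 s supported), null sizes B = 200 for
calibration and B = 100 for the recovery arms (percentile resolution 0.5
and 1 point respectively), a 12-recording null database, 200 calibration
epochs, and 100 epochs per recovery arm. The DTW oracle check covers 1000
random pairs up to length 64 with exhaustive window coverage on the
smaller pairs. These sizes are stated here so they can be reproduced or
enlarged; none of the statistical conclusions depend on the scaling.

## Known limitations

* Single-camera 2-D kinematics: out-of-plane motion compresses
  displacement; no triangulation.
* The null database must contain recordings at least as long as the epoch
  under test.
* `dlc_hdf` keypoint tables and HDF5 voltage containers are not readable
  in this build; use the CSV/TSV/WAV paths.
* The evaluation module reproduces group-level statistics for one session
  set at a time; multi-session meta-analysis is out of scope.
* Clinical validity: agreement with clinician labels on synthetic data
  says nothing about patient outcomes; the package measures signal
  similarity, not therapeutic benefit.
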