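---
title: "Multimodal empathy analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal empathy analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmempathy)
```

`mmempathy` implements the analysis chain of a two-paradigm empathy
experiment in which transcranial direct current stimulation (tDCS) over
the right temporoparietal junction (rTPJ) or left dorsolateral prefrontal
cortex (lDLPFC) is evaluated against sham with behavioural ratings,
EEG event-related potentials, and ECG-derived heart rate variability,
followed by multimodal decoding of the stimulus state. Because the human
data behind such experiments are not redistributable, the package pairs
every estimator with a synthetic cohort generator that has known ground
truth, so that each stage can be validated by parameter recovery rather
than by data matching.

## Rating-based signal detection

Trial ratings on a bounded integer scale are treated as graded evidence:
every scale value acts as an implicit decision criterion. For criterion
$c$, the hit rate is $P(\text{rating} \ge c)$ in the signal (painful)
condition and the false-alarm rate the same probability in the noise
(nonpainful) condition. The anchored hit/false-alarm points form the
rating ROC curve, and its trapezoidal area is the nonparametric
discrimination index

$$\mathrm{AUC} = P(X > Y) + \tfrac{1}{2} P(X = Y),$$

with $X$ a signal rating and $Y$ a noise rating — identical to the
Mann–Whitney rank statistic, an identity the test suite asserts to
machine precision over random rating draws. AUC is invariant to any
strictly increasing relabelling of the scale and to additive response
bias, which is the reason it is used as the bias-free behavioural
empathy index. The criterion sweep covers the entire declared scale
(including the always-true criterion), not only observed values; this
changes nothing about the area and makes curves comparable across cells.

## ERP preprocessing and the late positive potential

The EEG chain is deliberately linear: zero-phase band-pass (4th-order
Butterworth, 0.1–30 Hz, forward–backward), epoching around stimulus
onset (−1000 to 3000 ms), prestimulus baseline subtraction, peak-to-peak
threshold artifact masking, common-average re-referencing, and
within-cell averaging. The late positive potential (LPP) is the mean
voltage over CP1/CP2 in two half-open windows, 500–1000 ms (early) and
1000–3000 ms (late); the neural empathy index is the painful-minus-
nonpainful difference ΔLPP. Because every operation is linear, baseline
correction and re-referencing commute (asserted numerically), and for
noise-free synthetic epochs the extracted amplitude equals the generator
amplitude times an analytically computable window-overlap factor, which
the tests verify by direct quadrature to better than 1%.

Choices worth stating explicitly: the filter family and order are not
dictated by anything in the data — 4th-order Butterworth is a
conventional, numerically safe choice at these band edges; artifact
handling is a fixed ±100 µV peak-to-peak rule rather than visual
inspection or ICA, because the synthetic data contain no ocular
components and a deterministic rule is testable; windows are half-open
`[start, end)` so no sample is counted twice; cells that lose every
epoch are flagged and excluded, never imputed. One caveat for the
synthetic pipeline driver: on the reduced 8-channel montage the
common-average reference would subtract a large share of the broadly
distributed simulated signal itself (a genuine property of sparse
montages, not a bug), so `lpp_cell_features()` applies baseline
correction and artifact masking but leaves `rereference_average()` —
available and fully tested — to pipelines with denser recordings.

## ECG, EEMD and heart rate variability

Raw ECG is denoised by ensemble empirical mode decomposition: each of
`ensemble_size` (default 100) noise-perturbed copies (added white noise
SD 0.2 × signal SD) is sifted into intrinsic mode functions with
cubic-spline envelopes (mirror-extended extrema at the boundaries), an
SD-type stopping rule (threshold 0.2, at most 10 sifts per mode), and
the modes are averaged rank-wise. Reconstruction is exact without
ensemble noise and its error shrinks as $1/\sqrt{\text{ensemble}}$
otherwise. For denoising, leading modes whose spectral centroid exceeds
45 Hz (measurement noise) and trailing modes below 0.5 Hz plus the
residue (baseline wander) are discarded; the thresholds are package
choices, stated here because no standard exists.

R-peaks are local maxima above an adaptive threshold — a fraction
(default 0.5) of the near-maximal (0.999) amplitude quantile in a 2-s
neighbourhood, measured above the local median so slow wander cancels —
with a 250 ms refractory period resolved in favour of the larger
candidate. The near-maximal quantile matters: a milder quantile (e.g.
0.98) lets T-waves through. Automatic interval correction replaces beats
deviating more than 30% from an 11-beat rolling median with spline
interpolation and rejects series needing more than 20% correction.

HRV indices follow the standard three domains. Time domain: HR, SDNN,
RMSSD, pNN50. Frequency domain: the RR tachogram is spline-resampled at
4 Hz, mean- and trend-removed, and Welch-averaged (Hann window, 120-s
segments, 50% overlap; shorter series use one full-length segment);
LF power integrates 0.04–0.15 Hz and HF 0.15–0.40 Hz, with LF/HF
undefined (not infinite) when HF power is numerically zero. Nonlinear:
sample entropy ($m = 2$, $r = 0.2\,\mathrm{SD}$, self-matches excluded)
and the Poincaré axes. One convention is used everywhere and is worth
emphasising: dispersion is population-style (divide by $n$), and the
successive-difference dispersion is taken about zero, so that

$$\mathrm{SD1} = \mathrm{RMSSD} / \sqrt{2}$$

holds as an exact identity on every profile, not an approximation. SD2
is clamped at zero if numerical error drives its square negative.

## Decoding

Feature vectors are participant × condition aggregates — rating means
plus early/late LPP (picture design) or rating means plus the eleven HRV
indices (narrative design) — entered **on their original scale**; no
standardisation or normalisation happens anywhere in the decoding chain.
That choice follows the upstream analysis being emulated and is a real
caveat for the distance-based families (KNN, SVM), whose geometry then
depends on the units of each feature.

Five classifier families are provided: ridge logistic regression
(glmnet, $\lambda = 0.01$), 5-nearest-neighbours with explicit vote
fractions, random forest (500 trees, seeded), RBF SVM with scores from a
logistic transform of decision values, and Gaussian naive Bayes. All
hyperparameters are frozen defaults, configurable but never tuned.
Validation is leave-one-out: each sample is predicted by a model that
never saw it (a property the tests assert by flipping a held-out label
in separable data). A leave-one-participant-out unit is available
because aggregated rows from the same participant are correlated;
the default unit is a single row. Multiclass ROC uses one-vs-rest
curves with macro-averaged area; Cohen's κ is computed from the pooled
confusion matrix, defined as 0 when chance agreement is exactly 1.
Chance lines are 50% (binary) and 33.3% (three-class).

## The synthetic cohort generator

The generator reproduces the statistical skeleton of both designs, not
the physiology of real recordings.

* **Ratings** arise from a latent normal — participant intercept
  (SD 0.5) + condition shift + unit noise — discretised into equal-width
  bins (width 0.5 latent SD) over the declared scale: 0–10 for the
  picture design, 1–9 for the narrative design (the narrative scale
  bound is configurable). A shift of $s$ latent SD moves the expected
  rating by roughly $2s$ points mid-scale. The rTPJ rating effect is
  applied to painful-trial "other" ratings only: a shift common to both
  stimulus conditions would be pure response bias, which the AUC is
  designed to ignore.
* **Epochs** are 1/f-amplitude-shaped Gaussian noise (per channel SD
  `eeg_noise_sd`, prestimulus mean removed by construction) plus a
  half-cosine-ramped plateau (0.4–3.0 s, 0.3 s ramps) scaled by the
  condition amplitude and a spatial profile peaking at CP1/CP2. EEG is
  simulated at 250 Hz on a reduced 8-channel centroparietal montage —
  all window logic is expressed in seconds, so nothing depends on the
  rate, and only centroparietal channels enter the LPP.
* **RR series** follow
  $RR(t) = \overline{RR} + a_{LF}\sin(2\pi\,0.10\,t) +
  a_{HF}\sin(2\pi\,0.25\,t) + \varepsilon$, iterated over beat times.
  Deterministic sinusoids (rather than an integral-pulse model) give the
  spectral estimator a closed-form truth: the LF/HF power ratio is
  exactly $a_{LF}^2 / a_{HF}^2$, which the calibration tests recover
  within 20% on 5-minute series. Post-stimulation lDLPFC cells multiply
  depths and jitter by `hrv_effect_ldlpfc`. Defaults
  ($\overline{RR} = 800$ ms, $a_{LF} = 30$, $a_{HF} = 25$, jitter 15 ms)
  give SDNN ≈ 30 ms and LF/HF ≈ 1.4, ordinary resting values.
* **ECG traces** place a fixed sum-of-Gaussians P-QRS-T template (R
  amplitude 1 mV) at each beat time, after a 0.5-s lead-in, plus white
  noise and a slow wander sinusoid; template peak times are the exact
  ground truth for scoring the detector.

A single run seed fans out deterministically to named child streams
(`child_seed`), so ratings, epochs and each RR cell can be regenerated
independently and bit-identically.

What the generator does **not** emulate — and therefore what passing
recovery tests do not show about real data: no volume-conducted EEG
forward model, eye blinks or ICA-relevant artifacts; no 1/f fitting
beyond shaped noise; no ectopic beats, arrhythmia or respiration
coupling; ratings have no sequential or fatigue structure. Recovery on
this cohort demonstrates that the estimators are unbiased and directed
correctly under the assumed generative structure, not that the assumed
structure is the physiology.

## Calibration experiments and problem sizes

Two null-calibration quantities anchor the pipeline:
`null_decoding_accuracy_study1()` (binary) builds one 80-row zero-effect
feature matrix (5 participants per group, 10 trials per cell) and
averages LOOCV accuracy over the five families across 100 label
permutations; `null_decoding_accuracy_study2()` (three-class) does the
same over LR/RF/NB with 6 participants per group (54 rows). Their means
must sit at 50% and 33.3% respectively up to Monte-Carlo error; note
that leave-one-out on permuted labels is slightly pessimistic (holding a
sample out tips the training class balance against its class), so means
a fraction of a point *below* chance are expected behaviour, not bias.
Direction-of-effect recovery runs 100 seeds of small cohorts (2–3
participants per group) per effect: these sizes keep each experiment in
the minutes range while leaving Monte-Carlo standard errors far smaller
than the simulated effects.

## Known limitations

Sample entropy is quadratic in series length; profiles are intended for
the few-hundred-beat series of this design. The EEMD implementation is
plain EEMD (no CEEMDAN variant) with simple mirror boundary handling;
very short signals show boundary leakage between adjacent modes. The
decoder deliberately omits hyperparameter search, nested
cross-validation and calibration curves; accuracies on real data are
not reproducible here because the unit of analysis and per-fold counts
of the emulated experiment are not public — only chance behaviour and
effect directions are testable claims.
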