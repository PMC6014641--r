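---
title: "Measuring EEG-blood-pressure coupling: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring EEG-blood-pressure coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegbp)
```

## The problem

In preterm neonates, the interaction between cerebral activity and
arterial blood pressure is a window onto cerebral autoregulation: a
healthy brain-vasculature system keeps cerebral perfusion stable across a
plateau of arterial pressures, and a loss of that dynamic coupling — or a
shift in its direction — may accompany illness. `eegbp` implements a
complete pipeline for quantifying this coupling from long, unedited
multichannel EEG recordings and 1 Hz invasive blood-pressure series:
feature extraction, artifact handling, windowed linear and nonlinear
coupling measures, directed coupling, surrogate significance, and
cohort-level association with an illness-severity score (CRIB II, scale
1-27).

Because clinical recordings of this kind cannot be redistributed, the
package ships a synthetic-data module that generates EEG/BP recordings
and whole cohorts with *known* coupling strength, direction, artifact
content and score association. Every stage of the pipeline is exercised
and tested against that generator plus analytic closed forms.

## Signal representation

Raw EEG (8 bipolar channels, 256 or 1024 Hz) is band-passed 0.3-30 Hz
with a zero-phase 4th-order Butterworth filter and decimated to 64 Hz;
the 30 Hz edge sits below the 32 Hz output Nyquist, so the same filter
anti-aliases. The signal is cut into 60 s epochs shifted by 1 s; each
Hann-windowed epoch's power spectral density is integrated over four
sub-bands (0.3-3, 3-8, 8-15, 15-30 Hz — delta-through-beta edges adapted
to preterm maturational dynamics), and the per-band feature is the
*median over the eight channels*, which suppresses focal artifacts. Band
bins are half-open `[f1, f2)` with the last band closed at 30 Hz, so no
spectral bin is counted twice; the band integral is an exact bin sum
(tested against a direct summation oracle at 1e-9 relative tolerance).

Systolic and diastolic pressure at 1 Hz give mean arterial pressure by
the standard clinical formula MAP = DP + (SP − DP)/3. Cleaning removes:
MAP below 10 mmHg (transducer disconnection); outliers per
non-overlapping 1-hour block (|MAP − median| > 3 × IQR — the rule is
configuration, chosen for robustness); and ±10 minutes around every
clinical intervention. MAP is then smoothed with the same 60 s / 1 s
moving average used for the EEG epochs, and the EEG and BP validity
masks are intersected, so a second ignored in either signal is ignored
in both.

Amplitude-based EEG artifact thresholds (peak > 250 µV, or peak-to-peak
range < 0.1 µV within a second) are configuration with defaults chosen
at the scale of neonatal EEG; the mechanism, not the numbers, is the
fixed part of the design. On synthetic recordings with known injected
artifacts the defaults invalidate ≥ 95% of artifact seconds and < 5% of
clean ones (tested).

## Windowed coupling measures

All measures run on a 30-minute moving window shifted by 30 s (defaults;
both configurable), using only windows with ≥ 80% valid seconds.

**Correlation.** Pearson `r_xy = C_xy / sqrt(C_xx C_yy)` on the valid
samples of the window.

**Coherence.** Welch magnitude-squared coherence
`|S_xy(f)|^2 / (S_xx(f) S_yy(f))` on 400 s Hann segments with 50%
overlap (the overlap and taper follow standard Welch practice). The
window's scalar value is the sum of
coherence over the positive-frequency bins up to 0.5 Hz, excluding DC:
MAP dynamics live entirely below 0.5 Hz, so higher bins carry no signal,
and the DC bin only reflects mean levels.

**Adjusted mutual information.** The nonlinear measure. Within a window,
MAP is quantized by the *integer-range rule* — one label per integer
mmHg spanned, so MAP jitter within 1 mmHg creates no artificial
dynamics — and band power into 35 equal-width bins (the granularity that
maximizes corpus-mean AMI; `select_n_bins()` reproduces that calibration
on synthetic corpora with a planted optimum). With plug-in MI (log base
2) and entropies from the same histogram,

AMI = (MI − E[MI]) / (max(H(X), H(Y)) − E[MI]),

where E[MI] is the *exact* expectation of the plug-in MI under random
permutation of one sequence against the other. It is a sum of
hypergeometric terms over every contingency cell; factorials are
evaluated through `lgamma` and summed in ordinary space (terms are
probabilities, so no cancellation), which is stable at window sizes of
thousands of samples. The implementation is tested against the exhaustive
all-permutations mean for N ≤ 8 (exact), a Monte-Carlo permutation mean
at N = 100 (3 standard errors), and an independent reference AMI
implementation.

AMI is 1 for identical sequences, ≈ 0 (small negatives allowed) for
independent ones, at *any* label granularity — unlike raw MI, which
inflates with label count on pure chance (both behaviours are asserted
in the test suite). This is why the per-window AMI needs no surrogate
gate, while correlation and coherence do.

**Toy-data quantization.** For the synthetic sinusoid pairs used in the
validation studies (`toy_spec()` / `gen_toy_sinusoid()`), both sequences
are quantized with the integer-range rule. The 35-bin rule is a
calibration specific to EEG band power and has no meaning for toy
signals, so the signal-agnostic rule is the package default. Under this
choice the toy pair scores AMI ≈ 0.32 at Pearson r ≈ 0.91 and ≈ 0.2 at
r ≈ 0.8; AMI is necessarily monotone-decreasing in additive noise, so
any single quantization fixes the entire AMI-versus-correlation curve —
the two anchor values cannot be moved independently by binning choices.

The toy generator itself samples `x` on `n` equally spaced points of
`[0, 1)` (default `n = 1800`, one analysis window at 1 Hz) — an integer
number of periods of every sinusoid, so sample variance matches the
closed form `sum(a^2)/2` and the correlation under additive noise has
the analytic value `sqrt(V/(V + s^2))` used as the test oracle. The
first component's frequency multiplies `x` like the others.

## Directed coupling: transfer entropy

TE(X→Y) is the reduction in uncertainty of `y_{t+u}` given the source
past `x_t^{d_x}` beyond the target's own past `y_t^{d_y}`. Estimation is
the Kraskov-Stögbauer-Grassberger nearest-neighbour scheme (K = 4
neighbours, the standard bias/variance compromise): K-th neighbour
distances in the joint space under the max-norm are projected onto the
marginal spaces for strict-inequality neighbour counts, combined through
digamma functions, and averaged over time points. Estimates are in nats
and may be slightly negative; they are reported as-is.

Numerical choices: prediction time `u = 1` sample (the smallest causal
lag at 1 Hz); each stream is rank-normalized to (0, 1) before embedding
(TE is invariant to monotone marginal transforms in the continuous
limit, and ranks stabilize neighbour searches across units), with a
±1e-8 jitter breaking the exact distance ties the rank grid would
otherwise create; neighbour searches are brute force in C++ (quadratic,
exact — verified against an independent R implementation at n ≤ 200 to
1e-12).

Embedding dimensions are selected by active information storage,
`A_X(d) = MI(X_t^d, X_{t+1})`, estimated with the same KSG machinery.
Naively maximizing AIS over `d` fails: KSG estimator noise and bias grow
with dimension, so on autocorrelated data the argmax drifts upward. The
package therefore uses forward selection on *bias-corrected* AIS — at
each `d` the mean AIS of shuffled copies (same dimension, history
destroyed) is subtracted, and `d` is extended only while the corrected
gain exceeds a noise floor of max(2 × shuffle dispersion, 0.06 nats).
The floor was calibrated on independent AR(1)/AR(2)/IID simulations
(97%/83%/97% correct order recovery at n ≈ 1200) before being frozen.

TE significance uses surrogates that shuffle the source's *embedded past
vectors* as whole rows: the target's self-predictability is preserved
exactly, only the cross-conditioning is destroyed.

Closed-form anchors (all tested): for a memoryless Gaussian sequence
AIS ≈ 0; for Gaussian AR(1) with a = 0.8, AIS(1) = −½ ln(1 − 0.64) ≈
0.511 nats; for the coupled pair `y_t = a y_{t−1} + c x_{t−1} + ε` with
unit-variance IID `x`, TE(x→y) = ½ ln(1 + c²) and TE(y→x) = 0.

## Surrogates and significance

Per-window nulls permute both sequences independently (each marginal
histogram is preserved exactly) and re-evaluate the measure, 100 times
by default. Empirical p-values use the rank convention
`(r + 1)/(n + 1)`, always in (0, 1]. Signed measures (correlation) are
tested two-sided on |value|; non-negative measures one-sided. On
independent inputs the rejection rate matches the nominal level (tested
over 500 windows at α = 0.05). In the clinical pipeline, insignificant
correlation/coherence windows are excluded from per-subject medians;
AMI windows are not gated, because the chance correction is analytic.
A caveat: sample-level permutation ignores autocorrelation, so for
strongly autocorrelated windows the null is anti-conservative; the
package treats the gate as a filter, not as a calibrated test, and the
cohort statistics never rely on these per-window p-values.

## Cohort association

Each subject's coupling series is summarized as the median over valid
windows (optionally restricted to the first 24 h of life). The summary
is associated with the illness score by Spearman rank correlation
(average ranks on ties, two-tailed p), a least-squares line for
visualization, and a percentile bootstrap 95% CI over subject pairs
(1000 resamples by default; significance may be read either from
p < 0.05 or from the CI excluding zero — both are reported, as they can
disagree). Families of tests are corrected with Holm-Bonferroni
step-down: for five tests at α = 0.05 the smallest p must be below
0.01. Two dependent correlations sharing a variable (e.g. score-vs-AMI
against score-vs-MAP on the same subjects) are compared with Steiger's
z for overlapping correlations — the standard test for that design.

## What the synthetic generator does and does not emulate

The generator reproduces the statistical structure the pipeline relies
on: delta-dominated EEG (band-limited noise mixtures at 256 Hz, ~40 µV
rms), a slow MAP process (smoothed Ornstein-Uhlenbeck, mean 35 mmHg,
sd 4 mmHg, essentially all power below 0.05 Hz — only the band
limitation below 0.5 Hz is constrained by the physiology; the process
model itself is the package's invention), a monotone exponential link
between the MAP-side driver and the delta-band amplitude envelope with
tunable strength in [0, 1] and tunable direction (implemented with a
15 s lag), the four artifact types the cleaning stage must remove, and a
cohort whose per-subject coupling carries a planted rank correlation
with a CRIB-like score. The cohort generator imposes the planted
correlation *in-sample* (the coupling jitter is orthogonalized against
the score's latent variable): at n = 25 an expectation-only construction
leaves the realized rank correlation with a standard deviation of ~0.13,
which would make small-cohort recovery experiments a test of the draw
rather than of the pipeline.

Not emulated: cardiovascular physiology (pulse waveforms, baroreflex),
sleep-state cycling, maturational trends within a recording, NIRS, and
real artifact morphologies. Passing tests therefore demonstrate that the
estimators recover known coupling structure under realistic noise,
sampling and artifact *statistics* — not that any particular clinical
effect size would be reproduced on real recordings.

## Problem sizes and degenerate inputs

The test suite and the reproduction script run the estimators at the
sizes where their anchors are sharp but cheap: toy correlations at
n = 1e5; AMI axioms at the native window size n = 1800; exact
expected-MI checks at N ≤ 8 (exhaustive) and N = 100 (Monte-Carlo); KSG
closed forms at n = 1e4 and direction recovery over 100 replicates at
n = 800; surrogate calibration over 500 windows; cohort recovery over
20 replicates of 25 subjects at 1.5 h per subject with a 300 s window
shift. These sizes are the package's validation choices; the clinical
defaults (30 s shift, full-length recordings) remain the analysis
defaults.

Degenerate inputs are handled explicitly: constant windows quantize to
a single label and are skipped (AMI undefined when both entropies are
zero — an error for direct calls); zero-variance windows are skipped by
correlation/coherence and rejected by TE; physiologically impossible
SP < DP seconds are invalidated; empty margins contribute nothing to
the expected-MI sum; `|r| = 1` is rejected by the dependent-correlation
test (Fisher transform undefined).

## Known limitations

- The Welch coherence runs on the valid samples of a window
  concatenated across gaps; with ≥ 80% validity the distortion is
  small, but windows with structured gaps are better skipped entirely
  (raise `min_valid_fraction`).
- KSG neighbour search is exact brute force, O(n²) per window —
  appropriate at window sizes up to ~1e4 samples; a tree-based search
  would be needed well beyond that.
- The per-window surrogate null ignores autocorrelation (above).
- The EDF writer/reader covers plain 16-bit EDF with a constant
  per-signal rate — sufficient for the synthetic recordings and typical
  clinical exports, not a general EDF+ implementation.
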