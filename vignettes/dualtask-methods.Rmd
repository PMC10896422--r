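---
title: "Methods: dual-task executive-function analysis of EEG band power and gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-task executive-function analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualtaskEF)
```

## The analysis problem

Walking is not an automatic activity: it competes for executive resources
(inhibition, working memory) with any concurrent cognitive task. A
dual-task protocol makes that competition measurable. Subjects perform two
graded cognitive tasks — an auditory Go/NoGo task taxing inhibition, and
an N-Back task taxing working memory — first sitting, then while walking,
while an eight-channel wireless EEG (Fp1, Fp2, Fz, Cz, C3, C4, O1, O2) and
a marker-based 3D gait system record. The analysis question is which EEG
band-power features change *monotonically* as task difficulty rises
through three levels (no task, easier level, harder level), and how the
gait pattern degrades under cognitive load.

This package implements that analysis end to end, together with a
synthetic-data generator that reproduces the statistical structure the
analysis assumes, so every stage can be validated against known ground
truth.

## Task protocol

The Go/NoGo task presents 150 auditory stimuli; difficulty is scaled by
shortening the inter-trial distance from 2.0 s (level 1, a 300 s run) to
1.3 s (level 2, 195 s). The N-Back task presents 75 letter stimuli of
1.5 s each (about 113 s per run); difficulty is the load factor N = 1
or 2. `buildSchedule()` realizes these as onset sequences with the target
count (no-go stimuli, or N-back matches) fixed to the nearest trial.

Two protocol parameters are not part of the published design and were
fixed once here: the no-go fraction (0.30, the conventional choice for
Go/NoGo designs, which keeps prepotent responding dominant) and the
N-Back alphabet and match rate (8 consonants, 0.30). Both are
configurable.

Scoring normalizes Go/NoGo on all 150 trials. The N-Back score is
normalized on 44 trials although 75 stimuli are presented; no selection
rule accompanies that denominator, so `scoreResponses()` scores the
trials after the first N (which have a defined N-back identity),
truncated to 44 — the earliest well-defined window — and exposes the
denominator as a parameter.

## EEG cleaning

Preprocessing is a fourth-order Butterworth bandpass over 0.5–45 Hz. The
design is applied forward and backward (`bandpassFilter()`), trading a
doubled effective order for exactly zero phase distortion — the right
trade for offline feature extraction, where group delay would smear epoch
boundaries. Plain forward-backward filtering of finite records leaves
edge transients, so the implementation seeds each pass with its
steady-state initial conditions and pads with odd reflection (48 filter
lengths); a constant input then passes through with an exactly zero
output, and a 10 Hz tone is preserved to within 0.1%.

Transient artifacts are removed by a variance-threshold subspace method
(`asrClean()`): the recording is projected onto the principal directions
of its own covariance; within 0.5 s half-overlapping Hann windows the
variance of each component is measured; a per-component threshold is set
at median + cutoff × 1.4826 × MAD of that component's variance over all
windows (cutoff 15 by default); components above threshold are zeroed in
their window and the signal is rebuilt by weighted overlap-add. Classical
artifact subspace reconstruction calibrates the threshold on clean
reference data and reconstructs discarded directions from a calibration
mixing matrix; the variant here is the self-calibrating
discard-and-rebuild form, which needs no reference segment. Its key
property — exact identity on data that never crosses the threshold —
is what the tests pin down: the Hann windows at 50% overlap sum to a
constant, so with no discards the overlap-add returns the input.

Epochs are cut at stimulus onsets with length equal to the trial length
(2 s / 1.3 s for Go/NoGo, 1.5 s for N-Back); the un-stimulated baseline
is cut into 2 s epochs. Fractional sample counts are floored so all
epochs are equal length, and onsets whose window overruns the recording
are dropped and logged, never silently truncated.

## Band-power features

Per epoch and channel, power spectral density is estimated by Welch's
method (Hann window, segments of up to 1 s capped at the epoch length,
50% overlap — the standard compromise between variance and resolution
for 1.3–2 s epochs). Band powers integrate the density over delta
[1,4), theta [4,8), alpha [8,13), beta [13,30), low beta [13,20), high
beta [20,30) and gamma [30,45] Hz. Band edges are half-open so no bin is
counted twice, with gamma closed at 45 Hz; relative power divides by the
1–45 Hz total, so the five canonical bands partition the broadband
exactly — `relativePower()` sums to 100 by construction, a tested
invariant rather than an approximation. (The [0.5, 1) Hz residue of the
filter passband is deliberately excluded from the denominator.) Per-epoch
features are averaged arithmetically over epochs, giving 8 channels × 7
bands × {absolute, relative} = 112 features per (subject, setting,
condition) cell, stored as a `SummarizedExperiment`.

## Gait metrics

From heel-marker trajectories and gait events the seven spatial-temporal
parameters are computed per side: cadence (120/stride time), gait speed,
stance/swing/double-support percentages, stride length and step width.
The progression axis is not assumed to be a lab axis: it is the principal
horizontal direction of heel travel, which makes stride length robust to
walkway orientation. Joint-angle computation from markers is out of
scope (it is the motion-lab software's job); the package consumes
101-point time-normalized angle curves for the nine lower-limb variables.

Each Gait Variable Score is the RMS difference between a subject's curve
and a reference curve; a constant offset of c degrees scores exactly
|c|. The Gait Profile Score aggregates the nine GVS values. The
literature defines GPS as the RMS of the GVS vector, and that is the
default here; a plain-sum option (`gps(..., method = "sum")`) is kept
because the aggregation is sometimes described that way. The packaged
reference curve set is synthetic (smooth sinusoid shapes with plausible
ranges) and is meant for pipeline validation, not clinical comparison;
user-supplied references are accepted everywhere.

## Statistical screening

For each of the four analysis contexts (sitting/walking × Go-NoGo/N-Back)
every feature forms a subjects × 3 level matrix (level 1 = no task).
Screening is two-stage:

1. Spearman's rho between the *across-subject mean* values and the levels
   (with 3 points, rho = ±1 exactly when the trend is strictly monotone);
   only |rho| = 1 features pass.
2. A Friedman rank test across the three levels for the passing features,
   with Kendall's W = chi² / (n(k−1)) as effect size, classed as high
   (W ≥ 0.8), slightly high (0.5 < W < 0.8) or other.

"Inter-subject Spearman correlation" admits two readings — on the means,
or per subject. The screening rule (rho exactly ±1) only makes sense on
the 3-point mean series, so that is the screen; the per-subject
correlations are computed too (`perSubjectSpearman()`) with counts of
+1/−1 subjects, reproducing the subject-level confirmation tables.

No multiple-testing correction is applied across the 112 features by
default — the screening stage itself is the (informal) filter — but
`p.adjust`-style correction can be applied to the output by the user.
The left-right gait comparison uses paired Wilcoxon signed-rank tests;
the six between-condition contrasts (unperturbed walking vs each
dual-task condition, plus the two within-task level contrasts) use the
unpaired Wilcoxon-Mann-Whitney test. The conditions are in fact paired
within subject, and `gaitComparisons(paired = TRUE)` exposes the paired
alternative, but the unpaired test is the default because it is what the
analysis this package operationalizes prescribes. Friedman p-values use
the chi-square approximation (2 df), not the exact permutation
distribution, matching the chi-square reporting convention; the
wrappers delegate to `stats::friedman.test` / `stats::wilcox.test`, and
the test suite checks them against exhaustive-enumeration oracles for
all small samples (n ≤ 7).

## The synthetic-data generator

`simulateStudy()` emulates the full design: 13 subjects × {sitting,
walking} × 5 conditions. EEG is a 1/f background (exponent 1, 5 µV RMS)
plus band-limited Gaussian components per channel (delta 8, theta 6,
alpha 10, low beta 5, high beta 4, gamma 2 µV RMS — resting-EEG scale
amplitudes), generated by filtering white noise with the package's own
Butterworth design and rescaling to the exact target variance, so
configured and realized band powers agree by construction. Difficulty
effects multiply component amplitudes: the defaults inject a delta
increase at Fz across Go/NoGo levels (factors 1, 1.3, 1.6) and a
high-beta decrease at Fz across N-Back levels (1, 0.85, 0.7), and the
ground-truth registry (`groundTruth()`) lists exactly these. Subject
heterogeneity is log-normal amplitude jitter (sd 0.2) per subject and
band — positive, multiplicative, and constant across conditions within a
subject, as physiological amplitude differences are. Walking multiplies
the background by +10 dB, the typical dry-electrode degradation during
ambulation. Burst artifacts arrive as a Poisson process (2/min by
default), 0.2–0.5 s of 20× background RMS on 1–3 channels.

Gait trials advance heel markers along a straight progression axis with
stride time 1.1 s and stride length 1.30 m (healthy young adults at
self-selected speed), stance 62% — which in symmetric gait fixes total
double support at 2×62−100 = 24%, so double support is derived, not an
independent dial — and step width 0.10 m. Condition effects are a
−0.10 m stride delta and −5° foot-progression (external rotation) offset
under both Go/NoGo levels and a −3° foot-progression offset under
N-Back 2, the interference pattern the analysis should detect. Angle
curves are the reference plus the offset plus 1° noise.

What the generator does *not* emulate: volume conduction and channel
correlation, non-stationary oscillatory dynamics, event-related
potentials, realistic artifact morphology (blinks, EMG), curved walking
paths, and marker soft-tissue artifact. Passing recovery tests therefore
demonstrates that the pipeline's statistics behave correctly under the
assumed structure — monotone amplitude modulation plus stationary noise —
not that the pipeline would reach the same conclusions on any real
cohort.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses steady-state initial conditions plus
  odd-reflection padding; non-finite samples are a hard error, never
  interpolated.
* The subspace cleaner errors when the recording is shorter than 10
  analysis windows (no variance distribution to calibrate on). The
  outermost window at each end carries the zero-phase filter's edge
  transient (reflection-padded forward-backward filtering is inexact
  near a 0.5 Hz highpass edge), so those two windows are excluded from
  threshold calibration and passed through uncleaned; bursts in the
  first or last quarter second of a recording are therefore not removed.
* Welch/periodogram scaling is Parseval-consistent; a zero signal yields
  a zero spectrum, and relative power on it is an error, not NaN.
* Spearman rho on a constant 3-point series is `NA` (no ordering), which
  never passes the screen; a Friedman matrix whose rows are all constant
  returns chi² = 0, p = 1 (no ordering evidence).
* With 3 levels, |rho| = 1 is tested with tolerance 1e-9 on an exactly
  rational statistic, so screening is not float-sensitive.
* Sub-seeds for subjects, conditions and trials are derived
  deterministically from the master seed and stay below 2^31.

## Problem sizes used in validation

The recovery and calibration checks run the full pipeline on simulated
studies with 13 subjects and all five conditions but a reduced protocol —
20 trials per task run, a 40 s baseline, 128 Hz sampling — which keeps
epoch counts (about 20 per condition) large enough for stable Welch
estimates while making a 20-master-seed recovery experiment and a
5-master-seed null calibration run in minutes. Effect sizes, noise
levels, subject count and artifact rates are the generator defaults
throughout; only the recording lengths are scaled.

## Known limitations

* The subspace cleaner shares the discard logic of artifact subspace
  reconstruction but not its calibration-based reconstruction; heavily
  contaminated recordings lose the brain signal that lies in discarded
  directions for the affected windows.
* GVS/GPS against the synthetic reference measure pipeline correctness,
  not clinical deviation.
* The unpaired between-condition gait test is conservative for the
  within-subject design it is applied to; the paired option exists.
* EDF and C3D containers are not read natively; EEG travels as wide CSV,
  markers as long CSV, curves and events as CSV, schedules as TSV.
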