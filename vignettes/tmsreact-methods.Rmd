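---
title: "Methods: resting-EEG and TMS-EEG cortical reactivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-EEG and TMS-EEG cortical reactivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsreact)
```

## Scope and model

`tmsreact` implements the quantitative core of a combined resting-EEG /
TMS-EEG reactivity analysis in Parkinson's disease rehabilitation research:
how strongly does a cortical stimulation protocol (intermittent theta-burst
stimulation, iTBS, or 10-Hz repetitive TMS) change cortical excitability,
and can baseline EEG features predict which patients will respond
clinically? The package covers five analysis stages plus a synthetic-data
module that makes all of them testable without patient data:

1. **Resting spectra** — Welch PSD, relative band power over the
   δ/θ/α/β/γ partition (with δ1/δ2 sub-bands), and the slowing ratio
   *ratio 1* = (δ + θ)/(α + β).
2. **Connectivity** — phase lag index (PLI) between channel pairs per band.
3. **TMS-evoked potentials** — epoching around the pulse, artifact-window
   interpolation, amplitude-based trial rejection, averaging, global mean
   field amplitude (GMFA), local M1 cluster potentials, and
   P30/N45/P60/N100/P180 peak quantification.
4. **Responder analysis** — UPDRS-III-based responder labelling and a
   nested cross-validated linear-SVM classifier on the two baseline EEG
   features (frontal δ relative power, F2–F7 δ PLI).
5. **Cohort statistics** — normality-gated paired/between-group change
   tests and change–change correlations.

Generalized estimating equations for repeated measures are deliberately not
implemented: they are standard off-the-shelf longitudinal machinery,
orthogonal to the EEG signal processing that this package is about; the
per-timepoint within- and between-group tests in `cohort_stats` cover the
implementable statistics. Likewise out of scope: ICA-based artifact
decomposition (the threshold-based `reject_epochs()` stands in for
interactive cleaning when data are simulated or pre-cleaned), source
localization, and realistic head-model forward simulation.

The package has no command-line binary: it is a library, and its interface
is its functions (`run_pipeline()` ties the stages together on files) plus
this vignette.

## Spectral analysis

`welch_psd()` uses 2-s segments at the recording rate (0.5-Hz resolution at
1000 Hz), 50% overlap, per-segment mean detrending, and a Hann window. The
segment length is the one conventional for clinical resting EEG; Hann with
50% overlap is the field default, and the suite verifies the implementation
against a brute-force periodogram-averaging oracle to 1e-8.

Band powers are trapezoid integrals of the PSD over each band. Trapezoid
integration makes band power *additive* at shared edges: the sample at a
shared band edge is counted half in each neighbour, so δ1 + δ2 = δ exactly
and the five partition bands sum exactly to the total over 1–45 Hz. The
relative-power denominator is restricted to 1–45 Hz — the union of the
defined bands — precisely so that relative powers over the partition sum
to 1.

One leakage subtlety is worth knowing: a Hann window spreads exactly one
third of an on-bin sinusoid's power into the two adjacent 0.5-Hz bins.
Integrating a narrow interval that ends on those bins therefore
under-counts by up to ~17%; integrating any interval that contains the full
main lobe (e.g. a whole band for an interior peak) is exact. Tests assert
the sinusoid power identity over the containing band, not over a ±0.5-Hz
sliver.

`slow_fast_ratio()` computes ratio 1 per channel from absolute band powers
(the total-power denominator cancels, so relative powers give the same
value); regional reporting averages the per-channel ratio, since the
spatial level of the ratio is a reporting choice rather than part of its
definition.

## Phase lag index

`band_phase()` band-passes with a zero-phase FIR (Hamming-designed,
order ≥ 3 cycles of the band's low edge, applied by FFT convolution with
the group delay removed) and takes the analytic-signal phase. One filter
length at each record edge is masked out. `pli_matrix()` then computes

PLI(a,b) = | ⟨ sign( sin(φ_a − φ_b) ) ⟩ |

with sign(0) contributing 0, so zero-lag (volume-conduction) coupling is
invisible by construction — the tests plant one source mixed into two
channels at arbitrary gains and require PLI ≤ 0.05.

PLI is estimated over the **full masked record** by default. An
epoch-averaged variant (`epoch_seconds`) exists but is not the default:
|mean of ±1 signs| is biased upward at small effective sample counts, and a
2-s δ-band epoch contains only a handful of independent phase-difference
samples, so per-epoch PLI of *independent* channels averages near 0.3 —
a misleading floor. Over a continuous 60-s record the δ-band null is
≈ 0.05 on average, scaling as 1/√(effective samples); narrow bands sit
higher than wide ones at equal duration, and single seeds can exceed 0.1,
which is why null checks bound the seed-averaged value.

## TEP pipeline

Epochs span −1000..1000 ms around each pulse (the pulse sample is t = 0);
events without full window support are dropped with a warning. The magnetic
pulse artifact occupies −5..15 ms and is replaced by a cubic polynomial
fitted to 5 anchor samples on each side of the window; every sample outside
the window is bit-identical to the input, which the suite asserts with
`identical()`. Cubic was chosen as the lowest order that follows the local
curvature of the evoked response; the window and anchors are arguments.

Trials whose absolute amplitude exceeds 100 μV on any channel outside the
interpolated window are rejected and listed. Averaging subtracts a
−500..−50 ms baseline (ending 50 ms before the pulse to stay clear of any
pre-stimulus ringing).

GMFA(t) is the across-channel population standard deviation of the evoked
potential, so it is reference-free (adding a common offset changes
nothing) and needs no separate average-referencing step — the subtraction
of the spatial mean is part of the formula. Local TEPs average the nine
electrodes over the stimulated motor cortex (FC5…CP1 left, FC6…CP2 right).
Both the GMFA-trace peak and the local-cluster peak are computed for every
component, so either reading of "P60 amplitude over M1" is available.

Peak search windows follow the standard TEP literature — P30 20–40 ms,
N45 40–55, P60 55–80, N100 85–140, P180 150–250 — and are configurable,
since windows vary a few milliseconds between labs. Positive components are
local maxima, negative ones local minima; on the nonnegative GMFA trace
every component is a maximum. Among multiple qualifying extrema the largest
amplitude wins, and exact ties go to the earliest latency. A window with no
interior extremum of the right polarity reports `found = FALSE` rather
than clamping to a window edge.

M1(+) is the hemisphere contralateral to the more affected upper limb,
M1(−) ipsilateral; `map_m1_sides()` encodes that rule (an involution).
Stimulation intensity settings are metadata only; no computation depends on
them.

## Stimulation protocols

`build_protocol()` derives totals from structure rather than storing them:
iTBS = 2 sides × 20 trains × (10 bursts × 3 pulses at 50 Hz, bursts at
5 Hz — the standard 600-per-side iTBS train, and the only burst count
consistent with a 1200-pulse bilateral session); 10-Hz rTMS = 2 sides ×
20 trains × 30 pulses. `protocol_pulse_times()` enumerates every pulse, and
the scheduler reports the first-to-last-pulse duration; published session
durations typically include setup slack, so duration is reported, not
asserted.

## Synthetic data: what it emulates, and what it does not

`simulate_resting_eeg()` builds each channel as independent band-limited
components over a 1/f pink background plus white sensor noise. Components
are white noise shaped in the Fourier domain by a half-sine spectral
envelope over their band and then variance-rescaled, for three reasons:
the band fractions are hit exactly (the Parseval bookkeeping test requires
the band variances to sum to the signal variance within 1%); no component
power falls outside its band, unlike a realizable FIR whose transition
bands leak 10–20%; and a unimodal in-band spectrum resembles real rhythms,
which peak inside their band rather than filling it flat. Coupled pairs
share one band-limited component whose copy in the second channel has
every Fourier component rotated by a constant phase — an exact constant
lag at all frequencies, giving an analytic PLI of 1 at high coupling SNR.

`simulate_tep_epochs()` plants Gaussian bumps (latency, amplitude, width,
per-channel topography) plus a decaying artifact confined to −5..15 ms and
white trial noise. Gaussian bumps are *not* physiological dipole
projections; they are chosen exactly because their ground truth is
analytic, making amplitude/latency recovery a sharp test
(bias < 5%, latency within ±3 ms over 50 seeds at the study's own scale of
100 trials and 2 μV noise).

`simulate_cohort()` draws a two-arm cohort with a known responder fraction.
Responders draw baseline frontal δ relative power from N(0.355, 0.111²)
and non-responders from N(0.442, 0.088²) — the reported class separation
for this feature — while the F2–F7 δ PLI classes use N(0.15, 0.05²) vs
N(0.30, 0.08²), plausible resting δ-PLI magnitudes with a clear separation,
since only the direction (responders lower) is established. Baseline
UPDRS-III is N(35, 10²) truncated at 5 and rounded — a typical moderate,
ON-state motor score — and improvement rates after 10 sessions are
N(0.40, 0.08²) for true responders vs N(0.08, 0.08²) for non-responders,
straddling the 30%/5-point labelling rule so that rule-derived labels and
ground-truth classes agree imperfectly near the boundary, as they would in
practice. A simulated P60 amplitude change is coupled positively to the
improvement rate (2 μV per unit rate, 0.4 μV residual noise), so score
decreases accompany P60 increases and the change–change correlation has the
expected negative sign.

What passing tests on these simulations demonstrate is that the
*estimators and the pipeline plumbing* are correct: power bookkeeping,
phase-lag recovery, peak recovery, leakage-free cross-validation,
calibrated tests. They do not demonstrate performance on real EEG, which
has non-stationarity, correlated sensor noise, volume conduction across all
pairs, eye/muscle artifacts, and non-Gaussian evoked variability that the
generators deliberately omit.

## Classifier

`nested_cv_classify()` is a linear SVM under 5×5 nested cross-validation.
Outer folds are stratified; the inner loop, run on each outer-training set
only, picks the margin penalty C from the log grid 10⁻³..10³ (7 points) by
inner balanced accuracy, ties to the smaller C (the weaker-regularisation
tie-break). Feature z-scoring uses training-fold statistics at both levels;
a constant training column z-scores to zeros with a warning. Each
"repetition" is a fresh random draw of the outer partition, and balanced
accuracy / AUC are averaged over repetitions (1000 by default; the test
suite and acceptance script use 1–200 to keep runtimes sensible — the
estimate's Monte-Carlo error falls as 1/√repetitions, so the default
matters for the third decimal, not the conclusion). Folds that end up
single-class are redrawn, with failure after 100 attempts.

AUC is the midrank Mann–Whitney statistic on the pooled out-of-fold
decision scores (equal to the trapezoid area under the empirical ROC with
tied scores on the diagonal); the reported operating point maximises
Youden's J, ties resolving to the higher sensitivity. A permutation null is
obtained by re-permuting labels across repetitions — one fixed permutation
is itself a random draw with an AUC sd near 0.08 at n = 60, and
cross-validation on null data is slightly pessimistic, so only the
permutation-averaged AUC is expected to sit in the chance band.

## Statistics

All two-sample machinery is normality-gated at the conventional Shapiro–
Wilk α = 0.05: paired t vs Wilcoxon signed-rank within group, independent t
vs Mann–Whitney between groups, Pearson vs Spearman for change–change
correlations (degenerate samples count as non-normal). Within-group
families use Bonferroni (`min(1, p × family)`); between-class feature
comparisons use Benjamini–Hochberg FDR across features. All-zero
differences short-circuit to the degenerate result p = 1 rather than
erroring. The improvement rate (t0 − t10)/t0 is defined only for t0 > 0;
t0 = 0 subjects are excluded from rate-based analyses.

## Numerical and degenerate-input choices

* Time is milliseconds (t = 0 at the pulse), amplitudes microvolts,
  frequencies Hz; the epoch grid at 1000 Hz is integer milliseconds.
* Band edges are shared, and trapezoid integration splits the shared
  sample half-and-half — no bin is double-counted.
* The FIR edge mask removes one full kernel length per record edge; a
  record shorter than two kernel lengths is an error, which for the δ band
  (3-s kernel) means resting records must exceed ~7 s.
* `sign(0)` counts as 0 in PLI (zero-lag samples dilute rather than
  inflate).
* EDF output quantises to 16 bits over a per-channel symmetric integer
  range; round-trip error is bounded by half a quantisation step. Partial
  trailing seconds are zero-padded, so whole-second recordings round-trip
  cleanly.
* Problem sizes in the suite: 10–120-s single/two-channel recordings for
  spectral and PLI properties, 50 seeds × 100 trials × 59 channels for TEP
  recovery, n = 30/30 with 20–200 repetitions for the classifier, and
  500-replicate calibration runs — sizes at which every Monte-Carlo
  tolerance used has comfortable margin.

## Known limitations

* The threshold-based trial rejection is not a substitute for ICA cleaning
  of real TMS-EEG; it is the appropriate guard for simulated or
  pre-cleaned data.
* PLI on short narrowband records has a high null floor (see above);
  interpret δ-band PLI from minutes-long records, not epochs.
* The EDF writer covers continuous 16-bit recordings with a uniform
  sampling rate — no EDF+ annotations, no discontinuous records.
* Longitudinal dependence across the three assessment timepoints is
  handled per timepoint, not jointly (no GEE).
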