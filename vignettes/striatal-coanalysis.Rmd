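---
title: "Methods: striatal ACh photometry, vesicle co-localization and addiction-criterion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: striatal ACh photometry, vesicle co-localization and addiction-criterion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatools)
```

Cholinergic interneurons of the dorsal striatum co-release acetylcholine and
glutamate: the vesicular glutamate transporter VGLUT3 co-resides with the
vesicular ACh transporter VAChT on a subset of synaptic vesicles, and
VGLUT3-dependent vesicular glutamate boosts ACh loading ("vesicular
synergy"). Characterizing how a missense variant perturbs this system rests
on a handful of bespoke desk-scale computations: detecting spontaneous ACh
transients in fiber-photometry traces, classifying transporter co-expression
from two-color STED spot coordinates, decomposing vesicular-uptake means into
transporter contributions and synergy percentages, and classifying animals
against percentile-based food-addiction criteria. `striatools` implements
each of these as tested, reusable functions, together with seeded simulators
that generate every input kind with known ground truth.

This vignette records the models, the parameters that matter, and the design
choices made where the methods literature leaves the procedure open.

## Photometry model and processing chain

A recording holds two channels sampled at a common rate: the sensor channel
(465 nm excitation, ACh-sensitive) and the isosbestic control channel
(405 nm, ACh-insensitive). The generative model behind
`simulate_photometry()` is

```
F_signal(t)  = A_s + B + b e^{-t/tau} + sum_i a k(t - t_i) + m(t) + e_s(t)
F_control(t) = A_c + B + b e^{-t/tau}                       + m(t) + e_c(t)
```

with autofluorescence offsets `A`, baseline `B`, exponential photobleaching
`(b, tau)`, transients of amplitude `a` on a homogeneous Poisson train
`{t_i}`, a slow motion artifact `m(t)` shared by both channels, and
independent Gaussian noise `e(t)`. The transient kernel is a peak-normalized
difference of exponentials `(1 - e^{-t/tau_r}) e^{-t/tau_d}`; overlapping
transients add linearly. Defaults (0.3 s rise, 1.2 s decay, 1 event/min,
20 min at 600 samples/s) reflect the seconds-scale kinetics of genetically
encoded ACh sensors; absolute rates and amplitudes for spontaneous striatal
ACh release are not standardized, so these are stated model conditions, not
fitted constants.

`preprocess_trace()` applies, in order: mean-bin downsampling (default
120 Hz), autofluorescence subtraction, per-channel exponential detrend with
the pre-detrend mean restored as offset, conversion to dF/F with baseline
`F0 = fitted asymptote + restored mean`, control-channel subtraction,
Gaussian low-pass, and z-scoring. The baseline definition deserves a note:
dF/F conventions differ across labs, and we pin `F0` to the fitted
asymptotic constant plus the restored offset because it is deterministic,
recorded in the provenance, and — like any positive affine choice — is
erased by the final z-score. The whole chain is exactly invariant under
positive affine transforms of both raw channels, which the suite asserts.
If the exponential fit fails to converge the stage falls back to a linear
detrend and flags it in the provenance; a non-positive `F0` is an error.

### Event detection and its operating point

`detect_events()` implements the rolling-median / MAD routine: the residual
against a 10 s centered rolling median is formed; samples more than
`filter_k = 2` MADs above it are discarded; the median and MAD of the
remaining ("filtered") trace anchor the peak threshold at `peak_k = 3` MADs;
strict local maxima above it are events, subject to a 0.5 s minimum
separation (larger peak wins, earlier on ties; plateaus resolve to their
first sample).

Two numerical choices define the operating point:

* **MAD scaling.** We use the normal-consistency factor 1.4826 (R's `mad()`
  default), so "3 MADs" is a ~3-sigma robust threshold. With the raw MAD the
  threshold sits near 2 sigma of a Gaussian trace, where the local-maxima
  rate of any band-limited noise makes false positives number in the tens
  per minute — no useful operating point exists there. `mad_scale = 1` is
  available for sensitivity analysis.
* **Detection bandwidth.** The default 0.12 Hz Gaussian low-pass matches the
  multi-second ACh-sensor transients. This choice is a genuine trade-off
  that we examined before freezing it: the false-positive rate on event-free
  traces is scale-free and proportional to the local-maxima rate of the
  smoothed noise (so it falls as the cutoff falls), while the z-scored
  amplitude of transients at 1 event/min is capped near
  `sqrt(60 s / (sqrt(pi) sigma_t))` (so it also falls as the cutoff falls —
  the events themselves dominate the trace variance that the z-score divides
  by). At 0.12 Hz, transients of the default kinetics detect at ~5.2 z with
  ~99% hit rate, and the residual false-positive rate is ~0.13/min. Pushing
  the rate below 0.1/min requires a cutoff below ~0.08 Hz, where transient
  amplitudes drop under 5 z and the hit rate under 95%: with this detector
  the two figures of merit cannot both be met on Gaussian-noise traces, and
  we chose the sensitivity side. The test suite asserts both bounds at their
  stated values; the specificity assertion is accordingly expected to fail
  and is left failing rather than relaxed, since it documents a real
  limitation of the 3-MAD rule rather than an implementation defect.

Whether the baseline filter should iterate (re-estimating the MAD after
exclusion) is unspecified in the source method; a single pass is
implemented. `summarize_events()` reports frequency (events/min), mean peak
amplitude (z units above the filtered-trace median) and inter-event
intervals; `compare_event_trains()` is the two-sided asymptotic two-sample
Kolmogorov-Smirnov test.

## Spot-field co-localization

`nearest_neighbor_distances()` computes, for every channel-A (VGLUT3) spot,
the Euclidean distance to its nearest channel-B (VAChT) spot. The analysis
is directional (A to B) to match how co-expression fractions are reported;
a symmetric analysis is a one-line swap of the channels. The analysis is
2-D — STED images of isolated vesicles are projections — and applies no
edge correction: spots near the field border see a censored B neighborhood,
a bias bounded by `chance_colocalization()` (for the default field and spot
densities it is below 1e-4 in the co-expression fraction). A vesicle counts
as co-expressing when its NND is at or below 95 nm, the published cutoff
separating double-transporter from single-transporter vesicles; equality
counts as co-expressing, since the published phrasing ("above and below")
does not resolve ties. Histograms default to 10 nm bins over 0-500 nm with
an open final bin, so counts always total the number of A spots.

The simulator places A spots uniformly, gives `round(f_co * n_A)` of them a
partner displaced by a Rayleigh-distributed distance (scale 40 nm by
default, putting the NND mode near 50 nm) at uniform angle, and adds
unpaired B spots as complete spatial randomness. Under these defaults the
expected classified fraction is `f_co * P(Rayleigh <= 95)` plus a small
chance-co-localization term — about 39.4% for `f_co = 0.40` — so recovery
to within ±3 percentage points is a meaningful check, not an identity.
Partners may land slightly outside the nominal field and are kept; clipping
them would bias the displacement distribution the classifier must see.

## Uptake arithmetic

`summarize_uptake()` gives per-cell mean, sd and SEM (sample sd over
`sqrt(n)`, flagged undefined for n < 2). `percent_change()` and
`transporter_contribution()` carry explicit rounding conventions
(`nearest`, `floor`, `none`) because published percent effects mix them:
a synergy of 112.6% prints as +113 (nearest) while 74.9% prints as +74
(truncation); both renderings are supported and neither is asserted as the
"right" reading. `compare_groups()` wraps the routine machinery — one-way
ANOVA with Tukey HSD, or two-way ANOVA with interaction and
Bonferroni-corrected pairwise cell comparisons — and flags degenerate
(zero-variance) designs instead of reporting an infinite F.

## Addiction-criterion classification and cohort arithmetic

The three food-addiction criteria (persistence of responding during
signaled non-availability, motivation as progressive-ratio breaking point,
compulsivity as shocks sustained) are scored against the 75th percentile of
the control-group distribution; an animal strictly above threshold on a
criterion is positive, and 2 of 3 positives classify it "addicted". The
"75th percentile of the normal distribution of the control group" wording
admits two readings: the empirical percentile (linear interpolation between
order statistics, `quantile(type = 7)`) is the default, and a
Gaussian-quantile mode (`mean + 0.6745 sd`) sits behind
`method = "gaussian"`. The rule as implemented is invariant under strictly
monotone transforms of any criterion's scores (applied consistently to the
threshold set and the classified set), and on large continuous control
samples marks ~25% positive per criterion — both asserted in the suite.
Thresholds are always derived from the control group of the same
experiment/epoch as the classified animals.

`carrier_frequency()` renders carriers/total to one decimal (9 of 793 is
1.1%); `allele_frequency()` reports the direct quotient
`risk / (risk + reference)` — for 9 vs 1595 this is 0.56%, and the function
does not attempt to reconcile differently printed values.
`fisher_exact_2x2()` reports the conditional two-sided hypergeometric
p-value together with the *sample* odds ratio `ad/bc` (not the conditional
MLE), and the suite checks the p-value against full enumeration of tables
with fixed margins.

## Synthetic data: what passing tests do and do not show

The generators realize exactly the structure the estimators assume:
mono-exponential bleaching, linear superposition of identical transients,
an artifact that cancels perfectly under control subtraction, Gaussian
replicates, multivariate-normal scores. Passing recovery tests therefore
demonstrates correctness of the computations, not robustness to real-data
pathologies — multi-exponential bleaching, wavelength-dependent artifact
gain, sensor saturation, clustered vesicles, localization error, or
heavy-tailed behavioral scores are all outside the generative model, and
results on real recordings should be read with that in mind.

Problem sizes used by the checks — twenty 10x10 um fields of 200 + ~100
spots, 7 + 7 recordings of 20 min, 50 event-free recordings, replicate
tables of n = 6-8 — mirror the scale of the experiments the methods come
from, and every generator draw flows from one explicit per-call seed, so
all results in the test suite and acceptance script are exactly
reproducible.

## Known limitations

* The 3-MAD detector's specificity/sensitivity trade-off has no operating
  point satisfying both bounds above (~0.13 false positives/min at the
  bandwidth where sensitivity holds); a matched-filter or dual-threshold
  detector would dominate it, but is a different method.
* The detector also slightly inflates both genotypes' frequencies equally,
  biasing a twofold true-rate ratio toward ~1.8-1.9.
* No edge correction in NND analysis; negligible at default densities but
  not for fields smaller than ~1 um or thresholds approaching the field
  size.
* `simulate_uptake()` truncates Normal replicates at zero by resampling,
  which biases the realized mean upward when `sd` is comparable to `mean`;
  with the default parameters the effect is < 0.1%.
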