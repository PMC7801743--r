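---
title: "Numerosity pRF mapping: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerosity pRF mapping: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtopo)
```

`numtopo` implements a model-based analysis of numerosity-selective fMRI
responses: from the stimulus protocol, through per-voxel tuning-model
fits and voxel selection, to topographic-map statistics on a cortical
surface patch and the accompanying control analyses. This vignette
explains the models, the tunable parameters, what the synthetic-data
generators emulate, and the choices made where the design was genuinely
open.

## Stimulus protocols

The haptic protocol presents sets of 1–7 spheres plus a 20-sphere
baseline, each for a 3 s exploration period followed by a 4.5 s
inter-stimulus interval (a 7.5 s slot). One run is two repetitions of
*ascending 1–7, three baselines, descending 7–1, three baselines*; with
eight discarded initial frames at TR 1.5 s this gives 208 frames and
312 s, four presentations of each numerosity and twelve baselines.
The visual protocol flashes dot patterns for 300 ms with 350 ms of grey
in between, six flashes (3.9 s) per numerosity step, with 15.6 s
baseline blocks of 20 dots, four cycles per run; with six discarded
frames at TR 1.95 s this gives 182 frames and 354.9 s.

Two constructions are worth making explicit. First, time zero is the
first *retained* frame; discarded frames exist only as a count, because
all analysis operates on retained frames. Second, the visual baseline
blocks are modelled as 24 flashed presentations of numerosity 20 at the
same 650 ms rhythm (24 × 0.65 s = 15.6 s): the model consumes only
numerosity as a function of time, so the flash microstructure of the
baseline matters only through its duty cycle, which this choice keeps
identical to the numerosity steps. Stimulus intervals are half-open
`[onset, onset + duration)` so that sampling at any resolution is
unambiguous. The two haptic sphere conditions (equal individual size,
21 mm³ per sphere; equal total volume, 420 mm³ summed) share identical
timing and differ only in the sphere-set specification.

## The tuning model and its fit

A voxel's population receptive field is a Gaussian over the natural
logarithm of numerosity with mean `ln(pref)` and STD `sigma_log`.
Natural log is canonical here: a change of base rescales `sigma_log`
and leaves the model family unchanged. Width is reported in linear
units as the FWHM, `exp(ln p + c s) − exp(ln p − c s)` with
`c = sqrt(2 ln 2)`.

The forward model evaluates the tuning function on the stimulus trace
(zero where nothing is presented; the numerosity-20 baseline is included
and drives near-zero responses for preferences well below 20, acting as
an effective rest), convolves with a double-gamma HRF sampled at
`dt = 0.1` s, and reads off frame times. The double-gamma form (gamma
density peaking near 5 s minus a weighted undershoot density near 15 s,
unit-peak normalised) is the field standard; participant-level refits
adjust only the peak delay and undershoot ratio, on voxels whose initial
fit exceeds `r2 = 0.3`, in one outer iteration — a deliberately minimal
parameterisation of per-participant HRF variability.

Fitting is an exhaustive grid search: preferred numerosity log-spaced
over `[0.5, 40]` (60 points) and `sigma_log` log-spaced over
`[0.05, 3]` (40 points). The grid deliberately extends far beyond the
presented 1–7 range so that in-range estimates are not artefacts of a
truncated candidate set; estimates outside `[1, 7]` (closed interval)
are masked before map analyses. Because amplitude and baseline are
fitted by OLS per candidate, training variance explained equals the
squared correlation between series and prediction, and the search
reduces to one matrix product per voxel batch. Candidates whose OLS
amplitude would be negative are rejected: a tuned response is modelled
as positive-going. The winning candidate is refined by bounded
quasi-Newton search in `(ln pref, ln sigma)` to tolerance 1e-6;
refinement is optional (`refine = FALSE`) for large calibration batches
where grid resolution suffices, and the calibration tests use that mode.

## Voxel selection

Voxels responding to stimulation per se, rather than to numerosity, are
identified by cross-validation: runs are split into odd- and
even-indexed halves (1-based indexing — the convention had to be fixed
somewhere), the pRF and an on–off GLM (presence regressor convolved
with the HRF) are fitted per half-average, and each half's tuning
*shape* is evaluated on the other half with amplitude and baseline
refit, since raw scale differs between halves. A voxel is excluded when
the GLM's training variance explained exceeds the averaged
cross-validated pRF variance explained. Held-out goodness of fit is
`1 − RSS/TSS` after the OLS refit, which equals the squared correlation
with the fixed shape; whether the original analysis used squared
correlation or held-out residual variance is not determinable, so the
package documents its own definition.

Chance-level fits are calibrated by an empirical null: the same fitting
procedure applied to pure-noise voxels, with
`p = #(null r2 >= query) / N`. The original null came from white-matter
voxels of the same scans, which require the original data; the
synthetic null substitutes white Gaussian noise series, and the
calibration suite verifies that p-values of fresh null voxels are
uniform. The default inclusion threshold is variance explained above
0.30.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameters and an explicit
seed. The voxel simulator produces the three classes the selection
stage must separate: tuned voxels (log-Gaussian response through the
forward model), on–off voxels (constant-amplitude presence response)
and null voxels (noise only). The default noise level is "matched":
each voxel's noise STD equals its noiseless signal STD, so the
generating model explains about half the variance — chosen once as a
realistic mid-range regime for strong map voxels (no SNR is available
to copy, since the scan data are not public). An AR(1) option exists to
probe robustness to temporally correlated noise; the default is white.

The surface generator builds a regular triangulated strip with
preferred numerosity log-spaced along the column axis — a clean
topographic gradient with the low- and high-preference borders at the
two ends — and tuning width growing linearly in log preference
(`sigma = base + slope · ln p`). The glove generator renders
Poisson-count smooth movement bumps inside each exploration epoch
(slotted with jitter so individual movements remain separable) and
quiescence elsewhere; under a constant movement-rate profile its epoch
metrics are numerosity-independent by construction, which is exactly
the null the motion control analysis must not reject. The behavioural
generator produces error-free responses within a subitizing limit of 3,
error probability rising linearly above it (slope 0.15 per unit
numerosity, so 60% at numerosity 7), and reaction times increasing with
numerosity under log-normal noise.

None of these emulate realistic cortical folding, draining-vein or
laminar BOLD effects, exploration strategy, or spatially correlated
noise. Passing tests therefore demonstrate that the *analysis machinery*
is correct and calibrated on data whose ground truth is known — not that
real data satisfy the model.

## Map statistics

Distances along a map run over the mesh edge graph (multi-source
Dijkstra with Euclidean edge weights) — the standard deterministic
approximation to exact surface geodesics, adequate at 2 mm binning. Each
member vertex gets the normalised coordinate
`d_low / (d_low + d_high)`, rescaled by the mean ROI length so that
positions are in mm.

The progression fit bins sites into half-open 2 mm intervals and fits
`preference = a + b·ln(distance + eps)` to the bin means, with
`eps = 0.5 · bin width` guarding the logarithm at zero distance (the
original handling of zero distance is not stated; this is the package's
choice). Tuning-width progression is the linear analogue over 0.25-wide
preference bins; its abscissa is the within-bin mean preference, which
makes the fit exact on exactly linear data (the nominal bin centre
would introduce a binning bias). Inference follows the prescribed
resampling scheme: bins resampled with replacement (default 2,000
draws here; the reference analysis used 10,000 — the reduction keeps
the calibration suites fast and is immaterial for the quantities
checked), with the median slope/intercept as the best fit and the
2.5/97.5 percentiles as the 95% CI; and a permutation test shuffling
the assignment of bin means to bin positions, with the plain proportion
of permuted slopes at or above the observed slope as the p-value (an
add-one smoothing option exists but is off by default, matching the
plain-proportion definition). Empty bins are dropped; occupied bins are
retained regardless of count. Resampling sites instead of bins is
available via `boot_unit = "vertices"`.

One honest calibration caveat, measured during development and worth
stating: the percentile bootstrap over ~15–30 bins genuinely
undercovers slightly (≈93% rather than 95% for a nominal 95% CI in our
simulations). This is a known small-sample property of percentile
intervals, not an implementation defect; the calibration suite asserts
coverage in the 93–97% band at 30 bins, which sits at the edge of that
behaviour.

Cortical magnification uses seven unit-width bins centred on
numerosities 1–7, per-map coverage percentages (summing to 100 by
construction), and a planned linear-decrease contrast with centred
weights `(3, 2, 1, 0, −1, −2, −3)` — the exact contrast weights are not
printed anywhere, so a centred linear ramp is assumed — followed by a
one-sided t-test across maps and Benjamini–Hochberg FDR across map
groups.

## Cross-modal comparison and controls

Overlap between two thresholded maps is reported relative to each map
and as their mean (group summaries average across participants,
hemispheres and modalities, so both references are needed). Preference
correlations over shared vertices are Fisher z-transformed before any
group statistic (one-way ANOVA, all-pairs t-tests with Bonferroni
multiplication capped at 1, per-group one-sample t against 0); overlap
percentages are arcsine-transformed (`asin(sqrt(p))`). Each map
instance is treated as one observation in these ANOVAs. Correlations
with `|r| = 1` have infinite z and are excluded with a warning.

The glove analysis counts movement peaks above a prominence threshold of
10% of the epoch's signal range, takes the epoch STD, and measures
motion duration between the first and last successive-difference
exceeding three times the median absolute successive difference of the
quiescent inter-epoch segments — both thresholds are config-exposed
because no reference values exist, and an optional smoothing window
(default: none) is available. The numerosity effect is tested by a
two-way repeated-measures ANOVA on per-participant cell means, plus
`BF01 = exp((BIC_full − BIC_null)/2)` as a Bayes-factor approximation
for the null; this BIC approximation is explicitly *not* equivalent to
a default-prior Bayesian ANOVA and is labelled accordingly. Behavioural
statistics use Friedman tests on per-participant median reaction times
(average ranks for ties), participant-pooled pairwise 2×2 chi-square
tests of error counts with Bonferroni correction, and Spearman
correlations between per-participant per-numerosity profiles across
modalities.

## Numerical and degenerate-input conventions

Constant series fit with `r2 = 0` and a degenerate flag rather than
erroring; a series for which every positive-going candidate fails
(all-negative correlations) is likewise flagged. Disconnected mesh
vertices receive infinite geodesic distance and trigger an error only
when they belong to the analysed ROI. Line fits centre both variables so
that exactly constant ordinates give exactly zero slopes (and
permutation p = 1, not a float coin-flip). All resampling is seeded;
identical seeds give bit-identical bootstrap CIs and permutation
p-values. Problem sizes in the calibration suites (100 fitted voxels
per recovery batch, 2,000-voxel synthetic nulls, 500 permutation maps,
300 bootstrap-coverage replicates, 500 ANOVA null replicates at a
reduced 26 Hz/2-finger glove configuration) were chosen as the smallest
sizes at which the asserted properties are statistically meaningful.

## Known limitations

The on–off comparison is the only model-comparison control: suppressive
surrounds, multi-Gaussian pRFs or tuned-versus-monotonic contrasts are
out of scope. Geodesics are graph shortest paths, not exact polyhedral
geodesics. The synthetic null lacks the spatial autocorrelation of real
white matter. Map and border *detection* is not attempted — borders are
inputs, as in the reference workflow, and any claim about particular
cortical areas is outside what synthetic validation can support.
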