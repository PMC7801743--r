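# numtopo

Model-based analysis of numerosity-selective fMRI responses, in R.

Cortical neural populations are tuned to *numerosity* — the number of
items in a set — and in several association areas this tuning is arranged
in topographic maps, with preferred numerosity progressing systematically
along the cortical surface. `numtopo` implements the full analysis chain
used to detect and characterise such maps from ultra-high-field fMRI of
haptic (spheres explored in the hand) and visual (dot patterns)
numerosity stimulation, and ships synthetic-data generators with known
ground truth so every stage can be validated end to end without access
to scan data.

## The model

Each voxel's aggregate tuning is summarised by a population receptive
field (pRF): a Gaussian over log numerosity,

    r(n) = exp( -(ln n - ln p)^2 / (2 sigma^2) )

with preferred numerosity *p* and log-space tuning width *sigma*
(reported in linear units as the full width at half maximum,
`exp(ln p + c sigma) - exp(ln p - c sigma)`, `c = sqrt(2 ln 2)`). The
predicted BOLD series is the tuning response to the stimulus timeline
convolved with a double-gamma haemodynamic response function, sampled at
frame times; amplitude and baseline are fitted per candidate by ordinary
least squares, and the `(p, sigma)` pair with the highest variance
explained wins, followed by bounded local refinement. Untuned but
stimulus-responsive voxels are removed by a cross-validated comparison
against an "on–off" GLM whose only predictor is stimulus presence, and
noise voxels by an empirical-null threshold on variance explained.
Map structure is quantified by geodesic distances between hand-drawn
map borders, binned progression fits of preference against cortical
distance (log model, bootstrap CIs, permutation p), tuning-width
progression, cortical magnification contrasts, and cross-modal overlap
and correlation statistics.

## Worked example

```r
library(numtopo)

timeline <- build_haptic_run(tr = 1.5)
timeline$n_frames_total            # 208 frames, 312 s in total
#> [1] 208

# a tuned voxel at preferred numerosity 3, fitted back from its own signal
y <- simulate_voxel(timeline, pref = 3, sigma_log = 0.4,
                    noise_sd = "matched", seed = 1)
fit_prf(y, timeline)
#> # A tibble: 1 x 8
#>   voxel  pref sigma_log fwhm_lin amplitude baseline    r2 degenerate
#>   <int> <dbl>     <dbl>    <dbl>     <dbl>    <dbl> <dbl> <lgl>
#> 1     1  2.99     0.432     3.18      1.08   -0.662 0.583 FALSE

# a synthetic topographic map and its progression statistics
sp <- simulate_patch(n_rows = 6, n_cols = 15)
nd <- normalized_progression_distance(sp$patch, sp$roi)
binned_progression_fit(nd$distance, sp$truth$pref, seed = 1)
#> <progression_result> preference ~ ln(distance) (log fit)
#>   15 bins (width 2); slope 2.0226 [1.3105, 3.7394], permutation p = 0
```

The fitted voxel recovers its generating parameters (preference 3, log
width 0.4) with roughly half the variance explained, the regime the
noise default emulates; the map analysis finds a positive
preference-versus-distance slope whose permutation p is below 1/2000.

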