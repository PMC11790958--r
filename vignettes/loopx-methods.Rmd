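---
title: "Methods: quantifying condensin loop extrusion, peptide binding and ATPase kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying condensin loop extrusion, peptide binding and ATPase kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`loopx` implements the quantitative analysis used in single-molecule
studies of SMC-driven DNA loop extrusion, together with the two
plate-reader assays that usually accompany them: fluorescence-polarisation
(FP) equilibrium binding and phosphate-release ATPase kinetics.  Because
raw imaging data for such studies are rarely deposited, every analysis
stage is paired with a synthetic-data generator with known ground truth,
so the whole pipeline is validated by parameter recovery.  This vignette
documents the models, the defaults and their rationale, what the
generators do and do not emulate, and the numerical choices made where
the design was genuinely open.

## The imaging pipeline

### Geometry and observables

A 48.5 kbp lambda-DNA molecule is tethered at both ends to a passivated
surface, stained, and imaged as a fluorescent line.  A loop-extruding
condensin complex condenses part of the DNA into a bright punctum that
grows over time.  The pipeline converts a movie of one tether region of
interest into per-frame DNA amounts:

1. each frame is smoothed with a **disc median filter of radius 2 px**;
2. a **kymograph** is built by summing an **11-pixel band** centred on
   the DNA axis, one column per frame;
3. per-frame background (estimated as the median of off-band pixels,
   which carry no tether signal) is subtracted and columns clamped at
   zero;
4. local intensity maxima are detected in each kymograph line and the
   **most intense peak** is taken as the loop centre; per-frame centres
   are linked into tracks by nearest-neighbour association;
5. each line is partitioned into **Up / Loop / Down**, the Loop region
   being the **9 pixels** centred on the tracked peak;
6. the DNA in each region is its intensity fraction times the substrate
   size: `region_kbp = 48.5 * I_region / I_line`, which makes
   `up + loop + down = 48.5` an exact identity on every valid frame.

The loop growth curve `loop_kbp(t)` is smoothed with a
**Savitzky-Golay filter (order 2, 50-point window)** for display and for
locating the fit window; the **extrusion rate** is the ordinary
least-squares slope of a linear model `f(t) = k t + c` over the
**initial 5 s** of monotone growth of the *raw* curve.  Fitting raw
rather than smoothed data avoids filter-induced autocorrelation biasing
the slope and its nominal precision.

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `median_radius` | 2 | px | standard snapshot smoothing; disc (Euclidean ball, ties included) |
| `band_half_width` | 5 | px | 11-px summation band around the DNA axis |
| `loop_halfwidth` | 4 | px | 9-px Loop window about the tracked centre |
| `min_prominence` | 0.05 | fraction of line total | rejects shot-noise maxima at the default SNR |
| `search_range` | 10 | px | frame-to-frame linking limit |
| `link_memory` | 3 | frames | gaps bridged during linking |
| `min_track_length` | 10 | frames | replaces manual curation of loop tracks |
| `sg_order`, `sg_window` | 2, 50 | -, points | growth-curve smoothing |
| `fit_window_s` | 5 | s | linear rate-fit window |
| `monotone_drop_tol` | 0.5 | kbp | tolerated smoothed decrement when locating the window |
| `total_dna` | 48.5 | kbp | lambda-DNA substrate |
| `acquisition_span` | 1000 | s | span over which "at least one loop" is scored |

Notes on individual choices:

* **Odd smoothing windows.** Savitzky-Golay filters require odd window
  lengths; a requested even window (including the conventional 50) is
  rounded down to the nearest odd value, and windows longer than the
  series shrink to the largest odd length that fits, with a warning.
* **Fixed tether axis.** The 11-px band keeps one axis column per ROI
  (by default the column of maximal summed intensity).  Whether the band
  should be re-centred per frame is not specified by the conventional
  protocol; a fixed axis is the simpler assumption and is stated here
  explicitly.
* **Window selection.** Loop initiation is the last zero before the
  curve turns positive (or the first tracked point).  The fit window is
  the earliest 5-s stretch at/after initiation in which the smoothed
  curve is non-decreasing up to `monotone_drop_tol`; events with no such
  window are excluded from rate analysis, mirroring the usual exclusion
  of unstable events.  Whether an event that slips back *within* the
  initial window should be excluded outright or re-windowed is genuinely
  ambiguous; `loopx` re-windows (the exclusion path is what you get when
  no clean window exists at all).
* **Edge events.** Frames whose 9-px Loop window is truncated by the
  kymograph edge are flagged and excluded from rate fits: when a loop
  forms at the top or bottom of the tether the Up or Down amount cannot
  be determined.
* **Background.** Quantification operates on median-filtered,
  non-top-hat data; the white top-hat (disc radius 10) is provided for
  display and snapshot rendering.  Instead of the top-hat, the
  quantification path removes a per-frame *constant* background estimated
  from off-band pixels; without this the camera baseline enters the
  denominator of every intensity ratio and dilutes all DNA estimates.

## What the tether simulator emulates

`simulate_tether_movie()` renders a doubly-tethered molecule as a
Gaussian-blurred vertical line whose local intensity is proportional to
local DNA density, with a loop event as a punctum at the anchor position
carrying an intensity fraction exactly equal to its DNA fraction.  Two
modelling decisions deserve emphasis:

* **Slack-tether rendering.** In the no-flow imaging condition used for
  rate measurement the DNA is slack, and the visible non-looped segments
  *shorten* toward the loop at roughly constant linear density as DNA is
  reeled in — which is precisely the regime in which the intensity-ratio
  conversion is valid, because the 9-px Loop window then carries loop
  intensity only.  The alternative (fixed extent, thinning density)
  corresponds to a taut tether under flow; under that geometry about
  8 rows of non-loop DNA sit inside the Loop window and the ratio
  estimator inherits a structural offset.  The generator implements the
  slack regime, matching the assay configuration in which rates are
  measured.
* **Effective spot width.** `psf_sigma` (default 1.8 px) is the width of
  the *rendered* line and punctum: the optical PSF convolved with the
  transverse thermal motion of slack DNA over one exposure and the
  physical extent of the loop condensate.  It is deliberately larger
  than a bare diffraction-limited PSF.  This matters for accuracy: for
  narrow spots (sigma near 1 px) the radius-2 disc median filter erodes
  a disproportionate share of punctum mass and the ratio estimator reads
  low — a genuine limitation of the median-filter-then-ratio method that
  the test suite quantifies (the default pipeline is bounded at 8%
  relative error on noise-free movies, raw summation at 2%).

Photophysics defaults: 200 photons per kbp per frame, a background of
5 counts/pixel, Poisson shot noise plus 2-count Gaussian read noise —
bright nucleic-acid staining on a modern sCMOS/EMCCD.  All randomness
flows from a single integer seed per call, and identical configurations
reproduce movies bit for bit.

The generator does **not** emulate polymer dynamics, flow-stretching
hydrodynamics, photobleaching, dye-binding kinetics, loop-position
diffusion, or multiple simultaneous loops (events on one tether must not
overlap in time; the tracker follows a single, most intense punctum).
Passing recovery tests on these synthetics therefore validates the
*estimator chain*, not the microscope: real data add drift, neighbouring
molecules and heterogeneous staining that the quality flags
(`edge`, short-track, non-monotone) only partially absorb, which is why
the assay protocol retains manual supervision.

## The binding model

FP titrations with a fixed labelled-peptide (probe) concentration are
fit with the exact ligand-depletion (quadratic) solution of the
mass-action equilibrium, valid when the probe is *not* negligible
relative to the dissociation constant:

$$FP = \frac{FP_{max}}{2\,[Pep]} \left( ([C]+[Pep]+K_d) -
\sqrt{([C]+[Pep]+K_d)^2 - 4\,[C]\,[Pep]} \right)$$

with `[C]` the receptor and `[Pep]` the probe concentration in uM,
`FP_max` the saturating polarisation change in mP.  The discriminant is
clamped at zero against round-off near saturation.  As `[Pep] -> 0` the
model reduces to the hyperbola `FP_max [C] / ([C] + K_d)`, and the test
suite verifies the closed form against an independent numerical
equilibrium solver to 1e-9 relative.

Fitting (`fit_kd()`) is nonlinear least squares over `(K_d, FP_max)` on
per-concentration replicate means, with inverse-variance weights from
replicate SDs when available (unweighted otherwise), initialised at the
geometric mid-titration concentration and the largest observed mean, with
`K_d` bounded in `[1e-4, 1e4]` uM.  Reported standard errors come from
the fit covariance on the weighted means; errors across replicate-level
refits are a defensible alternative the package does not claim to match.
The probe concentration is fixed at its nominal value.  Identifiability
is surfaced rather than hidden: a titration that never approaches `K_d`
converges but reports a large `K_d` standard error.

Competition assays subtract matched background readings per condition
and compare conditions with unpaired two-tailed t-tests.

## ATPase rates and fold stimulation

Phosphate-release time courses are fitted by OLS over a steady-state
window.  The window is chosen automatically: per-sample noise is
estimated robustly from second differences (median absolute deviation,
insensitive to a lag kink), and the longest window whose linear-fit RMSE
stays within 1.5 times that noise is used — windows straddling an
initial lag phase have residuals far above the noise floor and are
rejected.  If nothing acceptably linear exists, the full trace is fitted
and flagged.  Rates are reported in uM/min and normalised by enzyme
concentration (ATP per enzyme per minute).  DNA **fold-stimulation** is
the rate at each DNA concentration divided by the DNA-free rate; the
baseline fold is exactly 1 by construction and relative uncertainties
propagate in quadrature.  No saturation-curve functional form is fitted
to the titration: the comparable quantity is the fold-change itself.

## Statistics

Per-experiment looped fractions (few independent experiments per
condition, no normality assumption) are compared with the two-sided
Wilcoxon rank-sum test.  For combined sample sizes up to 10 the p-value
is computed by full enumeration of rank assignments (mid-ranks under
ties), `p = min(1, 2 min(P(W <= w), P(W >= w)))`; larger samples use the
tie-corrected normal approximation with continuity correction.  Note the
exact-test floor: with 3 + 3 experiments the smallest attainable
two-sided p is 0.1.

Rates are compared with Welch's unpaired two-tailed t-test
(unequal variances, Welch-Satterthwaite degrees of freedom).  When both
groups have zero variance the statistic is undefined; `loopx` raises an
explicit error rather than silently inflating a variance, except in the
trivial equal-means case where `t = 0, p = 1`.

## Numerical and interface choices

* Pixel coordinates are 1-based row/column indices (R convention);
  kymograph row 1 is the top tether anchor.  Frame `i` is timestamped
  `i * frame_interval`.
* Disc structuring elements (median, erosion/dilation for the top-hat)
  are Euclidean balls with boundary ties included, shared between the
  compiled filters so both use one disc definition.  Median-filter
  borders are mirror-reflected; morphology clips neighbourhoods to the
  image domain, which keeps `0 <= tophat <= input` exact.
* Degenerate inputs error loudly with classed conditions
  (`loopx_bad_config`, `loopx_no_monotone_window`,
  `loopx_degenerate_groups`, ...), so pipelines can count and report
  exclusions by reason.
* Configuration is a flat list with strict key checking that round-trips
  losslessly through YAML/JSON; `run_pipeline()` is deterministic given
  the seed and emits a manifest (package version, config hash, seed).
  The package's exported functions are its interface; file-level entry
  points are thin wrappers around them.

## Validation problem sizes

The test suite validates by parameter recovery at the study conditions,
scaled to run quickly as a matter of design: six dissociation constants
(14.8, 5.9, 17.7, 2.8, 12.9 and 4.0 uM) each refit from 100 seeded
plates; 50 simulated extrusion events at 1 kbp/s (median recovered rate
within 10%), with a smaller sweep across 0.5-2 kbp/s; looped-tether
regimes of 96% and 24% detected on 50 simulated tethers each and
distinguished across 3 + 3 simulated experiments at the exact-test
floor; ATPase slopes recovered within 2% on average and a programmed
2.4-fold DNA stimulation within 5%.  `scripts/acceptance.R` re-runs the
recovery studies from scratch against the installed package.

## Known limitations

* The ratio estimator inherits the median filter's peak erosion; with
  narrow puncta it reads a few percent low (quantified above).  Rates
  from very dim or narrow-spot data should be treated as lower bounds.
* Tracking follows one punctum; colliding loops, Z-loops and
  multi-punctum tethers are out of scope.
* The automatic monotone-window choice replaces, but does not equal,
  expert curation; the quality flags are conservative approximations.
* FP fitting treats the probe concentration as exact and does not model
  intensity-weighted polarisation corrections or competitive-binding
  Ki conversion.
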