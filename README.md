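# loopx

Quantitative analysis of single-molecule DNA loop extrusion by SMC
complexes (condensin), plus the two companion biochemical assays:
fluorescence-polarisation (FP) peptide binding and phosphate-release
ATPase kinetics.  The package is aimed at people analysing TIRF/HiLo
movies of surface-tethered lambda DNA — and at anyone who wants a fully
reproducible, simulation-validated reimplementation of the standard
kymograph → Up/Loop/Down → rate workflow.

Raw imaging data for these experiments are rarely deposited, so every
stage ships with a seeded synthetic-data generator with exact ground
truth: movies with programmable loop events, FP plates drawn from the
exact binding model, and ATPase time courses.  The whole pipeline is
validated by parameter recovery.

## What it computes

**Imaging.** A movie of one 48.5 kbp tether is median-filtered (disc,
radius 2 px) and collapsed into a kymograph by summing an 11-pixel band
around the DNA axis.  Per line, the most intense local maximum is the
loop centre; centres are linked into tracks; each line is split into
Up / Loop / Down with a 9-pixel Loop window, and intensity fractions are
converted to DNA:

    region_kbp = 48.5 * I_region / I_line       (so up + loop + down = 48.5)

The extrusion rate is the OLS slope of `loop_kbp = k t + c` over the
initial 5 s of monotone growth (window located on a Savitzky–Golay
smoothed curve, order 2 / 50-point window; fitted on raw data).  The
fraction of looped DNA is the share of double-tethered molecules with at
least one loop event in a 1000-s acquisition; conditions are compared
with the exact Wilcoxon rank-sum test (fractions) and Welch's t-test
(rates).

**Binding.** FP titrations fit the exact ligand-depletion (quadratic)
model — valid when the probe is not negligible relative to Kd:

    FP = (FPmax / 2[Pep]) * ( ([C]+[Pep]+Kd) - sqrt( ([C]+[Pep]+Kd)^2 - 4 [C][Pep] ) )

over `(Kd, FPmax)` by weighted nonlinear least squares; competition
plates get background subtraction and pairwise t-tests.

**ATPase.** OLS slope over an automatically chosen steady-state window
(robust noise-scaled linearity criterion that skips lag phases), enzyme
normalisation, and DNA fold-stimulation = rate(DNA) / rate(no DNA) with
quadrature error propagation.

## Worked example

```r
library(loopx)

## simulate one tether with a 1.2 kbp/s loop event, then analyse it
cfg <- tether_sim_config(
  n_frames = 45,
  loop_events = list(loop_event(t_start = 5, rate = 1.2, max_loop = 30)),
  seed = 42)
sim <- simulate_tether_movie(cfg)

q <- quantify_tether(sim$series)
q$kymo
#> <kymograph> 126 positions x 45 frames (1s/frame), axis col 14, band 11 px
q$looped
#> [1] TRUE

estimate_loop_rate(q$dna)
#> <rate_estimate> k = 1.126 kbp/s (c = -6.33 kbp, r2 = 0.944, 6 pts in [17, 22] s)

head(q$dna[q$dna$valid, c("frame", "time_s", "up_kbp", "loop_kbp", "down_kbp")], 3)
#>   frame time_s   up_kbp loop_kbp down_kbp
#> 1    17     17 17.77145 13.45814 17.27042
#> 2    18     18 17.43752 13.70368 17.35880
#> 3    19     19 17.71834 14.36406 16.41759
```

The recovered rate (1.126 kbp/s) sits within the single-event scatter
around the programmed 1.2 kbp/s; over many seeded events the median
recovery is within 10% (see the test suite).  The three DNA amounts sum
to 48.5 kbp on every valid frame by construction.

```r
## an FP titration at Kd = 5.9 uM, 100 nM probe, 2 mP noise, 3 replicates
plate <- simulate_fp_plate(kd = 5.9, fp_max = 60, probe_conc = 0.1,
                           receptor_concs = 10^seq(-1, 2, length.out = 12),
                           noise_sd = 2, n_replicates = 3, seed = 1)
fit_kd(plate)
#> <binding_fit> Kd = 4.92 +/- 0.23 uM, FPmax = 58 +/- 1.1 mP
```

A single 3-replicate plate carries real uncertainty (this seed fits
4.9 uM against a true 5.9); the median over 100 seeded plates recovers
the truth to within a few percent.

## Layout

- `R/` — simulators, kymograph builder, tracker/partitioner, rate and
  statistics layer, FP binding, ATPase, pipeline/config.
- `src/` — compiled disc median filter and grayscale morphology.
- `vignettes/loopx-methods.Rmd` — models, defaults, design rationale and
  limitations.
- `tests/testthat/` — unit, property and end-to-end recovery tests.
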