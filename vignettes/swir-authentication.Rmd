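---
title: "Non-targeted authentication of almond powder from simulated SWIR hyperspectral images"
author: "swirauth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-targeted authentication of almond powder from simulated SWIR hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Almond powder is economically adulterated with cheaper nut powders --
typically apricot kernel powder (visually indistinguishable) or peanut
powder (compositionally similar, and a serious allergen). A targeted
classifier can only find adulterants it was trained on; screening instead
asks a *one-class* question: does this sample behave like pure almond
powder? This package implements that screening pipeline for line-scan
shortwave-infrared (SWIR, 900--2494 nm) hyperspectral images of powder
plates: a one-class DD-SIMCA classifier flags non-almond samples, a PLS1
regression quantifies the adulterant percentage, and the regression vector
is applied per pixel to draw concentration maps.

No public hyperspectral data set accompanies this problem, so the package
ships a synthetic-data module as first-class, tested code. Everything
downstream (calibration, segmentation, extraction, preprocessing, both
models, mapping) is exercised end to end against simulated plates whose
ground truth is known exactly.

## What the simulator emulates

**Acquisition geometry.** A pushbroom imager with a fixed spatial width and
a 275-band wavelength axis from 900 to 2494 nm (5.8 nm per band),
`make_wavelength_grid(900, 2494, 275)`. Plates hold 25 circular powder
wells (5 x 5) on a dark background. The constructor default for the image
width is 324 samples, the width of the emulated line-scan camera; the
bundled study configuration uses a compact 118-sample layout with 14-pixel
wells so that a full study (18 plates) stays small -- well spectra are
averages, so the spatial scale only sets how many pixels average into each
spectrum.

**Endmembers.** Each pure powder is a flat reflectance baseline (0.6) minus
Gaussian absorption features at the SWIR band positions known for nut
powders: C--H lipid overtones at 1165, 1395, 1692 and 1734 nm, protein near
1200 nm, and O--H water bands at 1450 and 1940 nm. Amplitudes encode the
compositional ordering reported for these powders: peanut deeper than
almond at 1165/1395 nm (peroxide-rich lipids) and 1200 nm (more protein);
almond deepest at 1734 nm (long-chain fatty acids); apricot's lipid bands
scaled to 0.6 of almond's with stronger water/carbohydrate absorption. The
net effect -- apricot spectrally farther from almond than peanut is --
reproduces the qualitative difficulty ordering of the screening problem.
Absolute amplitudes are not published anywhere; they are qualitative
choices constrained only by this ordering. A second almond variety is a
+/-4% multiplicative perturbation of all feature amplitudes
(`variety_shift`), standing in for a different geographical origin.

**Mixtures and noise.** Binary blends mix linearly in mass fraction
(`mix_spectra`); no non-linear mixing or particle-size physics is modeled.
Per-pixel corruption applies a multiplicative scatter slope
(`b ~ N(1, 0.02)`), an additive offset (`N(0, 0.005)`), a linear baseline
tilt across the band axis (`N(0, 0.005)`) and iid sensor noise
(`N(0, 0.01)` reflectance units per band). The additive 1% sensor noise is
the dominant term at the pixel level; averaging ~75 pixels per well half
brings it to ~0.1% on extracted spectra, which is what makes 5%
adulteration a borderline case, as it is in practice. Radiance is simulated
with a white reference at 0.9 of full scale and dark current at 0.05, so
reflectance calibration `(raw - dark) / (white - dark)` inverts the
construction exactly rather than trivially.

All randomness flows from one integer seed; per-well child seeds are
derived deterministically, so identical designs produce bit-identical
cubes.

**What the simulator does not capture.** Real powder spectra have
correlated within-well heterogeneity (packing density, particle size),
wavelength-dependent detector noise, stray specular highlights and
instrument drift. Passing tests here demonstrate that the *algorithms* are
correct and statistically calibrated under the stated model; they do not
certify performance figures on real instrument data.

## Image processing

Calibration divides out the references per band and refuses bands where
white equals dark (a dead reference). Background removal formalizes the
"average of background and powder pixels" rule: 2-means on the
mean-over-bands intensity image, threshold at the midpoint of the two
cluster means, with foreground specks under 10 px dropped. The analysis
band window is 935--1965 nm (177 of 275 bands on the default grid).
Reflectance is never clipped; values above 1 are kept as-is.

Each well is split at its centroid column into two halves (the centroid
column itself goes to the left half) and each half is averaged to one
spectrum -- two spectra per well, mirroring the two-halves extraction
scheme that yields 100 calibration spectra from two pure plates (2
varieties x 25 wells x 2 halves). Well centers sit on half-integer pixel
coordinates (the center of a block of `pitch` pixels), so the disks are
column-symmetric and the two halves are equal-sized; unequal halves would
give the two spectra per well systematically different noise levels.

## Pretreatments

Seven standard chemometric operators, each a pure row-wise transform
(`preprocess_spec`): mean/max/range normalization, SNV, MSC,
Savitzky-Golay smoothing and first/second derivatives, plus `raw`. Only
MSC is stateful -- its reference is the mean calibration spectrum, learned
by `fit_preprocess` on calibration data only, so validation statistics
never leak into the transform. SG filters (default window 11, polynomial
order 2; about 64 nm at this resolution) are applied only where the full
window fits: the band axis shrinks by `window - 1` and the wavelength axis
is updated, avoiding fabricated edge values. Derivatives are per band
index, not per nm -- on a uniform grid the difference is a constant factor
that downstream models absorb. Degenerate rows (constant under SNV, zero
maximum, vanishing MSC slope below 1e-8) are errors, except in per-pixel
mapping where they become missing pixels.

## DD-SIMCA

The target class (pure almond, both varieties pooled) is modeled by an
`A`-component PCA of the centered, pretreated spectra. Each sample gets

* a score distance `h` (leverage): squared scores normalized by the
  per-component eigenvalues `s_a^2 / (n - 1)`,
* an orthogonal distance `v`: squared residual norm outside the subspace.

Both are treated as scaled chi-square variables. The degrees of freedom are
estimated from the data by moments -- `N = round(2 * mean(d)^2 / var(d))`,
clipped to [1, 250], since a scaled chi-square with `N` degrees of freedom
has `2 mean^2 / var = N` at any scale. The total distance
`c = Nh * h / h0 + Nv * v / v0` is approximately chi-square with
`Nh + Nv` degrees of freedom; the acceptance boundary is its `1 - alpha`
quantile (alpha = 0.01) and the outlier boundary uses the order-statistic
correction `(1 - gamma)^(1/n)`, so a clean training set of size `n`
produces an outlier call with probability about `gamma`. Both boundaries
are inclusive (`c <= cutoff` is inside). On well-specified Gaussian data
the fresh-sample rejection rate matches `alpha` to within a percentage
point (this is tested by Monte Carlo).

**Factor selection.** `ddsimca_select_factors` fits `A = 1..A_max` and
returns the `A` whose observed count of extreme training samples at level
`alpha` is closest to the expected `alpha * n`, ties toward smaller `A`.
The bundled study caps `A_max` at 5: the pooled pure-almond class has only
about two structured variation sources (variety, residual tilt), and
letting the rule scan far beyond that lets it chase single chance extremes
at large `A`, where the shrinking training residual (`v0`) is an
optimistic estimate of fresh-sample residuals and pure validation samples
start being rejected.

**Pretreatment for the classifier.** The source study does not state which
pretreatment fed its one-class model; this package defaults to SNV, the
standard scatter correction for powder NIR one-class modeling, and exposes
the choice in the configuration. An 11-point second derivative -- the best
*regression* pretreatment -- is a poor default here because the simulator's
absorption features are wide (30--65 nm), so differentiation suppresses
most of the adulterant signal while passing sensor noise.

## PLS1 and mapping

`pls1_fit` is a sequential NIPALS PLS1 on centered data (no band scaling,
the spectroscopy convention), collapsed to one affine map
`y = intercept + x . beta`; at full rank it reproduces the least-squares
solution to numerical precision (tested against a normal-equations
oracle). The factor count is chosen by leave-one-out cross-validation:
`RMSECV(A) = sqrt(mean((y_i - yhat_{-i})^2))`, minimized with ties toward
fewer factors. SEC and SEP are root-mean-square errors on the calibration
and prediction sets; validation R-squared is computed about the validation
set's own mean.

`map_concentration` applies the model's pretreatment and beta vector to
every foreground pixel: `value = C + sum_i I_i R_i` with the regression
intercept as the constant `C` (the natural reading of that constant).
Stored values are unclipped; rendering clips to the display scale (0--50%)
on a blue-to-red ramp with black background, deterministically.

## The bundled study

`default_study_config()` mirrors the published study design at desk scale:

* one-class calibration: 2 pure plates (one per variety) -> 100 spectra;
* one-class validation: apricot and peanut at 0--50% in 5% steps
  (variety 1, 110 spectra) and 0/7/15/22/30% (variety 2, 50 spectra);
* regression: calibration 66 spectra (6 per concentration), two
  validations of 44 each -- the second-variety set uses 8 spectra per
  concentration plus 4 extra pure spectra, which reproduces the published
  design mean of 13.45%;
* external blind sets: 0/7/15/22/30/40/45/50% x 10 spectra for both
  adulterants, rendered with the scatter-slope SD doubled to emulate a
  re-imaged session with different illumination.

`run_study` executes simulate -> calibrate -> segment -> crop -> extract ->
preprocess -> classify/regress -> map and returns a report with a
classification-metrics table, the pretreatment x adulterant regression
grid, design summaries and per-well map statistics; with an output
directory it also writes models (YAML), decision CSVs, the map PNG and the
report JSON. Runs are byte-reproducible for a fixed seed. A full run
(about 18 simulated plates) takes tens of seconds on one core.

Models persist as single self-describing YAML files (matrices inlined):
the largest basis here is 177 x A, where plain text is simpler and
diffable.

## Numerical choices and limitations

* Classical (non-robust) moment estimators for `h0`, `v0`, `Nh`, `Nv`;
  robust or rigorous DD-SIMCA variants are out of scope.
* Degrees of freedom are rounded to the nearest integer in [1, 250];
  constant distance vectors hit the cap with a warning.
* Ties: factor selection (both models) breaks toward fewer factors;
  the centroid column goes to the left well half.
* Percentages are reported rounded half away from zero to one decimal
  (so 95.45 reports as 95.5); design summaries to two decimals.
* `calibrate_reflectance` is invariant to any common per-band gain on
  raw/dark/white, and acceptance decisions are invariant to a common
  orthogonal rotation of the spectra; both are tested properties.
* The simulator's linear mixing and iid pixel noise are idealizations;
  conclusions about absolute detection limits on real instruments should
  not be drawn from the synthetic study.
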