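---
title: "Methods and design notes for kiwispec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for kiwispec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kiwispec)
```

`kiwispec` implements a visible/near-infrared hyperspectral
chemometrics pipeline for fruit quality: reflectance calibration, SNV
preprocessing, SPXY partitioning, CARS/SPA wavelength selection,
PLSR/MLR calibration, RPD evaluation and pixel-wise quality mapping.
This vignette records the model assumptions, the parameters that
matter, and the design decisions taken where the method literature
leaves choices open. It states no empirical result that the package's
tests do not themselves compute.

## The wavelength grid

All spectra share one strictly increasing axis of 256 band centres over
390–1030 nm. The emulated instrument samples at a slightly irregular
~2.5 nm pitch and its full band table is not public, but the feature
wavelengths reported for the five quality indices are. Two facts rule
out a uniform axis: 404 nm lies 1.06 nm from the nearest point of
`seq(390, 1030, length.out = 256)`, and 595/597 nm would collapse onto
a single uniform band. The default grid therefore passes exactly
through all 121 distinct published band centres (plus the endpoints),
with the remaining 133 points interpolated into the gaps in proportion
to gap width. Published wavelengths consequently resolve with zero
error and injectively; `nearest_band()` enforces a 1 nm matching
tolerance when binding published coefficients.

## Reflectance calibration and ROI

Raw counts become relative reflectance per pixel and band,
$R = (R_{raw} - R_{dark}) / (R_{white} - R_{dark})$. The correction is
scale-free (multiplying all three frames by any $c > 0$ changes
nothing), which the tests assert. Values are deliberately *not* clipped
to $[0, 1]$; pixels whose white–dark dynamic range does not exceed
`epsilon` (default $10^{-6}$ counts) are removed from the mask instead,
so dead sensor pixels never contaminate downstream statistics.

The fruit ROI is segmented by thresholding the band nearest 800 nm
(default threshold 0.15 reflectance) and keeping the largest connected
component (via `EBImage::bwlabel()`). 800 nm sits where fruit tissue is
bright and the dark background is not; both parameters are exposed
because the delineation rule is a package choice — the source protocol
only states that the whole fruit was used as ROI.

## SNV convention

SNV transforms each spectrum to $(x - \bar x)/s_x$. The package fixes
$s_x$ to the **population** standard deviation (divide by the number of
bands, not bands−1). The convention is load-bearing: MLR coefficients
multiply SNV values, so a different denominator rescales every
predictor by $\sqrt{B/(B-1)}$ and silently biases predictions from
stored coefficients. The method literature rarely states which form was
used; population sd was chosen and is applied identically in fitting,
prediction and mapping, so the package is internally consistent.
Predictions from the *published* coefficient fixtures carry the
remaining convention uncertainty and are documented as demonstrative.

A second hard rule: SNV is applied to the **full 256-band spectrum
before any wavelength subsetting**, everywhere (selection, fitting,
mapping). Subsetting first changes each sample's mean and sd and puts
predictors on the wrong scale; a regression test asserts that the two
orders genuinely differ. Spectra tables carry a preprocessing tag and
`predict()` refuses tables whose tag does not match the model's.

## SPXY partitioning

Calibration/prediction splitting uses Kennard–Stone max–min selection
on the joint distance
$d(i,j) = d_x(i,j)/\max d_x + d_y(i,j)/\max d_y$ with Euclidean $d_x$
on SNV spectra and Euclidean $d_y$ on autoscaled reference values. Three
open choices were fixed as follows:

* **Joint y over all five indices** (autoscaled per index), because one
  split serves all five calibrations in the emulated study design.
* **SNV spectra for $d_x$**, matching the representation the models are
  fitted on.
* **Ties break to the lowest original sample index**, making the split
  reproducible and invariant to sample order (tested against a
  brute-force oracle on 8 samples).

The default design is 200 samples split 140/60.

## CARS

Each of 50 Monte Carlo sampling runs draws 80 % of calibration samples,
fits a PLSR on the currently retained wavelengths (latent variables by
5-fold RMSECV, capped at 10), ranks wavelengths by $|b|$, and shrinks
the retained set to the exponentially decreasing schedule
$r_i = a e^{-k i}$ with $r_1 = 1$ and $r_N = 2/B$
($k = \ln(B/2)/(N-1)$). The run with minimal 5-fold RMSECV on the full
calibration set wins.

The adaptive reweighted sampling step is implemented as a **weighted
draw without replacement** realising exactly the scheduled count, with
probability proportional to $|b|$. The more common textbook phrasing —
draw with replacement, keep unique — shrinks the retained set by at
least a further ~37 % per run on top of the schedule, which collapses
256 bands below 2 within about a dozen runs and cannot produce 50-run
trajectories; the published selected-set sizes also equal the scheduled
counts at the reported argmin runs exactly, which is only possible if
the realised sets are full-sized. The without-replacement draw keeps
the competitive character (weak coefficients rarely survive) while
following the schedule.

`max_select` optionally restricts the argmin to runs whose set fits a
subsequent MLR ($m \le n_{cal} - 2$); the pipeline sets it
automatically. CARS is deterministic given (data, seed); the seed is a
required argument. Because the Monte Carlo draws consume the RNG in
band order, band-permutation invariance holds for CARS only in
distribution, not draw-for-draw (SPA, being deterministic, is tested
for exact permutation invariance).

## SPA

Phase 1 builds, from every candidate start wavelength, a chain that
repeatedly adds the band of maximal residual norm after orthogonal
projection onto the span of the bands already chosen (so collinear
duplicates are eliminated). Phase 2 scores every (start, size) pair by
5-fold cross-validated MLR RMSE on the calibration set — the separate
validation protocol of the source study is unstated, so in-set
cross-validation was chosen as the least-assumption default. The
returned size is the smallest on the RMSE plateau: growth stops when
the relative improvement of the best achievable RMSE falls below 1 %
(or the RMSE is numerically zero). A brute-force start/size enumeration
on a 5-band, 12-sample instance is part of the permanent test suite.

## PLSR and MLR

PLSR is single-response NIPALS with y-deflation, written in-package
because the wavelength selector needs the raw coefficient vector $b$ at
every Monte Carlo run. The latent-variable count is the argmin of
k-fold RMSECV over 1..15 (capped at the design rank); fold assignment
is deterministic round-robin in row order, so no seed is needed. With
all components retained on a full-rank design, PLSR reproduces the OLS
fit — that oracle equivalence is tested rather than assumed. MLR is
ordinary least squares via QR with an explicit rank check that names
the collinear wavelengths. X gets no autoscaling beyond SNV (SNV
already row-standardises) and y stays in physical units, so fitted
coefficients are directly comparable with the packaged published
equations, which predict physical units from SNV values. Published
coefficients are stored to their printed decimal precision only.

## Evaluation

$R^2$ on each set is $1 - SS_{res}/SS_{tot}$ around that set's own
mean; RMSEC/RMSEP are root mean squares over the respective sets;
RPD = SD/RMSEP with SD the **sample** (n−1) standard deviation of the
prediction-set reference values — the mean ± SD convention of the
emulated study's tables, and the form that reproduces its printed RPDs
from printed SD/RMSEP pairs at two decimals for firmness, L\*, a\* and
b\* (the SSC pair recomputes to 3.10 against a printed 3.09, evidently
rounded from an unrounded SD, and is excluded from the exact-rounding
test). Report tables round half-up to two decimals for display; raw
doubles are kept internally. Qualitative bands: below-poor (< 1.4),
poor [1.4, 1.8), good [1.8, 2.0), excellent (≥ 2.0).

## Pixel mapping

`predict_map()` applies SNV to each masked pixel's full spectrum and
evaluates the model's linear form; constant-spectrum pixels (SNV
undefined) are dropped from the mask and counted. Note that the mean of
a prediction map over the mask is *not* the prediction of the mean
spectrum — SNV is nonlinear — and a regression test documents the
discrepancy instead of assuming equality. Rendering maps values
linearly onto a perceptually uniform colormap (default viridis) over a
display range whose default is the pooled 2.5th–97.5th percentile of
all maps in a batch, shared across maturity stages so colours stay
comparable between images; out-of-range values clip to the endpoints
and background renders neutral grey. Whether the emulated study scaled
colours per image or across stages is unstated; the shared scale is
this package's choice because it is what makes cross-stage trends
readable.

## The synthetic generator

The generator emulates the study conditions: four maturity stages of 50
fruit (200 samples), stage SSC ranges 4.63–5.73, 5.90–7.30, 6.50–9.20
and 9.20–12.20 °Brix, and 256-band spectra with absorption features
near 675 nm (chlorophyll, Gaussian sd 25 nm), 980 nm (water, sd 45 nm)
and a broad sugar-associated band near 910 nm (sd 60 nm). Per sample, a
maturity score drawn from the stage's SSC range drives three latent
concentrations (sugar-tracking, chlorophyll decreasing with maturity,
water mildly increasing); spectra are
`gain × (baseline + Σ ampₖ concₖ endmemberₖ) + offset + noise` with
negative amplitudes so features appear as reflectance dips, and the
reference indices are affine in the same concentrations plus
measurement noise. Consequences used by the tests: stage-mean SSC
increases and firmness decreases by construction; the scatter model is
exactly the class SNV removes; the noiseless limit lies in the span of
baseline and endmembers; and the informative-band ground truth (bands
where any endmember exceeds half its own maximum) gives selection
recovery tests an unambiguous target.

Choices not dictated by the emulated study: the baseline is a smooth
low-order polynomial in [0.25, 0.70] reflectance (the general shape of
fruit reflectance without digitising any figure); spectral noise is
additive, homoscedastic Gaussian (sd 0.002 reflectance), the simplest
model consistent with SNV's assumptions; per-stage couplings for
firmness and colour are calibrated so pooled values land near the
published min–max spans (firmness ≈ 12–24 kg·cm⁻², L\* ≈ 37–46), since
per-stage distributions for those indices are not printed anywhere —
they are a modelling choice, not a claim about fruit. Measurement-noise
sds (0.10 °Brix, 0.40 kg·cm⁻², 1.0/0.6/1.0 colour units) reflect
typical refractometer/penetrometer/colorimeter repeatability.

What the generator does **not** emulate: radiative transfer or tissue
optics, spatial texture within a fruit, instrument smile/keystone, or
the actual covariance structure of real kiwifruit spectra. Passing
tests therefore demonstrate that the algorithms are implemented
correctly and recover planted structure — not that the published
accuracies would be reproduced on real fruit, whose raw data are not
deposited.

## Problem sizes and numerical choices

The test suite runs the full emulated design where it matters (CARS on
140 × 256 calibration data, 50 runs × 5 folds) and toy scales
elsewhere; the end-to-end pipeline test uses 4 × 6 samples, chosen so
the whole suite stays interactive. Other numerics: SNV rejects spectra
with zero standard deviation rather than returning NaN; SPA treats
projected norms below 1e−10 as exhausted; the SPA plateau comparison
uses 1e−10 as "numerically zero"; CARS marks non-finite RMSECV runs
invalid and excludes them from the argmin; ENVI output writes float64
so write/read round trips are exact; and all display rounding is
half-up, matching how the comparison tables it imitates were rounded.

## Known limitations

* The published coefficient fixtures inherit an unknowable SNV
  denominator convention from their source; predictions made with them
  are demonstrations of mechanics.
* CARS selection quality on synthetic data should not be read as a
  statement about real fruit spectra (see the generator's non-goals).
* `spxy_split()` materialises the full pairwise distance matrix
  (O(N²) memory), fine for hundreds of samples, not for tens of
  thousands.
* Only SNV preprocessing is provided; MSC, derivatives and smoothing
  are out of scope because the final models of the emulated workflow do
  not use them.
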