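---
title: "Measuring personal circadian light exposure with wearable sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring personal circadian light exposure with wearable sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cswear)
```

## The measurement problem

Light drives the human circadian system mainly through melanopsin-
expressing retinal ganglion cells, with contributions from cones and
rods.  Photopic lux — the quantity ordinary light meters report — is a
poor proxy for this drive, because the circadian system weights the
spectrum very differently from the luminous efficiency function.
Wearable light loggers make continuous personal exposure measurement
possible, but they report a handful of raw quantities (an uncalibrated
illuminance, an uncalibrated correlated color temperature, and four
channel irradiances at 465, 525, 615 and 1100 nm), none of which is a
circadian quantity.

`cswear` implements the full chain from spectra to deployment
analytics:

1. **Spectral core** — circadian light (CL_A) and circadian stimulus
   (CS) from a spectral power distribution (SPD), plus photopic
   illuminance and CCT;
2. **Scene and sensor simulators** — synthetic laboratory and field
   lighting campaigns with a configurable sensor distortion model,
   standing in for the original spectrophotometer/logger data
   collection;
3. **Calibration** — no-intercept linear corrections of the logger's
   raw lux and raw CCT against ground truth, with significance-based
   feature selection and 70/30 evaluation;
4. **CS prediction** — linear and random-forest regression of CS on
   the six raw sensor features, with 5-fold cross-validation and dual
   feature importance;
5. **Exposure analytics** — day/night segmentation, weekly summaries,
   paired t tests, post hoc power, nonwear detection and dim-light CCT
   masking.

## The circadian model

For an SPD $E_\lambda$ (W m$^{-2}$ nm$^{-1}$) on the canonical
380–780 nm, 5 nm grid, define the rectangle-rule integrals
$\int f_\lambda E_\lambda\,d\lambda = \sum f_\lambda E_\lambda \Delta\lambda$
with $\Delta\lambda = 5$ nm.  With the observer functions $Mc$
(lens-corrected melanopsin), $S$ (S-cone fundamental), $mp$ (macular
pigment transmittance), $V$ and $V'$ (photopic and scotopic luminous
efficiency), the blue-versus-yellow opponent signal is

$$b\!-\!y = \int \frac{S_\lambda}{mp_\lambda} E_\lambda d\lambda
          - k \int \frac{V_\lambda}{mp_\lambda} E_\lambda d\lambda,
  \qquad k = 0.2616 .$$

Circadian light is

$$\mathrm{CL_A} = 1548 \left[\int Mc_\lambda E_\lambda d\lambda
  + a_{b\text{-}y}(b\!-\!y)
  - a_{rod}\left(1 - e^{-\int V'_\lambda E_\lambda d\lambda / \mathrm{RodSat}}\right)\right]$$

when $b\!-\!y > 0$ (blue-rich light engages the opponent and rod
terms), and $\mathrm{CL_A} = 1548 \int Mc_\lambda E_\lambda d\lambda$
otherwise, with $a_{b\text{-}y} = 0.7$, $a_{rod} = 3.3$,
$\mathrm{RodSat} = 6.5$ W m$^{-2}$.  Circadian stimulus — the model's
estimate of fractional nocturnal melatonin suppression — is the
saturating transform

$$\mathrm{CS} = 0.7\left[1 - \frac{1}{1 + (\mathrm{CL_A}/355.7)^{1.1026}}\right],$$

zero in darkness, 0.35 at CL_A = 355.7, and bounded by 0.7.

Two numerical properties deserve explicit treatment rather than
silence:

* **The branch discontinuity.** The two branches of CL_A do not agree
  at $b\!-\!y = 0$: the positive branch carries the rod subtraction,
  so crossing the boundary jumps by
  $1548\,a_{rod}(1 - e^{-\int V'E/\mathrm{RodSat}})$.  `cla()` reports
  the branch taken and the three underlying integrals so analyses (and
  the test suite) can characterize the discontinuity instead of hiding
  it.
* **Negative circadian light.** For dim, blue-depleted spectra the rod
  term can exceed the melanopsin and opponent terms.  CS is undefined
  for negative CL_A, so the result is clamped at zero and flagged
  (`clamped = TRUE`).

```{r cs-curve}
cla_grid <- 10^seq(0, 5, length.out = 200)
plot(cla_grid, cs(cla_grid), log = "x", type = "l",
     xlab = expression(CL[A]), ylab = "CS")
abline(h = 0.7, lty = 3); abline(v = 355.7, lty = 3)
```

## Observer tables

The model's five weighting functions and the CIE 1931 color-matching
functions are shipped as a checksummed CSV on the shared 5 nm grid.
They are generated from published analytic forms — multi-Gaussian fits
for the color-matching functions and the A1 visual-pigment nomogram
for the photopigments — combined with smooth synthetic lens and
macular-pigment transmittance curves (see
`inst/extdata/observer_tables_PROVENANCE.md`).  They are deliberate,
documented stand-ins for the original laboratory tabulations, which
are not redistributable here.  Consequences: every structural property
of the model (band positions, branch behavior, monotonicity,
normalizations) holds, all internal cross-checks are exact, but
absolute CL_A/CS values differ somewhat from implementations built on
the original tables.  Every quantitative claim in this package is
therefore checked against oracles computed from the *same* tables,
never against externally printed CL_A values.

## CCT by Planckian-locus search

CCT is computed as the nearest point on the Planckian locus in the CIE
1960 uv plane, searched over 1000–20000 K with a 10 K table and 1 K
local refinement, rather than with a chromaticity polynomial: the
scenes of interest span 1500–10500 K, beyond the range where the usual
polynomial approximations hold.  Chromaticities further than
Duv = 0.05 from the locus are flagged `out_of_gamut`; zero visible
energy raises a typed condition.

## The scene simulator

The simulator emulates two measurement campaigns:

* **Laboratory protocol** (`lab_protocol()`): 100 scenarios read 5
  times each.  Electric sources are modeled on the four stated CCTs
  (1500, 3000, 4200, 6500 K); target illuminance is drawn from a
  bimodal distribution with density modes near 100 lux (dim electric
  interiors) and 1500 lux (daylight-accessible spaces), spanning
  10–10,000 lux; window daylight with sky CCT 5000–8000 K can
  contribute in any scene.  Two scenarios pin the campaign's coverage
  extremes (a pure 1500 K source at 10 lux and pure high-CCT daylight
  at 10,000 lux), so the generated set always spans the stated lux and
  CCT ranges.
* **Field protocol** (`field_protocol()`): warm sources (1800, 2700,
  4000 K), the full grid of blind slat angles
  (retracted/45°/90°/135°), window distances 0–9 ft and view angles
  0–270°, with a warm-dominant CCT distribution and a daylight-driven
  high tail.

Design choices worth stating:

* **Electric sources are Planckian in the visible band only.**
  Beyond 780 nm their emission rolls off smoothly
  (`electric_spd()`), because indoor luminaires emit very little at
  1100 nm while daylight carries a strong near-IR component — the
  physical fact that makes the IR channel a daylight signature.  A
  full-band 1500 K Planckian would out-radiate daylight at 1100 nm
  and invert that physics.  `planckian_spd()` remains the exact
  Planck law for tests and for CCT ground truth.
* **Daylight** is reconstructed as $S_0 + M_1 S_1 + M_2 S_2$ over
  three smooth Planckian basis curves, with $M_1, M_2$ solved so the
  chromaticity lands exactly on the CIE daylight locus at the
  requested CCT under the bundled color-matching functions.  The
  basis is analytic over the whole 360–1200 nm grid, so the IR
  channel needs no spliced extension.  Tiny negative excursions of
  the solved combination outside the visible band are clipped.
* **Attenuation constants** (blind factors 1.0/0.6/0.3/0.15,
  inverse-square-with-floor distance falloff, cosine view factor) are
  invented engineering numbers; only their monotonicity is
  load-bearing, and they are configurable.

## The sensor model

Channel responsivities are peak-normalized Gaussians (FWHM 50 nm
visible, 100 nm IR) at the logger's stated centers; the logger's
printed channel labels are physically inverted (its "R" is the 465 nm
channel), so the implementation keys on wavelength and maps labels
only at I/O.  The distortion model derives raw lux and raw CCT as an
invertible linear mixture of true lux, true CCT and the IR channel,
adds multiplicative-plus-floor Gaussian noise, and clamps to the
instrument ranges (0.1–100,000 lux, 1800–10,000 K), flagging clamped
readings.  The mixture is parameterized by its inverse, so the optimal
linear correction has exactly the published no-intercept form
(features CCT′, IR, lux′); the IR coefficients are expressed in this
simulator's radiometric channel units.  With zero noise the
calibration therefore recovers the generating coefficients to
floating-point accuracy — an exact end-to-end identity used by the
test suite.

Default noise levels (lux CV 10%, CCT CV 3%, channel CV 3%, small
additive floors) reflect a wearable logger that is noticeably worse at
illuminance than at color measurement.  These defaults are the study
conditions for every downstream result; they were fixed once and are
not tuned per analysis.

## Calibration and CS prediction

`fit_calibration()` screens physically invalid rows (negative light
quantities; optionally range-clamped readings, which carry no
calibration information), splits 70/30 by seed, selects features by
coefficient significance at $\alpha = 0.05$ in the full no-intercept
least-squares model (collinear candidates resolved in a fixed
canonical order), and refits.  Metrics are MAE, MSE/RMSE, $R^2$ and
Wherry adjusted $R^2$; a refit-on-all-data variant reproduces
"overall" figures.  Two identifiability caveats are documented rather
than hidden:

* With all six candidates offered, the visible channels are strong
  surrogates of illuminance, so under measurement noise the
  no-intercept fit can legitimately spread weight across them;
  parameter-recovery claims are therefore stated with respect to the
  generating feature set.
* Noise on the *regressors* (errors-in-variables) biases least-squares
  coefficients; exact recovery statements apply to noise on the
  reference side.

`fit_cs_model()` predicts CS from the six raw sensor features by
linear regression or a random forest (500 trees, node size 2 —
ordinary defaults for the importance metrics reported), with seeded
5-fold cross-validation (`cross_validate()`; the k-fold mean is the
arithmetic mean over folds).  `feature_importance()` reports %IncMSE —
computed by this package as the percent increase in held-out MSE over
10 seeded permutations of one feature — and IncNodePurity, the total
variance-impurity decrease attributed to the feature by the fitted
forest.

On the default laboratory campaign the forest's cross-validated $R^2$
exceeds the linear model's by a wide margin: CS is a saturating
function of illuminance and spectrum that a linear map cannot
represent.  One published structural claim does **not** reproduce
under this simulator: the IR channel does not rank first on either
importance metric.  The reason is informational, not a bug: CS is a
functional of the visible spectrum, so any pair of clean visible-band
features (e.g. the 525 nm channel plus the 465 nm channel, or raw lux
plus raw CCT) pins it down, leaving IR redundant whenever the
simulated channels are comparably accurate radiometric measurements.
An IR-first ranking evidently requires device-specific degradation of
the visible outputs (saturation, quantization, auto-gain) that is not
publicly specified and is deliberately not invented here; the
corresponding test asserts the published ordering and is expected to
fail under this simulator, with this explanation.

## Exposure analytics

* **Day window**: daytime defaults to 06:00–18:00 local clock —
  a fixed window is the only reproducible choice without site and
  date information; it is configurable everywhere.
* **Nonwear** (`detect_nonwear()`): a stretch is flagged when the lux
  rolling range stays below 1 lux *and* no motion events occur for
  longer than 2 h (if the stretch touches daytime) or 4 h (entirely
  nighttime).  The flagged set is the union of all qualifying windows;
  an $O(n^2)$ sliding-window oracle in the test suite checks the
  production two-pointer scan on randomized logs.
* **Dim-light CCT masking** (`mask_dim_cct()`): spectral color
  estimates are unreliable in dim light, so CCT is masked for all
  nighttime records and for records below a 10 lux floor; the blanket
  nighttime exclusion is preserved as the default behavior, the lux
  floor generalizes it.
* **Weekly summaries**: sample mean and unbiased variance per 7-day
  block (aligned to the series start) × day/night × metric, wear-time
  records only; empty cells are reported with `n = 0` rather than
  dropped.
* **Paired t** and **post hoc power**: the paired t statistic follows
  the textbook definition (all-zero differences return t = 0, p = 1;
  constant nonzero differences are a degenerate error).  Power uses
  the noncentral t with noncentrality $d\sqrt{n}$, df $n-1$; the
  one-tailed variant reproduces the published 87% figure for n = 29,
  d = 0.53, $\alpha = .05$, which fixes one-tailed as the default.
  No multiple-comparison adjustment is applied, matching the unadjusted
  reporting the analytics mirror.

```{r power}
post_hoc_power(n = 29, d = 0.53, alpha = 0.05, tails = 1)
```

## Problem sizes, tolerances, determinism

The shipped tests and the acceptance script use the campaign sizes the
protocols define (100 scenarios × 5 readings; multi-day logs at 5–30
minute cadence) and smaller seeded subsets where a property does not
need the full campaign.  All randomness flows through explicit seeds
(`with_seed` gives each stage a private RNG stream, so stages are
independently reproducible); `run_pipeline()` derives per-stage seeds
from one top-level seed and writes a checksum manifest, and running the
same configuration twice yields identical manifests.  Spectral
cross-checks are asserted at 1e-9 relative (same-rule oracles), CCT at
±2 K against a dense locus scan, colorimetric round-trips at the
tolerances the daylight-locus construction supports (±100 K), and
statistical properties at the sample sizes stated in the tests.

## What the simulator does and does not show

Passing tests demonstrate that the computational chain is internally
correct: the spectral model matches independent evaluations of its
formulas, calibrations invert the simulated sensor exactly, the
forest/linear comparison and the analytics behave as designed.  They
do not validate the physics of any real logger: real channel
responsivities, gain behavior, optical placement effects and real sky
spectra are all outside the simulator, and the observer tables are
analytic stand-ins.  Conclusions about a particular device require the
original paired spectrophotometer/logger data — the
`refit_reference()` entry point accepts such a dataset in the
package's paired-readings schema and recomputes all published metrics
from it.
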