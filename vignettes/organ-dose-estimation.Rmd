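---
title: "Estimating CT organ doses from TLD readings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating CT organ doses from TLD readings: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdose)
```

## The measurement problem

Console dose indices (CTDI~vol~, DLP) describe how a CT scanner was
operated, not how much energy a patient's organs absorbed. A direct way to
get organ doses is to load an anthropomorphic phantom with small
thermoluminescent dosimeter (TLD) chips, scan it with the clinical
protocol, and read the chips out. `ctdose` implements that estimation chain
for chest CT on two phantom layouts — an adult thorax with 40 TLD triplets
in the lung slices and a pediatric (5-year-old) phantom with 32 lung and 4
thyroid triplets — plus the comparison statistics used to set measured
doses against protocol parameters and externally simulated reference doses.

## The estimation model

Each chip yields a "TL value", the numeric integral of its glow curve,
proportional to absorbed dose. Four steps turn raw TL values into a
whole-organ dose:

1. **Calibration.** A straight line $K_{air} = a \cdot TL + b$ per beam
   quality, fitted by (weighted) least squares to exposures at known air
   kerma (`fit_calibration()`). The control group's mean TL is subtracted
   from every exposed chip first (`subtract_background()`).
2. **Slice air kerma.** Chips are physically grouped in co-located
   triplets; the groups of slice $i$ are combined by the inverse-variance
   weighted mean
   $$K_i = \frac{\sum_n K_n/\sigma_n^2}{\sum_n 1/\sigma_n^2},$$
   where $K_n$ and $\sigma_n^2$ are the mean and unbiased sample variance
   of the chip kermas of group $n$ (`group_stats()`,
   `slice_weighted_kerma()`). Purely statistical scatter is assumed: each
   group sees the full beam, so no partial-volume weighting is needed.
3. **Slice dose.** $D_i = K_i \cdot
   (\mu_{en}/\rho)_{organ} / (\mu_{en}/\rho)_{air}$ with tabulated
   mass-energy absorption coefficients keyed on the tube-voltage label
   (120 or 80 kV); no effective-energy interpolation (`slice_dose()`).
4. **Organ dose.** $D = \sum_i f_i D_i$ with the organ mass fractions
   $f_i$ of the phantom layout, which sum to one (`organ_dose()`).

`run_pipeline()` composes the four steps and logs stage-by-stage
intermediates.

## The uncertainty budget (k = 1)

The original uncertainty appendix for this methodology is not publicly
specified, so the budget implemented here is declared explicitly; it is
first-order Gaussian propagation, reported at one standard deviation:

* **Calibration parameters.** Slope/intercept variances and covariance
  from the standard linear-regression covariance matrix, attached at slice
  level as a *systematic* term evaluated at the slice's mean TL (the same
  curve converts every chip, so this error does not average down within a
  slice).
* **Group scatter.** The sample variance of each triplet's kermas drives
  the inverse-variance weights above. A group of identical or single chips has zero
  sample variance, which would give it infinite weight; such variances are
  replaced by a floor of $(0.01 \cdot \bar K)^2$ — 1% of the group mean,
  a typical LiF:Mg,Ti batch reproducibility. The floor fraction is a
  visible argument (`floor_frac`).
* **Weight-estimation noise.** With three chips per group the sample
  variances have only two degrees of freedom, which makes the textbook
  internal variance $1/\sum 1/\sigma_n^2$ anti-conservative: simulated
  coverage of a $\pm 2\sigma$ interval was about 89% instead of 95%. The
  pipeline therefore takes, per slice, the larger of the internal variance
  and a delete-one-group jackknife variance of the weighted mean. The
  jackknife captures the extra scatter injected by noisy weights; on 200
  simulated replicates of the adult standard scenario the 2-sigma coverage
  is then 0.97 and the propagated sigma agrees with the empirical SD
  within 10%. `slice_weighted_kerma()` itself still returns the plain
  internal variance, so the textbook formula remains available unchanged.
* **Fraction weighting.** $\sigma_D^2 = \sum_i f_i^2 \sigma_{D_i}^2$,
  treating slices as independent. The calibration systematic is, strictly,
  correlated across slices too; folding that correlation through the
  fraction weights is a known simplification here and makes the reported
  sigma slightly conservative relative to a full covariance treatment.

Internal math is full precision; report writers round doses to 2 decimals
and percentages to 1 decimal, matching the precision conventions of the
published tables the fixtures transcribe.

## Protocol metrics and comparison statistics

`tube_mAs()` is current × rotation time for fixed-current protocols;
modulated (TCM) protocols have no single mAs and raise an error instead of
guessing. `effective_mAs()` uses the standard helical definition
mAs/pitch; this convention reproduces the published dose/mAs~eff~ values
from the printed doses and acquisition parameters, which is how it was
validated. Two published pediatric tables print mAs as the display-rounded
products (55 and 146 for 121 mA and 323 mA × 0.45 s); `dose_per_mAs()`
accepts an `mAs_override` so both the full-precision and display
conventions are available.

`percent_decrease()` is $(ref - new)/ref \times 100$ (positive = dose
saving); `percent_difference()` against a simulated reference is
$(D_{sim} - D_{exp})/D_{sim} \times 100$ (positive = simulation higher),
with the simulated dose treated as exact since Monte Carlo reference
calculators report no uncertainty. `ctdi_based_dose()` implements the
console-index shortcut $D = f_{organ} \cdot CTDI_{vol}$ with the packaged
coefficient $f_{lung} = 1.50 \pm 0.06$ at 120 kV.

`bland_altman()` follows the standard construction: bias = mean of the
percent differences, limits of agreement = bias ± 1.96 × sample (n−1) SD,
plotted against pair means. The sample SD is a choice (the source
methodology does not specify n vs n−1); with ≥5 pairs the distinction is
below reporting precision.

## What the synthetic generator does and does not emulate

`generate_readings()` inverts the estimation chain from stated true slice
doses: dose → kerma via the coefficient ratio, kerma → TL via the
calibration line, then per-chip multiplicative Gaussian noise
$(1+\varepsilon)$, $\varepsilon \sim N(0, \mathrm{cv})$, plus a background
signal, with exactly the layout's group placements. Defaults: chip CV
0.05 (consistent with the ~5% relative sigmas of the published dose
tables), background 100 counts at CV 0.05, calibration CV 0.02. All
randomness flows from one explicit seed; fixed seed ⇒ byte-identical
output files.

It emulates the *statistical* structure the pipeline assumes — nothing
more. There is no X-ray spectrum, attenuation, scatter, partial-volume or
chip-sensitivity physics; true doses are inputs. A green recovery test
therefore establishes that the estimator is consistent and its uncertainty
model calibrated *under its own assumptions*, not that the physics of a
real phantom is captured. TCM profiles (`generate_tcm_profile()`) are
likewise qualitative: smooth clipped ramps reproducing the observed
contrast that patient profiles start high at the neck and fall toward the
lungs while phantom profiles do the opposite — sufficient for testing
profile-aware consumers, not for dosimetry.

## Numerical choices and edge cases

* Fraction tables must sum to 1 within 5e-3 by default (published tables
  are rounded to two decimals); exact tables can demand 1e-9.
* Calibration fits require ≥2 distinct TL values (1 with a forced zero
  intercept); all-equal TL is a singular design, and a negative fitted
  slope is rejected as corrupted input rather than propagated.
* Background subtraction clamps negative TL differences to zero with a
  warning — a reading below background carries no dose information.
* Slice indices are 1-based physical slice numbers; no slice thickness or
  3D geometry is modeled because the dose math never uses it.
* Which calibration beam quality (RQT 9 vs the scanner itself) converts
  which data set is an explicit per-run input; the methodology source used
  both without stating the mapping, so the package refuses to guess.

## Known limitations

* Organs outside the scan range are out of scope; the weighting scheme
  assumes every layout slice is directly irradiated.
* No supralinearity, fading, or per-chip sensitivity corrections.
* The uncertainty budget above is this package's declared model; it is not
  claimed to be numerically identical to the unpublished appendix of the
  methodology it re-implements.
* Three cells of the published pediatric normalized-dose table and two of
  the published simulation-comparison percent differences cannot be
  reproduced from the printed inputs at printed precision (rounding of
  unprinted intermediates); the tests document these as exclusions rather
  than matching them.
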