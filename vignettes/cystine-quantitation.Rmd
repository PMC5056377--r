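---
title: "Second-derivative ATR-FTIR quantitation of insoluble urinary cystine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-derivative ATR-FTIR quantitation of insoluble urinary cystine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystir)
```

## The measurement problem

Cystine is poorly soluble in urine (about 1 mM); in cystinuria the excess
spills over into microcrystals, and it is this *insoluble* fraction that
drives stone formation. The assay implemented here separates the insoluble
material by centrifugation, dries a 5 µL aliquot of the resuspended pellet
on an ATR prism, and reads the cystine content of the film from its
mid-infrared absorbance spectrum. Two companion measurements on the
*undried* urine — urea and creatinine from the 1510–1445 cm⁻¹ region —
provide the dilution normalisation (cystine:creatinine, µM per mM) and a
plausibility check.

The package implements the full analysis chain plus a forward simulator,
so every stage can be exercised and validated at desk scale without an
instrument.

## The quantitation model

**Spectral currency.** A spectrum is a strictly monotonic wavenumber grid
with one absorbance per point. Internally grids are stored descending
(4000 → 750 cm⁻¹, the FTIR display convention); one fixed orientation
eliminates sign errors in band lookups. The default working grid spans
4000–750 cm⁻¹ at 2 cm⁻¹ spacing: spectra acquired at 4 cm⁻¹ optical
resolution are digitised at about half that interval, and the spacing puts
the analysis wavenumbers 1296 and 1280 cm⁻¹ exactly on grid points. Band
positions are quoted to about ±1 cm⁻¹, so lookups accept the nearest grid
point within 1 cm⁻¹, ties broken toward the higher wavenumber.

**Water removal.** Water vapour in the optical path and, for undried
samples, liquid water are removed by fractional subtraction: a fitted
scale factor times a pure reference spectrum is subtracted. The factor is
the least-squares projection of the sample onto the reference over a fit
window — 1900–1700 cm⁻¹ for vapour (lines strong, film features weak),
3900–3100 cm⁻¹ for liquid water (OH stretch). Two refinements proved
necessary and are the package's own design:

* a free polynomial (order 2 by default) is co-fitted with the factor, so
  baseline drift and the tails of broad neighbouring bands do not leak
  into it — a sparse, strictly positive vapour comb otherwise soaks up any
  smooth pedestal on its window;
* `subtract_water()` estimates the vapour and liquid-water factors
  *jointly* on the union of the two windows. The liquid-water bend
  (~1640 cm⁻¹) tails far across the vapour window; in a joint design the
  water reference explains its own tail instead of biasing the comb
  factor. `fractional_subtract()` keeps the plain pairwise projection for
  use as a primitive.

**The cystine signal.** Quantitation uses the Savitzky–Golay second
derivative of the film spectrum (window 9 points, polynomial order 3 by
default; the references for the method do not pin these, and 9 points at
2 cm⁻¹ spacing preserves features separated by 16 cm⁻¹ while suppressing
noise). The response is the second-derivative intensity difference between
1296 and 1280 cm⁻¹. Two properties make this a good analytical signal:
it is linear in concentration, and any baseline that is affine across the
filter window is annihilated exactly — smooth drifts never reach the
calibration.

A sign convention worth stating explicitly: the second derivative of an
absorbance band is *negative* at the band centre, so the raw difference
d²A(1296) − d²A(1280) decreases with cystine concentration. The
quantitation pipeline therefore works with the inverted (band-sharpened,
−d²A) response via `cystine_response()`, which grows positively with
concentration and yields calibration slopes with the conventional positive
sign. `band_response()` exposes the raw difference for anyone who prefers
the other convention.

**Calibration.** Standards of 0–3 mM total cystine (default series in
0.5 mM steps) are fitted by a linear line of best fit *through the origin*
with no error weighting: slope = Σcᵢrᵢ / Σcᵢ². Diagnostics are the
uncentred R² (the standard no-intercept definition), the residual sd on
n − 1 degrees of freedom, and the calibrated range. Predictions are
response/slope, clipped at zero; values above the calibrated range are
flagged rather than refused, because linearity beyond 3 mM is unverified.
The limit of detection follows the standard 3σ convention,
LOD = 3 × residual sd / slope; the sources describe detection only
qualitatively, so a numeric rule had to be chosen, and 3σ is the field
default.

**Linearity and the film capacity argument.** Through-origin linearity up
to 3 mM is physically reasonable because the dried film stays inside the
volume probed by the evanescent wave: a cylinder of ~3 mm diameter and
~1 µm active height holds
π(1.5 mm)²·(1 µm) / 193 Å³ / N_A ≈ 60.8 nmol ≈ 60 nmol
of cystine (molecular volume 193 Å³) — exactly the content of a 5 µL drop
of a 12 mM suspension, twelvefold more than the highest 3 mM standard
(15 nmol). `spot_capacity()` computes this; the simulator's
`saturate_film()` models the complementary regime as a hard plateau,
scaling the response by min(1, capacity/amount).

**Urea and creatinine.** The 1510–1445 cm⁻¹ region of undried urine is
dominated by urea and creatinine. After water removal the region is fitted
by non-negative least squares on the two pure reference spectra plus a
free affine baseline (order 1 default): coefficients are physically scales
of pure-component spectra and may not be negative, while the local
baseline is unconstrained (implemented by the usual split of each baseline
column into a difference of two non-negative columns). Collinear
references are refused with the condition number in the message.
Concentrations follow as coefficient × the concentration at which the
reference was measured. Urea is reported for context; creatinine is the
normalisation denominator.

**Reporting conventions.** Per sample, triplicate film estimates are
summarised as mean ± SEM (n − 1 sd). A sample is *detected* if the mean
exceeds the detection threshold. Because the spectroscopic method sees
only the insoluble fraction while the clinical comparator (ion-exchange
chromatography) reports total cystine, detected samples get a 1 mM offset
— urine carrying insoluble cystine is saturated, so ~1 mM soluble cystine
must have been present. Undetected samples must have been below the
solubility limit and are carried as the censored interval 0.5 ± 0.5 mM
(an explicit interval object, not a point). The cystine:creatinine ratio
is reported in µM per mM.

**Method comparison.** Agreement with comparator methods uses Pearson
correlation and Bland–Altman analysis: mean bias with 95% limits of
agreement at bias ± 1.96 sd (n − 1 sd — standard Bland–Altman practice).
Differences are oriented comparator − FTIR, so a clinical method that
reads high (as the Jaffe reaction does for creatinine) yields a positive
bias. Censored samples enter the cystine comparison as 0.5 mM points with
their 0.5 mM half-width drawn as error bars; a flag excludes them
instead, since either treatment is defensible.

## What the simulator emulates — and what it does not

The generator is a forward model with the statistical structure the
analysis assumes:

* **Bands.** Components are sums of pseudo-Voigt bands (η = 0.5 default;
  the pure Gaussian/Lorentzian limits are recovered at η = 0 and 1).
  Cystine: 1296 cm⁻¹ (primary), 845 and 775 cm⁻¹ (weaker); urea
  (1462 cm⁻¹, fwhm 28) and creatinine (1490 cm⁻¹, fwhm 20) overlap inside
  the deconvolution window; liquid water has broad bands at 1640 and
  3350 cm⁻¹ (the OH stretch is what the 3900–3100 cm⁻¹ fit window sees);
  water vapour is a comb of 40 Lorentzian lines (fwhm 4 cm⁻¹) across
  2000–1300 cm⁻¹ with a fixed, deterministic height pattern.
* **Responsivities are synthetic.** True molar absorptivities at these
  wavenumbers are not tabulated in the package's sources. The cystine
  peak height (0.033 AU/mM) was set once so that a 3 mM film gives a
  second-derivative response ≈50× the default spectral noise
  (noise_sd = 2 × 10⁻⁴ AU), matching the qualitative claim that the 0–3 mM
  range is comfortably quantifiable.
* **Measurement model.** Sample spectrum = Σ concentration × component +
  water_factor × water + vapour_factor × vapour + polynomial baseline +
  i.i.d. Gaussian noise. Everything is a pure function of its parameters
  and seed; per-sample streams derive from one master seed by a stable
  hash, so cohorts are bit-reproducible.
* **Cohorts.** Defaults mirror the study shape: 22 patients + 5 controls;
  urea log-uniform 28–443 mM; creatinine uniform 0.5–20 mM; insoluble
  cystine uniform 0–3.1 mM for patients, 0 for controls; triplicate
  aliquots with 2% concentration CV (replicates are treated as
  independent aliquots). Comparators: Jaffe creatinine = truth + 1.4 mM
  bias + N(0, 1 mM); IEC total = insoluble + soluble + N(0, 0.1 mM).
* **The soluble fraction follows saturation thermodynamics.** Any urine
  carrying insoluble cystine is saturated, so its soluble fraction sits at
  the 1 mM solubility limit — the same argument that justifies the 1 mM
  reporting offset. Unsaturated urines draw a sub-limit value (U[0.5, 1]
  mM for patients, U[0, 1] mM for controls, making the 0.5 ± 0.5 mM
  censoring convention unbiased for them). An earlier draft drew patient
  soluble fractions below the limit even in saturated urines; that
  contradicts both the physics and the expectation that the offset
  comparison shows no systematic bias, and was dropped.

Passing the closed-loop tests therefore shows that the analysis correctly
inverts *this* generative model. Real dried films add effects the
simulator deliberately omits: anomalous-dispersion band distortion and
penetration-depth wavelength dependence of ATR, crystal-orientation and
film-inhomogeneity effects, drifting vapour line shapes, co-precipitated
urate/oxalate interferents, and instrument drift. Validation on real
specimens remains essential; the simulator's job is to make the code's
own logic falsifiable.

## Numerical choices

* Grid resampling is linear interpolation and never extrapolates.
* Savitzky–Golay derivatives are computed with respect to the grid index;
  endpoint regions use the standard asymmetric startup filters. The
  window must be odd and exceed the polynomial order (≥ 2 for a second
  derivative).
* The through-origin slope is degenerate if all standard concentrations
  are zero (error); a non-positive fitted slope flags a warning on the
  model and is refused at prediction time.
* NNLS solves are by the active-set method; window fits require at least
  twice as many grid points as free parameters.
* Window endpoints are inclusive on the nearest-grid-point convention;
  ties in band lookup go toward the higher wavenumber.
* The seed hash and the configuration digest use small multipliers so all
  intermediates stay exact in double arithmetic.

## Problem sizes used by the test-suite experiments

The packaged experiments run at desk scale, chosen to make the
statistical checks sharp while keeping the suite quick: calibration
series of 7 standards (0–3 mM in 0.5 mM steps), parameter recovery over
200 films spanning 0–3.1 mM plus 30 blanks, and end-to-end cohorts of
22 + 5 subjects in triplicate. One end-to-end unbiasedness check
(|bias| < 2·SE of the offset comparison) is a calibrated ~95% containment
test, so the suite requires it to hold for at least 4 of 5 fixed master
seeds rather than betting on a single draw.

## A worked end-to-end run

```{r, eval = FALSE}
library(cystir)
res <- run_pipeline(run_config(seed = 1))
head(res$results[, c("sample_id", "insoluble_mM", "sem_mM", "detected",
                     "total_mM", "ratio_uM_per_mM")])
res$calibration
res$cystine_comparison
```

The returned table mirrors the per-sample reporting format (insoluble
cystine ± SEM, detection flag, offset/censored total, creatinine-normalised
ratio), and the two `method_comparison` objects summarise Jaffe-vs-FTIR
creatinine and IEC-vs-FTIR total cystine agreement, with plot methods for
the scatter and Bland–Altman views.

## Known limitations

* JCAMP-DX support covers single-block `(X++(Y..Y))` tables in AFFN and
  SQZ/DIF/DUP form; multi-block files and vendor binaries are rejected.
* The deconvolution is a two-component NNLS with a local polynomial
  baseline; it does not model other urine solutes (glucose, phosphate) or
  use full-spectrum multivariate calibration.
* Quantitation uses the 1296/1280 cm⁻¹ pair only; the 845 and 775 cm⁻¹
  cystine bands are rendered by the simulator but not yet used
  analytically.
* The saturation model is a hard plateau; no optical modelling of the
  evanescent field is attempted.
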