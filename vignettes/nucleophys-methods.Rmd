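---
title: "Quantifying nucleolar physicochemistry: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleolar physicochemistry: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleophys)
```

## The measurement problem

The nucleolus is a membrane-less nuclear body whose material state — how
densely packed it is, and how freely probe molecules move through it — can
be read out by two complementary live-cell measurements. Optical
diffraction tomography (ODT) reconstructs a three-dimensional map of the
refractive index (RI), which is approximately proportional to local
macromolecular mass concentration; because the nucleolus is the densest
structure in the nucleus, it appears as rounded high-RI bodies. Fluorescence
correlation spectroscopy (FCS) records intensity fluctuations of a
fluorescent probe in a sub-femtolitre confocal volume and infers the
probe's diffusion coefficient `D`, an inverse viscosity probe of the same
compartments.

`nucleophys` implements the full analysis chain for both modalities on
synthetic data with known ground truth: RI phantom generation, band
segmentation and volume quantification; Brownian-dynamics trace simulation,
autocorrelation, and diffusion-model fitting; and condition-comparison
statistics. Every estimator can therefore be validated against
construction-level truth before it is pointed at instrument data.

## The tomography arm

### Phantoms

`generate_phantom()` paints ellipsoidal compartments, listed outermost
first, into a voxel grid initialised at the medium RI (default 1.337, a
typical refractometer value for culture medium). Later compartments
overwrite earlier ones, so nested anatomy — cell, nucleus, nucleoli,
sub-nucleolar shells — is expressed naturally. Membership uses a
voxel-centre test rather than partial-volume weighting: a voxel belongs to
a compartment exactly when its centre does. This makes the phantom an exact
oracle (segmentation of a noiseless phantom must reproduce the ground-truth
masks voxel for voxel), at the cost of a staircase boundary whose volume
error at 0.1 um voxels is below 3% for radii of 1.5 um and above — the
bound the tests assert.

The reference fixture `five_nucleoli_cell()` mimics an S-phase HeLa cell:
cytoplasm and nucleoplasm at RI 1.349, five nucleoli of diameter 2.2-3.0 um
at RI 1.363, and one 1.4 um distractor of the same density that the 2 um
rule must reject. Default voxel size is (0.356, 0.11, 0.11) um in (z, y, x);
these are the axial and lateral optical resolutions of a commercial ODT
instrument, used as a stand-in sampling grid since reconstruction grids are
instrument-specific. Noise, when requested, is additive i.i.d. Gaussian RI
noise; real tomograms carry structured reconstruction artifacts
(missing-cone elongation, speckle) that the phantom deliberately does not
model, so passing tests demonstrate correctness of the estimators, not
robustness to instrument physics.

### Band segmentation and the two RI estimators

On the instrument, compartments are rendered by adjusting transfer
functions — RI intervals — until the rendering matches the raw data. The
package mirrors this with explicit half-open bands `[lo, hi)`
(`ri_band()`); half-openness gives deterministic tie-breaking when bands
share a boundary, and overlapping bands are resolved by list order.
Connected components are computed with 26-connectivity, and "size" is
operationalised as the equivalent spherical diameter `(6V/pi)^(1/3)` from
the component's voxel volume, so the 2 um nucleolus rule has a precise
meaning on anisotropic grids.

Two mean-RI estimators ship side by side:

* `band_median_ri()` — the midpoint of the rendering band. This is the
  instrument-side convention (the median of the RI range used for
  rendering stands in for the compartment mean) and is the default for
  reproducing instrument-style numbers.
* `voxel_mean_ri()` — the arithmetic mean over the mask, the direct
  estimator and the recommended oracle.

Whenever the mask is drawn from the band itself the two can differ by at
most half the band width, a bound the tests verify. Time-lapse summaries
(`timelapse_summary()`) report both, but percent changes are computed on
the voxel mean, since a fixed band set cannot register a drift of the mean
within the band.

### Percent change and the fold ratio

`percent_change()` uses the earlier time point as denominator. On the
single-cell ATP-depletion endpoints (nucleolus 1.364 to 1.376, cytoplasm
1.348 to 1.354) it returns 0.880% and 0.445%, a fold ratio of 1.98 that
rounds to 2: the nucleolus concentrates roughly twice as strongly as the
surrounding cytoplasm under energy depletion.

## The FCS arm

### The model

The fitted autocorrelation model for free 3D diffusion through a Gaussian
detection volume of lateral radius `w` and structure parameter `s = z/w`
is, in the "+1" convention,

$$G(\tau) = 1 + \frac{1}{N}\sum_i y_i\,
  \Bigl(1+\frac{\tau}{\tau_{D,i}}\Bigr)^{-1}
  \Bigl(1+\frac{1}{s^2}\frac{\tau}{\tau_{D,i}}\Bigr)^{-1/2},
  \qquad \tau_{D,i} = \frac{w^2}{4 D_i},$$

with one or two components, fractions summing to one, and an optional
triplet (dark-state) factor $(1-T+T e^{-\tau/\tau_T})/(1-T)$ multiplying
the fluctuation term. The amplitude law $G(0^+)-1 = 1/N$ identifies the
mean molecule number in the effective volume
$V_\mathrm{eff} = \pi^{3/2} w^3 s$. Diffusion coefficients can be obtained
either geometrically (`tau_to_D()`, requiring `w`) or by ratio to a
reference dye measured in the same volume (`calibrate_D()`, default
rhodamine 6G at 280 um^2/s — the conventional FCS standard, which cancels
`w` entirely).

### Trace simulation

`simulate_trace()` integrates point emitters taking i.i.d. Gaussian steps
of per-axis SD `sqrt(2 D dt)` in a box containing the detection volume,
with expected per-particle signal
`brightness * exp(-2(x^2+y^2)/w^2 - 2 z^2/(s w)^2)` and optional Poisson
shot noise. Because Brownian increments are exactly Gaussian at any step
size, the autocorrelation of the simulated signal matches the continuous
model at every sampled lag — there is no time-discretisation bias, only
finite-volume effects (next section). The particle number is fixed at
`round(density x box volume)` per run rather than Poisson-resampled,
trading open-volume number statistics for lower variance in recovery
studies. The triplet option is a two-state telegraph process using the
exact two-state propagator per step, so its correlation decays exactly
exponentially with the prescribed relaxation time.

Defaults were fixed once as the study conditions: `D = 25` um^2/s (a
GFP-multimer scale mobility in cells), `w = 0.2` um, `s = 5`,
`mean N = 2`, `dt = 2` us, 10 s traces, brightness 0.5 counts/sample.
The instrument parameters (`w`, `s`, count rates) are conventional confocal
values; they are configuration, not constants of the method.

### Finite simulation volume: geometry and boundary treatment

Two design choices here deserve their own account, because naive choices
measurably bias recovered diffusion coefficients.

**Box geometry.** The detection volume is strongly elongated (axial radius
`s w`). A cubic box sized by the lateral rule alone truncates the axial
Gaussian tail: with `w = 0.2` um and `s = 5`, a 1.5 um cube cuts the axial
profile at 32% of its peak and biases fitted `D` upward by roughly +18%
(measured). The simulation box is therefore anisotropic, defaulting to
six times the 1/e^2 radius per axis — `(6w, 6w, 6sw)` — where the profile
has fallen to 1.5e-8 of peak; `simulate_trace()` rejects anything smaller
as a contract violation.

**Boundary condition.** In a plain periodic box, a particle leaving one
face re-enters as a *correlated image* of itself. With the fixed particle
count, the exact expectation of the estimated curve can be written as a
discrete diffusion-mode sum, and it differs from the open-volume model by
(i) a constant pedestal `-1/n_particles` and (ii) a positive
mode-discretisation surplus appearing at lags of 5-100 ms. Both live inside
the fitted lag range and together bias fitted `D` by up to ~+10% at an
affordable box volume (we verified the simulated curves against this mode
sum to 0.2%, so the artifact is understood exactly). The default boundary
treatment therefore emulates reservoir exchange: a crossing particle
re-enters on the opposite face with its transverse coordinates re-drawn
uniformly. Crossing particles are at least three detection radii from the
volume centre (guaranteed by the box contract), hence invisible, and the
re-draw preserves the uniform stationary density exactly while destroying
image correlations. Plain periodic wrapping remains available as an option
for comparison.

### Correlation estimation

`autocorrelate()` provides the O(n k) direct summation estimator (the
oracle) and the standard multi-tau scheme: lags 1..16 samples at full
resolution, then lags 9..16 on a pairwise-binned series at each further
level, lag spacing doubling per level, truncated at a quarter of the trace
duration. All levels are normalised by the global trace mean, so the
multi-tau values agree with direct summation on the binned series to
numerical precision — the equivalence the tests assert — while binning
averages the raw-lag curve over at most one bin width. Per-point error
bars can optionally be estimated by splitting the trace into eight blocks
and taking the spread of block-wise estimates; by default, weighting is
left to replicate averaging (`average_fafs()`), which attaches
cross-replicate SDs, mirroring the acquisition protocol of several short
measurements used to recognise non-stationary drift.

### Fitting protocol

`fit_faf()` minimises weighted squared residuals with
Levenberg-Marquardt, multi-started from a coarse logarithmic grid of
candidate diffusion times (all pairs for two components) so that no single
bad start decides the fit; positivity and range constraints are enforced by
log/logit reparameterisation. Weights are `1/sd` when the curve carries
per-point SDs, else uniform. Two numerical safeguards are defaults:

* **Free baseline.** An additive offset is fitted alongside the model.
  This is the conventional guard against correlation pedestals (detector
  afterpulsing, drift) and absorbs the small closed-volume pedestal noted
  above. On noise-free model data it converges to zero and does not
  degrade exactness.
* **Adaptive fit window.** The curve is first fitted in full, then refitted
  using only lags up to 50 times the largest fitted diffusion time, and the
  windowed fit is reported. By 50 diffusion times the lateral model term
  has decayed to 2% of the amplitude — the fit window keeps essentially
  all diffusion information while excluding the far tail, where residual
  slow correlations (whatever their source) would otherwise leverage the
  fit. On simulated 10 s traces at the default conditions this protocol
  recovers `D` with a mean bias within a few percent and per-seed spread
  of about 4%.

Model choice between one and two components is a nested F-test on the
weighted residual sums of squares at alpha = 0.05, computed on the full
lag grid (a common window for both candidates) before the chosen model is
refitted with its own window; numerically zero one-component residuals
short-circuit to one component, so noise-free single-species curves are
never over-fitted. The structure parameter is fixed at `s = 5` by default —
the standard practice when no calibration measurement is available — and
can be freed.

For nucleolar measurements, two-component fits are reduced to a single
characteristic value by the slow-component rule
(`characteristic_D()`): the smaller `D` characterises the nucleolar
matrix, while the fast component (probe in interstitial fluid or
nucleoplasmic exchange) is set aside. Outside the nucleolus a
fraction-weighted mean is reported with both components retained.

## Condition statistics

`group_summary()` reports mean, SD, SEM and n per
(condition, compartment, metric) group; `ttest()` is the two-sided
pooled-variance Student's test (Welch available behind a flag) with
significance at p < 0.05 and a defined degenerate case (zero variance with
equal means returns t = 0, p = 1); `condition_report()` compares every
condition against a baseline per compartment and metric, reporting percent
change of the group mean, raw p-values (no multiple-testing correction, by
design) and a significance flag. Missing combinations are skipped with a
warning rather than failing the whole report.

## Problem sizes used by the tests and the acceptance script

The automated checks run the full pipeline at deliberately desk-scale
sizes chosen once as the study conditions: phantoms of roughly 40 x 169 x
169 voxels (the five-nucleoli cell) down to 50^3 (volume oracles);
recovery studies of twenty 10 s traces at 2 us sampling (5e6 samples each,
78 particles); and model-selection studies of twenty two-component traces.
A full run recomputes everything from scratch in well under half an hour
on one core.

## Known limitations

* The phantom's noise model (i.i.d. Gaussian RI) and geometry (ellipsoids)
  do not emulate reconstruction artifacts, partial-volume effects, or
  irregular organelle shapes; exactness results transfer to real tomograms
  only insofar as segmentation bands are well separated from noise.
* The simulator omits photobleaching, cell-boundary confinement,
  anomalous diffusion and detector afterpulsing; the fitted model is the
  free-diffusion form, so systematic deviations from it in real data are
  out of scope.
* Band limits for real data are user inputs: the package ships no
  automatic transfer-function search.
* With a fixed particle count in a finite box, a small residual
  finite-volume distortion of the correlation curve remains even under
  reservoir boundaries; at the default geometry its effect on fitted `D`
  is at the percent level and is quantified in the tests rather than
  corrected for.
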