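---
title: "Models and methods behind lasertherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lasertherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lasertherm)
library(dplyr)
```

This vignette is the package's account of the science it implements: the
fluorescence-thermometry model, the laser-heating field, the exposure
planner, the morphometric statistics, and — importantly — the choices made
where more than one reasonable convention existed, and what the synthetic
data can and cannot tell you about real microscope data.

## Ratiometric fluorescence thermometry

mCherry fluorescence decreases linearly with temperature over the 15–40 °C
window in which it was calibrated, by a fraction `s` per °C (about 0.017).
The package models total cell fluorescence as

$$F(T) = F_{\mathrm{ref}}\,\bigl(1 - s\,(T - T_{\mathrm{ref}})\bigr),$$

with $T_{\mathrm{ref}} = 20\,°C$ the normalisation anchor. `fit_sensitivity()`
follows the experimental procedure literally: fluorescence totals are
normalised to the value observed at (or interpolated at) the reference
temperature, an ordinary least-squares line is fitted, and `s` is minus its
slope. Normalising by the *observed* reference value rather than a fitted
one keeps the estimator identical to the bench protocol; the additional
variance this injects is negligible when per-cell totals run to $10^5$
counts, as they do under the default scene.

**Ratio inversion.** A laser ON/OFF acquisition at base temperature $T_0$
gives the ratio

$$R = \frac{F(T_0 + \Delta T)}{F(T_0)}
    = \frac{1 - s\,(T_0 + \Delta T - T_{\mathrm{ref}})}{1 - s\,(T_0 - T_{\mathrm{ref}})},$$

which the package inverts *exactly*:

$$\Delta T = \frac{(1 - R)\,\bigl(1 - s\,(T_0 - T_{\mathrm{ref}})\bigr)}{s}.$$

The widely used shortcut $\Delta T = (1-R)/s$ is exposed via
`anchored = FALSE`; the two coincide when $T_0 = T_{\mathrm{ref}}$ and differ
by the factor $1 - s(T_0 - T_{\mathrm{ref}})$ otherwise (3.4% at
$T_0 = 22\,°C$). Both are provided because the conversion convention is not
uniquely determined by the measurement procedure; the anchored form is the
default because it round-trips the generative model to machine precision,
which is what makes the pipeline testable end to end.

**Temperature maps.** `temperature_map()` downsamples both images by a
non-overlapping block mean (default $3\times3$; trailing rows/columns that do
not fill a block are dropped — the simplest reading of "downsample by 3×"),
subtracts the background, divides ON by OFF and inverts. Two numerical
guards matter:

* *Validity floor.* Pixels whose background-subtracted OFF signal falls
  below $5\sigma_{\mathrm{bg}}$ are masked: the ratio of two
  near-zero numbers is noise amplified without bound. In the exactly
  noiseless case ($\sigma_{\mathrm{bg}} = 0$) a tiny relative floor
  ($10^{-9}$ of the OFF maximum) plays the same role.
* *Background estimator.* When no background ROI is supplied, the
  background level is the modal intensity (exact modal value if a single
  value dominates >5% of pixels, as in flat synthetic backgrounds;
  otherwise the modal histogram bin). Supplying an explicit ROI is always
  better and is what the pipeline driver does.

Within a block of uniform cell occupancy the block-mean ratio equals the
mean ratio, so the inversion is exact there; blocks straddling the softened
cell edge mix temperature-scaled and temperature-independent intensity and
are biased. This is why accuracy statements about the map are made *away
from mask edges*: in tests, the valid region is eroded by the soft-edge
extent (4 grid pixels at the default geometry) before comparing with the
downsampled truth, where the round-trip error is at float precision
(~$10^{-8}\,°C$).

## The laser-heating field

The field is phenomenological, not a heat-conduction solution — that is the
point of calibrating it in vivo. Three facts define it:

1. focal elevation linear in power, $\Delta T(0) = kP$ with
   $k \approx 4\,°C/mW$ (the rounded working value; the raw regression
   estimate is 4.1 — both are carried in `heating_constants()`, neither
   silently preferred);
2. in-plane decay that is exponential with the *same shape at every power*,
   halving at $r_{1/2} \approx 11\,\mu m$:
   $\Delta T(r) = kP\,2^{-r/r_{1/2}}$ (equivalently $e$-folding length
   $r_{1/2}/\ln 2 \approx 15.9\,\mu m$). The base-2 parameterisation is used
   because the half-maximal distance is the directly reported, directly
   interpretable quantity;
3. first-order step-response kinetics. "Steady state within 500 ms" is
   operationalised as *95% of the asymptote at 500 ms*, fixing the default
   $\tau = 500/\ln 20 \approx 167\,ms$. The 95% level is a declared
   convention, not a measured constant; any function taking `tau` accepts a
   measured value.

The axial (z) dimension is not modelled: the calibration measurements are
in-plane, and so are the package's distances.

**Fitting.** `fit_power_slope()` regresses elevation on power with the
intercept fixed at zero by default — elevation must vanish at zero power —
with a free-intercept option retained purely as a diagnostic for background
drift. `fit_spatial_profile()` fits all powers jointly by
Levenberg–Marquardt with one shared $r_{1/2}$, per-power amplitudes $A_p$,
and the far-field plateau fixed at zero elevation (ambient). Start values:
$r_{1/2}$ from the first distance at which the binned elevation drops below
half its maximum (first crossing wins as the tie-break), amplitudes from the
innermost bin. The fit reports a *collapse residual* — the RMS relative
deviation of $A_p$ from strict proportionality to power — as the diagnostic
for the multiplicative-scaling assumption; on the default synthetic data it
is below 0.5%.

**Pulsed operation.** A schedule of frequency $f$ (Hz) and pulse width $w$
(ms) has duty cycle $fw/1000$ and time-averaged power
$P_{\mathrm{avg}} = P_{\mathrm{peak}} \cdot \mathrm{duty}$. The 6 Hz /
8.3 ms ablation schedule has duty 0.0498, so 13 mW peak averages to
0.65 mW — two orders of magnitude below what would induce neighbours. When
$w < 3\tau$ the focal peak is attenuated by the step-response factor
$1 - e^{-w/\tau}$; at 8.3 ms this is only ~5% of the steady-state
elevation, which is exactly why short pulses can deposit ablative peak
*power* while the *temperature* field stays clamped — the feasibility logic
of `plan_ablation()` rests on the time-averaged power at the neighbour.

## Planning

`plan_induction()` solves the band constraint analytically: powers in
$[(T_{\mathrm{low}} - T_a)/k,\ (T_{\mathrm{high}} - T_a)/k]$ put the focus
inside the band at ambient $T_a$. The adopted power is the interval
*midpoint* — a symmetric margin against both failure modes (no induction /
off-target induction); `edge = "low"` reproduces the band-lower-edge choice
(3.0 mW at 20 °C for the 32–34 °C band with $k=4$). Feasibility additionally
requires the predicted neighbour temperature
$T_a + kP\,2^{-d/r_{1/2}}$ to stay below the band. The neighbour geometry is
deliberately reduced to a single distance with *no default* — it is the one
genuinely specimen-specific input — while `classify_cells()` handles full
per-cell geometries.

For ablation, the lethal temperature defaults to 50 °C. No measured lethal
threshold exists for this protocol; 50 °C is the lower edge of the range at
which legacy continuous-exposure protocols destroyed cells outright, and it
is a documented, exposed parameter rather than a constant.

## Morphometrics

Neurite length is the 3D polyline sum
$\sum_i \sqrt{\Delta x_i^2 + \Delta y_i^2 + \Delta z_i^2}$ over consecutive
annotated points — tested against a brute-force loop oracle and for rigid
invariance, since those two properties are what distinguish a correct
implementation from an indexing bug.

The developmental clock maps the tail-to-head measure linearly to a stage in
$[0,1]$ (comma stage → 0, 2-fold → 1). The measure is taken as the *chord*
(straight-line 3D distance) between the tail and head landmarks, a
convention this package declares because curved-axis alternatives exist;
out-of-range stages are clamped and flagged, not rejected, because pre-comma
and post-2-fold observations are real and useful.

`compare_outgrowth()` defines outgrowth onset as the first stage at which
length exceeds 1 µm — the threshold is a convention (no numeric criterion
exists for "initiation") and is a parameter. Group differences in onset and
post-onset rate get seeded percentile-bootstrap CIs (default 1000
resamples); a bootstrap was chosen over a parametric test because per-curve
onset estimates are discretised by the imaging interval and not plausibly
normal at $n \sim 4$–8 embryos per group.

`division_delay_stats()` distinguishes the *paired* mode (signed
heated-minus-control delay) from the *control* mode, which reports the mean
**absolute** left–right difference — the natural variability benchmark is a
magnitude, not a signed quantity. The percent cycle increase is a per-embryo
mean of $(c_T - c_C)/c_C$; per-embryo (rather than pooled) averaging is the
implemented choice where both are defensible.

## What the synthetic data emulate — and what they do not

The generators reproduce the *statistical structure the analyses assume*:

* a thin sheet of reporter-expressing cells rendered as uniform discs with a
  1-pixel Gaussian-softened edge (cell appearance is otherwise
  unconstrained; a uniform disc is the simplest shape supporting ROI
  summation);
* the linear fluorescence law applied per pixel, background
  temperature-independent;
* Poisson shot noise plus Gaussian read noise (sd 2 counts by default). No
  noise model is canonical here; the defaults were set so the per-cell
  temperature readout scatters by ≈0.3 °C — with per-cell totals near
  $10^5$ counts, the shot-noise-limited ratio error of
  $\sqrt{2/N} \approx 0.005$ divided by $s = 0.017$ gives ≈0.27 °C —
  matching the scatter regime of per-cell spatial-profile data;
* per-cell measurement noise of sd 0.3 °C and 3–7 cells per distance bin in
  the profile-fitting conditions (three powers, 40 cells per power, distances
  uniform within 35 µm, 2 µm bins);
* neurite tracks whose polyline length equals the growth schedule exactly
  (jitter off by default), and paired division records whose
  treated-minus-control difference is `mean_delay` plus Gaussian noise. The
  default control cycle of 63 min makes a 17 min delay a ~27% cycle
  increase, tying the two reported summaries together.

They do **not** emulate: embryo twitching or eggshell rotation, z-drift,
out-of-focus light, axial heat-field structure, detector nonlinearity, or
biological variability in heat-shock responsiveness (the empirical ~60%
induction rate at the band edge is an observation without a stated
generative model, and simulating it would be invention). Passing tests
therefore demonstrate that the *estimators are correct for the model the
measurements assume* — linear thermometry, exponentially decaying field,
Gaussian/Poisson noise — not that a particular microscope meets those
assumptions. On real data the calibration diagnostics ($R^2$ of the
sensitivity fit, the collapse residual of the joint spatial fit, the free
intercept of the power fit) are the checks that the assumptions hold.

## Numerical choices and degenerate inputs

* Coordinates: pixel centres, 0-based pixel $k$ spanning
  $[k, k+1) \cdot \mathrm{pixel\ size}$ µm; all distances in µm.
* Distance bins are half-open $[kw, (k+1)w)$; a single-member bin reports
  sd 0 rather than NA so downstream weighting never divides by a missing
  value.
* `fit_sensitivity()` requires ≥3 distinct temperatures and strictly
  positive fluorescence; identical temperatures are a degenerate fit, not a
  zero-sensitivity result.
* Apparent cooling (ON/OFF ratio > 1) yields a *negative elevation with a
  flag and warning*, never an error: under noise, ratios straddle 1 at large
  distances, and rejecting them would bias binned means upward.
* TIFF I/O stores intensities scaled into $[0,1]$ as 32-bit float with the
  scale factor and pixel size in a YAML sidecar (float TIFF storage is
  confined to the unit interval); round trips are exact to float32
  (~$10^{-7}$ relative).
* All stochastic generators take explicit integer seeds and are
  bit-reproducible; `run_pipeline()` hashes a canonicalised form of each
  stage output (model objects reduced to coefficients and fitted values,
  which is what "the same numeric result" means) into its manifest.

## Problem sizes

The test and example workloads are sized for interactive use: 192×192 px
scenes (one cell for calibration), 11-temperature calibration series,
120-cell spatial-profile tables, bootstrap comparisons at 200–1000
resamples, property sweeps of 200–1000 random cases, and coverage checks at
20 repetitions with 6 curves per group. These sizes put Monte-Carlo
tolerances (10% on recovered parameters, 2 min on a 17 min delay at
$n = 50$) comfortably above their sampling error while keeping a full run in
tens of seconds; all are parameters, and scaling them up only tightens the
recoveries.

## Known limitations

* The heat field is 2D and phenomenological; do not extrapolate the decay
  law beyond the calibrated 0–35 µm range or across media with different
  infrared absorption.
* The thermometer is only as linear as its reporter: outside 15–40 °C the
  calibration window errors, by design.
* The planner treats thresholds as sharp; real induction probability rises
  smoothly through the band, so plans near the feasibility boundary should
  be read as marginal.
* Stage alignment assumes the tail-to-head clock is comparable across
  embryos; temperature variation during imaging shifts developmental rate
  and is not corrected here.
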