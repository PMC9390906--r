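---
title: "Radiochromic film in vivo dosimetry: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiochromic film in vivo dosimetry: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(filmdose)
```

`filmdose` implements an in vivo dosimetry protocol for GafChromic EBT2 film
on a Cobalt-60 teletherapy beam: optical-density calibration, an uncertainty
budget, correction factors for irradiation conditions, and entrance- and
skin-dose estimation. This vignette explains the underlying models, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The dose model

A radiochromic film darkens by polymerization when irradiated. A point
densitometer reads the darkening as an optical density; the dose signal is
the **net optical density**

$$\mathrm{NOD} = OD_2 - OD_1,$$

the post-irradiation reading minus the pre-irradiation background of the same
film. Dose is related to NOD by a cubic calibration

$$D(\mathrm{NOD}) = a\,\mathrm{NOD}^3 + b\,\mathrm{NOD}^2 + c\,\mathrm{NOD} + d
\quad [\mathrm{cGy}],$$

fitted by unweighted least squares to film sets irradiated to known
chamber-referenced doses (the ten-point schedule 50–450 cGy in 50 cGy steps
plus 800 cGy is the package default). A cubic with four free coefficients is
flexible enough for the mild saturation of the film response over this range
while remaining invertible; the package enforces strict monotonicity of
every curve on its OD domain (1000-point grid, zero tolerance on the sign of
increments) at construction, so the inverse `dose_to_od()` — needed by the
synthetic generator — is a well-posed bisection, converged to
$|\Delta D| < 10^{-9}$ cGy.

All doses are in centigray throughout. The reference cubic shipped as
`ebt2_co60_curve()` (coefficients 1685, −187.9, 1006, −2.328) produces
47.7 cGy at OD 0.05 and 139.5 cGy at OD 0.14 by direct evaluation; these are
the values the package reports. The fitted intercept $d$ is not constrained
to zero, so the raw polynomial is slightly negative at OD 0; negative doses
are never silently clamped — `od_to_dose(..., clamp = TRUE)` floors them at
zero *with a warning*, and only at reporting time.

The fit quality statistic `r_fit` is the Pearson correlation between
observed and fitted doses: the protocol's "correlation coefficient" is not
otherwise specified, and this definition applies unchanged to the nonlinear
fitted values.

## Uncertainty budget

Two sources are propagated per dose estimate:

- **Experimental**: the densitometer reading uncertainty maps to dose
  through the local slope of the calibration,
  $\delta_e = |3a\,OD^2 + 2b\,OD + c|\,\delta_{OD}$. The densitometer
  display is limited to two decimals, so the readout quantum 0.01 OD is used
  as the reading standard deviation $\delta_{OD}$ by default (configurable
  via `densitometer()`).
- **Fitting**: coefficient standard deviations from the least-squares
  covariance combine as
  $\delta_f = \sqrt{\delta_a^2 OD^6 + \delta_b^2 OD^4 + \delta_c^2 OD^2 + \delta_d^2}$.

The total is the quadrature sum $\delta = \sqrt{\delta_e^2 + \delta_f^2}$,
which assumes the two sources are independent — reasonable, since one is
instrument readout and the other is fit sampling error. The budget's
defining identities (quadrature symmetry, exact linearity in
$\delta_{OD}$, monotone growth of the absolute uncertainty with dose on the
calibration range) are what the test suite verifies; absolute percentage
bands depend on the coefficient standard deviations of a particular fit and
are not portable constants.

```{r budget}
fit <- fit_calibration(generate_calibration_dataset(
  response_scenario(noise_sd_od = 0.003, seed = 1)))
uncertainty_budget(fit, c(0.1, 0.3, 0.5))
```

## Correction factors

A surface film over-responds when contaminating electrons from the
collimator head and air reach it — increasingly with field size and gantry
angle — and under-responds behind a wedge (beam hardening) and at long SSD.
The correction factor for a condition normalizes the chamber-to-film ratio
by the reference ratio:

$$CF = \frac{(R_{ic}/R_f)_{\text{clinical}}}{(R_{ic}/R_f)_{\text{reference}}},$$

with reference conditions 10 cm × 10 cm open field, SSD 100 cm, gantry 0°.
CF is exactly 1 at the reference knot by construction, and invariant to any
common rescaling of the chamber readings. Conditions combine as a plain
product $\Pi CF$, treating the four parameters as separable — they are
characterized one at a time, and no interaction data exist to support more.

Two choices here were genuinely open:

- **Between-knot behavior.** CFs are measured on grids (field 4–24 cm, SSD
  75–120 cm, gantry 0–90°, wedge 15–60°). Piecewise-linear interpolation is
  the minimal assumption, and extrapolation beyond the measured range is
  refused with an error rather than guessed — a wrong silent CF is a wrong
  patient dose.
- **The configuration comparison test.** Responses of the unencapsulated and
  encapsulated film are compared across matched settings; the protocol fixes
  only a significance level. `compare_configurations()` uses a two-sided
  paired t-test on the matched normalized responses (the settings are
  paired by design) and records the method in its output. The degenerate
  zero-variance case (identical series, or an exact constant shift) is
  answered exactly (p = 1 or 0) instead of erroring.

## Entrance dose, depth dose, skin dose

The entrance dose is defined at the depth of maximum dose
(Dmax = 0.5 cm for Co-60). A surface film does not sit at Dmax, so its dose
reading $D_f$ is scaled by the **entrance calibration factor**
$F_{cal,entrance} = R_{ic}/R_f$ measured at reference conditions (4.134 for
the unencapsulated film used as the package's reference value), and by the
correction-factor product:

$$D_{entrance} = D_f \cdot F_{cal,entrance} \cdot \Pi CF.$$

Dose at depth follows by multiplying with a percentage-depth-dose table,
linearly interpolated; a small representative Co-60 10 × 10 SSD-100 table
(illustrative values, marked synthetic in its filename) ships in
`inst/extdata/` for examples and tests.

The skin dose is referenced to 0.070 mm depth (the radiosensitive basal
layer). The film's active layer lies at 0.080 mm, so a **skin calibration
factor** converts the film dose: from the OD of a single film (active layer
0.080 mm) and of the bottom film of a four-film stack (0.935 mm), the OD at
0.070 mm is linearly extrapolated in depth; the factor is the ratio of the
corresponding film doses. With the standard geometry the extrapolated OD is
0.0294, which reads 0.03 at the densitometer's two-decimal display, giving
$F_{cal,skin} = 0.03/0.03 = 1.00$. By default the factor is computed on
display-rounded ODs, reproducing what a densitometer user would obtain;
`round_od = FALSE` gives the raw-OD ratio (0.979), and the gap between the
two is a fair estimate of the rounding's effect. Percent skin dose reduces
algebraically to the factors alone:

$$\%\,\text{skin dose} = \frac{100 \cdot F_{cal,skin}}{F_{cal,entrance} \cdot \Pi CF},$$

24 % at reference conditions for the unencapsulated film. Skin-dose
percentages are reported integer-rounded (the raw value is always kept
alongside). Reference depths (0.070 mm target, 0.080 mm and 0.935 mm active
layers) are configurable arguments, with film-layer depths in millimetres
and all other depths in centimetres, as the field writes them.

## The synthetic-data generator

The generator exists so that every stage of the pipeline — calibration,
budget, CF estimation, dose reconstruction — runs and is tested end-to-end
with no measured data. It emulates:

- the cubic OD–dose response (the reference curve above as ground truth);
- densitometer quantization to 0.01 OD, applied after any Gaussian noise;
- saturating post-exposure OD growth, $\mathrm{NOD}(t) = p(1 - e^{-t/\tau})$
  with the plateau $p$ given by the inverse calibration of the delivered
  dose and $\tau$ rising linearly with dose (120 min at 50 cGy to 250 min at
  800 cGy). Low doses stabilize sooner, and with the display quantization
  the slowest (800 cGy) series settles onto its final displayed value at
  roughly 1150 min — comfortably before the protocol's 24 h (1440 min)
  read-out time. A larger high-dose time constant would contradict that
  stabilization property once quantization is accounted for, which is why
  the default ramp tops out at 250 min;
- correction-factor landscapes with the observed qualitative structure:
  unencapsulated response rising with field size and gantry angle, falling
  with SSD and wedge angle; encapsulated response flat in field size and
  gantry angle. The relative-response slopes are linear in the parameter
  (the minimal monotone shape), the chamber dose scales inverse-square with
  SSD relative to 100 cm and exponentially with wedge angle, and the
  ground-truth CF is exactly the reciprocal of the relative response.

Noise model: a recorded OD is the mean over a set of `n_films` films
irradiated together (default 10; film protocols irradiate sets, and a set
mean is what enters analysis), with independent per-film Gaussian noise of
`noise_sd_od` added before quantization. Characterization irradiations for
the CF landscape deliver 600 cGy at the reference condition by default —
the upper part of the calibrated range, where the film's relative dose
resolution is best, while keeping every film dose (including the
encapsulated film at SSD 75 cm, which reads near the chamber dose scaled by
inverse square) inside the calibrated range. Under these defaults, with
per-film noise 0.001 OD, estimated correction factors recover their ground
truth to well under 1 % and reconstructed entrance doses stay within 3 % of
the prescription across the 20-condition sweep — the test suite checks both
at fixed seeds, and `scripts/acceptance.R` recomputes the sweep for any
seed.

What the generator does **not** emulate: spatial structure (each film is a
point reading; no scanner lateral response, no 2-D dose maps), film-to-film
batch variation beyond i.i.d. Gaussian noise, energy-spectrum physics of
electron contamination (the response slopes are a phenomenological
surrogate), chamber reference uncertainty, and the non-monotone gantry
response peak near 70–80° seen in real contamination data (the surrogate is
monotone). Passing tests therefore demonstrate that the *analysis chain* is
correct and stable under realistic noise — not that the generator's
response surfaces are physically accurate.

```{r landscape, fig.alt = "Normalized film response by irradiation parameter"}
plot_normalized_response(
  generate_cf_landscape(response_scenario(seed = 5)))
```

## Numerical choices and degenerate inputs

- Calibration fits require ≥ 5 points with ≥ 4 distinct NOD values;
  anything less is a rank-deficiency error, and a fitted polynomial that is
  not strictly increasing on the data range is rejected outright.
- Instrument readings are quantized to 0.01 OD (round-half-even via R's
  `round`); derived quantities keep full precision, and quantization for
  reporting is always explicit.
- Negative NOD and negative raw doses warn and pass through; clamping is a
  reporting option, never a default.
- `lookup_cf`, `dose_at_depth` and `dose_to_od` all refuse out-of-range
  inputs with typed errors instead of extrapolating.
- Equal depths in the OD extrapolation, zero film readings in CF ratios and
  sub-minimal comparison series raise specific error classes
  (`filmdose_degenerate_geometry`, `filmdose_division_error`,
  `filmdose_insufficient_data`) so pipelines can react precisely.
- Problem sizes in the shipped tests are the protocol's own: ten
  calibration doses, 11-knot field-size grids, 20-condition sweeps, 108
  hourly growth readings. These run in seconds.

## Known limitations

Exit dose and exit-side skin dose are out of scope, as are peripheral
(off-axis) doses, multi-channel scanner dosimetry and film-orientation
effects. The paired t-test assumes approximately normal within-pair
differences; with very short series (n = 4 wedge settings) its power is
limited, which is inherent to the data size rather than the implementation.
Clinical use of the uncertainty budget should add patient-related sources
(movement, anatomy) that a phantom-based budget omits.
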