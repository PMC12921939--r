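---
title: "Simulating perimetry across devices with unequal dynamic range"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating perimetry across devices with unequal dynamic range}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisim)
library(dplyr)
```

## The problem

Static perimetry maps differential light sensitivity: at each visual-field
location, the dimmest luminance increment the observer can just detect on a
uniform background. Projection perimeters present increments spanning more
than three orders of magnitude; head-mounted perimeters built on smartphone
displays cannot. A display behind a neutral-density filter may span only a
16 dB window where a projection device spans 33 dB, so the head-mounted
exam *floors* wherever true sensitivity is poor (it cannot present a bright
enough stimulus; the result is reported as 0 dB) and *ceilings* wherever
sensitivity is excellent (it cannot present a dim enough one). In inherited
retinal diseases — where fields combine near-normal regions with deep or
absolute scotomas — both limits bite at once.

`perisim` simulates this situation end to end: device models, the 10-2 test
grid, synthetic ground-truth fields with disease-typical loss patterns, a
Bayesian ZEST threshold exam against a frequency-of-seeing observer, and
the method-comparison statistics used to quantify agreement between two
devices measuring the same eye.

## Device models and the decibel scale

Perimetric sensitivity is defined relative to the *device's own* brightest
increment:

$$ S\,[\mathrm{dB}] = 10 \log_{10}\!\frac{\Delta L_{max}}{\Delta L_{thr}} $$

so 0 dB means "the brightest stimulus this device can show was just
detected". All logarithms here are base 10 with the factor 10 (attenuation
convention), never 20. Two devices with different $\Delta L_{max}$ therefore
use shifted decibel scales; the shift is
$10\log_{10}(\Delta L_{max,A}/\Delta L_{max,B})$, which for the shipped
presets (318 vs 12.76 cd/m²) is 13.97 dB, conventionally rounded to 14.
`to_octopus_equivalent()` applies the rounded shift to every nonzero value;
an exact 0 dB stays 0 because a floored measurement carries no threshold
information to shift.

```{r devices}
octopus900()
iowa_hmp()
round(offset_between(octopus900(), iowa_hmp()))
```

Numerical choices worth stating:

* **Projection minimum increment.** The projection preset's
  `delta_L_min = 0.1594` cd/m² is a derived constant chosen so that the
  device's stated 33 dB dynamic range holds; it is configurable.
* **Head-mounted minimum increment.** A display can render a 0.13 cd/m²
  step (kept as `display_min_increment` metadata, and it is what makes the
  dimmest *resolvable* stimulus worth 19.9 dB), but the effective dynamic
  range of reliable presentation is taken as 16 dB, i.e.
  `delta_L_min = 0.3206` cd/m² — a 40-fold luminance ratio. Both constants
  are configurable; the tension between them is a property of real display
  hardware, not something the package resolves.
* **Quantization.** Displays drive stimuli through an RGB ladder: 255
  equally spaced increments between `delta_L_min` and `delta_L_max`.
  `quantize_increment()` snaps any requested increment to the nearest
  ladder member and clamps outside the range; projection devices only
  clamp. Linear spacing in luminance means the ladder is coarse in decibels
  near the top of the range — one reason head-mounted estimates of high
  sensitivities are grainy.
* **Neutral-density filter.** A filter of optical density $d$ attenuates by
  $10^d$; `screen_setting_for_background(10, 0.6)` returns the 39.8 cd/m²
  the screen must emit for a 10 cd/m² background at the eye. The filter
  trades ceiling for floor: it lets the device present dimmer stimuli (less
  ceiling) at the cost of a brighter floor.

## The 10-2 grid

`generate_10_2()` returns the 68 locations with odd-integer coordinates in
$\{\pm1,\dots,\pm9\}$ degrees and $x^2+y^2 \le 82$. No authoritative
coordinate list ships with commercial devices' documentation; this rule is
adopted because it is the unique symmetric odd-lattice disc with exactly 68
points inside the central 10°. Coordinates are visual-field coordinates;
left/right-eye laterality affects only the blind-spot marker on plots
(`blind_spot_position()`, drawn at ±15° temporally, below the meridian —
outside the tested field, purely a display convention).

## Synthetic ground truth

`make_true_field()` builds one eye's true sensitivities on the
projection-equivalent scale: a linear hill of vision
$H(e) = \mathrm{peak} - \mathrm{decay}\cdot e$ (defaults 33 dB and
0.5 dB/deg, placing normal central sensitivities near the top of the
projection range) minus a diagnosis pattern:

| diagnosis | pattern | defaults |
|---|---|---|
| normal | none | — |
| OMD | Gaussian central depression $d\,e^{-e^2/2r^2}$ | depth 20 dB, r 4° |
| STGD | annular bull's-eye $d\,e^{-(e-\rho)^2/2w^2}$, optional absolute central scotoma | depth 25 dB, ring 4°, width 1.5° |
| RP | sigmoid concentric loss $d/(1+e^{-(e-\rho)/w})$ | depth 60 dB, preserved radius 4°, width 1° |

plus per-location Gaussian jitter (default SD 1 dB). Finite truths are
clipped to $[-10, 45]$ dB; anything driven below −10 dB becomes $-\infty$,
the encoding of an absolute scotoma. These pattern shapes and magnitudes
are stipulated, not fitted to patient data: no quantitative generative
model of inherited-retinal-disease fields exists to fit. They emulate the
*geometry* of the classic patterns (central, annular, concentric loss) and
realistic dB depths; they do not emulate spatial correlation of noise,
structure–function coupling, fixation instability, or adaptation
differences between backgrounds. A passing pipeline therefore demonstrates
correct behavior of the measurement and analysis machinery under plausible
fields, not clinical validity on real patients.

The default cohort (`cohort_config()`) mirrors a small pilot study: 1
normal, 2 OMD, 3 STGD and 6 RP subjects, both eyes each (24 fields, 1632
locations). Eyes of a subject share pattern parameters (a per-subject
hill-height shift, SD 2 dB, models inter-subject variability) and differ by
independent jitter.

`psychometric_observer()` attaches the response model: a stimulus at $s$ dB
against true threshold $t$ is reported seen with probability
$fp + (1-fp-fn)\,\Phi((t-s)/\sigma)$ — a cumulative-Gaussian
frequency-of-seeing curve with lapse rates. Defaults $\sigma=1.5$ dB,
$fp=fn=0.03$ are conventional perimetric values. An absolute scotoma
responds only through $fp$.

## The ZEST exam

Each location runs an independent ZEST procedure: a probability mass
function over candidate thresholds on the device's scale (0.5 dB spacing,
guard bands 5 dB beyond $[0, \mathrm{DR}]$, uniform prior), stimulus at the
posterior mean (clamped to the measurable range, then quantized to the
device ladder — the observer is asked about the level actually
presentable), Bayes update by the likelihood of the response under the
engine's *assumed* listener model ($\sigma_{model}=1.5$ dB,
$fp=fn=0.03$ — deliberately separate from the simulated observer's true
parameters, so misspecification can be studied), stopping when the
posterior SD falls below 1.5 dB or after 12 presentations. The estimate is
the posterior mean clamped to $[0, \mathrm{DR}]$; exactly 0 signals the
floor. Locations are interleaved in randomized order, as real perimeters
do. Named speed-optimized variants of ZEST are treated as this
configuration; the projection device's proprietary adaptive strategy is not
reimplemented — both simulated devices use the same engine with their own
device parameters, which isolates the effect of dynamic range from the
effect of strategy.

One ground truth drives both devices: truths live on the
projection-equivalent scale and each exam subtracts the rounded scale
offset (0 for the projection preset, 14 for the head-mounted preset) before
responding. `run_exam()` also exposes `threshold_shift_db`, an optional
device-effect hook for adaptation-related shifts under different
backgrounds; it defaults to 0 and no test relies on it.

At the defaults, recovery of mid-range thresholds is essentially unbiased
(|bias| well under 1 dB, RMSE under 2.5 dB at 200 replicates per level),
thresholds below the floor return exactly 0 and thresholds above the
ceiling return the range maximum.

## Agreement analysis

`compare_fields()` reproduces the method-comparison pipeline on matched
(subject, eye, location) pairs:

* **Censoring.** Regression uses only pairs whose projection sensitivity is
  *strictly* between 14 and 30 dB — the window where the head-mounted
  device is neither floored nor ceilinged. Boundary values are excluded
  (strict inequalities); the floor-detection contingency instead splits at
  `< 14` vs `>= 14`, matching the conventional table layout.
* **Deming regression** (both variables carry measurement error), on the
  raw scales without offset correction, with the closed-form slope
  $$ b = \frac{s_{yy} - \lambda s_{xx} +
     \sqrt{(s_{yy}-\lambda s_{xx})^2 + 4\lambda s_{xy}^2}}{2 s_{xy}}, $$
  $\lambda$ fixed at 1 (equal error variances — both exams use the same
  engine, so nothing motivates another value). Confidence intervals use the
  leave-one-out jackknife with a normal approximation: distribution-free,
  adequate at the pipeline's sample sizes, and independent of any
  asymptotic variance formula. Degenerate geometries (constant x, zero
  covariance with matched variances) are errors, not silent zeros.
* **Bland-Altman** on pairs with projection sensitivity above 14 dB:
  differences are raw projection minus raw head-mounted values, mean ± 1.96
  SD limits of agreement. Head-mounted floor values are kept as 0 by
  default (`ba_floor_rule = "floor_as_zero"`); `"drop_floored"` excludes
  them instead. Keeping them is the default because the projection-side
  filter already removes genuinely double-low pairs, and discarding floored
  values would hide exactly the disagreement of interest.
* **Floor-detection contingency**: condition-positive = projection below
  14 dB; test-positive = head-mounted estimate exactly at floor (0 dB).
  `diagnostic_metrics()` returns sensitivity $tp/(tp+fn)$ and specificity
  $tn/(tn+fp)$; zero denominators are errors (the metric is undefined, not
  zero).

Global indices (mean sensitivity / mean defect) are deliberately not
computed: with floor effects on one side they average incommensurable
quantities.

```{r report}
sim <- simulate_study(seed = 1)
report <- compare_fields(
  filter(sim$measured, device == "octopus900"),
  filter(sim$measured, device == "iowa_hmp")
)
report
```

In the simulated default cohort the Deming slope is close to 1 and the
mean Bland-Altman difference close to the 14 dB scale offset — as expected,
because the simulation gives both devices identical psychophysics and
differs only in range and quantization. Real paired patient data show a
flatter slope and a mean difference exceeding the offset by about 2 dB,
plausibly from adaptation differences between the two backgrounds; that
physiology is outside the default model (the `threshold_shift_db` hook can
emulate it, but the package does not assert values for it).

## Problem sizes and determinism

The shipped tests and the acceptance script use the default cohort (12
subjects × 2 eyes × 68 locations = 1632 paired locations), 200 replicate
single-location exams per threshold level for recovery checks, and 10,000
draws for the limits-of-agreement coverage property — sizes at which the
stochastic checks are stable under their fixed seeds while a full run
completes in well under a minute. Every stochastic path is reproducible
from one master seed (`simulate_study(seed = )`, or `set.seed()` before the
lower-level generators, which use the session RNG by tidyverse convention).

## Limitations

* Loss-pattern parameters are stipulated; nothing is fitted to patients.
* Per-location independence: no spatial prior or neighbour seeding in the
  exam, no spatially correlated noise in the truths.
* The same ZEST engine stands in for both devices' strategies.
* Background-luminance physiology (Weber-range behaviour, adaptation) is
  not modeled by default.
* Grids are assumed geometrically identical across devices; real headset
  optics may misalign them.
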