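---
title: "Methods: simulating and analysing a 2x2 temperature x pCO2 experiment on neonatal sharks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a 2x2 temperature x pCO2 experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Experiments that cross ocean-warming and ocean-acidification treatments on
large, protected, hard-to-study fishes are chronically small: a handful of
holding tanks per treatment, three or four animals per tank, and a dozen or
more derived traits per animal. `sharkstress` implements the complete
computational chain of such a study — a fully factorial 2x2 design with two
temperatures (28, 31 degC) and two pCO2 levels (650, 1050 uatm), three
replicate tanks of 3–4 neonatal sharks per cell — together with a
synthetic-data generator that produces every raw input with known ground
truth. Because each analysis stage can be fed generated data whose answer is
known, every stage is testable by parameter recovery without the field data.

The pipeline has five analysis layers:

1. **Seawater carbonate chemistry** — total alkalinity from open-cell Gran
   titrations, and pCO2 solved from (pH_NBS, A_T, temperature, salinity).
2. **Respirometry** — six oxygen-uptake metrics from a 24-h
   intermittent-flow trace: MO2Min, MO2Max, absolute and factorial aerobic
   scope, EPOC, recovery time.
3. **Behaviour** — detour-maze lateralisation indices, overall dynamic body
   acceleration (ODBA) with a windowed activity level, and the
   hypoxia-tolerance endpoint.
4. **Haematology** — Drabkin's haemoglobin, haematocrit, MCHC, and a
   pluggable blood-pH temperature correction.
5. **Inference and power** — per-trait Gaussian linear mixed models
   (temperature x pCO2 fixed, replicate tank random), simulation-based
   confidence intervals, inter-individual variability screens, and
   Monte-Carlo power analysis over replicate-group counts.

# The generative model for traits

Every trait is generated from the same linear mixed model the inference
layer fits:

y_ijk = beta_0 + beta_T T_i + beta_C C_j + beta_TC T_i C_j + b_k + e_ijk,

with tank intercepts b_k ~ N(0, sigma_g^2) and residuals
e ~ N(0, sigma_e^2). Treatment effects are specified as *ratios* r relative
to the control mean, the currency of cross-taxon meta-analyses; a ratio
enters the additive model as `(r - 1) * beta_0`. This makes ratio effect
sizes (e.g. 1.67 for temperature, 1.06 for pCO2, 1.60 for their interaction
on minimum oxygen uptake) directly usable as `beta` values, and keeps the
generated effects exactly additive: doubling `(r - 1)` doubles the mean
shift.

Default control means follow values representative of neonatal blacktip
reef sharks (minimum uptake 133.69 mg O2 kg^-0.89 h^-1, haematocrit 0.21,
blood lactate 3.58 mmol/L, ...); residual standard deviations are derived
from the within-group coefficients of variation reported for this species
(15.3% for minimum uptake, 8.4% for haematocrit, ~45% for lactate), and
tank standard deviations are set to 40% of the residual ones — the tank
component is not separately published, and this ratio produces the modest
intra-class correlation (~0.14) typical of replicated-tank designs. Body
masses are truncated-normal, mean 1.0 kg, sd 0.2 kg, bounded to the
observed 0.7–1.4 kg range. Aerobic scope (absolute and factorial) and MCHC
are derived arithmetically from their parents so the algebraic identities
linking them hold exactly, as in real data.

A single experiment seed fans out to per-shark and per-draw child seeds
(`child_seed()`), so enlarging a roster or adding a grid point never
perturbs draws already made.

# Carbonate chemistry

`solve_pco2()` follows the conventional CO2SYS recipe for the constants the
study community uses: K1/K2 from the Mehrbach measurements as refit by
Dickson & Millero (1987) on the seawater pH scale, K0 from Weiss (1974), KB
from Dickson (1990b), KW from Millero (1995), bisulfate from Dickson
(1990a), and total boron proportional to salinity. Choices the user should
know about:

* **NBS-scale pH** readings are converted to seawater-scale hydrogen-ion
  concentration with the Takahashi/Culberson activity factor fH, the
  documented CO2SYS behaviour for NBS input.
* **Fluoride is excluded by default** (the HF contribution at the
  microscale of these waters is negligible and the study reports no
  fluoride data); with it excluded, the total and seawater pH scales
  coincide. Nutrient alkalinity (phosphate, silicate) is assumed zero for
  the same reason.
* The solver partitions total alkalinity into carbonate alkalinity by
  subtracting borate and hydroxide and adding free H+ and bisulfate, then
  speciates DIC with K1/K2 and converts dissolved CO2 to partial pressure
  through K0 and the 1-atm fugacity factor.
* `gran_alkalinity()` computes the Gran function F = (V0 + V) 10^-pH over
  readings with pH in [3.0, 3.5] — the open-cell region where CO2 has been
  protonated and largely degassed — and takes the equivalence volume from
  the x-intercept of a straight-line fit. The x-intercept is invariant to
  the constant activity factor between pH scales, so meter (NBS) readings
  are used as-is. Conversion to umol per kg of seawater uses the EOS-80
  one-atmosphere density, implemented in-package because no installed
  package provides it.

A caveat on published treatment-water tables: treatment means of pCO2
computed per-sample and then averaged need not equal pCO2 computed at the
averaged inputs (the map is nonlinear and inputs covary). Two of the four
treatment rows used as benchmarks agree with the mean-input computation to
well within one printed SD; the other two cannot be matched by *any*
correct solver at their printed inputs — one of them would require pCO2 to
fall with temperature at fixed pH and alkalinity, which thermodynamics
forbids. The corresponding acceptance test asserts all four and documents
the two expected failures.

The titration generator simulates acid additions by mass balance and
solves the same carbonate model for pH at every step (closed-cell DIC; in
the Gran window all DIC is protonated, so degassing affects only the
curvature upstream of the fitted region). Round-trip recovery is within
0.25% noiseless and unbiased to <0.5% under 0.005-pH meter noise.

# Respirometry

The simulated respirometer runs 96 measure/flush cycles over 24 h. The
protocol length and determination count force the cadence: 96 x 15 min =
24 h, so the default is 10 min measure / 5 min flush, bracketed by 30-min
empty-chamber background recordings. The animal's true uptake follows an
exponential post-exercise recovery `MO2(t) = MO2Min + (MO2Max - MO2Min)
exp(-k t)`; within a measure phase the oxygen decline is the exact time
integral of uptake plus background, so a whole-phase regression slope
equals the phase-mean uptake.

Analysis choices:

* One least-squares slope per measure phase; uptake is
  `|slope| * V_eff * 3600 / mass^0.89`, with effective volume = chamber
  minus animal volume (animal volume defaults to mass at 1 kg/L) and the
  intraspecific mass-scaling exponent 0.89. Determinations with R^2 <=
  0.95 are dropped and counted.
* Background respiration is measured in the empty chamber before and
  after the trial, interpolated linearly in time, and subtracted from the
  whole-chamber rate before mass correction. The generator drifts its
  background linearly, so this correction is exact by construction — which
  is precisely what makes biased-vs-corrected comparisons testable.
  Corrected determinations that go negative are excluded, not clipped:
  they indicate drift, and clipping would bias the minimum-uptake estimate
  downward.
* **MO2Min** uses the Mean of the Lowest Normal Distribution: univariate
  Gaussian mixtures with 1–4 components fitted by EM (mclust), the count
  chosen by BIC, returning the lowest component's mean. The cited method
  leaves component selection open; BIC makes it reproducible.
* **MO2Max** is the steepest 30-s rolling-window slope inside measure
  phases of the first hour (windows never span a flush; ties go to the
  first occurrence), with the same volume/mass/background corrections.
* **EPOC and recovery**: a three-parameter decay `a exp(-k t) + c` is
  fitted to the corrected determinations by nonlinear least squares.
  Recovery is when the fitted curve reaches MO2Min and EPOC is the area
  between curve and MO2Min up to that time, both in closed form. The
  strict intersection time diverges logarithmically as `c` approaches
  MO2Min from below and does not exist above it, so the rule is
  regularised continuously: the curve is never required to approach its
  own asymptote closer than 10% of MO2Min; past that point recovery is
  the time excess uptake falls to `0.1 * MO2Min` and the result is
  flagged approximate. For well-separated fits this is exactly the strict
  rule. The generator, whose recovery asymptote *is* MO2Min (an animal
  recovers to its standard metabolism), stores its EPOC/recovery truth
  under the same threshold rule. Analytic areas agree with trapezoidal
  integration of the fitted curve to <0.1%.

On noiseless traces the full pipeline recovers all six metrics within 1%
of stored truth; the mixture step resolves the lower mode of a 0.7/0.3
normal mixture (means 140/260) within 5 units at n = 96.

# Behaviour

* **Lateralisation**: L_R = (R - L)/(R + L) x 100 over 20 turns, ten
  initiated per maze side; L_A = |L_R|.
* **ODBA**: per axis, static acceleration is a centred 2-s running mean —
  with shrinking windows at the trace edges, since the upstream tool's
  edge policy is undocumented and truncation preserves the mean — and
  ODBA is the sum of absolute dynamic components. Whether the original
  processing used a centred or trailing mean is unstated; centred is
  phase-preserving and is what the closed-form checks assume.
* The accelerometry generator's default tail-beat frequency (~1.96 Hz, a
  routine-swimming beat) completes an integer number of cycles per 51-
  sample averaging window, where the running mean's spectral leakage into
  the static estimate is exactly zero and the rectified-sine identity
  (mean ODBA = 2A/pi per axis) holds to <0.1%. Off-grid frequencies bias
  ODBA by up to the window's Dirichlet factor, about 2% — worth knowing
  when interpreting real 25-Hz tag data too.
* **Activity level** is the mean ODBA over a half-open clock window,
  default [11:00, 15:00): half-open so consecutive windows never double
  count a sample; the window starts two hours post-tagging so animals have
  resumed routine activity.
* **Hypoxia tolerance** is the percent air saturation, linearly
  interpolated, at the recorded onset of muscle spasms.

# Haematology

[Hb] follows Beer–Lambert under the cyanmethemoglobin convention with the
millimolar extinction coefficient 11 (per heme). The dilution factor is
201 — 5 uL of whole blood *added to* 1 mL of reagent — and the default
optical path is 0.56 cm, the depth of a 200-uL aliquot in a flat-bottom
96-well plate; both are configurable. MCHC = [Hb]/Hct with duplicate Hct
and triplicate absorbance replicates aggregated by arithmetic mean.
Species-specific temperature corrections of meter pH are not hard-coded
(the published equations live outside this package); `ph_correction()`
accepts any affine map and defaults to the identity.

# Inference

Each trait is fitted with `lmer` (REML for reporting): temperature and
pCO2 as interacting nominal fixed effects, replicate tank as a random
intercept. Significance is judged by 95% percentile intervals of 1000
draws of the fixed-effect vector from N(beta_hat, Vcov(beta_hat)) — the
'sim'-style posterior simulation — with variance components held at their
point estimates. That simplification is a stated limitation: it ignores
uncertainty in sigma_e and sigma_g, so realised coverage sits at the low
edge of nominal (~94% against a 95% target at this design, verified over
500 replicate studies in the acceptance suite). Missing trait values are
handled per-trait complete-case; no multiplicity correction is applied
across the 15 trait models (the Bonferroni correction belongs to the
correlation screen, where 105 tests share one question).

Screens: coefficients of variation are computed within treatment cells and
pooled as the mean of cell CVs, so treatment differences do not inflate
them; all 105 trait pairs get Pearson tests at Bonferroni alpha = 0.0005
with a separate "strong" flag (r > 0.80, p < 0.001); lateralisation
distributions are compared by two-sample Kolmogorov–Smirnov tests (all six
cell pairs, or each against ambient) and variances by Bartlett tests.

# Power analysis

`simulate_power()` simulates from the generative model, refits, and counts
rejections at alpha = 0.05, with Wilson binomial intervals. Two design
choices matter:

* **Test rule.** The nested-ML likelihood-ratio chi-square is
  anticonservative at this design's size (~6.4% measured null rejection at
  36 animals in 12 tanks), so the default single-df test is the t
  statistic with Satterthwaite denominator degrees of freedom (measured
  size 4.0–4.8%); the LRT remains available as `test = "lr"`. With no
  random effect the machinery drops to nested linear models and the exact
  F test, which matches closed-form two-sample t-test power to well within
  two percentage points.
* **Common random numbers.** `required_groups()` evaluates the power curve
  over increasing replicate-group counts with each simulation index
  reusing its child seed, so the curve is monotone up to Monte-Carlo error
  and the threshold search is meaningful. Both the strict answer (first
  count with power > 80%) and a plateau answer (power > 80% and successor
  gain < 2 points) are reported.

`observed_power()` rebuilds a power spec from a fitted trait model's own
estimates — post-hoc power, provided because observed-power numbers are
how such studies report their design's adequacy. Reproducing any
particular published observed-power value requires that study's fitted
variance components, which are not published; the machinery, not those
numbers, is the deliverable.

# What the generator does and does not emulate

It emulates: the factorial design with tank-level random intercepts;
Gaussian trait noise at realistic CVs; multiplicative treatment effect
ratios; truncated-normal body mass; exponential post-exercise recovery
with flush/measure cycling and linearly drifting background respiration;
25-Hz tri-axial acceleration as gravity + sinusoidal tail-beat + sensor
noise; Bernoulli maze turns; titration curves from the full carbonate
model; and blood panels consistent with Beer–Lambert.

It does not emulate: circadian activity rhythms or spontaneous activity
bursts (so MLND faces no genuine upper modes on clean traces), nonlinear
sensor drift, tag-attachment artefacts, non-Gaussian trait distributions,
correlated traits beyond the arithmetically derived ones, water-quality
covariates, or mortality/dropout. Passing recovery tests therefore shows
the analysis chain is correct and calibrated, not that real sharks are
this well behaved.

# Problem sizes and numerical settings

The test and acceptance suites run, on one CPU in a few minutes: 500
replicate studies for CI coverage (1000 posterior draws each), 1000
Monte-Carlo replicates for the null-size check and 3000 for the
degenerate-design comparison, 96-determination 24-h traces at 1 Hz,
100-replicate noisy titrations, and 400-replicate a-priori power at the
realised design. Nonlinear fits use Levenberg–Marquardt with analytic
closed forms downstream; mixture fits cap at 4 components; the Gran window
needs at least 3 points; all tolerances asserted in tests are stated
there.
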