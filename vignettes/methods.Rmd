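---
title: "Methods: skin water loss estimation, fluid-balance accounting, and the synthetic shock cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skin water loss estimation, fluid-balance accounting, and the synthetic shock cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tewlbalance)
```

## The problem

Insensible water loss — evaporation through skin and airways — is invisible
to the ICU fluid-balance chart and is usually approximated by a weight-based
formula. Transepidermal water loss (TEWL) can instead be measured directly
at the bedside with an open-chamber evaporimeter. `tewlbalance` implements
both routes to a 24-h skin water loss, folds either into the daily ledger,
quantifies their disagreement, and tests whether within-patient TEWL
fluctuations track vascular tone (SVRI). This vignette documents the models,
the tunable parameters, the numerical decisions, and what the synthetic
cohort does and does not emulate.

## The two estimators

**Formula route.** For a ventilated patient of weight $W$ (kg) and core
temperature $T$ (°C),

$$L_{\text{formula}} = 10\,W\,\bigl(1 + 0.2\,(T - 37)\bigr)\times 0.6
\quad\text{mL/24 h.}$$

The 20 %/°C correction is applied multiplicatively to the 10 mL/kg base and
the 40 % ventilation reduction multiplies the result; the two factors
commute, which is why the ventilated base rate is equivalently 6 mL/kg/24 h.
Three further conventions, chosen here because the source formula leaves
them open: the correction uses *core* temperature (the 37 °C anchor is a
core-temperature convention); sub-37 °C temperatures correct *downward*
symmetrically at the same 20 %/°C; and the result is floored at zero (the
linear correction crosses zero at 32 °C, below which a negative loss would
be meaningless). `cox_insensible_loss()` is strictly increasing in weight
and temperature on the un-floored range, and the ventilated value is exactly
0.6 × the non-ventilated one — both are enforced by tests.

**Measurement route.** Site TEWL (g/h/m²) at forehead, upper limb, lower
limb and trunk is collapsed with Wallace rule-of-nines fractions — both
lower limbs $2\times18\,\%$, both upper limbs $2\times9\,\%$, head $9\,\%$,
trunk $36\,\%$ — giving weights that sum to **0.99**, not 1: the 1 %
perineum has no measurement site. The weighted flux is deliberately *not*
renormalized by default, matching the clinical extrapolation as practised; a
renormalized mode (`renormalize = TRUE`, ÷0.99) is available for sensitivity
analysis. The whole-body flux is extrapolated as

$$L_{\text{TEWL}} = \text{TEWL}_{wb}\times 24\ \text{h}\times
\text{BSA}(W, H),$$

with grams of water converted to mL at density 1 g/mL. BSA defaults to Du
Bois ($0.007184\,W^{0.425}H^{0.725}$); Mosteller is selectable. A record
with any missing site is excluded from this route and logged — with only
four sites an imputation would dominate the estimate.

The per-record disagreement is reported as the signed relative deviation
$100\,(L_{\text{formula}} - L_{\text{TEWL}})/L_{\text{TEWL}}$, defined only
when $L_{\text{TEWL}} > 0$, and `deviation_regression()` fits it against
$L_{\text{TEWL}}$: a negative slope is the signature of a formula that
overestimates at low measured loss and underestimates at high loss.

## The evaporimeter model

An open-chamber probe holds two humidity/temperature sensor pairs at
heights $z_1 < z_2$ above the skin (defaults 3 mm and 8 mm inside a 2 cm
cylinder). Each reading is converted to an absolute vapor density via the
Magnus saturation pressure $e_s(T) = 6.112\exp(17.62\,T/(243.12+T))$ hPa
and the ideal gas law with $R_v = 461.5$ J kg⁻¹ K⁻¹; the flux follows
Fick's first law,

$$J = D\,\frac{\rho_1 - \rho_2}{z_2 - z_1}\times 3600
\quad\text{g/h/m}^2,$$

with $D = 2.49\times10^{-5}$ m²/s (water vapor in air near 25 °C). All
constants are arguments, since devices do not publish their internals.
Readings outside the device operating range (10–40 °C, 30–70 % RH) warn and
are flagged rather than refused — feasibility data brush these limits. No
rounding is applied internally; the 0.1 g/h/m² reporting resolution is a
display concern.

**Stabilization rule.** The field protocol records at 1 Hz "until the SD of
the current value relative to the running mean is below 0.2 g/h/m²". That
wording does not say whether the running mean is cumulative or windowed, so
`stabilize_tewl()` exposes both. The default is the **windowed** mean
(trailing `window = 10` readings; SD of those readings about that mean,
computed as a population SD so a constant window gives exactly zero):
after an initial probe-equilibration drift, a cumulative mean retains a
bias that decays only like $1/t$, so the value it reports sits near the
threshold itself; the windowed mean tracks the current flux. Convergence
failure within `max_duration_s = 240` s is an explicit flagged result
carrying the last running mean, not an exception. The simulated streams
(`generate_sensor_stream()`) relax exponentially toward the true flux with
time constant `drift_tau_s = 2` s and initial drift rate 1.0 g/h/m²/s plus
Gaussian sensor noise (default SD 0.05): the chamber microclimate
equilibrates within seconds of placement, and the minutes-long site times
of practice are dominated by probe handling, which is not modelled. Under
these defaults the rule converges with the stable value within the 0.2
g/h/m² threshold of truth (property-tested across 100 seeded streams).

## The ledger

`balance = (parenteral + enteral) − (urine + ultrafiltrate + skin loss
[+ other])`, one row per record and skin-loss method, with the identity
`balance = intake − output` held exactly. Drains/stool enter only through
the optional `other_output_ml` column (default 0). Missing fluid fields
mean *absent data*: the record is skipped and logged, never zero-filled.
Group summaries are mean ± SD per shock type with the gated two-group test
attached. No cumulative multi-day tracking and no body-weight
reconciliation is attempted.

## The statistical battery

* **Normality gate**: one-sample Kolmogorov–Smirnov against a normal with
  the sample's own mean/SD, α = 0.05. Estimating parameters from the same
  sample makes this anti-conservative as a test of normality; it is used
  only as a routing gate, and a Lilliefors-corrected variant is selectable.
  Constant samples fail with a `zero_variance` flag.
* **Two-group comparisons**: Welch's *t* when both groups pass the gate,
  two-sided Mann–Whitney U otherwise; the test used is recorded. Identical
  samples are flagged degenerate. The realized type-I error at α = 0.05 is
  property-tested into [0.03, 0.07] (1000 null replicates, n = 100/arm).
* **Paired method comparison**: two-sided Wilcoxon signed-rank on the
  formula − TEWL differences. Zero differences are dropped; absolute
  differences are mid-ranked. For ≤ 25 non-zero differences the p-value is
  **exact by full sign-flip enumeration** (the null distribution of the
  doubled-rank statistic is built by polynomial convolution, so ties are
  handled exactly — the standard exact algorithm refuses ties); beyond 25,
  a tie-corrected normal approximation with continuity correction is used.
  On untied data the enumeration reproduces `wilcox.test(exact = TRUE)` to
  1e-12, which the tests use as an independent cross-check.
* **Site comparison**: one-way ANOVA across the four sites (each
  patient-day panel contributing one value per site), then pairwise
  t-tests on the pooled ANOVA error variance with **step-down Šídák**
  adjustment: order the m raw p's ascending, adjust
  $\tilde p_{(i)} = 1-(1-p_{(i)})^{m-i+1}$, enforce monotonicity, cap at 1.
  Adjusted p dominates raw p, and the family-wise error under a global null
  is property-tested at ≤ 0.05 plus two Monte-Carlo standard errors over
  1000 replicates.
* **Normalization**: `normalize_to_patient_mean()` maps each value to
  $100\,v/\bar v_{patient}$; each patient's normalized mean is 100 to 1e-9
  (an exact identity up to floating point). A single-measurement patient
  contributes the uninformative value 100; such patients are kept by
  default (`include_singletons = TRUE`) since they only dilute, not bias,
  the pooled fit — a switch removes them. Both TEWL and SVRI are
  normalized before the coupling regression; an `absolute = TRUE` mode
  fits the raw scales for contrast.
* Repeated measurements within a patient are treated as independent
  observations in the group comparisons, the ANOVA and the regressions.
  This mirrors the analysis being reproduced and its stated n; it is a
  known limitation (it understates standard errors), stated rather than
  corrected — no mixed-effects layer is fitted.

## What the synthetic cohort emulates

`cohort_config()` defaults encode the structure of a two-arm feasibility
cohort: 5 septic + 3 cardiogenic patients, 2–6 daily measurements each,
one patient per arm without SVRI (no invasive monitor), leaving roughly 19
SVRI-paired records in about 26.

* **Site TEWL** is log-normal (strictly positive and right-skewed, matching
  SD/mean ratios near 1): trunk and limbs mean 6.83, SD 5.92 g/h/m²; the
  forehead mean is `forehead_multiplier = 1.553` × the trunk mean (10.61
  g/h/m²) with the same coefficient of variation. One base panel is drawn
  per patient; day-to-day variation enters through the coupling factor
  below.
* **SVRI** is drawn per patient-day: septic 1400 ± 350, cardiogenic
  2800 ± 700 dyn·s·cm⁻⁵·m² (vasodilated vs. afterload-elevated), i.e. a
  25 % day-to-day coefficient of variation in both arms, so the
  percent-normalized spread is ~25 points. An optional AR(1) parameter
  (`day_ar1`, default 0 = independent days) exposes within-patient
  autocorrelation, which the source data do not quantify.
* **Coupling** is planted on the percent-of-mean scale — the scale on which
  the association is analysed: normalized whole-body TEWL
  $= 100 + \beta\,(\text{SVRI}_{\%} - 100) + \varepsilon$, with
  $\beta = -1$ and $\varepsilon \sim N(0, 24)$ by default. With a 25-point
  SVRI spread this puts the expected normalized R² at
  $25^2/(25^2+24^2) \approx 0.52$, the documented coupling strength. The
  day's whole panel is scaled by the resulting factor, so site ratios are
  preserved within patient.
* **Fluids** are Gaussian per arm with the documented group means/SDs
  (parenteral 4581 ± 1337 vs 3012 ± 715 mL; enteral 137 ± 268 vs
  354 ± 372; urine 841 ± 873 vs 897 ± 1176; ultrafiltrate 426 ± 585 vs
  1728 ± 1454), negative draws truncated at 0 (simple, slightly biasing
  means upward at extreme SDs — documented, not resampled).
  Anthropometrics: weight 80 ± 15 kg, height 172 ± 9 cm, core temperature
  37.3 ± 0.8 °C; all patients ventilated.

Not emulated: physiological time dynamics (diurnal rhythm, treatment
response), death/censoring, arm differences in site TEWL (both arms share
one site distribution, since no significant arm difference in skin loss is
reported — as a consequence the synthetic septic arm's TEWL-based loss mean
sits below the cohort's printed septic value while the cardiogenic arm
matches closely), and any correlation between temperature and TEWL. Passing
tests therefore certify the pipeline's arithmetic, routing and recovery
properties under this structure — not the behaviour of real skin on real
patients.

All generation is seeded; the same configuration and seed reproduce a
byte-identical cohort, and the generating truth (seed, coupling, per-patient
base panels) is returned and written alongside the records.

## Problem sizes in the test suite

Property tests use sizes chosen to keep Monte-Carlo error well inside the
asserted bands: 1000 replicates for the type-I-error and family-wise-error
checks (binomial SE ≈ 0.007 at 0.05); 100 feasibility-size cohorts for
small-n slope recovery (mean slope within ±0.35 of −1); 10 cohorts of ~200
records for large-n recovery (each slope in [−1.35, −0.65], mean within
±0.15); 100 seeded streams for stabilization convergence; 150 + 90 patients
when checking generator means. The acceptance script averages the
normalized coupling over 30 feasibility-size cohorts and uses a 240-patient
cohort for the arm-level means.

## Known limitations

* The independence treatment of repeated measures (above) is faithful to
  the analysis being reproduced, not statistically ideal.
* The plain KS gate is anti-conservative with estimated parameters; the
  Lilliefors option exists but is not the default, to keep the default
  battery aligned with common practice.
* Zero-truncation of Gaussian fluid draws biases arm means slightly upward
  when SD/mean is large (ultrafiltrate in the septic arm is the worst
  case).
* The stabilization rule's windowed-mean default is one reading of an
  ambiguous protocol; analyses sensitive to it should sweep
  `mean_mode` and `window`.
* The evaporimeter constants (Magnus coefficients, $R_v$, $D$, sensor
  heights) are textbook values, not a specific device's calibration.
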