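---
title: "Methods: sensor-adjusted regulated deficit irrigation in closed loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-adjusted regulated deficit irrigation in closed loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdisim)
```

# The model

`rdisim` simulates a season of automated regulated deficit irrigation (RDI)
as a daily control loop with four coupled parts.

**Atmospheric demand.** Reference evapotranspiration comes from the daily
FAO-56 chain. `eto_penman_monteith()` is the standard reference-crop
formulation (soil heat flux zero at the daily step, albedo 0.23,
elevation-derived psychrometric constant, the 900/(T+273) and 0.34·u2
aerodynamic terms); when no radiation measurement exists it falls back to
the temperature-range estimate Rs = 0.16·√(Tmax−Tmin)·Ra and flags the
output, because automated stations at remote control points often carry
only an air-temperature sensor. `eto_hargreaves()` (0.0023 · 0.408·Ra ·
(Tmean+17.8) · √(Tmax−Tmin)) is what the simulated controller actually
uses, for the same reason. On synthetic Mediterranean years the annual
Hargreaves total sits a few percent above Penman–Monteith, consistent with
the known warm-season bias of temperature-based methods.

**Crop demand and the deficit strategy.** `ETc = ETo × Kc`. Two crop
coefficient curves matter: a *standard* curve describing what the crop
would transpire unrestrained, and a *deficit-modified* curve, deliberately
lowered between pit hardening and veraison (Phase II), that encodes the RDI
strategy. In the closed loop the soil loses water at the standard-Kc rate
while the controller doses at the modified-Kc rate — that asymmetry is what
dries the profile and expresses stress in Phase II. The default breakpoint
values (0.50–0.65 standard, dropping to 0.30 in the deficit window) are
plausible placeholders for a hedgerow olive orchard, not published
calibrations, and are expected to be replaced per campaign via the config.

**The daily decision.** `daily_dose()` computes
`base = max(0, Kc_mod·ETo − P_eff)`, multiplies by the sensor feedback
factor, then enforces the seasonal-plan envelope as a hard constraint
(truncate at the upper curve, top up to the lower curve). Effective rain
uses `P_eff = 0.75 · max(0, rain − 2 mm)`: a 2 mm canopy/surface wetting
loss, then a fixed credited fraction. No standard definition exists for
this quantity, so the rule is isolated in `effective_rain()` and
configurable.

**Sensor feedback.** Raw volumetric readings are normalized per sensor
between two campaign-specific anchors: the *high reference* (the reading at
field capacity, estimated by `estimate_high_reference()` as the median of
the 24–72 h post-drainage plateau after the largest rain event — the
plateau, not the transient peak) and the *low reference* (the campaign's
running driest value, `update_low_reference()`; `estimate_low_reference()`
adds a 5-sample running-median before taking daily minima so isolated noise
excursions do not pull the anchor down). Normalized indices are aggregated
to a point index by `aggregate_point()` with class weights 0.5/0.3/0.2 for
under-dripper 0.30 m, under-dripper 0.60 m, and between-dripper sensors;
faulty sensors (out-of-range, stuck, spike) are excluded and weights
renormalized, never imputed. The feedback law itself
(`feedback_factor()`) is a deliberately simple stand-in for proprietary
controllers whose rule is unpublished: piecewise-linear, exactly 1 inside
the comfort zone, clamped to [1−g, 1+g], and exactly 1 when no sensor
signal survives — which makes "sensors disabled equals pure water balance"
a provable identity rather than an approximation.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| feedback gain `g` | 0.3 | – | ±30% authority keeps the controller inside the envelope's ±20% headroom |
| comfort zone | [0.4, 0.8] | normalized | deficit target sits below field capacity but above stress collapse |
| envelope half-width | 0.2 | fraction of baseline | wide enough to let feedback act, narrow enough to bound a failed sensor |
| ψ proxy endpoints | −0.6 / −2.8 | MPa | spans the observed range of midday stem water potential in deficit-irrigated hedgerow olive |
| ψ thresholds | −1.4 / −2.0 / −1.6 | MPa | phase targets of a light-RDI strategy (most severe at pit hardening) |
| Kc breakpoints | 0.50–0.65; 0.30 in Phase II | – | placeholder hedgerow-olive values, config-replaceable |
| drainage coefficient | 0.5 | d⁻¹ | fraction of above-FC excess drained per day |
| wetting fractions | A 0.6; B 0.3×A, 1-day lag | – | drip wets a bulb under the emitter; between-dripper soil responds weaker and later |
| emitter geometry | 1.6 L/h, 0.67 m × 4 m | | gives an application rate of ≈0.60 mm/h |
| ECa / NDVI class breaks | 10, 15 mS/m / 0.40, 0.45 | | three-class management-zone convention; boundaries belong to the class above |

# What the synthetic layer emulates — and what it does not

`gen_weather()` produces sinusoidal temperature seasonality with Gaussian
noise, humidity opposite the temperature cycle, and rainfall from a
month-dependent Bernoulli/gamma process scaled so the expected wet-season
(October–May) share equals 80%. It does *not* produce multi-day frontal
persistence, heat waves, or interannual autocorrelation.

`gen_soil_traces()` is a two-layer (0–0.30, 0.30–0.60 m), two-column
(under-dripper A, between-dripper B) bucket: layer storage gains wetted
dose plus rain, loses partitioned uptake bounded by wilting point, and
drains above-FC excess downward (out of the system from the bottom layer).
Sensors read their column/layer with a per-campaign gain and offset and
i.i.d. noise, clipped to porosity. This reproduces the features the sensor
pipeline needs to have real work to do — persistent sensor-to-sensor
variability, depth attenuation, delayed between-dripper response, a
field-capacity plateau after heavy rain — but it is not Richards-equation
physics: no 3-D wet-bulb geometry, no hysteresis, no root growth.
`gen_stress_proxy()` is an affine map from profile water status to a stem
water potential proxy; it is monotone by construction, so closed-loop
stress ordering tests exercise the controller, not plant physiology.

Consequently, passing tests demonstrate that the *decision chain* is
correct and bounded under its stated assumptions — not that the package
predicts real orchard yields.

`gen_field_truth()` builds band-limited (60–250 m wavelength) cosine-mixture
surfaces, so kriging from a noiseless transect survey can recover the zone
map almost exactly; real ECa fields have nugget effects and anisotropy the
defaults do not include (both are representable: the variogram model has a
nugget, and noise is a survey parameter). The survey generator keeps the
published geometry (4 m transects, 2.5 m along-line) and exposes a
`coverage` fraction for campaigns that do not tile the whole plot.

# Numerical choices

- **Half-open conventions everywhere**: phase membership `[start, next)`,
  class breaks `[low, high)` with boundary values assigned upward.
- **Kriging**: the semivariogram diagonal is forced to zero so the
  predictor is exact at sample points when the nugget is zero; duplicate
  coordinates are averaged before solving; each cell solves a local system
  over the 16 nearest samples within 50 m (global solve available for toy
  sizes). Weights sum to 1 by the unbiasedness row; the variance is floored
  at zero.
- **Variogram fit**: weighted least squares (weights = pair counts) in
  log-parameter space from two starts; a collapsed partial sill returns an
  explicit pure-nugget model with a warning rather than a spurious
  structure.
- **Duncan's test**: critical ranges from the studentized range at
  protection level (1−α)^(p−1), harmonic-mean group size for unequal n,
  and the step-down rule that nothing inside a non-significant span is
  declared significant; letters are the maximal non-significant stretches
  of the ordered means, so the display is transitive-consistent by
  construction. Residual MSE below 1e-10 × var(values) is treated as the
  zero-variance degenerate case (exact-fit ANOVA leaves ~1e-31, not 0).
- **Negative ETo** under extreme Penman–Monteith inputs is floored at zero
  with a warning count; normalization clips to [−0.25, 1.25] but reports
  clip flags instead of discarding information.
- **Determinism**: every generator draws from a locally seeded RNG
  (`.Random.seed` is saved and restored), with per-component stream seeds
  derived from one master seed, kept below 2³¹.

# Design choices where the design was open

- The envelope curves are symmetric percentages of the baseline (default
  ±20%) with an explicit-curve override, since only the existence of
  max/min curves — not their shape — is specified in practice.
- References are per-sensor and per-campaign; configured seeds are
  overwritten once qualifying events are observed, reflecting that such
  systems re-anchor dynamically year to year.
- The uncovered zone-rule combination (medium/high ECa with low NDVI) is
  labelled `unclassified` rather than forced into a zone.
- The aggregation weights over sensor classes are a package convention
  (operational systems do not disclose theirs); they are arguments, and
  aggregation is invariant to sensor order and zero-weight duplication.

# Problem sizes

The shipped tests and the acceptance script use one-year daily seasons
(244 in-season days), 100 randomized seasons for the envelope-invariance
property, a 30 × 31-cell 10 m grid (9.3 ha) for zoning, ~1,900-point
noiseless surveys thinned 4× for variogram estimation, and 5-minute sensor
cadences over 40 days for reference recovery. These sizes were chosen so
every property is exercised at full fidelity while a complete run remains a
desk-scale computation.

# Known limitations

- One dose per day at a fixed hour; no pulsed irrigation, hydraulic
  network, or valve latency.
- Phase dates are inputs; no thermal-time phenology prediction.
- No soil-specific dielectric calibration of capacitance readings.
- The Hargreaves/Penman–Monteith agreement statistic depends on the
  synthetic radiation model; it is a qualitative anchor, not a calibration.
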