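# rdisim

Closed-loop simulation and analysis of **sensor-adjusted regulated deficit
irrigation (RDI)** in drip-irrigated orchards, with the management-zone
delineation used to site the monitoring points.

## The problem

Hedgerow (super-high-density) olive orchards are irrigated daily by drip and
are deliberately *under*-irrigated during the drought-tolerant phenophase
between pit hardening and veraison (Phase II), to restrain vigor without
hurting oil yield. Automating that strategy requires three pieces that this
package implements end to end:

1. **A feed-forward water balance.** Daily reference evapotranspiration
   (FAO-56 Penman–Monteith, or Hargreaves where only air temperature is
   available) scaled by a deficit-modified crop coefficient:
   `ETc = ETo × Kc`, dose = `max(0, Kc_mod · ETo − P_eff)`.
2. **Soil-moisture-sensor feedback.** Capacitance-sensor readings are
   normalized per sensor between a *high reference* (the reading at field
   capacity, observed after out-of-season rain) and a *low reference* (the
   running driest value of the campaign), aggregated to a per-point index
   `θ* ∈ [0, 1]`, and mapped through a piecewise-linear comfort-zone law to
   a dose multiplier in `[1 − g, 1 + g]`.
3. **A bounded seasonal plan.** Cumulative irrigation must stay between a
   lower and an upper envelope drawn around the pre-season baseline
   `Σ max(0, Kc_mod · ETo_clim − P_eff,clim)`, so the automation can never
   run away from the agronomist's intent.

Because no field data ship with the package, a first-class synthetic layer
generates every input with known ground truth: Mediterranean daily weather,
a two-layer / two-column drip-wetted soil bucket with per-sensor gain,
offset and noise, a stem-water-potential proxy, smooth ECa and vigor fields
with transect surveys, and NDVI-consistent reflectance rasters. Zone
delineation (empirical variogram → weighted-least-squares fit → ordinary
kriging → three-class maps → rule-based combination) and the agronomic
summary arithmetic (phase totals, water productivity, maturity index,
one-way ANOVA with Duncan's multiple range letters) complete the pipeline.

## Worked example

```r
library(rdisim)

w <- gen_weather(weather_scenario(), year = 2016, seed = 42)
season <- run_season(w, seed = 42)
print(season)
#> rdi_season: 2016-03-01 to 2016-10-30 (244 days), total irrigation 439.2 mm
#>   Phase I 201.1 | Phase II 149.0 | Phase III 89.0 mm
summary(season)
#>   phase days irrigation_mm mean_index mean_psi_proxy mean_factor
#> 1     I  122           201     0.7084          -1.06       0.965
#> 2    II   76           149     0.0891          -2.24       1.238
#> 3   III   46            89     0.1588          -2.56       1.181
```

The summary shows the deficit strategy working: in Phase II the normalized
soil-water index collapses (0.71 → 0.09), the stress proxy falls from
−1.06 to −2.24 MPa (between the −2.0 MPa Phase II target and full
depletion), and the feedback factor pushes against the drying (1.24) while
the plan envelope keeps cumulative irrigation bounded.

Metrics follow the field-study table conventions:

```r
water_productivity(5490, 232)  # kg/ha of fruit per mm of irrigation
#> [1] 23.66
dose_to_runtime(2)             # hours to apply 2 mm with 1.6 L/h drippers
#> [1] 3.35
```

`run_pipeline(validate_config(system.file("extdata", "example_config.yaml",
package = "rdisim")), "run1")` executes generation → zoning → season →
metrics into a self-describing directory with a checksum manifest.

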