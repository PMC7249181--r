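Package: rdisim
Title: Closed-Loop Simulation of Sensor-Adjusted Regulated Deficit Irrigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing automated regulated deficit
    irrigation (RDI) in drip-irrigated orchards. Implements FAO-56 reference
    evapotranspiration (Penman-Monteith and Hargreaves), crop-coefficient water
    balance, a seasonal cumulative-irrigation plan with bounding envelopes, and
    a daily irrigation controller that readjusts the water-balance dose with
    feedback from normalized capacitance soil-moisture sensors. Includes a
    synthetic-data layer (Mediterranean weather, two-layer soil buckets with
    per-sensor gain/offset, apparent electrical conductivity surveys,
    reflectance rasters), management-zone delineation from kriged ECa and NDVI
    maps, and agronomic summary statistics (phase irrigation totals, water
    productivity, maturity index, one-way ANOVA with Duncan's multiple range
    letters).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
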