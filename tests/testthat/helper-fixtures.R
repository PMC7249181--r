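# Shared fixtures, built in code.

# weather with a fixed diurnal cycle and no rain: ETo is positive and smooth
make_dry_weather <- function(n = 30, year = 2016, tmean = 22, drange = 12,
                             start = sprintf("%d-06-01", year)) {
  dates <- seq(as.Date(start), by = "day", length.out = n)
  w <- data.frame(
    date = dates, doy = as.integer(format(dates, "%j")),
    tmin = tmean - drange / 2, tmax = tmean + drange / 2, tmean = tmean,
    rh_mean = 50, wind_2m = 2, solar_radiation = 25, rainfall = 0
  )
  attr(w, "latitude") <- 38.82
  attr(w, "elevation") <- 185
  w
}

# identity-sensor soil: gain 1, offset 0, no noise
identity_soil <- function(...) {
  soil_bucket_params(sensor_gain_sd = 0, sensor_offset_sd = 0, noise_sd = 0, ...)
}

# fixed four-group dataset whose Duncan letters were hand-derived with the
# studentized-range table procedure (protection level (1-alpha)^(p-1))
duncan_fixture <- function() {
  list(
    values = c(
      10.1, 9.8, 10.3, 10.0, 9.9,
      10.2, 10.5, 10.1, 10.4, 10.3,
      14.5, 14.8, 14.9, 14.6, 14.7,
      14.6, 15.0, 14.8, 15.2, 14.7
    ),
    groups = rep(c("A", "B", "C", "D"), each = 5),
    expected = c(D = "a", C = "a", B = "b", A = "c")
  )
}

# small spherical-variogram toy configuration for kriging oracles
krige_toy <- function() {
  list(
    x = c(0, 40, 0, 40), y = c(0, 0, 40, 40),
    value = c(10, 12, 11, 15),
    vgm = structure(
      list(nugget = 0, psill = 8, range = 60, model = "spherical"),
      class = "variogram_model"
    )
  )
}
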