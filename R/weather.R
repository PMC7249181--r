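#' Describe a synthetic weather scenario
#'
#' Parameterizes a Mediterranean-type annual weather cycle: sinusoidal
#' temperature seasonality with additive noise, rainfall concentrated in a wet
#' season, and simple relative-humidity / wind climatologies. Defaults emulate
#' the inland southwestern-Iberia climate of a commercial hedgerow olive plot:
#' a June-September dry season, about 80% of annual precipitation between
#' October and May, long-term mean annual rainfall near 504 mm and reference
#' evapotranspiration near 1190 mm.
#'
#' @param latitude site latitude, degrees (positive north).
#' @param elevation site elevation, m above sea level.
#' @param year_length days in the generated year.
#' @param t_annual_mean annual mean temperature, degC.
#' @param t_amplitude semi-amplitude of the seasonal temperature cycle, degC.
#' @param diurnal_range_mean mean Tmax - Tmin, degC.
#' @param wet_season_months integer months (1-12) forming the wet season.
#' @param annual_rainfall expected annual rainfall, mm.
#' @param wet_season_rain_fraction expected share of rainfall falling in the
#'   wet season, in `[0, 1]`.
#' @param rh_mean annual mean relative humidity, percent.
#' @param wind_mean mean wind speed at 2 m, m/s.
#' @return an object of class `"weather_scenario"` (a validated list).
#' @examples
#' sc <- weather_scenario()
#' w <- gen_weather(sc, seed = 1)
#' head(w)
#' @export
weather_scenario <- function(latitude = 38.82,
                             elevation = 185,
                             year_length = 365L,
                             t_annual_mean = 16.5,
                             t_amplitude = 9,
                             diurnal_range_mean = 12,
                             wet_season_months = c(10:12, 1:5),
                             annual_rainfall = 503.56,
                             wet_season_rain_fraction = 0.8,
                             rh_mean = 68,
                             wind_mean = 1.8) {
  if (annual_rainfall < 0) stop("annual_rainfall must be >= 0")
  if (wet_season_rain_fraction < 0 || wet_season_rain_fraction > 1) {
    stop("wet_season_rain_fraction must be in [0, 1]")
  }
  if (t_amplitude < 0) stop("t_amplitude must be >= 0")
  if (diurnal_range_mean < 0) stop("diurnal_range_mean must be >= 0")
  if (year_length < 1) stop("year_length must be >= 1")
  if (!all(wet_season_months %in% 1:12)) stop("wet_season_months must be months 1-12")
  structure(list(
    latitude = latitude, elevation = elevation,
    year_length = as.integer(year_length),
    t_annual_mean = t_annual_mean, t_amplitude = t_amplitude,
    diurnal_range_mean = diurnal_range_mean,
    wet_season_months = as.integer(wet_season_months),
    annual_rainfall = annual_rainfall,
    wet_season_rain_fraction = wet_season_rain_fraction,
    rh_mean = rh_mean, wind_mean = wind_mean
  ), class = "weather_scenario")
}

#' Generate one year of daily weather
#'
#' Daily minimum/maximum/mean air temperature follow a sinusoid peaking in
#' late July plus AR-free Gaussian noise; relative humidity moves opposite to
#' the temperature cycle; solar radiation is a clear-sky fraction of
#' extraterrestrial radiation reduced on rain days; rainfall occurrence is a
#' month-dependent Bernoulli process with gamma-distributed depths, scaled so
#' the expected wet-season share equals the scenario's
#' `wet_season_rain_fraction`.
#'
#' @param scenario a [weather_scenario()].
#' @param year calendar year used for the date column.
#' @param seed integer seed; identical seeds give identical series.
#' @return a `data.frame` with columns `date`, `doy`, `tmin`, `tmax`, `tmean`,
#'   `rh_mean`, `wind_2m`, `solar_radiation` (MJ m-2 d-1) and `rainfall` (mm),
#'   with the scenario's `latitude` and `elevation` attached as attributes.
#' @export
gen_weather <- function(scenario = weather_scenario(), year = 2016L, seed = 1L) {
  stopifnot(inherits(scenario, "weather_scenario"))
  n <- scenario$year_length
  start <- as.Date(sprintf("%04d-01-01", year))
  dates <- seq(start, by = "day", length.out = n)
  doy <- as.integer(format(dates, "%j"))
  month <- as.integer(format(dates, "%m"))

  with_seed(derive_seed(seed, "weather"), {
    # temperature: annual sinusoid, peak ~ doy 205 (late July)
    cyc <- cos(2 * pi * (doy - 205) / 365.25)
    tmean <- scenario$t_annual_mean + scenario$t_amplitude * cyc + rnorm(n, 0, 1.5)
    # diurnal range wider in summer (drier air), never negative
    drange <- pmax(2, scenario$diurnal_range_mean + 3 * cyc + rnorm(n, 0, 1.5))
    tmax <- tmean + drange / 2
    tmin <- tmean - drange / 2

    # rainfall: month-dependent occurrence, gamma depths
    wet <- month %in% scenario$wet_season_months
    n_wet <- sum(wet); n_dry <- n - n_wet
    f <- scenario$wet_season_rain_fraction
    total <- scenario$annual_rainfall
    mean_depth <- 6 # mm per rain day
    p_wet <- if (n_wet > 0) min(0.95, total * f / (mean_depth * n_wet)) else 0
    p_dry <- if (n_dry > 0) min(0.95, total * (1 - f) / (mean_depth * n_dry)) else 0
    occurs <- rbinom(n, 1, ifelse(wet, p_wet, p_dry)) == 1L
    rainfall <- numeric(n)
    if (total > 0 && any(occurs)) {
      rainfall[occurs] <- rgamma(sum(occurs), shape = 0.9, scale = mean_depth / 0.9)
    }

    # humidity opposite the temperature cycle, wetter on rain days
    rh <- scenario$rh_mean - 12 * cyc + 8 * (rainfall > 0) + rnorm(n, 0, 4)
    rh <- pmin(100, pmax(15, rh))
    wind <- pmax(0.3, scenario$wind_mean + rnorm(n, 0, 0.6))

    ra <- extraterrestrial_radiation(scenario$latitude, doy)
    kt <- ifelse(rainfall > 0, runif(n, 0.25, 0.5), runif(n, 0.6, 0.75))
    rs <- kt * ra

    out <- data.frame(
      date = dates, doy = doy, tmin = tmin, tmax = tmax, tmean = tmean,
      rh_mean = rh, wind_2m = wind, solar_radiation = rs, rainfall = rainfall
    )
    attr(out, "latitude") <- scenario$latitude
    attr(out, "elevation") <- scenario$elevation
    out
  })
}

#' Write / read the daily weather CSV dialect
#'
#' ISO-8601 dates; latitude and elevation carried as commented header lines so
#' round-trips preserve the metadata the Penman-Monteith model needs.
#'
#' @param weather a weather data.frame from [gen_weather()].
#' @param path file path.
#' @return `read_weather_csv` returns the weather data.frame.
#' @export
write_weather_csv <- function(weather, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# latitude: %.6f", attr(weather, "latitude") %||% NA_real_), con)
  writeLines(sprintf("# elevation: %.2f", attr(weather, "elevation") %||% NA_real_), con)
  write.csv(weather, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  num <- function(x) suppressWarnings(as.numeric(sub("^#.*: *", "", x)))
  out <- read.csv(path, comment.char = "#")
  out$date <- as.Date(out$date)
  attr(out, "latitude") <- num(hdr[1])
  attr(out, "elevation") <- num(hdr[2])
  out
}
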