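#' Extraterrestrial radiation (FAO-56)
#'
#' Daily extraterrestrial radiation Ra from the standard astronomical chain:
#' inverse relative Earth-Sun distance, solar declination and sunset hour
#' angle.
#'
#' @param latitude degrees, positive north; must satisfy `abs(latitude) <= 66.5`
#'   for the standard daily formulation.
#' @param day_of_year integer day of year, 1-366 (vectorized).
#' @return Ra in MJ m-2 d-1.
#' @export
extraterrestrial_radiation <- function(latitude, day_of_year) {
  if (any(abs(latitude) > 66.5)) {
    stop("latitude beyond +/-66.5 degrees: polar day/night breaks the daily Ra formula")
  }
  if (any(day_of_year < 1 | day_of_year > 366)) stop("day_of_year must be in 1..366")
  gsc <- 0.0820 # solar constant, MJ m-2 min-1
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * day_of_year / 365)
  delta <- 0.409 * sin(2 * pi * day_of_year / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Hargreaves reference evapotranspiration
#'
#' `ETo = 0.0023 * (0.408 * Ra) * (Tmean + 17.8) * sqrt(Tmax - Tmin)`,
#' with Ra converted from MJ m-2 d-1 to mm-equivalent by the 0.408 factor.
#' Negative results (Tmean below -17.8 degC) are floored at zero.
#'
#' @param tmean,tmax,tmin daily air temperatures, degC (vectorized).
#' @param ra extraterrestrial radiation, MJ m-2 d-1.
#' @return ETo in mm/day.
#' @export
eto_hargreaves <- function(tmean, tmax, tmin, ra) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  pmax(0, 0.0023 * 0.408 * ra * (tmean + 17.8) * sqrt(tmax - tmin))
}

# saturation vapour pressure (kPa) at air temperature T (degC), FAO-56
svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

#' FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Daily reference-crop formulation with soil heat flux G = 0: net shortwave
#' with albedo 0.23, net longwave from the Stefan-Boltzmann term with humidity
#' and cloudiness corrections, psychrometric constant from elevation-derived
#' pressure, and the 900/(T+273) * 0.34 u2 aerodynamic terms. When
#' `solar_radiation` is missing, it is estimated from the diurnal temperature
#' range (Rs = krs * sqrt(Tmax - Tmin) * Ra, krs = 0.16 for interior sites)
#' and the result carries attribute `radiation_estimated = TRUE`.
#' Negative ETo under extreme inputs is floored at 0; the number of floored
#' days is returned as attribute `n_floored`.
#'
#' @param tmean,tmax,tmin air temperatures, degC (vectorized).
#' @param rh_mean mean relative humidity, percent.
#' @param wind_2m wind speed at 2 m, m/s.
#' @param latitude site latitude, degrees.
#' @param day_of_year day of year (needed for Ra / clear-sky radiation).
#' @param solar_radiation measured solar radiation, MJ m-2 d-1, or `NULL`.
#' @param elevation site elevation, m.
#' @return ETo in mm/day.
#' @export
eto_penman_monteith <- function(tmean, tmax, tmin, rh_mean, wind_2m,
                                latitude, day_of_year,
                                solar_radiation = NULL, elevation = 185) {
  for (nm in c("tmean", "tmax", "tmin", "rh_mean", "wind_2m", "latitude", "day_of_year")) {
    v <- get(nm)
    if (is.null(v) || any(is.na(v))) stop("missing required input: ", nm)
  }
  if (any(rh_mean < 0 | rh_mean > 100)) stop("rh_mean must be within [0, 100]")

  ra <- extraterrestrial_radiation(latitude, day_of_year)
  estimated <- FALSE
  rs <- solar_radiation
  if (is.null(rs)) {
    rs <- 0.16 * sqrt(pmax(0, tmax - tmin)) * ra
    estimated <- TRUE
  }

  p <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26 # kPa
  gamma <- 0.000665 * p
  delta <- 4098 * svp(tmean) / (tmean + 237.3)^2
  es <- (svp(tmax) + svp(tmin)) / 2
  ea <- rh_mean / 100 * es

  rso <- (0.75 + 2e-5 * elevation) * ra
  rns <- (1 - 0.23) * rs
  sigma <- 4.903e-9 # MJ K-4 m-2 d-1
  rel <- pmin(1, ifelse(rso > 0, rs / rso, 1))
  rnl <- sigma * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(0, ea))) * (1.35 * rel - 0.35)
  rn <- rns - rnl

  num <- 0.408 * delta * rn +
    gamma * 900 / (tmean + 273) * wind_2m * pmax(0, es - ea)
  den <- delta + gamma * (1 + 0.34 * wind_2m)
  eto <- num / den
  n_floored <- sum(eto < 0)
  if (n_floored > 0) {
    warning(n_floored, " day(s) produced negative ETo; floored at 0")
  }
  out <- pmax(0, eto)
  attr(out, "radiation_estimated") <- estimated
  attr(out, "n_floored") <- n_floored
  out
}

#' Crop evapotranspiration
#'
#' `ETc = ETo * Kc`.
#'
#' @param eto reference evapotranspiration, mm/day.
#' @param kc crop coefficient, unitless, `>= 0`.
#' @return ETc in mm/day.
#' @export
etc_crop <- function(eto, kc) {
  if (any(kc < 0)) stop("kc must be >= 0")
  eto * kc
}

#' Compute daily ETo series for a weather table
#'
#' Convenience wrapper applying [eto_penman_monteith()] and/or
#' [eto_hargreaves()] to the weather CSV dialect of [gen_weather()].
#'
#' @param weather a weather data.frame (see [gen_weather()]).
#' @param method `"penman-monteith"`, `"hargreaves"` or `"both"`.
#' @param use_radiation logical; if `FALSE` the Penman-Monteith model ignores
#'   the measured radiation column and uses the temperature-based estimate, as
#'   at stations with only an air-temperature sensor.
#' @return the weather data.frame with added columns `ra` and `eto_pm` and/or
#'   `eto_h`.
#' @export
eto_series <- function(weather, method = c("both", "penman-monteith", "hargreaves"),
                       use_radiation = TRUE) {
  method <- match.arg(method)
  lat <- attr(weather, "latitude") %||% stop("weather table lacks a latitude attribute")
  elev <- attr(weather, "elevation") %||% 185
  out <- weather
  out$ra <- extraterrestrial_radiation(lat, weather$doy)
  if (method %in% c("both", "hargreaves")) {
    out$eto_h <- eto_hargreaves(weather$tmean, weather$tmax, weather$tmin, out$ra)
  }
  if (method %in% c("both", "penman-monteith")) {
    rs <- if (use_radiation) weather$solar_radiation else NULL
    out$eto_pm <- as.numeric(eto_penman_monteith(
      weather$tmean, weather$tmax, weather$tmin, weather$rh_mean,
      weather$wind_2m, lat, weather$doy, solar_radiation = rs, elevation = elev
    ))
  }
  out
}
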