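#' Effective rainfall
#'
#' Converts gross daily rainfall to the fraction credited against crop
#' demand. Default convention: subtract a 2 mm canopy/surface wetting loss,
#' then credit 75% of the remainder (the rest is assumed lost to runoff and
#' evaporation). Small events below the threshold yield no credit.
#'
#' @param rain gross rainfall, mm/day (vectorized).
#' @param threshold wetting loss subtracted, mm.
#' @param cap_frac credited fraction of the above-threshold remainder.
#' @return effective rainfall, mm/day.
#' @export
effective_rain <- function(rain, threshold = 2, cap_frac = 0.75) {
  if (any(rain < 0)) stop("rain must be >= 0")
  cap_frac * pmax(0, rain - threshold)
}

#' Sensor-feedback multiplier on the water-balance dose
#'
#' Piecewise-linear clamped law: 1 anywhere inside the comfort zone; rising
#' linearly to `1 + gain` as the index falls from the zone's lower edge to 0;
#' falling linearly to `1 - gain` as it rises from the upper edge to 1;
#' clamped to `[1 - gain, 1 + gain]`. A missing index (`NA`, "no signal")
#' returns exactly 1, reducing the controller to pure water balance.
#'
#' This explicit, swappable law stands in for the proprietary feedback rule
#' of operational platforms, whose functional form is not published.
#'
#' @param swc_index normalized point index (vectorized; `NA` = no signal).
#' @param comfort a [comfort_zone()].
#' @param gain feedback gain in `(0, 1]`.
#' @return multiplier in `[1 - gain, 1 + gain]`.
#' @export
feedback_factor <- function(swc_index, comfort = comfort_zone(), gain = 0.3) {
  if (gain <= 0 || gain > 1) stop("gain must be in (0, 1]")
  lo <- comfort$lower
  hi <- comfort$upper
  f <- ifelse(is.na(swc_index), 1,
    ifelse(swc_index < lo, 1 + gain * (lo - swc_index) / lo,
      ifelse(swc_index > hi, 1 - gain * (swc_index - hi) / (1 - hi), 1)
    )
  )
  pmin(1 + gain, pmax(1 - gain, f))
}

#' Drip emitter geometry
#'
#' @param emitter_discharge emitter discharge, L/h.
#' @param emitter_spacing along-line emitter spacing, m.
#' @param row_spacing lateral (row) spacing, m.
#' @return an object of class `"emitter_geometry"` with the derived
#'   `application_rate` in mm/h.
#' @export
emitter_geometry <- function(emitter_discharge = 1.6, emitter_spacing = 0.67,
                             row_spacing = 4) {
  if (any(c(emitter_discharge, emitter_spacing, row_spacing) <= 0)) {
    stop("all geometry values must be > 0")
  }
  structure(list(
    emitter_discharge = emitter_discharge,
    emitter_spacing = emitter_spacing, row_spacing = row_spacing,
    application_rate = emitter_discharge / (emitter_spacing * row_spacing)
  ), class = "emitter_geometry")
}

#' Convert an irrigation depth to emitter runtime
#'
#' One emitter wets `emitter_spacing x row_spacing` of ground, so the
#' application rate is `discharge / (emitter_spacing * row_spacing)` mm/h and
#' runtime is depth over rate.
#'
#' @param depth dose, mm (vectorized).
#' @param geometry an [emitter_geometry()].
#' @return runtime, hours.
#' @export
dose_to_runtime <- function(depth, geometry = emitter_geometry()) {
  if (any(depth < 0)) stop("depth must be >= 0")
  depth / geometry$application_rate
}

#' Initialize a control-point state
#'
#' @param point_id label.
#' @param date state date (the day already accounted for).
#' @param cumulative_irrigation cumulative applied irrigation, mm.
#' @param comfort a [comfort_zone()].
#' @return an object of class `"control_point_state"`.
#' @export
control_point_state <- function(point_id = "CR1", date,
                                cumulative_irrigation = 0,
                                comfort = comfort_zone()) {
  structure(list(
    point_id = point_id, date = as.Date(date),
    cumulative_irrigation = cumulative_irrigation,
    swc_index = NA_real_, feedback_factor = 1, comfort = comfort
  ), class = "control_point_state")
}

#' One daily irrigation decision
#'
#' Feed-forward water balance (`max(0, kc_mod * eto - effective_rain)`)
#' multiplied by the sensor [feedback_factor()], then forced inside the
#' seasonal-plan envelope: truncated so cumulative irrigation never exceeds
#' the upper curve, raised so it never falls below the lower curve. The dose
#' is never negative; the state is updated atomically.
#'
#' @param date decision date; must be exactly one day after `state$date`.
#' @param eto reference evapotranspiration today, mm.
#' @param kc_mod deficit-modified crop coefficient today.
#' @param rain gross rainfall today, mm.
#' @param state a [control_point_state()] for yesterday.
#' @param plan a [build_seasonal_plan()] object.
#' @param swc_index today's normalized point index (`NA` = no signal).
#' @param gain feedback gain.
#' @param rain_rule function mapping gross to effective rain.
#' @return list with `dose` (mm), `base`, `factor` and the updated `state`.
#' @export
daily_dose <- function(date, eto, kc_mod, rain, state, plan,
                       swc_index = NA_real_, gain = 0.3,
                       rain_rule = effective_rain) {
  date <- as.Date(date)
  if (!is.na(state$date) && date != state$date + 1) {
    stop(sprintf(
      "date gap: state is at %s but decision requested for %s; resynchronize",
      state$date, date
    ))
  }
  base <- max(0, kc_mod * eto - rain_rule(rain))
  f <- feedback_factor(swc_index, state$comfort, gain)
  dose <- base * f
  env <- plan_at(plan, date)
  cum <- state$cumulative_irrigation
  if (cum + dose > env[["upper"]]) dose <- max(0, env[["upper"]] - cum)
  if (cum + dose < env[["lower"]]) dose <- env[["lower"]] - cum
  dose <- max(0, dose)
  state$date <- date
  state$cumulative_irrigation <- cum + dose
  state$swc_index <- swc_index
  state$feedback_factor <- f
  list(dose = dose, base = base, factor = f, state = state)
}

#' Simulate a full closed-loop irrigation season
#'
#' Runs the daily loop of an automated regulated-deficit-irrigation
#' controller against the package's synthetic soil: each day the two-column
#' soil bucket responds to yesterday's dose and today's rain, the sensors are
#' read (per-sensor gain/offset/noise), references and the normalized point
#' index are updated, and today's dose is computed by [daily_dose()] inside
#' the seasonal-plan envelope. Crop uptake follows the standard Kc curve
#' while the dose follows the deficit-modified curve, so the deficit phases
#' actually dry the profile. A stem-water-potential proxy is derived from the
#' true profile water status via [gen_stress_proxy()].
#'
#' @param weather daily weather covering the season (see [gen_weather()]).
#' @param calendar a [pheno_calendar()].
#' @param kc_standard,kc_deficit standard and deficit-modified
#'   [kc_curve()]s.
#' @param plan a [build_seasonal_plan()]; `NULL` builds one from this
#'   weather's Hargreaves ETo and effective-rain series (the "expert
#'   expectation" equals the climatology).
#' @param soil a [soil_bucket_params()].
#' @param sensors sensor layout (see [default_sensor_layout()]).
#' @param comfort starting [comfort_zone()].
#' @param gain feedback gain.
#' @param envelope_pct envelope half-width used when `plan` is `NULL`.
#' @param sensors_enabled `FALSE` disables feedback entirely (factor 1):
#'   the pure water-balance schedule.
#' @param refit_comfort refit the comfort zone monthly from the trailing
#'   index history.
#' @param seed integer seed (sensor noise, gains, offsets).
#' @return an object of class `"rdi_season"`: list with `ledger` (one row
#'   per day: doses, indices, envelopes, stress proxy), `phase_totals`,
#'   `sensors`, `plan`, `calendar`.
#' @export
run_season <- function(weather, calendar = pheno_calendar(),
                       kc_standard = default_kc_curves()$standard,
                       kc_deficit = default_kc_curves()$deficit,
                       plan = NULL,
                       soil = soil_bucket_params(),
                       sensors = default_sensor_layout(),
                       comfort = comfort_zone(),
                       gain = 0.3,
                       envelope_pct = 0.2,
                       sensors_enabled = TRUE,
                       refit_comfort = FALSE,
                       seed = 1L) {
  season <- weather[weather$date >= calendar$phase_1_start &
    weather$date < calendar$season_end, , drop = FALSE]
  if (nrow(season) == 0) stop("weather does not cover the season")
  attr(season, "latitude") <- attr(weather, "latitude")
  attr(season, "elevation") <- attr(weather, "elevation")
  n <- nrow(season)
  es <- eto_series(season, method = "hargreaves")
  eto <- es$eto_h
  kcs <- kc_at(season$date, kc_standard)
  kcm <- kc_at(season$date, kc_deficit)

  if (is.null(plan)) {
    plan <- build_seasonal_plan(kc_deficit, season$date, eto,
      peff_clim = effective_rain(season$rainfall), envelope_pct = envelope_pct
    )
  }

  ns <- nrow(sensors)
  rng <- with_seed(derive_seed(seed, "season"), {
    list(
      gain = rnorm(ns, 1, soil$sensor_gain_sd),
      offset = rnorm(ns, 0, soil$sensor_offset_sd),
      noise = matrix(
        if (soil$noise_sd > 0) rnorm(n * ns, 0, soil$noise_sd) else 0,
        n, ns
      )
    )
  })
  sensors$gain <- rng$gain
  sensors$offset <- rng$offset
  col_of <- ifelse(sensors$position == "A",
    ifelse(sensors$depth <= 0.45, 1L, 2L), 3L
  )

  # high references: calibrated at campaign start under field-capacity
  # conditions (out-of-season rain), i.e. the sensor's reading at FC
  fc_read <- rng$gain * soil$theta_fc[c(1, 2, 1)][col_of] + rng$offset
  high_ref <- fc_read
  low_ref <- rep(NA_real_, ns)

  th_a <- (soil$theta_fc + soil$theta_wp) / 2
  th_b <- th_a
  dose_hist <- numeric(n + 2) # with 2-step lookback padding
  state <- control_point_state(sensors$control_point_id[1],
    date = season$date[1] - 1, comfort = comfort
  )
  led <- data.frame(
    date = season$date, phase = phase_of(season$date, calendar),
    eto = eto, kc_mod = kcm, rain = season$rainfall,
    base = NA_real_, swc_index = NA_real_, factor = NA_real_,
    dose = NA_real_, cumulative = NA_real_,
    lower = NA_real_, upper = NA_real_, psi_proxy = NA_real_,
    stringsAsFactors = FALSE
  )
  idx_hist <- numeric(0)

  for (d in seq_len(n)) {
    # soil responds to yesterday's dose (B column lags one more day)
    in_a <- soil$wet_frac_a * dose_hist[d + 1] + season$rainfall[d]
    in_b <- soil$wet_frac_a * soil$wet_frac_b_ratio * dose_hist[d] +
      season$rainfall[d]
    uptake <- kcs[d] * eto[d]
    th_a <- bucket_step(th_a, in_a, uptake, soil)
    th_b <- bucket_step(th_b, in_b, uptake, soil)
    true_theta <- c(th_a[1], th_a[2], th_b[1])[col_of]

    if (sensors_enabled) {
      reading <- rng$gain * true_theta + rng$offset + rng$noise[d, ]
      reading <- pmin(soil$porosity, pmax(0, reading))
      low_ref <- mapply(update_low_reference, low_ref, reading)
      ok <- high_ref > low_ref + 1e-6
      z <- rep(NA_real_, ns)
      z[ok] <- vapply(which(ok), function(i) {
        as.numeric(normalize_theta(reading[i], sensor_reference(high_ref[i], low_ref[i])))
      }, numeric(1))
      idx <- aggregate_point(z, sensors, faulty = !ok)
      idx <- if (is.na(idx)) NA_real_ else min(1, max(0, idx))
    } else {
      idx <- NA_real_
    }

    if (refit_comfort && d %% 30 == 0) {
      state$comfort <- refit_comfort_zone(tail_window(idx_hist, 60), state$comfort)
    }

    dec <- daily_dose(season$date[d], eto[d], kcm[d], season$rainfall[d],
      state, plan, swc_index = idx, gain = gain
    )
    state <- dec$state
    dose_hist[d + 2] <- dec$dose
    idx_hist <- c(idx_hist, idx)

    # stress proxy from the true profile status of the under-dripper column
    swc_true <- mean(pmin(1, pmax(0, (th_a - soil$theta_wp) /
      (soil$theta_fc - soil$theta_wp))))
    env <- plan_at(plan, season$date[d])
    led$base[d] <- dec$base
    led$swc_index[d] <- idx
    led$factor[d] <- dec$factor
    led$dose[d] <- dec$dose
    led$cumulative[d] <- state$cumulative_irrigation
    led$lower[d] <- env[["lower"]]
    led$upper[d] <- env[["upper"]]
    led$psi_proxy[d] <- gen_stress_proxy(swc_true)
  }

  doses <- data.frame(point_id = state$point_id, date = led$date, depth = led$dose)
  structure(list(
    ledger = led,
    phase_totals = phase_totals(doses, calendar),
    sensors = sensors, plan = plan, calendar = calendar,
    seed = seed, sensors_enabled = sensors_enabled
  ), class = "rdi_season")
}

tail_window <- function(x, k) if (length(x) <= k) x else x[(length(x) - k + 1):length(x)]

#' @export
print.rdi_season <- function(x, ...) {
  l <- x$ledger
  cat(sprintf(
    "rdi_season: %s to %s (%d days), total irrigation %.1f mm%s\n",
    l$date[1], l$date[nrow(l)], nrow(l), l$cumulative[nrow(l)],
    if (x$sensors_enabled) "" else " [sensors disabled]"
  ))
  pt <- x$phase_totals
  cat(sprintf(
    "  Phase I %.1f | Phase II %.1f | Phase III %.1f mm\n",
    pt$phase_I, pt$phase_II, pt$phase_III
  ))
  invisible(x)
}

#' @export
summary.rdi_season <- function(object, ...) {
  l <- object$ledger
  by_phase <- split(l, l$phase)
  out <- do.call(rbind, lapply(names(by_phase), function(p) {
    s <- by_phase[[p]]
    data.frame(
      phase = p, days = nrow(s), irrigation_mm = sum(s$dose),
      mean_index = mean(s$swc_index, na.rm = TRUE),
      mean_psi_proxy = mean(s$psi_proxy),
      mean_factor = mean(s$factor)
    )
  }))
  out[order(match(out$phase, c("pre-season", "I", "II", "III", "post-season"))), ]
}

#' @export
plot.rdi_season <- function(x, ...) {
  l <- x$ledger
  op <- par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(par(op))
  plot(l$date, l$cumulative, type = "l", lwd = 2,
    ylab = "cumulative irrigation (mm)", xlab = "", ylim = range(0, l$upper), ...)
  lines(l$date, l$upper, lty = 2)
  lines(l$date, l$lower, lty = 2)
  legend("topleft", c("applied", "plan envelope"), lty = c(1, 2), bty = "n")
  plot(l$date, l$psi_proxy, type = "l", col = "brown",
    ylab = "stem potential proxy (MPa)", xlab = "")
  abline(v = as.numeric(c(x$calendar$phase_2_start, x$calendar$phase_3_start)),
    lty = 3)
}
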