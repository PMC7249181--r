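test_that("effective rainfall follows the threshold-and-cap rule", {
  expect_equal(effective_rain(0), 0)
  expect_equal(effective_rain(1.5), 0)
  expect_equal(effective_rain(20), 13.5) # 0.75 * (20 - 2)
  expect_equal(effective_rain(4), 1.5)
  expect_error(effective_rain(-1), "rain")
})

test_that("the feedback law is neutral in zone, clamped at the ends", {
  cz <- comfort_zone(0.4, 0.8)
  expect_equal(feedback_factor(0.6, cz, gain = 0.3), 1.0)
  expect_equal(feedback_factor(0, cz, gain = 0.3), 1.3)
  expect_equal(feedback_factor(1, cz, gain = 0.3), 0.7)
  expect_equal(feedback_factor(0.9, cz, gain = 0.3), 0.85) # halfway above zone
  expect_equal(feedback_factor(0.2, cz, gain = 0.3), 1.15) # halfway below
  expect_equal(feedback_factor(NA, cz, gain = 0.3), 1) # no signal
  expect_error(feedback_factor(0.5, cz, gain = 0), "gain")
  expect_error(feedback_factor(0.5, cz, gain = 1.5), "gain")
})

test_that("dose-to-runtime uses the emitter wetted-area application rate", {
  geo <- emitter_geometry(1.6, 0.67, 4)
  expect_equal(geo$application_rate, 1.6 / (0.67 * 4))
  expect_equal(geo$application_rate, 0.597, tolerance = 1e-3)
  expect_equal(dose_to_runtime(0, geo), 0)
  expect_equal(dose_to_runtime(3 * geo$application_rate, geo), 3)
  expect_error(emitter_geometry(0, 0.67, 4), "geometry")
})

test_that("daily doses combine water balance, feedback and envelopes", {
  dates <- seq(as.Date("2016-06-01"), by = "day", length.out = 30)
  flat <- kc_curve("2016-01-01", 0.4)
  plan <- build_seasonal_plan(flat, dates, eto_clim = 5, envelope_pct = 5)
  st <- control_point_state(date = dates[1] - 1)
  # neutral feedback: dose is the plain water balance
  d <- daily_dose(dates[1], eto = 5, kc_mod = 0.4, rain = 0, st, plan,
    swc_index = 0.6
  )
  expect_equal(d$dose, 2.0)
  expect_equal(d$state$cumulative_irrigation, 2.0)
  # rain credit wipes out demand
  d2 <- daily_dose(dates[2], 5, 0.4, rain = 30, d$state, plan, swc_index = 0.6)
  expect_equal(d2$dose, 0)
  # hard cap at the upper envelope
  st_full <- d2$state
  st_full$cumulative_irrigation <- plan$upper[3]
  d3 <- daily_dose(dates[3], 5, 0.4, 0, st_full, plan, swc_index = 0.1)
  expect_equal(d3$dose, 0)
  # date gaps are an explicit resynchronization error
  expect_error(daily_dose(dates[10], 5, 0.4, 0, d3$state, plan), "resynchronize")
})

test_that("a zero-demand season applies no water", {
  w <- make_dry_weather(245, tmean = 20, drange = 0, start = "2016-03-01")
  s <- run_season(w, seed = 1)
  expect_true(all(s$ledger$dose == 0))
  expect_equal(s$ledger$cumulative[nrow(s$ledger)], 0)
})

test_that("closed-loop seasons are deterministic and stay inside the envelope", {
  w <- gen_weather(weather_scenario(), seed = 8)
  s1 <- run_season(w, seed = 5)
  s2 <- run_season(w, seed = 5)
  expect_identical(s1$ledger, s2$ledger)
  l <- s1$ledger
  expect_true(all(l$cumulative >= l$lower - 1e-9))
  expect_true(all(l$cumulative <= l$upper + 1e-9))
  expect_true(all(diff(l$cumulative) >= -1e-12))
})

test_that("with sensors disabled the controller is the pure water-balance plan", {
  w <- gen_weather(weather_scenario(), seed = 3)
  s <- run_season(w, sensors_enabled = FALSE, seed = 3)
  l <- s$ledger
  # oracle: direct cumulative water balance with envelope clipping
  cum <- 0
  for (d in seq_len(nrow(l))) {
    base <- max(0, l$kc_mod[d] * l$eto[d] - effective_rain(l$rain[d]))
    dose <- base
    if (cum + dose > l$upper[d]) dose <- max(0, l$upper[d] - cum)
    if (cum + dose < l$lower[d]) dose <- l$lower[d] - cum
    cum <- cum + dose
    expect_equal(l$dose[d], dose, tolerance = 1e-9)
  }
  expect_equal(l$cumulative[nrow(l)], cum, tolerance = 1e-9)
  expect_true(all(l$factor == 1))
})

test_that("drier soils never receive less seasonal irrigation", {
  w <- gen_weather(weather_scenario(), seed = 10)
  totals <- vapply(c(0.2, 0.5, 0.9), function(k) {
    s <- run_season(w, soil = soil_bucket_params(drainage_coeff = k), seed = 10)
    s$ledger$cumulative[nrow(s$ledger)]
  }, numeric(1))
  expect_true(all(diff(totals) >= -1e-9))
})

test_that("the deficit Kc expresses stress in Phase II of the closed loop", {
  w <- gen_weather(weather_scenario(), seed = 6)
  s <- run_season(w, seed = 6)
  l <- s$ledger
  psi_I <- mean(l$psi_proxy[l$phase == "I"])
  psi_II <- mean(l$psi_proxy[l$phase == "II"])
  expect_lt(psi_II, psi_I)
})
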