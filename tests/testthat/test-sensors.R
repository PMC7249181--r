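test_that("the high reference recovers field capacity after a saturating rain", {
  n <- 15
  w <- make_dry_weather(n)
  w$rainfall[5] <- 60
  p <- identity_soil(theta_fc = c(0.36, 0.34), drainage_coeff = 0.9)
  tr <- gen_soil_traces(p, irrigation = rep(0, n), weather = w,
    et_demand = 0.5, cadence_min = 60, seed = 1
  )
  s1 <- tr$readings[tr$readings$sensor_id == "S1", ]
  est <- estimate_high_reference(s1, rain_events = w$date[5])
  expect_lt(abs(est - 0.36), 0.01)
})

test_that("the plateau, not the spike peak, defines the high reference", {
  stamps <- seq(as.POSIXct("2016-01-01 00:00", tz = "UTC"),
    by = 3600, length.out = 24 * 8
  )
  theta <- rep(0.30, length(stamps))
  ev <- as.Date("2016-01-03")
  spike_idx <- which(as.Date(stamps) == ev)
  theta[spike_idx] <- 0.45 # event-day peak
  after <- which(stamps > as.POSIXct(paste(ev + 1, "00:00"), tz = "UTC"))
  theta[after] <- 0.30 + 0.02 * exp(-(seq_along(after)) / 24) # settling tail
  est <- estimate_high_reference(data.frame(timestamp = stamps, theta = theta),
    rain_events = ev
  )
  expect_lt(est, 0.40)
  expect_gt(est, 0.28)
  expect_warning(
    estimate_high_reference(data.frame(timestamp = stamps, theta = theta),
      rain_events = as.Date(character(0))
    ),
    "reference unavailable"
  )
})

test_that("campaign reference anchors load from the bundled table", {
  refs <- load_reference_table("references")
  s6 <- refs[refs$sensor_id == "S6" & refs$year == 2016, ]
  expect_equal(s6$high_ref, 0.400)
  expect_equal(s6$low_ref, 0.280)
  # every row is a valid reference
  expect_true(all(refs$low_ref < refs$high_ref))
})

test_that("the low reference is a running minimum of daily minima", {
  expect_equal(update_low_reference(0.171, c(0.20, 0.19)), 0.171)
  expect_equal(update_low_reference(0.171, c(0.18, 0.150)), 0.150)
  expect_equal(update_low_reference(0.171, numeric(0)), 0.171)
  expect_equal(update_low_reference(NA_real_, 0.3), 0.3)
  # oracle: equals the global minimum over any sequence of days
  set.seed(9)
  days <- replicate(10, runif(24, 0.1, 0.4), simplify = FALSE)
  low <- NA_real_
  for (d in days) low <- update_low_reference(low, d)
  expect_equal(low, min(unlist(days)))
})

test_that("normalization anchors at the references and flags clipping", {
  ref <- sensor_reference(0.385, 0.165, "S8")
  expect_equal(as.numeric(normalize_theta(0.385, ref)), 1.0)
  expect_equal(as.numeric(normalize_theta(0.165, ref)), 0.0)
  expect_equal(as.numeric(normalize_theta(0.275, ref)), 0.500)
  z <- normalize_theta(c(0.05, 0.275, 0.55), ref)
  expect_equal(attr(z, "clipped"), c(TRUE, FALSE, TRUE))
  expect_true(all(z >= -0.25 & z <= 1.25))
  expect_error(sensor_reference(0.2, 0.3), "low_ref")
  # round trip on the valid range
  zz <- seq(0, 1, by = 0.1)
  expect_equal(as.numeric(normalize_theta(denormalize_theta(zz, ref), ref)), zz)
})

test_that("point aggregation weights classes and renormalizes over survivors", {
  specs <- default_sensor_layout()
  expect_equal(aggregate_point(rep(0.7, 5), specs), 0.7)
  v <- c(0.8, 0.6, 0.5, 0.4, 0.3)
  # one faulty A@0.30 sensor: direct recomputation with renormalized weights
  faulty <- c(FALSE, TRUE, FALSE, FALSE, FALSE)
  w <- c(0.5, 0.5, 0.3, 0.3, 0.2)[!faulty]
  expect_equal(
    aggregate_point(v, specs, faulty = faulty),
    sum(w * v[!faulty]) / sum(w)
  )
  # degenerate weights isolate one class
  expect_equal(
    aggregate_point(v, specs, weights = c(A30 = 1, A60 = 0, B30 = 0)),
    mean(v[1:2])
  )
  # order invariance
  perm <- c(3, 5, 1, 2, 4)
  expect_equal(
    aggregate_point(v[perm], specs[perm, ], faulty = faulty[perm]),
    aggregate_point(v, specs, faulty = faulty)
  )
  expect_true(is.na(aggregate_point(v, specs, faulty = rep(TRUE, 5))))
})

test_that("fault screening flags range, stuck and spike patterns precisely", {
  expect_true(all(detect_faults(rep(0.999, 10))$out_of_range))
  # a week of bit-identical 5-min samples is stuck
  fl <- detect_faults(c(runif(300, 0.2, 0.3), rep(0.25, 7 * 288)))
  expect_true(any(fl$stuck))
  expect_false(any(fl$stuck[1:300]))
  # an isolated glitch is flagged on the glitch sample only
  th <- rep(0.30, 50)
  th[25] <- 0.50
  fl <- detect_faults(th, spike_jump = 0.1)
  expect_equal(which(fl$spike), 25L)
  expect_equal(nrow(detect_faults(numeric(0))), 0)
})

test_that("comfort-zone refits track the observed percentile band", {
  set.seed(21)
  hist <- runif(3000)
  z <- refit_comfort_zone(hist, comfort_zone(0.4, 0.8))
  expect_lt(abs(z$lower - 0.2), 0.03)
  expect_lt(abs(z$upper - 0.8), 0.03)
  # degenerate spread: unchanged with a warning
  z0 <- comfort_zone(0.4, 0.8)
  expect_warning(z1 <- refit_comfort_zone(rep(0.5, 100), z0), "degenerate")
  expect_equal(z1, z0)
  # idempotence: identical history gives an identical zone
  expect_equal(refit_comfort_zone(hist, z), refit_comfort_zone(hist, z))
  # insufficient history: unchanged
  expect_equal(refit_comfort_zone(c(0.2, 0.9), z0), z0)
})
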