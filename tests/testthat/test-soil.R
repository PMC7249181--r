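test_that("bucket parameter invariants are enforced", {
  expect_error(soil_bucket_params(theta_wp = c(0.35, 0.1)), "theta_wp")
  expect_error(soil_bucket_params(layer_thickness = c(0, 0.3)), "thicknesses")
  expect_error(soil_bucket_params(drainage_coeff = 1.5), "drainage_coeff")
  expect_error(soil_bucket_params(uptake_partition = c(0.5, 0.4)), "uptake_partition")
})

test_that("traces dry monotonically without any water input", {
  w <- make_dry_weather(20)
  tr <- gen_soil_traces(identity_soil(), irrigation = rep(0, 20), weather = w,
    et_demand = 2, cadence_min = 360, seed = 1
  )
  for (sid in unique(tr$readings$sensor_id)) {
    th <- tr$readings$theta[tr$readings$sensor_id == sid]
    expect_true(all(diff(th) <= 1e-12), info = sid)
  }
})

test_that("sustained heavy irrigation drives the profile to field capacity", {
  w <- make_dry_weather(30)
  p <- identity_soil(drainage_coeff = 1)
  tr <- gen_soil_traces(p, irrigation = rep(20, 30), weather = w,
    et_demand = 0, cadence_min = 1440, seed = 1
  )
  last <- tr$truth[30, ]
  expect_equal(last$A1, p$theta_fc[1], tolerance = 1e-6)
  expect_equal(last$A2, p$theta_fc[2], tolerance = 1e-6)
})

test_that("an identity sensor reports the true bucket state exactly", {
  w <- make_dry_weather(10)
  tr <- gen_soil_traces(identity_soil(), irrigation = rep(3, 10), weather = w,
    et_demand = 2, cadence_min = 1440, seed = 1
  )
  # daily cadence: reading k of sensor S equals the end-of-day truth of the
  # column/layer that sensor occupies
  r <- tr$readings
  a30 <- r$theta[r$sensor_id == tr$sensors$sensor_id[1]]
  a60 <- r$theta[r$sensor_id == tr$sensors$sensor_id[3]]
  b30 <- r$theta[r$sensor_id == tr$sensors$sensor_id[5]]
  expect_equal(a30, tr$truth$A1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(a60, tr$truth$A2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(b30, tr$truth$B1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("water is conserved with drainage and uptake switched off", {
  n <- 12
  w <- make_dry_weather(n)
  p <- identity_soil(drainage_coeff = 0)
  irr <- c(5, 0, 8, 2, 0, 0, 12, 1, 0, 4, 7, 0)
  tr <- gen_soil_traces(p, irrigation = irr, weather = w,
    et_demand = 0, cadence_min = 720, seed = 2
  )
  d_mm <- p$layer_thickness * 1000
  stored0 <- sum((p$theta_fc + p$theta_wp) / 2 * d_mm)
  # position A: applied water x wetting fraction
  storedA <- sum(as.numeric(tr$truth[n, c("A1", "A2")]) * d_mm)
  expect_equal(storedA - stored0, sum(irr) * p$wet_frac_a, tolerance = 1e-9)
  # position B: lagged dose at the B wetting fraction (last dose not yet seen)
  storedB <- sum(as.numeric(tr$truth[n, c("B1", "B2")]) * d_mm)
  expect_equal(storedB - stored0,
    sum(irr[-n]) * p$wet_frac_a * p$wet_frac_b_ratio,
    tolerance = 1e-9
  )
})

test_that("trace generation rejects bad cadence and misaligned calendars", {
  w <- make_dry_weather(5)
  expect_error(
    gen_soil_traces(identity_soil(), rep(0, 5), w, 1, cadence_min = 0),
    "cadence"
  )
  expect_error(
    gen_soil_traces(identity_soil(), rep(0, 4), w, 1),
    "misaligned"
  )
})

test_that("the stress proxy is the stated affine map and is monotone", {
  expect_equal(gen_stress_proxy(1), -0.6)
  expect_equal(gen_stress_proxy(0), -2.8)
  expect_equal(gen_stress_proxy(0.5), -1.7)
  z <- seq(0, 1, by = 0.05)
  expect_true(all(diff(gen_stress_proxy(z)) > 0))
  expect_error(gen_stress_proxy(1.2), "0, 1")
  expect_error(gen_stress_proxy(0.5, psi_wet = -3, psi_dry = -1), "psi_dry")
})
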