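test_that("NDVI arithmetic, saturation and alignment checks", {
  r <- raster_grid(matrix(0.16, 2, 2))
  n <- raster_grid(matrix(0.42, 2, 2))
  expect_equal(compute_ndvi(r, n)$values[1, 1], 0.4483, tolerance = 1e-4)
  expect_equal(compute_ndvi(r, r)$values, matrix(0, 2, 2))
  z <- raster_grid(matrix(0, 2, 2))
  expect_equal(compute_ndvi(z, n)$values, matrix(1, 2, 2))
  expect_true(all(is.na(compute_ndvi(z, z)$values)))
  bad <- raster_grid(matrix(0.4, 3, 2))
  expect_error(compute_ndvi(r, bad), "aligned")
  expect_error(compute_ndvi(raster_grid(matrix(-0.1, 2, 2)), n), ">= 0")
})

test_that("the empirical variogram matches brute-force pair sums", {
  # five collinear points, hand-enumerable 10 pairs
  x <- c(0, 10, 20, 30, 40)
  y <- rep(0, 5)
  v <- c(2, 4, 3, 8, 5)
  emp <- empirical_variogram(x, y, v, lag_width = 10, max_lag = 50)
  # brute-force oracle over all pairs
  pairs <- t(combn(5, 2))
  h <- abs(x[pairs[, 1]] - x[pairs[, 2]])
  d2 <- (v[pairs[, 1]] - v[pairs[, 2]])^2
  for (b in unique(floor(h / 10))) {
    sel <- floor(h / 10) == b
    row <- emp[emp$lag == (b + 0.5) * 10, ]
    expect_equal(row$gamma, mean(d2[sel]) / 2)
    expect_equal(row$n_pairs, sum(sel))
  }
  expect_equal(sum(emp$n_pairs), choose(5, 2))
  # constant field: flat zero variogram
  emp0 <- empirical_variogram(x, y, rep(7, 5), lag_width = 10, max_lag = 50)
  expect_true(all(emp0$gamma == 0))
  expect_error(empirical_variogram(1, 1, 5), "2 samples")
})

test_that("variogram fitting recovers known parameters and degenerates safely", {
  lags <- seq(5, 95, by = 10)
  true <- list(nugget = 1, psill = 10, range = 50)
  g <- vapply(lags, function(h) {
    1 + 10 * ifelse(h < 50, 1.5 * h / 50 - 0.5 * (h / 50)^3, 1)
  }, numeric(1))
  emp <- data.frame(lag = lags, gamma = g, n_pairs = 100)
  fit <- fit_variogram(emp, "spherical")
  expect_lt(abs(fit$nugget - true$nugget) / true$nugget, 0.05)
  expect_lt(abs(fit$psill - true$psill) / true$psill, 0.05)
  expect_lt(abs(fit$range - true$range) / true$range, 0.05)
  # fitted curve at lag zero equals the nugget
  expect_equal(predict(fit, 0), fit$nugget)
  # flat variogram collapses to pure nugget with a warning
  flat <- data.frame(lag = lags, gamma = 3, n_pairs = 100)
  expect_warning(f2 <- fit_variogram(flat), "nugget")
  expect_equal(f2$nugget, 3, tolerance = 0.05)
})

test_that("kriging weights match a direct solve of the linear system", {
  toy <- krige_toy()
  x0 <- 15; y0 <- 22
  kp <- krige_point(toy$x, toy$y, toy$value, toy$vgm, x0, y0)
  # oracle: assemble and solve the 5x5 augmented system directly
  sph <- function(h) ifelse(h == 0, 0,
    ifelse(h < 60, 8 * (1.5 * h / 60 - 0.5 * (h / 60)^3), 8)
  )
  h <- as.matrix(dist(cbind(toy$x, toy$y)))
  a <- rbind(cbind(sph(h), 1), c(1, 1, 1, 1, 0))
  g0 <- sph(sqrt((toy$x - x0)^2 + (toy$y - y0)^2))
  sol <- solve(a, c(g0, 1))
  expect_equal(kp$weights, sol[1:4], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(kp$weights), 1, tolerance = 1e-9)
  expect_equal(kp$value, sum(sol[1:4] * toy$value), tolerance = 1e-9)
})

test_that("kriging is exact at samples and constant on constant fields", {
  toy <- krige_toy()
  # a grid cell whose center coincides with sample 1 at (0, 0)
  g <- raster_grid(matrix(0, 5, 5), origin_x = -2.5, origin_y = -22.5,
    cell_size = 5
  )
  kr <- ordinary_krige(toy$x, toy$y, toy$value, toy$vgm, g, global = TRUE)
  cc <- which(abs(kr$prediction$values - 10) < 1e-9)
  expect_gte(length(cc), 1) # the co-located cell reproduces sample value 10
  expect_true(all(kr$variance$values >= 0))
  # constant field
  kc <- ordinary_krige(toy$x, toy$y, rep(4, 4), toy$vgm, g)
  expect_equal(kc$prediction$values, matrix(4, 5, 5), tolerance = 1e-9)
  # duplicate points are averaged, not fatal
  kd <- krige_point(c(toy$x, 0), c(toy$y, 0), c(toy$value, 14), toy$vgm, 15, 22)
  expect_equal(sum(kd$weights), 1, tolerance = 1e-9)
  expect_error(ordinary_krige(c(0, 1), c(0, 0), c(1, 2), toy$vgm, g), "3 samples")
})

test_that("three-class layers use upward-closed half-open breaks", {
  g <- raster_grid(matrix(c(9.99, 12.3, 15.0, 21), 2, 2))
  cl <- classify_layer(g, breaks = c(10, 15))
  expect_equal(as.vector(cl$values), c(1L, 2L, 3L, 3L))
  nv <- raster_grid(matrix(c(0.38, 0.42, 0.45, 0.49), 2, 2))
  ncl <- classify_layer(nv, breaks = c(0.40, 0.45))
  expect_equal(as.vector(ncl$values), c(1L, 2L, 3L, 3L)) # 0.45 belongs upward
  expect_error(classify_layer(g, breaks = c(15, 10)), "increasing")
  # idempotent on repeated application of the rule to the same layer
  expect_identical(classify_layer(g, c(10, 15))$values, cl$values)
})

test_that("zone combination applies the three rules and flags the gap", {
  eca <- raster_grid(matrix(c(2L, 1L, 1L, 3L), 2, 2))
  ndvi <- raster_grid(matrix(c(3L, 1L, 2L, 1L), 2, 2))
  z <- combine_zones(eca, ndvi)
  expect_equal(as.vector(z$values), c(1L, 2L, 3L, 0L))
})

test_that("the survey-to-zones chain recovers the true zone map", {
  truth <- gen_field_truth(seed = 7)
  sv <- gen_eca_survey(truth, line_spacing = 10, sample_spacing = 5,
    noise_sd = 0, seed = 7
  )
  idx <- seq(1, nrow(sv), by = 4)
  emp <- empirical_variogram(sv$x[idx], sv$y[idx], sv$eca[idx],
    lag_width = 10, max_lag = 150
  )
  vgm <- fit_variogram(emp)
  kr <- ordinary_krige(sv$x, sv$y, sv$eca, vgm, truth$eca_field)
  refl <- gen_reflectance(truth, noise_sd = 0)
  ndvi <- compute_ndvi(refl$red, refl$nir)
  zones <- combine_zones(
    classify_layer(kr$prediction, c(10, 15)),
    classify_layer(ndvi, c(0.40, 0.45))
  )
  expect_gte(zone_recovery(zones, truth$zone_truth), 0.95)
})
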