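#' Normalized difference vegetation index
#'
#' `(NIR - R) / (NIR + R)` per cell. Cells where both bands are zero are set
#' to the grid's nodata (`NA`).
#'
#' @param red,nir aligned reflectance [raster_grid()]s, values `>= 0`.
#' @return a [raster_grid()] with values in `[-1, 1]`.
#' @export
compute_ndvi <- function(red, nir) {
  check_aligned(red, nir)
  if (any(red$values < 0, na.rm = TRUE) || any(nir$values < 0, na.rm = TRUE)) {
    stop("reflectances must be >= 0")
  }
  s <- nir$values + red$values
  out <- red
  out$values <- ifelse(s == 0, NA, (nir$values - red$values) / s)
  out
}

#' Empirical semivariogram
#'
#' Bins all point pairs by separation distance and computes
#' `gamma(h) = mean((z_i - z_j)^2) / 2` per bin.
#'
#' @param x,y planar coordinates, m.
#' @param value measured values.
#' @param lag_width bin width, m.
#' @param max_lag largest separation considered, m (default: half the maximum
#'   pair distance).
#' @return data.frame with columns `lag` (bin center), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(x, y, value, lag_width = 5, max_lag = NULL) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  h <- sqrt(dx^2 + dy^2)[lower.tri(matrix(0, n, n))]
  dz2 <- (outer(value, value, "-")^2)[lower.tri(matrix(0, n, n))]
  if (is.null(max_lag)) max_lag <- max(h) / 2
  keep <- h > 0 & h <= max_lag
  h <- h[keep]; dz2 <- dz2[keep]
  bin <- floor(h / lag_width)
  agg_g <- tapply(dz2, bin, mean) / 2
  agg_n <- tapply(dz2, bin, length)
  data.frame(
    lag = (as.numeric(names(agg_g)) + 0.5) * lag_width,
    gamma = as.numeric(agg_g),
    n_pairs = as.integer(agg_n)
  )
}

# model curve; h = 0 evaluates to the nugget (the kriging solver handles the
# at-zero discontinuity itself)
vgm_gamma <- function(h, nugget, psill, range, model) {
  g <- switch(model,
    spherical = ifelse(h < range,
      psill * (1.5 * h / range - 0.5 * (h / range)^3),
      psill
    ),
    exponential = psill * (1 - exp(-3 * h / range)),
    stop("unknown variogram model: ", model)
  )
  nugget + g
}

#' Fit a variogram model by weighted least squares
#'
#' Fits nugget, partial sill and range to an empirical variogram, weighting
#' squared residuals by the pair count of each bin. A fit whose partial sill
#' collapses below `psill_floor` is reported as pure nugget with a warning.
#'
#' @param emp an [empirical_variogram()] table.
#' @param model `"spherical"` (default, the common choice for ECa surveys) or
#'   `"exponential"`.
#' @param psill_floor smallest admissible partial sill.
#' @return object of class `"variogram_model"` with elements `nugget`,
#'   `psill`, `range`, `model`, `converged`, `wss`.
#' @export
fit_variogram <- function(emp, model = c("spherical", "exponential"),
                          psill_floor = 1e-6) {
  model <- match.arg(model)
  w <- emp$n_pairs
  obj <- function(p) {
    nugget <- exp(p[1]) - 1e-9
    psill <- exp(p[2])
    rng <- exp(p[3])
    sum(w * (vgm_gamma(emp$lag, nugget, psill, rng, model) - emp$gamma)^2)
  }
  g0 <- max(emp$gamma)
  init <- c(
    log(max(min(emp$gamma), 1e-6)),
    log(max(g0 - min(emp$gamma), 1e-6)),
    log(max(emp$lag) * 0.6)
  )
  fit <- optim(init, obj, method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-12)
  )
  # polish from a second start to dodge local minima
  fit2 <- optim(c(log(1e-6), log(max(g0, 1e-6)), log(max(emp$lag) * 0.3)), obj,
    method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-12)
  )
  if (fit2$value < fit$value) fit <- fit2
  if (fit$convergence != 0) {
    stop("variogram fit did not converge (code ", fit$convergence, ", wss ",
      signif(fit$value, 4), ")")
  }
  nugget <- max(0, exp(fit$par[1]) - 1e-9)
  psill <- exp(fit$par[2])
  rng <- exp(fit$par[3])
  if (psill < psill_floor || rng > 100 * max(emp$lag)) {
    warning("no spatial structure detected; returning a pure-nugget model")
    nugget <- sum(w * emp$gamma) / sum(w)
    psill <- psill_floor
    rng <- max(emp$lag)
  }
  structure(list(
    nugget = nugget, psill = psill, range = rng, model = model,
    converged = TRUE, wss = fit$value
  ), class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "%s variogram: nugget %.4g, partial sill %.4g, range %.4g m (wss %.4g)\n",
    x$model, x$nugget, x$psill, x$range, x$wss
  ))
  invisible(x)
}

#' @param object a `variogram_model`.
#' @param h lags at which to evaluate the fitted curve, m.
#' @param ... unused.
#' @rdname fit_variogram
#' @export
predict.variogram_model <- function(object, h, ...) {
  vgm_gamma(h, object$nugget, object$psill, object$range, object$model)
}

# average replicated coordinates so the kriging system is non-singular
dedupe_samples <- function(x, y, value) {
  key <- paste(signif(x, 10), signif(y, 10))
  if (!anyDuplicated(key)) return(list(x = x, y = y, value = value))
  agg <- tapply(value, key, mean)
  xy <- do.call(rbind, strsplit(names(agg), " "))
  list(x = as.numeric(xy[, 1]), y = as.numeric(xy[, 2]), value = as.numeric(agg))
}

# solve the ordinary-kriging system for one target given neighbor indices
ok_solve <- function(gmat, g0) {
  n <- length(g0)
  a <- rbind(cbind(gmat, 1), c(rep(1, n), 0))
  b <- c(g0, 1)
  sol <- tryCatch(solve(a, b), error = function(e) NULL)
  if (is.null(sol)) stop("singular kriging system")
  list(weights = sol[1:n], mu = sol[n + 1])
}

#' Ordinary kriging at a single location
#'
#' Exposes the kriging weights for one target point; mostly useful for
#' inspection and verification against a direct solve of the linear system.
#'
#' @param x,y,value sample coordinates (m) and values.
#' @param vgm a fitted [fit_variogram()] model (or a list with `nugget`,
#'   `psill`, `range`, `model`).
#' @param x0,y0 prediction location.
#' @return list with `value`, `variance`, `weights` (summing to 1) and the
#'   indices of the samples used.
#' @export
krige_point <- function(x, y, value, vgm, x0, y0) {
  d <- dedupe_samples(x, y, value)
  h <- as.matrix(dist(cbind(d$x, d$y)))
  gmat <- vgm_gamma(h, vgm$nugget, vgm$psill, vgm$range, vgm$model)
  diag(gmat) <- 0
  h0 <- sqrt((d$x - x0)^2 + (d$y - y0)^2)
  g0 <- ifelse(h0 == 0, 0, vgm_gamma(h0, vgm$nugget, vgm$psill, vgm$range, vgm$model))
  sol <- ok_solve(gmat, g0)
  list(
    value = sum(sol$weights * d$value),
    variance = max(0, sum(sol$weights * g0) + sol$mu),
    weights = sol$weights,
    used = seq_along(d$x)
  )
}

#' Ordinary kriging onto a raster grid
#'
#' Solves the ordinary-kriging system (unbiasedness constraint: weights sum
#' to 1) per grid cell. By default each cell uses its `max_points` nearest
#' samples within `max_radius`; `global = TRUE` uses every sample for every
#' cell (toy problem sizes only). With a zero nugget the predictor is exact
#' at sample locations.
#'
#' @param x,y,value sample coordinates (m) and values.
#' @param vgm a fitted [fit_variogram()] model.
#' @param grid a [raster_grid()] supplying the target geometry.
#' @param max_points,max_radius neighborhood: nearest `max_points` samples
#'   within `max_radius` m.
#' @param global use all samples at every cell.
#' @return list with `prediction` and `variance` [raster_grid()]s.
#' @export
ordinary_krige <- function(x, y, value, vgm, grid,
                           max_points = 16, max_radius = 50, global = FALSE) {
  d <- dedupe_samples(x, y, value)
  n <- length(d$x)
  if (n < 3) stop("need at least 3 samples")
  cc <- grid_coords(grid)
  pred <- numeric(length(cc$x))
  pvar <- numeric(length(cc$x))
  if (global) {
    h <- as.matrix(dist(cbind(d$x, d$y)))
    gmat <- vgm_gamma(h, vgm$nugget, vgm$psill, vgm$range, vgm$model)
    diag(gmat) <- 0
    a <- rbind(cbind(gmat, 1), c(rep(1, n), 0))
    ainv <- solve(a)
    for (i in seq_along(cc$x)) {
      h0 <- sqrt((d$x - cc$x[i])^2 + (d$y - cc$y[i])^2)
      g0 <- ifelse(h0 == 0, 0, vgm_gamma(h0, vgm$nugget, vgm$psill, vgm$range, vgm$model))
      sol <- ainv %*% c(g0, 1)
      w <- sol[1:n]
      pred[i] <- sum(w * d$value)
      pvar[i] <- max(0, sum(w * g0) + sol[n + 1])
    }
  } else {
    for (i in seq_along(cc$x)) {
      h0 <- sqrt((d$x - cc$x[i])^2 + (d$y - cc$y[i])^2)
      near <- which(h0 <= max_radius)
      if (length(near) < 3) near <- order(h0)[1:min(n, max(3, max_points))]
      if (length(near) > max_points) near <- near[order(h0[near])][1:max_points]
      hs <- as.matrix(dist(cbind(d$x[near], d$y[near])))
      gmat <- vgm_gamma(hs, vgm$nugget, vgm$psill, vgm$range, vgm$model)
      diag(gmat) <- 0
      g0 <- ifelse(h0[near] == 0, 0,
        vgm_gamma(h0[near], vgm$nugget, vgm$psill, vgm$range, vgm$model)
      )
      sol <- ok_solve(gmat, g0)
      pred[i] <- sum(sol$weights * d$value[near])
      pvar[i] <- max(0, sum(sol$weights * g0) + sol$mu)
    }
  }
  pg <- grid; vg <- grid
  pg$values <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  vg$values <- pg$values
  pg$values[cbind(cc$row, cc$col)] <- pred
  vg$values[cbind(cc$row, cc$col)] <- pvar
  list(prediction = pg, variance = vg)
}

#' Three-class layer classification
#'
#' Classifies a continuous layer into ordered classes by half-open intervals
#' `[break_i, break_{i+1})`: a value exactly on a break belongs to the class
#' above. Values outside the overall span are clamped into the nearest class.
#' Defaults follow the common management-zone convention for ECa
#' (low < 10, medium 10-15, high >= 15 mS/m); use breaks `c(0.40, 0.45)` for
#' NDVI.
#'
#' @param raster a [raster_grid()].
#' @param breaks increasing vector of two thresholds.
#' @param labels class labels, low to high.
#' @return a [raster_grid()] of integer classes 1..3 with a `labels`
#'   attribute.
#' @export
classify_layer <- function(raster, breaks = c(10, 15),
                           labels = c("low", "medium", "high")) {
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be strictly increasing")
  out <- raster
  v <- raster$values
  cl <- matrix(1L, nrow(v), ncol(v))
  cl[v >= breaks[1]] <- 2L
  cl[v >= breaks[2]] <- 3L
  cl[is.na(v)] <- NA_integer_
  out$values <- cl
  attr(out, "labels") <- labels
  out
}

#' Combine ECa and NDVI classes into management zones
#'
#' Cell-wise rules: zone 1 where both ECa and NDVI are medium or high; zone 2
#' where both are low; zone 3 where ECa is low and NDVI is medium or high.
#' The remaining combination (ECa medium/high with low NDVI) is not covered
#' by any rule and is labelled 0 (unclassified).
#'
#' @param eca_class,ndvi_class aligned classified [raster_grid()]s from
#'   [classify_layer()] (1 = low, 2 = medium, 3 = high).
#' @return a [raster_grid()] with labels 1, 2, 3 and 0 for unclassified.
#' @export
combine_zones <- function(eca_class, ndvi_class) {
  check_aligned(eca_class, ndvi_class)
  e <- eca_class$values
  v <- ndvi_class$values
  z <- matrix(0L, nrow(e), ncol(e))
  z[e >= 2 & v >= 2] <- 1L
  z[e == 1 & v == 1] <- 2L
  z[e == 1 & v >= 2] <- 3L
  z[is.na(e) | is.na(v)] <- NA_integer_
  out <- eca_class
  out$values <- z
  attr(out, "labels") <- c("unclassified", "zone1", "zone2", "zone3")
  out
}

#' Agreement between a recovered zone map and the truth
#'
#' @param zones,truth aligned zone [raster_grid()]s.
#' @param exclude_boundary drop cells adjacent (8-neighborhood) to a truth
#'   zone change before scoring, since arbitrarily small interpolation error
#'   flips class right at a boundary.
#' @return fraction of compared cells that agree.
#' @export
zone_recovery <- function(zones, truth, exclude_boundary = TRUE) {
  check_aligned(zones, truth)
  z <- zones$values
  t <- truth$values
  keep <- !is.na(z) & !is.na(t)
  if (exclude_boundary) {
    nr <- nrow(t); nc <- ncol(t)
    interior <- matrix(TRUE, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- matrix(NA_integer_, nr, nc)
      r_src <- max(1, 1 + dr):min(nr, nr + dr)
      c_src <- max(1, 1 + dc):min(nc, nc + dc)
      sh[r_src - dr, c_src - dc] <- t[r_src, c_src]
      interior <- interior & (is.na(sh) | sh == t)
    }
    keep <- keep & interior
  }
  mean(z[keep] == t[keep])
}
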