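#' Two-layer drip-wetted soil bucket parameters
#'
#' A minimal soil model mirroring the two capacitance-sensor depths of a
#' drip-irrigated control point: two stacked layers (0-0.30 m and 0.30-0.60 m)
#' for each of two wetted columns, position A under the dripper and position B
#' between drippers. Position A receives `wet_frac_a` of every irrigation
#' dose; position B receives `wet_frac_b_ratio` times that fraction with a
#' one-day lag, reproducing the attenuated/delayed response observed between
#' drippers. Rain enters both columns unscaled. Water above field capacity
#' drains to the layer below (and out of the system from the bottom layer) at
#' fraction `drainage_coeff` of the excess per day; crop uptake is partitioned
#' across layers and cannot draw a layer below wilting point.
#'
#' @param theta_fc volumetric water content at field capacity per layer,
#'   m3/m3, length 2.
#' @param theta_wp wilting point per layer, m3/m3, length 2.
#' @param layer_thickness layer thicknesses, m, length 2.
#' @param porosity physical ceiling for sensor readings, m3/m3.
#' @param drainage_coeff fraction of the above-FC excess drained per day,
#'   in `[0, 1]`.
#' @param wet_frac_a fraction of an irrigation dose wetting the position-A
#'   column.
#' @param wet_frac_b_ratio position-B wetting as a multiple of position A's.
#' @param uptake_partition fraction of crop uptake taken from each layer,
#'   length 2, sums to 1.
#' @param sensor_gain_sd,sensor_offset_sd spread of the per-sensor gain
#'   (around 1) and offset (around 0 m3/m3), drawn once per campaign.
#' @param noise_sd reading noise, m3/m3.
#' @return an object of class `"soil_bucket_params"`.
#' @export
soil_bucket_params <- function(theta_fc = c(0.32, 0.30),
                               theta_wp = c(0.10, 0.09),
                               layer_thickness = c(0.30, 0.30),
                               porosity = 0.46,
                               drainage_coeff = 0.5,
                               wet_frac_a = 0.6,
                               wet_frac_b_ratio = 0.3,
                               uptake_partition = c(0.65, 0.35),
                               sensor_gain_sd = 0.08,
                               sensor_offset_sd = 0.02,
                               noise_sd = 0.003) {
  if (any(theta_wp >= theta_fc)) stop("theta_wp must be < theta_fc in every layer")
  if (any(layer_thickness <= 0)) stop("layer thicknesses must be > 0")
  if (drainage_coeff < 0 || drainage_coeff > 1) stop("drainage_coeff must be in [0, 1]")
  if (wet_frac_a < 0 || wet_frac_a > 1) stop("wet_frac_a must be in [0, 1]")
  if (wet_frac_b_ratio < 0 || wet_frac_b_ratio > 1) stop("wet_frac_b_ratio must be in [0, 1]")
  if (abs(sum(uptake_partition) - 1) > 1e-9 || any(uptake_partition < 0)) {
    stop("uptake_partition must be non-negative and sum to 1")
  }
  structure(list(
    theta_fc = theta_fc, theta_wp = theta_wp,
    layer_thickness = layer_thickness, porosity = porosity,
    drainage_coeff = drainage_coeff,
    wet_frac_a = wet_frac_a, wet_frac_b_ratio = wet_frac_b_ratio,
    uptake_partition = uptake_partition,
    sensor_gain_sd = sensor_gain_sd, sensor_offset_sd = sensor_offset_sd,
    noise_sd = noise_sd
  ), class = "soil_bucket_params")
}

#' Default sensor layout of one control point
#'
#' Five capacitance sensors: two under a dripper (position A) at 0.30 m, two
#' at 0.60 m, and one between drippers (position B) at 0.30 m.
#'
#' @param point_id control point label.
#' @param ids optional sensor ids (length 5).
#' @return a data.frame with columns `sensor_id`, `control_point_id`,
#'   `position` (`"A"`/`"B"`) and `depth` (m).
#' @export
default_sensor_layout <- function(point_id = "CR1", ids = paste0("S", 1:5)) {
  stopifnot(length(ids) == 5L)
  data.frame(
    sensor_id = ids,
    control_point_id = point_id,
    position = c("A", "A", "A", "A", "B"),
    depth = c(0.30, 0.30, 0.60, 0.60, 0.30),
    stringsAsFactors = FALSE
  )
}

# one daily bucket step for a single column.
# theta: length-2 state; input_mm enters layer 1; et_mm is the day's uptake
# demand. Returns the new state. drain_frac may be < params$drainage_coeff
# for sub-daily steps.
bucket_step <- function(theta, input_mm, et_mm, params, drain_frac = params$drainage_coeff) {
  d_mm <- params$layer_thickness * 1000
  s <- theta * d_mm # storage, mm

  s[1] <- s[1] + input_mm
  # uptake, partitioned, limited by water above wilting point
  want <- et_mm * params$uptake_partition
  avail <- pmax(0, s - params$theta_wp * d_mm)
  take <- pmin(want, avail)
  # unmet demand in one layer falls on the other
  deficit <- sum(want - take)
  if (deficit > 0) {
    extra <- pmin(deficit, avail - take)
    if (extra[1] > 0) {
      take[1] <- take[1] + min(deficit, extra[1]); deficit <- deficit - min(deficit, extra[1])
    }
    if (deficit > 0 && extra[2] > 0) take[2] <- take[2] + min(deficit, extra[2])
  }
  s <- s - take
  # drainage: layer 1 excess to layer 2, layer 2 excess out
  ex1 <- max(0, s[1] - params$theta_fc[1] * d_mm[1]) * drain_frac
  s[1] <- s[1] - ex1
  s[2] <- s[2] + ex1
  ex2 <- max(0, s[2] - params$theta_fc[2] * d_mm[2]) * drain_frac
  s[2] <- s[2] - ex2
  s / d_mm
}

#' Generate soil-moisture sensor traces from a bucket model
#'
#' Drives the two-column, two-layer bucket of [soil_bucket_params()] with a
#' daily irrigation and rain series and an evapotranspiration demand, then
#' reports per-sensor readings at a fixed cadence. Reported readings are
#' `gain * true_theta + offset + noise`, clipped to `[0, porosity]`; gains and
#' offsets are drawn once per sensor per campaign, reproducing persistent
#' sensor-to-sensor variability. Within a day, irrigation is applied over the
#' first six hours, rain uniformly, and uptake over 06:00-20:00.
#'
#' @param params a [soil_bucket_params()].
#' @param irrigation daily dose, mm (vector, one element per day).
#' @param weather weather data.frame aligned with `irrigation` (uses
#'   `rainfall` and `date`).
#' @param et_demand daily crop water demand (ETc), mm; recycled if length 1.
#' @param cadence_min reading cadence, minutes (default 5).
#' @param sensors sensor layout (see [default_sensor_layout()]).
#' @param seed integer seed.
#' @return list with `readings` (data.frame `sensor_id`, `timestamp`, `theta`),
#'   `truth` (daily end-of-day true theta per column x layer), `sensors`
#'   (layout with the drawn `gain` and `offset`).
#' @export
gen_soil_traces <- function(params, irrigation, weather, et_demand,
                            cadence_min = 5, sensors = default_sensor_layout(),
                            seed = 1L) {
  if (cadence_min <= 0) stop("cadence_min must be > 0")
  n <- length(irrigation)
  if (nrow(weather) != n) stop("irrigation and weather calendars are misaligned")
  et_demand <- rep_len(et_demand, n)
  steps <- max(1L, round(1440 / cadence_min))
  dt <- 1 / steps
  drain_sub <- 1 - (1 - params$drainage_coeff)^dt

  with_seed(derive_seed(seed, "soil"), {
    ns <- nrow(sensors)
    gain <- rnorm(ns, 1, params$sensor_gain_sd)
    offset <- rnorm(ns, 0, params$sensor_offset_sd)
    sensors$gain <- gain
    sensors$offset <- offset

    # initial state: halfway between wp and fc
    th_a <- (params$theta_fc + params$theta_wp) / 2
    th_b <- th_a
    dose_b <- c(0, irrigation[-n]) * params$wet_frac_a * params$wet_frac_b_ratio
    dose_a <- irrigation * params$wet_frac_a

    n_rec <- n * steps
    truth <- matrix(NA_real_, n, 4,
      dimnames = list(NULL, c("A1", "A2", "B1", "B2"))
    )
    rec <- matrix(NA_real_, n_rec, 4)
    # apportion the day's irrigation over the morning window and uptake over
    # daylight; with a coarse cadence each collapses onto whatever substeps
    # exist, so daily totals are conserved exactly at any cadence
    hour <- (seq_len(steps) - 1) * 24 / steps
    irr_steps <- which(hour < 6)
    et_steps <- which(hour >= 6 & hour < 20)
    if (length(et_steps) == 0) et_steps <- steps
    for (d in seq_len(n)) {
      rain <- weather$rainfall[d]
      for (s in seq_len(steps)) {
        in_a <- rain * dt
        in_b <- rain * dt
        if (s %in% irr_steps) {
          in_a <- in_a + dose_a[d] / length(irr_steps)
          in_b <- in_b + dose_b[d] / length(irr_steps)
        }
        et_sub <- if (s %in% et_steps) et_demand[d] / length(et_steps) else 0
        th_a <- bucket_step(th_a, in_a, et_sub, params, drain_sub)
        th_b <- bucket_step(th_b, in_b, et_sub, params, drain_sub)
        rec[(d - 1) * steps + s, ] <- c(th_a, th_b)
      }
      truth[d, ] <- c(th_a, th_b)
    }

    t0 <- as.POSIXct(paste(weather$date[1], "00:00:00"), tz = "UTC")
    stamps <- t0 + (seq_len(n_rec)) * cadence_min * 60
    # map each sensor onto its column/layer trace
    col_of <- ifelse(sensors$position == "A",
      ifelse(sensors$depth <= 0.45, 1L, 2L),
      3L
    )
    readings <- do.call(rbind, lapply(seq_len(ns), function(i) {
      true <- rec[, col_of[i]]
      val <- gain[i] * true + offset[i] +
        if (params$noise_sd > 0) rnorm(n_rec, 0, params$noise_sd) else 0
      data.frame(
        sensor_id = sensors$sensor_id[i], timestamp = stamps,
        theta = pmin(params$porosity, pmax(0, val)),
        stringsAsFactors = FALSE
      )
    }))
    list(readings = readings, truth = as.data.frame(truth), sensors = sensors)
  })
}

#' Stem-water-potential proxy from normalized soil water
#'
#' An affine map standing in for midday stem water potential so deficit
#' thresholds can be exercised in simulation: a fully replenished profile
#' (index 1) maps to `psi_wet`, a fully depleted one (index 0) to `psi_dry`.
#' Defaults span the -0.57 to -2.69 MPa range typical of deficit-irrigated
#' hedgerow olive. Strictly monotone increasing in the index.
#'
#' @param normalized_swc normalized soil water index in `[0, 1]` (vectorized).
#' @param psi_wet,psi_dry endpoint potentials, MPa (both negative).
#' @return stem water potential proxy, MPa.
#' @export
gen_stress_proxy <- function(normalized_swc, psi_wet = -0.6, psi_dry = -2.8) {
  if (any(normalized_swc < 0 | normalized_swc > 1, na.rm = TRUE)) {
    stop("normalized_swc must lie in [0, 1]")
  }
  if (psi_dry >= psi_wet) stop("psi_dry must be more negative than psi_wet")
  psi_dry + normalized_swc * (psi_wet - psi_dry)
}
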