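#' Per-sensor high/low reference anchors
#'
#' Each capacitance sensor is anchored by two campaign-specific values: a
#' high reference (the reading at field capacity, typically observed after
#' out-of-season rain) and a low reference (the driest value recorded so
#' far). Normalizing raw readings between the two removes persistent
#' sensor-to-sensor offset and gain differences.
#'
#' @param high_ref,low_ref reference readings, m3/m3, `low_ref < high_ref`.
#' @param sensor_id optional id.
#' @return an object of class `"sensor_reference"`.
#' @export
sensor_reference <- function(high_ref, low_ref, sensor_id = NA_character_) {
  if (!is.finite(high_ref) || !is.finite(low_ref) || low_ref >= high_ref) {
    stop("need low_ref < high_ref")
  }
  structure(list(sensor_id = sensor_id, high_ref = high_ref, low_ref = low_ref),
    class = "sensor_reference"
  )
}

#' Estimate the high (field-capacity) reference from a trace
#'
#' After a saturating rain event the reading rises to a peak, then free
#' drainage settles it onto a plateau: the field-capacity reading. The
#' estimate is the median of readings in a window after the end of the
#' largest rain event (default 24-72 h), which targets the plateau rather
#' than the transient peak.
#'
#' @param series data.frame with `timestamp` (POSIXct) and `theta`.
#' @param rain_events `Date` vector of rain-event end dates.
#' @param window hours after event end defining the plateau window,
#'   length 2.
#' @param rain_amounts optional event sizes, used to pick the largest event
#'   (defaults to the last event).
#' @return the estimated high reference (m3/m3), or `NA` with a warning when
#'   no qualifying window exists ("reference unavailable": the caller should
#'   fall back to its configured value).
#' @export
estimate_high_reference <- function(series, rain_events, window = c(24, 72),
                                    rain_amounts = NULL) {
  if (length(rain_events) == 0) {
    warning("reference unavailable: no qualifying rain event")
    return(NA_real_)
  }
  ev <- as.Date(rain_events)
  pick <- if (!is.null(rain_amounts)) ev[which.max(rain_amounts)] else max(ev)
  t0 <- as.POSIXct(paste(pick, "23:59:59"), tz = "UTC")
  lo <- t0 + window[1] * 3600
  hi <- t0 + window[2] * 3600
  in_win <- series$timestamp >= lo & series$timestamp <= hi
  if (!any(in_win)) {
    warning("reference unavailable: trace does not cover the post-event window")
    return(NA_real_)
  }
  median(series$theta[in_win])
}

#' Update the low (deficit) reference with one day of readings
#'
#' The low reference is the running minimum of daily minima since the start
#' of the campaign; it never increases within a campaign and resets between
#' campaigns.
#'
#' @param current_low current low reference, m3/m3 (`NA` to initialize).
#' @param day_theta the day's readings for one sensor.
#' @return the updated low reference; an empty day leaves it unchanged.
#' @export
update_low_reference <- function(current_low, day_theta) {
  if (length(day_theta) == 0) return(current_low)
  m <- min(day_theta, na.rm = TRUE)
  if (is.na(current_low)) m else min(current_low, m)
}

#' Estimate the low (deficit) reference from a full trace
#'
#' The campaign-wide driest value: the running minimum of daily minima,
#' computed on a running-median-smoothed trace (window `smooth_k` samples)
#' so isolated noise excursions do not pull the reference down.
#'
#' @param series data.frame with `timestamp` and `theta`.
#' @param smooth_k odd running-median window, samples (1 = no smoothing).
#' @return the estimated low reference, m3/m3.
#' @export
estimate_low_reference <- function(series, smooth_k = 5) {
  th <- series$theta
  if (length(th) == 0) return(NA_real_)
  if (smooth_k > 1 && length(th) > smooth_k) {
    th <- stats::runmed(th, smooth_k)
  }
  day <- as.Date(series$timestamp)
  daily_min <- tapply(th, day, min)
  low <- NA_real_
  for (m in daily_min) low <- update_low_reference(low, m)
  low
}

#' Normalize a reading between its references
#'
#' `(theta - low) / (high - low)`: 0 at the low reference, 1 at the high
#' reference. Values are clipped to `[-0.25, 1.25]`; clipping is reported via
#' the `clipped` attribute rather than silently discarded, since readings
#' above the high reference after heavy rain are diagnostic.
#'
#' @param theta readings, m3/m3 (vectorized).
#' @param ref a [sensor_reference()].
#' @return normalized values with attribute `clipped` (logical vector).
#' @export
normalize_theta <- function(theta, ref) {
  if (ref$high_ref <= ref$low_ref) stop("invalid reference: high_ref <= low_ref")
  z <- (theta - ref$low_ref) / (ref$high_ref - ref$low_ref)
  clipped <- z < -0.25 | z > 1.25
  out <- pmin(1.25, pmax(-0.25, z))
  attr(out, "clipped") <- clipped
  out
}

#' Invert [normalize_theta()]
#' @param z normalized values.
#' @param ref a [sensor_reference()].
#' @return readings in m3/m3.
#' @export
denormalize_theta <- function(z, ref) {
  ref$low_ref + z * (ref$high_ref - ref$low_ref)
}

#' Aggregate sensor indices to a control-point index
#'
#' Weighted mean of the per-sensor normalized indices over non-faulty
#' sensors, with weights set per position-depth class and renormalized over
#' whatever sensors remain. Defaults weight the fast shallow under-dripper
#' sensors most (A at 0.30 m: 0.5), the deep sensors next (A at 0.60 m: 0.3)
#' and the between-dripper sensor least (B at 0.30 m: 0.2).
#'
#' @param values normalized index per sensor.
#' @param specs sensor layout data.frame with `position` and `depth` (see
#'   [default_sensor_layout()]).
#' @param weights named class weights (`A30`, `A60`, `B30`).
#' @param faulty logical vector marking sensors to exclude.
#' @return the point index, or `NA` ("no signal") when every sensor is
#'   faulty.
#' @export
aggregate_point <- function(values, specs,
                            weights = c(A30 = 0.5, A60 = 0.3, B30 = 0.2),
                            faulty = rep(FALSE, length(values))) {
  stopifnot(length(values) == nrow(specs), length(faulty) == length(values))
  cls <- paste0(specs$position, round(specs$depth * 100))
  w <- weights[cls]
  w[is.na(w)] <- 0
  keep <- !faulty & !is.na(values) & w > 0
  if (!any(keep)) return(NA_real_)
  sum(w[keep] * values[keep]) / sum(w[keep])
}

#' Screen a sensor trace for faults
#'
#' Three flags per sample: `out_of_range` (outside `[0, ceiling]`), `stuck`
#' (rolling variance below tolerance over a trailing window) and `spike`
#' (the sample departs from both neighbors by more than the jump threshold
#' in the same direction, so an isolated glitch is flagged on the glitch
#' sample only, not on the recovery sample).
#'
#' @param theta readings in time order.
#' @param ceiling physical ceiling, m3/m3.
#' @param stuck_window samples in the stuck-detection window.
#' @param stuck_tol variance tolerance below which the trace counts as
#'   stuck.
#' @param spike_jump single-step jump threshold, m3/m3.
#' @return data.frame of logical columns `out_of_range`, `stuck`, `spike`,
#'   `any`.
#' @export
detect_faults <- function(theta, ceiling = 0.60, stuck_window = 288,
                          stuck_tol = 1e-10, spike_jump = 0.1) {
  n <- length(theta)
  if (n == 0) {
    return(data.frame(
      out_of_range = logical(0), stuck = logical(0),
      spike = logical(0), any = logical(0)
    ))
  }
  oor <- theta < 0 | theta > ceiling | !is.finite(theta)
  spike <- rep(FALSE, n)
  if (n >= 3) {
    mid <- 2:(n - 1)
    d_prev <- theta[mid] - theta[mid - 1]
    d_next <- theta[mid] - theta[mid + 1]
    spike[mid] <- abs(d_prev) > spike_jump & abs(d_next) > spike_jump &
      sign(d_prev) == sign(d_next)
  }
  stuck <- rep(FALSE, n)
  if (n >= stuck_window) {
    # rolling variance via cumulative sums
    cs <- cumsum(c(0, theta))
    cs2 <- cumsum(c(0, theta^2))
    i <- stuck_window:n
    m <- (cs[i + 1] - cs[i + 1 - stuck_window]) / stuck_window
    v <- (cs2[i + 1] - cs2[i + 1 - stuck_window]) / stuck_window - m^2
    stuck[i] <- v < stuck_tol
  }
  data.frame(out_of_range = oor, stuck = stuck, spike = spike,
    any = oor | stuck | spike)
}

#' Comfort zone for the normalized soil-water index
#'
#' The band of normalized readings within which the controller applies no
#' feedback correction.
#'
#' @param lower,upper band edges, `0 <= lower < upper <= 1`.
#' @return an object of class `"comfort_zone"`.
#' @export
comfort_zone <- function(lower = 0.4, upper = 0.8) {
  if (!(lower >= 0 && lower < upper && upper <= 1)) {
    stop("need 0 <= lower < upper <= 1")
  }
  structure(list(lower = lower, upper = upper), class = "comfort_zone")
}

#' Refit the comfort zone to observed conditions
#'
#' Empirical readjustment: the new band spans the configured percentiles
#' (default 20th-80th) of the trailing window of point indices. With too
#' little history, or a degenerate (zero-spread) band, the previous zone is
#' kept.
#'
#' @param history recent normalized point indices.
#' @param zone current [comfort_zone()].
#' @param band percentile pair, fractions.
#' @param min_days minimum history length required to refit.
#' @return a [comfort_zone()].
#' @export
refit_comfort_zone <- function(history, zone = comfort_zone(),
                               band = c(0.2, 0.8), min_days = 10) {
  history <- history[!is.na(history)]
  if (length(history) < min_days) return(zone)
  q <- unname(quantile(history, band, type = 7))
  q <- pmin(1, pmax(0, q))
  if (q[2] - q[1] < 1e-6) {
    warning("degenerate comfort band (zero spread); keeping previous zone")
    return(zone)
  }
  comfort_zone(q[1], q[2])
}

#' Read/write sensor reference tables
#'
#' CSV layout mirroring a per-campaign reference table: columns
#' `control_point`, `position`, `sensor_id`, `year`, `high_ref`, `low_ref`.
#'
#' @param refs data.frame in that layout.
#' @param path file path.
#' @return `read_reference_csv` returns the data.frame.
#' @export
write_reference_csv <- function(refs, path) {
  write.csv(refs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
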