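#' Phenology calendar
#'
#' Phase boundaries of the olive irrigation season: Phase I runs from
#' sprouting to the start of pit hardening, Phase II (the drought-tolerant
#' deficit window) from pit hardening to veraison, Phase III from veraison to
#' harvest. Defaults encode the verbal calendar of an Extremadura hedgerow
#' orchard: early March, beginning of July, mid-September, harvest at the end
#' of October.
#'
#' @param phase_1_start,phase_2_start,phase_3_start,season_end `Date`s (or
#'   coercible), strictly increasing.
#' @return an object of class `"pheno_calendar"`.
#' @export
pheno_calendar <- function(phase_1_start = "2016-03-01",
                           phase_2_start = "2016-07-01",
                           phase_3_start = "2016-09-15",
                           season_end = "2016-10-31") {
  d <- as.Date(c(phase_1_start, phase_2_start, phase_3_start, season_end))
  if (any(is.na(d))) stop("calendar dates must be valid dates")
  if (is.unsorted(d, strictly = TRUE)) stop("calendar dates must be strictly increasing")
  structure(list(
    phase_1_start = d[1], phase_2_start = d[2],
    phase_3_start = d[3], season_end = d[4]
  ), class = "pheno_calendar")
}

#' Phenological phase of a date
#'
#' Half-open convention: each phase includes its start date and excludes the
#' next phase's start; dates before Phase I map to `"pre-season"`, dates on or
#' after `season_end` to `"post-season"`. Never errors on out-of-range dates.
#'
#' @param date `Date` vector.
#' @param calendar a [pheno_calendar()].
#' @return character vector in
#'   `c("pre-season", "I", "II", "III", "post-season")`.
#' @export
phase_of <- function(date, calendar) {
  date <- as.Date(date)
  out <- rep("pre-season", length(date))
  out[date >= calendar$phase_1_start] <- "I"
  out[date >= calendar$phase_2_start] <- "II"
  out[date >= calendar$phase_3_start] <- "III"
  out[date >= calendar$season_end] <- "post-season"
  out
}

#' Stem-water-potential thresholds per phase
#'
#' Deficit targets for midday stem water potential: a slight deficit in
#' Phase I (-1.4 MPa), the most severe target during pit hardening in
#' Phase II (-2.0 MPa), and recovery in Phase III (-1.6 MPa).
#'
#' @param phase_1,phase_2,phase_3 thresholds, MPa, all `<= 0` with
#'   `phase_2 <= phase_3 <= phase_1`.
#' @return an object of class `"psi_thresholds"`.
#' @export
psi_thresholds <- function(phase_1 = -1.4, phase_2 = -2.0, phase_3 = -1.6) {
  if (any(c(phase_1, phase_2, phase_3) > 0)) stop("thresholds must be <= 0 MPa")
  if (!(phase_2 <= phase_3 && phase_3 <= phase_1)) {
    stop("expected phase_2 <= phase_3 <= phase_1 (Phase II most severe)")
  }
  structure(list(phase_1 = phase_1, phase_2 = phase_2, phase_3 = phase_3),
    class = "psi_thresholds"
  )
}

#' @param phase phase label(s), `"I"`, `"II"` or `"III"`.
#' @param thresholds a [psi_thresholds()].
#' @rdname psi_thresholds
#' @export
psi_threshold <- function(phase, thresholds = psi_thresholds()) {
  vapply(as.character(phase), function(p) {
    switch(p,
      I = thresholds$phase_1, II = thresholds$phase_2, III = thresholds$phase_3,
      NA_real_
    )
  }, numeric(1), USE.NAMES = FALSE)
}

#' Crop-coefficient curve
#'
#' A Kc curve as dated breakpoints with step or linear interpolation. The
#' `"deficit"` variant encodes a regulated-deficit strategy: its Phase II
#' values are deliberately below the standard curve.
#'
#' @param dates breakpoint dates.
#' @param kc breakpoint Kc values, `>= 0`.
#' @param interpolation `"linear"` or `"step"`.
#' @param variant `"standard"` or `"deficit"`.
#' @return an object of class `"kc_curve"`.
#' @export
kc_curve <- function(dates, kc, interpolation = c("linear", "step"),
                     variant = c("standard", "deficit")) {
  interpolation <- match.arg(interpolation)
  variant <- match.arg(variant)
  dates <- as.Date(dates)
  if (length(dates) == 0) stop("empty Kc curve")
  if (length(dates) != length(kc)) stop("dates and kc lengths differ")
  if (any(kc < 0)) stop("kc values must be >= 0")
  o <- order(dates)
  structure(list(
    dates = dates[o], kc = kc[o],
    interpolation = interpolation, variant = variant
  ), class = "kc_curve")
}

#' Kc value at given dates
#'
#' Outside the breakpoint span the nearest endpoint value holds. With step
#' interpolation a date on a breakpoint takes that breakpoint's value.
#'
#' @param date `Date` vector.
#' @param curve a [kc_curve()].
#' @return numeric Kc values.
#' @export
kc_at <- function(date, curve) {
  date <- as.Date(date)
  xs <- as.numeric(curve$dates)
  x <- as.numeric(date)
  if (length(xs) == 1L) return(rep(curve$kc, length(date)))
  if (curve$interpolation == "linear") {
    stats::approx(xs, curve$kc, xout = x, rule = 2)$y
  } else {
    idx <- findInterval(x, xs)
    curve$kc[pmax(1L, idx)]
  }
}

#' Default Kc curves for a hedgerow olive season
#'
#' Plausible placeholder curves (the study plot's calibrated values are not
#' published as numbers): a standard curve rising from 0.50 in spring to 0.65
#' near harvest, and a deficit-modified variant dropping to 0.30 during
#' Phase II to encode the regulated-deficit strategy. Edit or replace per
#' campaign.
#'
#' @param year calendar year for the breakpoint dates.
#' @return list with `standard` and `deficit` [kc_curve()]s.
#' @export
default_kc_curves <- function(year = 2016L) {
  d <- function(md) as.Date(sprintf("%04d-%s", year, md))
  list(
    standard = kc_curve(
      d(c("03-01", "06-01", "07-01", "09-15", "10-31")),
      c(0.50, 0.55, 0.60, 0.60, 0.65),
      variant = "standard"
    ),
    deficit = kc_curve(
      d(c("03-01", "06-01", "07-01", "09-14", "09-15", "10-31")),
      c(0.45, 0.50, 0.30, 0.30, 0.55, 0.60),
      variant = "deficit"
    )
  )
}

#' Build the seasonal cumulative-irrigation plan
#'
#' The pre-season baseline is the cumulative expected net demand,
#' `sum(max(0, Kc_mod * ETo_clim - Peff_clim))` from the season start, with
#' upper and lower envelopes at `baseline * (1 +/- envelope_pct)`. The
#' automated controller must keep cumulative irrigation between the
#' envelopes. All three curves are non-decreasing by construction.
#'
#' @param curve the deficit-modified [kc_curve()].
#' @param dates season dates (`Date` vector).
#' @param eto_clim expected ETo per date, mm/day.
#' @param peff_clim expected effective rainfall per date, mm/day (default 0).
#' @param envelope_pct half-width of the envelope as a fraction of baseline,
#'   `>= 0`.
#' @return object of class `"seasonal_plan"`: data.frame-backed list with
#'   `date`, `baseline`, `lower`, `upper` (all cumulative mm).
#' @export
build_seasonal_plan <- function(curve, dates, eto_clim, peff_clim = 0,
                                envelope_pct = 0.2) {
  if (envelope_pct < 0) stop("envelope_pct must be >= 0")
  dates <- as.Date(dates)
  n <- length(dates)
  eto_clim <- rep_len(eto_clim, n)
  peff_clim <- rep_len(peff_clim, n)
  daily <- pmax(0, kc_at(dates, curve) * eto_clim - peff_clim)
  base <- cumsum(daily)
  structure(list(
    date = dates, baseline = base,
    lower = base * (1 - envelope_pct),
    upper = base * (1 + envelope_pct),
    envelope_pct = envelope_pct
  ), class = "seasonal_plan")
}

# envelope values at one date (last defined value carries past the end)
plan_at <- function(plan, date) {
  i <- findInterval(as.numeric(as.Date(date)), as.numeric(plan$date))
  if (i < 1) {
    c(lower = 0, upper = 0, baseline = 0)
  } else {
    c(lower = plan$lower[i], upper = plan$upper[i], baseline = plan$baseline[i])
  }
}

#' @export
print.seasonal_plan <- function(x, ...) {
  cat(sprintf(
    "seasonal_plan: %s to %s, baseline %.1f mm, envelope +/-%.0f%%\n",
    x$date[1], x$date[length(x$date)], x$baseline[length(x$baseline)],
    100 * x$envelope_pct
  ))
  invisible(x)
}
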