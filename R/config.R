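#' Validate a run configuration file
#'
#' Reads a YAML configuration, checks it against the schema (unknown keys,
#' missing sections, invariant violations are all collected and reported
#' together, none silently ignored), materializes defaults and returns the
#' validated configuration.
#'
#' Top-level sections: `seed`, `scenario` (see [weather_scenario()] plus
#' `year`), `calendar` (see [pheno_calendar()]), `kc` (optional `standard` /
#' `deficit` breakpoint lists), `thresholds` (see [psi_thresholds()]),
#' `envelope_pct`, `feedback_gain`, `comfort_zone`, `emitter` (see
#' [emitter_geometry()]), `soil` (see [soil_bucket_params()]) and `field`
#' (grid of the synthetic plot).
#'
#' @param path YAML file path.
#' @return an object of class `"run_config"`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  errs <- character(0)
  known <- c(
    "seed", "scenario", "calendar", "kc", "thresholds", "envelope_pct",
    "feedback_gain", "comfort_zone", "emitter", "soil", "field"
  )
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$seed)) errs <- c(errs, "missing required key: seed")

  grab <- function(section, build, label) {
    tryCatch(do.call(build, section %||% list()), error = function(e) {
      errs <<- c(errs, paste0(label, ": ", conditionMessage(e)))
      NULL
    })
  }
  year <- raw$scenario$year %||% 2016L
  sc_args <- raw$scenario
  sc_args$year <- NULL
  scenario <- grab(sc_args, weather_scenario, "scenario")
  calendar <- grab(raw$calendar, pheno_calendar, "calendar")
  thresholds <- grab(raw$thresholds, psi_thresholds, "thresholds")
  comfort <- grab(raw$comfort_zone, comfort_zone, "comfort_zone")
  emitter <- grab(raw$emitter, emitter_geometry, "emitter")
  soil <- grab(raw$soil, soil_bucket_params, "soil")

  kc <- default_kc_curves(year)
  for (v in c("standard", "deficit")) {
    if (!is.null(raw$kc[[v]])) {
      kc[[v]] <- tryCatch(
        kc_curve(raw$kc[[v]]$dates, raw$kc[[v]]$kc, variant = v),
        error = function(e) {
          errs <<- c(errs, paste0("kc$", v, ": ", conditionMessage(e)))
          kc[[v]]
        }
      )
    }
  }
  envelope_pct <- raw$envelope_pct %||% 0.2
  if (envelope_pct < 0) errs <- c(errs, "envelope_pct: must be >= 0")
  gain <- raw$feedback_gain %||% 0.3
  if (gain <= 0 || gain > 1) errs <- c(errs, "feedback_gain: must be in (0, 1]")
  field <- raw$field %||% list()
  field$n_rows <- field$n_rows %||% 30
  field$n_cols <- field$n_cols %||% 31
  field$cell_size <- field$cell_size %||% 10
  if (field$cell_size <= 0) errs <- c(errs, "field$cell_size: must be > 0")

  if (length(errs)) {
    stop(
      "invalid configuration (", length(errs), " problem(s)):\n  - ",
      paste(errs, collapse = "\n  - ")
    )
  }
  structure(list(
    seed = as.integer(raw$seed), year = as.integer(year),
    scenario = scenario, calendar = calendar, kc = kc,
    thresholds = thresholds, envelope_pct = envelope_pct,
    feedback_gain = gain, comfort = comfort, emitter = emitter,
    soil = soil, field = field, source = normalizePath(path)
  ), class = "run_config")
}

#' Run the full pipeline into a self-describing output directory
#'
#' Executes the requested stages in dependency order -- `gen-data` (weather,
#' field truth, ECa survey, reflectances), `zoning` (variogram fit, kriged
#' ECa, NDVI, zone map), `season` (closed-loop simulation ledger) and
#' `metrics` (phase totals) -- writing every artifact as CSV or ASCII grid
#' plus a manifest with per-file MD5 checksums. Inputs are never mutated;
#' rerunning with the same configuration reproduces identical checksums.
#'
#' @param config a [validate_config()] object.
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("gen-data", "zoning", "season", "metrics")`.
#' @return invisibly, the manifest data.frame (`stage`, `file`, `md5`).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("gen-data", "zoning", "season", "metrics")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(0), file = character(0), md5 = character(0))
  note <- function(stage, files) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files))
    ))
  }
  p <- function(f) file.path(out_dir, f)

  if ("gen-data" %in% stages) {
    weather <- gen_weather(config$scenario, year = config$year, seed = config$seed)
    write_weather_csv(weather, p("weather.csv"))
    truth <- gen_field_truth(config$field$n_rows, config$field$n_cols,
      config$field$cell_size,
      seed = config$seed
    )
    survey <- gen_eca_survey(truth, seed = config$seed)
    write.csv(survey, p("eca_survey.csv"), row.names = FALSE)
    refl <- gen_reflectance(truth, seed = config$seed)
    write_ascii_grid(refl$red, p("red.asc"))
    write_ascii_grid(refl$nir, p("nir.asc"))
    write_ascii_grid(truth$zone_truth, p("zones_truth.asc"))
    note("gen-data", p(c(
      "weather.csv", "eca_survey.csv", "red.asc", "nir.asc", "zones_truth.asc"
    )))
  }

  if ("zoning" %in% stages) {
    need <- p(c("eca_survey.csv", "red.asc", "nir.asc"))
    missing <- need[!file.exists(need)]
    if (length(missing)) {
      stop("zoning needs artifacts from gen-data; missing: ",
        paste(basename(missing), collapse = ", "))
    }
    survey <- read.csv(p("eca_survey.csv"))
    red <- read_ascii_grid(p("red.asc"))
    nir <- read_ascii_grid(p("nir.asc"))
    # thin the survey for variogram estimation; kriging uses all points
    idx <- seq(1, nrow(survey), by = max(1L, nrow(survey) %/% 400))
    emp <- empirical_variogram(survey$x[idx], survey$y[idx], survey$eca[idx],
      lag_width = 10, max_lag = 150
    )
    vgm <- fit_variogram(emp)
    kr <- ordinary_krige(survey$x, survey$y, survey$eca, vgm, red)
    ndvi <- compute_ndvi(red, nir)
    zones <- combine_zones(
      classify_layer(kr$prediction, breaks = c(10, 15)),
      classify_layer(ndvi, breaks = c(0.40, 0.45))
    )
    write_ascii_grid(kr$prediction, p("eca_kriged.asc"))
    write_ascii_grid(ndvi, p("ndvi.asc"))
    write_ascii_grid(zones, p("zones.asc"))
    note("zoning", p(c("eca_kriged.asc", "ndvi.asc", "zones.asc")))
  }

  if ("season" %in% stages) {
    if (!file.exists(p("weather.csv"))) {
      stop("season needs artifacts from gen-data; missing: weather.csv")
    }
    weather <- read_weather_csv(p("weather.csv"))
    season <- run_season(weather,
      calendar = config$calendar,
      kc_standard = config$kc$standard, kc_deficit = config$kc$deficit,
      soil = config$soil, comfort = config$comfort,
      gain = config$feedback_gain, envelope_pct = config$envelope_pct,
      seed = config$seed
    )
    write.csv(season$ledger, p("season_ledger.csv"), row.names = FALSE)
    note("season", p("season_ledger.csv"))
  }

  if ("metrics" %in% stages) {
    if (!file.exists(p("season_ledger.csv"))) {
      stop("metrics needs artifacts from season; missing: season_ledger.csv")
    }
    led <- read.csv(p("season_ledger.csv"))
    doses <- data.frame(point_id = "CR", date = as.Date(led$date), depth = led$dose)
    pt <- phase_totals(doses, config$calendar)
    write.csv(pt, p("phase_totals.csv"), row.names = FALSE)
    note("metrics", p("phase_totals.csv"))
  }

  cfg_copy <- p("config.yaml")
  file.copy(config$source, cfg_copy, overwrite = TRUE)
  manifest <- rbind(manifest, data.frame(
    stage = "config", file = "config.yaml",
    md5 = unname(tools::md5sum(cfg_copy))
  ))
  write.csv(manifest, p("manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
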