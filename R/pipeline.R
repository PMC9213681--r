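## End-to-end orchestration: simulate -> qc -> metrics -> events -> project
## -> surface -> report, with a YAML-backed configuration and a JSON run
## manifest.  Every stage writes plain CSV; later stages reload prerequisites
## from the output directory when run standalone.

#' Default pipeline configuration
#'
#' All stage parameters with their conventional defaults: frost events below
#' -1 C for >= 3 h (analysis weeks 2-10), abnormal heat above 25 C for >= 3 h
#' (weeks 49-8), chill window 1 Nov - 28 Feb, heat window 1 Jan - 8 Apr, QC
#' rule >= 90 % window completeness and >= 5 complete seasons, IDW power 2
#' with a 50 km mask on a 0.05 degree grid, 10 % probability display cutoff,
#' and the four default warming scenarios with 11 pseudo-GCMs.  The default
#' network is a 12-station fixture spanning the three archetypes.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 42L,
    network = list(n_stations = 12L,
                   bbox = c(lat_min = 37, lat_max = 43,
                            lon_min = -7, lon_max = 1),
                   archetype_mix = c(warm_coastal = 0.25,
                                     intermediate = 0.375,
                                     cold_interior = 0.375),
                   years = c(2000L, 2020L)),
    qc = list(min_years = 5L, min_fraction = 0.9),
    events = list(frost = list(threshold = -1, min_hours = 3L,
                               weeks = 2:10),
                  abnormal_heat = list(threshold = 25, min_hours = 3L,
                                       weeks = c(49:52, 1:8)),
                  probability_cutoff = 0.10),
    scenarios = list(`2035_RCP4.5` = list(horizon = "2035", rcp = "RCP4.5",
                                          mean_offset = 1.2),
                     `2035_RCP8.5` = list(horizon = "2035", rcp = "RCP8.5",
                                          mean_offset = 1.5),
                     `2055_RCP4.5` = list(horizon = "2055", rcp = "RCP4.5",
                                          mean_offset = 1.9),
                     `2055_RCP8.5` = list(horizon = "2055", rcp = "RCP8.5",
                                          mean_offset = 2.9)),
    projection = list(ensemble_size = 11L, gcm_spread_sd = 0.3,
                      n_seasons = 5L),
    idw = list(power = 2, mask_km = 50, cell_deg = 0.05),
    classes = list(low_bound = 60, high_bound = 80)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults; everything else keeps
#' its [default_config()] value.
#'
#' @param path YAML file path (`NULL` for pure defaults).
#' @return configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  stop_if_not(file.exists(path), "config file not found: %s", path)
  user <- yaml::read_yaml(path)
  merge_config(cfg, user)
}

#' @noRd
merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(user[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      v <- user[[k]]
      if (!is.null(names(base[[k]])) && is.null(names(v)) &&
          length(v) == length(base[[k]])) names(v) <- names(base[[k]])
      base[[k]] <- v
    }
  }
  base
}

## Stable hash of the semantic configuration (md5 of its deparsed form).
#' @noRd
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config, control = "exact"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the agroclimatic pipeline
#'
#' Executes the requested stages in order, writing each stage's outputs as
#' CSV under `outdir` and finishing with a JSON manifest (configuration
#' hash, package version, seeds, per-stage files and row counts).  The run
#' is deterministic given the configuration.  Stages not requested are
#' loaded from `outdir` when a later stage needs them.
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir output directory (created if missing).
#' @param stages character vector of stages, in pipeline order, among
#'   `"simulate"`, `"qc"`, `"metrics"`, `"events"`, `"project"`,
#'   `"surface"`, `"report"`.
#' @param quiet suppress per-stage progress messages.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir,
                         stages = c("simulate", "qc", "metrics", "events",
                                    "project", "surface", "report"),
                         quiet = FALSE) {
  all_stages <- c("simulate", "qc", "metrics", "events", "project",
                  "surface", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(parent = emptyenv())
  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(
                     utils::packageVersion("agrochill")),
                   seed = config$seed, stages = list())
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(fmt, ...))
  }
  t_all <- proc.time()[["elapsed"]]

  record <- function(stage, files) {
    rows <- vapply(files, function(f) {
      length(readLines(file.path(outdir, f))) - 1L
    }, integer(1))
    manifest$stages[[stage]] <<- list(files = as.list(setNames(rows, files)))
  }

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    files <- switch(
      stage,
      simulate = stage_simulate(config, outdir, env),
      qc = stage_qc(config, outdir, env),
      metrics = stage_metrics(config, outdir, env),
      events = stage_events(config, outdir, env),
      project = stage_project(config, outdir, env),
      surface = stage_surface(config, outdir, env),
      report = stage_report(config, outdir, env)
    )
    record(stage, files)
    say("[%s] wrote %s (%.1f s)", stage, paste(files, collapse = ", "),
        proc.time()[["elapsed"]] - t0)
  }

  say("pipeline finished in %.1f s", proc.time()[["elapsed"]] - t_all)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

## ---- stage helpers ---------------------------------------------------------

#' @noRd
pipe_stations <- function(config, outdir, env) {
  if (is.null(env$stations)) {
    f <- file.path(outdir, "stations.csv")
    stop_if_not(file.exists(f), "stage needs stations.csv; run 'simulate'")
    env$stations <- read_station_csv(f)
  }
  env$stations
}

#' @noRd
pipe_retained <- function(config, outdir, env) {
  if (is.null(env$retained)) {
    f <- file.path(outdir, "qc_report.csv")
    stop_if_not(file.exists(f), "stage needs qc_report.csv; run 'qc'")
    qc <- read.csv(f, stringsAsFactors = FALSE,
                   colClasses = c(station_id = "character"))
    stations <- pipe_stations(config, outdir, env)
    keep <- qc$station_id[qc$retained]
    env$retained <- station_set(
      stations$meta[stations$meta$station_id %in% keep, , drop = FALSE],
      stations$records[stations$records$station_id %in% keep, , drop = FALSE])
  }
  env$retained
}

#' @noRd
pipe_means <- function(config, outdir, env) {
  if (is.null(env$means)) {
    f <- file.path(outdir, "station_means.csv")
    stop_if_not(file.exists(f), "stage needs station_means.csv; run 'metrics'")
    env$means <- read.csv(f, stringsAsFactors = FALSE,
                          colClasses = c(station_id = "character"))
  }
  env$means
}

#' @noRd
stage_simulate <- function(config, outdir, env) {
  spec <- network_spec(n_stations = config$network$n_stations,
                       bbox = unlist(config$network$bbox),
                       archetype_mix = unlist(config$network$archetype_mix),
                       years = config$network$years,
                       seed = config$seed)
  env$stations <- generate_station_network(spec)
  write_station_csv(env$stations, file.path(outdir, "stations.csv"))
  write.csv(env$stations$meta, file.path(outdir, "stations_meta.csv"),
            row.names = FALSE)
  c("stations.csv", "stations_meta.csv")
}

#' @noRd
stage_qc <- function(config, outdir, env) {
  stations <- pipe_stations(config, outdir, env)
  qc <- screen_network(stations, min_years = config$qc$min_years,
                       min_fraction = config$qc$min_fraction)
  write.csv(qc, file.path(outdir, "qc_report.csv"), row.names = FALSE)
  keep <- qc$station_id[qc$retained]
  env$retained <- station_set(
    stations$meta[stations$meta$station_id %in% keep, , drop = FALSE],
    stations$records[stations$records$station_id %in% keep, , drop = FALSE])
  env$qc <- qc
  "qc_report.csv"
}

#' @noRd
stage_metrics <- function(config, outdir, env) {
  retained <- pipe_retained(config, outdir, env)
  sm <- season_metrics(retained, min_fraction = config$qc$min_fraction)
  means <- station_means(sm)
  write.csv(sm, file.path(outdir, "season_metrics.csv"), row.names = FALSE)
  write.csv(means, file.path(outdir, "station_means.csv"), row.names = FALSE)
  env$season_metrics <- sm
  env$means <- means
  c("season_metrics.csv", "station_means.csv")
}

#' @noRd
event_defs_from_config <- function(config) {
  list(frost = event_definition(
    "frost", threshold = config$events$frost$threshold,
    min_consecutive_hours = config$events$frost$min_hours),
    abnormal_heat = event_definition(
      "abnormal_heat", threshold = config$events$abnormal_heat$threshold,
      min_consecutive_hours = config$events$abnormal_heat$min_hours))
}

#' @noRd
stage_events <- function(config, outdir, env) {
  retained <- pipe_retained(config, outdir, env)
  defs <- event_defs_from_config(config)
  qc <- screen_network(retained, min_years = config$qc$min_years,
                       min_fraction = config$qc$min_fraction)
  ny <- setNames(qc$years_complete, qc$station_id)
  frost_ev <- detect_events(retained, defs$frost)
  heat_ev <- detect_events(retained, defs$abnormal_heat)
  frost_p <- weekly_probabilities(frost_ev, ny,
                                  weeks = config$events$frost$weeks,
                                  station_ids = retained$meta$station_id)
  heat_p <- weekly_probabilities(heat_ev, ny,
                                 weeks = config$events$abnormal_heat$weeks,
                                 station_ids = retained$meta$station_id)
  frost_p$kind <- "frost"
  heat_p$kind <- "abnormal_heat"
  events <- rbind(frost_ev, heat_ev)
  events$start <- format(events$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  probs <- rbind(frost_p, heat_p)
  write.csv(events, file.path(outdir, "events.csv"), row.names = FALSE)
  write.csv(probs, file.path(outdir, "event_probabilities.csv"),
            row.names = FALSE)
  env$event_probs <- probs
  c("events.csv", "event_probabilities.csv")
}

#' @noRd
stage_project <- function(config, outdir, env) {
  retained <- pipe_retained(config, outdir, env)
  files <- character(0)
  env$ensembles <- list()
  for (k in seq_along(config$scenarios)) {
    sc <- config$scenarios[[k]]
    spec <- warming_scenario_spec(sc$horizon, sc$rcp,
                                  mean_offset = sc$mean_offset,
                                  gcm_spread_sd =
                                    config$projection$gcm_spread_sd,
                                  ensemble_size =
                                    config$projection$ensemble_size,
                                  seed = config$seed + k)
    proj <- generate_projection_ensemble(retained, spec,
                                         n_seasons =
                                           config$projection$n_seasons)
    em <- run_scenario(retained, proj,
                       frost_weeks = config$events$frost$weeks,
                       heat_weeks = config$events$abnormal_heat$weeks)
    label <- paste(spec$horizon, spec$rcp, sep = "_")
    env$ensembles[[label]] <- em
    f1 <- sprintf("scenario_%s_per_gcm.csv", label)
    f2 <- sprintf("scenario_%s_ensemble.csv", label)
    f3 <- sprintf("scenario_%s_event_probabilities.csv", label)
    write.csv(em$per_gcm, file.path(outdir, f1), row.names = FALSE)
    write.csv(em$ensemble, file.path(outdir, f2), row.names = FALSE)
    write.csv(em$event_probabilities, file.path(outdir, f3),
              row.names = FALSE)
    files <- c(files, f1, f2, f3)
  }
  files
}

#' @noRd
pipe_ensembles <- function(config, outdir, env) {
  if (is.null(env$ensembles)) {
    env$ensembles <- list()
    for (label in names(config$scenarios)) {
      f <- file.path(outdir, sprintf("scenario_%s_ensemble.csv", label))
      stop_if_not(file.exists(f), "stage needs %s; run 'project'", basename(f))
      env$ensembles[[label]] <- list(
        ensemble = read.csv(f, stringsAsFactors = FALSE,
                            colClasses = c(station_id = "character")))
    }
  }
  env$ensembles
}

#' @noRd
stage_surface <- function(config, outdir, env) {
  retained <- pipe_retained(config, outdir, env)
  means <- pipe_means(config, outdir, env)
  ensembles <- pipe_ensembles(config, outdir, env)
  coords <- retained$meta[, c("station_id", "lat", "lon")]
  layers <- list(current_chill_portions =
                   setNames(means$chill_portions, means$station_id),
                 current_gdh_anderson =
                   setNames(means$gdh_anderson, means$station_id))
  for (label in names(ensembles)) {
    e <- if (inherits(ensembles[[label]], "ensemble_metrics"))
      ensembles[[label]]$ensemble else ensembles[[label]]$ensemble
    layers[[sprintf("%s_chill_portions", label)]] <-
      setNames(e$chill_portions, e$station_id)
    layers[[sprintf("%s_gdh_anderson", label)]] <-
      setNames(e$gdh_anderson, e$station_id)
  }
  files <- character(0)
  for (nm in names(layers)) {
    v <- layers[[nm]]
    vals <- data.frame(station_id = coords$station_id, lat = coords$lat,
                       lon = coords$lon,
                       value = as.numeric(v[coords$station_id]),
                       stringsAsFactors = FALSE)
    surf <- idw_surface(vals, power = config$idw$power,
                        mask_km = config$idw$mask_km,
                        cell_deg = config$idw$cell_deg)
    f1 <- sprintf("surface_%s.csv", nm)
    f2 <- sprintf("surface_%s.geojson", nm)
    write.csv(as.data.frame(surf), file.path(outdir, f1), row.names = FALSE)
    surface_to_geojson(surf, file.path(outdir, f2))
    files <- c(files, f1)
  }
  files
}

#' @noRd
stage_report <- function(config, outdir, env) {
  means <- pipe_means(config, outdir, env)
  ensembles <- pipe_ensembles(config, outdir, env)
  cls <- classify_station(means$chill_portions,
                          low_bound = config$classes$low_bound,
                          high_bound = config$classes$high_bound)
  classes <- data.frame(station_id = means$station_id,
                        chill_portions = means$chill_portions,
                        class = cls, stringsAsFactors = FALSE)

  agree_chill <- model_agreement(means$chill_utah, means$chill_portions)
  agree_heat <- model_agreement(means$gdh_richardson, means$gdh_anderson)
  agreement <- data.frame(
    comparison = c("utah_vs_dynamic", "richardson_vs_anderson"),
    r_squared = c(agree_chill$r_squared, agree_heat$r_squared),
    pearson_r = c(agree_chill$pearson_r, agree_heat$pearson_r),
    n = c(agree_chill$n, agree_heat$n))

  box_rows <- list(data.frame(station_id = classes$station_id,
                              class = classes$class, scenario = "current",
                              value = means$chill_portions,
                              stringsAsFactors = FALSE))
  deltas <- list()
  for (label in names(ensembles)) {
    e <- if (inherits(ensembles[[label]], "ensemble_metrics"))
      ensembles[[label]]$ensemble else ensembles[[label]]$ensemble
    m <- match(classes$station_id, e$station_id)
    box_rows[[length(box_rows) + 1L]] <-
      data.frame(station_id = classes$station_id, class = classes$class,
                 scenario = label, value = e$chill_portions[m],
                 stringsAsFactors = FALSE)
    d <- chill_delta(means, e)
    d$scenario <- label
    deltas[[label]] <- d
  }
  boxes <- class_summary(do.call(rbind, box_rows))
  deltas <- do.call(rbind, deltas)
  delta_cor <- do.call(rbind, lapply(split(deltas, deltas$scenario),
                                     function(d) {
    data.frame(scenario = d$scenario[1L],
               pearson_r = cor(d$chill_lost, d$heat_gained),
               n = nrow(d), stringsAsFactors = FALSE)
  }))

  write.csv(classes, file.path(outdir, "report_classes.csv"),
            row.names = FALSE)
  write.csv(agreement, file.path(outdir, "report_model_agreement.csv"),
            row.names = FALSE)
  write.csv(boxes, file.path(outdir, "report_class_boxstats.csv"),
            row.names = FALSE)
  write.csv(deltas, file.path(outdir, "report_chill_delta.csv"),
            row.names = FALSE)
  write.csv(delta_cor, file.path(outdir, "report_delta_correlation.csv"),
            row.names = FALSE)
  c("report_classes.csv", "report_model_agreement.csv",
    "report_class_boxstats.csv", "report_chill_delta.csv",
    "report_delta_correlation.csv")
}
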