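## Per-GCM scenario runs, station-to-grid matching, and ensemble averaging.

#' Validate a scenario key
#'
#' @param horizon `"2035"` (2025-2045) or `"2055"` (2045-2065).
#' @param rcp `"RCP4.5"` or `"RCP8.5"`.
#' @return list with `horizon`, `rcp` and `label` (`"<horizon>_<rcp>"`).
#' @export
scenario_key <- function(horizon, rcp) {
  horizon <- match.arg(as.character(horizon), c("2035", "2055"))
  rcp <- match.arg(rcp, c("RCP4.5", "RCP8.5"))
  list(horizon = horizon, rcp = rcp, label = paste(horizon, rcp, sep = "_"))
}

#' Match stations to their nearest grid points
#'
#' Nearest neighbour by great-circle distance (spherical earth, radius
#' 6371 km).  Summary distance statistics (min/mean/max, km) are attached as
#' attribute `"distance_summary"`.
#'
#' @param stations a `station_set` or a data.frame with station_id, lat, lon.
#' @param grid data.frame with grid_id, lat, lon.
#' @return data.frame: station_id, grid_id, distance_km.
#' @export
match_stations_to_grid <- function(stations, grid) {
  meta <- if (inherits(stations, "station_set")) stations$meta else stations
  stop_if_not(is.data.frame(grid) && nrow(grid) >= 1, "empty grid")
  dm <- distance_matrix_km(meta$lat, meta$lon, grid$lat, grid$lon)
  nearest <- apply(dm, 1L, which.min)
  dist <- dm[cbind(seq_len(nrow(meta)), nearest)]
  out <- data.frame(station_id = meta$station_id,
                    grid_id = grid$grid_id[nearest],
                    distance_km = dist, stringsAsFactors = FALSE)
  attr(out, "distance_summary") <-
    c(min = min(dist), mean = mean(dist), max = max(dist))
  out
}

#' Run the full metric stack for one warming scenario
#'
#' For every station and pseudo-GCM: reconstruct hourly temperatures from the
#' matched grid point's daily projections ([idealize_series()]), accumulate
#' season metrics over the chill and heat windows, average over season-years
#' (per-GCM climatology first), and detect frost / abnormal-heat events with
#' their weekly probabilities.  The ensemble value is the unweighted
#' arithmetic mean (optionally the median) across GCMs.
#'
#' @param stations a `station_set` (provides station coordinates).
#' @param projections a `projection_set` or its long daily data.frame.
#' @param matches optional precomputed [match_stations_to_grid()] result;
#'   computed from the projection grid when omitted.
#' @param events if `TRUE` (default) also compute weekly event
#'   probabilities per GCM and their ensemble average.
#' @param frost_weeks,heat_weeks analysis week ranges.
#' @param statistic `"mean"` (default) or `"median"` across GCMs.
#' @return object of class `ensemble_metrics`: list with `per_gcm`
#'   (station_id, gcm, n_seasons, metric means), `ensemble` (station_id,
#'   metric means across GCMs), `event_probabilities` (station_id, kind,
#'   week, probability averaged across GCMs; `NULL` if `events = FALSE`),
#'   `matches`, and `scenario`.
#' @export
run_scenario <- function(stations, projections, matches = NULL,
                         events = TRUE, frost_weeks = 2:10,
                         heat_weeks = c(49:52, 1:8),
                         statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (inherits(projections, "projection_set")) {
    proj_df <- projections$projections
    grid <- projections$grid
    scen <- projections$scenario
  } else {
    proj_df <- projections
    grid <- unique(proj_df[, c("grid_id", "lat", "lon")])
    scen <- NULL
  }
  meta <- stations$meta
  if (is.null(matches)) {
    matches <- match_stations_to_grid(stations, grid)
  }
  gcms <- sort(unique(proj_df$gcm))
  by_cell <- split(proj_df, list(proj_df$grid_id, proj_df$gcm), drop = TRUE)

  per_gcm <- vector("list", nrow(meta) * length(gcms))
  ev_rows <- list()
  k <- 0L
  for (i in seq_len(nrow(meta))) {
    gid <- matches$grid_id[matches$station_id == meta$station_id[i]]
    glat <- grid$lat[match(gid, grid$grid_id)]
    for (g in gcms) {
      cell <- by_cell[[paste(gid, g, sep = ".")]]
      stop_if_not(!is.null(cell) && nrow(cell) > 0,
                  "missing projections for grid point %s, GCM %s", gid, g)
      daily <- cell[order(cell$date), c("date", "tmin_c", "tmax_c")]
      hourly <- idealize_series(daily, glat)
      hourly$station_id <- meta$station_id[i]
      sm <- season_metrics(station_set(meta[i, , drop = FALSE], hourly))
      sm <- sm[sm$complete, , drop = FALSE]
      stop_if_not(nrow(sm) > 0,
                  "no complete projected season for station %s, GCM %s",
                  meta$station_id[i], g)
      k <- k + 1L
      per_gcm[[k]] <- data.frame(
        station_id = meta$station_id[i], gcm = g,
        n_seasons = nrow(sm),
        chill_utah = mean(sm$chill_utah),
        chill_portions = mean(sm$chill_portions),
        gdh_richardson = mean(sm$gdh_richardson),
        gdh_anderson = mean(sm$gdh_anderson), stringsAsFactors = FALSE)
      if (events) {
        ny <- nrow(sm)
        frost <- weekly_probabilities(
          detect_events(hourly, event_definition("frost")),
          n_years = ny, weeks = frost_weeks,
          station_ids = meta$station_id[i])
        heat <- weekly_probabilities(
          detect_events(hourly, event_definition("abnormal_heat")),
          n_years = ny, weeks = heat_weeks,
          station_ids = meta$station_id[i])
        frost$kind <- "frost"
        heat$kind <- "abnormal_heat"
        ev <- rbind(frost, heat)
        ev$gcm <- g
        ev_rows[[length(ev_rows) + 1L]] <- ev
      }
    }
  }
  per_gcm <- do.call(rbind, per_gcm[seq_len(k)])

  stat_fun <- if (statistic == "mean") mean else stats::median
  metric_cols <- c("chill_utah", "chill_portions", "gdh_richardson",
                   "gdh_anderson")
  ids <- meta$station_id
  ens <- data.frame(station_id = ids, stringsAsFactors = FALSE)
  for (m in metric_cols) {
    v <- tapply(per_gcm[[m]], per_gcm$station_id, stat_fun)
    ens[[m]] <- as.numeric(v[ids])
  }

  ev_tab <- NULL
  if (events) {
    ev_all <- do.call(rbind, ev_rows)
    keyv <- paste(ev_all$station_id, ev_all$kind, ev_all$week)
    p <- tapply(ev_all$probability, keyv, stat_fun)
    u <- unique(ev_all[, c("station_id", "kind", "week")])
    ev_tab <- data.frame(u,
                         probability = as.numeric(
                           p[paste(u$station_id, u$kind, u$week)]),
                         stringsAsFactors = FALSE)
    rownames(ev_tab) <- NULL
  }

  structure(list(per_gcm = per_gcm, ensemble = ens,
                 event_probabilities = ev_tab, matches = matches,
                 scenario = scen),
            class = "ensemble_metrics")
}

#' Chill lost and heat gained between current and future scenarios
#'
#' @param current per-station current means (result of [station_means()]).
#' @param future an `ensemble_metrics` object or its `ensemble` data.frame.
#' @return data.frame: station_id, chill_lost (current - future chill
#'   portions), heat_gained (future - current Anderson GDH).
#' @export
chill_delta <- function(current, future) {
  if (inherits(future, "ensemble_metrics")) future <- future$ensemble
  m <- merge(current[, c("station_id", "chill_portions", "gdh_anderson")],
             future[, c("station_id", "chill_portions", "gdh_anderson")],
             by = "station_id", suffixes = c("_current", "_future"))
  stop_if_not(nrow(m) > 0, "no stations shared between current and future")
  data.frame(station_id = m$station_id,
             chill_lost = m$chill_portions_current - m$chill_portions_future,
             heat_gained = m$gdh_anderson_future - m$gdh_anderson_current,
             stringsAsFactors = FALSE)
}
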