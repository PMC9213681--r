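## Seasonal accumulation of the four model kernels over the chill window
## (1 Nov - 28 Feb) and heat window (1 Jan - 8 Apr).

#' Accumulate season metrics for one station-season
#'
#' Sums the Utah and Dynamic chill kernels over the chill window and the
#' Richardson and Anderson GDH kernels over the heat window, using exactly
#' the hours present in the record; missing hours contribute nothing and show
#' up as an `hours_*` shortfall.  The Dynamic-model recursion runs over the
#' present chill-window hours in time order (state persists across gaps).
#'
#' @param records one station's hourly records (station_id, timestamp, year,
#'   doy, hour, temp_c), or a `station_set` restricted to one station.
#' @param season_year season label (calendar year of the 1 November start).
#' @param min_fraction completeness fraction below which a window is flagged
#'   incomplete (default 0.9).
#' @return one-row data.frame: station_id, season_year, chill_utah,
#'   chill_portions, gdh_richardson, gdh_anderson, hours_chill, hours_heat,
#'   complete.
#' @export
accumulate_season <- function(records, season_year, min_fraction = 0.9) {
  if (inherits(records, "station_set")) records <- records$records
  season_year <- as.integer(season_year)
  sid <- if (nrow(records) > 0) records$station_id[1L] else NA_character_

  chill_idx <- window_mask(records$year, records$doy, "chill", season_year)
  heat_idx <- window_mask(records$year, records$doy, "heat", season_year)
  chill <- records[chill_idx, ]
  heat <- records[heat_idx, ]
  chill <- chill[order(chill$timestamp), ]
  heat <- heat[order(heat$timestamp), ]

  chill_cap <- season_window("chill", season_year)$capacity_hours
  heat_cap <- season_window("heat", season_year)$capacity_hours

  data.frame(
    station_id = sid, season_year = season_year,
    chill_utah = sum(utah_hour(chill$temp_c)),
    chill_portions = dynamic_portions(chill$temp_c)$portions,
    gdh_richardson = sum(gdh_richardson_hour(heat$temp_c)),
    gdh_anderson = sum(gdh_anderson_hour(heat$temp_c)),
    hours_chill = nrow(chill), hours_heat = nrow(heat),
    complete = nrow(chill) >= min_fraction * chill_cap &
      nrow(heat) >= min_fraction * heat_cap,
    stringsAsFactors = FALSE)
}

#' Season metrics for every station-season of a network
#'
#' @param stations a `station_set` (observed or idealized records).
#' @param min_fraction completeness flag threshold per window (default 0.9).
#' @return data.frame with one row per station x candidate season (see
#'   [accumulate_season()]).
#' @export
season_metrics <- function(stations, min_fraction = 0.9) {
  stopifnot(inherits(stations, "station_set"))
  by_station <- split(stations$records, stations$records$station_id)
  rows <- lapply(by_station, function(r) {
    seasons <- station_candidate_seasons(r)
    do.call(rbind, lapply(seasons, accumulate_season, records = r,
                          min_fraction = min_fraction))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Candidate seasons of one station: those with records in the chill window.
#' @noRd
station_candidate_seasons <- function(records) {
  years <- sort(unique(records$year))
  cand <- sort(unique(c(years - 1L, years)))
  keep <- vapply(cand, function(y) {
    any(window_mask(records$year, records$doy, "chill", y))
  }, logical(1))
  cand[keep]
}

#' Per-station climatological means over complete seasons
#'
#' @param metrics result of [season_metrics()].
#' @param complete_only average only seasons whose windows meet the
#'   completeness flag (default `TRUE`).
#' @return data.frame: station_id, n_seasons, chill_utah, chill_portions,
#'   gdh_richardson, gdh_anderson (means over the retained seasons).
#' @export
station_means <- function(metrics, complete_only = TRUE) {
  if (complete_only) metrics <- metrics[metrics$complete, ]
  stop_if_not(nrow(metrics) > 0, "no complete station-seasons to average")
  agg <- function(v) tapply(v, metrics$station_id, mean)
  ids <- sort(unique(metrics$station_id))
  data.frame(station_id = ids,
             n_seasons = as.integer(table(metrics$station_id)[ids]),
             chill_utah = as.numeric(agg(metrics$chill_utah)[ids]),
             chill_portions = as.numeric(agg(metrics$chill_portions)[ids]),
             gdh_richardson = as.numeric(agg(metrics$gdh_richardson)[ids]),
             gdh_anderson = as.numeric(agg(metrics$gdh_anderson)[ids]),
             stringsAsFactors = FALSE)
}
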