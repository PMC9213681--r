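## Fixtures built in code: window-aligned hourly records and a lazily
## computed shared synthetic network for the heavier end-to-end checks.

## Hourly POSIXct sequence covering a season window.
window_hours <- function(kind, season_year) {
  w <- season_window(kind, season_year)
  seq(as.POSIXct(paste(w$start, "00:00:00"), tz = "UTC"),
      as.POSIXct(paste(w$end, "23:00:00"), tz = "UTC"), by = "hour")
}

## Records data.frame from timestamps and temperatures (recycled).
records_from_hours <- function(ts, temp_c, station_id = "S1") {
  lt <- as.POSIXlt(ts, tz = "UTC")
  data.frame(station_id = station_id, timestamp = ts,
             year = lt$year + 1900L, doy = lt$yday + 1L, hour = lt$hour,
             temp_c = rep_len(temp_c, length(ts)), stringsAsFactors = FALSE)
}

## Both windows of a season at a constant temperature, excluding 29 Feb from
## the chill window by construction of window_hours().
season_records <- function(season_year, temp_c = 6, station_id = "S1") {
  ts <- unique(c(window_hours("chill", season_year),
                 window_hours("heat", season_year)))
  records_from_hours(sort(ts), temp_c, station_id)
}

## One-archetype network spec helper.
single_archetype_spec <- function(n_stations, years, seed, name = "only") {
  network_spec(n_stations = n_stations,
               archetype_mix = setNames(1, name), years = years, seed = seed)
}

## Shared 60-station network spanning the three archetypes, its current
## climatology, and two scenario runs; computed once per test session.
.acc <- new.env(parent = emptyenv())

acc_network <- function() {
  if (is.null(.acc$net)) {
    spec <- network_spec(n_stations = 60, years = c(2000, 2020), seed = 1234)
    .acc$net <- generate_station_network(spec)
  }
  .acc$net
}

acc_means <- function() {
  if (is.null(.acc$means)) {
    .acc$means <- station_means(season_metrics(acc_network()))
  }
  .acc$means
}

acc_scenario <- function(label) {
  key <- paste0("sc_", label)
  if (is.null(.acc[[key]])) {
    sc <- default_scenarios()[[label]]
    proj <- generate_projection_ensemble(acc_network(), sc)
    .acc[[key]] <- run_scenario(acc_network(), proj, events = FALSE)
  }
  .acc[[key]]
}
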