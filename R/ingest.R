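## Station container, hourly CSV input/output, and the completeness screen
## that mirrors a regulatory station-selection step (retain a station only if
## it has enough complete dormancy seasons).

#' Construct a station set
#'
#' @param meta data.frame with at least station_id, lat, lon.
#' @param records long hourly data.frame with station_id, timestamp (POSIXct,
#'   UTC), year, doy, hour, temp_c.
#' @return object of class `station_set`.
#' @export
station_set <- function(meta, records) {
  stopifnot(is.data.frame(meta), is.data.frame(records))
  stop_if_not(all(c("station_id", "lat", "lon") %in% names(meta)),
              "meta needs station_id, lat, lon")
  stop_if_not(all(c("station_id", "timestamp", "temp_c") %in% names(records)),
              "records need station_id, timestamp, temp_c")
  stop_if_not(all(meta$lat >= -90 & meta$lat <= 90), "latitude out of range")
  stop_if_not(all(meta$lon >= -180 & meta$lon <= 180),
              "longitude out of range")
  if (nrow(records) > 0) {
    stop_if_not(all(records$temp_c >= -40 & records$temp_c <= 55),
                "temperatures outside physical bounds [-40, 55] C")
  }
  if (!all(c("year", "doy", "hour") %in% names(records))) {
    lt <- as.POSIXlt(records$timestamp, tz = "UTC")
    records$year <- lt$year + 1900L
    records$doy <- lt$yday + 1L
    records$hour <- lt$hour
  }
  structure(list(meta = meta, records = records), class = "station_set")
}

#' @export
print.station_set <- function(x, ...) {
  cat(sprintf("<station_set> %d stations, %d hourly records\n",
              nrow(x$meta), nrow(x$records)))
  invisible(x)
}

#' Write a station set to long-format hourly CSV
#'
#' Columns: station_id, lat, lon, timestamp (ISO-8601, UTC, hourly), temp_c.
#'
#' @param stations a `station_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(stations, path) {
  stopifnot(inherits(stations, "station_set"))
  r <- stations$records
  m <- match(r$station_id, stations$meta$station_id)
  out <- data.frame(station_id = r$station_id,
                    lat = stations$meta$lat[m],
                    lon = stations$meta$lon[m],
                    timestamp = format(r$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                       tz = "UTC"),
                    temp_c = r$temp_c, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read hourly station records from long-format CSV
#'
#' Expects the exact header `station_id, lat, lon, timestamp, temp_c` with
#' ISO-8601 hourly timestamps (a trailing `Z` and a `T` or space separator
#' are both accepted).  Rows are sorted by time within station; malformed
#' timestamps and duplicate (station, timestamp) pairs are errors that name
#' the offending row.
#'
#' @param path CSV file path.
#' @return a `station_set`.
#' @export
read_station_csv <- function(path) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(station_id = "character"))
  expected <- c("station_id", "lat", "lon", "timestamp", "temp_c")
  stop_if_not(identical(names(d), expected),
              "unexpected header: %s (expected %s)",
              paste(names(d), collapse = ","),
              paste(expected, collapse = ","))
  if (nrow(d) == 0) {
    meta <- data.frame(station_id = character(0), lat = numeric(0),
                       lon = numeric(0), stringsAsFactors = FALSE)
    recs <- data.frame(station_id = character(0),
                       timestamp = as.POSIXct(character(0), tz = "UTC"),
                       year = integer(0), doy = integer(0), hour = integer(0),
                       temp_c = numeric(0), stringsAsFactors = FALSE)
    return(station_set(meta, recs))
  }
  raw <- sub("Z$", "", sub("T", " ", d$timestamp, fixed = TRUE))
  ts <- as.POSIXct(raw, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop(sprintf("malformed timestamp '%s' at row %d", d$timestamp[bad], bad),
         call. = FALSE)
  }
  key <- paste(d$station_id, raw)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(sprintf("duplicate record for station %s at %s (row %d)",
                 d$station_id[bad], d$timestamp[bad], bad), call. = FALSE)
  }
  ord <- order(d$station_id, ts)
  d <- d[ord, ]
  ts <- ts[ord]
  meta <- unique(d[, c("station_id", "lat", "lon")])
  stop_if_not(!anyDuplicated(meta$station_id),
              "inconsistent coordinates within a station")
  rownames(meta) <- NULL
  recs <- data.frame(station_id = d$station_id, timestamp = ts,
                     temp_c = d$temp_c, stringsAsFactors = FALSE)
  station_set(meta, recs)
}

#' Season accumulation windows
#'
#' The chill window of season `y` runs 1 November of `y` to 28 February of
#' `y + 1` (29 February excluded); the heat window runs 1 January to 8 April
#' of `y + 1` (29 February included when present).  Seasons are labeled by
#' the calendar year containing the 1 November start.
#'
#' @param kind `"chill"` or `"heat"`.
#' @param season_year season label (calendar year of the 1 November start).
#' @return list with `kind`, `season_year`, `start`, `end` (Dates) and
#'   `capacity_hours` (24 x days in the window).
#' @export
season_window <- function(kind = c("chill", "heat"), season_year) {
  kind <- match.arg(kind)
  season_year <- as.integer(season_year)
  if (kind == "chill") {
    start <- as.Date(sprintf("%d-11-01", season_year))
    end <- as.Date(sprintf("%d-02-28", season_year + 1L))
    capacity <- 120L * 24L
  } else {
    start <- as.Date(sprintf("%d-01-01", season_year + 1L))
    end <- as.Date(sprintf("%d-04-08", season_year + 1L))
    capacity <- (98L + as.integer(is_leap(season_year + 1L))) * 24L
  }
  list(kind = kind, season_year = season_year, start = start, end = end,
       capacity_hours = capacity)
}

## Logical mask of records (year, doy vectors) inside a season window.
#' @noRd
window_mask <- function(year, doy, kind, season_year) {
  if (kind == "chill") {
    (year == season_year & doy >= nov1_doy(season_year)) |
      (year == season_year + 1L & doy <= FEB28_DOY)
  } else {
    year == season_year + 1L & doy <= apr8_doy(season_year + 1L)
  }
}

#' Screen one station for season completeness
#'
#' A season is complete iff the fraction of present hourly records is at
#' least `min_fraction` in each of its chill and heat windows; the station is
#' retained iff it has at least `min_years` complete seasons.  Missing hours
#' are never imputed.
#'
#' @param records one station's hourly records (data.frame with station_id,
#'   year, doy, temp_c at minimum), or a 1-station `station_set`.
#' @param min_years minimum number of complete seasons (>= 1; default 5).
#' @param min_fraction minimum per-window completeness fraction (default 0.9).
#' @return a one-row data.frame (station_id, years_total, years_complete,
#'   retained) with per-season fractions attached as attribute `"seasons"`.
#' @export
screen_station <- function(records, min_years = 5L, min_fraction = 0.9) {
  stop_if_not(min_years >= 1, "min_years must be >= 1")
  stop_if_not(min_fraction > 0 && min_fraction <= 1,
              "min_fraction must lie in (0, 1]")
  if (inherits(records, "station_set")) records <- records$records
  sid <- if (nrow(records) > 0) records$station_id[1L] else NA_character_
  if (nrow(records) == 0) {
    out <- data.frame(station_id = sid, years_total = 0L,
                      years_complete = 0L, retained = FALSE,
                      stringsAsFactors = FALSE)
    attr(out, "seasons") <- data.frame(season_year = integer(0),
                                       chill_fraction = numeric(0),
                                       heat_fraction = numeric(0),
                                       complete = logical(0))
    return(out)
  }

  ## Candidate seasons: any record inside the chill window.
  years <- sort(unique(records$year))
  candidates <- sort(unique(c(years - 1L, years)))
  rows <- lapply(candidates, function(y) {
    chill <- window_mask(records$year, records$doy, "chill", y)
    if (!any(chill)) return(NULL)
    heat <- window_mask(records$year, records$doy, "heat", y)
    chill_frac <- sum(chill) / season_window("chill", y)$capacity_hours
    heat_frac <- sum(heat) / season_window("heat", y)$capacity_hours
    data.frame(season_year = y, chill_fraction = chill_frac,
               heat_fraction = heat_frac,
               complete = chill_frac >= min_fraction &
                 heat_frac >= min_fraction)
  })
  seasons <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(seasons)) {
    seasons <- data.frame(season_year = integer(0),
                          chill_fraction = numeric(0),
                          heat_fraction = numeric(0), complete = logical(0))
  }
  out <- data.frame(station_id = sid, years_total = nrow(seasons),
                    years_complete = sum(seasons$complete),
                    retained = sum(seasons$complete) >= min_years,
                    stringsAsFactors = FALSE)
  attr(out, "seasons") <- seasons
  out
}

#' Screen every station of a network
#'
#' @param stations a `station_set`.
#' @inheritParams screen_station
#' @return data.frame with one QC row per station (see [screen_station()]);
#'   per-station season detail in attribute `"seasons"`.
#' @export
screen_network <- function(stations, min_years = 5L, min_fraction = 0.9) {
  stopifnot(inherits(stations, "station_set"))
  by_station <- split(stations$records, stations$records$station_id)
  reports <- lapply(stations$meta$station_id, function(id) {
    r <- by_station[[id]]
    if (is.null(r)) r <- stations$records[0, ]
    rep <- screen_station(r, min_years = min_years,
                          min_fraction = min_fraction)
    rep$station_id <- id
    det <- attr(rep, "seasons")
    if (nrow(det) > 0) det$station_id <- id
    attr(rep, "seasons") <- det
    rep
  })
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  attr(out, "seasons") <-
    do.call(rbind, lapply(reports, attr, "seasons"))
  out
}
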