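## Frost and abnormal winter-heat event detection and the weekly occurrence
## probability statistic (share of years in which a week had at least one
## qualifying event).

#' Event definition
#'
#' A frost event is a run of at least `min_consecutive_hours` hours strictly
#' below the threshold; an abnormal-heat event a run strictly above it.
#' Defaults follow the conventional definitions for dormant stone fruit:
#' frost = below -1 C for >= 3 h; abnormal heat = above 25 C for >= 3 h.
#'
#' @param kind `"frost"` or `"abnormal_heat"`.
#' @param threshold temperature threshold (C); default -1 for frost, 25 for
#'   abnormal heat.
#' @param direction `"below"` or `"above"`; defaults to the kind's
#'   convention.
#' @param min_consecutive_hours minimum run length (>= 1; default 3).
#' @return object of class `event_definition`.
#' @export
event_definition <- function(kind = c("frost", "abnormal_heat"),
                             threshold = NULL, direction = NULL,
                             min_consecutive_hours = 3L) {
  kind <- match.arg(kind)
  if (is.null(threshold)) threshold <- if (kind == "frost") -1 else 25
  if (is.null(direction)) direction <- if (kind == "frost") "below" else "above"
  direction <- match.arg(direction, c("below", "above"))
  stop_if_not(min_consecutive_hours >= 1,
              "min_consecutive_hours must be >= 1")
  structure(list(kind = kind, threshold = threshold, direction = direction,
                 min_consecutive_hours = as.integer(min_consecutive_hours)),
            class = "event_definition")
}

#' Analysis week index of a timestamp
#'
#' Week 1 starts on 1 January; week `w` covers days of year
#' `(w - 1) * 7 + 1` through `w * 7` of the timestamp's own calendar year.
#' The 1-2 day fragment beyond day 364 is merged into week 52.  December
#' weeks therefore carry indices 49-52 and, in the event analysis, attach to
#' the following season.
#'
#' @param x POSIXct/Date vector, or an integer day-of-year vector.
#' @return integer week indices in 1..52.
#' @examples
#' week_of(as.Date(c("2020-01-01", "2020-01-08", "2020-12-05")))
#' @export
week_of <- function(x) {
  doy <- if (is.numeric(x)) as.integer(x)
  else as.integer(format(as.Date(x, tz = "UTC"), "%j"))
  stopifnot(all(doy >= 1 & doy <= 366))
  pmin(as.integer(ceiling(doy / 7)), 52L)
}

#' Detect frost or abnormal-heat runs in hourly records
#'
#' Finds maximal runs of consecutive hours satisfying the strict comparison
#' with length at least the definition's minimum.  Runs interrupted by a
#' missing hour are split; a run spanning a week boundary is attributed to
#' the week (and year) of its first hour.
#'
#' @param stations a `station_set`, or one station's records data.frame.
#' @param defn an [event_definition()].
#' @return data.frame of event runs: station_id, kind, start (POSIXct),
#'   duration_h, extreme_c (coldest/warmest hour of the run), week,
#'   season_year.  For abnormal heat, December events (weeks 49-52) are
#'   attached to the following calendar year's season.
#' @export
detect_events <- function(stations, defn = event_definition("frost")) {
  records <- if (inherits(stations, "station_set")) stations$records
  else stations
  stopifnot(inherits(defn, "event_definition"))
  empty <- data.frame(station_id = character(0), kind = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      duration_h = integer(0), extreme_c = numeric(0),
                      week = integer(0), season_year = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  parts <- lapply(split(records, records$station_id),
                  detect_events_station, defn = defn)
  out <- do.call(rbind, c(parts, list(empty)))
  rownames(out) <- NULL
  out
}

#' @noRd
detect_events_station <- function(r, defn) {
  r <- r[order(r$timestamp), ]
  hit <- if (defn$direction == "below") r$temp_c < defn$threshold
  else r$temp_c > defn$threshold
  n <- nrow(r)
  gap <- c(TRUE, diff(as.numeric(r$timestamp)) != 3600)
  grp <- cumsum(gap | c(TRUE, hit[-1L] != hit[-n]))
  runs <- which(hit)
  if (length(runs) == 0) return(NULL)
  lens <- tapply(runs, grp[runs], length)
  firsts <- tapply(runs, grp[runs], min)
  keep <- lens >= defn$min_consecutive_hours
  if (!any(keep)) return(NULL)
  firsts <- firsts[keep]
  lens <- lens[keep]
  extreme <- vapply(seq_along(firsts), function(i) {
    v <- r$temp_c[firsts[i]:(firsts[i] + lens[i] - 1L)]
    if (defn$direction == "below") min(v) else max(v)
  }, numeric(1))
  week <- week_of(r$doy[firsts])
  year <- r$year[firsts]
  season_year <- if (defn$kind == "abnormal_heat")
    ifelse(week >= 49L, year + 1L, year) else year
  data.frame(station_id = r$station_id[1L], kind = defn$kind,
             start = r$timestamp[firsts], duration_h = as.integer(lens),
             extreme_c = extreme, week = week,
             season_year = as.integer(season_year),
             stringsAsFactors = FALSE)
}

#' Weekly occurrence probabilities of events
#'
#' For each station and analysis week, the probability is the number of years
#' in which that week had at least one event, divided by the number of years
#' considered; multiple events in the same station-week-year count once.
#'
#' @param events result of [detect_events()].
#' @param n_years number of years considered: a single count applied to all
#'   stations, or a named vector / data.frame (station_id, n_years).
#' @param weeks analysis week range, in display order: frost defaults to
#'   2-10; for abnormal heat use `c(49:52, 1:8)`.
#' @param station_ids stations to tabulate (defaults to those present in
#'   `events`); stations with no events get all-zero rows.
#' @return data.frame: station_id, kind, week, probability, n_years, with
#'   every requested station x week present.
#' @export
weekly_probabilities <- function(events, n_years, weeks = 2:10,
                                 station_ids = NULL) {
  if (is.data.frame(n_years)) {
    n_years <- setNames(n_years$n_years, n_years$station_id)
  }
  stop_if_not(all(n_years >= 1), "n_years must be >= 1")
  if (is.null(station_ids)) {
    station_ids <- if (length(names(n_years)) > 0) names(n_years)
    else sort(unique(events$station_id))
  }
  kind <- if (nrow(events) > 0) events$kind[1L] else NA_character_
  grid <- expand.grid(week = weeks, station_id = station_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ev <- events[events$week %in% weeks, , drop = FALSE]
  ## at-least-one semantics: one hit per station-week-year
  hits <- unique(ev[, c("station_id", "week", "season_year")])
  cnt <- if (nrow(hits) > 0)
    tapply(hits$season_year, paste(hits$station_id, hits$week), length)
  else integer(0)
  key <- paste(grid$station_id, grid$week)
  n_events <- as.integer(cnt[key])
  n_events[is.na(n_events)] <- 0L
  ny <- if (length(names(n_years)) > 0) as.numeric(n_years[grid$station_id])
  else as.numeric(n_years)
  stop_if_not(!anyNA(ny), "n_years missing for some station")
  data.frame(station_id = grid$station_id, kind = kind, week = grid$week,
             probability = n_events / ny, n_years = ny,
             stringsAsFactors = FALSE)
}

#' Filter a weekly probability table at a cutoff
#'
#' Keeps entries with probability greater than or equal to the cutoff
#' (inclusive), dropping the rest — the conventional ">= 10%" display rule.
#'
#' @param table result of [weekly_probabilities()].
#' @param cutoff probability cutoff in [0, 1] (default 0.10).
#' @return the filtered table.
#' @export
threshold_mask <- function(table, cutoff = 0.10) {
  stop_if_not(cutoff >= 0 && cutoff <= 1, "cutoff must lie in [0, 1]")
  out <- table[table$probability >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}
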