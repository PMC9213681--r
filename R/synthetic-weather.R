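## Synthetic multi-station hourly weather and pseudo-GCM daily projections.
##
## Stations are generated per dormancy-season block (1 Oct - 30 Apr of the
## following year): both accumulation windows (Nov-Feb chill, Jan-Apr 8 heat)
## and both event-analysis week ranges fall entirely inside the block, so a
## station sampled with n seasons contributes exactly n complete seasons.

#' Generate a synthetic hourly station network
#'
#' Each station's hourly temperature is the sum of an annual sinusoid with
#' its trough on 15 January, a diurnal sinusoid peaking at 15:00 solar time,
#' an AR(1) Gaussian residual, and injected frost / abnormal-heat episodes
#' (4-8 h blocks in winter, depressed below -1 C or raised above 25 C by a
#' sampled margin, Poisson counts per season with the archetype propensity).
#' Station coordinates are uniform in the bbox; per-station season coverage
#' is sampled on 5-21 seasons with median 20.  The output is a deterministic
#' function of the spec and archetypes.
#'
#' @param spec a [network_spec()].
#' @param archetypes named list of [climate_archetype()] objects covering the
#'   names used in `spec$archetype_mix`.
#' @return object of class `station_set`: list with `meta` (one row per
#'   station: station_id, lat, lon, archetype, first_season, n_seasons) and
#'   `records` (long hourly data.frame: station_id, timestamp, year, doy,
#'   hour, temp_c).  The injected episodes are attached as attribute
#'   `"injected_events"`.
#' @export
generate_station_network <- function(spec, archetypes = default_archetypes()) {
  stopifnot(inherits(spec, "network_spec"))
  stop_if_not(length(archetypes) >= 1, "archetype list is empty")
  mix <- spec$archetype_mix
  stop_if_not(!is.null(names(mix)) && all(names(mix) %in% names(archetypes)),
              "archetype_mix names must match the archetype list")

  set.seed(spec$seed)
  n <- spec$n_stations
  counts <- largest_remainder_counts(mix, n)
  assign <- sample(rep(names(mix), counts))
  lat <- runif(n, spec$bbox[["lat_min"]], spec$bbox[["lat_max"]])
  lon <- runif(n, spec$bbox[["lon_min"]], spec$bbox[["lon_max"]])

  ## Season coverage: range [5, 21], median 20 (skewed toward full coverage).
  span_max <- spec$years[2] - spec$years[1] + 1L
  n_seasons <- pmin(pmax(5L, 21L - rgeom(n, 0.30)), span_max)
  slack <- span_max - n_seasons
  first <- spec$years[1] + vapply(slack, function(m) {
    if (m == 0L) 0L else sample.int(m + 1L, 1L) - 1L
  }, integer(1))

  ids <- sprintf("ST%03d", seq_len(n))
  recs <- vector("list", n)
  inj <- vector("list", n)
  for (i in seq_len(n)) {
    g <- synth_station_records(ids[i], archetypes[[assign[i]]],
                               first[i], n_seasons[i])
    recs[[i]] <- g$records
    inj[[i]] <- g$injected
  }

  meta <- data.frame(station_id = ids, lat = lat, lon = lon,
                     archetype = assign, first_season = first,
                     n_seasons = n_seasons, stringsAsFactors = FALSE)
  out <- station_set(meta, do.call(rbind, recs))
  attr(out, "injected_events") <- do.call(rbind, inj)
  out
}

## Largest-remainder apportionment of n stations over mix proportions.
#' @noRd
largest_remainder_counts <- function(mix, n) {
  raw <- mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

## One station's records over its contiguous season blocks.
#' @noRd
synth_station_records <- function(station_id, arch, first_season, n_seasons) {
  blocks <- vector("list", n_seasons)
  injected <- vector("list", n_seasons)
  for (k in seq_len(n_seasons)) {
    y0 <- first_season + k - 1L
    b <- synth_season_block(arch, y0)
    blocks[[k]] <- b$records
    if (nrow(b$injected) > 0) b$injected$station_id <- station_id
    injected[[k]] <- b$injected
  }
  records <- do.call(rbind, blocks)
  records$station_id <- station_id
  records <- records[, c("station_id", "timestamp", "year", "doy", "hour",
                         "temp_c")]
  list(records = records, injected = do.call(rbind, injected))
}

## Hourly temperatures for one season block (1 Oct y0 - 30 Apr y0+1).
#' @noRd
synth_season_block <- function(arch, y0) {
  ts <- seq(utc_time(y0, 10L, 1L, 0L), utc_time(y0 + 1L, 4L, 30L, 23L),
            by = "hour")
  lt <- as.POSIXlt(ts)
  doy <- lt$yday + 1L
  hour <- lt$hour
  year <- lt$year + 1900L
  nh <- length(ts)

  annual <- arch$annual_mean - arch$seasonal_amplitude *
    cos(2 * pi * (doy + hour / 24 - 15) / 365.25)
  diurnal <- arch$diurnal_amplitude * cos(2 * pi * (hour - 15) / 24)
  if (arch$noise_sd > 0) {
    ## AR(1) with stationary sd = noise_sd; 48 h burn-in discarded.
    eps <- rnorm(nh + 48L, 0,
                 arch$noise_sd * sqrt(1 - arch$noise_autocorr^2))
    noise <- as.numeric(stats::filter(eps, arch$noise_autocorr,
                                      method = "recursive"))[-seq_len(48L)]
  } else {
    noise <- 0
  }
  temp <- annual + diurnal + noise

  ## Winter episode injection (Dec 1 - Feb 28 of the block).
  winter <- (year == y0 & doy >= 335L + as.integer(is_leap(y0))) |
    (year == y0 + 1L & doy <= FEB28_DOY)
  day_key <- year * 1000L + doy
  winter_days <- unique(day_key[winter])
  inj <- list()

  n_frost <- rpois(1L, arch$frost_propensity)
  n_frost <- min(n_frost, length(winter_days))
  if (n_frost > 0) {
    days <- sample(winter_days, n_frost)
    for (d in days) {
      h0 <- sample(0:3, 1L)
      dur <- sample(4:8, 1L)
      depth <- runif(1L, 0.5, 3)
      idx <- which(day_key == d & hour >= h0 & hour < h0 + dur)
      temp[idx] <- temp[idx] - (max(temp[idx]) + 1 + depth)
      inj[[length(inj) + 1L]] <-
        data.frame(kind = "frost", start = ts[idx[1L]],
                   duration_h = length(idx), stringsAsFactors = FALSE)
    }
  }
  n_heat <- rpois(1L, arch$heatspike_propensity)
  n_heat <- min(n_heat, length(winter_days))
  if (n_heat > 0) {
    days <- sample(winter_days, n_heat)
    for (d in days) {
      h0 <- sample(11:14, 1L)
      dur <- sample(4:8, 1L)
      margin <- runif(1L, 0.5, 3)
      idx <- which(day_key == d & hour >= h0 & hour < h0 + dur)
      lift <- 25 + margin - min(temp[idx])
      if (lift > 0) temp[idx] <- temp[idx] + lift
      inj[[length(inj) + 1L]] <-
        data.frame(kind = "abnormal_heat", start = ts[idx[1L]],
                   duration_h = length(idx), stringsAsFactors = FALSE)
    }
  }

  temp <- pmin(pmax(temp, -39.9), 54.9)  # physical-bounds safety clamp
  injected <- if (length(inj) > 0) do.call(rbind, inj) else
    data.frame(kind = character(0), start = as.POSIXct(character(0), tz = "UTC"),
               duration_h = integer(0), stringsAsFactors = FALSE)
  list(records = data.frame(timestamp = ts, year = year, doy = doy,
                            hour = hour, temp_c = temp),
       injected = injected)
}

#' Generate a pseudo-GCM daily projection ensemble
#'
#' Grid points are the station coordinates jittered by 0.2-3.9 km (emulating
#' nearest-grid-point matching of a 5 km grid).  Each pseudo-GCM applies a
#' fixed warming offset `mean_offset + N(0, gcm_spread_sd)` to the daily
#' minimum and maximum temperatures extracted from the station's hourly
#' record over its most recent seasons.
#'
#' @param stations a `station_set`.
#' @param scenario a [warming_scenario_spec()].
#' @param n_seasons number of most recent dormancy seasons per station to
#'   project (default 5).
#' @return object of class `projection_set`: list with `projections` (long
#'   daily data.frame: grid_id, lat, lon, gcm, horizon, rcp, date, tmin_c,
#'   tmax_c), `grid` (grid_id, lat, lon and the source station), and
#'   `offsets` (named per-GCM warming offsets, C).
#' @export
generate_projection_ensemble <- function(stations, scenario, n_seasons = 5L) {
  stopifnot(inherits(stations, "station_set"),
            inherits(scenario, "warming_scenario_spec"))
  stop_if_not(scenario$ensemble_size >= 1, "ensemble_size must be >= 1")

  set.seed(scenario$seed)
  meta <- stations$meta
  ns <- nrow(meta)
  offs <- scenario$mean_offset +
    if (scenario$gcm_spread_sd > 0)
      rnorm(scenario$ensemble_size, 0, scenario$gcm_spread_sd)
    else rep(0, scenario$ensemble_size)
  gcms <- gcm_labels(scenario$ensemble_size)
  names(offs) <- gcms

  rkm <- runif(ns, 0.2, 3.9)
  brg <- runif(ns, 0, 360)
  p <- geosphere::destPoint(cbind(meta$lon, meta$lat), brg, rkm * 1000,
                            a = EARTH_RADIUS_KM * 1000, f = 0)
  grid <- data.frame(grid_id = paste0("G-", meta$station_id),
                     lat = p[, 2], lon = p[, 1],
                     station_id = meta$station_id, stringsAsFactors = FALSE)

  per_station <- vector("list", ns)
  for (i in seq_len(ns)) {
    r <- stations$records[stations$records$station_id == meta$station_id[i], ]
    season <- ifelse(r$doy >= 200L, r$year, r$year - 1L)
    keep_seasons <- sort(unique(season))
    keep_seasons <- keep_seasons[seq.int(
      max(1L, length(keep_seasons) - n_seasons + 1L), length(keep_seasons))]
    r <- r[season %in% keep_seasons, ]
    date <- as.Date(r$timestamp, tz = "UTC")
    tmin <- tapply(r$temp_c, date, min)
    tmax <- tapply(r$temp_c, date, max)
    daily <- data.frame(date = as.Date(names(tmin)),
                        tmin_c = as.numeric(tmin),
                        tmax_c = as.numeric(tmax))
    daily <- daily[order(daily$date), ]
    rows <- vector("list", length(gcms))
    for (g in seq_along(gcms)) {
      rows[[g]] <- data.frame(grid_id = grid$grid_id[i],
                              lat = grid$lat[i], lon = grid$lon[i],
                              gcm = gcms[g], horizon = scenario$horizon,
                              rcp = scenario$rcp, date = daily$date,
                              tmin_c = daily$tmin_c + offs[g],
                              tmax_c = daily$tmax_c + offs[g],
                              stringsAsFactors = FALSE)
    }
    per_station[[i]] <- do.call(rbind, rows)
  }

  structure(list(projections = do.call(rbind, per_station),
                 grid = grid, offsets = offs, scenario = scenario),
            class = "projection_set")
}
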