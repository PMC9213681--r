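## Shared small helpers: calendar arithmetic and great-circle distances.

is_leap <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

## Day-of-year of 1 November (chill-window start) in a given calendar year.
nov1_doy <- function(year) 305L + as.integer(is_leap(year))

## 28 February is day-of-year 59 in every year; 29 February (doy 60 in leap
## years) is excluded from the chill window by the `doy <= 59` convention.
FEB28_DOY <- 59L

## 8 April: 31 + 28 + 31 + 8 (+1 in leap years, since Feb 29 is included).
apr8_doy <- function(year) 98L + as.integer(is_leap(year))

## Great-circle distance in km on a sphere of radius 6371 km, adequate at the
## <= 50 km scales used for grid matching and surface masking.
EARTH_RADIUS_KM <- 6371

#' @noRd
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

## Full pairwise distance matrix (rows = points p1, cols = points p2), km.
#' @noRd
distance_matrix_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distm(cbind(lon1, lat1), cbind(lon2, lat2),
                   fun = function(x, y) {
                     geosphere::distHaversine(x, y, r = EARTH_RADIUS_KM)
                   })
}

## POSIXct (UTC) from calendar components, vectorized.
#' @noRd
utc_time <- function(year, month, day, hour = 0L) {
  as.POSIXct(sprintf("%04d-%02d-%02d %02d:00:00", year, month, day, hour),
             tz = "UTC")
}

#' @noRd
stop_if_not <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
}
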