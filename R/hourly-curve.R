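## Idealized hourly temperatures from daily Tmin/Tmax: a sine from sunrise
## through the afternoon maximum over (daylength + 4) hours, and a
## logarithmic night decay from the sunset temperature toward the next
## sunrise's minimum (Linvill-style construction).  Used for the projection
## path, where only daily extremes are available.

#' Solar geometry for a day of year
#'
#' Sunrise/sunset in local solar hours from the standard solar-declination /
#' hour-angle computation, symmetric about solar noon (hour 12).
#'
#' @param lat latitude in degrees; must satisfy `abs(lat) < 60` (no
#'   polar day/night handling).
#' @param doy day of year (1-366); vectorized.
#' @return data.frame with columns doy, lat, sunrise, sunset, daylength
#'   (solar hours).
#' @examples
#' solar_geometry(40, c(80, 172, 355))
#' @export
solar_geometry <- function(lat, doy) {
  stop_if_not(length(lat) == 1L && is.finite(lat), "lat must be a scalar")
  stop_if_not(abs(lat) < 60,
              "latitudes with polar day/night behaviour (|lat| >= 60) are not supported")
  stopifnot(all(doy >= 1 & doy <= 366))
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  cos_w <- -tan(lat * pi / 180) * tan(decl)
  stop_if_not(all(abs(cos_w) < 1), "no sunrise/sunset at this latitude")
  half_day <- acos(cos_w) * 180 / pi / 15  # hour angle -> hours
  data.frame(doy = doy, lat = lat, sunrise = 12 - half_day,
             sunset = 12 + half_day, daylength = 2 * half_day)
}

## Night-decay evaluation shared by the single-day and series paths.
## n_h = hours since sunset (clamped below at 1 so the curve starts at the
## sunset temperature), nightlen = hours from sunset to the next sunrise.
#' @noRd
night_temp <- function(t_sunset, t_target, n_h, nightlen) {
  t_sunset - (t_sunset - t_target) * log(pmax(n_h, 1)) / log(nightlen)
}

#' @noRd
sunset_temp <- function(tmin, tmax, daylength) {
  tmin + (tmax - tmin) * sin(pi * daylength / (daylength + 4))
}

#' Idealized 24 hourly temperatures for one day
#'
#' Daytime (sunrise to sunset) follows a sine rising from `tmin_today` at
#' sunrise over a half-period of `daylength + 4` hours (so the maximum falls
#' in mid-afternoon); night hours decay logarithmically from the sunset
#' temperature toward `tmin_tomorrow` at the next sunrise.  Pre-dawn hours of
#' the same calendar day lie on the previous night's decay targeting
#' `tmin_today`.  Samples are on the hour (0-23), local solar time.
#'
#' @param tmin_today,tmax_today daily extremes (C), `tmin_today <= tmax_today`.
#' @param tmin_tomorrow next day's minimum (C); the night decay target.
#' @param solar a one-row result of [solar_geometry()].
#' @return numeric vector of 24 temperatures (hours 0-23).
#' @export
idealize_day <- function(tmin_today, tmax_today, tmin_tomorrow = tmin_today,
                         solar) {
  stop_if_not(tmin_today <= tmax_today,
              "inverted daily extremes (tmin %.2f > tmax %.2f)",
              tmin_today, tmax_today)
  stopifnot(is.data.frame(solar), nrow(solar) == 1L)
  sr <- solar$sunrise
  ss <- solar$sunset
  dl <- solar$daylength
  ts <- sunset_temp(tmin_today, tmax_today, dl)
  nightlen <- 24 - dl  # own sunrise stands in for tomorrow's
  h <- 0:23
  temp <- numeric(24L)
  day <- h >= sr & h <= ss
  temp[day] <- tmin_today + (tmax_today - tmin_today) *
    sin(pi * (h[day] - sr) / (dl + 4))
  eve <- h > ss
  temp[eve] <- night_temp(ts, tmin_tomorrow, h[eve] - ss, nightlen)
  pre <- h < sr
  temp[pre] <- night_temp(ts, tmin_today, h[pre] + 24 - ss, nightlen)
  temp
}

#' Idealized hourly series from a daily Tmin/Tmax record
#'
#' Applies the single-day construction over consecutive days, keeping the
#' night continuous across midnight (the decay after sunset of day *d*
#' targets day *d + 1*'s minimum at its sunrise).  Non-consecutive dates
#' split the series into independent blocks; the first night of each block
#' decays toward the block's own first minimum, and the last night toward its
#' own day's minimum (no tomorrow available).
#'
#' @param daily data.frame with columns `date` (Date, strictly increasing),
#'   `tmin_c`, `tmax_c`.
#' @param lat latitude in degrees (`abs(lat) < 60`).
#' @return data.frame with columns timestamp (POSIXct UTC), year, doy, hour,
#'   temp_c — the same shape as observed station records.
#' @export
idealize_series <- function(daily, lat) {
  stopifnot(is.data.frame(daily),
            all(c("date", "tmin_c", "tmax_c") %in% names(daily)))
  stop_if_not(all(diff(as.numeric(daily$date)) > 0),
              "dates must be strictly increasing")
  stop_if_not(all(daily$tmin_c <= daily$tmax_c),
              "inverted daily extremes in input")
  block <- cumsum(c(TRUE, diff(as.numeric(daily$date)) > 1))
  parts <- lapply(split(daily, block), idealize_block, lat = lat)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' @noRd
idealize_block <- function(daily, lat) {
  n <- nrow(daily)
  doy <- as.integer(format(daily$date, "%j"))
  sg <- solar_geometry(lat, doy)
  sr <- sg$sunrise
  ss <- sg$sunset
  dl <- sg$daylength
  tmin <- daily$tmin_c
  tmax <- daily$tmax_c
  ts_sun <- sunset_temp(tmin, tmax, dl)
  tmin_next <- c(tmin[-1L], tmin[n])
  sr_next <- c(sr[-1L], sr[n])

  d <- rep(seq_len(n), each = 24L)
  h <- rep(0:23, n)
  dp <- pmax(d - 1L, 1L)  # previous day; virtual day 0 == day 1
  temp <- numeric(length(h))

  day <- h >= sr[d] & h <= ss[d]
  temp[day] <- tmin[d][day] + (tmax[d] - tmin[d])[day] *
    sin(pi * (h - sr[d])[day] / (dl[d] + 4)[day])

  eve <- h > ss[d]
  nl_eve <- 24 - ss[d] + sr_next[d]
  temp[eve] <- night_temp(ts_sun[d][eve], tmin_next[d][eve],
                          (h - ss[d])[eve], nl_eve[eve])

  pre <- h < sr[d]
  nl_pre <- 24 - ss[dp] + sr[d]
  temp[pre] <- night_temp(ts_sun[dp][pre], tmin[d][pre],
                          (h + 24 - ss[dp])[pre], nl_pre[pre])

  stamp <- rep(as.POSIXct(paste(daily$date, "00:00:00"), tz = "UTC"),
               each = 24L) + h * 3600
  data.frame(timestamp = stamp,
             year = rep(as.integer(format(daily$date, "%Y")), each = 24L),
             doy = rep(doy, each = 24L), hour = h, temp_c = temp)
}
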