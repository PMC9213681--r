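## Independent oracles, each a literal transcription of the published form
## it checks, coded separately from the package implementation.

## Chill-portion recursion: plain R loop over the two-step kinetics with the
## canonical constants, Kelvin = C + 273.15.
oracle_dynamic_portions <- function(temp_c) {
  e0 <- 4153.5; e1 <- 12888.8; a0 <- 1.395e5; a1 <- 2.567e18
  slp <- 1.6; tetmlt <- 277
  inter <- 0
  portions <- 0
  for (tc in temp_c) {
    tk <- tc + 273.15
    ftmprt <- slp * tetmlt * (tk - tetmlt) / tk
    sr <- exp(ftmprt)
    xi <- sr / (1 + sr)
    xs <- (a0 / a1) * exp((e1 - e0) / tk)
    ak1 <- a1 * exp(-e1 / tk)
    e <- xs - (xs - inter) * exp(-ak1)
    if (e >= 1) {
      delt <- xi * e
      portions <- portions + delt
      inter <- e - delt
    } else {
      inter <- e
    }
  }
  portions
}

## Idealized day curve at arbitrary fractional hour t in [0, 24): day sine
## over (daylength + 4) h, logarithmic night decay (hours-since-sunset
## clamped below at 1), pre-dawn on the previous night's decay toward today's
## minimum.  Literal re-statement of the curve family, used as a fine-grid
## oracle.
oracle_day_curve <- function(t, tmin, tmax, tmin_next, sunrise, sunset) {
  dl <- sunset - sunrise
  ts <- tmin + (tmax - tmin) * sin(pi * dl / (dl + 4))
  nightlen <- 24 - dl
  vapply(t, function(h) {
    if (h >= sunrise && h <= sunset) {
      tmin + (tmax - tmin) * sin(pi * (h - sunrise) / (dl + 4))
    } else if (h > sunset) {
      n <- max(h - sunset, 1)
      ts - (ts - tmin_next) * log(n) / log(nightlen)
    } else {
      n <- max(h + 24 - sunset, 1)
      ts - (ts - tmin) * log(n) / log(nightlen)
    }
  }, numeric(1))
}

## Brute-force double-loop IDW with exactness at stations.
oracle_idw <- function(cell_lat, cell_lon, st_lat, st_lon, st_val, power) {
  vapply(seq_along(cell_lat), function(i) {
    d <- geosphere::distHaversine(cbind(st_lon, st_lat),
                                  c(cell_lon[i], cell_lat[i]), r = 6371)
    if (any(d < 1e-6)) return(st_val[which.min(d)])
    w <- d^(-power)
    sum(w * st_val) / sum(w)
  }, numeric(1))
}

## Closed-form Pearson r via the covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

## Type-7 quartiles by the explicit interpolation formula on sorted data.
oracle_quartiles <- function(v) {
  s <- sort(v)
  n <- length(s)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  c(q1 = q(0.25), median = q(0.5), q3 = q(0.75))
}
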