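hours_at <- function(start, temps, station_id = "S1") {
  ts <- as.POSIXct(start, tz = "UTC") + 3600 * (seq_along(temps) - 1)
  records_from_hours(ts, temps, station_id)
}

test_that("week numbering starts at 1 January in 7-day blocks", {
  expect_equal(week_of(as.Date("2020-01-01")), 1L)
  expect_equal(week_of(as.Date("2020-01-08")), 2L)
  expect_equal(week_of(as.Date("2021-12-05")), 49L)  # doy 339
  expect_equal(week_of(339), 49L)
  expect_equal(week_of(c(365, 366)), c(52L, 52L))    # fragment merged
})

test_that("frost runs need >= 3 consecutive hours strictly below -1 C", {
  d <- event_definition("frost")
  expect_equal(nrow(detect_events(hours_at("2020-01-10 02:00:00",
                                           c(-2, -2, -2)), d)), 1)
  expect_equal(detect_events(hours_at("2020-01-10 02:00:00",
                                      c(-2, -2, -2)), d)$duration_h, 3L)
  expect_equal(nrow(detect_events(hours_at("2020-01-10 02:00:00",
                                           c(-5, -5)), d)), 0)
  expect_equal(nrow(detect_events(hours_at("2020-01-10 02:00:00",
                                           rep(-1, 6)), d)), 0)
})

test_that("runs are maximal, split by gaps, and attributed to their first hour", {
  d <- event_definition("frost")
  ## one 7-h run is one event, not several overlapping 3-h events
  one <- detect_events(hours_at("2020-01-10 00:00:00", rep(-3, 7)), d)
  expect_equal(nrow(one), 1)
  expect_equal(one$duration_h, 7L)
  expect_equal(one$extreme_c, -3)

  ## a missing hour splits a qualifying run
  r <- hours_at("2020-01-10 00:00:00", rep(-3, 7))
  r <- r[-4, ]
  split2 <- detect_events(r, d)
  expect_equal(nrow(split2), 2)

  ## run starting in week 2 and ending in week 3 counts once, in week 2
  r <- hours_at("2020-01-14 22:00:00", rep(-4, 5))  # doy 14 -> 15
  ev <- detect_events(r, d)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$week, 2L)
})

test_that("abnormal heat uses strict above-25 and December attaches forward", {
  d <- event_definition("abnormal_heat")
  expect_equal(nrow(detect_events(hours_at("2020-12-05 12:00:00",
                                           rep(25, 5)), d)), 0)
  ev <- detect_events(hours_at("2020-12-05 12:00:00", rep(26, 4)), d)
  expect_equal(ev$week, 49L)
  expect_equal(ev$season_year, 2021L)  # December belongs to the next season
})

test_that("weekly probabilities equal hand counts with at-least-one semantics", {
  d <- event_definition("frost")
  recs <- rbind(
    hours_at("2001-01-16 02:00:00", rep(-2, 3)),   # week 3, year 2001
    hours_at("2002-01-17 02:00:00", rep(-2, 4)),   # week 3, year 2002
    hours_at("2003-01-25 02:00:00", rep(-2, 3)),   # week 4, year 2003
    hours_at("2003-01-26 02:00:00", rep(-2, 3)),   # week 4 again, same year
    hours_at("2003-02-20 02:00:00", rep(-2, 3)))   # week 8, year 2003
  ev <- detect_events(recs, d)
  tab <- weekly_probabilities(ev, n_years = 3, weeks = 2:10)
  p <- setNames(tab$probability, tab$week)
  expect_equal(p[["3"]], 2 / 3)
  expect_equal(p[["4"]], 1 / 3)   # two events in one year count once
  expect_equal(p[["8"]], 1 / 3)
  expect_equal(unname(p[c("2", "5", "6", "7", "9", "10")]), rep(0, 6))

  ## 7 of 21 years with an event in week 3 -> exactly 1/3
  many <- do.call(rbind, lapply(2000:2006, function(y) {
    hours_at(sprintf("%d-01-16 02:00:00", y), rep(-2, 3))
  }))
  t21 <- weekly_probabilities(detect_events(many, d), n_years = 21,
                              weeks = 2:10)
  expect_equal(t21$probability[t21$week == 3], 7 / 21)

  ## order invariance
  shuf <- ev[sample(nrow(ev)), ]
  expect_equal(weekly_probabilities(shuf, n_years = 3, weeks = 2:10), tab)
})

test_that("no events yields an all-zero table over the requested grid", {
  tab <- weekly_probabilities(detect_events(hours_at("2001-01-16 02:00:00",
                                                     rep(5, 10)),
                                            event_definition("frost")),
                              n_years = 4, weeks = 2:10, station_ids = "S1")
  expect_equal(nrow(tab), 9)
  expect_true(all(tab$probability == 0))
})

test_that("threshold mask keeps probabilities >= cutoff inclusively", {
  tab <- data.frame(station_id = "S1", kind = "frost", week = 1:3,
                    probability = c(0.05, 0.10, 0.5), n_years = 10)
  kept <- threshold_mask(tab, 0.10)
  expect_equal(kept$probability, c(0.10, 0.5))
  expect_equal(nrow(threshold_mask(tab, 0)), 3)
  expect_equal(nrow(threshold_mask(tab, 0.9)), 0)
})

test_that("detected winter-event frequency converges to the injected rate", {
  ## warm winters (no natural frost): P(>=1 event per season) = 1 - exp(-l)
  lambda <- 0.3
  arch <- climate_archetype("mild", annual_mean = 15, seasonal_amplitude = 5,
                            diurnal_amplitude = 3, noise_sd = 1,
                            noise_autocorr = 0.5, frost_propensity = lambda)
  spec <- single_archetype_spec(16, c(2000, 2020), seed = 55, name = "mild")
  net <- generate_station_network(spec, list(mild = arch))
  ev <- detect_events(net, event_definition("frost"))
  n_winters <- sum(net$meta$n_seasons)
  lt <- as.POSIXlt(ev$start, tz = "UTC")
  dormancy_season <- ifelse(lt$mon + 1 >= 7, lt$year + 1900, lt$year + 1899)
  hit_keys <- unique(paste(ev$station_id, dormancy_season))
  p_hat <- length(hit_keys) / n_winters
  p_exp <- 1 - exp(-lambda)
  se <- sqrt(p_exp * (1 - p_exp) / n_winters)
  expect_gt(n_winters, 200)
  expect_lt(abs(p_hat - p_exp), 3 * se)
})
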