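make_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("station CSV round-trips through write and read", {
  net <- generate_station_network(
    network_spec(n_stations = 2, years = c(2019, 2020), seed = 2))
  path <- tempfile(fileext = ".csv")
  write_station_csv(net, path)
  back <- read_station_csv(path)
  expect_equal(back$meta$station_id, net$meta$station_id)
  expect_equal(back$meta$lat, net$meta$lat)
  expect_equal(back$records$temp_c, net$records$temp_c)
  expect_equal(as.numeric(back$records$timestamp),
               as.numeric(net$records$timestamp))
})

test_that("empty file with a valid header yields an empty set", {
  path <- make_csv(data.frame(station_id = character(0), lat = numeric(0),
                              lon = numeric(0), timestamp = character(0),
                              temp_c = numeric(0)))
  s <- read_station_csv(path)
  expect_equal(nrow(s$meta), 0)
  expect_equal(nrow(s$records), 0)
})

test_that("two stations of 48 h parse into two series of length 48", {
  ts <- seq(utc <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
            by = "hour", length.out = 48)
  df <- rbind(
    data.frame(station_id = "A", lat = 40, lon = -3,
               timestamp = format(ts, "%Y-%m-%dT%H:%M:%SZ"), temp_c = 5),
    data.frame(station_id = "B", lat = 41, lon = -2,
               timestamp = format(ts, "%Y-%m-%dT%H:%M:%SZ"), temp_c = 7))
  s <- read_station_csv(make_csv(df))
  expect_equal(nrow(s$meta), 2)
  expect_equal(as.integer(table(s$records$station_id)), c(48L, 48L))
})

test_that("malformed and duplicate timestamps are named in errors", {
  base <- data.frame(station_id = "A", lat = 40, lon = -3,
                     timestamp = c("2020-01-01T00:00:00Z",
                                   "2020-01-01T01:00:00Z"), temp_c = 5)
  bad <- base
  bad$timestamp[2] <- "2020-13-01T00:00:00Z"
  expect_error(read_station_csv(make_csv(bad)), "malformed timestamp.*row 2")
  dup <- base
  dup$timestamp[2] <- dup$timestamp[1]
  expect_error(read_station_csv(make_csv(dup)), "duplicate record.*A")
  wrong <- base
  names(wrong)[5] <- "temperature"
  expect_error(read_station_csv(make_csv(wrong)), "unexpected header")
})

test_that("screening counts complete seasons against window capacity", {
  ## 5 complete seasons + 3 seasons with most of the chill window missing
  full <- do.call(rbind, lapply(2010:2014, season_records, temp_c = 6))
  partial <- do.call(rbind, lapply(2015:2017, function(y) {
    r <- season_records(y, temp_c = 6)
    chill <- window_hours("chill", y)
    drop <- r$timestamp %in% chill[seq_len(floor(0.5 * length(chill)))]
    r[!drop, ]
  }))
  rec <- rbind(full, partial)
  rep5 <- screen_station(rec, min_years = 5, min_fraction = 0.9)
  expect_equal(rep5$years_total, 8)
  expect_equal(rep5$years_complete, 5)
  expect_true(rep5$retained)
  rep6 <- screen_station(rec, min_years = 6, min_fraction = 0.9)
  expect_false(rep6$retained)

  ## fractions equal the brute-force present/expected count per window
  det <- attr(rep5, "seasons")
  for (y in 2010:2017) {
    expected_chill <- length(window_hours("chill", y))
    present <- sum(rec$timestamp %in% window_hours("chill", y))
    expect_equal(det$chill_fraction[det$season_year == y],
                 present / expected_chill)
  }
})

test_that("a single missing hour fails completeness at min_fraction = 1", {
  r <- season_records(2012, temp_c = 6)
  drop <- which(r$timestamp == window_hours("chill", 2012)[100])
  r1 <- r[-drop, ]
  rep <- screen_station(r1, min_years = 1, min_fraction = 1.0)
  expect_false(attr(rep, "seasons")$complete[1])
  expect_true(attr(screen_station(r, min_years = 1,
                                  min_fraction = 1.0), "seasons")$complete[1])
})

test_that("screening is monotone: adding records never drops retention", {
  r <- season_records(2012, temp_c = 6)
  half <- r[seq(1, nrow(r), 2), ]
  rep_half <- screen_station(half, min_years = 1)
  rep_full <- screen_station(r, min_years = 1)
  expect_gte(rep_full$years_complete, rep_half$years_complete)
  expect_false(rep_half$retained && !rep_full$retained)

  expect_false(screen_station(r[0, ], min_years = 1)$retained)
  expect_equal(screen_station(r[0, ], min_years = 1)$years_complete, 0)
})
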