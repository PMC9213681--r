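test_that("generation is bitwise deterministic given the seed", {
  spec <- network_spec(n_stations = 3, years = c(2016, 2020), seed = 99)
  a <- generate_station_network(spec)
  b <- generate_station_network(spec)
  expect_identical(a$records, b$records)
  expect_identical(a$meta, b$meta)
})

test_that("zero noise and zero diurnal amplitude yield the pure annual sinusoid", {
  arch <- climate_archetype("flat", annual_mean = 12, seasonal_amplitude = 7,
                            diurnal_amplitude = 0, noise_sd = 0,
                            noise_autocorr = 0)
  spec <- single_archetype_spec(1, c(2018, 2019), seed = 4, name = "flat")
  net <- generate_station_network(spec, list(flat = arch))
  r <- net$records
  expected <- 12 - 7 * cos(2 * pi * (r$doy + r$hour / 24 - 15) / 365.25)
  expect_equal(r$temp_c, expected, tolerance = 1e-12)
})

test_that("winter temperature ordering follows the archetype gradient", {
  spec <- network_spec(n_stations = 6, years = c(2014, 2020), seed = 21,
                       archetype_mix = c(warm_coastal = 1/3,
                                         intermediate = 1/3,
                                         cold_interior = 1/3))
  net <- generate_station_network(spec)
  r <- net$records
  winter <- r$doy >= 335 | r$doy <= 59
  wmean <- tapply(r$temp_c[winter], r$station_id[winter], mean)
  arch <- net$meta$archetype[match(names(wmean), net$meta$station_id)]
  by_arch <- tapply(wmean, arch, mean)
  expect_lt(by_arch[["cold_interior"]], by_arch[["intermediate"]])
  expect_lt(by_arch[["intermediate"]], by_arch[["warm_coastal"]])
})

test_that("injected frost episodes satisfy the event definition and are detected", {
  ## winter mean ~ 10.7 C with small noise: every frost run must be injected
  arch <- climate_archetype("mild", annual_mean = 15, seasonal_amplitude = 5,
                            diurnal_amplitude = 3, noise_sd = 1,
                            noise_autocorr = 0.5, frost_propensity = 2)
  spec <- single_archetype_spec(2, c(2013, 2020), seed = 31, name = "mild")
  net <- generate_station_network(spec, list(mild = arch))
  inj <- attr(net, "injected_events")
  expect_gt(nrow(inj), 0)
  ev <- detect_events(net, event_definition("frost"))
  expect_gte(nrow(ev), nrow(inj))
  ## every injected start lies inside some detected run of >= 3 h
  for (i in seq_len(nrow(inj))) {
    sid <- inj$station_id[i]
    hit <- ev$station_id == sid &
      ev$start <= inj$start[i] &
      ev$start + ev$duration_h * 3600 > as.numeric(inj$start[i])
    expect_true(any(hit))
  }
})

test_that("cold archetype accumulates more portions than warm in every season", {
  cold <- climate_archetype("cold", annual_mean = 11, seasonal_amplitude = 7,
                            diurnal_amplitude = 5, noise_sd = 2,
                            noise_autocorr = 0.8)
  warm <- climate_archetype("warm", annual_mean = 18, seasonal_amplitude = 6,
                            diurnal_amplitude = 4, noise_sd = 1.5,
                            noise_autocorr = 0.8)
  run1 <- function(a, nm) {
    spec <- single_archetype_spec(1, c(2015, 2020), seed = 8, name = nm)
    season_metrics(generate_station_network(spec, setNames(list(a), nm)))
  }
  mc <- run1(cold, "cold")
  mw <- run1(warm, "warm")
  shared <- intersect(mc$season_year, mw$season_year)
  expect_gt(length(shared), 3)
  expect_true(all(mc$chill_portions[match(shared, mc$season_year)] >
                    mw$chill_portions[match(shared, mw$season_year)]))
})

test_that("season coverage respects the 5-21 range and the bbox bounds", {
  spec <- network_spec(n_stations = 40, years = c(2000, 2020), seed = 77)
  net <- generate_station_network(spec)
  expect_true(all(net$meta$n_seasons >= 5 & net$meta$n_seasons <= 21))
  expect_true(all(net$meta$lat >= 37 & net$meta$lat <= 43))
  expect_true(all(net$meta$lon >= -7 & net$meta$lon <= 1))
  counts <- table(net$meta$archetype)
  expect_equal(sum(counts), 40)
})

test_that("invalid specs are rejected", {
  expect_error(network_spec(archetype_mix = c(a = 0.5, b = 0.6)),
               "sum to 1")
  expect_error(network_spec(n_stations = 0), "n_stations")
  expect_error(generate_station_network(
    network_spec(n_stations = 2, seed = 1), archetypes = list()), "empty")
  expect_error(climate_archetype("x", 10, -1, 1, 1, 0.5), "seasonal")
  expect_error(climate_archetype("x", 10, 5, 1, 1, 1.2), "autocorr")
})

test_that("projection ensemble: identity offsets reproduce the daily extremes", {
  spec <- single_archetype_spec(1, c(2018, 2020), seed = 3,
                                name = "intermediate")
  spec$archetype_mix <- c(intermediate = 1)
  net <- generate_station_network(spec)
  sc <- warming_scenario_spec("2035", "RCP4.5", mean_offset = 0,
                              gcm_spread_sd = 0, ensemble_size = 2, seed = 6)
  proj <- generate_projection_ensemble(net, sc, n_seasons = 2)
  p <- proj$projections[proj$projections$gcm == proj$projections$gcm[1], ]
  r <- net$records
  date <- as.Date(r$timestamp, tz = "UTC")
  season <- ifelse(r$doy >= 200, r$year, r$year - 1)
  keep <- season %in% tail(sort(unique(season)), 2)
  ref_min <- tapply(r$temp_c[keep], date[keep], min)
  expect_equal(unname(p$tmin_c), unname(as.numeric(ref_min)))
  expect_true(all(p$tmin_c <= p$tmax_c))
})

test_that("projection ensemble size and warming offsets behave as specified", {
  net <- generate_station_network(
    single_archetype_spec(2, c(2017, 2020), seed = 14, name = "cold_interior"))
  sc11 <- warming_scenario_spec("2055", "RCP8.5", mean_offset = 2.9,
                                ensemble_size = 11, seed = 2)
  proj <- generate_projection_ensemble(net, sc11, n_seasons = 2)
  per_grid <- table(proj$projections$grid_id, proj$projections$gcm)
  expect_equal(ncol(per_grid), 11)
  expect_length(proj$offsets, 11)
  expect_error(warming_scenario_spec("2055", "RCP8.5", 2.9,
                                     ensemble_size = 0), "ensemble_size")
})
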