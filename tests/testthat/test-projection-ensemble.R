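test_that("scenario keys validate the four horizon x RCP combinations", {
  k <- scenario_key("2055", "RCP8.5")
  expect_equal(k$label, "2055_RCP8.5")
  expect_error(scenario_key("2070", "RCP8.5"))
  expect_error(scenario_key("2035", "RCP6.0"))
})

test_that("stations match their nearest grid point by great-circle distance", {
  st <- data.frame(station_id = c("A", "B"), lat = c(40, 41.5),
                   lon = c(-3, -1))
  grid <- data.frame(grid_id = c("g1", "g2", "g3"),
                     lat = c(40, 41, 42), lon = c(-3, -1.2, -0.8))
  m <- match_stations_to_grid(st, grid)
  expect_equal(m$grid_id[m$station_id == "A"], "g1")
  expect_equal(m$distance_km[m$station_id == "A"], 0)

  ## exhaustive arg-min on random layouts
  set.seed(17)
  for (i in 1:20) {
    s1 <- data.frame(station_id = "X", lat = runif(1, 37, 43),
                     lon = runif(1, -7, 1))
    g <- data.frame(grid_id = paste0("g", 1:6), lat = runif(6, 37, 43),
                    lon = runif(6, -7, 1))
    d <- geosphere::distHaversine(cbind(g$lon, g$lat),
                                  c(s1$lon, s1$lat), r = 6371)
    m <- match_stations_to_grid(s1, g)
    expect_equal(m$grid_id, g$grid_id[which.min(d)])
    expect_equal(m$distance_km, min(d), tolerance = 1e-9)
  }
  expect_error(match_stations_to_grid(st, grid[0, ]), "empty grid")
})

test_that("synthetic grid jitter keeps match distances below 4 km", {
  net <- generate_station_network(
    network_spec(n_stations = 8, years = c(2018, 2020), seed = 23))
  proj <- generate_projection_ensemble(
    net, warming_scenario_spec("2035", "RCP4.5", 1.2, ensemble_size = 1,
                               seed = 5), n_seasons = 1)
  m <- match_stations_to_grid(net, proj$grid)
  expect_true(all(m$distance_km <= 4))
  s <- attr(m, "distance_summary")
  expect_true(s[["min"]] >= 0 && s[["max"]] <= 4 &&
                s[["mean"]] <= s[["max"]])
})

test_that("ensemble means are arithmetic means across GCMs", {
  net <- generate_station_network(single_archetype_spec(
    2, c(2017, 2020), seed = 19, name = "intermediate"))
  ## zero spread: every GCM identical, ensemble equals any member
  sc0 <- warming_scenario_spec("2035", "RCP4.5", mean_offset = 1,
                               gcm_spread_sd = 0, ensemble_size = 3,
                               seed = 7)
  em <- run_scenario(net, generate_projection_ensemble(net, sc0,
                                                       n_seasons = 2))
  for (sid in em$ensemble$station_id) {
    per <- em$per_gcm[em$per_gcm$station_id == sid, ]
    expect_equal(length(unique(per$chill_portions)), 1)
    expect_equal(em$ensemble$chill_portions[em$ensemble$station_id == sid],
                 per$chill_portions[1])
  }

  ## with spread, the ensemble is the exact mean of the per-GCM values,
  ## permutation-invariant and linear (50 and 70 average to 60)
  sc <- warming_scenario_spec("2055", "RCP8.5", mean_offset = 2.9,
                              gcm_spread_sd = 0.5, ensemble_size = 4,
                              seed = 9)
  em2 <- run_scenario(net, generate_projection_ensemble(net, sc,
                                                        n_seasons = 2),
                      events = FALSE)
  for (sid in em2$ensemble$station_id) {
    per <- em2$per_gcm[em2$per_gcm$station_id == sid, ]
    expect_equal(em2$ensemble$chill_portions[em2$ensemble$station_id == sid],
                 mean(per$chill_portions), tolerance = 1e-12)
    expect_equal(mean(sample(per$gdh_anderson)),
                 em2$ensemble$gdh_anderson[em2$ensemble$station_id == sid],
                 tolerance = 1e-12)
    ## leave-one-out perturbation bound: |mean - loo_mean| <= (max-min)/n
    n <- nrow(per)
    loo <- vapply(seq_len(n), function(j) mean(per$chill_portions[-j]),
                  numeric(1))
    expect_true(all(abs(loo - mean(per$chill_portions)) <=
                      (max(per$chill_portions) - min(per$chill_portions)) / n
                    + 1e-12))
  }
  expect_equal(mean(c(50, 70)), 60)
})

test_that("chill_delta is zero at identity and positive under warming", {
  net <- generate_station_network(network_spec(
    n_stations = 6, years = c(2015, 2020), seed = 29,
    archetype_mix = c(warm_coastal = 0.5, cold_interior = 0.5)))
  means <- station_means(season_metrics(net))
  ident <- chill_delta(means, means[, c("station_id", "chill_portions",
                                        "gdh_anderson")])
  expect_true(all(ident$chill_lost == 0 & ident$heat_gained == 0))

  sc <- warming_scenario_spec("2055", "RCP8.5", mean_offset = 2.9,
                              ensemble_size = 2, seed = 3)
  em <- run_scenario(net, generate_projection_ensemble(net, sc,
                                                       n_seasons = 2),
                     events = FALSE)
  d <- chill_delta(means, em)
  warm_ids <- net$meta$station_id[net$meta$archetype == "warm_coastal"]
  expect_true(all(d$chill_lost[d$station_id %in% warm_ids] > 0))
  expect_true(all(d$heat_gained[d$station_id %in% warm_ids] > 0))
})

test_that("a missing GCM series is a hard error naming the gap", {
  net <- generate_station_network(single_archetype_spec(
    2, c(2019, 2020), seed = 37, name = "intermediate"))
  sc <- warming_scenario_spec("2035", "RCP4.5", 1.2, ensemble_size = 2,
                              seed = 11)
  proj <- generate_projection_ensemble(net, sc, n_seasons = 1)
  gcm1 <- proj$projections$gcm == proj$projections$gcm[1]
  broken <- proj$projections[gcm1, ]
  expect_error(
    run_scenario(net, structure(list(projections = broken, grid = proj$grid,
                                     offsets = proj$offsets[1],
                                     scenario = sc),
                                class = "projection_set"),
                 events = FALSE),
    NA)  # one GCM alone still runs
  ## drop one grid cell for one GCM only -> error
  drop <- proj$projections$grid_id == proj$grid$grid_id[1] & !gcm1
  expect_error(
    run_scenario(net, structure(list(projections = proj$projections[!drop, ],
                                     grid = proj$grid,
                                     offsets = proj$offsets,
                                     scenario = sc),
                                class = "projection_set"),
                 events = FALSE),
    "missing projections")
})
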