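## Climate archetypes and generator/scenario specifications.

#' Define a climate archetype for the synthetic station generator
#'
#' An archetype fixes the statistical structure of a station's hourly
#' temperature: annual sinusoid (trough in mid-January), diurnal sinusoid
#' (peak at 15:00 solar time), AR(1) Gaussian residual, and expected counts
#' of injected frost and abnormal winter-heat episodes per dormancy season.
#'
#' @param name archetype label, e.g. `"warm_coastal"`.
#' @param annual_mean annual mean temperature (C).
#' @param seasonal_amplitude semi-amplitude of the annual sinusoid (C), > 0.
#' @param diurnal_amplitude semi-amplitude of the diurnal sinusoid (C), > 0.
#' @param noise_sd stationary standard deviation of the AR(1) hourly
#'   residual (C), >= 0.
#' @param noise_autocorr lag-1 hourly autocorrelation, in [0, 1).
#' @param frost_propensity,heatspike_propensity expected injected episodes
#'   per winter, >= 0 (Poisson counts).
#' @return object of class `climate_archetype`.
#' @export
climate_archetype <- function(name, annual_mean, seasonal_amplitude,
                              diurnal_amplitude, noise_sd, noise_autocorr,
                              frost_propensity = 0,
                              heatspike_propensity = 0) {
  stop_if_not(is.character(name) && length(name) == 1L, "name must be a label")
  stop_if_not(seasonal_amplitude > 0, "seasonal_amplitude must be > 0")
  stop_if_not(diurnal_amplitude >= 0, "diurnal_amplitude must be >= 0")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(noise_autocorr >= 0 && noise_autocorr < 1,
              "noise_autocorr must lie in [0, 1)")
  stop_if_not(frost_propensity >= 0 && heatspike_propensity >= 0,
              "episode propensities must be >= 0")
  structure(list(name = name, annual_mean = annual_mean,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_amplitude = diurnal_amplitude,
                 noise_sd = noise_sd, noise_autocorr = noise_autocorr,
                 frost_propensity = frost_propensity,
                 heatspike_propensity = heatspike_propensity),
            class = "climate_archetype")
}

#' Default climate archetypes
#'
#' Three archetypes spanning the warm-to-cold gradient of a Mediterranean
#' fruit-growing station network, tuned so that their long-run mean seasonal
#' chill lands in the three conventional classes: warm_coastal below 60
#' portions, intermediate in [60, 80], cold_interior above 80.
#'
#' @return named list of `climate_archetype` objects.
#' @export
default_archetypes <- function() {
  list(
    warm_coastal = climate_archetype(
      "warm_coastal", annual_mean = 17.6, seasonal_amplitude = 6.0,
      diurnal_amplitude = 3.5, noise_sd = 1.5, noise_autocorr = 0.8,
      frost_propensity = 0.05, heatspike_propensity = 2.5),
    intermediate = climate_archetype(
      "intermediate", annual_mean = 15.2, seasonal_amplitude = 6.0,
      diurnal_amplitude = 4.5, noise_sd = 1.8, noise_autocorr = 0.8,
      frost_propensity = 1.2, heatspike_propensity = 0.6),
    cold_interior = climate_archetype(
      "cold_interior", annual_mean = 12.2, seasonal_amplitude = 7.2,
      diurnal_amplitude = 5.5, noise_sd = 2.0, noise_autocorr = 0.8,
      frost_propensity = 3.5, heatspike_propensity = 0.05)
  )
}

#' Specification of a synthetic station network
#'
#' @param n_stations number of stations (>= 1).
#' @param bbox named numeric vector `c(lat_min, lat_max, lon_min, lon_max)`
#'   in degrees; station coordinates are drawn uniformly inside it.
#' @param archetype_mix named proportions over archetypes, summing to 1.
#' @param years inclusive calendar range of candidate dormancy seasons
#'   (length-2 integer vector); each station covers a contiguous block of
#'   5-21 seasons (median 20) inside it.
#' @param seed integer RNG seed; the generated network is a deterministic
#'   function of the spec.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(n_stations = 60,
                         bbox = c(lat_min = 37, lat_max = 43,
                                  lon_min = -7, lon_max = 1),
                         archetype_mix = c(warm_coastal = 0.125,
                                           intermediate = 0.45,
                                           cold_interior = 0.425),
                         years = c(2000L, 2020L),
                         seed = 42L) {
  stop_if_not(n_stations >= 1, "n_stations must be >= 1")
  stop_if_not(all(c("lat_min", "lat_max", "lon_min", "lon_max") %in%
                    names(bbox)), "bbox needs lat/lon min and max")
  stop_if_not(bbox[["lat_min"]] < bbox[["lat_max"]] &&
                bbox[["lon_min"]] < bbox[["lon_max"]], "degenerate bbox")
  stop_if_not(abs(sum(archetype_mix) - 1) <= 1e-9,
              "archetype_mix must sum to 1 (got %.6f)", sum(archetype_mix))
  stop_if_not(all(archetype_mix >= 0), "archetype_mix must be non-negative")
  years <- as.integer(range(years))
  stop_if_not(years[2] >= years[1], "years range is empty")
  structure(list(n_stations = as.integer(n_stations), bbox = bbox,
                 archetype_mix = archetype_mix, years = years,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Specification of a warming scenario for the pseudo-GCM ensemble
#'
#' @param horizon `"2035"` (period 2025-2045) or `"2055"` (2045-2065).
#' @param rcp `"RCP4.5"` or `"RCP8.5"`.
#' @param mean_offset mean warming (C) added to daily temperatures.
#' @param gcm_spread_sd between-GCM spread (C) of the fixed per-GCM offsets.
#' @param ensemble_size number of pseudo-GCMs (default 11).
#' @param seed integer RNG seed.
#' @return object of class `warming_scenario_spec`.
#' @export
warming_scenario_spec <- function(horizon, rcp, mean_offset,
                                  gcm_spread_sd = 0.3,
                                  ensemble_size = 11L, seed = 42L) {
  horizon <- match.arg(as.character(horizon), c("2035", "2055"))
  rcp <- match.arg(rcp, c("RCP4.5", "RCP8.5"))
  stop_if_not(ensemble_size >= 1, "ensemble_size must be >= 1")
  stop_if_not(gcm_spread_sd >= 0, "gcm_spread_sd must be >= 0")
  structure(list(horizon = horizon, rcp = rcp,
                 mean_offset = mean_offset, gcm_spread_sd = gcm_spread_sd,
                 ensemble_size = as.integer(ensemble_size),
                 seed = as.integer(seed)),
            class = "warming_scenario_spec")
}

#' Default warming scenarios
#'
#' Four scenario specifications (two horizons x two RCPs) with mean offsets
#' representative of downscaled projections for Iberia: +1.2 C (2035,
#' RCP4.5), +1.5 C (2035, RCP8.5), +1.9 C (2055, RCP4.5) and +2.9 C (2055,
#' RCP8.5), each with a 0.3 C between-GCM spread and 11 pseudo-GCMs.
#'
#' @param ensemble_size number of pseudo-GCMs per scenario.
#' @param seed base seed; each scenario uses `seed + k` for scenario k.
#' @return named list of `warming_scenario_spec` objects, keyed
#'   `"<horizon>_<rcp>"`.
#' @export
default_scenarios <- function(ensemble_size = 11L, seed = 42L) {
  specs <- list(
    `2035_RCP4.5` = c("2035", "RCP4.5", 1.2),
    `2035_RCP8.5` = c("2035", "RCP8.5", 1.5),
    `2055_RCP4.5` = c("2055", "RCP4.5", 1.9),
    `2055_RCP8.5` = c("2055", "RCP8.5", 2.9)
  )
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    out[[k]] <- warming_scenario_spec(s[1], s[2],
                                      mean_offset = as.numeric(s[3]),
                                      ensemble_size = ensemble_size,
                                      seed = seed + k)
  }
  out
}

#' Labels of the pseudo-GCM ensemble members
#'
#' The first eleven labels follow the global climate models commonly used for
#' statistically downscaled Iberian projections; larger ensembles are padded
#' with generic labels.
#'
#' @param n number of labels.
#' @return character vector of length `n`.
#' @export
gcm_labels <- function(n = 11L) {
  base <- c("bcc-csm1-1-m", "BNU-ESM", "CanESM2", "CMCC-CM", "GFDL-ESM2G",
            "inmcm4", "IPSL-CM5A-LR", "MIROC-ESM", "MPI-ESM-LR",
            "MPI-ESM-MR", "MRI-CGCM3")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("GCM-%02d", seq_len(n - length(base))))
}
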