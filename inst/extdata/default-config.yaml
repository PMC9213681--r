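# Default agrochill pipeline configuration.  Every value here mirrors
# default_config(); fields omitted from a user config fall back to these.
seed: 42
network:
  n_stations: 12
  bbox:
    lat_min: 37.0
    lat_max: 43.0
    lon_min: -7.0
    lon_max: 1.0
  archetype_mix:
    warm_coastal: 0.25
    intermediate: 0.375
    cold_interior: 0.375
  years: [2000, 2020]
qc:
  min_years: 5          # complete seasons required to retain a station
  min_fraction: 0.9     # hourly completeness per accumulation window
events:
  frost:
    threshold: -1.0     # degrees C, strict "falls below"
    min_hours: 3
    weeks: [2, 3, 4, 5, 6, 7, 8, 9, 10]
  abnormal_heat:
    threshold: 25.0     # degrees C, strict "rises above"
    min_hours: 3
    weeks: [49, 50, 51, 52, 1, 2, 3, 4, 5, 6, 7, 8]
  probability_cutoff: 0.10
scenarios:
  2035_RCP4.5: {horizon: "2035", rcp: "RCP4.5", mean_offset: 1.2}
  2035_RCP8.5: {horizon: "2035", rcp: "RCP8.5", mean_offset: 1.5}
  2055_RCP4.5: {horizon: "2055", rcp: "RCP4.5", mean_offset: 1.9}
  2055_RCP8.5: {horizon: "2055", rcp: "RCP8.5", mean_offset: 2.9}
projection:
  ensemble_size: 11     # pseudo-GCMs per scenario
  gcm_spread_sd: 0.3    # between-GCM offset spread, degrees C
  n_seasons: 5          # most recent seasons projected per station
idw:
  power: 2
  mask_km: 50           # validity radius around the nearest station
  cell_deg: 0.05        # ~5 km grid
classes:
  low_bound: 60         # portions; < 60 -> low
  high_bound: 80        # portions; > 80 -> high, [60, 80] -> medium
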