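## Station classification by chill level, inter-model agreement statistics,
## per-class distribution summaries, and IDW interpolation onto a regular
## lat/lon grid with a distance validity mask.

#' Classify stations by mean chill portions
#'
#' Conventional chill classes: low below 60 portions, medium in the closed
#' interval [60, 80], high above 80.
#'
#' @param mean_portions numeric vector of per-station mean chill portions.
#' @param low_bound,high_bound class boundaries (default 60 and 80; the
#'   boundaries themselves belong to the medium class).
#' @return character vector of `"low"`, `"medium"`, `"high"`.
#' @examples
#' classify_station(c(55, 60, 80, 85))
#' @export
classify_station <- function(mean_portions, low_bound = 60, high_bound = 80) {
  stopifnot(is.numeric(mean_portions), low_bound < high_bound)
  ifelse(mean_portions < low_bound, "low",
         ifelse(mean_portions <= high_bound, "medium", "high"))
}

#' Regular lat/lon grid of cell centres
#'
#' @param bbox named numeric `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param cell_deg cell size in degrees (default 0.05, about 5 km).
#' @return data.frame with columns lat, lon.
#' @export
make_grid <- function(bbox, cell_deg = 0.05) {
  stopifnot(cell_deg > 0)
  lats <- seq(bbox[["lat_min"]] + cell_deg / 2, bbox[["lat_max"]],
              by = cell_deg)
  lons <- seq(bbox[["lon_min"]] + cell_deg / 2, bbox[["lon_max"]],
              by = cell_deg)
  out <- expand.grid(lon = lons, lat = lats, KEEP.OUT.ATTRS = FALSE)
  out[, c("lat", "lon")]
}

#' Inverse-distance-weighted surface of a station metric
#'
#' Cell value = sum(w_i v_i) / sum(w_i) with w_i = d_i^(-power) over all
#' stations; a cell within numerical tolerance of a station takes that
#' station's value exactly; cells farther than `mask_km` from every station
#' are masked (value `NA`).  Coincident stations with different values are
#' averaged with a warning.
#'
#' @param values data.frame with station_id, lat, lon, value.
#' @param grid data.frame of cell centres (lat, lon); defaults to a
#'   `cell_deg` grid over the station bounding box padded by `mask_km`.
#' @param power IDW exponent (> 0; default 2).
#' @param mask_km validity radius in km (default 50).
#' @param cell_deg cell size for the default grid (default 0.05 degrees).
#' @return object of class `scenario_surface`: data.frame lat, lon, value,
#'   nearest_km, masked; parameters in attributes.
#' @export
idw_surface <- function(values, grid = NULL, power = 2, mask_km = 50,
                        cell_deg = 0.05) {
  stopifnot(is.data.frame(values),
            all(c("station_id", "lat", "lon", "value") %in% names(values)))
  stop_if_not(nrow(values) >= 1, "no stations to interpolate")
  stop_if_not(power > 0, "power must be > 0")
  stop_if_not(all(is.finite(values$value)), "non-finite station values")

  ## collapse coincident stations (within 1 m) to their mean
  if (nrow(values) > 1) {
    key <- paste(round(values$lat, 5), round(values$lon, 5))
    if (anyDuplicated(key)) {
      warning("coincident stations averaged before interpolation")
      values <- do.call(rbind, lapply(split(values, key), function(d) {
        data.frame(station_id = d$station_id[1L], lat = d$lat[1L],
                   lon = d$lon[1L], value = mean(d$value),
                   stringsAsFactors = FALSE)
      }))
    }
  }

  if (is.null(grid)) {
    pad <- mask_km / 111  # ~ degrees latitude per km
    grid <- make_grid(c(lat_min = min(values$lat) - pad,
                        lat_max = max(values$lat) + pad,
                        lon_min = min(values$lon) - pad,
                        lon_max = max(values$lon) + pad),
                      cell_deg = cell_deg)
  }

  dm <- distance_matrix_km(grid$lat, grid$lon, values$lat, values$lon)
  nearest <- apply(dm, 1L, min)
  w <- dm^(-power)
  val <- as.numeric(w %*% values$value) / rowSums(w)

  ## exactness at station locations
  at_station <- nearest < 1e-6
  if (any(at_station)) {
    idx <- apply(dm[at_station, , drop = FALSE], 1L, which.min)
    val[at_station] <- values$value[idx]
  }
  masked <- nearest > mask_km
  val[masked] <- NA_real_

  out <- data.frame(lat = grid$lat, lon = grid$lon, value = val,
                    nearest_km = nearest, masked = masked)
  structure(out, class = c("scenario_surface", "data.frame"),
            power = power, mask_km = mask_km)
}

#' Export a surface as GeoJSON points
#'
#' Unmasked cells become Point features with `value` and `nearest_km`
#' properties.
#'
#' @param surface a `scenario_surface`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
surface_to_geojson <- function(surface, path) {
  s <- surface[!surface$masked, , drop = FALSE]
  features <- lapply(seq_len(nrow(s)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(s$lon[i], s$lat[i])),
         properties = list(value = s$value[i],
                           nearest_km = s$nearest_km[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Agreement between two per-station metrics
#'
#' Ordinary least-squares coefficient of determination and Pearson
#' correlation on paired station means.
#'
#' @param x,y paired numeric vectors (>= 3 finite pairs).
#' @return list with `r_squared`, `pearson_r`, `n`.
#' @export
model_agreement <- function(x, y) {
  stop_if_not(length(x) == length(y), "x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  stop_if_not(sum(ok) >= 3, "need at least 3 finite pairs")
  x <- x[ok]
  y <- y[ok]
  fit <- lm(y ~ x)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  list(r_squared = r2, pearson_r = cor(x, y), n = length(x))
}

#' Distribution summaries per chill class and scenario
#'
#' Tukey box statistics per class: quartiles (type-7), 1.5 x IQR whiskers
#' drawn to the most extreme points inside the fences, and the station ids of
#' points outside them.  Classes are assigned from the current scenario and
#' held fixed across scenarios.
#'
#' @param values data.frame with station_id, class, scenario, value.
#' @return data.frame: class, scenario, n, q1, median, q3, whisker_low,
#'   whisker_high, outliers (";"-joined station ids).
#' @export
class_summary <- function(values) {
  stopifnot(all(c("station_id", "class", "scenario", "value") %in%
                  names(values)))
  groups <- split(values, list(values$class, values$scenario), drop = TRUE)
  rows <- lapply(groups, function(d) {
    q <- quantile(d$value, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- d$value >= lo_fence & d$value <= hi_fence
    data.frame(class = d$class[1L], scenario = d$scenario[1L],
               n = nrow(d), q1 = q[1], median = q[2], q3 = q[3],
               whisker_low = min(d$value[inside]),
               whisker_high = max(d$value[inside]),
               outliers = paste(d$station_id[!inside], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$class, out$scenario), , drop = FALSE]
}
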