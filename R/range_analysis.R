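#' Maximum sensitivity-specificity threshold
#'
#' The suitability cut-off that maximises sensitivity + specificity over the
#' finite candidate set of midpoints between consecutive sorted unique
#' scores. Ties are broken toward the lower threshold (favouring
#' sensitivity). Classification uses `score >= threshold` for presences, so
#' the chosen threshold exactly reproduces the sensitivity/specificity pair
#' that selected it.
#'
#' @param scores_presence,scores_absence suitability scores at presence /
#'   (pseudo-)absence sites
#' @return the MSS threshold in `[0, 1]`
#' @export
mss_threshold <- function(scores_presence, scores_absence) {
  stopifnot(length(scores_presence) > 0L, length(scores_absence) > 0L)
  u <- sort(unique(c(scores_presence, scores_absence)))
  if (length(u) < 2L) stop("degenerate scores: all values identical")
  cand <- (u[-length(u)] + u[-1]) / 2
  ss <- vapply(cand, function(t) {
    mean(scores_presence >= t) + mean(scores_absence < t)
  }, numeric(1))
  cand[which.max(ss)]   # which.max returns the first (lowest) maximiser
}

#' Binarize suitability into a potential-range map
#'
#' @param suitability a [raster_grid()] in `[0, 1]`
#' @param threshold cut-off in `[0, 1]`; cells with suitability `>=`
#'   threshold are inside the range
#' @return a [raster_grid()] with values in `{0, 1}` (nodata propagated) and
#'   attribute `threshold`
#' @export
binarize <- function(suitability, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  g <- grid_like(suitability, (suitability$values >= threshold) * 1)
  attr(g, "threshold") <- threshold
  g
}

#' Area of a binary range map
#'
#' @param range a binary [raster_grid()] (1 = inside)
#' @param areas a [cell_area_grid()] on the same grid
#' @return total area in km^2
#' @export
range_area <- function(range, areas) {
  stop_if_misaligned(range, areas, "range and area grids")
  sum(areas$values[which(range$values == 1)])
}

#' Range expansion ratio
#'
#' RER = future range area / current range area; values above 1 mean the
#' potential range grows.
#'
#' @param rc_area current range area (km^2, > 0)
#' @param rf_area future range area (km^2)
#' @return dimensionless ratio
#' @export
compute_rer <- function(rc_area, rf_area) {
  if (rc_area <= 0) stop("undefined RER: current range area is zero")
  rf_area / rc_area
}

#' Range similarity index
#'
#' Sorensen overlap of the current and future binary ranges:
#' RSI = 2 * shared area / (current area + future area), in `[0, 1]`;
#' 1 means identical ranges, 0 disjoint ranges.
#'
#' @param current,future binary [raster_grid()]s on one grid
#' @param areas a [cell_area_grid()] on the same grid
#' @return RSI in `[0, 1]`
#' @export
compute_rsi <- function(current, future, areas) {
  stop_if_misaligned(current, future, "range maps")
  rc <- range_area(current, areas)
  rf <- range_area(future, areas)
  if (rc + rf <= 0) stop("both ranges empty: RSI undefined")
  shared <- grid_like(current,
                      ((current$values == 1) & (future$values == 1)) * 1)
  2 * range_area(shared, areas) / (rc + rf)
}

#' Expanding range
#'
#' Cells inside the future range but outside the current one — territory a
#' species could newly occupy under the scenario.
#'
#' @param current,future binary [raster_grid()]s on one grid
#' @return binary [raster_grid()]
#' @export
expanding_range <- function(current, future) {
  stop_if_misaligned(current, future, "range maps")
  v <- ((future$values == 1) & (current$values != 1)) * 1
  v[is.na(future$values)] <- NA_real_
  grid_like(current, v)
}

# area-weighted spherical centroid of a binary range: mean of the cell-centre
# unit vectors, projected back to the sphere
range_centroid <- function(range, areas) {
  cells <- which(range$values == 1)
  if (!length(cells)) stop("empty range: centroid undefined")
  ny <- nrow(range$values)
  row <- (cells - 1L) %% ny + 1L
  col <- (cells - 1L) %/% ny + 1L
  lon <- grid_lon(range)[col] * pi / 180
  lat <- grid_lat(range)[row] * pi / 180
  w <- areas$values[cells]
  x <- sum(w * cos(lat) * cos(lon)); y <- sum(w * cos(lat) * sin(lon))
  z <- sum(w * sin(lat))
  c(lon = atan2(y, x) * 180 / pi,
    lat = atan2(z, sqrt(x^2 + y^2)) * 180 / pi)
}

# initial great-circle bearing from point 1 to point 2, degrees from north
initial_bearing <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dl <- (lon2 - lon1) * r
  th <- atan2(sin(dl) * cos(lat2 * r),
              cos(lat1 * r) * sin(lat2 * r) -
                sin(lat1 * r) * cos(lat2 * r) * cos(dl))
  (th * 180 / pi) %% 360
}

#' Centroid shift between two ranges
#'
#' Great-circle distance and initial bearing from the area-weighted centroid
#' of the current range to that of the future range.
#'
#' @param current,future non-empty binary [raster_grid()]s on one grid
#' @param areas a [cell_area_grid()]
#' @return list with `distance_km`, `bearing_deg`, `from` and `to`
#'   (lon/lat centroids)
#' @export
centroid_shift <- function(current, future, areas) {
  stop_if_misaligned(current, future, "range maps")
  a <- range_centroid(current, areas)
  b <- range_centroid(future, areas)
  list(distance_km = unname(great_circle_km(a[["lon"]], a[["lat"]],
                                            b[["lon"]], b[["lat"]])),
       bearing_deg = unname(initial_bearing(a[["lon"]], a[["lat"]],
                                            b[["lon"]], b[["lat"]])),
       from = a, to = b)
}

#' Paired-samples t-test of current vs future range sizes
#'
#' Two-sided paired t-test across species of current-scenario range areas
#' against one future scenario's areas.
#'
#' @param current_areas,future_areas per-species areas (km^2), equal length,
#'   n >= 2
#' @return list with `t`, `df`, `p_value`, `mean_difference`
#' @export
paired_t_test <- function(current_areas, future_areas) {
  stopifnot(length(current_areas) == length(future_areas),
            length(current_areas) >= 2L)
  d <- future_areas - current_areas
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
    stop("zero variance of paired differences: t statistic undefined")
  }
  tt <- stats::t.test(future_areas, current_areas, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Full range-dynamics summary for one species and scenario pair
#'
#' @param current,future binary [raster_grid()]s (current / future potential
#'   range)
#' @param areas a [cell_area_grid()]
#' @param species,scenario labels carried into the output row
#' @return one-row data.frame: species, scenario, rc_km2, rf_km2, rs_km2,
#'   rer, rsi, expanding_km2, centroid_shift_km, bearing_deg
#' @export
range_dynamics <- function(current, future, areas,
                           species = "species", scenario = "future") {
  rc <- range_area(current, areas)
  rf <- range_area(future, areas)
  shared <- grid_like(current,
                      ((current$values == 1) & (future$values == 1)) * 1)
  rs <- range_area(shared, areas)
  exp_map <- expanding_range(current, future)
  shift <- centroid_shift(current, future, areas)
  data.frame(
    species = species, scenario = scenario,
    rc_km2 = rc, rf_km2 = rf, rs_km2 = rs,
    rer = compute_rer(rc, rf),
    rsi = 2 * rs / (rc + rf),
    expanding_km2 = range_area(exp_map, areas),
    centroid_shift_km = shift$distance_km,
    bearing_deg = shift$bearing_deg,
    stringsAsFactors = FALSE
  )
}
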