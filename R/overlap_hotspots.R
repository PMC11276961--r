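#' Overlap index of habitat suitability (OIHS)
#'
#' Cell-wise sum of the species' continuous suitability maps; values lie in
#' `[0, N]` for `N` species, and high values flag cells suitable for many
#' invaders simultaneously.
#'
#' @param maps list of aligned suitability [raster_grid()]s
#' @return a [raster_grid()] of summed suitabilities
#' @export
overlap_suitability <- function(maps) {
  stopifnot(length(maps) >= 1L)
  for (m in maps[-1]) stop_if_misaligned(maps[[1]], m, "suitability maps")
  acc <- maps[[1]]$values
  for (m in maps[-1]) acc <- acc + m$values
  grid_like(maps[[1]], acc)
}

#' Overlap index of potential range (OIPR)
#'
#' Cell-wise count of species whose binary potential range covers the cell;
#' an integer map in `0..N`.
#'
#' @param maps list of aligned binary range [raster_grid()]s
#' @return a [raster_grid()] of counts
#' @export
overlap_ranges <- function(maps) {
  stopifnot(length(maps) >= 1L)
  for (m in maps[-1]) stop_if_misaligned(maps[[1]], m, "range maps")
  acc <- (maps[[1]]$values == 1) * 1
  for (m in maps[-1]) acc <- acc + (m$values == 1) * 1
  grid_like(maps[[1]], acc)
}

#' Overlap of expanding ranges
#'
#' Identical operator to [overlap_ranges()], applied to per-species expanding
#' range maps: counts how many species could newly invade each cell.
#'
#' @param maps list of aligned binary expanding-range [raster_grid()]s
#' @return a [raster_grid()] of counts
#' @export
overlap_expanding <- function(maps) overlap_ranges(maps)

#' Future-minus-current change map
#'
#' Positive values mean an increase under the future scenario. Defined
#' wherever both inputs are valid.
#'
#' @param current,future aligned [raster_grid()]s of the same kind
#'   (suitability, or an overlap index)
#' @return a [raster_grid()] of `future - current`
#' @export
suitability_change <- function(current, future) {
  stop_if_misaligned(current, future, "change inputs")
  grid_like(current, future$values - current$values)
}

#' Percentage of land area with increasing values
#'
#' Area-weighted share of valid cells on which the change map is strictly
#' positive, as a percentage of all valid land area.
#'
#' @param change a [suitability_change()] map
#' @param areas a [cell_area_grid()]
#' @return percentage in `[0, 100]`
#' @export
fraction_area_increasing <- function(change, areas) {
  stop_if_misaligned(change, areas, "change and area grids")
  valid <- !is.na(change$values)
  if (!any(valid)) stop("no valid cells in change map")
  100 * sum(areas$values[valid & change$values > 0]) /
    sum(areas$values[valid])
}

#' Invasion-hotspot mask from an overlap map
#'
#' Flags cells whose overlap value exceeds the area-weighted quantile of the
#' overlap distribution over valid land cells, so the mask covers roughly a
#' `1 - quantile` share of land area (top decile by default).
#'
#' @param overlap an overlap [raster_grid()] ([overlap_suitability()] or
#'   [overlap_ranges()])
#' @param areas a [cell_area_grid()]
#' @param quantile fraction in (0, 1); default 0.9
#' @return binary [raster_grid()] with attribute `threshold` (the quantile
#'   value of the overlap index)
#' @export
hotspot_mask <- function(overlap, areas, quantile = 0.9) {
  stopifnot(quantile > 0, quantile < 1)
  stop_if_misaligned(overlap, areas, "overlap and area grids")
  cells <- which(!is.na(overlap$values))
  v <- overlap$values[cells]
  if (max(v) == min(v)) stop("no quantile contrast: overlap map is constant")
  w <- areas$values[cells]
  o <- order(v)
  cum <- cumsum(w[o]) / sum(w)
  thr <- v[o][match(TRUE, cum >= quantile)]
  out <- grid_like(overlap, (overlap$values > thr) * 1)
  attr(out, "threshold") <- thr
  out
}
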