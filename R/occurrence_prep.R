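#' Per-species occurrence records
#'
#' A thin wrapper around a data.frame of presence records (`lon`, `lat`,
#' `uncertainty_km`) carrying the species label and a provenance note
#' (`"raw"`, `"filtered"`, `"thinned"`).
#'
#' @param species species label (single string)
#' @param records data.frame with numeric `lon`, `lat` and optional
#'   `uncertainty_km` columns
#' @param provenance provenance note
#' @return an `occurrence_set`
#' @export
occurrence_set <- function(species, records, provenance = "raw") {
  stopifnot(is.character(species), length(species) == 1L)
  records <- as.data.frame(records)
  if (!all(c("lon", "lat") %in% names(records))) {
    stop("records must have 'lon' and 'lat' columns")
  }
  if (!"uncertainty_km" %in% names(records)) records$uncertainty_km <- NA_real_
  ok_lon <- is.na(records$lon) | (records$lon >= -180 & records$lon <= 180)
  ok_lat <- is.na(records$lat) | (records$lat >= -90 & records$lat <= 90)
  if (!all(ok_lon, na.rm = TRUE) || !all(ok_lat, na.rm = TRUE)) {
    stop("coordinates outside [-180,180] x [-90,90]")
  }
  structure(list(species = species,
                 records = records[, c("lon", "lat", "uncertainty_km")],
                 provenance = provenance),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d records (%s)\n",
              x$species, nrow(x$records), x$provenance))
  invisible(x)
}

#' Number of records in an occurrence set
#' @param occ an [occurrence_set()]
#' @export
n_records <- function(occ) nrow(occ$records)

#' Drop records with large coordinate uncertainty
#'
#' Records whose stated coordinate uncertainty exceeds `max_uncertainty_km`
#' are removed. Records with *missing* uncertainty are retained by default:
#' absence of metadata is not treated as evidence of error (set
#' `keep_missing = FALSE` to drop them). Input order is preserved.
#'
#' @param occ an [occurrence_set()]
#' @param max_uncertainty_km retention limit in km (default 5)
#' @param keep_missing keep records whose uncertainty is `NA`?
#' @return a filtered [occurrence_set()] with provenance `"filtered"`
#' @export
filter_uncertainty <- function(occ, max_uncertainty_km = 5, keep_missing = TRUE) {
  u <- occ$records$uncertainty_km
  keep <- if (keep_missing) is.na(u) | u <= max_uncertainty_km
          else !is.na(u) & u <= max_uncertainty_km
  occurrence_set(occ$species, occ$records[keep, , drop = FALSE],
                 provenance = "filtered")
}

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over points.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees
#' @return distance(s) in km
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(sqrt(a), 1))
}

#' Spatially thin occurrence records
#'
#' Randomised greedy thinning: records are visited in an order shuffled by
#' `seed` and accepted iff they lie at least `diameter_km` (great-circle)
#' from every previously accepted record. The result therefore has minimum
#' pairwise distance >= `diameter_km`, is maximal (every removed record is
#' within `diameter_km` of a retained one), and is idempotent.
#'
#' @param occ an [occurrence_set()]
#' @param diameter_km minimum pairwise distance between retained records (km)
#' @param seed integer seed controlling the visit order
#' @return a thinned [occurrence_set()] with provenance `"thinned"`,
#'   retained records in original row order
#' @export
thin_spatial <- function(occ, diameter_km = 5, seed = 1L) {
  rec <- occ$records
  n <- nrow(rec)
  if (n <= 1L) {
    return(occurrence_set(occ$species, rec, provenance = "thinned"))
  }
  order_idx <- with_seed(seed, sample.int(n))
  kept <- integer(0)
  for (i in order_idx) {
    if (length(kept) == 0L) {
      kept <- i
      next
    }
    d <- great_circle_km(rec$lon[i], rec$lat[i], rec$lon[kept], rec$lat[kept])
    if (all(d >= diameter_km)) kept <- c(kept, i)
  }
  occurrence_set(occ$species, rec[sort(kept), , drop = FALSE],
                 provenance = "thinned")
}

#' Read occurrence records from CSV
#'
#' Accepts the package's own column names (`species`, `lon`, `lat`,
#' `uncertainty_km`) and common Darwin-Core aliases (`decimalLongitude`,
#' `decimalLatitude`, `coordinateUncertaintyInMeters`; metres are converted
#' to km).
#'
#' @param path CSV file path
#' @param species species label; defaults to the file's `species` column
#'   (which must then be single-valued)
#' @return an [occurrence_set()]
#' @export
read_occurrences_csv <- function(path, species = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  alias <- c(decimalLongitude = "lon", decimalLatitude = "lat")
  for (a in names(alias)) {
    if (a %in% names(d) && !(alias[[a]] %in% names(d))) {
      names(d)[names(d) == a] <- alias[[a]]
    }
  }
  if ("coordinateUncertaintyInMeters" %in% names(d) &&
      !("uncertainty_km" %in% names(d))) {
    d$uncertainty_km <- d$coordinateUncertaintyInMeters / 1000
  }
  if (is.null(species)) {
    if (!"species" %in% names(d)) stop("no species column and no label given")
    sp <- unique(d$species)
    if (length(sp) != 1L) stop("file holds multiple species; pass `species`")
    species <- sp
  } else if ("species" %in% names(d)) {
    d <- d[d$species == species, , drop = FALSE]
  }
  occurrence_set(species, d, provenance = "raw")
}

#' Write an occurrence set to CSV
#' @param occ an [occurrence_set()]
#' @param path output CSV path
#' @export
write_occurrences_csv <- function(occ, path) {
  d <- cbind(species = occ$species, occ$records)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
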