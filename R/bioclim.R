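#' The 19 bioclimatic variables from monthly climate
#'
#' Computes BIO1-BIO19 per cell from 12 months of average, minimum and
#' maximum temperature and precipitation, following the WorldClim
#' definitions:
#' \itemize{
#'   \item BIO1 annual mean temperature (mean of monthly tavg)
#'   \item BIO2 mean diurnal range (mean of monthly tmax - tmin)
#'   \item BIO3 isothermality, 100 * BIO2 / BIO7
#'   \item BIO4 temperature seasonality, 100 * population SD of monthly tavg
#'   \item BIO5 / BIO6 max tmax / min tmin of any month
#'   \item BIO7 annual temperature range, BIO5 - BIO6
#'   \item BIO8-BIO11 mean temperature of the wettest / driest / warmest /
#'     coldest quarter
#'   \item BIO12 annual precipitation (sum)
#'   \item BIO13 / BIO14 precipitation of the wettest / driest month
#'   \item BIO15 precipitation seasonality, 100 * SD(prec) / (1 + BIO12/12)
#'   \item BIO16-BIO19 precipitation of the wettest / driest / warmest /
#'     coldest quarter
#' }
#' Quarters are the 12 windows of 3 consecutive months with December-January
#' wraparound; ties between quarters are broken toward the earliest quarter.
#' Standard deviations are population SDs (divisor n), the convention under
#' which the published layers were derived.
#'
#' @param climate list with elements `tavg`, `tmin`, `tmax`, `prec`, each a
#'   list of 12 [raster_grid()]s (the `climate` slot of a `synthetic_world`)
#' @return named list `BIO1` ... `BIO19` of [raster_grid()]s
#' @export
compute_bioclim <- function(climate) {
  for (v in c("tavg", "tmin", "tmax", "prec")) {
    if (is.null(climate[[v]]) || length(climate[[v]]) != 12L) {
      stop("climate$", v, " must hold 12 monthly layers")
    }
  }
  tmpl <- climate$tavg[[1]]
  as_cube <- function(layers) {
    # cells x 12 matrix (explicit cbind: sapply would drop to a vector on
    # single-cell grids)
    do.call(cbind, lapply(layers, function(g) as.vector(g$values)))
  }
  TA <- as_cube(climate$tavg); TN <- as_cube(climate$tmin)
  TX <- as_cube(climate$tmax); PR <- as_cube(climate$prec)

  pop_sd <- function(m) {
    mu <- rowMeans(m)
    sqrt(rowMeans((m - mu)^2))
  }
  # quarter sums/means over 3 consecutive months, wrapping Dec -> Jan
  qidx <- lapply(1:12, function(s) ((s - 1):(s + 1)) %% 12 + 1)
  qstat <- function(m, f) {
    out <- sapply(qidx, function(ix) f(m[, ix, drop = FALSE]))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1)  # single-cell grids
    out
  }
  q_t <- qstat(TA, rowMeans)           # mean temperature per quarter
  q_p <- qstat(PR, rowSums)            # precipitation total per quarter
  pick <- function(stat_matrix, by, which_fn) {
    # value of stat_matrix at the quarter arg-opt of `by` (earliest on ties)
    j <- apply(by, 1L, which_fn)
    stat_matrix[cbind(seq_len(nrow(stat_matrix)), j)]
  }

  bio1 <- rowMeans(TA)
  bio2 <- rowMeans(TX - TN)
  bio4 <- 100 * pop_sd(TA)
  bio5 <- apply(TX, 1L, max)
  bio6 <- apply(TN, 1L, min)
  bio7 <- bio5 - bio6
  bio3 <- ifelse(bio7 == 0, NA_real_, 100 * bio2 / bio7)
  bio12 <- rowSums(PR)
  bio13 <- apply(PR, 1L, max)
  bio14 <- apply(PR, 1L, min)
  bio15 <- 100 * pop_sd(PR) / (1 + bio12 / 12)
  bio8 <- pick(q_t, q_p, which.max)
  bio9 <- pick(q_t, q_p, which.min)
  bio10 <- pick(q_t, q_t, which.max)
  bio11 <- pick(q_t, q_t, which.min)
  bio16 <- pick(q_p, q_p, which.max)
  bio17 <- pick(q_p, q_p, which.min)
  bio18 <- pick(q_p, q_t, which.max)
  bio19 <- pick(q_p, q_t, which.min)

  vals <- list(bio1, bio2, bio3, bio4, bio5, bio6, bio7, bio8, bio9, bio10,
               bio11, bio12, bio13, bio14, bio15, bio16, bio17, bio18, bio19)
  ny <- nrow(tmpl$values)
  out <- lapply(vals, function(v) grid_like(tmpl, matrix(v, nrow = ny)))
  names(out) <- paste0("BIO", 1:19)
  out
}

#' Slope and aspect from a DEM
#'
#' Horn's 8-neighbour finite differences. Slope in degrees (>= 0); aspect in
#' degrees clockwise from north, pointing in the downslope direction, in
#' `[0, 360)`; flat cells carry the sentinel aspect -1. Cell size is
#' converted from degrees to metres with a `cos(latitude)` factor for the
#' east-west spacing. The outermost ring of cells, lacking 8 neighbours, is
#' nodata.
#'
#' @param dem a [raster_grid()] of elevations in metres
#' @return list with [raster_grid()]s `slope` and `aspect`
#' @export
compute_terrain <- function(dem) {
  z <- dem$values
  ny <- nrow(z); nx <- ncol(z)
  if (ny < 3 || nx < 3) stop("DEM must be at least 3x3 cells")
  m_per_deg <- 6371000 * pi / 180
  dy <- dem$cellsize * m_per_deg
  lat <- grid_lat(dem)
  dx <- dem$cellsize * m_per_deg * cos(lat * pi / 180)

  ri <- 2:(ny - 1); ci <- 2:(nx - 1)
  zNW <- z[ri - 1, ci - 1]; zN <- z[ri - 1, ci]; zNE <- z[ri - 1, ci + 1]
  zW  <- z[ri, ci - 1];                          zE  <- z[ri, ci + 1]
  zSW <- z[ri + 1, ci - 1]; zS <- z[ri + 1, ci]; zSE <- z[ri + 1, ci + 1]

  dzdx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * dx[ri])
  # row index increases southward, so the "upper" row is +y (north)
  dzdy <- ((zNW + 2 * zN + zNE) - (zSW + 2 * zS + zSE)) / (8 * dy)

  slope_i <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect_i <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect_i[slope_i == 0] <- -1

  slope <- matrix(NA_real_, ny, nx); aspect <- matrix(NA_real_, ny, nx)
  slope[ri, ci] <- slope_i
  aspect[ri, ci] <- aspect_i
  slope[is.na(z)] <- NA_real_; aspect[is.na(z)] <- NA_real_
  list(slope = grid_like(dem, slope), aspect = grid_like(dem, aspect))
}
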