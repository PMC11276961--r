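#' Lon/lat raster grid
#'
#' The universal spatial currency of the package: a single-layer raster on a
#' regular WGS84 longitude/latitude grid. Values are stored as a matrix whose
#' first row is the northernmost row (map orientation); `NA` cells are nodata.
#'
#' @param values numeric matrix, `nrow` = rows (north to south), `ncol` =
#'   columns (west to east). `NA` marks nodata.
#' @param xmin western edge of the grid (degrees longitude).
#' @param ymin southern edge of the grid (degrees latitude).
#' @param cellsize cell size in decimal degrees (square cells).
#' @return an object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:12, 3, 4), xmin = 0, ymin = 40, cellsize = 0.5)
#' grid_lat(g)
#' @export
raster_grid <- function(values, xmin, ymin, cellsize) {
  values <- as.matrix(values)
  stopifnot(is.numeric(cellsize), length(cellsize) == 1L)
  if (!is.finite(cellsize) || cellsize <= 0) {
    stop("cellsize must be a positive number of degrees")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("degenerate grid: values must have at least one row and column")
  }
  storage.mode(values) <- "double"
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<raster_grid> %d rows x %d cols, cellsize %g deg\n  lon [%g, %g]  lat [%g, %g]\n",
    nrow(v), ncol(v), x$cellsize,
    x$xmin, x$xmin + ncol(v) * x$cellsize,
    x$ymin, x$ymin + nrow(v) * x$cellsize
  ))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  values [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' Is an object a raster_grid?
#' @param x object to test
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Longitudes of cell centres (west to east)
#' @param g a [raster_grid()]
#' @export
grid_lon <- function(g) {
  g$xmin + (seq_len(ncol(g$values)) - 0.5) * g$cellsize
}

#' Latitudes of cell centres, north to south (matching row order)
#' @param g a [raster_grid()]
#' @export
grid_lat <- function(g) {
  ymax <- g$ymin + nrow(g$values) * g$cellsize
  ymax - (seq_len(nrow(g$values)) - 0.5) * g$cellsize
}

#' Do two rasters share one grid?
#' @param a,b [raster_grid()] objects
#' @export
same_grid <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                     c(b$xmin, b$ymin, b$cellsize), tolerance = 1e-9))
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) stop("misaligned grids: ", what, " must share one grid")
  invisible(TRUE)
}

#' Build a raster on the same grid as a template
#' @param template a [raster_grid()] supplying the geotransform
#' @param values replacement matrix (defaults to all-NA)
#' @export
grid_like <- function(template, values = NULL) {
  if (is.null(values)) {
    values <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  }
  raster_grid(values, template$xmin, template$ymin, template$cellsize)
}

#' Map lon/lat coordinates to cell indices
#'
#' @param g a [raster_grid()]
#' @param lon,lat coordinate vectors (degrees)
#' @return data.frame with columns `row`, `col`, `cell` (column-major linear
#'   index into `g$values`); coordinates outside the grid give `NA`.
#' @export
cell_index <- function(g, lon, lat) {
  nx <- ncol(g$values); ny <- nrow(g$values)
  col <- floor((lon - g$xmin) / g$cellsize) + 1L
  ymax <- g$ymin + ny * g$cellsize
  row <- floor((ymax - lat) / g$cellsize) + 1L
  # points exactly on the east/north edge belong to the last cell
  col[lon == g$xmin + nx * g$cellsize] <- nx
  row[lat == g$ymin] <- ny
  bad <- col < 1L | col > nx | row < 1L | row > ny |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col, cell = (col - 1L) * ny + row)
}

#' Per-cell surface area on the sphere
#'
#' Area of each grid cell in km^2 from the spherical formula
#' A = R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom)), R = 6371 km.
#' Areas depend on latitude only and shrink towards the poles.
#'
#' @param g a [raster_grid()] supplying the geotransform
#' @return a [raster_grid()] of cell areas (km^2)
#' @export
cell_area_grid <- function(g) {
  R <- 6371
  ny <- nrow(g$values); nx <- ncol(g$values)
  ymax <- g$ymin + ny * g$cellsize
  lat_top <- ymax - (seq_len(ny) - 1L) * g$cellsize
  lat_bot <- lat_top - g$cellsize
  dl <- g$cellsize * pi / 180
  band <- R^2 * dl * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
  raster_grid(matrix(band, ny, nx), g$xmin, g$ymin, g$cellsize)
}

#' Resample a raster onto a target grid
#'
#' @param layer source [raster_grid()]
#' @param target [raster_grid()] defining the output geotransform (its values
#'   are ignored)
#' @param method `"bilinear"` (default), `"nearest"`, or `"mean"` (block
#'   average of source cell centres falling in each target cell)
#' @return a [raster_grid()] on the target grid; nodata is propagated.
#' @export
resample_to <- function(layer, target, method = c("bilinear", "nearest", "mean")) {
  method <- match.arg(method)
  sx <- grid_lon(layer); sy <- grid_lat(layer)
  src_xmax <- layer$xmin + ncol(layer$values) * layer$cellsize
  src_ymax <- layer$ymin + nrow(layer$values) * layer$cellsize
  tgt_xmax <- target$xmin + ncol(target$values) * target$cellsize
  tgt_ymax <- target$ymin + nrow(target$values) * target$cellsize
  if (target$xmin >= src_xmax || tgt_xmax <= layer$xmin ||
      target$ymin >= src_ymax || tgt_ymax <= layer$ymin) {
    stop("disjoint extents: source does not overlap the target grid")
  }
  tx <- grid_lon(target); ty <- grid_lat(target)
  ny <- length(ty); nx <- length(tx)
  out <- matrix(NA_real_, ny, nx)
  v <- layer$values

  if (method == "nearest") {
    ci <- pmin(pmax(round((tx - layer$xmin) / layer$cellsize + 0.5), 1), length(sx))
    ri <- pmin(pmax(round((src_ymax - ty) / layer$cellsize + 0.5), 1), length(sy))
    out <- v[ri, ci, drop = FALSE]
  } else if (method == "mean") {
    idx <- cell_index(target, rep(sx, each = length(sy)), rep(sy, times = length(sx)))
    ok <- !is.na(idx$cell)
    sums <- rep(0, ny * nx); cnts <- rep(0L, ny * nx)
    val <- as.vector(v)[ok]; cell <- idx$cell[ok]
    keep <- !is.na(val)
    agg <- tapply(val[keep], cell[keep], mean)
    out[as.integer(names(agg))] <- as.numeric(agg)
  } else { # bilinear on source cell centres
    fx <- (tx - sx[1]) / layer$cellsize
    fy <- (sy[1] - ty) / layer$cellsize   # sy decreases with row
    x0 <- floor(fx); y0 <- floor(fy)
    wx <- fx - x0; wy <- fy - y0
    x0 <- pmin(pmax(x0, 0), length(sx) - 2L)
    y0 <- pmin(pmax(y0, 0), length(sy) - 2L)
    wx <- pmin(pmax(fx - x0, 0), 1); wy <- pmin(pmax(fy - y0, 0), 1)
    for (j in seq_len(nx)) {
      c0 <- x0[j] + 1L; c1 <- c0 + 1L
      r0 <- y0 + 1L; r1 <- r0 + 1L
      v00 <- v[cbind(r0, c0)]; v01 <- v[cbind(r0, c1)]
      v10 <- v[cbind(r1, c0)]; v11 <- v[cbind(r1, c1)]
      out[, j] <- (1 - wy) * ((1 - wx[j]) * v00 + wx[j] * v01) +
        wy * ((1 - wx[j]) * v10 + wx[j] * v11)
    }
  }
  raster_grid(out, target$xmin, target$ymin, target$cellsize)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` raster exchange format readable by standard GIS tools.
#'
#' @param g a [raster_grid()]
#' @param path output file path
#' @param nodata value written for `NA` cells (default -9999)
#' @export
write_asc <- function(g, path, nodata = -9999) {
  v <- g$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path `.asc` file path
#' @return a [raster_grid()]
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  n_hdr <- sum(key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                          "cellsize", "nodata_value"))
  v <- matrix(scan(path, skip = n_hdr, quiet = TRUE),
              nrow = val[["nrows"]], ncol = val[["ncols"]], byrow = TRUE)
  if ("nodata_value" %in% key) v[v == val[["nodata_value"]]] <- NA_real_
  raster_grid(v, val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]])
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# derive a reproducible sub-seed (kept below 2^31) from a base seed and tags
derive_seed <- function(seed, ...) {
  tags <- unlist(list(...))
  h <- as.double(seed) %% 2147483647
  for (t in tags) {
    for (ch in utf8ToInt(as.character(t))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}
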