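#' Configuration for the virtual study system
#'
#' Defines a self-contained landscape whose statistical structure mirrors the
#' inputs of a range-dynamics study: 12-month temperature and precipitation
#' cubes, eight land-use fraction layers and a DEM, all on one lon/lat grid.
#' Occurrences can then be drawn from a known logistic niche so that every
#' downstream stage is verifiable against ground truth.
#'
#' Spatial structure comes from Gaussian-filtered white-noise random fields;
#' `corr_length` is the distance (in cells) at which the field's spatial
#' correlation falls to 1/e.
#'
#' @param xmin,xmax,ymin,ymax grid extent in degrees (WGS84 lon/lat)
#' @param res_arcmin cell size in arc-minutes
#' @param corr_length correlation length of the random fields, in cells
#' @param t_mean mean annual temperature at the southern edge (deg C)
#' @param seasonal_amp amplitude of the seasonal temperature cycle (deg C)
#' @param seasonal_lat_gain fractional increase of the seasonal amplitude
#'   from the southern to the northern edge (stronger seasonality poleward);
#'   0 gives one cycle everywhere
#' @param lat_gradient mean cooling per degree of latitude moving poleward
#'   (deg C); the total south-to-north span is `lat_gradient * extent`
#' @param lat_gradient_shape exponent shaping the gradient: temperature
#'   falls as `lat_frac^shape`, so values below 1 give a gradient that is
#'   steep near the warm edge and flattens poleward — isotherms spread out
#'   at the cool edge, so a warming shift opens disproportionately more area
#'   than it closes (1 = linear gradient)
#' @param diurnal_spread tmax - tmin spread (deg C)
#' @param lapse_rate temperature lapse with elevation (deg C per km)
#' @param noise_sd_t spatial temperature anomaly SD (deg C)
#' @param prec_mean mean monthly precipitation (mm)
#' @param prec_seasonal_amp relative amplitude of the precipitation cycle
#' @param noise_sd_p log-scale SD of the precipitation anomaly field
#' @param elev_max relief: maximum elevation of the DEM (m); 0 gives a flat DEM
#' @param warm_month,wet_month month (1-12) of the temperature / precipitation
#'   seasonal peak
#' @param seed integer seed fixing all stochastic output bit-for-bit
#' @return a `world_config` list
#' @export
world_config <- function(xmin = 0, xmax = 20, ymin = 30, ymax = 40,
                         res_arcmin = 6, corr_length = 10,
                         t_mean = 20, seasonal_amp = 8, seasonal_lat_gain = 0.3,
                         lat_gradient = 1.6, lat_gradient_shape = 0.5,
                         diurnal_spread = 8, lapse_rate = 3,
                         noise_sd_t = 0.6,
                         prec_mean = 80, prec_seasonal_amp = 0.5,
                         noise_sd_p = 0.3,
                         elev_max = 1200, warm_month = 7, wet_month = 1,
                         seed = 1L) {
  if (!is.finite(res_arcmin) || res_arcmin <= 0) stop("res_arcmin must be > 0")
  if (xmax <= xmin || ymax <= ymin) stop("degenerate extent")
  stopifnot(corr_length > 0, prec_mean > 0, diurnal_spread >= 0,
            elev_max >= 0, warm_month %in% 1:12, wet_month %in% 1:12)
  cfg <- list(
    xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
    res_arcmin = res_arcmin, corr_length = corr_length,
    t_mean = t_mean, seasonal_amp = seasonal_amp,
    seasonal_lat_gain = seasonal_lat_gain,
    lat_gradient = lat_gradient, lat_gradient_shape = lat_gradient_shape,
    diurnal_spread = diurnal_spread,
    lapse_rate = lapse_rate, noise_sd_t = noise_sd_t,
    prec_mean = prec_mean, prec_seasonal_amp = prec_seasonal_amp,
    noise_sd_p = noise_sd_p, elev_max = elev_max,
    warm_month = warm_month, wet_month = wet_month, seed = as.integer(seed)
  )
  class(cfg) <- "world_config"
  cfg
}

# stationary Gaussian random field: white noise smoothed with a Gaussian
# kernel by FFT convolution (periodic), then standardised to unit variance.
# Correlation falls to 1/e at distance `corr_length` cells (kernel sd L/2).
gaussian_random_field <- function(ny, nx, corr_length) {
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  if (corr_length <= 0.5) return(z)
  sk <- corr_length / 2
  dy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1))
  dx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1))
  if (ny %% 2 == 0) dy <- c(0:(ny / 2 - 1), -(ny / 2):-1)
  if (nx %% 2 == 0) dx <- c(0:(nx / 2 - 1), -(nx / 2):-1)
  k <- exp(-(outer(dy^2, dx^2, "+")) / (2 * sk^2))
  k <- k / sum(k)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (ny * nx)
  s <- stats::sd(as.vector(sm))
  if (s > 0) sm / s else sm
}

month_cycle <- function(month, peak) cos(2 * pi * (month - peak) / 12)

#' Generate the virtual study system
#'
#' Builds per-month `tavg`, `tmin`, `tmax` and `prec` rasters, eight land-use
#' fraction layers and a DEM on a common grid. Monthly temperature is the
#' configured seasonal cycle plus a smooth poleward cooling gradient, an
#' elevation lapse, and a spatially correlated anomaly field; precipitation is
#' a seasonal cycle modulated by a log-normal anomaly field. Output is a pure
#' function of the configuration (including its seed).
#'
#' @param config a [world_config()]
#' @return a `synthetic_world`: list with elements `climate` (lists `tavg`,
#'   `tmin`, `tmax`, `prec` of 12 [raster_grid()]s each), `landuse` (8 named
#'   fraction layers), `dem`, `scenario` (label, `"current"`), and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  cs <- config$res_arcmin / 60
  nx <- round((config$xmax - config$xmin) / cs)
  ny <- round((config$ymax - config$ymin) / cs)
  if (nx < 2 || ny < 2) stop("degenerate extent: fewer than 2 cells per axis")
  mk <- function(v) raster_grid(v, config$xmin, config$ymin, cs)

  with_seed(config$seed, {
    lat <- config$ymin + cs * ny - (seq_len(ny) - 0.5) * cs  # north -> south
    latM <- matrix(lat, ny, nx)

    dem_field <- gaussian_random_field(ny, nx, config$corr_length)
    if (config$elev_max > 0) {
      rngf <- range(dem_field)
      dem <- (dem_field - rngf[1]) / max(rngf[2] - rngf[1], 1e-12) * config$elev_max
    } else {
      dem <- matrix(0, ny, nx)
    }

    t_anom <- config$noise_sd_t *
      gaussian_random_field(ny, nx, config$corr_length)
    p_anom <- config$noise_sd_p *
      gaussian_random_field(ny, nx, config$corr_length)
    # month-specific anomaly fields (scaled down) give the seasonality
    # summaries (BIO4, BIO15) spatial structure of their own
    t_anom_m <- lapply(1:12, function(m) {
      0.4 * config$noise_sd_t * gaussian_random_field(ny, nx, config$corr_length)
    })
    p_anom_m <- lapply(1:12, function(m) {
      0.4 * config$noise_sd_p * gaussian_random_field(ny, nx, config$corr_length)
    })
    # spatially varying diurnal spread keeps BIO2/BIO3/BIO7 non-degenerate
    spread_mod <- pmax(
      1 + 0.5 * config$noise_sd_t *
        gaussian_random_field(ny, nx, config$corr_length),
      0.1
    )
    # seasonality has continental structure of its own, not a pure latitude
    # ramp: modulate the amplitude with a correlated anomaly field
    amp_mod <- pmax(
      1 + 0.4 * config$noise_sd_t *
        gaussian_random_field(ny, nx, config$corr_length),
      0.1
    )

    lat_frac <- (latM - config$ymin) / (config$ymax - config$ymin)
    amp <- config$seasonal_amp *
      (1 + config$seasonal_lat_gain * lat_frac) * amp_mod
    base_t <- config$t_mean -
      config$lat_gradient * (config$ymax - config$ymin) *
        lat_frac^config$lat_gradient_shape -
      config$lapse_rate * dem / 1000 + t_anom

    tavg <- tmin <- tmax <- prec <- vector("list", 12)
    for (m in 1:12) {
      tm <- base_t + amp * month_cycle(m, config$warm_month) + t_anom_m[[m]]
      half <- (config$diurnal_spread / 2) * spread_mod *
        (1 + 0.3 * month_cycle(m, config$warm_month))
      pm <- config$prec_mean *
        (1 + config$prec_seasonal_amp * month_cycle(m, config$wet_month)) *
        exp(p_anom + p_anom_m[[m]])
      tavg[[m]] <- mk(tm)
      tmin[[m]] <- mk(tm - half)
      tmax[[m]] <- mk(tm + half)
      prec[[m]] <- mk(pmax(pm, 0))
    }

    lu_names <- c("urban", "crop", "range", "secdn", "primn",
                  "primf", "secdf", "pastr")
    z <- lapply(seq_along(lu_names), function(i) {
      gaussian_random_field(ny, nx, config$corr_length)
    })
    # softmax over the 8 classes plus a bare-ground slot, so fractions sum < 1
    ez <- lapply(z, exp)
    denom <- Reduce(`+`, ez) + exp(0.5)
    landuse <- stats::setNames(
      lapply(ez, function(e) mk(e / denom)), lu_names
    )

    w <- list(
      climate = list(tavg = tavg, tmin = tmin, tmax = tmax, prec = prec),
      landuse = landuse,
      dem = mk(dem),
      scenario = "current",
      config = config
    )
    class(w) <- "synthetic_world"
    w
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  g <- x$dem
  cat(sprintf(
    "<synthetic_world> scenario '%s': %d x %d cells, cellsize %g deg\n",
    x$scenario, nrow(g$values), ncol(g$values), g$cellsize
  ))
  invisible(x)
}

#' Scenario perturbation of a synthetic world
#'
#' @param label scenario label (must not be `"current"`)
#' @param dtemp additive temperature shift (deg C), a scalar or a
#'   [raster_grid()] on the world grid
#' @param prec_factor multiplicative precipitation factor (> 0)
#' @param landuse_shift optional named list of `from = list(to, fraction)`
#'   transitions moving a fraction of one land-use class into another
#' @return a `scenario_delta` list
#' @export
scenario_delta <- function(label, dtemp = 0, prec_factor = 1,
                           landuse_shift = NULL) {
  if (identical(label, "current")) stop('delta label must not be "current"')
  if (!is_raster_grid(dtemp)) stopifnot(is.numeric(dtemp), length(dtemp) == 1L)
  stopifnot(is.numeric(prec_factor), prec_factor > 0)
  structure(list(label = label, dtemp = dtemp, prec_factor = prec_factor,
                 landuse_shift = landuse_shift),
            class = "scenario_delta")
}

#' Apply a scenario delta to a synthetic world
#'
#' Shifts all temperature layers additively, scales precipitation
#' multiplicatively, and optionally moves land-use fractions between classes.
#' The grid is unchanged.
#'
#' @param world a `synthetic_world`
#' @param delta a [scenario_delta()]
#' @return a new `synthetic_world` labelled with the scenario
#' @export
apply_scenario <- function(world, delta) {
  stopifnot(inherits(world, "synthetic_world"), inherits(delta, "scenario_delta"))
  dt <- if (is_raster_grid(delta$dtemp)) {
    stop_if_misaligned(world$dem, delta$dtemp, "temperature delta")
    delta$dtemp$values
  } else {
    delta$dtemp
  }
  shift_t <- function(g) grid_like(g, g$values + dt)
  scale_p <- function(g) grid_like(g, g$values * delta$prec_factor)
  out <- world
  out$climate$tavg <- lapply(world$climate$tavg, shift_t)
  out$climate$tmin <- lapply(world$climate$tmin, shift_t)
  out$climate$tmax <- lapply(world$climate$tmax, shift_t)
  out$climate$prec <- lapply(world$climate$prec, scale_p)
  if (!is.null(delta$landuse_shift)) {
    for (from in names(delta$landuse_shift)) {
      tr <- delta$landuse_shift[[from]]
      to <- tr$to; frac <- tr$fraction
      stopifnot(from %in% names(out$landuse), to %in% names(out$landuse),
                frac >= 0, frac <= 1)
      moved <- out$landuse[[from]]$values * frac
      out$landuse[[from]] <- grid_like(out$landuse[[from]],
                                       out$landuse[[from]]$values - moved)
      out$landuse[[to]] <- grid_like(out$landuse[[to]],
                                     out$landuse[[to]]$values + moved)
    }
  }
  out$scenario <- delta$label
  out
}

#' Specify a logistic niche over named predictors
#'
#' Ground truth for recovery experiments: suitability is
#' `plogis(intercept + sum(coef * x) + sum(quadratic * x^2))` per cell.
#'
#' @param species species label
#' @param coefficients named numeric vector of linear coefficients over
#'   predictor names (e.g. `c(BIO1 = 0.8)`)
#' @param intercept scalar intercept
#' @param quadratic optional named numeric vector of quadratic coefficients
#' @return a `niche_spec`
#' @export
niche_spec <- function(species, coefficients, intercept = 0, quadratic = NULL) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  if (!is.null(quadratic)) stopifnot(is.numeric(quadratic), !is.null(names(quadratic)))
  structure(list(species = species, coefficients = coefficients,
                 intercept = intercept, quadratic = quadratic),
            class = "niche_spec")
}

#' True habitat suitability of a niche on a world
#'
#' @param world a `synthetic_world`
#' @param niche a [niche_spec()]
#' @param stack optional pre-built [build_predictor_stack()] for the world
#'   (saves recomputing the bioclim variables)
#' @return a [raster_grid()] of suitabilities in `[0, 1]`
#' @export
true_suitability <- function(world, niche, stack = NULL) {
  if (is.null(stack)) stack <- build_predictor_stack(world)
  need <- union(names(niche$coefficients), names(niche$quadratic))
  missing <- setdiff(need, names(stack$layers))
  if (length(missing)) {
    stop("unknown predictor name(s) in niche: ", paste(missing, collapse = ", "))
  }
  tmpl <- stack$layers[[1]]
  eta <- matrix(niche$intercept, nrow(tmpl$values), ncol(tmpl$values))
  for (p in names(niche$coefficients)) {
    eta <- eta + niche$coefficients[[p]] * stack$layers[[p]]$values
  }
  for (p in names(niche$quadratic)) {
    eta <- eta + niche$quadratic[[p]] * stack$layers[[p]]$values^2
  }
  grid_like(tmpl, stats::plogis(eta))
}

#' Sample presence records from a suitability surface
#'
#' Cells are drawn with probability proportional to suitability; each record
#' is jittered uniformly within its cell and carries a coordinate uncertainty
#' drawn uniformly from `uncertainty_range_km`.
#'
#' @param truth a [raster_grid()] of suitabilities
#' @param n number of records (>= 1)
#' @param seed integer seed
#' @param uncertainty_range_km length-2 interval for the per-record
#'   coordinate uncertainty (km)
#' @param species species label attached to the records
#' @return an [occurrence_set()] with provenance `"raw"`
#' @export
sample_occurrences <- function(truth, n, seed,
                               uncertainty_range_km = c(0, 8),
                               species = "virtual_species") {
  stopifnot(n >= 1)
  w <- as.vector(truth$values)
  w[is.na(w)] <- 0
  if (all(w <= 0)) stop("no sampleable mass: suitability is zero everywhere")
  with_seed(seed, {
    cells <- sample.int(length(w), n, replace = TRUE, prob = w)
    ny <- nrow(truth$values)
    row <- (cells - 1L) %% ny + 1L
    col <- (cells - 1L) %/% ny + 1L
    lon0 <- truth$xmin + (col - 1L) * truth$cellsize
    ymax <- truth$ymin + ny * truth$cellsize
    lat0 <- ymax - row * truth$cellsize
    lon <- lon0 + stats::runif(n) * truth$cellsize
    lat <- lat0 + stats::runif(n) * truth$cellsize
    unc <- stats::runif(n, uncertainty_range_km[1], uncertainty_range_km[2])
    occurrence_set(species,
                   data.frame(lon = lon, lat = lat, uncertainty_km = unc),
                   provenance = "raw")
  })
}

#' Write a synthetic world to disk
#'
#' One ESRI ASCII grid per layer (`tavg_01.asc` ... `prec_12.asc`, the eight
#' land-use fractions, `dem.asc`) plus the configuration as YAML.
#'
#' @param world a `synthetic_world`
#' @param dir output directory (created if needed)
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in c("tavg", "tmin", "tmax", "prec")) {
    for (m in 1:12) {
      write_asc(world$climate[[v]][[m]],
                file.path(dir, sprintf("%s_%02d.asc", v, m)))
    }
  }
  for (nm in names(world$landuse)) {
    write_asc(world$landuse[[nm]], file.path(dir, paste0("landuse_", nm, ".asc")))
  }
  write_asc(world$dem, file.path(dir, "dem.asc"))
  cfg <- world$config
  class(cfg) <- NULL
  yaml::write_yaml(c(list(scenario = world$scenario), cfg),
                   file.path(dir, "world.yaml"))
  invisible(dir)
}
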