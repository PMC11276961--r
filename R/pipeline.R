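#' Default virtual-species niches for the demo configuration
#'
#' Two three-predictor logistic niches: a temperature band (quadratic in
#' annual mean temperature, BIO1) with linear responses to annual
#' precipitation (BIO12) and urban land fraction. The thermal optima sit in
#' the middle of the default landscape's temperature span, so warming
#' scenarios shift the suitable band poleward; the narrow thermal tolerance
#' (about +/- 1 deg C around the optimum at half-saturation) emulates a
#' specialist invader whose presences contrast clearly with background.
#'
#' @return list of [niche_spec()]s
#' @export
default_niches <- function() {
  band <- function(species, t_opt, t_curv, extra, centers, peak_eta = 4) {
    niche_spec(
      species,
      coefficients = c(c(BIO1 = 2 * t_curv * t_opt), extra),
      intercept = peak_eta - t_curv * t_opt^2 - sum(extra * centers),
      quadratic = c(BIO1 = -t_curv)
    )
  }
  list(
    band("virtual_sp1", t_opt = 16, t_curv = 1.5,
         extra = c(BIO12 = 0.004, urban = 2), centers = c(960, 0.1)),
    band("virtual_sp2", t_opt = 13, t_curv = 1.2,
         extra = c(BIO12 = -0.004, urban = 1), centers = c(960, 0.1))
  )
}

#' Default future-scenario deltas
#'
#' Two emission-pathway-style perturbations: a moderate scenario (+1.5 deg C,
#' slightly wetter) and a pessimistic one (+3 deg C, drier).
#'
#' @return named list of [scenario_delta()]s
#' @export
default_scenarios <- function() {
  list(
    F126 = scenario_delta("F126", dtemp = 1.5, prec_factor = 1.03),
    F585 = scenario_delta("F585", dtemp = 3.0, prec_factor = 0.93)
  )
}

#' Build a pipeline run configuration
#'
#' Collects every tunable of the study design with its standard value:
#' 5 km coordinate-uncertainty cut and 5 km thinning, |r| > 0.7 collinearity
#' screen, TSS > 0.6 / AUC > 0.8 ensemble gate, 70/30 cross-validation with
#' five pseudo-absence and five split repetitions, at least 1000
#' pseudo-absences per repetition.
#'
#' @param world a [world_config()]
#' @param scenarios named list of [scenario_delta()]s (the current scenario
#'   is implicit)
#' @param species list of [niche_spec()]s (synthetic species) or named list
#'   of occurrence CSV paths
#' @param n_occurrences occurrence records sampled per synthetic species
#' @param uncertainty_range_km sampled coordinate-uncertainty interval (km)
#' @param max_uncertainty_km record-retention limit (km)
#' @param thin_km spatial thinning distance (km)
#' @param corr_threshold collinearity threshold on |r|
#' @param tss_gate,auc_gate ensemble gate thresholds
#' @param cv_fraction calibration fraction of the cross-validation split
#' @param n_pa_reps,n_cv_reps pseudo-absence / split repetition counts
#' @param n_pa_min minimum pseudo-absences per repetition
#' @param algorithms algorithm roster
#' @param hotspot_quantile area-weighted quantile defining hotspots
#' @param seed base integer seed for the whole run
#' @param out_dir optional output directory for CSV/raster artifacts
#' @param write_rasters write suitability/range/overlap rasters as `.asc`?
#' @return a `run_config`
#' @export
run_config <- function(world = world_config(),
                       scenarios = default_scenarios(),
                       species = default_niches(),
                       n_occurrences = 600L,
                       uncertainty_range_km = c(0, 8),
                       max_uncertainty_km = 5,
                       thin_km = 5,
                       corr_threshold = 0.7,
                       tss_gate = 0.6, auc_gate = 0.8,
                       cv_fraction = 0.7,
                       n_pa_reps = 5L, n_cv_reps = 5L, n_pa_min = 1000L,
                       algorithms = c("sre", "glm", "rf", "xgb"),
                       hotspot_quantile = 0.9,
                       seed = 1L,
                       out_dir = NULL, write_rasters = FALSE) {
  cfg <- list(world = world, scenarios = scenarios, species = species,
              n_occurrences = n_occurrences,
              uncertainty_range_km = uncertainty_range_km,
              max_uncertainty_km = max_uncertainty_km, thin_km = thin_km,
              corr_threshold = corr_threshold,
              tss_gate = tss_gate, auc_gate = auc_gate,
              cv_fraction = cv_fraction,
              n_pa_reps = n_pa_reps, n_cv_reps = n_cv_reps,
              n_pa_min = n_pa_min, algorithms = algorithms,
              hotspot_quantile = hotspot_quantile,
              seed = as.integer(seed),
              out_dir = out_dir, write_rasters = write_rasters)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' @param config a [run_config()]
#' @return character vector of issues, each naming the offending field and a
#'   remedy; empty iff the configuration is runnable
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (!inherits(config$world, "world_config")) {
    add("world: must be a world_config()")
  }
  labels <- vapply(config$scenarios, `[[`, "", "label")
  if ("current" %in% labels) {
    add('scenarios: the label "current" is reserved for the baseline; rename the delta')
  }
  if (anyDuplicated(labels)) add("scenarios: labels must be unique")
  if (length(config$scenarios) < 1L) add("scenarios: need at least one future scenario")
  if (length(config$species) < 1L) add("species: need at least one species")
  if (!(config$cv_fraction > 0 && config$cv_fraction < 1)) {
    add("cv_fraction: must lie strictly between 0 and 1")
  }
  for (f in c("corr_threshold", "tss_gate", "auc_gate", "hotspot_quantile")) {
    v <- config[[f]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      add(paste0(f, ": must lie strictly between 0 and 1"))
    }
  }
  if (config$thin_km < 0) add("thin_km: must be >= 0")
  if (config$max_uncertainty_km < 0) add("max_uncertainty_km: must be >= 0")
  if (config$n_pa_reps < 1 || config$n_cv_reps < 1) {
    add("n_pa_reps / n_cv_reps: must be >= 1")
  }
  bad_alg <- setdiff(config$algorithms, c("sre", "glm", "rf", "xgb"))
  if (length(bad_alg)) {
    add(paste0("algorithms: unknown id(s) ", paste(bad_alg, collapse = ", ")))
  }
  if (config$n_occurrences < 30) {
    add("n_occurrences: need at least 30 records per synthetic species")
  }
  issues
}

# run the per-species stages: prep -> selection -> ensemble -> per-scenario
# suitability, MSS, range
run_species <- function(config, stacks, world_current, label, niche_or_path,
                        areas) {
  seed_sp <- derive_seed(config$seed, "species", label)
  cur <- stacks[["current"]]

  if (inherits(niche_or_path, "niche_spec")) {
    truth <- true_suitability(world_current, niche_or_path, stack = cur)
    occ_raw <- sample_occurrences(truth, config$n_occurrences, seed_sp,
                                  config$uncertainty_range_km, species = label)
  } else {
    truth <- NULL
    occ_raw <- read_occurrences_csv(niche_or_path, species = label)
  }
  occ_filt <- filter_uncertainty(occ_raw, config$max_uncertainty_km)
  occ_thin <- thin_spatial(occ_filt, config$thin_km, seed = seed_sp)

  pres_cells <- unique(stats::na.omit(
    cell_index(cur$layers[[1]], occ_thin$records$lon, occ_thin$records$lat)$cell
  ))
  pres_cells <- intersect(pres_cells, valid_cells(cur))

  corr <- pearson_matrix(cur, max_cells = 4000L)
  pa0 <- sample_pseudo_absences(cur, pres_cells, repetition = 0L,
                                seed = seed_sp, n_pa_min = config$n_pa_min)
  imp <- jackknife_importance(cur, pres_cells, pa0,
                              seed = derive_seed(seed_sp, "jack"))
  retained <- select_predictors(corr, imp, config$corr_threshold)

  ens <- fit_ensemble(cur, pres_cells, retained,
                      algorithms = config$algorithms,
                      n_pa_reps = config$n_pa_reps,
                      n_cv_reps = config$n_cv_reps,
                      cv_fraction = config$cv_fraction,
                      tss_gate = config$tss_gate, auc_gate = config$auc_gate,
                      n_pa_min = config$n_pa_min, seed = seed_sp)
  pa_cells <- sort(unique(unlist(ens$pa_sets)))

  suit <- list(); ranges <- list(); mss <- numeric(0)
  for (sc in names(stacks)) {
    s_map <- ensemble_predict(ens, stacks[[sc]])
    sv <- as.vector(s_map$values)
    thr <- mss_threshold(sv[pres_cells], sv[pa_cells])
    suit[[sc]] <- s_map
    ranges[[sc]] <- binarize(s_map, thr)
    mss[sc] <- thr
  }

  dyn <- do.call(rbind, lapply(setdiff(names(stacks), "current"), function(sc) {
    range_dynamics(ranges[["current"]], ranges[[sc]], areas,
                   species = label, scenario = sc)
  }))

  list(species = label,
       n_raw = n_records(occ_raw), n_filtered = n_records(occ_filt),
       n_thinned = n_records(occ_thin), n_presence_cells = length(pres_cells),
       occurrences = occ_thin, presence_cells = pres_cells,
       truth = truth, correlation = corr, importance = imp,
       retained = retained, ensemble = ens, evaluation = ensemble_evaluation(ens),
       suitability = suit, ranges = ranges, mss = mss, dynamics = dyn)
}

#' Run the full range-dynamics pipeline
#'
#' Per species: occurrence sampling (or loading), uncertainty filtering and
#' spatial thinning, collinearity + jackknife predictor selection, the gated
#' ensemble fit, and suitability / MSS-binarized potential-range maps under
#' every scenario, with range-shift indices against the current baseline.
#' Across species: overlap indices of habitat suitability (OIHS) and
#' potential range (OIPR) per scenario, expanding-range overlaps,
#' future-minus-current change maps with the percentage of land area
#' increasing, hotspot masks, and a paired t-test of current vs future range
#' areas (when more than one species is configured). Rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param config a [run_config()]; must validate
#' @return a `run_report` list: `species` (per-species results),
#'   `range_dynamics`, `evaluation`, `mss_thresholds`, `retained`,
#'   `overlap` (per-scenario OIHS/OIPR maps and summaries), `t_tests`,
#'   `failed` (per-species failure records), `config`, `stacks`, `areas`
#' @export
run_pipeline <- function(config) {
  issues <- validate_config(config)
  if (length(issues)) {
    stop("invalid configuration:\n  - ", paste(issues, collapse = "\n  - "))
  }
  world <- generate_world(config$world)
  worlds <- c(list(current = world),
              stats::setNames(
                lapply(config$scenarios, function(d) apply_scenario(world, d)),
                vapply(config$scenarios, `[[`, "", "label")))
  stacks <- lapply(worlds, build_predictor_stack)
  areas <- cell_area_grid(world$dem)

  labels <- if (!is.null(names(config$species)) &&
                all(nzchar(names(config$species)))) {
    names(config$species)
  } else {
    vapply(seq_along(config$species), function(i) {
      sp <- config$species[[i]]
      if (inherits(sp, "niche_spec")) sp$species else paste0("species_", i)
    }, "")
  }

  species_results <- list(); failed <- list()
  for (i in seq_along(config$species)) {
    res <- tryCatch(
      run_species(config, stacks, world, labels[i], config$species[[i]], areas),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed[[labels[i]]] <- conditionMessage(res)
      message("species ", labels[i], " failed: ", conditionMessage(res))
    } else {
      species_results[[labels[i]]] <- res
    }
  }
  if (!length(species_results)) stop("all species failed")

  scen_names <- names(stacks)
  fut_names <- setdiff(scen_names, "current")
  oihs <- lapply(scen_names, function(sc) {
    overlap_suitability(lapply(species_results, function(r) r$suitability[[sc]]))
  })
  names(oihs) <- scen_names
  oipr <- lapply(scen_names, function(sc) {
    overlap_ranges(lapply(species_results, function(r) r$ranges[[sc]]))
  })
  names(oipr) <- scen_names
  exp_overlap <- lapply(fut_names, function(sc) {
    overlap_expanding(lapply(species_results, function(r) {
      expanding_range(r$ranges[["current"]], r$ranges[[sc]])
    }))
  })
  names(exp_overlap) <- fut_names

  overlap_summary <- do.call(rbind, lapply(fut_names, function(sc) {
    chg <- suitability_change(oihs[["current"]], oihs[[sc]])
    hs <- tryCatch(hotspot_mask(oihs[[sc]], areas, config$hotspot_quantile),
                   error = function(e) NULL)
    data.frame(
      scenario = sc,
      pct_land_increasing = fraction_area_increasing(chg, areas),
      hotspot_area_km2 = if (is.null(hs)) NA_real_ else range_area(hs, areas),
      hotspot_threshold = if (is.null(hs)) NA_real_ else attr(hs, "threshold"),
      stringsAsFactors = FALSE
    )
  }))

  dynamics <- do.call(rbind, lapply(species_results, `[[`, "dynamics"))
  rownames(dynamics) <- NULL
  evaluation <- do.call(rbind, lapply(species_results, function(r) {
    cbind(species = r$species, r$evaluation)
  }))
  rownames(evaluation) <- NULL
  mss_tab <- do.call(rbind, lapply(species_results, function(r) {
    data.frame(species = r$species, scenario = names(r$mss),
               mss_threshold = unname(r$mss), stringsAsFactors = FALSE)
  }))
  rownames(mss_tab) <- NULL

  t_tests <- NULL
  if (length(species_results) >= 2L) {
    t_tests <- do.call(rbind, lapply(fut_names, function(sc) {
      cur_a <- vapply(species_results,
                      function(r) range_area(r$ranges[["current"]], areas),
                      numeric(1))
      fut_a <- vapply(species_results,
                      function(r) range_area(r$ranges[[sc]], areas), numeric(1))
      tt <- tryCatch(paired_t_test(cur_a, fut_a), error = function(e) {
        list(t = NA_real_, df = NA_real_, p_value = NA_real_,
             mean_difference = mean(fut_a - cur_a))
      })
      data.frame(scenario = sc, t = tt$t, df = tt$df, p_value = tt$p_value,
                 mean_difference_km2 = tt$mean_difference,
                 stringsAsFactors = FALSE)
    }))
  }

  report <- list(species = species_results, failed = failed,
                 range_dynamics = dynamics, evaluation = evaluation,
                 mss_thresholds = mss_tab,
                 retained = lapply(species_results, `[[`, "retained"),
                 overlap = list(oihs = oihs, oipr = oipr,
                                expanding = exp_overlap,
                                summary = overlap_summary),
                 t_tests = t_tests, config = config,
                 stacks = stacks, areas = areas)
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d species x %d scenarios; %d failed species\n",
              length(x$species), length(x$stacks), length(x$failed)))
  if (nrow(x$range_dynamics)) {
    cat("range dynamics (RER / RSI):\n")
    print(x$range_dynamics[, c("species", "scenario", "rer", "rsi")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write pipeline artifacts to disk
#'
#' CSV tables always (`evaluation.csv`, `range_dynamics.csv`,
#' `mss_thresholds.csv`, `retained_predictors.csv`, `overlap_summary.csv`,
#' `t_tests.csv`, `occurrences_<species>.csv`); rasters as ESRI ASCII grids
#' when the configuration sets `write_rasters`.
#'
#' @param report a `run_report`
#' @param dir output directory (created if needed)
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) {
    utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  }
  wcsv(report$evaluation, "evaluation.csv")
  wcsv(report$range_dynamics, "range_dynamics.csv")
  wcsv(report$mss_thresholds, "mss_thresholds.csv")
  wcsv(data.frame(
    species = rep(names(report$retained), lengths(report$retained)),
    predictor = unlist(report$retained, use.names = FALSE)
  ), "retained_predictors.csv")
  wcsv(report$overlap$summary, "overlap_summary.csv")
  if (!is.null(report$t_tests)) wcsv(report$t_tests, "t_tests.csv")
  for (r in report$species) {
    write_occurrences_csv(r$occurrences,
                          file.path(dir, paste0("occurrences_", r$species, ".csv")))
  }
  if (isTRUE(report$config$write_rasters)) {
    for (r in report$species) {
      for (sc in names(r$suitability)) {
        write_asc(r$suitability[[sc]],
                  file.path(dir, sprintf("suitability_%s_%s.asc", r$species, sc)))
        write_asc(r$ranges[[sc]],
                  file.path(dir, sprintf("range_%s_%s.asc", r$species, sc)))
      }
    }
    for (sc in names(report$overlap$oihs)) {
      write_asc(report$overlap$oihs[[sc]], file.path(dir, sprintf("oihs_%s.asc", sc)))
      write_asc(report$overlap$oipr[[sc]], file.path(dir, sprintf("oipr_%s.asc", sc)))
    }
    for (sc in names(report$overlap$expanding)) {
      write_asc(report$overlap$expanding[[sc]],
                file.path(dir, sprintf("expanding_overlap_%s.asc", sc)))
    }
  }
  invisible(dir)
}

#' Load a run configuration from YAML
#'
#' Reads the scalar thresholds, seeds, world parameters and scenario deltas
#' from a YAML file; synthetic species are specified as
#' `species: {name: {coefficients: {...}, intercept: x, quadratic: {...}}}`.
#'
#' @param path YAML file path
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  world <- do.call(world_config, y$world %||% list())
  scenarios <- if (is.null(y$scenarios)) default_scenarios() else {
    out <- lapply(names(y$scenarios), function(nm) {
      s <- y$scenarios[[nm]]
      scenario_delta(nm, dtemp = s$dtemp %||% 0,
                     prec_factor = s$prec_factor %||% 1)
    })
    stats::setNames(out, names(y$scenarios))
  }
  species <- if (is.null(y$species)) default_niches() else {
    lapply(names(y$species), function(nm) {
      s <- y$species[[nm]]
      if (!is.null(s$csv)) return(s$csv)
      niche_spec(nm, coefficients = unlist(s$coefficients),
                 intercept = s$intercept %||% 0,
                 quadratic = if (is.null(s$quadratic)) NULL else unlist(s$quadratic))
    })
  }
  extra <- y[setdiff(names(y), c("world", "scenarios", "species"))]
  do.call(run_config, c(list(world = world, scenarios = scenarios,
                             species = species), extra))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
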