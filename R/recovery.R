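#' Niche-recovery trial on a synthetic world
#'
#' The package's core self-check: build a virtual landscape, sample
#' occurrences from a known logistic niche, hold out a fraction of the
#' presence cells, run the full modelling path (cleaning, thinning,
#' collinearity + jackknife predictor selection, gated ensemble) on the
#' rest, and measure how well the ensemble recovers the truth:
#' \itemize{
#'   \item `auc_holdout` — rank AUC of the ensemble map at the held-out
#'     presence cells against a random background sample;
#'   \item `spearman_truth` — Spearman correlation between predicted and true
#'     suitability over all valid land cells.
#' }
#'
#' @param seed integer seed driving the world, the occurrences and the model
#' @param world a [world_config()] (its seed is overridden by `seed`)
#' @param niche a [niche_spec()]; default: the first [default_niches()]
#'   species
#' @param n_occurrences occurrence records sampled (default 600)
#' @param holdout fraction of presence cells held out (default 0.3)
#' @param n_background background cells scored against the held-out
#'   presences (default 1000)
#' @param n_pa_reps,n_cv_reps ensemble repetition counts (default 5 each)
#' @param select_predictors run the collinearity/jackknife selection
#'   (default TRUE); FALSE fits on the niche's own predictors plus elevation
#' @return list with `auc_holdout`, `spearman_truth`, `retained`,
#'   `n_presence_cells`, `n_included`, plus the fitted `ensemble`, the
#'   `stack`, `truth` map, `suitability` map and the held-out cells
#' @export
recovery_trial <- function(seed, world = world_config(seed = seed),
                           niche = default_niches()[[1]],
                           n_occurrences = 600L, holdout = 0.3,
                           n_background = 1000L,
                           n_pa_reps = 5L, n_cv_reps = 5L,
                           select_predictors = TRUE) {
  world$seed <- as.integer(seed)
  w <- generate_world(world)
  st <- build_predictor_stack(w)
  truth <- true_suitability(w, niche, stack = st)

  occ <- sample_occurrences(truth, n_occurrences, derive_seed(seed, "occ"))
  occ <- thin_spatial(filter_uncertainty(occ), 5,
                      seed = derive_seed(seed, "thin"))
  cells <- intersect(
    unique(stats::na.omit(
      cell_index(truth, occ$records$lon, occ$records$lat)$cell)),
    valid_cells(st)
  )

  held <- with_seed(derive_seed(seed, "holdout"), {
    sort(sample(cells, max(1L, round(holdout * length(cells)))))
  })
  train <- setdiff(cells, held)

  if (select_predictors) {
    corr <- pearson_matrix(st, max_cells = 4000L)
    pa0 <- sample_pseudo_absences(st, train, repetition = 0L, seed = seed)
    imp <- jackknife_importance(st, train, pa0,
                                seed = derive_seed(seed, "jack"))
    retained <- select_predictors(corr, imp)
  } else {
    retained <- union(names(niche$coefficients), names(niche$quadratic))
    retained <- union(retained, "elevation")
  }

  ens <- fit_ensemble(st, train, retained, n_pa_reps = n_pa_reps,
                      n_cv_reps = n_cv_reps, seed = seed)
  pred <- ensemble_predict(ens, st)

  bg <- with_seed(derive_seed(seed, "bg"), {
    sample(setdiff(valid_cells(st), cells), n_background)
  })
  sv <- as.vector(pred$values)
  ok <- !is.na(pred$values) & !is.na(truth$values)
  list(
    auc_holdout = auc_rank(sv[held], sv[bg]),
    spearman_truth = stats::cor(pred$values[ok], truth$values[ok],
                                method = "spearman"),
    retained = retained,
    n_presence_cells = length(cells),
    n_included = sum(vapply(ens$members, `[[`, logical(1), "included")),
    ensemble = ens, stack = st, world = w, truth = truth,
    suitability = pred, held_cells = held, train_cells = train,
    background_cells = bg
  )
}

#' Directional scenario-recovery trial
#'
#' Continues a [recovery_trial()] under a uniform warming delta: predicts
#' suitability on the perturbed world, binarizes both scenarios at their own
#' maximum sensitivity-specificity thresholds, and measures whether the
#' pipeline reproduces the qualitative signature of a poleward niche shift —
#' a range expansion ratio above 1 for a niche whose suitable band widens
#' poleward, an expanding range concentrated poleward of the current range,
#' and a poleward centroid-shift bearing.
#'
#' @param seed integer seed
#' @param dtemp uniform warming (deg C, default +2)
#' @param prec_factor precipitation factor of the scenario (default 1)
#' @param ... passed to [recovery_trial()]
#' @return list with `rer`, `rsi`, `bearing_deg`, `centroid_shift_km`,
#'   `poleward_bearing` (TRUE iff the shift points into the northern
#'   half-plane), `expanding_poleward` (TRUE iff the area-weighted mean
#'   latitude of the expanding range exceeds that of the current range),
#'   `dynamics` (the [range_dynamics()] row) and the underlying trial
#' @export
scenario_recovery_trial <- function(seed, dtemp = 2, prec_factor = 1, ...) {
  trial <- recovery_trial(seed, ...)
  delta <- scenario_delta("warmed", dtemp = dtemp, prec_factor = prec_factor)
  w_fut <- apply_scenario(trial$world, delta)
  st_fut <- build_predictor_stack(w_fut)
  pred_fut <- ensemble_predict(trial$ensemble, st_fut)

  pa_cells <- sort(unique(unlist(trial$ensemble$pa_sets)))
  pres <- trial$train_cells
  thr_cur <- mss_threshold(as.vector(trial$suitability$values)[pres],
                           as.vector(trial$suitability$values)[pa_cells])
  thr_fut <- mss_threshold(as.vector(pred_fut$values)[pres],
                           as.vector(pred_fut$values)[pa_cells])
  cur_range <- binarize(trial$suitability, thr_cur)
  fut_range <- binarize(pred_fut, thr_fut)

  areas <- cell_area_grid(trial$truth)
  dyn <- range_dynamics(cur_range, fut_range, areas,
                        species = "virtual", scenario = "warmed")
  expand <- expanding_range(cur_range, fut_range)

  mean_lat <- function(rng) {
    cells <- which(rng$values == 1)
    if (!length(cells)) return(NA_real_)
    ny <- nrow(rng$values)
    lat <- grid_lat(rng)[(cells - 1L) %% ny + 1L]
    stats::weighted.mean(lat, areas$values[cells])
  }
  bearing <- dyn$bearing_deg
  list(
    rer = dyn$rer, rsi = dyn$rsi,
    bearing_deg = bearing, centroid_shift_km = dyn$centroid_shift_km,
    poleward_bearing = cos(bearing * pi / 180) > 0,
    expanding_poleward = isTRUE(mean_lat(expand) > mean_lat(cur_range)),
    mss_current = thr_cur, mss_future = thr_fut,
    dynamics = dyn, current_range = cur_range, future_range = fut_range,
    trial = trial
  )
}
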