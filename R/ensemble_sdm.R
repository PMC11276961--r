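#' Rank-based AUC
#'
#' Mann-Whitney AUC: the probability that a presence score outranks an
#' absence score, with ties counted 0.5.
#'
#' @param scores_presence,scores_absence numeric score vectors (non-empty)
#' @return AUC in `[0, 1]`
#' @export
auc_rank <- function(scores_presence, scores_absence) {
  np <- length(scores_presence); na <- length(scores_absence)
  stopifnot(np > 0L, na > 0L)
  r <- rank(c(scores_presence, scores_absence))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Sensitivity, specificity and TSS at a threshold
#'
#' Presences scoring at or above the threshold count as detected
#' (sensitivity); absences scoring below it count as rejected (specificity);
#' TSS = sensitivity + specificity - 1.
#'
#' @param scores_presence,scores_absence numeric score vectors
#' @param threshold classification threshold in `[0, 1]`
#' @return list with `sensitivity`, `specificity`, `tss`, `threshold`, `auc`
#' @export
tss_at_threshold <- function(scores_presence, scores_absence, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  sens <- mean(scores_presence >= threshold)
  spec <- mean(scores_absence < threshold)
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1,
       threshold = threshold,
       auc = auc_rank(scores_presence, scores_absence))
}

#' Sample pseudo-absences for one repetition
#'
#' Pseudo-absences are drawn uniformly, without replacement, from cells that
#' are valid in every required predictor layer and hold no presence. The
#' number drawn is `max(1000, n presences)` (the study rule: 1000 background
#' points for species with fewer than 1000 records, otherwise as many as
#' there are records). Each repetition uses its own derived seed, so the
#' standard five repetitions give five independently seeded sets.
#'
#' @param stack a `predictor_stack`
#' @param presence_cells linear cell indices of the presences
#' @param repetition repetition id (integer, used in seed derivation)
#' @param seed base integer seed
#' @param predictors predictor layers that must be valid (default all)
#' @param n_pa_min minimum pseudo-absence count (default 1000)
#' @return integer vector of pseudo-absence cell indices
#' @export
sample_pseudo_absences <- function(stack, presence_cells, repetition = 1L,
                                   seed = 1L,
                                   predictors = names(stack$layers),
                                   n_pa_min = 1000L) {
  n_pa <- max(n_pa_min, length(presence_cells))
  candidates <- setdiff(valid_cells(stack, predictors), presence_cells)
  if (length(candidates) < n_pa) {
    stop("fewer candidate cells (", length(candidates),
         ") than pseudo-absences requested (", n_pa, ")")
  }
  with_seed(derive_seed(seed, "pa", repetition), {
    sort(sample(candidates, n_pa))
  })
}

#' Stratified 70/30 split of a training set
#'
#' Presences and pseudo-absences are split independently so both classes
#' appear in both parts (classes are split at their own `fraction`).
#'
#' @param presence_cells,absence_cells cell index vectors
#' @param fraction calibration fraction (default 0.7)
#' @param repetition repetition id (used in seed derivation)
#' @param seed base integer seed
#' @return list with `train` and `test`, each holding `presence` and
#'   `absence` cell vectors; the two parts partition the input
#' @export
split_cv <- function(presence_cells, absence_cells, fraction = 0.7,
                     repetition = 1L, seed = 1L) {
  if (length(presence_cells) + length(absence_cells) < 10L) {
    stop("need at least 10 records to split")
  }
  with_seed(derive_seed(seed, "cv", repetition), {
    take <- function(cells) {
      n_tr <- round(fraction * length(cells))
      n_tr <- min(max(n_tr, 1L), length(cells) - 1L)
      idx <- sample(length(cells), n_tr)
      list(train = cells[sort(idx)], test = cells[sort(setdiff(seq_along(cells), idx))])
    }
    p <- take(presence_cells); a <- take(absence_cells)
    list(train = list(presence = p$train, absence = a$train),
         test = list(presence = p$test, absence = a$test))
  })
}

#' Fit one SDM algorithm
#'
#' Native roster: `"sre"` (surface range envelope — the strict BIOCLIM box
#' spanned by the training presences), `"glm"` (ridge-penalised logistic
#' regression), `"rf"` (random forest, probability votes) and `"xgb"`
#' (gradient-boosted trees, logistic objective). All fitted models predict
#' scores in `[0, 1]` via [predict_sdm()].
#'
#' @param algorithm one of `"sre"`, `"glm"`, `"rf"`, `"xgb"`
#' @param x_presence,x_absence predictor matrices (rows = records)
#' @param seed integer seed (stochastic learners)
#' @return an `sdm_fit` (or a fit with `failed = TRUE` if the algorithm
#'   errored, which downstream gating excludes)
#' @export
fit_algorithm <- function(algorithm = c("sre", "glm", "rf", "xgb"),
                          x_presence, x_absence, seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- rbind(x_presence, x_absence)
  y <- c(rep(1L, nrow(x_presence)), rep(0L, nrow(x_absence)))
  fit <- tryCatch(switch(
    algorithm,
    sre = list(lo = apply(x_presence, 2L, min), hi = apply(x_presence, 2L, max)),
    glm = {
      # linear + quadratic terms, as ensemble-platform GLMs conventionally use
      xx <- cbind(x, `colnames<-`(x^2, paste0(colnames(x), "_sq")))
      glmnet::glmnet(xx, y, family = "binomial", alpha = 0, lambda = 0.01,
                     standardize = TRUE)
    },
    rf = with_seed(derive_seed(seed, "rf"), {
      randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                 ntree = 150L)
    }),
    xgb = with_seed(derive_seed(seed, "xgb"), {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.1, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = 60L, verbose = 0
      )
    })
  ), error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(algorithm = algorithm, failed = TRUE,
                          message = conditionMessage(fit)),
                     class = "sdm_fit"))
  }
  structure(list(algorithm = algorithm, model = fit, failed = FALSE,
                 predictors = colnames(x)),
            class = "sdm_fit")
}

#' Predict suitability scores from a fitted SDM
#' @param fit an `sdm_fit`
#' @param x predictor matrix with the fit's predictor columns
#' @return scores in `[0, 1]`
#' @export
predict_sdm <- function(fit, x) {
  if (isTRUE(fit$failed)) stop("cannot predict from a failed fit")
  x <- x[, fit$predictors[fit$predictors != "pad_zero"], drop = FALSE]
  out <- switch(
    fit$algorithm,
    sre = {
      inside <- rep(TRUE, nrow(x))
      for (j in seq_len(ncol(x))) {
        inside <- inside & x[, j] >= fit$model$lo[j] & x[, j] <= fit$model$hi[j]
      }
      as.numeric(inside)
    },
    glm = {
      xx <- cbind(x, `colnames<-`(x^2, paste0(colnames(x), "_sq")))
      as.numeric(stats::predict(fit$model, xx, type = "response"))
    },
    rf = as.numeric(stats::predict(fit$model, x, type = "prob")[, "1"]),
    xgb = as.numeric(stats::predict(fit$model,
                                    xgboost::xgb.DMatrix(x, nthread = 1)))
  )
  pmin(pmax(out, 0), 1)
}

#' Gate candidate models into an ensemble
#'
#' A candidate enters the ensemble iff its test TSS exceeds `tss_gate` OR its
#' test AUC exceeds `auc_gate`. Included members are weighted by TSS
#' (normalised to sum to 1; `weighting = "equal"` gives committee averaging),
#' excluded members get weight 0.
#'
#' @param members list of candidates, each a list with elements `fit` (an
#'   `sdm_fit`) and `metrics` (from [tss_at_threshold()])
#' @param tss_gate,auc_gate gate thresholds (defaults 0.6 / 0.8)
#' @param weighting `"tss"` (default) or `"equal"`
#' @return an `ensemble_model`: the members with `included` flags and
#'   `weight`s summing to 1 over included members
#' @export
gate_models <- function(members, tss_gate = 0.6, auc_gate = 0.8,
                        weighting = c("tss", "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(length(members) >= 1L)
  included <- vapply(members, function(m) {
    !isTRUE(m$fit$failed) &&
      (isTRUE(m$metrics$tss > tss_gate) || isTRUE(m$metrics$auc > auc_gate))
  }, logical(1))
  if (!any(included)) stop("ensemble empty: no candidate passed the gate")
  w <- rep(0, length(members))
  if (weighting == "tss") {
    raw <- vapply(members, function(m) m$metrics$tss, numeric(1))
    raw <- pmax(raw, 1e-6)   # AUC-gated members with tiny TSS keep tiny weight
    w[included] <- raw[included] / sum(raw[included])
  } else {
    w[included] <- 1 / sum(included)
  }
  for (i in seq_along(members)) {
    members[[i]]$included <- included[i]
    members[[i]]$weight <- w[i]
  }
  structure(list(members = members, tss_gate = tss_gate, auc_gate = auc_gate,
                 weighting = weighting),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  inc <- vapply(x$members, `[[`, logical(1), "included")
  cat(sprintf("<ensemble_model> %d/%d members included (gates: TSS > %g or AUC > %g)\n",
              sum(inc), length(inc), x$tss_gate, x$auc_gate))
  invisible(x)
}

#' Evaluation table of an ensemble
#' @param ensemble an `ensemble_model`
#' @return data.frame: algorithm, pa_rep, cv_rep, auc, tss, sensitivity,
#'   specificity, threshold, included, weight
#' @export
ensemble_evaluation <- function(ensemble) {
  do.call(rbind, lapply(ensemble$members, function(m) {
    data.frame(algorithm = m$fit$algorithm,
               pa_rep = if (is.null(m$pa_rep)) NA_integer_ else m$pa_rep,
               cv_rep = if (is.null(m$cv_rep)) NA_integer_ else m$cv_rep,
               auc = m$metrics$auc, tss = m$metrics$tss,
               sensitivity = m$metrics$sensitivity,
               specificity = m$metrics$specificity,
               threshold = m$metrics$threshold,
               included = m$included, weight = m$weight,
               stringsAsFactors = FALSE)
  }))
}

#' Predict an ensemble suitability map
#'
#' Cell-wise weighted mean of the included members' scores over all cells
#' valid in every required predictor layer; nodata is propagated.
#'
#' @param ensemble an `ensemble_model` from [gate_models()]
#' @param stack a `predictor_stack` holding the fitted predictors
#' @return a [raster_grid()] suitability map in `[0, 1]`
#' @export
ensemble_predict <- function(ensemble, stack) {
  inc <- Filter(function(m) m$included, ensemble$members)
  if (!length(inc)) stop("ensemble empty")
  predictors <- inc[[1]]$fit$predictors
  predictors <- predictors[predictors != "pad_zero"]
  cells <- valid_cells(stack, predictors)
  x <- extract_cells(stack, cells, predictors)
  acc <- rep(0, length(cells))
  for (m in inc) acc <- acc + m$weight * predict_sdm(m$fit, x)
  tmpl <- stack$layers[[predictors[1]]]
  v <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
  v[cells] <- acc
  grid_like(tmpl, v)
}

#' Fit the full gated ensemble for one species
#'
#' Runs the study design end to end for one species on one (current)
#' predictor stack: for each of `n_pa_reps` pseudo-absence repetitions and
#' `n_cv_reps` stratified 70/30 splits, fits every algorithm in the roster on
#' the calibration part and evaluates it on the held-out part (TSS at the
#' held-out maximum sensitivity-specificity threshold, rank AUC). All
#' candidates then pass through the TSS/AUC gate.
#'
#' @param stack a `predictor_stack` (training scenario)
#' @param presence_cells linear cell indices of thinned presences
#' @param predictors retained predictor names
#' @param algorithms roster subset of `c("sre","glm","rf","xgb")`
#' @param n_pa_reps,n_cv_reps repetition counts (study default 5 each)
#' @param cv_fraction calibration fraction (default 0.7)
#' @param tss_gate,auc_gate gate thresholds
#' @param n_pa_min minimum pseudo-absence count (default 1000)
#' @param seed base integer seed
#' @return an `ensemble_model`; each member records its `pa_rep` and `cv_rep`
#' @export
fit_ensemble <- function(stack, presence_cells, predictors,
                         algorithms = c("sre", "glm", "rf", "xgb"),
                         n_pa_reps = 5L, n_cv_reps = 5L, cv_fraction = 0.7,
                         tss_gate = 0.6, auc_gate = 0.8, n_pa_min = 1000L,
                         seed = 1L) {
  ok <- valid_cells(stack, predictors)
  dropped <- setdiff(presence_cells, ok)
  if (length(dropped)) {
    message(length(dropped), " presence cell(s) on nodata dropped")
    presence_cells <- intersect(presence_cells, ok)
  }
  members <- list()
  pa_sets <- list()
  for (pa_rep in seq_len(n_pa_reps)) {
    absence_cells <- sample_pseudo_absences(stack, presence_cells, pa_rep,
                                            seed, predictors, n_pa_min)
    pa_sets[[pa_rep]] <- absence_cells
    for (cv_rep in seq_len(n_cv_reps)) {
      sp <- split_cv(presence_cells, absence_cells, cv_fraction,
                     repetition = (pa_rep - 1L) * n_cv_reps + cv_rep,
                     seed = seed)
      xtr_p <- extract_cells(stack, sp$train$presence, predictors)
      xtr_a <- extract_cells(stack, sp$train$absence, predictors)
      xte_p <- extract_cells(stack, sp$test$presence, predictors)
      xte_a <- extract_cells(stack, sp$test$absence, predictors)
      for (alg in algorithms) {
        fit <- fit_algorithm(alg, xtr_p, xtr_a,
                             seed = derive_seed(seed, alg, pa_rep, cv_rep))
        if (isTRUE(fit$failed)) {
          metrics <- list(sensitivity = NA_real_, specificity = NA_real_,
                          tss = -1, threshold = NA_real_, auc = 0)
        } else {
          s_p <- predict_sdm(fit, xte_p)
          s_a <- predict_sdm(fit, xte_a)
          thr <- tryCatch(mss_threshold(s_p, s_a), error = function(e) 0.5)
          metrics <- tss_at_threshold(s_p, s_a, thr)
        }
        members[[length(members) + 1L]] <-
          list(fit = fit, metrics = metrics, pa_rep = pa_rep, cv_rep = cv_rep)
      }
    }
  }
  ens <- gate_models(members, tss_gate, auc_gate)
  ens$pa_sets <- pa_sets
  ens$presence_cells <- presence_cells
  ens$predictors <- predictors
  ens
}
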