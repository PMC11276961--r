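#' Assemble the 30-predictor stack for one scenario
#'
#' 19 bioclim variables from the monthly climate cube, the 8 land-use
#' fractions, and elevation / slope / aspect from the DEM, all grid-aligned.
#'
#' @param world a `synthetic_world` (any scenario)
#' @param terrain logical; include elevation, slope, aspect
#' @return a `predictor_stack`: list with `scenario` and named `layers`
#' @export
build_predictor_stack <- function(world, terrain = TRUE) {
  layers <- compute_bioclim(world$climate)
  layers <- c(layers, world$landuse)
  if (terrain) {
    tr <- compute_terrain(world$dem)
    layers$elevation <- world$dem
    layers$slope <- tr$slope
    layers$aspect <- tr$aspect
  }
  if (anyDuplicated(names(layers))) stop("duplicate layer names in stack")
  g1 <- layers[[1]]
  for (nm in names(layers)) stop_if_misaligned(g1, layers[[nm]], nm)
  structure(list(scenario = world$scenario, layers = layers),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> scenario '%s': %d layers (%s ...)\n",
              x$scenario, length(x$layers),
              paste(utils::head(names(x$layers), 5), collapse = ", ")))
  invisible(x)
}

#' Linear (column-major) indices of cells valid in every layer
#' @param stack a `predictor_stack`
#' @param predictors layer names to require (default: all)
#' @export
valid_cells <- function(stack, predictors = names(stack$layers)) {
  ok <- !is.na(as.vector(stack$layers[[predictors[1]]]$values))
  for (p in predictors[-1]) ok <- ok & !is.na(as.vector(stack$layers[[p]]$values))
  which(ok)
}

#' Predictor values at given cells
#' @param stack a `predictor_stack`
#' @param cells linear cell indices (column-major)
#' @param predictors layer names (default: all)
#' @return numeric matrix, one row per cell, one column per predictor
#' @export
extract_cells <- function(stack, cells, predictors = names(stack$layers)) {
  missing <- setdiff(predictors, names(stack$layers))
  if (length(missing)) {
    stop("missing predictor layer(s): ", paste(missing, collapse = ", "))
  }
  out <- vapply(predictors, function(p) as.vector(stack$layers[[p]]$values)[cells],
                numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, predictors))
  out
}

#' Pairwise Pearson correlations between predictors
#'
#' Correlations are computed over a set of cells (by default all cells valid
#' in every layer, optionally subsampled). Zero-variance predictors yield
#' undefined correlations; these are set to 0 with a warning so that the
#' collinearity screen never drops a constant layer's partner on undefined
#' evidence.
#'
#' @param stack a `predictor_stack`
#' @param cells cell indices to use (default all valid cells)
#' @param predictors layer names (default all)
#' @param max_cells optional cap; a deterministic regular subsample is taken
#'   above it
#' @return symmetric correlation matrix with unit diagonal
#' @export
pearson_matrix <- function(stack, cells = NULL,
                           predictors = names(stack$layers),
                           max_cells = 10000L) {
  if (is.null(cells)) cells <- valid_cells(stack, predictors)
  if (length(cells) < 3L) stop("need at least 3 cells")
  if (length(predictors) < 2L) stop("need at least 2 predictors")
  if (length(cells) > max_cells) {
    cells <- cells[round(seq(1, length(cells), length.out = max_cells))]
  }
  x <- extract_cells(stack, cells, predictors)
  sds <- apply(x, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    warning("zero-variance predictor(s): ",
            paste(predictors[sds == 0], collapse = ", "),
            "; their correlations are undefined and treated as 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  r[!is.finite(r)] <- 0
  r
}

# cross-validated AUC of a ridge-penalised logistic model with linear +
# quadratic terms per predictor (so unimodal niche responses are
# representable); folds fixed by the caller so every leave-one-predictor-out
# run sees the same partition
cv_auc_ridge <- function(x, y, folds, lambda = 0.01) {
  x <- cbind(x, `colnames<-`(x^2, paste0(colnames(x), "_sq")))
  if (ncol(x) == 1L) x <- cbind(x, pad_zero = 0)  # glmnet needs >= 2 columns
  scores <- rep(NA_real_, length(y))
  for (k in unique(folds)) {
    tr <- folds != k
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 0, lambda = lambda, standardize = TRUE)
    scores[!tr] <- as.numeric(stats::predict(fit, x[!tr, , drop = FALSE],
                                             type = "response"))
  }
  auc_rank(scores[y == 1], scores[y == 0])
}

#' Jackknife predictor importance
#'
#' Importance of each predictor as the drop in cross-validated AUC when that
#' predictor is left out of a fast preliminary model (a ridge-penalised
#' logistic regression with linear and quadratic terms, so unimodal niche
#' responses register), floored at zero. The cross-validation folds are fixed
#' across all leave-one-out runs so differences reflect the predictor, not
#' the partition.
#'
#' @param stack a `predictor_stack`
#' @param presence_cells linear cell indices of presences
#' @param absence_cells linear cell indices of pseudo-absences
#' @param predictors candidate predictor names (default all layers)
#' @param n_folds number of CV folds (default 4)
#' @param seed integer seed fixing the fold assignment
#' @return data.frame with columns `predictor`, `importance` (>= 0), and
#'   `full_auc` attribute
#' @export
jackknife_importance <- function(stack, presence_cells, absence_cells,
                                 predictors = names(stack$layers),
                                 n_folds = 4L, seed = 1L) {
  if (length(presence_cells) < 10L) stop("need at least 10 presences")
  if (length(presence_cells) < n_folds || length(absence_cells) < n_folds) {
    stop("fewer records than folds")
  }
  x <- rbind(extract_cells(stack, presence_cells, predictors),
             extract_cells(stack, absence_cells, predictors))
  y <- c(rep(1L, length(presence_cells)), rep(0L, length(absence_cells)))
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  folds <- with_seed(seed, {
    f <- integer(length(y))
    f[y == 1] <- sample(rep_len(seq_len(n_folds), sum(y == 1)))
    f[y == 0] <- sample(rep_len(seq_len(n_folds), sum(y == 0)))
    f
  })
  full <- cv_auc_ridge(x, y, folds)
  imp <- vapply(seq_along(predictors), function(j) {
    if (length(predictors) == 1L) return(max(full - 0.5, 0))
    loo <- cv_auc_ridge(x[, -j, drop = FALSE], y, folds)
    max(full - loo, 0)
  }, numeric(1))
  out <- data.frame(predictor = predictors, importance = imp,
                    stringsAsFactors = FALSE)
  attr(out, "full_auc") <- full
  out
}

# exact maximum-total-importance subset with no |r| > threshold pair, within
# one connected component of the conflict graph: branch-and-bound search over
# independent sets; ties broken toward the larger, then lexicographically
# first subset, so the result is deterministic and order-invariant
best_subset_component <- function(nodes, conflict, importance) {
  w <- importance
  best_val <- -Inf; best_set <- character(0)
  consider <- function(set, val) {
    better <- val > best_val + 1e-12
    tie <- !better && abs(val - best_val) <= 1e-12 &&
      (length(set) > length(best_set) ||
         (length(set) == length(best_set) &&
            paste(sort(set), collapse = "|") <
              paste(sort(best_set), collapse = "|")))
    if (better || tie) {
      best_val <<- val
      best_set <<- set
    }
  }
  rec <- function(cand, set, val) {
    consider(set, val)
    if (!length(cand)) return(invisible(NULL))
    if (val + sum(w[cand]) < best_val - 1e-12) return(invisible(NULL))
    v <- cand[1]; rest <- cand[-1]
    rec(rest[!conflict[v, rest]], c(set, v), val + w[[v]])
    rec(rest, set, val)
  }
  ord <- nodes[order(-w[nodes], nodes)]
  rec(ord, character(0), 0)
  best_set
}

#' Resolve collinearity by importance
#'
#' Retains a subset of predictors such that no retained pair has
#' `|r| > threshold`, preferring predictors with higher jackknife importance.
#' Within each connected component of the conflict graph the retained subset
#' is the exact maximum-total-importance conflict-free subset (components are
#' enumerated exhaustively up to `exact_limit` members; larger components
#' fall back to a greedy that repeatedly drops the lower-importance member of
#' the strongest remaining conflict, with a warning). The result is
#' deterministic and invariant to the input ordering of predictors.
#'
#' @param corr symmetric correlation matrix with predictor dimnames
#' @param importance data.frame (`predictor`, `importance`) or named vector
#' @param threshold collinearity threshold on `|r|` (default 0.7)
#' @param exact_limit largest conflict component solved exhaustively
#' @return character vector of retained predictor names, in the order of
#'   `sort(colnames(corr))`
#' @export
select_predictors <- function(corr, importance, threshold = 0.7,
                              exact_limit = 22L) {
  if (is.data.frame(importance)) {
    imp <- stats::setNames(importance$importance, importance$predictor)
  } else {
    imp <- importance
  }
  preds <- sort(colnames(corr))
  if (!setequal(preds, names(imp))) {
    stop("correlation matrix and importance table cover different predictors")
  }
  corr <- corr[preds, preds]
  imp <- imp[preds]
  conflict <- abs(corr) > threshold
  diag(conflict) <- FALSE

  # connected components of the conflict graph
  comp <- stats::setNames(rep(NA_integer_, length(preds)), preds)
  cid <- 0L
  for (p in preds) {
    if (!is.na(comp[p])) next
    cid <- cid + 1L
    queue <- p
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[q])) next
      comp[q] <- cid
      queue <- c(queue, preds[conflict[q, ] & is.na(comp)])
    }
  }

  retained <- character(0)
  for (k in unique(comp)) {
    nodes <- preds[comp == k]
    if (length(nodes) == 1L) {
      retained <- c(retained, nodes)
    } else if (length(nodes) <= exact_limit) {
      retained <- c(retained, best_subset_component(nodes, conflict, imp))
    } else {
      warning("conflict component with ", length(nodes),
              " predictors: using greedy resolution")
      keep <- nodes
      repeat {
        sub <- abs(corr[keep, keep, drop = FALSE])
        diag(sub) <- 0
        if (max(sub) <= threshold) break
        ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
        pair <- keep[ij]
        drop <- pair[which.min(imp[pair])]
        keep <- setdiff(keep, drop)
      }
      retained <- c(retained, keep)
    }
  }
  sort(retained)
}

#' Write a correlation matrix or importance table to CSV
#' @param x matrix or data.frame
#' @param path output path
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path,
                   row.names = is.matrix(x))
  invisible(path)
}
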