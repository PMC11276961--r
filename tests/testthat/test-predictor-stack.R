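test_that("the stack holds 30 aligned, uniquely named layers", {
  st <- cached_stack(1)
  expect_length(st$layers, 30L)
  expect_setequal(
    names(st$layers),
    c(paste0("BIO", 1:19), "urban", "crop", "range", "secdn", "primn",
      "primf", "secdf", "pastr", "elevation", "slope", "aspect")
  )
  expect_false(anyDuplicated(names(st$layers)) > 0)
})

test_that("pearson matrix matches the textbook formula and flags constants", {
  st <- cached_stack(1)
  r <- pearson_matrix(st, max_cells = 500)
  expect_equal(diag(r), rep(1, 30), ignore_attr = TRUE)
  expect_equal(r, t(r))
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))

  # direct-formula oracle on a random table routed through a handmade stack
  set.seed(8)
  x <- matrix(rnorm(20), 5, 4)
  layers <- lapply(1:4, function(j) raster_grid(matrix(x[, j], 5, 1), 0, 0, 1))
  names(layers) <- paste0("p", 1:4)
  hand <- structure(list(scenario = "current", layers = layers),
                    class = "predictor_stack")
  r2 <- pearson_matrix(hand, cells = 1:5)
  oracle <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:4) for (j in 1:4) {
    expect_equal(r2[i, j], oracle(x[, i], x[, j]), tolerance = 1e-12)
  }
  # y = -x gives exactly -1
  layers$p5 <- raster_grid(matrix(-x[, 1], 5, 1), 0, 0, 1)
  hand$layers <- layers
  expect_equal(pearson_matrix(hand, cells = 1:5)["p1", "p5"], -1)
  # zero-variance predictor: warned and zeroed
  layers$p6 <- raster_grid(matrix(2, 5, 1), 0, 0, 1)
  hand$layers <- layers
  expect_warning(r3 <- pearson_matrix(hand, cells = 1:5), "zero-variance")
  expect_true(all(r3["p6", colnames(r3) != "p6"] == 0))
})

test_that("jackknife importance recovers a single-predictor truth", {
  # candidate set without near-duplicates of the driver, so the
  # leave-one-out drop is attributable
  cand <- c("BIO1", "BIO12", "BIO15", "urban", "slope")
  wins <- 0L
  for (s in 1:3) {
    w <- cached_world(s); st <- cached_stack(s)
    niche <- niche_spec("b1", c(BIO1 = 2 * 1.5 * 16), intercept = 4 - 1.5 * 256,
                        quadratic = c(BIO1 = -1.5))
    truth <- true_suitability(w, niche, stack = st)
    occ <- sample_occurrences(truth, 300, seed = 50 + s)
    cells <- intersect(
      unique(stats::na.omit(cell_index(truth, occ$records$lon,
                                       occ$records$lat)$cell)),
      valid_cells(st)
    )
    pa <- sample_pseudo_absences(st, cells, 1, 60 + s, cand, n_pa_min = 400)
    imp <- jackknife_importance(st, cells, pa, predictors = cand, seed = s)
    if (imp$predictor[which.max(imp$importance)] == "BIO1") wins <- wins + 1L
    # appended pure-noise predictor stays unimportant
    st2 <- st
    st2$layers$noise <- grid_like(st$layers$BIO1,
                                  with_seed_test(70 + s, matrix(
                                    rnorm(length(st$layers$BIO1$values)),
                                    nrow(st$layers$BIO1$values))))
    imp2 <- jackknife_importance(st2, cells, pa,
                                 predictors = c(cand, "noise"), seed = s)
    top <- max(imp2$importance)
    expect_lt(imp2$importance[imp2$predictor == "noise"], 0.1 * top)
  }
  expect_gte(wins, 2L)  # majority over seeds
})

test_that("duplicated predictors share redundancy: each alone is droppable", {
  st <- cached_stack(1)
  st$layers$BIO1copy <- st$layers$BIO1
  niche <- niche_spec("b1", c(BIO1 = 48), intercept = -380,
                      quadratic = c(BIO1 = -1.5))
  truth <- true_suitability(cached_world(1), niche,
                            stack = cached_stack(1))
  occ <- sample_occurrences(truth, 300, seed = 5)
  cells <- intersect(
    unique(stats::na.omit(cell_index(truth, occ$records$lon,
                                     occ$records$lat)$cell)),
    valid_cells(st)
  )
  cand <- c("BIO1", "BIO1copy", "BIO12", "urban")
  pa <- sample_pseudo_absences(st, cells, 1, 2, cand, n_pa_min = 400)
  imp <- jackknife_importance(st, cells, pa, predictors = cand, seed = 3)
  i1 <- imp$importance[imp$predictor == "BIO1"]
  i2 <- imp$importance[imp$predictor == "BIO1copy"]
  expect_lt(i1, 0.01)
  expect_lt(i2, 0.01)
})

test_that("selection drops the lower-importance member of each conflict", {
  mk_corr <- function(m, nms) {
    dimnames(m) <- list(nms, nms)
    m
  }
  # all below threshold: identity
  r <- mk_corr(diag(3) * 0.5 + 0.5 * diag(3), c("a", "b", "c"))
  diag(r) <- 1
  imp <- c(a = 1, b = 2, c = 3)
  expect_setequal(select_predictors(r, imp), c("a", "b", "c"))

  # perfectly correlated pair: higher importance retained
  r2 <- mk_corr(matrix(c(1, 1, 1, 1), 2), c("x", "y"))
  expect_equal(select_predictors(r2, c(x = 0.5, y = 0.1)), "x")

  # chain a~b (.9), b~c (.9), a~c (.1), importances a > c > b: {a, c}
  r3 <- mk_corr(matrix(c(1, .9, .1, .9, 1, .9, .1, .9, 1), 3),
                c("a", "b", "c"))
  imp3 <- c(a = 0.5, b = 0.2, c = 0.3)
  sel <- select_predictors(r3, imp3)
  expect_equal(sel, c("a", "c"))
  expect_equal(sel, selection_oracle(r3, imp3))
})

test_that("selection equals the exhaustive oracle and is order-invariant", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    nms <- letters[1:n]
    r <- diag(n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r[i, j] <- r[j, i] <- runif(1, -1, 1)
    }
    dimnames(r) <- list(nms, nms)
    imp <- stats::setNames(runif(n), nms)
    sel <- select_predictors(r, imp)
    # constraint always satisfied
    if (length(sel) > 1) {
      sub <- abs(r[sel, sel]); diag(sub) <- 0
      expect_lte(max(sub), 0.7)
    }
    expect_equal(sel, selection_oracle(r, imp))
    # invariant to predictor ordering
    perm <- sample(n)
    expect_equal(select_predictors(r[perm, perm], imp[perm]), sel)
  }
})
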