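test_that("rank AUC equals exhaustive pair counting", {
  expect_equal(auc_rank(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(auc_rank(rep(0.4, 5), rep(0.4, 7)), 0.5)
  # spelled-out case: 3 wins, 0 ties over 4 pairs
  expect_equal(auc_rank(c(0.8, 0.4), c(0.6, 0.2)), 0.75)
  pair_oracle <- function(p, a) {
    wins <- 0
    for (x in p) for (y in a) wins <- wins + (x > y) + 0.5 * (x == y)
    wins / (length(p) * length(a))
  }
  set.seed(2)
  for (rep in 1:25) {
    p <- round(runif(sample(2:12, 1)), 2)  # rounding forces some ties
    a <- round(runif(sample(2:12, 1)), 2)
    expect_equal(auc_rank(p, a), pair_oracle(p, a), tolerance = 1e-12)
  }
})

test_that("TSS is sensitivity + specificity - 1 at the stated threshold", {
  m <- tss_at_threshold(c(0.9, 0.8), c(0.1, 0.2), 0.5)
  expect_equal(m$tss, 1)
  m2 <- tss_at_threshold(c(rep(1, 9), 0), c(rep(0, 8), 1, 1), 0.5)
  expect_equal(m2$sensitivity, 0.9)
  expect_equal(m2$specificity, 0.8)
  expect_equal(m2$tss, 0.7, tolerance = 1e-12)
  # max over a sweep equals the brute-force maximum
  set.seed(3)
  for (rep in 1:10) {
    p <- runif(20); a <- runif(30)
    cand <- seq(0, 1, by = 0.001)
    brute <- max(vapply(cand, function(t) {
      mean(p >= t) + mean(a < t) - 1
    }, numeric(1)))
    best <- max(vapply(cand, function(t) tss_at_threshold(p, a, t)$tss,
                       numeric(1)))
    expect_equal(best, brute, tolerance = 1e-12)
  }
})

test_that("pseudo-absence counts follow the 1000-or-n rule, seeded", {
  st <- cached_stack(1)
  cells <- valid_cells(st)
  pres_small <- cells[1:100]
  pa <- sample_pseudo_absences(st, pres_small, 1, 7, n_pa_min = 300)
  expect_length(pa, 300L)              # n_occ < floor -> floor
  pa_big <- sample_pseudo_absences(st, cells[1:400], 1, 7, n_pa_min = 350)
  expect_length(pa_big, 400L)          # n_occ above floor -> n_occ
  expect_length(intersect(pa, pres_small), 0L)
  expect_identical(pa, sample_pseudo_absences(st, pres_small, 1, 7,
                                              n_pa_min = 300))
  # different repetitions draw different sets
  pa2 <- sample_pseudo_absences(st, pres_small, 2, 7, n_pa_min = 300)
  expect_false(identical(pa, pa2))
  expect_error(
    sample_pseudo_absences(st, cells[1:5], 1, 7, n_pa_min = length(cells)),
    "fewer candidate cells"
  )
})

test_that("the 70/30 split stratifies, partitions, and reproduces", {
  p <- 1:10; a <- 101:110
  sp <- split_cv(p, a, 0.7, 1, 3)
  expect_length(sp$train$presence, 7L)
  expect_length(sp$test$presence, 3L)
  expect_length(sp$train$absence, 7L)
  expect_setequal(c(sp$train$presence, sp$test$presence), p)
  expect_setequal(c(sp$train$absence, sp$test$absence), a)
  expect_length(intersect(sp$train$presence, sp$test$presence), 0L)
  expect_identical(sp, split_cv(p, a, 0.7, 1, 3))
  expect_error(split_cv(1:4, 5:8), "at least 10")
})

test_that("the envelope model is a strict BIOCLIM box", {
  xp <- cbind(BIO1 = c(5, 10, 15), BIO12 = c(100, 150, 200))
  xa <- cbind(BIO1 = c(30, 40), BIO12 = c(500, 600))
  f <- fit_algorithm("sre", xp, xa)
  expect_equal(predict_sdm(f, cbind(BIO1 = 10, BIO12 = 150)), 1)
  expect_equal(predict_sdm(f, cbind(BIO1 = 20, BIO12 = 150)), 0)
  expect_equal(predict_sdm(f, cbind(BIO1 = 15, BIO12 = 200)), 1)  # boundary in
})

test_that("all algorithms score linearly separable data perfectly in [0,1]", {
  set.seed(11)
  xp <- cbind(a = rnorm(40, 5), b = rnorm(40))
  xa <- cbind(a = rnorm(40, -5), b = rnorm(40))
  xt <- cbind(a = rnorm(30, c(5, -5)), b = rnorm(30))
  y <- rep(c(1, 0), 15)
  for (alg in c("sre", "glm", "rf", "xgb")) {
    f <- fit_algorithm(alg, xp, xa, seed = 4)
    expect_false(isTRUE(f$failed))
    s <- predict_sdm(f, xt)
    expect_true(all(s >= 0 & s <= 1))
    auc <- auc_rank(s[y == 1], s[y == 0])
    if (alg == "sre") {
      # the strict envelope can clip test presences outside the training box
      expect_gte(auc, 0.9)
    } else {
      expect_equal(auc, 1)
    }
  }
})

test_that("gating applies the TSS-or-AUC rule and normalizes weights", {
  mk <- function(tss, auc) {
    list(fit = structure(list(algorithm = "glm", failed = FALSE),
                         class = "sdm_fit"),
         metrics = list(tss = tss, auc = auc, sensitivity = NA,
                        specificity = NA, threshold = 0.5))
  }
  ens <- gate_models(list(mk(0.65, 0.75), mk(0.50, 0.85), mk(0.50, 0.70)))
  inc <- vapply(ens$members, `[[`, logical(1), "included")
  expect_equal(inc, c(TRUE, TRUE, FALSE))   # OR rule; both branches count
  w <- vapply(ens$members, `[[`, numeric(1), "weight")
  expect_equal(sum(w), 1)
  expect_equal(w[3], 0)
  expect_gt(w[1], w[2])  # TSS-weighted
  # equal weighting alternative
  ens_eq <- gate_models(list(mk(0.65, 0.75), mk(0.50, 0.85)),
                        weighting = "equal")
  expect_equal(vapply(ens_eq$members, `[[`, numeric(1), "weight"),
               c(0.5, 0.5))
  expect_error(gate_models(list(mk(0.1, 0.5))), "ensemble empty")
  # raising the TSS gate never adds members
  for (gate in c(0.6, 0.7, 0.9)) {
    inc_hi <- tryCatch({
      e <- gate_models(list(mk(0.65, 0.75), mk(0.50, 0.85), mk(0.50, 0.70)),
                       tss_gate = gate)
      sum(vapply(e$members, `[[`, logical(1), "included"))
    }, error = function(e) 0L)
    expect_lte(inc_hi, sum(inc))
  }
})

test_that("ensemble prediction is a convex combination of member maps", {
  st <- cached_stack(1)
  truth <- true_suitability(cached_world(1), default_niches()[[1]], stack = st)
  occ <- sample_occurrences(truth, 250, seed = 21)
  cells <- intersect(
    unique(stats::na.omit(cell_index(truth, occ$records$lon,
                                     occ$records$lat)$cell)),
    valid_cells(st)
  )
  preds <- c("BIO1", "BIO12", "urban", "elevation")
  ens <- fit_ensemble(st, cells, preds, n_pa_reps = 1, n_cv_reps = 2,
                      n_pa_min = 300, seed = 9)
  map <- ensemble_predict(ens, st)
  expect_true(all(map$values >= 0 & map$values <= 1, na.rm = TRUE))

  inc <- Filter(function(m) m$included, ens$members)
  x <- extract_cells(st, valid_cells(st, preds), preds)
  member_scores <- sapply(inc, function(m) predict_sdm(m$fit, x))
  lo <- apply(member_scores, 1, min); hi <- apply(member_scores, 1, max)
  mv <- map$values[valid_cells(st, preds)]
  expect_true(all(mv >= lo - 1e-9 & mv <= hi + 1e-9))

  # single included member: ensemble equals that member
  one <- ens
  keep <- which(vapply(one$members, `[[`, logical(1), "included"))[1]
  for (i in seq_along(one$members)) {
    one$members[[i]]$included <- i == keep
    one$members[[i]]$weight <- as.numeric(i == keep)
  }
  map1 <- ensemble_predict(one, st)
  expect_equal(map1$values[valid_cells(st, preds)],
               predict_sdm(one$members[[keep]]$fit, x), tolerance = 1e-12)
})
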