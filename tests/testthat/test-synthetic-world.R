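test_that("config validation rejects degenerate worlds", {
  expect_error(world_config(res_arcmin = 0), "res_arcmin")
  expect_error(world_config(xmin = 5, xmax = 5), "degenerate")
  expect_error(generate_world(world_config(xmax = 0.05, res_arcmin = 12)),
               "degenerate")
})

test_that("a noise-free flat world reproduces the seasonal cycle exactly", {
  cfg <- small_world_config(noise_sd_t = 0, noise_sd_p = 0, lat_gradient = 0,
                            seasonal_lat_gain = 0, elev_max = 0,
                            t_mean = 12, seasonal_amp = 6, warm_month = 7)
  w <- generate_world(cfg)
  for (m in 1:12) {
    expected <- 12 + 6 * cos(2 * pi * (m - 7) / 12)
    expect_true(all(abs(w$climate$tavg[[m]]$values - expected) < 1e-12))
  }
  expect_true(all(w$dem$values == 0))
})

test_that("generation is a pure function of the config seed", {
  w1 <- generate_world(small_world_config(seed = 42))
  w2 <- generate_world(small_world_config(seed = 42))
  expect_identical(w1, w2)
  w3 <- generate_world(small_world_config(seed = 43))
  expect_false(identical(w1$dem$values, w3$dem$values))
})

test_that("worlds satisfy the physical invariants", {
  w <- cached_world(5)
  for (m in 1:12) {
    expect_true(all(w$climate$tmin[[m]]$values <= w$climate$tavg[[m]]$values))
    expect_true(all(w$climate$tavg[[m]]$values <= w$climate$tmax[[m]]$values))
    expect_true(all(w$climate$prec[[m]]$values >= 0))
  }
  lu_sum <- Reduce(`+`, lapply(w$landuse, `[[`, "values"))
  expect_true(all(lu_sum <= 1 + 1e-12))
  for (l in w$landuse) {
    expect_true(all(l$values >= 0 & l$values <= 1))
  }
})

test_that("random fields carry the configured correlation length", {
  # brute-force semivariogram on one generated anomaly field; the range where
  # the semivariance reaches (1 - 1/e) of the sill should sit near the
  # configured correlation length
  L <- 10
  f <- with_seed_test(99, rangedyn:::gaussian_random_field(120, 120, L))
  set.seed(7)
  i <- sample(120L * 120L, 6000, replace = TRUE)
  j <- sample(120L * 120L, 6000, replace = TRUE)
  ri <- (i - 1) %% 120 + 1; ci <- (i - 1) %/% 120 + 1
  rj <- (j - 1) %% 120 + 1; cj <- (j - 1) %/% 120 + 1
  d <- sqrt((ri - rj)^2 + (ci - cj)^2)
  gam <- 0.5 * (f[i] - f[j])^2
  bins <- cut(d, breaks = seq(0, 40, by = 2))
  emp <- tapply(gam, bins, mean)
  sill <- stats::var(as.vector(f))
  lag_mid <- seq(1, 39, by = 2)
  cross <- lag_mid[match(TRUE, emp >= (1 - exp(-1)) * sill)]
  expect_true(abs(cross - L) / L <= 0.3)
})

test_that("scenario deltas shift temperature and scale precipitation", {
  w <- cached_world(1)
  expect_error(scenario_delta("current"), "current")
  ident <- apply_scenario(w, scenario_delta("same", dtemp = 0, prec_factor = 1))
  for (m in c(1, 6, 12)) {
    expect_equal(ident$climate$tavg[[m]]$values, w$climate$tavg[[m]]$values)
    expect_equal(ident$climate$prec[[m]]$values, w$climate$prec[[m]]$values)
  }
  warm <- apply_scenario(w, scenario_delta("warm", dtemp = 2))
  for (m in c(3, 9)) {
    expect_true(all(abs(warm$climate$tavg[[m]]$values -
                          w$climate$tavg[[m]]$values - 2) < 1e-12))
  }
  # halving precipitation halves annual precipitation (BIO12) cell-wise
  dry <- apply_scenario(w, scenario_delta("dry", prec_factor = 0.5))
  b_cur <- compute_bioclim(w$climate)$BIO12$values
  b_dry <- compute_bioclim(dry$climate)$BIO12$values
  expect_equal(b_dry, b_cur / 2, tolerance = 1e-12)
})

test_that("true suitability is the logistic of the configured niche", {
  w <- cached_world(1); st <- cached_stack(1)
  flat <- true_suitability(w, niche_spec("x", c(BIO1 = 0), intercept = 0),
                           stack = st)
  expect_true(all(abs(flat$values - 0.5) < 1e-12))
  sat <- true_suitability(w, niche_spec("x", c(BIO1 = 0), intercept = 50),
                          stack = st)
  expect_true(all(sat$values > 1 - 1e-12))
  expect_error(
    true_suitability(w, niche_spec("x", c(NOPE = 1)), stack = st),
    "unknown predictor"
  )
  # one-predictor niche: suitability strictly monotone in that predictor
  mono <- true_suitability(w, niche_spec("x", c(BIO12 = 0.01)), stack = st)
  o <- order(st$layers$BIO12$values)
  expect_true(all(diff(mono$values[o]) >= 0))
  expect_true(stats::cor(st$layers$BIO12$values[o],
                         mono$values[o], method = "spearman") > 0.9999)
})

test_that("occurrence sampling is suitability-weighted and seeded", {
  g <- flat_grid(0, ny = 10, nx = 10, cellsize = 0.1)
  expect_error(sample_occurrences(g, 10, 1), "sampleable")

  point <- g; point$values[4, 7] <- 1
  occ <- sample_occurrences(point, 50, seed = 3)
  ci <- cell_index(point, occ$records$lon, occ$records$lat)
  expect_true(all(ci$row == 4 & ci$col == 7))

  # two-level map: 0.8 vs 0.2 sampling ratio ~ 4:1 within binomial error
  two <- g
  two$values[, 1:5] <- 0.8; two$values[, 6:10] <- 0.2
  n <- 10000
  occ2 <- sample_occurrences(two, n, seed = 11)
  ci2 <- cell_index(two, occ2$records$lon, occ2$records$lat)
  p_hat <- mean(ci2$col <= 5)
  expect_true(abs(p_hat - 0.8) < 4 * sqrt(0.8 * 0.2 / n))

  expect_identical(sample_occurrences(two, 100, seed = 5),
                   sample_occurrences(two, 100, seed = 5))
})

test_that("worlds can be written to and read back from ASCII layers", {
  w <- generate_world(world_config(xmax = 2, ymax = 32, res_arcmin = 30,
                                   seed = 2))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_true(file.exists(file.path(dir, "tavg_01.asc")))
  expect_true(file.exists(file.path(dir, "world.yaml")))
  rt <- read_asc(file.path(dir, "prec_07.asc"))
  expect_equal(rt$values, w$climate$prec[[7]]$values, tolerance = 1e-8)
})
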