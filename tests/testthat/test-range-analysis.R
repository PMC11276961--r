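test_that("the MSS threshold equals an exhaustive sweep", {
  # perfect separation: the midpoint candidate between the classes wins,
  # ties broken toward the lower threshold
  expect_equal(mss_threshold(c(0.9, 0.8), c(0.1, 0.2)), 0.5)
  expect_error(mss_threshold(rep(0.4, 3), rep(0.4, 2)), "degenerate")

  sweep_oracle <- function(p, a) {
    u <- sort(unique(c(p, a)))
    cand <- (u[-length(u)] + u[-1]) / 2
    ss <- sapply(cand, function(t) mean(p >= t) + mean(a < t))
    cand[which(ss == max(ss))[1]]
  }
  set.seed(12)
  p <- c(0.9, 0.4); a <- c(0.6, 0.1)
  expect_equal(mss_threshold(p, a), sweep_oracle(p, a))
  for (rep in 1:50) {
    p <- round(runif(sample(3:20, 1)), 2)
    a <- round(runif(sample(3:20, 1)), 2)
    if (length(unique(c(p, a))) < 2) next
    expect_equal(mss_threshold(p, a), sweep_oracle(p, a), tolerance = 1e-12)
  }
  # duplicating a presence score never lowers the attainable sens+spec sum
  p <- runif(10); a <- runif(10)
  best <- function(p, a) {
    t <- mss_threshold(p, a)
    mean(p >= t) + mean(a < t)
  }
  expect_gte(best(c(p, p[1]), a) * 11, best(p, a) * 10 - 1e-12)
})

test_that("binarization thresholds with >= and propagates nodata", {
  v <- matrix(c(0.1, 0.5, 0.9, NA), 2, 2)
  g <- raster_grid(v, 0, 0, 1)
  expect_equal(binarize(g, 0)$values[!is.na(v)], c(1, 1, 1))
  expect_equal(binarize(g, 0.5)$values[2, 1], 1)  # equality is inside
  expect_true(is.na(binarize(g, 0.5)$values[2, 2]))
  expect_equal(sum(binarize(g, 0.95)$values, na.rm = TRUE), 0)
  # monotone: raising the threshold never adds cells
  prev <- Inf
  for (t in c(0.2, 0.5, 0.8)) {
    n <- sum(binarize(g, t)$values, na.rm = TRUE)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("range areas, RER, RSI and expansion obey their identities", {
  g <- flat_grid(0, ny = 6, nx = 6, ymin = 40, cellsize = 0.5)
  areas <- cell_area_grid(g)
  cur <- g; cur$values[1:3, ] <- 1
  fut <- g; fut$values[2:5, ] <- 1

  expect_equal(range_area(g, areas), 0)
  full <- g; full$values[] <- 1
  expect_equal(range_area(full, areas), sum(areas$values))

  rc <- range_area(cur, areas); rf <- range_area(fut, areas)
  expect_equal(compute_rer(rc, rf), rf / rc)
  expect_equal(compute_rer(1, 2.36), 2.36)
  expect_error(compute_rer(0, 5), "undefined")

  shared <- g; shared$values[2:3, ] <- 1
  rs <- range_area(shared, areas)
  expect_equal(compute_rsi(cur, fut, areas), 2 * rs / (rc + rf))
  expect_equal(compute_rsi(cur, cur, areas), 1)
  disj <- g; disj$values[6, ] <- 1
  expect_equal(compute_rsi(cur, disj, areas), 0)

  ex <- expanding_range(cur, fut)
  expect_equal(which(ex$values == 1), which(fut$values == 1 & cur$values == 0))
  # exact accounting: RF = RS + expanding
  expect_equal(rf, rs + range_area(ex, areas), tolerance = 1e-12)
  # future = current -> empty expansion; empty current -> expansion = future
  expect_equal(sum(expanding_range(cur, cur)$values), 0)
  expect_equal(expanding_range(g, fut)$values, fut$values)
})

test_that("centroid shifts have the right distance and bearing", {
  g <- flat_grid(0, ny = 3, nx = 5, ymin = -1.5, cellsize = 1)
  areas <- cell_area_grid(g)
  a <- g; a$values[2, 2] <- 1   # centre cell at (1.5, 0)
  b <- g; b$values[2, 3] <- 1   # one degree east on the equator
  s <- centroid_shift(a, b, areas)
  expect_equal(s$distance_km, 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(s$bearing_deg, 90, tolerance = 1e-6)
  expect_equal(centroid_shift(a, a, areas)$distance_km, 0)
  # distance symmetric under swapping
  s2 <- centroid_shift(b, a, areas)
  expect_equal(s2$distance_km, s$distance_km, tolerance = 1e-9)
  expect_error(centroid_shift(a, g, areas), "empty")
})

test_that("the paired t-test matches a hand-computed oracle", {
  cur <- c(4.1, 3.3, 5.0, 2.2, 6.7)
  fut <- c(5.2, 3.1, 6.4, 2.9, 8.0)
  res <- paired_t_test(cur, fut)
  d <- fut - cur
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(5))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = 4)
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(res$df, 4)
  # antisymmetry
  swap <- paired_t_test(fut, cur)
  expect_equal(swap$t, -res$t, tolerance = 1e-12)
  expect_equal(swap$p_value, res$p_value, tolerance = 1e-12)
  expect_error(paired_t_test(cur, cur + 3), "zero variance")
})

test_that("range_dynamics rows are internally consistent", {
  g <- flat_grid(0, ny = 8, nx = 8, ymin = 35, cellsize = 0.25)
  areas <- cell_area_grid(g)
  set.seed(20)
  for (rep in 1:5) {
    cur <- g; cur$values[] <- rbinom(64, 1, 0.4)
    fut <- g; fut$values[] <- rbinom(64, 1, 0.5)
    if (sum(cur$values) == 0 || sum(fut$values) == 0) next
    row <- range_dynamics(cur, fut, areas, "sp", "future")
    expect_equal(row$rf_km2, row$rs_km2 + row$expanding_km2, tolerance = 1e-9)
    expect_lte(row$rs_km2, min(row$rc_km2, row$rf_km2) + 1e-12)
    expect_equal(row$rer, row$rf_km2 / row$rc_km2, tolerance = 1e-12)
    expect_gte(row$rsi, 0); expect_lte(row$rsi, 1)
  }
})
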