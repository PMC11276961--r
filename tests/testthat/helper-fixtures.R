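# shared fixtures: small worlds/stacks are expensive enough to cache per run
.fixtures <- new.env(parent = emptyenv())

with_seed_test <- function(seed, expr) rangedyn:::with_seed(seed, expr)

small_world_config <- function(seed = 1L, ...) {
  # 50 x 25 cells: fast but large enough for spatial structure
  world_config(xmax = 10, ymax = 35, res_arcmin = 12, seed = seed, ...)
}

cached_world <- function(seed = 1L) {
  key <- paste0("world_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_world(small_world_config(seed))
  }
  .fixtures[[key]]
}

cached_stack <- function(seed = 1L) {
  key <- paste0("stack_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- build_predictor_stack(cached_world(seed))
  }
  .fixtures[[key]]
}

flat_grid <- function(value = 0, ny = 5, nx = 5, xmin = 0, ymin = 0,
                      cellsize = 1) {
  raster_grid(matrix(value, ny, nx), xmin, ymin, cellsize)
}

rand_maps <- function(n, seed, binary = FALSE, ny = 6, nx = 7) {
  with_seed_test(seed, lapply(seq_len(n), function(i) {
    v <- if (binary) matrix(rbinom(ny * nx, 1, 0.5), ny, nx)
         else matrix(runif(ny * nx), ny, nx)
    raster_grid(v, 0, 30, 0.5)
  }))
}

# a scaled-down pipeline configuration so orchestration tests run in seconds
small_run_config <- function(seed = 1L, ...) {
  run_config(
    world = world_config(xmax = 8, ymax = 37, res_arcmin = 12, seed = seed),
    n_occurrences = 200L, n_pa_min = 300L,
    n_pa_reps = 2L, n_cv_reps = 2L,
    seed = seed, ...
  )
}

# independent single-cell bioclim oracle: plain loops over the 12 windows
bioclim_oracle_cell <- function(tavg, tmin, tmax, prec) {
  popsd <- function(x) sqrt(mean((x - mean(x))^2))
  qt <- numeric(12); qp <- numeric(12)
  for (s in 1:12) {
    ix <- ((s - 1):(s + 1)) %% 12 + 1
    qt[s] <- mean(tavg[ix])
    qp[s] <- sum(prec[ix])
  }
  b5 <- max(tmax); b6 <- min(tmin); b2 <- mean(tmax - tmin)
  c(BIO1 = mean(tavg), BIO2 = b2, BIO3 = 100 * b2 / (b5 - b6),
    BIO4 = 100 * popsd(tavg), BIO5 = b5, BIO6 = b6, BIO7 = b5 - b6,
    BIO8 = qt[which.max(qp)], BIO9 = qt[which.min(qp)],
    BIO10 = qt[which.max(qt)], BIO11 = qt[which.min(qt)],
    BIO12 = sum(prec), BIO13 = max(prec), BIO14 = min(prec),
    BIO15 = 100 * popsd(prec) / (1 + sum(prec) / 12),
    BIO16 = qp[which.max(qp)], BIO17 = qp[which.min(qp)],
    BIO18 = qp[which.max(qt)], BIO19 = qp[which.min(qt)])
}

# exhaustive conflict-free subset maximizing summed importance (oracle)
selection_oracle <- function(corr, imp, threshold = 0.7) {
  preds <- colnames(corr)
  n <- length(preds)
  best <- character(0); best_val <- -Inf
  for (mask in 0:(2^n - 1)) {
    members <- preds[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L]
    if (length(members) > 1L) {
      sub <- abs(corr[members, members])
      diag(sub) <- 0
      if (max(sub) > threshold) next
    }
    val <- sum(imp[members])
    if (val > best_val + 1e-12 ||
        (abs(val - best_val) <= 1e-12 && length(members) > length(best))) {
      best_val <- val; best <- members
    }
  }
  sort(best)
}
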