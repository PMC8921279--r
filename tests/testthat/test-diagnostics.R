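test_that("residual metrics reproduce hand-computable cases", {
  obs <- c(10, 20, 30, 40)
  perfect <- matrix(rep(obs, 50), 4, 50)
  m <- residual_metrics(obs, perfect)
  expect_equal(m$bias, 0); expect_equal(m$imprecision, 0)
  expect_equal(m$inaccuracy, 0); expect_equal(m$r2, 1)
  expect_equal(m$coverage, 100)

  shifted <- perfect + 3
  m2 <- residual_metrics(obs, shifted)
  expect_equal(m2$bias, 3); expect_equal(m2$imprecision, 0)
  expect_equal(m2$inaccuracy, 3)

  expect_warning(residual_metrics(rep(5, 4), perfect), "zero-variance")
})

test_that("residual metrics match an independent formula-by-formula oracle", {
  set.seed(31)
  obs <- rpois(40, 100)
  draws <- matrix(rpois(40 * 400, 95), 40, 400)
  m <- residual_metrics(obs, draws)

  pm <- numeric(40); lo <- numeric(40); hi <- numeric(40)
  for (i in 1:40) {
    pm[i] <- mean(draws[i, ])
    lo[i] <- quantile(draws[i, ], 0.025); hi[i] <- quantile(draws[i, ], 0.975)
  }
  res <- pm - obs
  expect_equal(m$bias, sum(res) / 40, tolerance = 1e-10)
  expect_equal(m$imprecision, sqrt(sum((res - mean(res))^2) / 40),
               tolerance = 1e-10)
  expect_equal(m$inaccuracy, sum(abs(res)) / 40, tolerance = 1e-10)
  expect_equal(m$r2, cor(obs, pm)^2, tolerance = 1e-10)
  expect_equal(m$coverage, 100 * mean(obs >= lo & obs <= hi), tolerance = 1e-10)
  expect_equal(m$bias_scaled, mean(res / pm), tolerance = 1e-10)

  # metric identities
  expect_gte(m$inaccuracy, abs(m$bias))
  expect_equal(m$imprecision^2 + m$bias^2, mean(res^2), tolerance = 1e-10)

  # literal residual-correlation variant is available
  ml <- residual_metrics(obs, draws, r2_on = "residuals")
  expect_equal(ml$r2, cor(obs, res)^2, tolerance = 1e-10)
})

test_that("Moran's I matches the double-sum formula and detects structure", {
  set.seed(41)
  xy <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  z <- rnorm(10)
  got <- morans_i(z, xy, nperm = 199, seed = 1)
  # brute-force double sum with row-standardized inverse-distance weights
  n <- 10
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j)
    W[i, j] <- 1 / sqrt(sum((xy[i, ] - xy[j, ])^2))
  W <- W / rowSums(W)
  zc <- z - mean(z)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * zc[i] * zc[j]
  I_brute <- (n / sum(W)) * num / sum(zc^2)
  expect_equal(got$I, I_brute, tolerance = 1e-10)
  expect_equal(got$expected, -1 / 9)

  # cross-check the statistic against ape's implementation
  ape_I <- ape::Moran.I(z, W)$observed
  expect_equal(got$I, ape_I, tolerance = 1e-10)

  # planted gradient: strong positive autocorrelation, small p
  set.seed(5)
  xy2 <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  grad <- morans_i(xy2[, 1] / 50, xy2, nperm = 499, seed = 2)
  expect_gt(grad$I, 0.2)
  expect_lt(grad$p_perm, 0.05)

  # spatially random residuals: I near its null expectation
  rnd <- morans_i(rnorm(40), xy2, nperm = 499, seed = 3)
  expect_gt(rnd$p_perm, 0.05)
  expect_lt(abs(rnd$I - rnd$expected), 0.15)

  expect_error(morans_i(rep(1, 10), xy), "constant")
  expect_error(morans_i(rnorm(5), xy[1:5, ]), ">= 8")
})

test_that("semivariogram equals brute-force pairwise computation", {
  xy <- cbind(c(0, 1, 2, 3, 10), c(0, 0, 0, 0, 0))
  z <- c(1, 3, 2, 5, 4)
  breaks <- c(0, 2, 5, 11)
  got <- semivariogram(z, xy, breaks)
  brute <- rep(0, 3); cnt <- rep(0, 3)
  for (i in 1:4) for (j in (i + 1):5) {
    h <- abs(xy[i, 1] - xy[j, 1])
    b <- findInterval(h, breaks, left.open = TRUE, rightmost.closed = TRUE)
    b <- max(b, 1)
    brute[b] <- brute[b] + (z[i] - z[j])^2; cnt[b] <- cnt[b] + 1
  }
  expect_equal(got$np, as.integer(cnt))
  expect_equal(got$gamma, brute / (2 * cnt), tolerance = 1e-10)

  # constant residuals: zero semivariance at every populated lag
  flat <- semivariogram(rep(2, 8), cbind(1:8, 0), breaks = 3)
  expect_true(all(flat$gamma[flat$np > 0] == 0))

  # iid residuals: flat semivariogram near the variance
  set.seed(6)
  z2 <- rnorm(400); xy2 <- cbind(runif(400, 0, 100), runif(400, 0, 100))
  sv <- semivariogram(z2, xy2, breaks = 5)
  expect_true(all(abs(sv$gamma[sv$np > 100] - var(z2)) < 0.2))
})

test_that("cross-validation partitions clusters and predicts each once", {
  cl <- tiny_clusters(n = 24, seed = 61, K = 1)
  cv <- crossvalidate(cl, quick_config(seed = 1, iterations = 500, burnin = 150),
                      k = 4, seed = 9, n_draws = 150, covariates = "x1")
  expect_equal(sort(unique(cv$fold)), 1:4)
  expect_equal(length(cv$fold), 24)
  expect_true(all(table(cv$fold) >= 2))
  expect_true(all(is.finite(cv$N)))

  cv2 <- crossvalidate(cl, quick_config(seed = 1, iterations = 500, burnin = 150),
                       k = 4, seed = 9, n_draws = 150, covariates = "x1")
  expect_identical(cv$fold, cv2$fold)

  met <- cv_metrics(cv)
  expect_equal(met$estimate, c("population totals", "population densities"))
  expect_true(all(met$coverage >= 0 & met$coverage <= 100))
  expect_true(all(met$inaccuracy >= abs(met$bias)))
})

test_that("age-sex holdout validation reports near-perfect province fits", {
  cfg <- world_config(seed = 71, grid_shape = c(100, 100))
  w <- generate_world(cfg)
  tr <- draw_truth(cfg)
  sv <- simulate_survey(w, tr, survey_design(mode = "random", n_clusters = 200))
  out <- crossvalidate_agesex(sv$individuals, frac = 0.15, n_draws = 1000,
                              seed = 2)
  expect_gt(out$metrics$r2, 0.85)
  expect_lt(out$metrics$inaccuracy, 0.01)
})
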