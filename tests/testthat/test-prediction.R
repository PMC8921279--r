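# A single small fit shared by the prediction tests (file-level, built once).
pred_fit <- local({
  cl <- tiny_clusters(n = 60, seed = 51, K = 1)
  fit_density_model(cl, quick_config(seed = 7, iterations = 1500, burnin = 400),
                    covariates = "x1")
})

test_that("pooled precision equals the sqrt(v)-weighted average of cluster scales", {
  tau <- matrix(runif(20, 0.2, 0.8), 10, 2)
  v <- runif(7, 0.01, 0.4)
  stratum <- c(1, 1, 1, 2, 2, 2, 2)
  got <- pooled_precision(tau, v, stratum)
  # brute-force direct summation per draw and stratum
  for (s in 1:2) {
    idx <- which(stratum == s)
    for (dr in 1:10) {
      num <- 0; den <- 0
      for (i in idx) {
        num <- num + (tau[dr, s] / sqrt(v[i])) * sqrt(v[i])
        den <- den + sqrt(v[i])
      }
      expect_equal(got[dr, s], num / den, tolerance = 1e-12)
    }
  }
  # algebraic reduction: n_s * tau / sum(sqrt(v))
  s1 <- which(stratum == 1)
  expect_equal(got[, 1], tau[, 1] * length(s1) / sum(sqrt(v[s1])),
               tolerance = 1e-12)

  # equal weights: tau_hat = tau / sqrt(v); single cluster: the cluster scale
  expect_equal(pooled_precision(tau[, 1], rep(0.25, 4), rep(1, 4))[, 1],
               tau[, 1] / 0.5, tolerance = 1e-12)
  expect_equal(pooled_precision(tau[, 1], 0.09, 1)[, 1], tau[, 1] / 0.3,
               tolerance = 1e-12)
})

test_that("cells without footprints predict exactly zero", {
  nd <- data.frame(A = c(0, 0.4, 0), type = c(NA, "rural", "urban"),
                   province = 1, local_area = 1, x1 = c(NA, 0.2, NA))
  pr <- predict(pred_fit, nd, n_draws = 200, seed = 1, keep_draws = TRUE)
  expect_true(all(pr$draws[1, ] == 0))
  expect_true(all(pr$draws[3, ] == 0))
  expect_equal(pr$summary$lower[c(1, 3)], c(0, 0))
  expect_equal(pr$summary$upper[c(1, 3)], c(0, 0))
  expect_true(all(pr$summary$lower <= pr$summary$mean + 1e-12))
  expect_true(all(pr$summary$mean <= pr$summary$upper + 1e-12))
})

test_that("cell means match the lognormal-Poisson closed form within MC error", {
  nd <- data.frame(A = 0.5, type = "rural", province = 1, local_area = 1,
                   x1 = 0.3)
  pr <- predict(pred_fit, nd, n_draws = 20000, seed = 5, keep_draws = TRUE)
  m <- posterior_draws(pred_fit)
  idx <- round(seq(1, nrow(m), length.out = min(20000, nrow(m))))
  db <- m[idx, "alpha[rural.1.1]"] + 0.3 * m[idx, "beta[x1,rural]"]
  th <- m[idx, "tau_hat[rural.1]"]
  analytic <- mean(0.5 * exp(db + th^2 / 2))
  mc_se <- sd(pr$draws[1, ]) / sqrt(ncol(pr$draws))
  expect_lt(abs(mean(pr$draws[1, ]) - analytic), 3 * mc_se)
})

test_that("unseen local areas fall back to the stratum level with a message", {
  nd <- data.frame(A = 0.4, type = "rural", province = 1, local_area = 99,
                   x1 = 0)
  expect_message(pr <- predict(pred_fit, nd, n_draws = 300, seed = 2),
                 "unseen group")
  expect_gt(pr$summary$mean, 0)
})

test_that("age-sex disaggregation is exact in the degenerate and uniform cases", {
  nd <- data.frame(A = c(0.3, 0.5), type = "rural", province = 1,
                   local_area = 1, x1 = 0)
  pr <- predict(pred_fit, nd, n_draws = 400, seed = 3, keep_draws = TRUE)

  G <- 36
  degenerate <- structure(list(
    draws = array(rep(c(1, rep(0, G - 1)), each = 400), c(400, G, 1),
                  dimnames = list(NULL, paste0("g", 1:G), "1")),
    mean = NULL, groups = paste0("g", 1:G), provinces = "1", n_draws = 400),
    class = "agesex_fit")
  out <- apply_agesex(pr, degenerate)
  expect_equal(out$g1$mean, pr$summary$mean)
  expect_equal(out$g2$mean, c(0, 0))

  uniform <- degenerate
  uniform$draws[] <- 1 / G
  outu <- apply_agesex(pr, uniform)
  expect_equal(outu$g5$mean, pr$summary$mean / G, tolerance = 1e-12)
  # group means add back to the total mean per cell
  tot <- Reduce(`+`, lapply(outu, `[[`, "mean"))
  expect_equal(tot, pr$summary$mean, tolerance = 1e-12)

  # province without fitted proportions errors
  bad <- pr; bad$province <- 2
  expect_error(apply_agesex(bad, degenerate), "without fitted")
})

test_that("polygon aggregation conserves totals draw by draw", {
  cl <- data.frame(A = runif(12, 0.2, 0.6), type = "rural", province = 1,
                   local_area = 1, x1 = rnorm(12),
                   x = rep(seq(50, 350, by = 100), 3),
                   y = rep(c(50, 150, 250), each = 4))
  pr <- predict(pred_fit, cl, n_draws = 300, seed = 9, keep_draws = TRUE)

  whole <- aggregate_zones(pr, rep("all", 12))
  per_draw_tot <- colSums(pr$draws)
  expect_equal(whole$mean, mean(per_draw_tot))
  expect_equal(whole$lower, quantile(per_draw_tot, 0.025, names = FALSE))

  halves <- rep(c("west", "east"), each = 6)
  agg <- aggregate_zones(pr, halves)
  expect_equal(sum(agg$mean), whole$mean, tolerance = 1e-9)
  # the interval of a sum is not the sum of intervals, but means add exactly
  expect_lte(whole$upper, sum(agg$upper) + 1e-9)

  # rectangles map to zones by cell-centre containment
  zones <- rectangles_to_zones(cl, data.frame(zone = c("a", "b"),
                                              xmin = c(0, 200), xmax = c(200, 400),
                                              ymin = 0, ymax = 300))
  expect_equal(sort(unique(zones)), c("a", "b"))
  expect_warning(rectangles_to_zones(cl, data.frame(zone = "far", xmin = 1e6,
                                                    xmax = 2e6, ymin = 0,
                                                    ymax = 1)),
                 "covers no grid cell")
})

test_that("popfit methods expose the fitted model coherently", {
  expect_output(print(pred_fit), "hierarchical population density model")
  s <- summary(pred_fit)
  expect_true(all(c("parameter", "mean", "rhat") %in% names(s)))
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  cf <- coef(pred_fit)
  expect_true(any(startsWith(names(cf), "alpha[")))
  r <- residuals(pred_fit, n_draws = 200, seed = 1)
  expect_equal(length(r), pred_fit$data$n)
  sim <- simulate(pred_fit, nsim = 50, seed = 2)
  expect_equal(dim(sim), c(pred_fit$data$n, 50))
  expect_true(all(sim >= 0))
})
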