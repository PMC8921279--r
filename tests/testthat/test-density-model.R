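test_that("the regression layer reproduces hand-computed expectations", {
  cl <- tiny_clusters(n = 20, K = 2)
  d <- pop_model_data(cl, covariates = c("x1", "x2"))
  p <- legalize_params(random_params(d), d)

  p0 <- p; p0$beta[] <- 0
  expect_equal(expected_log_density(p0, d), p$alpha[d$g])

  # alpha = 0, beta = (1, 0), x1 = 2 -> Dbar = 2
  one <- pop_model_data(data.frame(N = 1, A = 1, type = "rural", province = 1,
                                   local_area = 1, x1 = 2, x2 = 5),
                        covariates = c("x1", "x2"))
  p1 <- legalize_params(random_params(one), one)
  p1$alpha[] <- 0; p1$beta <- matrix(c(1, 0), 2, 1)
  expect_equal(expected_log_density(p1, one), 2)

  # vector case equals an independent per-cluster dot product
  manual <- vapply(seq_len(d$n), function(i)
    p$alpha[d$g[i]] + sum(p$beta[, d$t[i]] * d$X[i, ]), 0)
  expect_equal(expected_log_density(p, d), manual, tolerance = 1e-12)
})

test_that("weighted precision rescales the lognormal scale by sqrt(v)", {
  expect_equal(effective_scale(0.7, 1), 0.7)
  expect_equal(effective_scale(0.7, 4), 0.35)
  set.seed(8)
  v <- runif(30, 0.001, 0.2)
  sc <- effective_scale(0.5, v)
  expect_equal(sc * sqrt(v), rep(0.5, 30), tolerance = 1e-12)
  expect_error(effective_scale(0.5, c(1, 0)), "positive")
})

test_that("log joint matches an independent term-by-term computation", {
  for (seed in 1:5) {
    cl <- tiny_clusters(n = 15, seed = seed, K = 2)
    d <- pop_model_data(cl, covariates = c("x1", "x2"))
    cfg <- model_config()
    p <- legalize_params(random_params(d, seed = seed + 100), d)
    expect_equal(log_joint(p, d, cfg), brute_log_joint(p, d, cfg),
                 tolerance = 1e-10)
  }
  # fixed-effect mode: constant beta rows, fixed-effect prior
  cl <- tiny_clusters(n = 12, seed = 3, K = 2)
  d <- pop_model_data(cl, covariates = c("x1", "x2"))
  cfg <- model_config(effect_mode = "fixed")
  p <- legalize_params(random_params(d, 7), d)
  p$beta[1, ] <- 0.25; p$beta[2, ] <- -0.4
  expect_equal(log_joint(p, d, cfg), brute_log_joint(p, d, cfg),
               tolerance = 1e-10)
})

test_that("log joint handles zero footprint area and support violations", {
  cl <- tiny_clusters(n = 6, seed = 5, K = 0)
  cl$A[1] <- 0; cl$N[1] <- 0
  d <- pop_model_data(cl, covariates = character(0))
  cfg <- model_config()
  p <- legalize_params(random_params(d), d)
  expect_true(is.finite(log_joint(p, d, cfg)))

  cl2 <- cl; cl2$N[1] <- 3          # people without any footprint
  d2 <- pop_model_data(cl2, covariates = character(0))
  expect_equal(log_joint(p, d2, cfg), -Inf)

  bad <- p; bad$tau_tp[1] <- -0.1
  expect_equal(log_joint(bad, d, cfg), -Inf)
  bad2 <- p; bad2$nu_tp[] <- p$nu_t[d$s2t] * 2   # above the uniform bound
  expect_equal(log_joint(bad2, d, cfg), -Inf)
})

test_that("log joint vanishes as latent densities degenerate", {
  cl <- tiny_clusters(n = 10, seed = 2, K = 0)
  d <- pop_model_data(cl, covariates = character(0))
  cfg <- model_config()
  p <- legalize_params(random_params(d), d)
  base <- log_joint(p, d, cfg)
  lo <- p; lo$logD <- rep(-60, d$n)
  hi <- p; hi$logD <- rep(60, d$n)
  expect_lt(log_joint(lo, d, cfg), base - 100)
  expect_true(log_joint(hi, d, cfg) < base - 100 ||
                log_joint(hi, d, cfg) == -Inf)
})

test_that("equal model weights reduce to the unweighted model after tau rescaling", {
  cl <- tiny_clusters(n = 14, seed = 9, K = 1)
  cfg <- model_config()
  d_eq <- pop_model_data(cl, covariates = "x1")              # v = 1/n each
  cl1 <- cl; cl1$v <- rep(1, nrow(cl))
  d_one <- pop_model_data(cl1, covariates = "x1")            # v = 1 each
  I <- nrow(cl)
  for (s in 1:4) {
    p <- legalize_params(random_params(d_eq, seed = s), d_eq)
    p1 <- p; p1$tau_tp <- p$tau_tp * sqrt(I)   # same effective scale under v = 1
    p1$mu_tp <- p$mu_tp * sqrt(I); p1$sigma_tp <- p$sigma_tp * sqrt(I)
    p1$mu_t <- p$mu_t * sqrt(I)
    p1$sigma_t <- p$sigma_t * sqrt(I)
    # every data layer agrees once tau is rescaled; only the (rescaled)
    # half-normal prior layer differs, and by exactly the prior terms
    prior_diff <-
      sum(dhalfnorm(p$tau_tp, p$mu_tp, p$sigma_tp, log = TRUE)) -
      sum(dhalfnorm(p1$tau_tp, p1$mu_tp, p1$sigma_tp, log = TRUE)) +
      sum(dhalfnorm(p$mu_tp, p$mu_t[d_eq$s2t], p$sigma_t[d_eq$s2t], log = TRUE)) -
      sum(dhalfnorm(p1$mu_tp, p1$mu_t[d_eq$s2t], p1$sigma_t[d_eq$s2t], log = TRUE)) -
      sum(log(p$sigma_t[d_eq$s2t])) + sum(log(p1$sigma_t[d_eq$s2t])) +
      sum(dnorm(p$mu_t, 0, cfg$prior_sd0, log = TRUE)) -
      sum(dnorm(p1$mu_t, 0, cfg$prior_sd0, log = TRUE))
    expect_equal(log_joint(p, d_eq, cfg) - log_joint(p1, d_one, cfg),
                 prior_diff, tolerance = 1e-10)
  }
})

test_that("Poisson layer simulations have mean D*A", {
  set.seed(6)
  D <- runif(200, 100, 900); A <- runif(200, 0.05, 0.5)
  N <- rpois(200, D * A)
  se <- sqrt(sum(D * A)) / 200          # sd of the mean of independent Poissons
  expect_lt(abs(mean(N) - mean(D * A)), 3 * se)
})

test_that("effect-mode conversion follows the between-type contrast interval", {
  set.seed(10)
  same <- matrix(rnorm(4000, 0.3, 0.1), ncol = 2)
  dec <- decide_effect_mode(list(same))
  expect_equal(dec$mode, "fixed")

  identical_draws <- cbind(rnorm(500), 0)
  identical_draws[, 2] <- identical_draws[, 1]
  expect_equal(decide_effect_mode(list(identical_draws))$mode, "fixed")

  disjoint <- cbind(runif(500, 0.5, 1), runif(500, -1, -0.5))
  expect_equal(decide_effect_mode(list(disjoint))$mode, "random")

  # planted equal effects: the fixed decision is made in >= 90% of replicates
  hits <- mean(vapply(1:60, function(i) {
    m <- matrix(rnorm(2000, 0.2, 0.15), ncol = 2)
    decide_effect_mode(list(m))$mode == "fixed"
  }, TRUE))
  expect_gte(hits, 0.9)
})

test_that("dhalfnorm is a renormalized truncated normal", {
  for (mu in c(-0.5, 0, 0.8)) {
    total <- integrate(function(x) dhalfnorm(x, mu, 0.6), 0, Inf)$value
    expect_equal(total, 1, tolerance = 1e-6)   # integrates to 1
  }
  expect_equal(dhalfnorm(-1, 0, 1), 0)
  set.seed(3)
  draws <- rhalfnorm(20000, 0.4, 0.3)
  expect_true(all(draws >= 0))
  num <- integrate(function(x) x * dhalfnorm(x, 0.4, 0.3), 0, Inf)$value
  expect_lt(abs(mean(draws) - num), 0.01)
  expect_equal(rhalfnorm(3, 0.7, 0), rep(0.7, 3))
})
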