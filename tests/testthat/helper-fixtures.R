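# Shared fixtures, built in code at test time.

# A small model-ready cluster table with two settlement types, two provinces
# and two local areas per province; counts drawn from the model's own layers.
tiny_clusters <- function(n = 40, seed = 42, K = 2) {
  set.seed(seed)
  type <- sample(c("rural", "urban"), n, replace = TRUE)
  province <- sample(1:2, n, replace = TRUE)
  local_area <- sample(1:2, n, replace = TRUE)
  A <- runif(n, 0.1, 0.8)
  X <- matrix(rnorm(n * K), n, K)
  alpha <- ifelse(type == "rural", 6, 5.5) + 0.2 * province
  dbar <- alpha + if (K > 0) X %*% rep(0.3, K) else 0
  logD <- rnorm(n, dbar, 0.4)
  cl <- data.frame(N = rpois(n, exp(logD) * A), A = A,
                   type = type, province = province, local_area = local_area,
                   x = runif(n, 0, 5000), y = runif(n, 0, 5000),
                   v = NA)
  for (k in seq_len(K)) cl[[paste0("x", k)]] <- X[, k]
  cl$v <- rep(1 / n, n)
  cl
}

# Random parameter set consistent with a pop_model_data layout, for
# log-joint oracle tests.
random_params <- function(d, seed = 1) {
  set.seed(seed)
  K <- d$K
  list(
    logD = rnorm(d$n, 6, 0.5),
    alpha = rnorm(d$nG, 6, 0.5),
    xi_tp = rnorm(d$nS, 6, 0.3),
    nu_tp = runif(d$nS, 0.1, 0.4),
    xi_t = rnorm(d$nT, 6, 0.3),
    nu_t = runif(d$nT, 0.5, 1),
    beta = matrix(rnorm(K * d$nT, 0, 0.3), K, d$nT),
    rho = rnorm(K, 0, 0.2),
    omega = runif(K, 0.2, 0.6),
    tau_tp = runif(d$nS, 0.2, 0.6),
    mu_tp = runif(d$nS, 0.2, 0.6),
    sigma_tp = runif(d$nS, 0.05, 0.15),
    mu_t = runif(d$nT, 0.2, 0.6),
    sigma_t = runif(d$nT, 0.2, 0.4),
    check_support = TRUE
  )
}

# Ensure the support constraints hold (nu_tp < nu_t etc.)
legalize_params <- function(p, d) {
  p$nu_t <- pmax(p$nu_t, vapply(seq_len(d$nT), function(tt)
    max(p$nu_tp[d$s2t == tt]) * 1.1, 0))
  p$sigma_t <- pmax(p$sigma_t, vapply(seq_len(d$nT), function(tt)
    max(p$sigma_tp[d$s2t == tt]) * 1.1, 0))
  p
}

# Independent, loop-based log-joint computation: same model, written
# term-by-term with scalar loops and stats d* functions only.
brute_log_joint <- function(p, d, config = model_config()) {
  sd0 <- config$prior_sd0; U <- 1000
  lp <- 0
  for (i in seq_len(d$n)) {
    Di <- exp(p$logD[i])
    lp <- lp + dpois(d$N[i], Di * d$A[i], log = TRUE)
    db <- p$alpha[d$g[i]]
    if (d$K > 0) for (k in seq_len(d$K))
      db <- db + p$beta[k, d$t[i]] * d$X[i, k]
    sc <- p$tau_tp[d$s[i]] / sqrt(d$v[i])
    lp <- lp + dnorm(p$logD[i], db, sc, log = TRUE)
  }
  for (g in seq_len(d$nG)) {
    s <- d$g2s[g]
    lp <- lp + dnorm(p$alpha[g], p$xi_tp[s], p$nu_tp[s], log = TRUE)
  }
  for (s in seq_len(d$nS)) {
    tt <- d$s2t[s]
    lp <- lp + dnorm(p$xi_tp[s], p$xi_t[tt], p$nu_t[tt], log = TRUE)
    lp <- lp + dunif(p$nu_tp[s], 0, p$nu_t[tt], log = TRUE)
    hn <- function(x, mu, sg)
      dnorm(x, mu, sg, log = TRUE) - pnorm(0, mu, sg, lower.tail = FALSE, log.p = TRUE)
    lp <- lp + hn(p$tau_tp[s], p$mu_tp[s], p$sigma_tp[s])
    lp <- lp + hn(p$mu_tp[s], p$mu_t[tt], p$sigma_t[tt])
    lp <- lp + dunif(p$sigma_tp[s], 0, p$sigma_t[tt], log = TRUE)
  }
  em <- rep_len(config$effect_mode, d$K)
  for (k in seq_len(d$K)) {
    if (em[k] == "fixed") {
      lp <- lp + dnorm(p$beta[k, 1], 0, sd0, log = TRUE)
    } else {
      for (tt in seq_len(d$nT))
        lp <- lp + dnorm(p$beta[k, tt], p$rho[k], p$omega[k], log = TRUE)
      lp <- lp + dnorm(p$rho[k], 0, sd0, log = TRUE) + dunif(p$omega[k], 0, U, log = TRUE)
    }
  }
  for (tt in seq_len(d$nT)) {
    lp <- lp + dnorm(p$xi_t[tt], 0, sd0, log = TRUE) +
      dunif(p$nu_t[tt], 0, U, log = TRUE) +
      dnorm(p$mu_t[tt], 0, sd0, log = TRUE) +
      dunif(p$sigma_t[tt], 0, U, log = TRUE)
  }
  lp
}

# Fast model config for tests that need a real (small) MCMC fit.
quick_config <- function(seed = 1, chains = 2, iterations = 1200, burnin = 300,
                         ...)
  model_config(chains = chains, iterations = iterations, burnin = burnin,
               seed = seed, ...)

# Look up the true alpha / beta values matching fitted parameter names.
truth_of <- function(parameter, truth) {
  vapply(parameter, function(pn) {
    if (startsWith(pn, "alpha")) {
      v <- strsplit(sub("^alpha\\[(.*)\\]$", "\\1", pn), ".", fixed = TRUE)[[1]]
      truth$alpha[v[1], paste0("p", v[2]), paste0("l", v[3])]
    } else if (grepl("^beta\\[.*,", pn)) {
      v <- strsplit(sub("^beta\\[(.*)\\]$", "\\1", pn), ",", fixed = TRUE)[[1]]
      truth$beta[v[2], v[1]]
    } else NA_real_
  }, 0)
}
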