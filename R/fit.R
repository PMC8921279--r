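#' Fit the weighted-precision hierarchical density model
#'
#' Samples the posterior of the Poisson-lognormal hierarchical model by
#' Metropolis-within-Gibbs: conjugate Gibbs updates for the location
#' parameters (latent-scale intercepts, hierarchy means, and the coefficient
#' block) and adaptive random-walk Metropolis updates for the latent
#' log-densities and the scale/hyper-scale parameters.  Proposal scales
#' adapt during burn-in only.  Chains are initialized at dispersed,
#' data-informed starting points so the Gelman-Rubin diagnostic is
#' meaningful.
#'
#' @param data a [pop_model_data()] (or a data.frame accepted by it).
#' @param config a [model_config()].
#' @param covariates covariate columns, used when `data` is a data.frame.
#' @return object of class `popfit`: posterior draws per chain (including
#'   the derived pooled prediction scale `tau_hat`), the data and config,
#'   convergence summaries, and the posterior mean latent log-densities.
#' @seealso [gelman_rubin()], [predict.popfit()], [decide_effect_mode()]
#' @export
fit_density_model <- function(data, config = model_config(),
                              covariates = c("x1", "x2", "x3")) {
  if (!inherits(data, "pop_model_data"))
    data <- pop_model_data(data, covariates)
  em <- effect_modes(config, data$K)

  chains <- lapply(seq_len(config$chains), function(ch) {
    with_seed((config$seed %% 1000000L) * 1000 + ch, run_chain(data, config, em))
  })
  draws <- lapply(chains, `[[`, "draws")
  logD_mean <- Reduce(`+`, lapply(chains, `[[`, "logD_mean")) / length(chains)
  logD_draws <- if (config$keep_latent) lapply(chains, `[[`, "logD_draws")

  monitored <- monitored_columns(colnames(draws[[1]]), config$monitor)
  rhat <- if (config$chains >= 2)
    gelman_rubin(lapply(draws, function(m) m[, monitored, drop = FALSE]))
  else NULL

  structure(list(draws = draws, data = data, config = config,
                 effect_mode = em, logD_mean = logD_mean,
                 logD_draws = logD_draws,
                 rhat = rhat, monitored = monitored,
                 accept = lapply(chains, `[[`, "accept")),
            class = "popfit")
}

monitored_columns <- function(cols, monitor) {
  fam <- sub("\\[.*$", "", cols)
  cols[fam %in% monitor]
}

#' Stack posterior draws of one parameter across chains
#'
#' @param fit a `popfit`.
#' @param par parameter column name, e.g. `"alpha[rural.1.2]"`; omit to get
#'   the full stacked draw matrix.
#' @return numeric vector (or matrix) of post-burn-in draws, chains stacked.
#' @export
posterior_draws <- function(fit, par = NULL) {
  m <- do.call(rbind, fit$draws)
  if (is.null(par)) return(m)
  check(par %in% colnames(m), paste("unknown parameter:", par))
  m[, par]
}

# ---- sampler internals -----------------------------------------------------

run_chain <- function(d, cfg, em) {
  n <- d$n; K <- d$K; nG <- d$nG; nS <- d$nS; nT <- d$nT
  sd0 <- cfg$prior_sd0; U <- cfg$unif_upper
  sqv <- sqrt(d$v)

  # design matrix for the coefficient block: fixed covariates get one
  # column, random covariates one column per settlement type
  if (K > 0) {
    cols <- list(); b0 <- c(); bmap <- list()
    for (k in seq_len(K)) {
      if (em[k] == "fixed") {
        cols[[length(cols) + 1L]] <- d$X[, k]
        bmap[[length(bmap) + 1L]] <- c(k, 0L)
      } else for (tt in seq_len(nT)) {
        cols[[length(cols) + 1L]] <- d$X[, k] * (d$t == tt)
        bmap[[length(bmap) + 1L]] <- c(k, tt)
      }
    }
    Z <- do.call(cbind, cols)
    nb <- ncol(Z)
    bmap <- do.call(rbind, bmap)   # row: (covariate, type or 0=fixed)
  } else { Z <- matrix(0, n, 0); nb <- 0L; bmap <- NULL }

  # ---- dispersed, data-informed initial values
  Apos <- pmax(d$A, min(d$A[d$A > 0], na.rm = TRUE))
  y <- log((d$N + 0.5) / Apos)
  alpha <- as.vector(rowsum(y, d$g)) / tabulate(d$g, nG) + rnorm(nG, 0, 0.3)
  b <- if (nb > 0) rnorm(nb, 0, 0.1) else numeric(0)
  rho <- rep(0, K); omega <- rep(NA_real_, K)
  omega[em == "random"] <- runif(sum(em == "random"), 0.2, 0.6)
  xi_tp <- as.vector(rowsum(alpha, d$g2s)) / tabulate(d$g2s, nS) + rnorm(nS, 0, 0.2)
  nu_tp <- runif(nS, 0.2, 0.5)
  xi_t <- as.vector(rowsum(xi_tp, d$s2t)) / tabulate(d$s2t, nT) + rnorm(nT, 0, 0.2)
  nu_t <- vapply(seq_len(nT), function(tt) max(nu_tp[d$s2t == tt]), 0) *
    runif(nT, 1.3, 2)
  res <- y - alpha[d$g]
  tau <- vapply(seq_len(nS), function(ss) {
    r <- res[d$s == ss]; max(sd(r) * sqrt(mean(d$v[d$s == ss])), 0.05)
  }, 0) * exp(rnorm(nS, 0, 0.2))
  tau[!is.finite(tau)] <- 0.3
  mu_tp <- tau * exp(rnorm(nS, 0, 0.1))
  sigma_tp <- runif(nS, 0.05, 0.2)
  mu_t <- vapply(seq_len(nT), function(tt) mean(mu_tp[d$s2t == tt]), 0)
  sigma_t <- vapply(seq_len(nT), function(tt) max(sigma_tp[d$s2t == tt]), 0) *
    runif(nT, 1.3, 2)

  beta_of <- function(b) {
    B <- matrix(0, K, nT)
    if (nb > 0) for (j in seq_len(nb)) {
      if (bmap[j, 2] == 0L) B[bmap[j, 1], ] <- b[j]
      else B[bmap[j, 1], bmap[j, 2]] <- b[j]
    }
    B
  }
  xb <- if (nb > 0) as.vector(Z %*% b) else rep(0, n)

  # adaptive proposal scales
  sy <- rep(0.5, n); s_tau <- rep(0.3, nS); s_nutp <- rep(0.4, nS)
  s_nut <- rep(0.5, nT); s_mutp <- rep(0.3, nS); s_sigtp <- rep(0.5, nS)
  s_mut <- rep(0.2, nT); s_sigt <- rep(0.5, nT); s_om <- rep(0.5, K)
  acc <- list(y = 0, tau = 0)
  ay <- rep(0, n); atau <- rep(0, nS); anutp <- rep(0, nS); anut <- rep(0, nT)
  amutp <- rep(0, nS); asigtp <- rep(0, nS); amut <- rep(0, nT)
  asigt <- rep(0, nT); aom <- rep(0, K)
  batch <- 50L

  n_save <- (cfg$iterations - cfg$burnin) %/% cfg$thin
  par_names <- c(
    paste0("alpha[", d$group_labels, "]"),
    if (nb > 0) vapply(seq_len(nb), function(j) {
      if (bmap[j, 2] == 0L) sprintf("beta[%s]", d$covariates[bmap[j, 1]])
      else sprintf("beta[%s,%s]", d$covariates[bmap[j, 1]],
                   d$type_labels[bmap[j, 2]])
    }, ""),
    if (any(em == "random")) paste0("rho[", d$covariates[em == "random"], "]"),
    if (any(em == "random")) paste0("omega[", d$covariates[em == "random"], "]"),
    paste0("xi_tp[", d$stratum_labels, "]"),
    paste0("nu_tp[", d$stratum_labels, "]"),
    paste0("xi_t[", d$type_labels, "]"),
    paste0("nu_t[", d$type_labels, "]"),
    paste0("tau[", d$stratum_labels, "]"),
    paste0("tau_hat[", d$stratum_labels, "]"),
    paste0("mu_tp[", d$stratum_labels, "]"),
    paste0("sigma_tp[", d$stratum_labels, "]"),
    paste0("mu_t[", d$type_labels, "]"),
    paste0("sigma_t[", d$type_labels, "]"))
  out <- matrix(NA_real_, n_save, length(par_names),
                dimnames = list(NULL, par_names))
  logD_sum <- rep(0, n); nsum <- 0L
  logD_draws <- if (cfg$keep_latent) matrix(NA_real_, n_save, n)

  # per-stratum bookkeeping
  n_s <- tabulate(d$s, nS); L_s <- tabulate(d$g2s, nS); P_t <- tabulate(d$s2t, nT)
  sum_sqv_s <- as.vector(rowsum(sqv, d$s))
  irow <- 0L

  for (it in seq_len(cfg$iterations)) {
    W <- d$v / tau[d$s]^2

    # latent log-densities: vectorized random-walk MH
    m <- alpha[d$g] + xb
    prop <- y + rnorm(n) * sy
    logr <- d$N * (prop - y) - d$A * (exp(prop) - exp(y)) -
      0.5 * W * ((prop - m)^2 - (y - m)^2)
    ok <- log(runif(n)) < logr
    y[ok] <- prop[ok]; ay <- ay + ok

    # intercepts: conjugate Gibbs per (t,p,l) group
    r <- y - xb
    prec <- as.vector(rowsum(W, d$g)) + 1 / nu_tp[d$g2s]^2
    mean_g <- (as.vector(rowsum(W * r, d$g)) + xi_tp[d$g2s] / nu_tp[d$g2s]^2) / prec
    alpha <- rnorm(nG, mean_g, 1 / sqrt(prec))

    # coefficient block: conjugate multivariate Gibbs
    if (nb > 0) {
      u <- y - alpha[d$g]
      prior_prec <- numeric(nb); prior_mean <- numeric(nb)
      for (j in seq_len(nb)) {
        if (bmap[j, 2] == 0L) { prior_prec[j] <- 1 / sd0^2; prior_mean[j] <- 0 }
        else { prior_prec[j] <- 1 / omega[bmap[j, 1]]^2
               prior_mean[j] <- rho[bmap[j, 1]] }
      }
      Pm <- crossprod(Z, Z * W); diag(Pm) <- diag(Pm) + prior_prec
      rhs <- crossprod(Z, W * u) + prior_prec * prior_mean
      ch <- chol(Pm)
      b <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE)) +
        backsolve(ch, rnorm(nb))
      b <- as.vector(b)
      xb <- as.vector(Z %*% b)
    }
    B <- beta_of(b)

    # effect hyperparameters (random covariates only)
    for (k in which(em == "random")) {
      pr <- nT / omega[k]^2 + 1 / sd0^2
      rho[k] <- rnorm(1, sum(B[k, ]) / omega[k]^2 / pr, 1 / sqrt(pr))
      ssb <- sum((B[k, ] - rho[k])^2)
      prop_o <- omega[k] * exp(rnorm(1) * s_om[k])
      if (prop_o < U) {
        lr <- (-nT * log(prop_o) - ssb / (2 * prop_o^2)) -
          (-nT * log(omega[k]) - ssb / (2 * omega[k]^2)) +
          log(prop_o) - log(omega[k])
        if (log(runif(1)) < lr) { omega[k] <- prop_o; aom[k] <- aom[k] + 1 }
      }
    }

    # intercept hierarchy
    sum_a <- as.vector(rowsum(alpha, d$g2s))
    pr_s <- L_s / nu_tp^2 + 1 / nu_t[d$s2t]^2
    xi_tp <- rnorm(nS, (sum_a / nu_tp^2 + xi_t[d$s2t] / nu_t[d$s2t]^2) / pr_s,
                   1 / sqrt(pr_s))
    ss_a <- as.vector(rowsum((alpha - xi_tp[d$g2s])^2, d$g2s))
    for (ss in seq_len(nS)) {
      prop_n <- nu_tp[ss] * exp(rnorm(1) * s_nutp[ss])
      if (prop_n < nu_t[d$s2t[ss]]) {
        lr <- (-L_s[ss] * log(prop_n) - ss_a[ss] / (2 * prop_n^2)) -
          (-L_s[ss] * log(nu_tp[ss]) - ss_a[ss] / (2 * nu_tp[ss]^2)) +
          log(prop_n) - log(nu_tp[ss])
        if (log(runif(1)) < lr) { nu_tp[ss] <- prop_n; anutp[ss] <- anutp[ss] + 1 }
      }
    }
    sum_x <- as.vector(rowsum(xi_tp, d$s2t))
    pr_t <- P_t / nu_t^2 + 1 / sd0^2
    xi_t <- rnorm(nT, (sum_x / nu_t^2) / pr_t, 1 / sqrt(pr_t))
    for (tt in seq_len(nT)) {
      ssx <- sum((xi_tp[d$s2t == tt] - xi_t[tt])^2)
      lb <- max(nu_tp[d$s2t == tt])
      prop_n <- nu_t[tt] * exp(rnorm(1) * s_nut[tt])
      if (prop_n > lb && prop_n < U) {
        lr <- (-2 * P_t[tt] * log(prop_n) - ssx / (2 * prop_n^2)) -
          (-2 * P_t[tt] * log(nu_t[tt]) - ssx / (2 * nu_t[tt]^2)) +
          log(prop_n) - log(nu_t[tt])
        # the 2*P_t: P_t normal densities for xi_tp plus P_t U(0, nu_t) priors
        if (log(runif(1)) < lr) { nu_t[tt] <- prop_n; anut[tt] <- anut[tt] + 1 }
      }
    }

    # density scale per stratum
    m <- alpha[d$g] + xb
    ssw <- as.vector(rowsum(d$v * (y - m)^2, d$s))
    for (ss in seq_len(nS)) {
      prop_t <- tau[ss] * exp(rnorm(1) * s_tau[ss])
      lr <- (-n_s[ss] * log(prop_t) - ssw[ss] / (2 * prop_t^2) +
               dhalfnorm(prop_t, mu_tp[ss], sigma_tp[ss], log = TRUE)) -
        (-n_s[ss] * log(tau[ss]) - ssw[ss] / (2 * tau[ss]^2) +
           dhalfnorm(tau[ss], mu_tp[ss], sigma_tp[ss], log = TRUE)) +
        log(prop_t) - log(tau[ss])
      if (is.finite(lr) && log(runif(1)) < lr) {
        tau[ss] <- prop_t; atau[ss] <- atau[ss] + 1
      }
    }

    # precision hyperparameters
    for (ss in seq_len(nS)) {
      tt <- d$s2t[ss]
      prop_m <- mu_tp[ss] * exp(rnorm(1) * s_mutp[ss])
      lr <- (dhalfnorm(tau[ss], prop_m, sigma_tp[ss], log = TRUE) +
               dhalfnorm(prop_m, mu_t[tt], sigma_t[tt], log = TRUE)) -
        (dhalfnorm(tau[ss], mu_tp[ss], sigma_tp[ss], log = TRUE) +
           dhalfnorm(mu_tp[ss], mu_t[tt], sigma_t[tt], log = TRUE)) +
        log(prop_m) - log(mu_tp[ss])
      if (is.finite(lr) && log(runif(1)) < lr) {
        mu_tp[ss] <- prop_m; amutp[ss] <- amutp[ss] + 1
      }
      prop_s <- sigma_tp[ss] * exp(rnorm(1) * s_sigtp[ss])
      if (prop_s < sigma_t[tt]) {
        lr <- dhalfnorm(tau[ss], mu_tp[ss], prop_s, log = TRUE) -
          dhalfnorm(tau[ss], mu_tp[ss], sigma_tp[ss], log = TRUE) +
          log(prop_s) - log(sigma_tp[ss])
        if (is.finite(lr) && log(runif(1)) < lr) {
          sigma_tp[ss] <- prop_s; asigtp[ss] <- asigtp[ss] + 1
        }
      }
    }
    for (tt in seq_len(nT)) {
      sel <- d$s2t == tt
      prop_m <- mu_t[tt] + rnorm(1) * s_mut[tt]
      lr <- (sum(dhalfnorm(mu_tp[sel], prop_m, sigma_t[tt], log = TRUE)) +
               dnorm(prop_m, 0, sd0, log = TRUE)) -
        (sum(dhalfnorm(mu_tp[sel], mu_t[tt], sigma_t[tt], log = TRUE)) +
           dnorm(mu_t[tt], 0, sd0, log = TRUE))
      if (is.finite(lr) && log(runif(1)) < lr) {
        mu_t[tt] <- prop_m; amut[tt] <- amut[tt] + 1
      }
      lb <- max(sigma_tp[sel])
      prop_s <- sigma_t[tt] * exp(rnorm(1) * s_sigt[tt])
      if (prop_s > lb && prop_s < U) {
        lr <- (sum(dhalfnorm(mu_tp[sel], mu_t[tt], prop_s, log = TRUE)) -
                 P_t[tt] * log(prop_s)) -
          (sum(dhalfnorm(mu_tp[sel], mu_t[tt], sigma_t[tt], log = TRUE)) -
             P_t[tt] * log(sigma_t[tt])) +
          log(prop_s) - log(sigma_t[tt])
        if (is.finite(lr) && log(runif(1)) < lr) {
          sigma_t[tt] <- prop_s; asigt[tt] <- asigt[tt] + 1
        }
      }
    }

    # adapt proposal scales during burn-in
    if (it <= cfg$burnin && it %% batch == 0L) {
      g <- function(sc, a, target = 0.3)
        pmin(5, pmax(1e-3, sc * exp(1.5 * (a / batch - target))))
      sy <- g(sy, ay, 0.44); s_tau <- g(s_tau, atau)
      s_nutp <- g(s_nutp, anutp); s_nut <- g(s_nut, anut)
      s_mutp <- g(s_mutp, amutp); s_sigtp <- g(s_sigtp, asigtp)
      s_mut <- g(s_mut, amut); s_sigt <- g(s_sigt, asigt)
      s_om <- g(s_om, aom)
      ay[] <- 0; atau[] <- 0; anutp[] <- 0; anut[] <- 0; amutp[] <- 0
      asigtp[] <- 0; amut[] <- 0; asigt[] <- 0; aom[] <- 0
    }

    if (it > cfg$burnin && (it - cfg$burnin) %% cfg$thin == 0L) {
      irow <- irow + 1L
      tau_hat <- tau * n_s / sum_sqv_s
      bsave <- if (nb > 0) b else numeric(0)
      out[irow, ] <- c(alpha, bsave,
                       if (any(em == "random")) rho[em == "random"],
                       if (any(em == "random")) omega[em == "random"],
                       xi_tp, nu_tp, xi_t, nu_t, tau, tau_hat,
                       mu_tp, sigma_tp, mu_t, sigma_t)
      logD_sum <- logD_sum + y; nsum <- nsum + 1L
      if (cfg$keep_latent) logD_draws[irow, ] <- y
    }
  }

  list(draws = out, logD_mean = logD_sum / max(nsum, 1L),
       logD_draws = logD_draws,
       accept = list(y = mean(ay) / max(1L, cfg$iterations - cfg$burnin)))
}

#' Gelman-Rubin potential scale reduction
#'
#' Classic between/within-chain variance-ratio diagnostic, computed per
#' scalar parameter: `Rhat = sqrt(((n-1)/n * W + B/n) / W)` with `W` the
#' mean within-chain variance and `B/n` the variance of chain means.
#' Parameters with zero total variance across chains report 1.
#'
#' @param draws list of >= 2 chains, each an iterations x parameters matrix
#'   with identical column names.
#' @return named numeric vector of Rhat values.
#' @export
gelman_rubin <- function(draws) {
  check(is.list(draws) && length(draws) >= 2, "need >= 2 chains")
  draws <- lapply(draws, as.matrix)
  niter <- unique(vapply(draws, nrow, 0L))
  check(length(niter) == 1 && niter >= 10, "chains must share >= 10 iterations")
  vapply(seq_len(ncol(draws[[1]])), function(j) {
    ch <- vapply(draws, function(m) m[, j], numeric(niter))  # iter x chain
    W <- mean(apply(ch, 2, var))
    Bn <- var(colMeans(ch))                                  # = B/n
    if (W == 0 && Bn == 0) return(1)
    if (W == 0) return(Inf)
    sqrt(((niter - 1) / niter * W + Bn) / W)
  }, 0) |> setNames(colnames(draws[[1]]))
}
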