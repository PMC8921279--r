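#' Assemble model-ready cluster data
#'
#' Validates and indexes prepared microcensus clusters for the hierarchical
#' density model: population count `N`, footprint area `A` (ha), settlement
#' type / province / local area labels, scaled covariates, and model weights
#' `v` (defaulting to equal weights summing to one, i.e. the unweighted
#' model).  Builds the (type, province, local-area) group and
#' (type, province) stratum index structures the likelihood uses.
#'
#' @param clusters data.frame with columns `N`, `A`, `type`, `province`,
#'   `local_area`, the covariate columns, and optionally `v`.
#' @param covariates names of the scaled covariate columns (may be empty for
#'   an intercept-only model).
#' @return object of class `pop_model_data`.
#' @export
pop_model_data <- function(clusters, covariates = c("x1", "x2", "x3")) {
  need <- c("N", "A", "type", "province", "local_area", covariates)
  check(all(need %in% names(clusters)), paste("missing columns:",
        paste(setdiff(need, names(clusters)), collapse = ", ")))
  check(all(clusters$N >= 0 & clusters$N == round(clusters$N)),
        "N must be non-negative integers")
  check(all(clusters$A >= 0), "A must be non-negative")
  n <- nrow(clusters)
  check(n >= 1, "no clusters")
  v <- if ("v" %in% names(clusters)) clusters$v else rep(1 / n, n)
  check(all(v > 0), "model weights must be positive")

  type <- as.character(clusters$type)
  type_labels <- sort(unique(type))
  t_idx <- match(type, type_labels)
  stratum_labels <- sort(unique(paste(type, clusters$province, sep = ".")))
  s_idx <- match(paste(type, clusters$province, sep = "."), stratum_labels)
  group_labels <- sort(unique(paste(type, clusters$province,
                                    clusters$local_area, sep = ".")))
  g_idx <- match(paste(type, clusters$province, clusters$local_area, sep = "."),
                 group_labels)
  # group -> stratum, stratum -> type maps
  g2s <- s_idx[match(group_labels, paste(type, clusters$province,
                                         clusters$local_area, sep = "."))]
  s2t <- t_idx[match(stratum_labels, paste(type, clusters$province, sep = "."))]

  X <- if (length(covariates)) as.matrix(clusters[, covariates, drop = FALSE])
       else matrix(0, n, 0)
  check(!anyNA(X), "covariates contain NA")

  structure(list(
    clusters = clusters, n = n, N = clusters$N, A = clusters$A, v = v,
    X = X, K = ncol(X), covariates = covariates,
    t = t_idx, s = s_idx, g = g_idx,
    g2s = g2s, s2t = s2t,
    nT = length(type_labels), nS = length(stratum_labels),
    nG = length(group_labels),
    type_labels = type_labels, stratum_labels = stratum_labels,
    group_labels = group_labels,
    coords = if (all(c("x", "y") %in% names(clusters)))
      as.matrix(clusters[, c("x", "y")]) else NULL
  ), class = "pop_model_data")
}

#' Model configuration
#'
#' @param effect_mode `"random"` or `"fixed"`, recycled per covariate, or a
#'   character vector naming the mode of each covariate.  Random effects are
#'   estimated independently by settlement type around a shared mean; fixed
#'   effects are common to both types.
#' @param chains number of MCMC chains (>= 2 for convergence assessment;
#'   default 3).
#' @param iterations total iterations per chain (default 10000).
#' @param burnin burn-in iterations discarded per chain (default 1000).
#' @param thin keep every `thin`-th post-burn-in draw (default 1).
#' @param seed integer seed for the sampler.
#' @param normal_scale2_is_variance interpret the literal `Normal(0, 1000)`
#'   hyperpriors as variance 1000 (default TRUE; FALSE reads 1000 as the sd).
#' @param monitor which parameter families enter convergence summaries;
#'   defaults to the prediction-relevant set.
#' @param keep_latent store the latent per-cluster log-density draws
#'   (memory-hungry; their running posterior mean is always kept).
#' @return object of class `pop_model_config`.
#' @export
model_config <- function(effect_mode = "random", chains = 3L,
                         iterations = 10000L, burnin = 1000L, thin = 1L,
                         seed = 1L, normal_scale2_is_variance = TRUE,
                         monitor = c("alpha", "beta", "tau", "tau_hat", "xi_tp"),
                         keep_latent = FALSE) {
  check(iterations > burnin && burnin >= 0, "need iterations > burnin >= 0")
  check(chains >= 1, "need >= 1 chain")
  stopifnot(all(effect_mode %in% c("random", "fixed")))
  structure(list(effect_mode = effect_mode, chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 prior_sd0 = if (normal_scale2_is_variance) sqrt(1000) else 1000,
                 unif_upper = 1000,
                 monitor = monitor, keep_latent = keep_latent),
            class = "pop_model_config")
}

# per-covariate effect mode vector for data with K covariates
effect_modes <- function(config, K) {
  em <- rep_len(config$effect_mode, K)
  names(em) <- NULL
  em
}

#' Expected log-density of the regression layer
#'
#' `Dbar_i = alpha[t,p,l] + sum_k beta[k, t] x[k, i]`, the linear predictor
#' of the lognormal density layer.  For covariates in fixed mode the rows of
#' `beta` are constant across settlement types.
#'
#' @param params parameter list (see [log_joint()] for the layout).
#' @param data a [pop_model_data()].
#' @return numeric vector `Dbar` over clusters.
#' @export
expected_log_density <- function(params, data) {
  db <- params$alpha[data$g]
  if (data$K > 0)
    db <- db + rowSums(data$X * t(params$beta)[data$t, , drop = FALSE])
  db
}

#' Per-cluster lognormal scale under the weighted-precision rule
#'
#' `scale_i = tau[t,p] / sqrt(v_i)`: the stratum scale inflated for clusters
#' with small model weight, so oversampled clusters carry less likelihood
#' precision.
#'
#' @param tau_tp positive stratum scale (scalar or per-cluster vector).
#' @param v positive model weights.
#' @return per-cluster lognormal (log-scale) standard deviations.
#' @export
effective_scale <- function(tau_tp, v) {
  check(all(v > 0), "model weights must be positive")
  check(all(tau_tp > 0), "tau must be positive")
  tau_tp / sqrt(v)
}

#' Log joint density of the weighted-precision hierarchical model
#'
#' Sum of the Poisson likelihood of the counts given the latent densities,
#' the lognormal layer of the latent densities around the regression mean
#' with weighted precision, and all prior layers (nested normal hierarchy of
#' intercepts, covariate effect hierarchy, half-normal/uniform scale
#' hierarchy).  Returns `-Inf` outside the support.
#'
#' The parameter list layout: `logD` (n), `alpha` (per group), `xi_tp`,
#' `nu_tp`, `tau_tp`, `mu_tp`, `sigma_tp` (per stratum), `xi_t`, `nu_t`,
#' `mu_t`, `sigma_t` (per type), `beta` (K x nT matrix; fixed rows constant),
#' `rho`, `omega` (per random covariate, NA for fixed ones).
#'
#' @param params parameter list.
#' @param data a [pop_model_data()].
#' @param config a [model_config()].
#' @return scalar log joint density.
#' @export
log_joint <- function(params, data, config = model_config()) {
  p <- params; d <- data
  em <- effect_modes(config, d$K)
  sd0 <- config$prior_sd0; U <- config$unif_upper

  # support checks
  if (any(!is.finite(p$logD)) || any(!is.finite(p$alpha))) return(-Inf)
  if (any(p$tau_tp <= 0) || any(p$nu_tp <= 0) || any(p$nu_t <= 0) ||
      any(p$sigma_tp <= 0) || any(p$sigma_t <= 0) || any(p$mu_tp < 0))
    return(-Inf)
  if (any(p$nu_tp > p$nu_t[d$s2t]) || any(p$nu_t > U)) return(-Inf)
  if (any(p$sigma_tp > p$sigma_t[d$s2t]) || any(p$sigma_t > U)) return(-Inf)
  if (d$K > 0) {
    if (any(em == "random")) {
      r <- which(em == "random")
      if (any(p$omega[r] <= 0) || any(p$omega[r] > U)) return(-Inf)
    }
    if (any(em == "fixed")) {
      f <- which(em == "fixed")
      if (any(abs(p$beta[f, , drop = FALSE] - p$beta[f, 1]) > 0))
        return(-Inf)                      # fixed rows must be constant
    }
  }

  D <- exp(p$logD)
  lp <- sum(dpois(d$N, D * d$A, log = TRUE))
  if (!is.finite(lp)) return(-Inf)

  dbar <- expected_log_density(p, d)
  sc <- effective_scale(p$tau_tp[d$s], d$v)
  lp <- lp + sum(dnorm(p$logD, dbar, sc, log = TRUE))

  # intercept hierarchy
  lp <- lp + sum(dnorm(p$alpha, p$xi_tp[d$g2s], p$nu_tp[d$g2s], log = TRUE))
  lp <- lp + sum(dnorm(p$xi_tp, p$xi_t[d$s2t], p$nu_t[d$s2t], log = TRUE))
  lp <- lp - sum(log(p$nu_t[d$s2t]))          # nu_tp ~ U(0, nu_t)
  lp <- lp + sum(dnorm(p$xi_t, 0, sd0, log = TRUE))
  lp <- lp - d$nT * log(U)                    # nu_t ~ U(0, 1000)

  # covariate effects
  if (d$K > 0) {
    for (k in seq_len(d$K)) {
      if (em[k] == "fixed") {
        lp <- lp + dnorm(p$beta[k, 1], 0, sd0, log = TRUE)
      } else {
        lp <- lp + sum(dnorm(p$beta[k, ], p$rho[k], p$omega[k], log = TRUE))
        lp <- lp + dnorm(p$rho[k], 0, sd0, log = TRUE) - log(U)
      }
    }
  }

  # precision hierarchy
  lp <- lp + sum(dhalfnorm(p$tau_tp, p$mu_tp, p$sigma_tp, log = TRUE))
  lp <- lp + sum(dhalfnorm(p$mu_tp, p$mu_t[d$s2t], p$sigma_t[d$s2t], log = TRUE))
  lp <- lp - sum(log(p$sigma_t[d$s2t]))       # sigma_tp ~ U(0, sigma_t)
  lp <- lp + sum(dnorm(p$mu_t, 0, sd0, log = TRUE))
  lp <- lp - d$nT * log(U)                    # sigma_t ~ U(0, 1000)
  lp
}

#' Decide fixed versus random mode for each covariate effect
#'
#' A covariate's settlement-type random effects are converted to a fixed
#' effect when their posteriors are similar across types; the operational
#' criterion is that the 95% credible interval of the between-type contrast
#' `beta[k, urban] - beta[k, rural]` contains zero.
#'
#' @param fit a `popfit` fitted with `effect_mode = "random"` (or a K-list of
#'   two-column draw matrices, columns = settlement types).
#' @param level credible level for the contrast interval, default 0.95.
#' @return data.frame: covariate, contrast CI bounds, decided mode.
#' @export
decide_effect_mode <- function(fit, level = 0.95) {
  draws <- if (inherits(fit, "popfit")) {
    d <- fit$data
    check(d$nT == 2, "effect-mode decision needs two settlement types")
    lapply(seq_len(d$K), function(k) {
      cbind(posterior_draws(fit, sprintf("beta[%s,%s]", d$covariates[k],
                                         d$type_labels[1])),
            posterior_draws(fit, sprintf("beta[%s,%s]", d$covariates[k],
                                         d$type_labels[2])))
    })
  } else fit
  check(length(draws) >= 1, "no effect draws")
  a <- (1 - level) / 2
  rows <- lapply(seq_along(draws), function(k) {
    m <- draws[[k]]
    check(is.matrix(m) && ncol(m) == 2 && nrow(m) >= 2, "missing draws")
    diff <- m[, 2] - m[, 1]
    ci <- unname(quantile(diff, c(a, 1 - a)))
    data.frame(covariate = k, lower = ci[1], upper = ci[2],
               mode = if (ci[1] <= 0 && ci[2] >= 0) "fixed" else "random")
  })
  out <- do.call(rbind, rows)
  if (inherits(fit, "popfit")) out$covariate <- fit$data$covariates
  out
}
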