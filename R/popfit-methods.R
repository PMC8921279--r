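#' @export
print.popfit <- function(x, ...) {
  d <- x$data
  cat("Weighted-precision hierarchical population density model\n")
  cat(sprintf("  clusters: %d   settlement types: %d   strata: %d   local areas: %d\n",
              d$n, d$nT, d$nS, d$nG))
  cat(sprintf("  covariates: %s\n",
              if (d$K) paste(sprintf("%s (%s)", d$covariates, x$effect_mode),
                             collapse = ", ") else "none (intercept-only)"))
  cat(sprintf("  chains: %d   post-burn-in draws/chain: %d\n",
              x$config$chains, nrow(x$draws[[1]])))
  if (!is.null(x$rhat))
    cat(sprintf("  max Gelman-Rubin Rhat (monitored): %.3f\n", max(x$rhat)))
  invisible(x)
}

#' Posterior summary of a fitted density model
#'
#' @param object a `popfit`.
#' @param level credible level, default 0.95.
#' @param ... unused.
#' @return data.frame with posterior mean, sd, credible bounds, and Rhat for
#'   each monitored parameter.
#' @export
summary.popfit <- function(object, level = 0.95, ...) {
  m <- posterior_draws(object)[, object$monitored, drop = FALSE]
  a <- (1 - level) / 2
  out <- data.frame(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, sd),
    lower = apply(m, 2, quantile, a),
    upper = apply(m, 2, quantile, 1 - a),
    rhat = if (!is.null(object$rhat)) object$rhat[colnames(m)] else NA_real_,
    row.names = NULL)
  class(out) <- c("summary.popfit", "data.frame")
  out
}

#' @export
print.summary.popfit <- function(x, digits = 3, ...) {
  cat("Posterior summary (monitored parameters)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Posterior-mean coefficients
#'
#' @param object a `popfit`.
#' @param ... unused.
#' @return named vector of posterior means for the intercepts and effects.
#' @export
coef.popfit <- function(object, ...) {
  m <- posterior_draws(object)
  keep <- grepl("^(alpha|beta)\\[", colnames(m))
  colMeans(m[, keep, drop = FALSE])
}

#' In-sample posterior-predictive residuals
#'
#' Residual = posterior-mean predicted count minus observed count, with the
#' prediction drawn from the pooled-precision predictive distribution (the
#' same distribution used for unsurveyed locations).
#'
#' @param object a `popfit`.
#' @param n_draws posterior draws used, default 2000.
#' @param seed RNG seed for the predictive draws.
#' @param ... unused.
#' @return numeric vector of residuals (one per cluster).
#' @export
residuals.popfit <- function(object, n_draws = 2000, seed = 1L, ...) {
  pp <- posterior_predict(object, newdata = object$data$clusters,
                          n_draws = n_draws, seed = seed)
  rowMeans(pp$N) - object$data$N
}

#' Simulate from the posterior predictive distribution
#'
#' @param object a `popfit`.
#' @param nsim number of posterior-predictive draws.
#' @param seed RNG seed.
#' @param ... unused.
#' @return matrix clusters x nsim of simulated counts.
#' @export
simulate.popfit <- function(object, nsim = 100, seed = 1L, ...) {
  posterior_predict(object, newdata = object$data$clusters,
                    n_draws = nsim, seed = seed)$N
}

#' Observed versus predicted plot
#'
#' @param x a `popfit`.
#' @param n_draws posterior draws for the predictive intervals.
#' @param seed RNG seed.
#' @param log axes on the log scale (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @export
plot.popfit <- function(x, n_draws = 1000, seed = 1L, log = TRUE, ...) {
  pp <- posterior_predict(x, newdata = x$data$clusters,
                          n_draws = n_draws, seed = seed)
  obs <- x$data$N
  pm <- rowMeans(pp$N)
  lo <- apply(pp$N, 1, quantile, 0.025)
  hi <- apply(pp$N, 1, quantile, 0.975)
  lg <- if (log) "xy" else ""
  off <- if (log) 1 else 0
  plot(obs + off, pm + off, log = lg,
       xlab = "observed population (people/cluster)",
       ylab = "mean posterior prediction", pch = 16,
       col = c("turquoise3", "deeppink3")[x$data$t], ...)
  segments(obs + off, lo + off, obs + off, hi + off,
           col = adjustcolor("grey50", 0.5))
  abline(0, 1, lwd = 1.5)
  invisible(x)
}
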