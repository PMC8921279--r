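#' k-fold cross-validation of the density model
#'
#' Partitions the clusters into `k` folds (stratified by (type, province) so
#' no stratum is ever emptied from a training set where its size allows),
#' refits the model `k` times, and predicts each held-out cluster from the
#' fit that excluded it, using the pooled stratum scale for the held-out
#' precision.  Model weights are renormalized within each training set.
#'
#' @param data a [pop_model_data()] (or a data.frame accepted by it).
#' @param config a [model_config()]; each fold fit uses `config` as-is.
#' @param k number of folds, default 10.
#' @param seed seed for the fold assignment.
#' @param n_draws posterior-predictive draws per held-out cluster.
#' @param covariates covariate columns when `data` is a data.frame.
#' @return object of class `popcv`: `observed` (counts), `observed_density`,
#'   `N` and `D` (cluster x draw predictive matrices), `fold` assignment.
#' @export
crossvalidate <- function(data, config = model_config(), k = 10, seed = 1L,
                          n_draws = 1000, covariates = c("x1", "x2", "x3")) {
  if (!inherits(data, "pop_model_data"))
    data <- pop_model_data(data, covariates)
  n <- data$n
  check(k >= 2 && n >= k, "need 2 <= k <= number of clusters")
  fold <- with_seed(seed, {
    f <- integer(n)
    for (s in unique(data$s)) {        # stratified round-robin assignment
      idx <- sample(which(data$s == s))
      f[idx] <- rep_len(sample(k), length(idx))
    }
    f
  })
  Nout <- matrix(NA_real_, n, n_draws); Dout <- matrix(NA_real_, n, n_draws)
  cl <- data$clusters
  for (fk in sort(unique(fold))) {
    train <- cl[fold != fk, , drop = FALSE]
    test <- cl[fold == fk, , drop = FALSE]
    train$v <- data$v[fold != fk] / sum(data$v[fold != fk])
    fit <- fit_density_model(pop_model_data(train, data$covariates), config)
    pp <- posterior_predict(fit, test, n_draws = n_draws,
                            seed = seed + fk)
    Nout[fold == fk, seq_len(ncol(pp$N))] <- pp$N
    Dout[fold == fk, seq_len(ncol(pp$D))] <- pp$D
  }
  keep <- !colSums(is.na(Nout)) > 0
  structure(list(observed = data$N,
                 observed_density = data$N / data$A,
                 N = Nout[, keep, drop = FALSE],
                 D = Dout[, keep, drop = FALSE],
                 fold = fold, k = k, seed = seed),
            class = "popcv")
}

#' Hold-out validation of province age-sex proportions
#'
#' Withholds a fraction of clusters per province, refits the
#' Dirichlet-multinomial model on the remaining individuals, and compares
#' the held-out empirical proportions with the posterior.
#'
#' @param individuals individual records (see [aggregate_agesex()]) with a
#'   `cluster` column.
#' @param frac fraction of clusters withheld per province, default 0.1.
#' @param n_draws posterior draws.
#' @param seed RNG seed.
#' @return list: `observed` held-out proportions, `pred` (the `agesex_fit`
#'   on the training individuals), `metrics` via [residual_metrics()].
#' @export
crossvalidate_agesex <- function(individuals, frac = 0.1, n_draws = 2000,
                                 seed = 1L) {
  with_seed(seed, {
    cp <- unique(individuals[, c("cluster", "province")])
    held <- unlist(lapply(split(cp$cluster, cp$province),
                          function(cls) sample(cls, max(1, round(frac * length(cls))))))
    test <- individuals[individuals$cluster %in% held, , drop = FALSE]
    train <- individuals[!individuals$cluster %in% held, , drop = FALSE]
    fitas <- fit_agesex(aggregate_agesex(train), n_draws = n_draws,
                        seed = seed + 1L)
    obs_tab <- agesex_count_matrix(aggregate_agesex(test))
    obs_tab <- obs_tab[agesex_fit_order(fitas, rownames(obs_tab)),
                       fitas$provinces, drop = FALSE]
    obs_prop <- sweep(obs_tab, 2, colSums(obs_tab), "/")
    draws <- matrix(aperm(fitas$draws, c(2, 3, 1)),
                    nrow = length(fitas$groups) * length(fitas$provinces))
    metrics <- residual_metrics(as.vector(obs_prop), draws)
    list(observed = obs_prop, pred = fitas, metrics = metrics)
  })
}

agesex_fit_order <- function(fit, have) match(fit$groups, have)

#' Residual goodness-of-fit metrics
#'
#' Residual = posterior-mean prediction minus observed.  Reports bias (mean
#' residual), imprecision (standard deviation of residuals, population
#' form), inaccuracy (mean absolute residual), `R^2` (squared Pearson
#' correlation of observed versus posterior-mean predicted by default; the
#' literal correlation-of-residuals variant via `r2_on = "residuals"`), and
#' the percentage of observations inside the central 95% prediction
#' interval.  Scaled companions divide residuals by the predictions.
#'
#' @param observed numeric vector.
#' @param pred_draws matrix (observations x draws) of predictive draws.
#' @param level prediction-interval level, default 0.95.
#' @param r2_on `"predictions"` (conventional) or `"residuals"` (literal).
#' @return one-row data.frame of metrics (coverage in percent).
#' @export
residual_metrics <- function(observed, pred_draws, level = 0.95,
                             r2_on = c("predictions", "residuals")) {
  r2_on <- match.arg(r2_on)
  check(length(observed) >= 3, "need >= 3 observations")
  pred_draws <- as.matrix(pred_draws)
  check(nrow(pred_draws) == length(observed),
        "pred_draws rows must match observations")
  pm <- rowMeans(pred_draws)
  res <- pm - observed
  a <- (1 - level) / 2
  lo <- apply(pred_draws, 1, quantile, a)
  hi <- apply(pred_draws, 1, quantile, 1 - a)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  r2 <- if (sd(observed) == 0) {
    warning("zero-variance observations: R^2 undefined")
    NA_real_
  } else if (r2_on == "predictions") cor(observed, pm)^2
  else if (sd(res) == 0) NA_real_ else cor(observed, res)^2
  sres <- res / pm
  data.frame(bias = mean(res), imprecision = pop_sd(res),
             inaccuracy = mean(abs(res)), r2 = r2,
             coverage = 100 * mean(observed >= lo & observed <= hi),
             bias_scaled = mean(sres), imprecision_scaled = pop_sd(sres),
             inaccuracy_scaled = mean(abs(sres)))
}

#' Diagnostics report for a cross-validated model
#'
#' @param cv a `popcv` from [crossvalidate()].
#' @param ... passed to [residual_metrics()].
#' @return data.frame with one row per estimate type (totals, densities).
#' @export
cv_metrics <- function(cv, ...) {
  tot <- residual_metrics(cv$observed, cv$N, ...)
  den <- residual_metrics(cv$observed_density, cv$D, ...)
  cbind(estimate = c("population totals", "population densities"),
        rbind(tot, den))
}

#' Moran's I spatial autocorrelation test
#'
#' Global Moran's I with row-standardized inverse-distance weights and a
#' permutation p-value (two-sided around the permutation mean), plus a
#' normal approximation from the permutation moments.
#'
#' @param residuals numeric vector (non-constant).
#' @param coords matrix/data.frame of point coordinates (metres).
#' @param nperm permutations for the p-value, default 999.
#' @param seed RNG seed for the permutations.
#' @return list: `I`, `expected` (-1/(n-1)), `p_perm`, `p_norm`, `nperm`.
#' @export
morans_i <- function(residuals, coords, nperm = 999, seed = 1L) {
  n <- length(residuals)
  check(n >= 8, "need >= 8 locations")
  check(sd(residuals) > 0, "constant residuals: Moran's I undefined")
  coords <- as.matrix(coords)
  dm <- as.matrix(dist(coords))
  check(all(dm[upper.tri(dm)] > 0), "coincident points give infinite weights")
  W <- 1 / dm; diag(W) <- 0
  W <- W / rowSums(W)
  stat <- function(z) {
    zc <- z - mean(z)
    (n / sum(W)) * sum(W * outer(zc, zc)) / sum(zc^2)
  }
  I <- stat(residuals)
  perm <- with_seed(seed,
                    vapply(seq_len(nperm), function(i) stat(sample(residuals)), 0))
  ctr <- mean(perm)
  p_perm <- (1 + sum(abs(perm - ctr) >= abs(I - ctr))) / (nperm + 1)
  z <- (I - ctr) / sd(perm)
  list(I = I, expected = -1 / (n - 1), p_perm = p_perm,
       p_norm = 2 * pnorm(-abs(z)), nperm = nperm)
}

#' Empirical semivariogram
#'
#' `gamma(h) = mean(squared differences) / 2` over point pairs whose
#' separation falls in each distance bin; pair counts are reported and
#' empty bins are NA.
#'
#' @param residuals numeric vector.
#' @param coords matrix/data.frame of coordinates.
#' @param breaks bin boundaries (metres), or a single bin count over the
#'   observed distance range (default 10 bins).
#' @return data.frame: bin midpoint `h`, semivariance `gamma`, pair count
#'   `np`.
#' @export
semivariogram <- function(residuals, coords, breaks = 10) {
  coords <- as.matrix(coords)
  dm <- as.matrix(dist(coords))
  dd <- dm[upper.tri(dm)]
  sq <- outer(residuals, residuals, "-")^2
  sqd <- sq[upper.tri(sq)]
  if (length(breaks) == 1)
    breaks <- seq(0, max(dd), length.out = breaks + 1)
  check(length(breaks) >= 3, "need >= 2 lag bins")
  bin <- cut(dd, breaks, include.lowest = TRUE)
  gamma <- tapply(sqd, bin, function(v) mean(v) / 2)
  np <- tapply(sqd, bin, length)
  np[is.na(np)] <- 0
  data.frame(h = (head(breaks, -1) + tail(breaks, -1)) / 2,
             gamma = as.numeric(gamma), np = as.integer(np))
}
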