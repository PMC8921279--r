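#' Fit the Dirichlet-multinomial age-sex model
#'
#' Province-level counts over the 36 age-sex groups are modelled as
#' Multinomial with proportions on the simplex; the uninformative conjugate
#' Dirichlet prior with concentration `1/G` per group gives the exact
#' posterior `Dirichlet(1/G + counts)`, sampled directly (no MCMC needed).
#'
#' @param counts an `agesex_table` from [aggregate_agesex()], or a G x P
#'   matrix of counts (rows = groups, columns = provinces).
#' @param n_draws posterior draws per province, default 10000.
#' @param seed RNG seed.
#' @return object of class `agesex_fit`: `draws` (array n_draws x G x P),
#'   `mean`, `lower`, `upper` (G x P), `counts`, `groups`, `provinces`.
#' @export
fit_agesex <- function(counts, n_draws = 10000, seed = 1L) {
  cm <- agesex_count_matrix(counts)
  G <- nrow(cm); P <- ncol(cm)
  check(all(cm >= 0), "counts must be non-negative")
  tot <- colSums(cm)
  if (any(tot == 0))
    stop("province(s) with zero total count: ",
         paste(colnames(cm)[tot == 0], collapse = ", "))
  with_seed(seed, {
    draws <- array(NA_real_, c(n_draws, G, P),
                   dimnames = list(NULL, rownames(cm), colnames(cm)))
    for (p in seq_len(P))
      draws[, , p] <- rdirichlet(n_draws,
                                 matrix(1 / G + cm[, p], nrow = 1)[rep(1, n_draws), ])
    structure(list(
      draws = draws,
      mean = apply(draws, c(2, 3), mean),
      lower = apply(draws, c(2, 3), quantile, 0.025),
      upper = apply(draws, c(2, 3), quantile, 0.975),
      counts = cm, groups = rownames(cm), provinces = colnames(cm),
      n_draws = n_draws, seed = seed
    ), class = "agesex_fit")
  })
}

#' Closed-form Dirichlet posterior moments
#'
#' Analytic mean and variance of the conjugate posterior
#' `Dirichlet(1/G + counts)`: mean `(N_g + 1/G) / (N_p + 1)`, the standard
#' Dirichlet moments.  Serves as the exact oracle for [fit_agesex()].
#'
#' @param counts as in [fit_agesex()].
#' @return list of G x P matrices `mean` and `var`.
#' @export
closed_form_summary <- function(counts) {
  cm <- agesex_count_matrix(counts)
  G <- nrow(cm)
  a <- cm + 1 / G
  a0 <- rep(colSums(a), each = G)
  m <- a / a0
  v <- m * (1 - m) / (a0 + 1)
  dimnames(v) <- dimnames(cm)
  list(mean = m, var = v)
}

agesex_count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  check(inherits(counts, "agesex_table") ||
          all(c("province", "sex", "age_group", "count") %in% names(counts)),
        "counts must be an agesex_table or a matrix")
  grp <- paste(counts$sex, counts$age_group, sep = ".")
  glev <- unique(grp)
  plev <- unique(counts$province)
  cm <- matrix(0, length(glev), length(plev),
               dimnames = list(glev, as.character(plev)))
  cm[cbind(match(grp, glev), match(as.character(counts$province), plev))] <-
    counts$count
  cm
}

#' @export
print.agesex_fit <- function(x, ...) {
  cat(sprintf("Dirichlet-multinomial age-sex posterior: %d groups x %d provinces, %d draws\n",
              length(x$groups), length(x$provinces), x$n_draws))
  invisible(x)
}

#' Population pyramid of posterior age-sex proportions
#'
#' @param x an `agesex_fit`.
#' @param province province to plot (name or index), default the first.
#' @param ... unused.
#' @export
plot.agesex_fit <- function(x, province = 1, ...) {
  p <- if (is.numeric(province)) x$provinces[province] else province
  m <- x$mean[, p]; lo <- x$lower[, p]; hi <- x$upper[, p]
  male <- grepl("^male", x$groups)
  labs <- sub("^(male|female)\\.", "", x$groups[male])
  nbin <- sum(male)
  xm <- -m[male]; xf <- m[!male]
  xlim <- range(c(-hi[male], hi[!male]))
  plot(NULL, xlim = xlim, ylim = c(0.5, nbin + 0.5), yaxt = "n",
       xlab = "proportion of the population", ylab = "",
       main = paste("age-sex structure,", p))
  axis(2, at = seq_len(nbin), labels = labs, las = 1, cex.axis = 0.6)
  rect(0, seq_len(nbin) - 0.4, xm, seq_len(nbin) + 0.4, col = "steelblue")
  rect(0, seq_len(nbin) - 0.4, xf, seq_len(nbin) + 0.4, col = "salmon")
  segments(-hi[male], seq_len(nbin), -lo[male], seq_len(nbin))
  segments(lo[!male], seq_len(nbin), hi[!male], seq_len(nbin))
  abline(v = 0)
  invisible(x)
}
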