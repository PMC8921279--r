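#' Pooled prediction-scale estimate per stratum
#'
#' The per-cluster weighted-precision scales cannot be formed where no model
#' weight exists (every unsurveyed location), so predictions use a pooled
#' stratum scale: the sqrt(v)-weighted average of the per-cluster scales
#' `tau[t,p]/sqrt(v_i)` over the clusters of the stratum, computed per
#' posterior draw.
#'
#' @param tau_draws numeric matrix of posterior draws of `tau[t,p]`
#'   (draws x strata) or a vector for a single stratum.
#' @param v model weights of the training clusters.
#' @param stratum stratum index (column of `tau_draws`) per training cluster.
#' @return matrix (draws x strata) of pooled scales `tau_hat[t,p]`.
#' @export
pooled_precision <- function(tau_draws, v, stratum) {
  if (is.vector(tau_draws)) tau_draws <- matrix(tau_draws, ncol = 1)
  check(length(v) == length(stratum), "v and stratum must align")
  check(all(v > 0), "model weights must be positive")
  out <- tau_draws
  for (s in seq_len(ncol(tau_draws))) {
    sv <- sqrt(v[stratum == s])
    check(length(sv) >= 1, "stratum with no clusters")
    num <- 0
    for (s1 in sv) num <- num + (tau_draws[, s] / s1) * s1
    out[, s] <- num / sum(sv)
  }
  out
}

# Posterior-predictive draws for arbitrary zones (cells or clusters).
# Returns list(N = zones x draws counts, D = zones x draws densities,
# idx = posterior draw indices used).
posterior_predict <- function(fit, newdata, n_draws = 1000, seed = 1L) {
  d <- fit$data
  m <- posterior_draws(fit)
  total <- nrow(m)
  idx <- if (n_draws >= total) seq_len(total)
         else round(seq(1, total, length.out = n_draws))
  m <- m[idx, , drop = FALSE]
  nd <- nrow(m)

  type <- as.character(newdata$type)
  glab <- paste(type, newdata$province, newdata$local_area, sep = ".")
  slab <- paste(type, newdata$province, sep = ".")
  gi <- match(glab, d$group_labels)
  si <- match(slab, d$stratum_labels)
  ti <- match(type, d$type_labels)
  check(!anyNA(ti), "settlement type absent from the fitted model")

  A <- newdata$A
  X <- if (d$K > 0) as.matrix(newdata[, d$covariates, drop = FALSE])
       else matrix(0, nrow(newdata), 0)
  nz <- nrow(newdata)

  alpha_cols <- match(paste0("alpha[", d$group_labels, "]"), colnames(m))
  tau_hat_cols <- match(paste0("tau_hat[", d$stratum_labels, "]"), colnames(m))
  xi_cols <- match(paste0("xi_tp[", d$stratum_labels, "]"), colnames(m))
  nu_cols <- match(paste0("nu_tp[", d$stratum_labels, "]"), colnames(m))
  xit_cols <- match(paste0("xi_t[", d$type_labels, "]"), colnames(m))
  nut_cols <- match(paste0("nu_t[", d$type_labels, "]"), colnames(m))

  # beta draws organized as draws x K x T
  Bd <- array(0, c(nd, d$K, d$nT))
  if (d$K > 0) for (k in seq_len(d$K)) {
    nm_f <- sprintf("beta[%s]", d$covariates[k])
    if (nm_f %in% colnames(m)) {
      for (tt in seq_len(d$nT)) Bd[, k, tt] <- m[, nm_f]
    } else for (tt in seq_len(d$nT))
      Bd[, k, tt] <- m[, sprintf("beta[%s,%s]", d$covariates[k],
                                 d$type_labels[tt])]
  }

  unseen_groups <- unique(glab[is.na(gi) & A > 0])
  if (length(unseen_groups))
    message("prediction: intercept drawn from the stratum level for unseen group(s): ",
            paste(unseen_groups, collapse = ", "))

  with_seed(seed, {
    # per-draw intercepts for unseen groups, one draw per (group, draw)
    extra <- list()
    for (ug in unseen_groups) {
      us <- match(sub("^([^.]+\\.[^.]+)\\..*$", "\\1", ug), d$stratum_labels)
      extra[[ug]] <- if (!is.na(us))
        rnorm(nd, m[, xi_cols[us]], m[, nu_cols[us]])
      else {
        ut <- match(sub("\\..*$", "", ug), d$type_labels)
        rnorm(nd, m[, xit_cols[ut]], m[, nut_cols[ut]])
      }
    }

    # pooled scale per draw; strata absent from training fall back to the
    # sqrt(v)-weighted type-level pool
    tauhat_type <- matrix(NA_real_, nd, d$nT)
    if (anyNA(si)) {
      sv <- sqrt(d$v)
      for (tt in seq_len(d$nT)) {
        sel <- which(d$t == tt)
        if (!length(sel)) next
        # weighted average of per-cluster scales tau_s(i)/sqrt(v_i) with
        # weights sqrt(v_i), over every cluster of this settlement type
        tau_cl <- m[, match(paste0("tau[", d$stratum_labels[d$s[sel]], "]"),
                            colnames(m)), drop = FALSE]
        tauhat_type[, tt] <- rowSums(tau_cl) / sum(sv[sel])
      }
      message("prediction: pooled scale fell back to the settlement-type level for stratum(s) absent from training")
    }

    Nmat <- matrix(0, nz, nd)
    Dmat <- matrix(0, nz, nd)
    settled <- which(A > 0)
    for (j in settled) {
      a_j <- if (!is.na(gi[j])) m[, alpha_cols[gi[j]]] else extra[[glab[j]]]
      db <- a_j
      if (d$K > 0)
        db <- db + as.vector(matrix(Bd[, , ti[j]], nrow = nd) %*% X[j, ])
      th <- if (!is.na(si[j])) m[, tau_hat_cols[si[j]]] else tauhat_type[, ti[j]]
      Dd <- exp(rnorm(nd, db, th))
      Nmat[j, ] <- rpois(nd, Dd * A[j])
      Dmat[j, ] <- Dd
    }
    list(N = Nmat, D = Dmat, idx = idx)
  })
}

#' Posterior-predictive gridded population estimates
#'
#' For each posterior draw and settled grid cell, draws a density from the
#' lognormal layer with the pooled stratum scale and a count from the
#' Poisson layer, then summarizes over draws.  Cells with zero footprint
#' area are exactly zero.
#'
#' @param object a `popfit`.
#' @param newdata a `study_grid` (or data.frame of cells with `A`, `type`,
#'   `province`, `local_area`, and the covariate columns scaled with the
#'   training constants).
#' @param n_draws posterior draws to propagate, default 1000.
#' @param seed RNG seed.
#' @param keep_draws keep the cells x draws count matrix (needed for exact
#'   polygon aggregation and age-sex disaggregation).
#' @param ... unused.
#' @return object of class `pop_prediction`: `summary` data.frame (per cell:
#'   posterior mean, median, 2.5% and 97.5% quantiles of people/cell) and,
#'   if requested, the per-draw count matrix `draws`.
#' @export
predict.popfit <- function(object, newdata, n_draws = 1000, seed = 1L,
                           keep_draws = FALSE, ...) {
  nd <- as.data.frame(newdata)
  nd$A[is.na(nd$A)] <- 0
  # unsettled cells carry NA labels; park them in placeholder levels,
  # their prediction is identically zero anyway
  blank <- nd$A <= 0 | is.na(nd$type)
  if (any(blank)) {
    nd$A[blank] <- 0
    nd$type[blank] <- object$data$type_labels[1]
    nd$local_area[blank] <- -1L
    for (cv in object$data$covariates) nd[[cv]][blank] <- 0
  }
  pp <- posterior_predict(object, nd, n_draws = n_draws, seed = seed)
  s <- data.frame(
    cell = if (!is.null(nd$cell)) nd$cell else seq_len(nrow(nd)),
    mean = rowMeans(pp$N),
    median = apply(pp$N, 1, median),
    lower = apply(pp$N, 1, quantile, 0.025),
    upper = apply(pp$N, 1, quantile, 0.975))
  structure(list(summary = s,
                 draws = if (keep_draws) pp$N,
                 density_draws = if (keep_draws) pp$D,
                 n_draws = ncol(pp$N), seed = seed,
                 province = nd$province),
            class = "pop_prediction")
}

#' @export
print.pop_prediction <- function(x, ...) {
  cat(sprintf("Gridded posterior-predictive population estimates: %d cells, %d draws\n",
              nrow(x$summary), x$n_draws))
  cat(sprintf("  total (posterior mean of the grid sum): %.0f people\n",
              if (!is.null(x$draws)) mean(colSums(x$draws))
              else sum(x$summary$mean)))
  invisible(x)
}

#' Disaggregate gridded count draws into age-sex groups
#'
#' Multiplies each cell's per-draw count by the province's age-sex
#' proportion draw, aligning posterior draws by index, so the group-level
#' uncertainty reflects both sources.
#'
#' @param prediction a `pop_prediction` with `keep_draws = TRUE`.
#' @param agesex an `agesex_fit`.
#' @param groups group names to report (default all 36).
#' @return list per group: data.frame of per-cell mean, lower, upper.
#' @export
apply_agesex <- function(prediction, agesex, groups = NULL) {
  check(!is.null(prediction$draws), "prediction must keep draws")
  prov <- as.character(prediction$province)
  check(!is.null(prov), "prediction lacks province labels")
  miss <- setdiff(unique(prov), agesex$provinces)
  check(length(miss) == 0,
        paste("province(s) without fitted age-sex proportions:",
              paste(miss, collapse = ", ")))
  if (is.null(groups)) groups <- agesex$groups
  nd <- ncol(prediction$draws)
  check(agesex$n_draws >= nd, "fewer age-sex draws than count draws")
  pi_idx <- seq_len(nd)
  pj <- match(prov, agesex$provinces)
  out <- lapply(groups, function(g) {
    gk <- match(g, agesex$groups)
    pig <- agesex$draws[pi_idx, gk, , drop = TRUE]   # nd x P
    if (is.null(dim(pig))) pig <- matrix(pig, ncol = 1)
    w <- t(pig)[pj, , drop = FALSE]                  # cells x nd
    gd <- prediction$draws * w
    data.frame(cell = prediction$summary$cell,
               mean = rowMeans(gd),
               lower = apply(gd, 1, quantile, 0.025),
               upper = apply(gd, 1, quantile, 0.975))
  })
  names(out) <- groups
  out
}

#' Aggregate per-draw cell counts within polygons
#'
#' Sums the per-draw cell counts within each zone and summarizes the sums
#' over draws, so credible intervals are intervals of totals (sums commute
#' with draws, not with quantiles).  Zones may be given as a factor over
#' cells or derived from rectangular polygons by cell-center containment
#' via [rectangles_to_zones()].
#'
#' @param prediction a `pop_prediction` with `keep_draws = TRUE`.
#' @param zones factor/vector over cells; NA = outside every polygon.
#' @return data.frame per zone: posterior mean, median, 2.5%/97.5% bounds
#'   of the zone total.
#' @export
aggregate_zones <- function(prediction, zones) {
  check(!is.null(prediction$draws), "prediction must keep draws")
  check(length(zones) == nrow(prediction$draws), "zones must cover all cells")
  zl <- unique(zones[!is.na(zones)])
  rows <- lapply(zl, function(z) {
    tot <- colSums(prediction$draws[which(zones == z), , drop = FALSE])
    data.frame(zone = z, mean = mean(tot), median = median(tot),
               lower = quantile(tot, 0.025, names = FALSE),
               upper = quantile(tot, 0.975, names = FALSE))
  })
  do.call(rbind, rows)
}

#' Map rectangular polygons to grid cells by cell-center containment
#'
#' @param grid a `study_grid` (needs `x`, `y` cell centres in metres).
#' @param rects data.frame with columns `zone`, `xmin`, `xmax`, `ymin`,
#'   `ymax` (metres).  Later rectangles win where rectangles overlap.
#' @return zone vector over cells (NA outside every rectangle); a warning is
#'   emitted for rectangles covering no cell.
#' @export
rectangles_to_zones <- function(grid, rects) {
  zones <- rep(NA, nrow(grid))
  for (r in seq_len(nrow(rects))) {
    inr <- grid$x >= rects$xmin[r] & grid$x <= rects$xmax[r] &
      grid$y >= rects$ymin[r] & grid$y <= rects$ymax[r]
    if (!any(inr))
      warning(sprintf("polygon '%s' covers no grid cell; its total is 0",
                      rects$zone[r]))
    zones[inr] <- rects$zone[r]
  }
  zones
}
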