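#' Configuration for a synthetic study region
#'
#' Defines the geography and generative settings of a synthetic study region:
#' a rectangular grid of ~100 m cells carved into provinces (vertical strips)
#' and nested local areas (horizontal sub-strips), a settled mask, and
#' building-footprint attribute fields from which the model covariates are
#' derived.  The defaults describe a predominantly rural region with a few
#' dense urban cores per province, which is what the density model's
#' settlement-type stratification needs to be exercised.
#'
#' @param n_provinces number of provinces (vertical strips), >= 1.
#' @param n_localareas_per_province local areas nested within each province.
#' @param grid_shape integer vector `c(rows, cols)` of ~100 m cells.
#' @param settled_fraction fraction of cells carrying any building footprint,
#'   in (0, 1].
#' @param n_urban_cores_per_province number of dense settlement cores planted
#'   per province; these become the urban class under the morphological rule
#'   (>= 40 footprint ha and >= 13 buildings per connected component).
#' @param field_range correlation range (in cells) of the smooth fields used
#'   for settlement intensity, attributes, and the density residual field.
#' @param mean_footprint_area_ha typical mean building-footprint area per
#'   cell (ha); urban cells get larger buildings.
#' @param seed integer seed; the whole world is reproducible given the seed.
#' @return an object of class `world_config` (a validated list).
#' @seealso [generate_world()], [draw_truth()], [simulate_survey()]
#' @export
world_config <- function(n_provinces = 2L,
                         n_localareas_per_province = 4L,
                         grid_shape = c(150L, 150L),
                         settled_fraction = 0.25,
                         n_urban_cores_per_province = 1L,
                         field_range = 4L,
                         mean_footprint_area_ha = 0.012,
                         seed = 1L) {
  check(n_provinces >= 1, "n_provinces must be >= 1")
  check(n_localareas_per_province >= 1, "n_localareas_per_province must be >= 1")
  check(length(grid_shape) == 2 && all(grid_shape >= 1),
        "grid_shape must be two positive integers")
  check(prod(grid_shape) > 0, "degenerate grid (0 cells)")
  check(settled_fraction > 0 && settled_fraction <= 1,
        "settled_fraction must be in (0, 1]")
  structure(list(
    n_provinces = as.integer(n_provinces),
    n_localareas_per_province = as.integer(n_localareas_per_province),
    grid_shape = as.integer(grid_shape),
    settled_fraction = settled_fraction,
    n_urban_cores_per_province = as.integer(n_urban_cores_per_province),
    field_range = as.integer(field_range),
    mean_footprint_area_ha = mean_footprint_area_ha,
    seed = as.integer(seed)
  ), class = "world_config")
}

#' Generate a synthetic study grid
#'
#' Builds the gridded world: per-cell building-footprint summaries (total
#' footprint area in ha, building count, mean building area, building
#' proximity as inverse nearest-building distance, 2 km focal building
#' count), province and local-area labels, an urban/rural settlement label
#' from the morphological classification rule, scaled model covariates, and
#' a standardized smooth residual field that later drives cluster-level
#' density deviations.  Unsettled cells have exactly zero footprint area.
#'
#' Covariates are scaled by the settled-cell grid mean and standard
#' deviation; the constants are stored in the `scaling` attribute so survey
#' clusters can be scaled with the *same* constants.
#'
#' @param config a [world_config()].
#' @return a `study_grid`: a data.frame with one row per cell and attributes
#'   `dims`, `cell_km`, `scaling`, and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, {
    nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
    n <- nr * nc
    cell <- seq_len(n)
    row <- ((cell - 1L) %% nr) + 1L
    col <- ((cell - 1L) %/% nr) + 1L
    x <- (col - 0.5) * 100; y <- (row - 0.5) * 100   # metres, cell centres

    # province = vertical strip, local area = horizontal sub-strip: nesting
    # by construction
    province <- pmin(config$n_provinces,
                     1L + ((col - 1L) * config$n_provinces) %/% nc)
    local_area <- pmin(config$n_localareas_per_province,
                       1L + ((row - 1L) * config$n_localareas_per_province) %/% nr)

    # settlement intensity: smooth field plus planted urban cores
    s <- smooth_field(nr, nc, config$field_range)
    core_mask <- matrix(0, nr, nc)
    for (p in seq_len(config$n_provinces)) {
      pcols <- range(col[province == p])
      for (k in seq_len(config$n_urban_cores_per_province)) {
        if (k == 1L) {
          # the first core sits near the strip centre (small jitter), so
          # every province reliably carries an urban settlement
          cr <- round(nr / 2) + sample(-3:3, 1)
          cc <- round(mean(pcols)) + sample(-3:3, 1)
        } else {
          # further cores anywhere, kept off the edges where possible
          rlo <- min(8L, nr); rhi <- max(rlo, nr - 7L)
          clo <- min(pcols[1] + 7L, pcols[2]); chi <- max(clo, pcols[2] - 7L)
          cr <- if (rhi > rlo) sample(rlo:rhi, 1) else rlo
          cc <- if (chi > clo) sample(clo:chi, 1) else clo
        }
        dd <- outer(seq_len(nr), seq_len(nc),
                    function(i, j) sqrt((i - cr)^2 + (j - cc)^2))
        core_mask <- core_mask + 2.4 * exp(-(dd / 8)^2)
      }
    }
    s <- s + core_mask
    sv <- s[cbind(row, col)]
    settled <- sv >= quantile(sv, 1 - config$settled_fraction, names = FALSE)
    # the town discs are always settled, whatever the background field does
    corev0 <- core_mask[cbind(row, col)]
    town <- corev0 >= 2.4 * exp(-(6.5 / 8)^2)
    settled <- settled | town

    # footprint attribute fields (settled cells only)
    f_area <- smooth_field(nr, nc, config$field_range)[cbind(row, col)]
    f_size <- smooth_field(nr, nc, config$field_range)[cbind(row, col)]
    corev <- core_mask[cbind(row, col)]
    # total footprint area per cell, ha (cell = 1 ha): denser near cores
    A <- ifelse(settled,
                pmin(0.9, exp(-3.2 + 0.45 * f_area + 1.3 * corev +
                                rnorm(n, 0, 0.25))), 0)
    # town discs carry dense building cover so the morphological urban rule
    # (>= 40 footprint ha per contiguous component) is met by construction
    A[town] <- pmax(A[town], 0.55 * exp(rnorm(sum(town), 0, 0.15)))
    # mean building area, ha: larger buildings in urban cores
    mean_area <- ifelse(settled,
                        config$mean_footprint_area_ha *
                          exp(0.3 * f_size + 0.25 * corev + rnorm(n, 0, 0.15)),
                        NA_real_)
    bcount <- ifelse(settled, pmax(1L, round(A / mean_area)), 0L)
    # nearest-building distance shrinks with local building density
    nn_dist <- ifelse(settled,
                      100 / sqrt(1 + bcount) * exp(rnorm(n, 0, 0.2)), NA_real_)
    proximity <- 1 / nn_dist

    count_mat <- matrix(0, nr, nc); count_mat[cbind(row, col)] <- bcount
    focal2km <- focal_summary(count_mat, window_m = 2000)[cbind(row, col)]

    area_mat <- matrix(0, nr, nc); area_mat[cbind(row, col)] <- A
    type <- classify_settlement(area_mat, count_mat)[cbind(row, col)]
    type[!settled] <- NA_character_

    grid <- data.frame(
      cell = cell, row = row, col = col, x = x, y = y,
      province = province, local_area = local_area,
      settled = settled, A = A, bcount = bcount,
      mean_area = mean_area, proximity = proximity, focal2km = focal2km,
      type = type,
      e = smooth_field(nr, nc, config$field_range)[cbind(row, col)]
    )
    # residual field standardized over settled cells
    es <- grid$e[settled]
    grid$e <- (grid$e - mean(es)) / sd(es)

    # model covariates: log mean building area, proximity, 2 km focal count,
    # scaled by settled-cell grid mean/sd (the constants the model reuses)
    raw <- cbind(log_mean_area = log(grid$mean_area),
                 proximity = grid$proximity,
                 focal2km = grid$focal2km)
    ctr <- colMeans(raw[settled, , drop = FALSE])
    scl <- apply(raw[settled, , drop = FALSE], 2, sd)
    scl[!is.finite(scl) | scl == 0] <- 1   # constant attribute -> scaled to 0
    sc <- scale_covariates(raw, ctr, scl)
    grid$x1 <- ifelse(settled, sc[, 1], NA_real_)
    grid$x2 <- ifelse(settled, sc[, 2], NA_real_)
    grid$x3 <- ifelse(settled, sc[, 3], NA_real_)

    structure(grid,
              dims = c(nr, nc), cell_km = 0.1,
              scaling = list(center = ctr, scale = scl),
              config = config,
              class = c("study_grid", "data.frame"))
  })
}

#' Draw ground-truth parameters for a synthetic world
#'
#' Draws every unknown of the density and age-sex models from a realistic
#' generative hierarchy: settlement-type intercept means, province means,
#' local-area intercepts, covariate effects by settlement type, lognormal
#' density scales by stratum, and province age-sex proportions on the
#' 36-group simplex.  All draws are recorded so recovery experiments can
#' compare posteriors against known truth.
#'
#' Defaults encode the field's stylized facts: higher people-per-footprint-ha
#' densities in rural than urban settlements, a strongly negative effect of
#' mean building area, a proximity effect active in rural areas, and a focal
#' count effect with opposite signs by settlement type.
#'
#' @param config a [world_config()].
#' @param overrides named list overriding hyperparameters:
#'   `xi_t` (length-2, rural/urban mean log-density), `nu_t`, `nu_tp`
#'   (intercept sds), `rho` (length-3 covariate effect means), `omega`
#'   (effect sds by type), `mu_t`, `sigma_t` (density-scale hyperpars),
#'   `agesex_concentration`.
#' @param seed optional seed (defaults to `config$seed + 1`).
#' @return object of class `synthetic_truth`.
#' @export
draw_truth <- function(config, overrides = list(), seed = NULL) {
  stopifnot(inherits(config, "world_config"))
  if (is.null(seed)) seed <- config$seed + 1L
  h <- list(xi_t = c(rural = log(450), urban = log(260)),
            nu_t = 0.30, nu_tp = 0.25,
            rho = c(x1 = -0.45, x2 = 0.18, x3 = 0.00),
            omega = c(x1 = 0.00, x2 = 0.15, x3 = 0.30),
            mu_t = c(rural = 0.55, urban = 0.45), sigma_t = 0.08,
            agesex_concentration = 400)
  for (nm in names(overrides)) h[[nm]] <- overrides[[nm]]
  check(all(unlist(h[c("nu_t", "nu_tp", "omega", "sigma_t")]) >= 0),
        "scale overrides must be non-negative")
  check(all(is.finite(unlist(h[c("xi_t", "nu_t", "nu_tp", "rho", "omega")]))),
        "hyperparameter overrides must be finite")

  types <- c("rural", "urban"); P <- config$n_provinces
  L <- config$n_localareas_per_province
  with_seed(seed, {
    xi_tp <- matrix(rnorm(2 * P, rep(h$xi_t, P), h$nu_t), 2, P,
                    dimnames = list(types, paste0("p", seq_len(P))))
    alpha <- array(rnorm(2 * P * L, rep(xi_tp, L), h$nu_tp), c(2, P, L),
                   dimnames = list(types, paste0("p", seq_len(P)),
                                   paste0("l", seq_len(L))))
    K <- length(h$rho)
    beta <- matrix(rnorm(2 * K, rep(h$rho, each = 2), rep(h$omega, each = 2)),
                   2, K, dimnames = list(types, names(h$rho)))
    tau_tp <- matrix(rhalfnorm(2 * P, rep(h$mu_t, P), h$sigma_t), 2, P,
                     dimnames = dimnames(xi_tp))

    # age-sex: 36 groups = 2 sexes x 18 age bins, declining stable pyramid
    bins <- agesex_bins()
    mids <- c(0.5, 3, seq(7.5, 77.5, by = 5), 85)
    widths <- c(1, 4, rep(5, 15), 10)
    base <- widths * exp(-0.042 * mids)
    base <- rep(base / sum(base) / 2, times = 2)      # split over sexes
    pi_gp <- t(rdirichlet(P, matrix(h$agesex_concentration * base,
                                    nrow = 1)[rep(1, P), , drop = FALSE]))
    rownames(pi_gp) <- paste(rep(c("male", "female"), each = 18), bins$label,
                             sep = ".")
    colnames(pi_gp) <- paste0("p", seq_len(P))

    structure(list(alpha = alpha, xi_tp = xi_tp, xi_t = h$xi_t,
                   nu_t = h$nu_t, nu_tp = h$nu_tp,
                   beta = beta, rho = h$rho, omega = h$omega,
                   tau_tp = tau_tp, mu_t = h$mu_t, sigma_t = h$sigma_t,
                   pi_gp = pi_gp, types = types, seed = seed),
              class = "synthetic_truth")
  })
}

#' Survey design for the synthetic microcensus
#'
#' @param mode `"random"` (weights unrecorded, as in a simple random round)
#'   or `"population_weighted"` (cluster seeds drawn proportional to a noisy
#'   population proxy; the selection weight is recorded as `w`).
#' @param n_clusters number of clusters to enumerate.
#' @param cluster_settled_area_target target settled footprint area per
#'   cluster, ha (default 3).
#' @param nonresponse_rate fraction of households with missing size.
#' @param undercount_cluster_rate fraction of clusters with artificially
#'   thinned counts (flagged in the hidden truth column).
#' @param zero_footprint_rate fraction of clusters whose footprint area is
#'   zeroed after counts are drawn (emulates failed footprint detection).
#' @param weight_outlier_rate fraction of recorded weights multiplied by a
#'   heavy-tailed factor (emulates weight outliers that the 90th-percentile
#'   truncation is meant to absorb).
#' @param proxy_noise_sd lognormal sd of the noise in the population proxy
#'   used for population-weighted seed selection.
#' @param proxy_flatten exponent applied to the cell population surface
#'   when forming the selection proxy (< 1 emulates the shrinkage of prior
#'   gridded population estimates relative to the truth).
#' @param residual_field_share share (in sd units) of the cluster density
#'   deviation carried by the smooth spatial residual field; the remainder
#'   is iid per cluster.  The field share makes preferential sampling
#'   informative about the deviations; the marginal deviation is N(0, tau^2)
#'   either way.
#' @return object of class `survey_design`.
#' @export
survey_design <- function(mode = c("population_weighted", "random"),
                          n_clusters = 150L,
                          cluster_settled_area_target = 3,
                          nonresponse_rate = 0.01,
                          undercount_cluster_rate = 0,
                          zero_footprint_rate = 0,
                          weight_outlier_rate = 0,
                          proxy_noise_sd = 0.3,
                          proxy_flatten = 0.6,
                          residual_field_share = 0.6) {
  mode <- match.arg(mode)
  rates <- c(nonresponse_rate, undercount_cluster_rate, zero_footprint_rate,
             weight_outlier_rate)
  check(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")
  structure(list(mode = mode, n_clusters = as.integer(n_clusters),
                 cluster_settled_area_target = cluster_settled_area_target,
                 nonresponse_rate = nonresponse_rate,
                 undercount_cluster_rate = undercount_cluster_rate,
                 zero_footprint_rate = zero_footprint_rate,
                 weight_outlier_rate = weight_outlier_rate,
                 proxy_noise_sd = proxy_noise_sd,
                 proxy_flatten = proxy_flatten,
                 residual_field_share = residual_field_share),
            class = "survey_design")
}

#' Simulate a microcensus survey over a synthetic world
#'
#' Delineates clusters of contiguous settled cells grown around seed cells
#' until the target settled footprint area (~3 ha) is reached, then simulates
#' enumeration: cluster density `D_i` is lognormal around the regression mean
#' `Dbar_i = alpha[t,p,l] + sum_k beta[k,t] x[k,i]` with stratum scale
#' `tau[t,p]` (tied to the world's smooth residual field at the seed cell,
#' so selection can be genuinely informative), and the count is
#' `N_i ~ Poisson(D_i * A_i)`.  Households, individual age-sex records, and
#' the design artifacts (nonresponse, undercounting, zero-footprint clusters,
#' weight outliers) are generated per the design.
#'
#' @param grid a `study_grid` from [generate_world()].
#' @param truth a `synthetic_truth` from [draw_truth()].
#' @param design a [survey_design()].
#' @param seed optional seed (defaults to the world seed + 2).
#' @param with_individuals generate the individual-level age-sex records
#'   (can be bulky for large worlds).
#' @return list of class `bupop_survey` with elements `clusters`,
#'   `households`, `individuals` (or NULL), and `design`.  Hidden-truth
#'   columns (`true_N`, `true_logD`, `flag_undercount`, `flag_zero_footprint`)
#'   let tests score the preparation pipeline.
#' @export
simulate_survey <- function(grid, truth, design = survey_design(),
                            seed = NULL, with_individuals = TRUE) {
  stopifnot(inherits(grid, "study_grid"), inherits(truth, "synthetic_truth"))
  cfg <- attr(grid, "config")
  if (is.null(seed)) seed <- cfg$seed + 2L
  dims <- attr(grid, "dims")
  with_seed(seed, {
    settled_idx <- which(grid$settled)
    check(length(settled_idx) > 0, "world has no settled cells")

    # expected log-density per settled cell, for the selection proxy
    tmat <- match(grid$type, truth$types)
    X <- as.matrix(grid[, c("x1", "x2", "x3")])
    dbar_cell <- rep(NA_real_, nrow(grid))
    ok <- grid$settled
    aidx <- cbind(tmat[ok], grid$province[ok], grid$local_area[ok])
    dbar_cell[ok] <- truth$alpha[aidx] +
      rowSums(X[ok, , drop = FALSE] * truth$beta[tmat[ok], , drop = FALSE])
    tau_cell <- rep(NA_real_, nrow(grid))
    tau_cell[ok] <- truth$tau_tp[cbind(tmat[ok], grid$province[ok])]
    # selection proxy: a smoothed prior population surface -- flatter than
    # the true cell population (prior gridded estimates are shrunk), noisy
    proxy <- rep(0, nrow(grid))
    proxy[ok] <- (grid$A[ok] * exp(dbar_cell[ok] + tau_cell[ok] * grid$e[ok]))^
      design$proxy_flatten *
      exp(rnorm(sum(ok), 0, design$proxy_noise_sd))

    # sequential seed selection + contiguous growth (4-neighbour) until the
    # target settled area is reached; cells are never reused
    nr <- dims[1]; nc <- dims[2]
    avail <- grid$settled
    n_cl <- design$n_clusters
    check(n_cl <= sum(avail), "design asks for more clusters than settled cells")
    cluster_cells <- vector("list", n_cl)
    seed_cells <- integer(n_cl)
    for (i in seq_len(n_cl)) {
      cand <- which(avail)
      if (length(cand) == 0) { n_cl <- i - 1L; break }
      sc <- if (design$mode == "population_weighted")
        cand[sample.int(length(cand), 1, prob = proxy[cand] + 1e-12)]
      else cand[sample.int(length(cand), 1)]
      seed_cells[i] <- sc
      members <- sc; avail[sc] <- FALSE
      # each settled cell is 1 ha of settled land; grow contiguously until
      # the target settled area (~3 ha, i.e. ~3 cells) is reached
      frontier <- sc
      while (length(members) < design$cluster_settled_area_target &&
             length(frontier)) {
        nb <- unique(unlist(lapply(frontier, function(j) {
          r <- grid$row[j]; cl <- grid$col[j]
          c(if (r > 1) j - 1L, if (r < nr) j + 1L,
            if (cl > 1) j - nr, if (cl < nc) j + nr)
        })))
        nb <- nb[avail[nb]]
        if (!length(nb)) break
        need <- design$cluster_settled_area_target - length(members)
        sel <- nb[order(-grid$A[nb])][seq_len(min(need, length(nb)))]
        members <- c(members, sel); avail[sel] <- FALSE
        frontier <- sel
      }
      cluster_cells[[i]] <- members
    }
    cluster_cells <- cluster_cells[seq_len(n_cl)]
    seed_cells <- seed_cells[seq_len(n_cl)]

    A_i <- vapply(cluster_cells, function(m) sum(grid$A[m]), 0)
    wmean <- function(v, m) sum(v[m] * grid$A[m]) / sum(grid$A[m])
    x1 <- vapply(cluster_cells, function(m) wmean(grid$x1, m), 0)
    x2 <- vapply(cluster_cells, function(m) wmean(grid$x2, m), 0)
    x3 <- vapply(cluster_cells, function(m) wmean(grid$x3, m), 0)
    cx <- vapply(cluster_cells, function(m) mean(grid$x[m]), 0)
    cy <- vapply(cluster_cells, function(m) mean(grid$y[m]), 0)
    prov <- grid$province[seed_cells]
    larea <- grid$local_area[seed_cells]
    type <- grid$type[seed_cells]
    ti <- match(type, truth$types)

    dbar <- truth$alpha[cbind(ti, prov, larea)] +
      truth$beta[cbind(ti, rep(1L, n_cl))] * x1 +
      truth$beta[cbind(ti, rep(2L, n_cl))] * x2 +
      truth$beta[cbind(ti, rep(3L, n_cl))] * x3
    tau_i <- truth$tau_tp[cbind(ti, prov)]
    # cluster density deviation: an iid component plus a share of the
    # smooth residual field at the seed (marginally still N(0, tau^2), but
    # the field share is what makes population-weighted selection
    # informative about the deviation, not only about the regression mean)
    a <- design$residual_field_share
    logD <- dbar + tau_i * (sqrt(1 - a^2) * rnorm(n_cl) + a * grid$e[seed_cells])
    N <- rpois(n_cl, exp(logD) * A_i)

    # recorded sampling weight: the (noisy) selection weight, known only in
    # population-weighted mode
    w <- if (design$mode == "population_weighted") {
      wr <- proxy[seed_cells] / mean(proxy[seed_cells])
      n_out <- rbinom(1, n_cl, design$weight_outlier_rate)
      if (n_out > 0) {
        idx <- sample.int(n_cl, n_out)
        wr[idx] <- wr[idx] * (5 + rexp(n_out, rate = 0.25))  # heavy tail
      }
      wr
    } else rep(NA_real_, n_cl)

    # artifacts: undercounting (thinned people), zero footprints
    flag_uc <- rep(FALSE, n_cl)
    n_uc <- rbinom(1, n_cl, design$undercount_cluster_rate)
    if (n_uc > 0) flag_uc[sample.int(n_cl, n_uc)] <- TRUE
    N_obs <- N
    N_obs[flag_uc] <- rbinom(sum(flag_uc), N[flag_uc], runif(sum(flag_uc), 0.3, 0.6))
    flag_zf <- rep(FALSE, n_cl)
    n_zf <- rbinom(1, n_cl, design$zero_footprint_rate)
    if (n_zf > 0) flag_zf[sample.int(n_cl, n_zf)] <- TRUE
    A_rec <- ifelse(flag_zf, 0, A_i)

    clusters <- data.frame(
      id = seq_len(n_cl), province = prov, local_area = larea, type = type,
      A = A_rec, x1 = x1, x2 = x2, x3 = x3, N = N_obs, w = w,
      x = cx, y = cy,
      flag_undercount = flag_uc, flag_zero_footprint = flag_zf,
      true_N = N, true_logD = logD, true_A = A_i
    )

    # households: people split across ~4.6-person households; nonresponse
    # hides sizes (at least one respondent kept per cluster)
    hh <- do.call(rbind, lapply(seq_len(n_cl), function(i) {
      H <- max(1L, round(N_obs[i] / 4.6))
      sizes <- as.vector(rmultinom(1, N_obs[i], rep(1, H)))
      data.frame(cluster = i, household = seq_len(H), size_true = sizes)
    }))
    miss <- runif(nrow(hh)) < design$nonresponse_rate
    # keep >= 1 respondent per cluster
    first <- !duplicated(hh$cluster)
    miss[first] <- FALSE
    hh$size <- ifelse(miss, NA_real_, hh$size_true)

    individuals <- NULL
    if (with_individuals) {
      G <- nrow(truth$pi_gp)
      bins <- agesex_bins()
      glab <- rownames(truth$pi_gp)
      individuals <- do.call(rbind, lapply(seq_len(n_cl), function(i) {
        if (N_obs[i] == 0) return(NULL)
        g <- sample.int(G, N_obs[i], replace = TRUE, prob = truth$pi_gp[, prov[i]])
        bin <- ((g - 1L) %% 18L) + 1L
        sex <- ifelse(g <= 18L, "male", "female")
        lo <- bins$lower[bin]
        hi <- ifelse(is.finite(bins$upper[bin]), bins$upper[bin], 95)
        data.frame(cluster = i, province = prov[i], sex = sex,
                   age = floor(runif(N_obs[i], lo, hi)))
      }))
    }

    structure(list(clusters = clusters, households = hh,
                   individuals = individuals, design = design, seed = seed),
              class = "bupop_survey")
  })
}
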