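#' Impute household nonresponse by the cluster mean
#'
#' Households with a missing size are assigned the mean size of the
#' responding households in the same cluster; cluster totals are the sums of
#' recorded and imputed sizes.
#'
#' @param households data.frame with columns `cluster` and `size` (NA marks
#'   a nonresponse).
#' @return list with `households` (column `size_imputed` completed) and
#'   `totals` (data.frame `cluster`, `N` with the completed cluster totals).
#' @export
impute_nonresponse <- function(households) {
  check(all(c("cluster", "size") %in% names(households)),
        "households needs columns cluster, size")
  sp <- split(households$size, households$cluster)
  all_na <- vapply(sp, function(s) all(is.na(s)), TRUE)
  if (any(all_na))
    stop("cluster(s) with no responding household: ",
         paste(names(sp)[all_na], collapse = ", "))
  cmean <- vapply(sp, function(s) mean(s, na.rm = TRUE), 0)
  out <- households
  out$size_imputed <- ifelse(is.na(out$size),
                             cmean[as.character(out$cluster)], out$size)
  totals <- data.frame(cluster = names(sp),
                       N = as.numeric(tapply(out$size_imputed, out$cluster, sum)[names(sp)]),
                       row.names = NULL)
  # preserve the cluster id type where it was numeric
  if (is.numeric(households$cluster)) totals$cluster <- as.numeric(totals$cluster)
  list(households = out, totals = totals)
}

#' Discard spurious clusters
#'
#' Drops clusters flagged as undercounted and clusters with zero recorded
#' footprint area; the two rules are applied as a set union, so a cluster
#' matching both is discarded (and counted) once.
#'
#' @param clusters data.frame with columns `A` (footprint area, ha) and
#'   `flag_undercount` (logical).
#' @return list with `retained`, `discarded`, and `report` (counts:
#'   `n_input`, `n_undercount`, `n_zero_footprint`, `n_discarded`,
#'   `n_retained`).
#' @export
filter_clusters <- function(clusters) {
  check(all(c("A", "flag_undercount") %in% names(clusters)),
        "clusters needs columns A, flag_undercount")
  uc <- clusters$flag_undercount %in% TRUE
  zf <- clusters$A <= 0
  drop <- uc | zf
  report <- list(n_input = nrow(clusters),
                 n_undercount = sum(uc),
                 n_zero_footprint = sum(zf),
                 n_discarded = sum(drop),
                 n_retained = sum(!drop))
  if (report$n_retained == 0) message("filter_clusters: no clusters retained")
  list(retained = clusters[!drop, , drop = FALSE],
       discarded = clusters[drop, , drop = FALSE],
       report = report)
}

#' Truncate sampling weights at an upper percentile
#'
#' Caps weights at the given percentile of their distribution (default the
#' 90th), absorbing outliers that arise from uncertainty in the gridded
#' population data behind a population-weighted sampling design.  The
#' percentile uses the linear-interpolation quantile convention
#' (`stats::quantile` type 7).
#'
#' @param weights positive numeric vector (NAs passed through).
#' @param percentile cap percentile in (0, 100].
#' @return weights with values above the cap replaced by the cap.
#' @export
truncate_weights <- function(weights, percentile = 90) {
  check(length(weights) > 0, "empty weight vector")
  obs <- weights[!is.na(weights)]
  check(length(obs) > 0, "all weights missing")
  check(all(obs > 0), "weights must be positive")
  cap <- quantile(obs, percentile / 100, names = FALSE, type = 7)
  pmin(weights, cap)
}

#' Impute missing sampling weights proportionally
#'
#' Clusters from a randomly sampled round carry no recorded sampling weight;
#' each such cluster is assigned the mean of the observed weights, so the two
#' rounds contribute to the weight total in proportion to their cluster
#' counts.  (The allocation rule is configurable through `share`; the default
#' is the equal-share rule.)
#'
#' @param weights numeric vector, NA = missing.
#' @param share either `"mean"` (each missing weight = mean observed weight)
#'   or a positive scalar multiplier applied to the mean.
#' @return complete positive weight vector.
#' @export
impute_missing_weights <- function(weights, share = "mean") {
  check(length(weights) > 0, "empty weight vector")
  obs <- weights[!is.na(weights)]
  check(length(obs) > 0, "all weights missing; cannot impute")
  check(all(obs > 0), "observed weights must be positive")
  fill <- mean(obs)
  if (is.numeric(share)) fill <- fill * share
  ifelse(is.na(weights), fill, weights)
}

#' Normalize sampling weights into model weights
#'
#' Model weight `v_i = w_i^{-1} / sum_i w_i^{-1}`: the inverse sampling
#' weight rescaled to sum to one across all clusters.  Clusters oversampled
#' by a population-weighted design (large `w`) therefore receive small model
#' weights, i.e. reduced likelihood precision.
#'
#' @param weights complete positive weight vector.
#' @return model weights `v` summing to one.
#' @export
normalize_weights <- function(weights) {
  check(length(weights) > 0, "empty weight vector")
  check(!anyNA(weights) && all(weights > 0), "weights must be positive and complete")
  inv <- 1 / weights
  inv / sum(inv)
}

# The 18 standard age bins: [0,1), [1,5), 5-year bins to 80, then 80+.
agesex_bins <- function() {
  lower <- c(0, 1, seq(5, 80, by = 5))
  upper <- c(lower[-1], Inf)
  label <- c("0", "1-4",
             paste(seq(5, 75, by = 5), seq(9, 79, by = 5), sep = "-"),
             "80+")
  data.frame(lower = lower, upper = upper, label = label)
}

#' Aggregate individual records into age-sex count tables
#'
#' Bins individuals into the 36 standard groups (2 sexes x 18 age bins:
#' under 1, 1-4, five-year bins to 79, 80 and over) per province.
#'
#' @param individuals data.frame with columns `province`, `sex`
#'   (`"male"`/`"female"`), `age` (years, >= 0).
#' @return an `agesex_table`: data.frame with columns `province`, `sex`,
#'   `age_group`, `count`, carrying all 36 groups per province (zero-filled),
#'   with province totals in attribute `totals`.
#' @export
aggregate_agesex <- function(individuals) {
  check(all(c("province", "sex", "age") %in% names(individuals)),
        "individuals needs columns province, sex, age")
  check(all(individuals$age >= 0), "negative age")
  check(all(individuals$sex %in% c("male", "female")),
        "sex must be 'male' or 'female'")
  bins <- agesex_bins()
  idx <- findInterval(individuals$age, bins$lower)
  ag <- factor(bins$label[idx], levels = bins$label)
  sex <- factor(individuals$sex, levels = c("male", "female"))
  prov <- factor(individuals$province)
  tab <- as.data.frame(table(province = prov, sex = sex, age_group = ag),
                       responseName = "count")
  tab <- tab[order(tab$province, tab$sex, tab$age_group), ]
  rownames(tab) <- NULL
  totals <- tapply(tab$count, tab$province, sum)
  structure(tab, totals = totals, class = c("agesex_table", "data.frame"))
}

#' Constrain cluster extent to footprints near surveyed households
#'
#' Keeps, per cluster, only the building footprints lying within `radius`
#' metres of at least one surveyed household (closed boundary: exactly
#' `radius` is kept).  Footprints farther away are excluded from the
#' footprint area and covariate computation, mirroring field practice where
#' parts of a delineated cluster were not reachable.
#'
#' @param households data.frame with columns `cluster`, `x`, `y` (projected
#'   metres).
#' @param footprints data.frame with columns `cluster`, `x`, `y` (and any
#'   attribute columns, carried through).
#' @param radius metres, default 50.
#' @return `footprints` subset to the retained rows, with a logical
#'   attribute-free column `within_radius` dropped.
#' @export
constrain_cluster_extent <- function(households, footprints, radius = 50) {
  check(nrow(households) > 0, "empty household set")
  keep <- logical(nrow(footprints))
  for (cl in unique(footprints$cluster)) {
    fi <- which(footprints$cluster == cl)
    hh <- households[households$cluster == cl, , drop = FALSE]
    if (nrow(hh) == 0) { keep[fi] <- FALSE; next }
    d2 <- outer(footprints$x[fi], hh$x, "-")^2 + outer(footprints$y[fi], hh$y, "-")^2
    keep[fi] <- sqrt(apply(d2, 1, min)) <= radius
  }
  footprints[keep, , drop = FALSE]
}

#' Prepare a raw survey for model fitting
#'
#' Convenience pipeline: impute household nonresponse into cluster totals,
#' discard undercounted and zero-footprint clusters, truncate recorded
#' weights at the 90th percentile, impute the missing (randomly sampled)
#' weights, and normalize to model weights `v`.
#'
#' @param survey a `bupop_survey` (or any list with `clusters` and
#'   `households` shaped alike).
#' @param truncate_percentile weight truncation percentile, default 90.
#' @return data.frame of model-ready clusters (columns `N`, `A`, `type`,
#'   `province`, `local_area`, `x1..x3`, `v`, coordinates) with the discard
#'   report in attribute `filter_report`.
#' @export
prepare_survey <- function(survey, truncate_percentile = 90) {
  cl <- survey$clusters
  if (!is.null(survey$households)) {
    imp <- impute_nonresponse(survey$households)
    m <- match(cl$id, imp$totals$cluster)
    cl$N <- round(imp$totals$N[m])
  }
  f <- filter_clusters(cl)
  keep <- f$retained
  w <- keep$w
  if (all(is.na(w))) {
    v <- rep(1 / nrow(keep), nrow(keep))   # unweighted: equal model weights
  } else {
    w <- truncate_weights(w, truncate_percentile)
    w <- impute_missing_weights(w)
    v <- normalize_weights(w)
  }
  keep$v <- v
  structure(keep, filter_report = f$report)
}
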