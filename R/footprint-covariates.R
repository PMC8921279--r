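#' Summarize building-footprint attributes per zone
#'
#' Computes the morphological/topological attribute summaries used as model
#' covariates: total footprint area (ha), building count, mean building area
#' (ha), mean perimeter (m), coefficient of variation of building area, mean
#' nearest-building distance (m, centroid-to-centroid) and its inverse, the
#' building proximity.  Zones with no footprints get zero area/count and NA
#' means; zones with a single footprint get NA nearest-distance summaries.
#'
#' @param footprints data.frame of footprint centroids with columns `x`, `y`
#'   (projected metres), `area_m2`, optionally `perimeter_m`, and `zone`.
#' @param zones optional vector of zone ids to report (defaults to the zones
#'   present); zones absent from `footprints` are reported as empty.
#' @return data.frame, one row per zone.
#' @export
summarize_footprints <- function(footprints, zones = NULL) {
  check(all(c("x", "y", "area_m2", "zone") %in% names(footprints)),
        "footprints needs columns x, y, area_m2, zone")
  check(all(footprints$area_m2 >= 0), "invalid footprint area")
  if (is.null(zones)) zones <- sort(unique(footprints$zone))
  rows <- lapply(zones, function(z) {
    f <- footprints[footprints$zone == z, , drop = FALSE]
    n <- nrow(f)
    if (n == 0)
      return(data.frame(zone = z, n = 0L, total_area_ha = 0,
                        mean_area_ha = NA_real_, cv_area = NA_real_,
                        mean_perimeter_m = NA_real_,
                        mean_nn_dist_m = NA_real_, mean_proximity = NA_real_))
    nn <- if (n >= 2) {
      d <- as.matrix(dist(cbind(f$x, f$y)))
      diag(d) <- Inf
      mean(apply(d, 1, min))
    } else NA_real_
    data.frame(
      zone = z, n = n,
      total_area_ha = sum(f$area_m2) / 1e4,
      mean_area_ha = mean(f$area_m2) / 1e4,
      cv_area = if (n >= 2 && mean(f$area_m2) > 0)
        sd(f$area_m2) / mean(f$area_m2) else if (n >= 2) NA_real_ else NA_real_,
      mean_perimeter_m = if ("perimeter_m" %in% names(f))
        mean(f$perimeter_m) else NA_real_,
      mean_nn_dist_m = nn,
      mean_proximity = if (is.na(nn) || nn == 0) NA_real_ else 1 / nn
    )
  })
  do.call(rbind, rows)
}

#' Focal (moving-window) mean of a gridded attribute
#'
#' Mean of the attribute over a square window centred on each cell; edge
#' cells use the available cells only.  The window is specified in metres
#' and converted to an odd cell count (`2*floor(window/(2*cell)) + 1`).
#'
#' @param mat numeric matrix (rows x cols of grid cells).
#' @param window_m window side length in metres (>= cell size).
#' @param cell_m cell size in metres, default 100.
#' @return matrix of focal means, same shape as `mat`.
#' @export
focal_summary <- function(mat, window_m = 2000, cell_m = 100) {
  check(is.matrix(mat) && is.numeric(mat), "mat must be a numeric matrix")
  check(window_m >= cell_m, "window smaller than one cell")
  hw <- floor(window_m / (2 * cell_m))
  box_mean(mat, hw)
}

#' Classify settled cells into urban and rural settlements
#'
#' Applies the morphological rule: a connected component (8-neighbour) of
#' settled cells is urban when its total building-footprint area is at least
#' `min_area_ha` (default 40 ha) *and* it contains at least `min_count`
#' building footprints (default 13); every other settled cell is rural.
#'
#' @param area_mat matrix of per-cell footprint area (ha); 0 = unsettled.
#' @param count_mat matrix of per-cell building counts.
#' @param min_area_ha urban area threshold, ha.
#' @param min_count urban building-count threshold.
#' @return character matrix: `"urban"`, `"rural"`, or NA for unsettled cells.
#' @export
classify_settlement <- function(area_mat, count_mat,
                                min_area_ha = 40, min_count = 13) {
  stopifnot(all(dim(area_mat) == dim(count_mat)))
  nr <- nrow(area_mat); nc <- ncol(area_mat)
  settled <- area_mat > 0
  comp <- matrix(0L, nr, nc)
  cur <- 0L
  # queue-based flood fill, 8-neighbour
  for (start in which(settled & comp == 0L)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      r <- ((j - 1L) %% nr) + 1L; cl <- ((j - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        jj <- (cc - 1L) * nr + rr
        if (settled[jj] && comp[jj] == 0L) { comp[jj] <- cur; queue <- c(queue, jj) }
      }
    }
  }
  out <- matrix(NA_character_, nr, nc)
  if (cur > 0L) {
    idx <- which(settled)
    carea <- tapply(area_mat[idx], comp[idx], sum)
    ccount <- tapply(count_mat[idx], comp[idx], sum)
    urban_comps <- as.integer(names(carea))[carea >= min_area_ha & ccount >= min_count]
    out[idx] <- ifelse(comp[idx] %in% urban_comps, "urban", "rural")
  }
  out
}

#' Screen candidate covariates against observed log-densities
#'
#' Ranks candidates by the absolute Pearson correlation of each candidate
#' with observed log population density, then greedily walks the ranking and
#' drops any candidate whose absolute pairwise correlation with an
#' already-kept, better-ranked candidate reaches `collinearity_threshold`.
#' Candidates named in `drop_circular` (by default the building count, which
#' enters the model through other channels) and zero-variance candidates are
#' excluded up front.  Every decision is itemized in the report.
#'
#' @param candidates data.frame/matrix of candidate covariates (columns).
#' @param log_density numeric vector of observed log densities.
#' @param n_keep retain at most this many covariates, default 5.
#' @param collinearity_threshold absolute pairwise correlation at or above
#'   which the lower-ranked candidate is dropped, default 0.8.
#' @param drop_circular candidate names dropped a priori for circularity.
#' @return list with `selected` (character), `report` (data.frame: candidate,
#'   abs_r, decision, reason).
#' @export
select_covariates <- function(candidates, log_density, n_keep = 5,
                              collinearity_threshold = 0.8,
                              drop_circular = "building_count") {
  candidates <- as.data.frame(candidates)
  check(ncol(candidates) >= 2, "need at least two candidates")
  check(length(log_density) == nrow(candidates) && length(log_density) >= 3,
        "need >= 3 observations")
  nm <- names(candidates)
  absr <- rep(NA_real_, length(nm)); names(absr) <- nm
  decision <- reason <- setNames(rep("", length(nm)), nm)
  for (j in nm) {
    v <- candidates[[j]]
    if (j %in% drop_circular) {
      decision[j] <- "dropped"; reason[j] <- "circular: used elsewhere in the model"
    } else if (sd(v) == 0 || anyNA(v)) {
      decision[j] <- "excluded"; reason[j] <- "zero variance or missing values"
    } else {
      absr[j] <- abs(cor(v, log_density))
    }
  }
  ranked <- names(sort(absr[decision == ""], decreasing = TRUE))
  kept <- character(0)
  for (j in ranked) {
    if (length(kept) >= n_keep) {
      decision[j] <- "dropped"; reason[j] <- "beyond n_keep"
      next
    }
    rr <- if (length(kept)) abs(cor(candidates[, kept, drop = FALSE],
                                    candidates[[j]])) else 0
    if (any(rr >= collinearity_threshold)) {
      partner <- kept[which.max(rr)]
      decision[j] <- "dropped"
      reason[j] <- sprintf("collinear with %s (|r| = %.3f)", partner, max(rr))
    } else {
      kept <- c(kept, j)
      decision[j] <- "kept"
      reason[j] <- sprintf("|r| with log-density = %.3f", absr[j])
    }
  }
  report <- data.frame(candidate = nm, abs_r = absr[nm],
                       decision = decision[nm], reason = reason[nm],
                       row.names = NULL)
  list(selected = kept, report = report)
}

#' Scale covariates with grid-level constants
#'
#' `z = (x - center) / scale` with constants computed once at the grid-cell
#' level and applied identically to grid cells and cluster summaries, so
#' cluster covariates live on the prediction grid's scale.
#'
#' @param x numeric vector or matrix (columns scaled independently).
#' @param center,scale grid-level means and sds (scalars or per-column).
#' @return scaled values, same shape as `x`.
#' @export
scale_covariates <- function(x, center, scale) {
  check(all(scale > 0), "zero grid sd")
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  } else (x - center) / scale
}
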