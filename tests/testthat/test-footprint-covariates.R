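test_that("footprint summaries convert units and handle degenerate zones", {
  fp <- data.frame(x = 0, y = 0, area_m2 = 100, zone = "z1")
  s <- summarize_footprints(fp)
  expect_equal(s$total_area_ha, 0.01)
  expect_equal(s$n, 1L)
  expect_true(is.na(s$mean_nn_dist_m))

  fp2 <- data.frame(x = c(0, 10), y = c(0, 0), area_m2 = c(50, 50), zone = 1)
  s2 <- summarize_footprints(fp2)
  expect_equal(s2$cv_area, 0)
  expect_equal(s2$mean_nn_dist_m, 10)

  # empty zone reported with zero counts
  s3 <- summarize_footprints(fp, zones = c("z1", "z2"))
  expect_equal(s3$n, c(1L, 0L))
  expect_equal(s3$total_area_ha, c(0.01, 0))
})

test_that("mean nearest-neighbour distance matches brute-force pairwise search", {
  fp <- data.frame(x = c(0, 10, 30), y = 0, area_m2 = 1, zone = 1)
  s <- summarize_footprints(fp)
  expect_equal(s$mean_nn_dist_m, (10 + 10 + 20) / 3)
  expect_equal(s$mean_proximity, 3 / 40)

  set.seed(4)
  fpr <- data.frame(x = runif(25, 0, 500), y = runif(25, 0, 500),
                    area_m2 = runif(25, 20, 200), zone = 1)
  nn <- vapply(seq_len(25), function(i) {
    min(sqrt((fpr$x[i] - fpr$x[-i])^2 + (fpr$y[i] - fpr$y[-i])^2))
  }, 0)
  expect_equal(summarize_footprints(fpr)$mean_nn_dist_m, mean(nn),
               tolerance = 1e-12)
})

test_that("focal means equal brute-force window means", {
  m <- matrix(5, 8, 8)
  expect_equal(focal_summary(m, 300), m)

  m1 <- matrix(0, 9, 9); m1[5, 5] <- 1
  f1 <- focal_summary(m1, 300)      # 3x3 window
  expect_true(all(f1[abs(row(f1) - 5) <= 1 & abs(col(f1) - 5) <= 1] > 0))
  expect_true(all(f1[abs(row(f1) - 5) > 1 | abs(col(f1) - 5) > 1] == 0))

  set.seed(7)
  m2 <- matrix(rnorm(100), 10, 10)
  hw <- 2                            # 500 m window at 100 m cells
  brute <- matrix(NA_real_, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    rr <- max(1, i - hw):min(10, i + hw)
    cc <- max(1, j - hw):min(10, j + hw)
    brute[i, j] <- mean(m2[rr, cc])
  }
  expect_equal(focal_summary(m2, 500), brute, tolerance = 1e-10)

  expect_error(focal_summary(m2, 50), "window")
})

test_that("settlement classification applies the 40 ha / 13 building rule", {
  # single 10-cell component; tune area and count around the thresholds
  mk <- function(total_area, count) {
    am <- matrix(0, 5, 10); cm <- matrix(0L, 5, 10)
    am[3, 1:10] <- total_area / 10
    cm[3, 1:10] <- c(rep(ceiling(count / 10), count %% 10),
                     rep(floor(count / 10), 10 - count %% 10))
    if (sum(cm[3, ]) != count) cm[3, 1] <- cm[3, 1] + count - sum(cm[3, ])
    classify_settlement(am, cm)[3, 1]
  }
  expect_equal(mk(39.9, 100), "rural")
  expect_equal(mk(45, 12), "rural")
  expect_equal(mk(40, 13), "urban")

  # 8-neighbour connectivity: diagonal cells join a component
  am <- matrix(0, 4, 4); am[1, 1] <- 30; am[2, 2] <- 10
  cm <- matrix(0L, 4, 4); cm[1, 1] <- 10L; cm[2, 2] <- 3L
  cls <- classify_settlement(am, cm)
  expect_equal(cls[1, 1], "urban")
  expect_equal(cls[2, 2], "urban")
  expect_true(is.na(cls[4, 4]))

  # classification is invariant to cell enumeration order (transpose world)
  set.seed(11)
  am2 <- matrix(rbinom(400, 1, 0.3) * runif(400, 0.5, 6), 20, 20)
  cm2 <- matrix(rpois(400, 3) * (am2 > 0), 20, 20)
  expect_equal(t(classify_settlement(am2, cm2)),
               classify_settlement(t(am2), t(cm2)))
})

test_that("covariate screening ranks by |r| and drops collinear candidates", {
  set.seed(3)
  y <- rnorm(60)
  cand <- data.frame(a = y, b = rnorm(60))
  sel <- select_covariates(cand, y, n_keep = 2)
  expect_equal(sel$report$decision[sel$report$candidate == "a"], "kept")
  expect_equal(sel$selected[1], "a")

  # a duplicate of a kept candidate is dropped for collinearity
  cand2 <- data.frame(a = y, dup = y + rnorm(60, 0, 1e-8), b = rnorm(60))
  sel2 <- select_covariates(cand2, y, n_keep = 3)
  expect_true("dup" %in% sel2$report$candidate[sel2$report$decision == "dropped"])

  # circular and zero-variance candidates are excluded with reasons
  cand3 <- data.frame(building_count = rnorm(60), flat = rep(1, 60), b = rnorm(60),
                      c = rnorm(60))
  sel3 <- select_covariates(cand3, y)
  rep3 <- sel3$report
  expect_match(rep3$reason[rep3$candidate == "building_count"], "circular")
  expect_equal(rep3$decision[rep3$candidate == "flat"], "excluded")
})

test_that("screening recovers planted correlation strengths", {
  set.seed(19)
  n <- 4000
  rs <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  y <- rnorm(n)
  cand <- sapply(rs, function(r) r * y + sqrt(1 - r^2) * rnorm(n))
  colnames(cand) <- paste0("c", seq_along(rs))
  sel <- select_covariates(as.data.frame(cand), y, n_keep = 5,
                           collinearity_threshold = 0.99)
  expect_equal(sel$selected, paste0("c", 1:5))
  # report's |r| agrees with an independent correlation computation
  ind_r <- abs(apply(cand, 2, function(v)
    sum((v - mean(v)) * (y - mean(y))) /
      sqrt(sum((v - mean(v))^2) * sum((y - mean(y))^2))))
  expect_equal(unname(sel$report$abs_r), unname(ind_r), tolerance = 1e-12)
})

test_that("covariate scaling applies shared grid constants", {
  expect_equal(scale_covariates(3, 3, 2), 0)
  expect_equal(scale_covariates(5, 3, 2), 1)
  set.seed(2)
  g <- rnorm(100, 10, 4)
  z <- scale_covariates(g, mean(g), sd(g))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(scale_covariates(1, 0, 0), "zero grid sd")
})
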