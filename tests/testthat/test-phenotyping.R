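test_that("coefficient of variation reproduces published summary rows", {
  ## sample path: vectors constructed with the printed moments
  x <- sample_with_moments(93, 95997.4, 48223.0)
  expect_equal(cv_percent(x), 50.2, tolerance = 0.002)
  y <- sample_with_moments(45, 45.76, 6.68)
  expect_equal(cv_percent(y), 14.6, tolerance = 0.005)
  ## moment path over all frozen rows, to the printed 0.1 precision
  expect_true(all(abs(cv_from_moments(PRINTED_CVS$mean, PRINTED_CVS$sd) -
                        PRINTED_CVS$cv) <= 0.1))
  ## degenerate and invariance behavior
  expect_equal(cv_percent(rep(4.2, 10)), 0)
  set.seed(2); v <- abs(rnorm(30, 10))
  expect_equal(cv_percent(17 * v), cv_percent(v), tolerance = 1e-12)
  expect_error(cv_percent(c(-1, 1)), class = "sf_undefined_error")
  expect_error(cv_percent(5), class = "sf_input_error")
})

test_that("min-max scaling hits [0,1], inverts, and handles constants", {
  pm <- minmax_scale(cbind(a = c(2, 4, 6), b = c(1, 0, 1)))
  expect_equal(pm$scaled[, "a"], c(0, 0.5, 1))
  ## idempotence on an already-[0,1] column
  expect_equal(minmax_scale(pm$scaled)$scaled, pm$scaled)
  ## inverse round trip on a random matrix
  set.seed(12)
  x <- matrix(rnorm(60, 5, 3), 12, 5, dimnames = list(NULL, letters[1:5]))
  expect_equal(minmax_inverse(minmax_scale(x)), x, tolerance = 1e-12)
  ## constant columns go to zero with a classed warning
  expect_warning(cm <- minmax_scale(cbind(k = rep(3, 4), v = 1:4)),
                 class = "sf_constant_column_warning")
  expect_equal(unname(cm$scaled[, "k"]), rep(0, 4))
  expect_error(minmax_scale(matrix(1, 1, 2)), class = "sf_input_error")
})

test_that("PCA explains rank-1 data fully and is variance-conserving", {
  line <- cbind(x = 1:10, y = 2 * (1:10) + 3)
  p <- run_pca(line)
  expect_equal(p$explained_proportion[1], 1, tolerance = 1e-12)
  set.seed(4)
  x <- matrix(rnorm(200), 40, 5)
  p <- run_pca(x, n_components = 5)
  expect_equal(sum(p$explained_proportion), 1, tolerance = 1e-12)
  expect_true(all(diff(p$explained_proportion) <= 1e-12))
  ## isotropic 2-D gaussian: each component ~0.5
  set.seed(100)
  g <- matrix(rnorm(20000), 10000, 2)
  pg <- run_pca(g)
  expect_equal(pg$explained_proportion[1], 0.5, tolerance = 0.04)
  ## full-rank scores preserve pairwise distances (isometry)
  d0 <- dist(scale(x, scale = FALSE))
  d1 <- dist(p$all_scores)
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  ## deterministic sign: largest loading positive
  for (j in 1:2) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  expect_error(run_pca(matrix(1, 5, 3)), class = "sf_degenerate_error")
})

test_that("average linkage matches its definition and brute-force oracle", {
  ## singleton merge height = Euclidean distance
  x <- rbind(a = c(0, 0), b = c(3, 4))
  hc <- run_hclust(x, k = NULL)$hclust
  expect_equal(hc$height, 5)
  ## {a} vs {b, c}: merge at (d(a,b) + d(a,c)) / 2
  y <- rbind(a = c(0, 0), b = c(10, 0), c = c(12, 0))
  hy <- run_hclust(y, k = NULL)$hclust
  expect_equal(sort(hy$height), c(2, 11))
  ## brute-force cophenetic oracle, all random instances n <= 8
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(3:8, 1)
    m <- matrix(rnorm(n * 4), n, 4)
    hc <- run_hclust(m, k = NULL)$hclust
    coph <- as.matrix(stats::cophenetic(hc))
    oracle <- upgma_oracle_cophenetic(as.matrix(dist(m)))
    dimnames(oracle) <- dimnames(coph)
    expect_equal(coph, oracle, tolerance = 1e-9)
    ## merge heights non-decreasing (UPGMA is monotone for Euclidean data)
    expect_true(all(diff(hc$height) >= -1e-12))
  }
  expect_error(run_hclust(rbind(c(1, 2)), k = 1), class = "sf_input_error")
  expect_error(run_hclust(x, k = 5), class = "sf_input_error")
})

test_that("two separated groups are recovered by a 2-cut", {
  set.seed(77)
  sd_w <- 1
  a <- matrix(rnorm(25 * 4, 0, sd_w), 25, 4)
  b <- matrix(rnorm(25 * 4, 4 * sd_w, sd_w), 25, 4)  # 4x within-group SD
  cl <- run_hclust(rbind(a, b), k = 2)
  expect_gte(cluster_purity(cl$labels, rep(c("a", "b"), each = 25)), 0.95)
})

test_that("group comparison matches the closed-form Welch formula", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  ## identical groups: t = 0, p = 1 (and the vacuous constant case)
  expect_equal(compare_groups(c(5, 5), c(5, 5)), list(t = 0, p_value = 1, stars = ""))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  set.seed(9)
  a <- rnorm(50, 0, 1); b <- rnorm(50, 5, 1)
  expect_lt(compare_groups(a, b)$p_value, 0.001)
  expect_equal(compare_groups(a, b)$stars, "***")
  ## closed-form oracle on a hand-specified fixture
  x <- c(2.1, 3.4, 1.9, 4.0, 2.8); y <- c(5.5, 6.1, 4.9, 7.2)
  se <- sqrt(var(x) / 5 + var(y) / 4)
  t_oracle <- (mean(x) - mean(y)) / se
  df_oracle <- se^4 / ((var(x) / 5)^2 / 4 + (var(y) / 4)^2 / 3)
  p_oracle <- 2 * pt(abs(t_oracle), df_oracle, lower.tail = FALSE)
  got <- compare_groups(x, y)
  expect_equal(got$t, t_oracle, tolerance = 1e-10)
  expect_equal(got$p_value, p_oracle, tolerance = 1e-10)
  expect_error(compare_groups(1, c(1, 2)), class = "sf_input_error")
})

test_that("bioenergetic maps aggregate basal and stressed points per group", {
  rec1 <- data.frame(cell_line = "L1", size_class = "(07-10)k",
                     last_basal_ocr = 3, last_basal_ecar = 1.2,
                     stressed_ocr = 5, stressed_ecar = 1.6)
  m1 <- bioenergetic_map(rec1)
  expect_equal(m1$basal_ocr_mean, 3)
  expect_equal(m1$n, 1)
  expect_true(is.na(m1$basal_ocr_sd))

  ## null stress (fccp multiplier 1, stress ecar multiplier 1): stressed
  ## and basal coincide within noise
  prof_null <- cell_line_profile("null", 3.8, 1.5, oligo_fraction = 0.55,
                                 fccp_multiplier = 1, non_mito_fraction = 0.3,
                                 stress_ecar_multiplier = 1)
  cfg <- cohort_config("single", n_wells = 30, seed = 6)
  pk <- assign_phases(simulate_cohort(cfg, prof_null)$kinetics)
  p <- extract_params_plate(pk)
  expect_lt(abs(mean(p$stressed_ocr) / mean(p$last_basal_ocr) - 1), 0.1)

  ## plastic profile (fccp multiplier 1.6): stressed OCR > basal OCR
  pk2 <- assign_phases(simulate_cohort(cfg, profile_aerobic())$kinetics)
  p2 <- extract_params_plate(pk2)
  tt <- compare_groups(p2$stressed_ocr, p2$last_basal_ocr)
  expect_gt(mean(p2$stressed_ocr), mean(p2$last_basal_ocr))
  expect_lt(tt$p_value / 2, 0.01)  # one-sided
})

test_that("cv_summary lays out group x parameter rows", {
  df <- data.frame(g = rep(c("a", "b"), each = 5),
                   p1 = c(rnorm(5, 10), rnorm(5, 20)),
                   p2 = rnorm(10))
  s <- cv_summary(df, "g", c("p1", "p2"))
  expect_equal(nrow(s), 4)
  expect_equal(s$n, rep(5, 4))
  row <- s[s$group == "a" & s$parameter == "p1", ]
  expect_equal(row$cv_pct, 100 * row$sd / row$mean)
})
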