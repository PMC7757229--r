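test_that("ROC on separable classes reaches perfect discrimination", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  roc <- roc_threshold(scores, labels)
  expect_equal(roc$best_sensitivity, 1)
  expect_equal(roc$best_specificity, 1)
  expect_equal(roc$best_threshold, 6.5)  # midpoint of the class gap
  expect_error(roc_threshold(1:5, rep(TRUE, 5)), "both classes")
})

test_that("ROC curve is monotone and its best point dominates in Youden's J", {
  set.seed(42)
  scores <- rnorm(60)
  labels <- scores + rnorm(60) > 0
  roc <- roc_threshold(scores, labels)
  expect_true(all(diff(roc$sensitivity) <= 1e-12))
  expect_true(all(diff(roc$specificity) >= -1e-12))
  expect_equal(max(roc$youden_j),
               roc$best_sensitivity + roc$best_specificity - 1)
})

test_that("ROC on permuted labels finds no discriminating threshold", {
  set.seed(7)
  scores <- rnorm(1000)
  labels <- sample(rep(c(TRUE, FALSE), 500))
  roc <- roc_threshold(scores, labels)
  expect_lt(max(roc$youden_j), 0.12)
})

test_that("ROC equals the counting oracle on random inputs", {
  set.seed(88)
  for (n in c(5, 17, 60)) {
    scores <- round(rnorm(n), 1)  # duplicated scores exercise tie handling
    labels <- runif(n) > 0.5
    if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
    got <- roc_threshold(scores, labels)
    want <- brute_roc(scores, labels)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    expect_equal(got$best_threshold, want$best_threshold)
  }
})

test_that("dual thresholds recover the generative class structure", {
  rep <- run_pipeline(run_config(seed = 3))
  th <- rep$thresholds
  r <- rep$records
  # theta_ratio sits between the two generative ratio distributions
  expect_gt(th$theta_ratio, max(r$ratio_bbp_chl[!r$bloom_truth]) * 0.5)
  expect_lt(th$theta_ratio, min(r$ratio_bbp_chl[r$bloom_truth]) * 2)
  expect_gte(th$sensitivity, 90)
  expect_gte(th$specificity, 90)
  expect_error(fit_dual_thresholds(r[r$bloom_label, ]), "both classes")
})

test_that("combined rule is at least as specific as the ratio threshold alone", {
  rep <- run_pipeline(run_config(seed = 9))
  r <- rep$records
  th <- rep$thresholds
  stage1 <- r$ratio_bbp_chl > th$theta_ratio
  combined <- classify_records(r, th)
  spec1 <- sum(!stage1 & !r$bloom_label) / sum(!r$bloom_label)
  spec2 <- sum(!combined & !r$bloom_label) / sum(!r$bloom_label)
  expect_gte(spec2, spec1)
})

test_that("classification follows the strict dual-threshold conjunction", {
  na_row <- published_thresholds()[1, ]  # North Atlantic subpolar gyre
  rec <- tibble::tibble(ratio_bbp_chl = c(0.012, 0.012, 0.004, 0.0063, NA),
                        bbp_surf = c(0.004, 0.001, 0.004, 0.004, 0.002))
  calls <- classify_records(rec, na_row)
  expect_identical(calls, c(TRUE, FALSE, FALSE, FALSE, NA))
  # record exactly on the threshold is non-bloom (strict inequality)
  expect_false(calls[4])
})

test_that("classification is invariant to record order and duplication", {
  th <- list(theta_ratio = 0.0063, theta_bbp = 0.0033)
  set.seed(5)
  rec <- tibble::tibble(ratio_bbp_chl = runif(20, 0, 0.02),
                        bbp_surf = runif(20, 0, 0.01))
  calls <- classify_records(rec, th)
  perm <- sample(20)
  expect_identical(classify_records(rec[perm, ], th), calls[perm])
  expect_identical(classify_records(rec[rep(1:20, 2), ], th), rep(calls, 2))
})

test_that("group comparison matches a hand-computed rank statistic", {
  # ranks 1..6 alternate between groups: H = 12/42 * (27 + 48) - 21 = 3/7
  out <- compare_groups(c(1, 3, 5), c(2, 4, 6))
  expect_equal(out$statistic, 3 / 7, tolerance = 1e-12)
  ident <- compare_groups(rep(2, 5), rep(2, 7))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
})

test_that("a 3x ratio contrast is detected at p < 1e-2", {
  set.seed(202)
  hits <- 0
  for (k in 1:100) {
    x_in <- rnorm(50, 0.012, 0.003)
    x_out <- rnorm(50, 0.004, 0.001)
    if (compare_groups(x_in, x_out)$p_value < 1e-2) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("refractive index model behaves physically", {
  # pure-water limit
  expect_lt(refractive_index(1e-9), 1.0001)
  # in-bloom backscattering ratio maps near the calcite-influenced 1.13
  expect_equal(refractive_index(0.013), 1.13, tolerance = 0.02)
  # bloom vs non-bloom means order correctly (monotone in the ratio)
  expect_lt(refractive_index(0.008), refractive_index(0.013))
  bt <- seq(0.001, 0.05, length.out = 50)
  expect_true(all(diff(refractive_index(bt)) > 0))
  expect_true(all(refractive_index(bt) > 1 & refractive_index(bt) < 1.3))
  expect_error(refractive_index(0))
  expect_error(refractive_index(0.2), "validity")
})

test_that("region polygons contain their nominal float locations", {
  polys <- region_polygons()
  expect_true(point_in_polygon(60, -30, polys[["North Atlantic subpolar gyre"]]))
  expect_true(point_in_polygon(-47, 52,
                               polys[["Indian sector of the Southern Ocean"]]))
  expect_false(point_in_polygon(0, 0, polys[["Patagonian shelf"]]))
  th <- published_thresholds()
  expect_equal(nrow(th), 4)
  expect_true(all(th$theta_ratio > 0 & th$theta_bbp > 0))
})
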