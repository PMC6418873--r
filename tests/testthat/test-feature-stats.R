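test_that("quantization: endpoints, constants, full range", {
  expect_true(all(quantize_map(array(2.7, c(3, 3, 3))) == 0L))
  q <- quantize_map(array(c(0, 1, 0, 1), c(2, 2, 1)))
  expect_setequal(unique(as.vector(q)), c(0L, 255L))
  set.seed(21)
  for (r in 1:20) {
    q <- quantize_map(array(rnorm(5 * 5 * 5), c(5, 5, 5)))
    expect_equal(min(q), 0L)
    expect_equal(max(q), 255L)
    expect_true(all(q >= 0 & q <= 255))
  }
  expect_error(quantize_map(array(c(1, NA), c(2, 1, 1))), "non-finite")
})

test_that("entropy: closed-form cases and bounds", {
  expect_equal(map_entropy(array(0L, c(4, 4, 4))), 0)
  expect_equal(map_entropy(array(rep(0:255, 2), c(16, 16, 2))), log(256))
  expect_equal(map_entropy(array(rep(c(0L, 255L), 8), c(4, 4, 1))), log(2))
  # bounds and relabeling invariance, property-style
  set.seed(31)
  for (r in 1:20) {
    q <- quantize_map(array(runif(6 * 6 * 6), c(6, 6, 6)))
    H <- map_entropy(q)
    expect_gte(H, 0)
    expect_lte(H, log(256))
    perm <- sample(0:255)
    q2 <- array(perm[as.vector(q) + 1L], dim(q))
    expect_equal(map_entropy(q2), H)
  }
  expect_error(map_entropy(integer()), "empty")
})

test_that("Welch t-test matches an independently coded formula", {
  a <- c(1.1, 2.3, 0.7, 1.9, 1.5)
  b <- c(2.8, 3.1, 2.2, 3.6, 2.9)
  got <- two_sample_ttest(a, b)
  # hand-coded Welch
  se2 <- var(a) / 5 + var(b) / 5
  t_ref <- (mean(a) - mean(b)) / sqrt(se2)
  df_ref <- se2^2 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  p_ref <- 2 * pt(abs(t_ref), df_ref, lower.tail = FALSE)
  expect_equal(unname(got["t"]), t_ref, tolerance = 1e-12)
  expect_equal(unname(got["p"]), p_ref, tolerance = 1e-12)
  # antisymmetry under group swap
  swp <- two_sample_ttest(b, a)
  expect_equal(unname(swp["t"]), -t_ref, tolerance = 1e-12)
  expect_equal(unname(swp["p"]), p_ref, tolerance = 1e-12)
  # identical lists: equal means, t = 0, p = 1
  same <- two_sample_ttest(a, a)
  expect_equal(unname(same["t"]), 0)
  expect_equal(unname(same["p"]), 1)
  expect_error(two_sample_ttest(rep(1, 3), rep(1, 3)), "degenerate")
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("Bonferroni threshold", {
  expect_equal(bonferroni_threshold(0.05, 32), 1.5625e-3)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(1.2, 4), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("family-wise error of the 32 Bonferroni-corrected tests <= 0.05", {
  # 200 null cohorts of per-subject statistics, 32 features each
  set.seed(71)
  thr <- bonferroni_threshold(0.05, 32)
  fam_err <- 0
  for (r in 1:200) {
    ps <- vapply(1:32, function(f)
      two_sample_ttest(rnorm(15), rnorm(15))["p"], 0)
    if (any(ps < thr)) fam_err <- fam_err + 1
  }
  # binomial(200, 0.05) upper band: 10 + 3 * sqrt(200 * .05 * .95) ~ 19
  expect_lte(fam_err, 19)
})

test_that("feature_group_analysis: shape, flags, degenerate features", {
  ds <- make_separable_dataset(16, c(8, 8, 8), seed = 11)
  cfg <- training_config(batch_size = 8, epochs = 2, seed = 12)
  tr <- dticnn:::.subset_dataset(ds, ds$subject_ids[1:12])
  va <- dticnn:::.subset_dataset(ds, ds$subject_ids[13:16])
  fit <- train_cnn3d(build_cnn3d(c(8, 8, 8), cfg), tr, va, cfg)
  tab <- feature_group_analysis(fit$model, ds)
  expect_equal(nrow(tab), 32)
  expect_named(tab, c("feature", "mean_A", "mean_B", "t_mean", "p_mean",
                      "sig_mean", "H_A", "H_B", "t_H", "p_H", "sig_H"))
  expect_equal(attr(tab, "threshold"), 0.05 / 32)
  expect_identical(tab$sig_mean, tab$p_mean < 0.05 / 32)
  expect_identical(tab$sig_H, tab$p_H < 0.05 / 32)
  # the two constant-intensity classes differ strongly in mean voxel values
  expect_gt(sum(tab$sig_mean), 0)
  # degenerate features (if any) are t = 0 / p = 1, never NA
  expect_false(anyNA(tab$p_mean))
  expect_false(anyNA(tab$p_H))
  # missing group errors
  one <- dticnn:::.subset_dataset(ds, ds$subject_ids[c(1, 3, 5)])
  one <- prepared_dataset(one$volumes, one$labels, one$subject_ids)
  expect_error(feature_group_analysis(fit$model, one), "both groups")
})
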