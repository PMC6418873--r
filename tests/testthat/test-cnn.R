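test_that("architecture arithmetic matches hand calculation", {
  cfg <- training_config(seed = 1)
  m <- build_cnn3d(c(58, 70, 58), cfg)
  expect_equal(m$arch$spatial[[1]], c(29L, 35L, 29L))
  expect_equal(m$arch$spatial[[2]], c(15L, 18L, 15L))
  expect_equal(m$arch$spatial[[3]], c(8L, 9L, 8L))
  expect_equal(m$arch$flat_size, 8 * 9 * 8 * 128)    # 73728
  pc <- parameter_counts(m)
  expect_equal(unname(pc["W1"] + pc["b1"]), 27 * 1 * 32 + 32)   # 896
  expect_equal(unname(pc["Wl"] + pc["bl"]), 73728 * 2 + 2)      # 147458
  expect_equal(m$arch$channels, c(32L, 64L, 128L))
  # two more input shapes, independently hand-propagated
  m2 <- build_cnn3d(c(24, 28, 24), cfg)
  expect_equal(m2$arch$spatial[[3]], c(3L, 4L, 3L))
  expect_equal(m2$arch$flat_size, 3 * 4 * 3 * 128)
  m3 <- build_cnn3d(c(8, 8, 8), cfg)
  expect_equal(m3$arch$spatial[[3]], c(1L, 1L, 1L))
  expect_error(build_cnn3d(c(6, 24, 24), cfg), ">= 8")
})

test_that("initialization is truncated, seeded and deterministic", {
  cfg <- training_config(seed = 5, init_sd = 0.1)
  m1 <- build_cnn3d(c(8, 8, 8), cfg)
  m2 <- build_cnn3d(c(8, 8, 8), cfg)
  expect_identical(m1$params, m2$params)
  expect_lte(max(abs(m1$params$W1)), 0.2)           # +- 2 sd truncation
  expect_gt(sd(m1$params$W2), 0.08)
  expect_true(all(m1$params$b1 == 0))
  expect_true(all(m1$params$g1 == 1))
})

test_that("forward produces normalized, batch-independent probabilities", {
  cfg <- training_config(seed = 2)
  m <- build_cnn3d(c(8, 10, 8), cfg)
  set.seed(9)
  batch <- array(rnorm(8 * 10 * 8 * 45), c(8, 10, 8, 45))
  pr <- forward(m, batch)
  expect_equal(rowSums(pr), rep(1, 45), tolerance = 1e-6)
  expect_true(all(pr >= 0))
  # one volume alone vs inside the batch of 45 (inference batch-norm contract)
  pr1 <- forward(m, batch[, , , 1])
  expect_equal(unname(pr1[1, ]), unname(pr[1, ]), tolerance = 1e-6)
  # zero linear weights: exact symmetry
  m0 <- m
  m0$params$Wl[] <- 0; m0$params$bl[] <- 0
  pr0 <- forward(m0, batch[, , , 1:3])
  expect_equal(as.vector(pr0), rep(0.5, 6))
  expect_error(forward(m, array(0, c(9, 10, 8, 2))), "does not match")
})

test_that("cross-entropy cost matches hand-summed oracle", {
  expect_equal(cross_entropy_cost(c(1, 0), c(1, 0)), 0)
  expect_equal(cross_entropy_cost(c(0.5, 0.5), c(0, 1)), log(2))
  p <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.6, 0.4))
  y <- rbind(c(1, 0), c(0, 1), c(0, 1))
  expect_equal(cross_entropy_cost(p, y),
               -(log(0.9) + log(0.8) + log(0.4)))
  expect_error(cross_entropy_cost(p, y[1:2, ]), "matching")
  expect_gte(cross_entropy_cost(rbind(c(1, 0)), rbind(c(0, 1))), 0)
})

test_that("fused training step agrees with the composable reference ops", {
  cfg <- training_config(batch_size = 5, seed = 7)
  m <- build_cnn3d(c(8, 10, 8), cfg)
  set.seed(2)
  xb <- array(rnorm(8 * 10 * 8 * 5, sd = 0.4), c(8, 10, 8, 1, 5))
  yb <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1), c(1, 0))
  ref_fw <- dticnn:::.forward_train(m, xb, yb)
  ref_g <- dticnn:::.backward(m, ref_fw$cache, yb)
  stp <- dticnn:::.cnn_step(xb, yb, m$params, m$arch$pool, dticnn:::BN_EPS)
  expect_equal(stp$cost, ref_fw$cost, tolerance = 1e-5)
  expect_equal(stp$probs, ref_fw$probs, tolerance = 1e-5, ignore_attr = TRUE)
  for (k in c("W1", "g1", "be1", "W2", "g2", "be2", "W3", "g3", "be3",
              "Wl", "bl")) {
    scale <- max(abs(ref_g[[k]]), 1e-6)
    expect_lt(max(abs(stp$grads[[k]] - ref_g[[k]])) / scale, 1e-4,
              label = paste("grad", k))
  }
  # conv biases: analytically ~0 through batch norm; both paths must agree
  for (k in c("b1", "b2", "b3"))
    expect_lt(max(abs(stp$grads[[k]])), 1e-2, label = paste("grad", k))
  # fused inference equals the composed stack
  batch <- array(xb, c(8, 10, 8, 5))
  pr_fused <- forward(m, batch)
  a <- dticnn:::.forward_infer_stack(m, xb)
  flat <- matrix(a, m$arch$flat_size, 5)
  logits <- crossprod(m$params$Wl, flat) + m$params$bl
  pr_ref <- t(dticnn:::softmax_cols(logits))
  expect_equal(pr_fused, pr_ref, tolerance = 1e-5)
})

test_that("training solves a separable problem and is deterministic", {
  ds <- make_separable_dataset(20, c(8, 8, 8), seed = 1)
  cfg <- training_config(batch_size = 8, epochs = 5, seed = 2)
  tr <- dticnn:::.subset_dataset(ds, ds$subject_ids[1:14])
  va <- dticnn:::.subset_dataset(ds, ds$subject_ids[15:17])
  te <- dticnn:::.subset_dataset(ds, ds$subject_ids[18:20])
  fit1 <- train_cnn3d(build_cnn3d(c(8, 8, 8), cfg), tr, va, cfg)
  expect_equal(nrow(fit1$history), 5)
  expect_equal(max(fit1$history$val_accuracy), 1)
  pred <- predict_groups(fit1$model, te$volumes)
  expect_equal(accuracy(pred, ifelse(te$labels[, 1] == 1, "A", "B")), 1)
  # training cost is non-increasing after the first epoch (5% tolerance,
  # plus an absolute floor for near-zero costs)
  cost <- fit1$history$train_cost
  for (e in 2:(length(cost) - 1))
    expect_lte(cost[e + 1], cost[e] * 1.05 + 1e-3)
  # determinism
  fit2 <- train_cnn3d(build_cnn3d(c(8, 8, 8), cfg), tr, va, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_error(train_cnn3d(build_cnn3d(c(8, 8, 8), cfg), tr,
                           list(volumes = array(0, c(8, 8, 8, 0)),
                                labels = matrix(0, 0, 2)), cfg),
               "nonempty")
})

test_that("feature-map extraction yields 32/64/128 maps deterministically", {
  ds <- make_separable_dataset(12, c(8, 8, 8), seed = 3)
  cfg <- training_config(batch_size = 6, epochs = 2, seed = 4)
  tr <- dticnn:::.subset_dataset(ds, ds$subject_ids[1:8])
  va <- dticnn:::.subset_dataset(ds, ds$subject_ids[9:12])
  fit_a <- train_cnn3d(build_cnn3d(c(8, 8, 8), cfg), tr, va, cfg)
  fit_b <- train_cnn3d(build_cnn3d(c(8, 8, 8), cfg), tr, va, cfg)
  v <- ds$volumes[, , , 1]
  maps1 <- extract_feature_maps(fit_a$model, v, 1)
  expect_length(maps1, 32)
  expect_equal(dim(maps1[[1]]), c(4L, 4L, 4L))
  expect_length(extract_feature_maps(fit_a$model, v, 2), 64)
  maps3 <- extract_feature_maps(fit_a$model, v, 3)
  expect_length(maps3, 128)
  expect_error(extract_feature_maps(fit_a$model, v, 4), "layer_index")
  # identical training runs give bitwise-identical maps
  expect_identical(maps1, extract_feature_maps(fit_b$model, v, 1))
})

test_that("model checkpoints round-trip through HDF5", {
  ds <- make_separable_dataset(12, c(8, 8, 8), seed = 5)
  cfg <- training_config(batch_size = 6, epochs = 1, seed = 6)
  tr <- dticnn:::.subset_dataset(ds, ds$subject_ids[1:8])
  va <- dticnn:::.subset_dataset(ds, ds$subject_ids[9:12])
  fit <- train_cnn3d(build_cnn3d(c(8, 8, 8), cfg), tr, va, cfg)
  p <- tempfile(fileext = ".h5")
  save_model(fit$model, p)
  m2 <- load_model(p)
  expect_equal(m2$arch$input_shape, fit$model$arch$input_shape)
  expect_equal(m2$params$W2, fit$model$params$W2, ignore_attr = TRUE)
  expect_equal(forward(m2, ds$volumes[, , , 1:4]),
               forward(fit$model, ds$volumes[, , , 1:4]))
})
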