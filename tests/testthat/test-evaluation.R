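test_that("fold plan realizes 80/10/10 with disjoint covering test sets", {
  ids100 <- sprintf("s%03d", 1:100)
  plan <- make_fold_plan(ids100, seed = 1)
  for (f in plan$folds) {
    expect_length(f$train_ids, 80)
    expect_length(f$val_ids, 10)
    expect_length(f$test_ids, 10)
    expect_length(intersect(f$train_ids, f$val_ids), 0)
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    expect_length(intersect(f$val_ids, f$test_ids), 0)
    expect_setequal(c(f$train_ids, f$val_ids, f$test_ids), ids100)
  }
  # n = 10: one subject per block
  p10 <- make_fold_plan(sprintf("s%02d", 1:10), seed = 2)
  for (f in p10$folds) {
    expect_length(f$train_ids, 8)
    expect_length(f$val_ids, 1)
    expect_length(f$test_ids, 1)
  }
  expect_error(make_fold_plan(sprintf("s%d", 1:9), 1), "at least 10")
})

test_that("fold partition properties hold for arbitrary n (property-style)", {
  for (n in c(11, 23, 37, 50)) {
    ids <- sprintf("s%03d", seq_len(n))
    plan <- make_fold_plan(ids, seed = n)
    tests <- unlist(lapply(plan$folds, `[[`, "test_ids"))
    expect_length(tests, n)               # disjoint (no duplicates) ...
    expect_setequal(tests, ids)           # ... and jointly covering
    sizes <- vapply(plan$folds, function(f) length(f$test_ids), 0L)
    expect_lte(max(sizes) - min(sizes), 1)
    for (f in plan$folds)
      expect_setequal(c(f$train_ids, f$val_ids, f$test_ids), ids)
  }
})

test_that("accuracy is the exact-match fraction", {
  expect_equal(accuracy(c("A", "B"), c("A", "B")), 1)
  expect_equal(accuracy(c("A", "B"), c("B", "A")), 0)
  expect_equal(accuracy(c("A", "A", "B", "B"), c("A", "A", "B", "A")), 0.75)
  expect_error(accuracy(character(), character()), "empty")
  expect_error(accuracy("A", c("A", "B")), "mismatch")
})

test_that("nested CV recovers a separable problem end to end", {
  ds <- make_separable_dataset(20, c(8, 8, 8), seed = 7)
  plan <- make_fold_plan(ds$subject_ids, seed = 3)
  cfg <- training_config(batch_size = 8, epochs = 3, seed = 5)
  cv <- run_nested_cv(ds, cfg, plan)
  expect_length(cv$fold_accuracies, 10)
  expect_equal(cv$mean_accuracy, 1)
  expect_s3_class(cv$model, "cnn3d_model")
})

test_that("linear SVM matches scikit-learn's hinge-loss optimum", {
  set.seed(13)
  n <- 30; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.5) > 0, 1, -1)
  Xt <- rbind(t(X), 1)                      # bias as an augmented feature
  w <- dticnn:::linear_svm_fit(Xt, y, C = 1, max_iter = 200, tol = 1e-8,
                               seed = 1)
  obj <- function(w) 0.5 * sum(w^2) + sum(pmax(0, 1 - y * crossprod(Xt, w)))
  csv <- tempfile(fileext = ".csv")
  write.table(cbind(y, X), csv, sep = ",", row.names = FALSE, col.names = FALSE)
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np; from sklearn.svm import LinearSVC; ",
    "d = np.loadtxt('", csv, "', delimiter=','); y = d[:,0]; X = d[:,1:]; ",
    "Xa = np.hstack([X, np.ones((len(y),1))]); ",
    "m = LinearSVC(C=1.0, loss='hinge', fit_intercept=False, max_iter=200000, tol=1e-10).fit(Xa, y); ",
    "w = m.coef_.ravel(); ",
    "print(0.5*(w**2).sum() + np.maximum(0, 1 - y*(Xa@w)).sum())"
  ))), stdout = TRUE)
  sk_obj <- as.numeric(out[length(out)])
  expect_lte(obj(w), sk_obj * 1.01 + 1e-6)
  expect_gte(obj(w), sk_obj * 0.99 - 1e-6)
})

test_that("SVM baseline: separable limit and null calibration", {
  ds <- make_separable_dataset(20, c(8, 8, 8), seed = 9)
  plan <- make_fold_plan(ds$subject_ids, seed = 4)
  sv <- svm_baseline(ds, plan, seed = 1)
  expect_length(sv$fold_accuracies, 10)
  expect_equal(sv$mean_accuracy, 1)
  # labels independent of content: over 10 seeds the mean stays near chance
  accs <- vapply(1:10, function(s) {
    nds <- make_noise_dataset(40, c(6, 6, 6), seed = 100 + s)
    svm_baseline(nds, make_fold_plan(nds$subject_ids, seed = s),
                 seed = s)$mean_accuracy
  }, 0)
  expect_gte(mean(accs), 0.42)
  expect_lte(mean(accs), 0.58)
})
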