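# Nested cross-validation (80/10/10, ten rotating folds), accuracy, and the
# flattened-voxel linear SVM baseline.

#' Build a 10-fold nested cross-validation plan
#'
#' Subjects are shuffled once (seeded) and split into 10 near-equal blocks.
#' Fold i uses block i as the test set, block i+1 (mod 10) as the validation
#' set for snapshot selection, and the remaining 8 blocks for training, so
#' every subject is tested exactly once and the per-fold proportions are
#' 80%/10%/10% up to rounding.
#'
#' @param subject_ids Character vector (>= 10 subjects).
#' @param seed Integer seed for the single shuffle.
#' @return Object of class `fold_plan`: list of 10 folds, each with
#'   `train_ids`, `val_ids`, `test_ids`, plus `n_total` and `seed`.
#' @export
make_fold_plan <- function(subject_ids, seed) {
  n <- length(subject_ids)
  if (n < 10) stop("need at least 10 subjects for a 10-fold plan, got ", n)
  shuffled <- with_seed(seed, sample(subject_ids))
  sizes <- rep(n %/% 10, 10) + (seq_len(10) <= n %% 10)
  ends <- cumsum(sizes)
  blocks <- lapply(seq_len(10), function(i)
    shuffled[(ends[i] - sizes[i] + 1):ends[i]])
  folds <- lapply(seq_len(10), function(i) {
    vi <- i %% 10 + 1
    list(train_ids = unlist(blocks[-c(i, vi)], use.names = FALSE),
         val_ids = blocks[[vi]], test_ids = blocks[[i]])
  })
  structure(list(folds = folds, n_total = n, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Classification accuracy
#'
#' @param predictions,truth Equal-length nonempty label vectors.
#' @return Fraction of exact matches, in [0, 1].
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) == 0) stop("empty input")
  if (length(predictions) != length(truth)) stop("length mismatch")
  mean(predictions == truth)
}

.subset_dataset <- function(data, ids) {
  sel <- match(ids, data$subject_ids)
  if (anyNA(sel)) stop("fold plan contains unknown subject ids")
  list(volumes = data$volumes[, , , sel, drop = FALSE],
       labels = data$labels[sel, , drop = FALSE],
       subject_ids = data$subject_ids[sel])
}

#' Run nested cross-validation with the 3D CNN
#'
#' For each fold a fresh model is built (fold-specific seed derived from
#' `config$seed`), trained on the training block, snapshot-selected on the
#' validation block, and scored once on the held-out test block. The final
#' result is the mean (and SD) of the 10 test accuracies.
#'
#' @param data A [prepared_dataset()] (or path to a record store).
#' @param config A [training_config()].
#' @param plan A [make_fold_plan()] over the dataset's subjects.
#' @param pool Pooling flags forwarded to [build_cnn3d()].
#' @param keep_best_model Return the trained model from the fold with the
#'   highest validation accuracy (used downstream for feature analysis).
#' @return List of class `cv_result`: `fold_accuracies` (length 10),
#'   `mean_accuracy`, `sd_accuracy`, `model` (best-fold model or NULL),
#'   `histories`.
#' @export
run_nested_cv <- function(data, config, plan, pool = c(TRUE, TRUE, TRUE),
                          keep_best_model = TRUE) {
  if (is.character(data)) data <- load_prepared(data)
  stopifnot(inherits(plan, "fold_plan"))
  accs <- numeric(10)
  hists <- vector("list", 10)
  best_val <- -Inf; best_model <- NULL
  for (i in seq_len(10)) {
    f <- plan$folds[[i]]
    tr <- .subset_dataset(data, f$train_ids)
    va <- .subset_dataset(data, f$val_ids)
    te <- .subset_dataset(data, f$test_ids)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "fold", i)
    fit <- tryCatch(
      train_cnn3d(build_cnn3d(dim(data$volumes)[1:3], cfg, pool), tr, va, cfg),
      error = function(e) stop("fold ", i, ": ", conditionMessage(e)))
    pred <- predict_groups(fit$model, te$volumes, config$batch_size)
    truth <- ifelse(te$labels[, 1] == 1, "A", "B")
    accs[i] <- accuracy(pred, truth)
    hists[[i]] <- fit$history
    fold_best_val <- max(fit$history$val_accuracy)
    if (keep_best_model && fold_best_val > best_val) {
      best_val <- fold_best_val
      best_model <- fit$model
    }
  }
  structure(list(fold_accuracies = accs, mean_accuracy = mean(accs),
                 sd_accuracy = sd(accs), model = best_model,
                 histories = hists),
            class = "cv_result")
}

# L2-regularized L1-loss linear SVM by dual coordinate descent
# (the liblinear algorithm). Xt: p x n matrix (columns = samples, already
# standardized, with an appended bias feature); y in {-1, +1}.
linear_svm_fit <- function(Xt, y, C = 1, max_iter = 60L, tol = 1e-4,
                           seed = 1L) {
  n <- ncol(Xt); p <- nrow(Xt)
  w <- numeric(p)
  alpha <- numeric(n)
  qii <- colSums(Xt^2)
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      viol <- 0
      for (i in sample(n)) {
        g <- y[i] * sum(w * Xt[, i]) - 1
        pg <- if (alpha[i] <= 0) min(g, 0) else if (alpha[i] >= C) max(g, 0) else g
        if (abs(pg) > 1e-12) {
          viol <- max(viol, abs(pg))
          anew <- min(max(alpha[i] - g / qii[i], 0), C)
          if (anew != alpha[i]) {
            w <- w + (anew - alpha[i]) * y[i] * Xt[, i]
            alpha[i] <- anew
          }
        }
      }
      if (viol < tol) break
    }
  })
  w
}

#' Flattened-voxel SVM baseline under the same fold plan
#'
#' Each volume is flattened to a voxel vector, standardized per voxel on the
#' fold's training portion (train + validation, which is what the SVM is fit
#' on), and classified with a linear support-vector machine (L2-regularized
#' L1-loss, C = 1, trained by dual coordinate descent). Folds and the
#' accuracy metric match [run_nested_cv()] for a head-to-head comparison.
#'
#' @inheritParams run_nested_cv
#' @param C Soft-margin constant.
#' @param seed Seed for the coordinate-descent sweep order.
#' @return List of class `cv_result` (without a model).
#' @export
svm_baseline <- function(data, plan, C = 1, seed = 1L) {
  if (is.character(data)) data <- load_prepared(data)
  stopifnot(inherits(plan, "fold_plan"))
  d <- dim(data$volumes)
  X <- matrix(data$volumes, prod(d[1:3]), d[4])  # p x n
  ygrp <- ifelse(data$labels[, 1] == 1, 1, -1)
  accs <- numeric(10)
  for (i in seq_len(10)) {
    f <- plan$folds[[i]]
    tr <- match(c(f$train_ids, f$val_ids), data$subject_ids)
    te <- match(f$test_ids, data$subject_ids)
    mu <- rowMeans(X[, tr, drop = FALSE])
    sg <- apply(X[, tr, drop = FALSE], 1, sd)
    sg[sg == 0] <- 1
    Xtr <- (X[, tr, drop = FALSE] - mu) / sg
    Xte <- (X[, te, drop = FALSE] - mu) / sg
    Xtr <- rbind(Xtr, 1)  # bias feature
    Xte <- rbind(Xte, 1)
    w <- linear_svm_fit(Xtr, ygrp[tr], C = C,
                        seed = derive_seed(seed, "svm", i))
    pred <- ifelse(crossprod(Xte, w) >= 0, 1, -1)
    accs[i] <- accuracy(as.vector(pred), ygrp[te])
  }
  structure(list(fold_accuracies = accs, mean_accuracy = mean(accs),
                 sd_accuracy = sd(accs), model = NULL, histories = NULL),
            class = "cv_result")
}
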