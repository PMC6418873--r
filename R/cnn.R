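# The 3D convolutional classifier: three hidden layers (3x3x3 SAME
# convolution -> batch normalization -> ReLU -> 2x2x2 ceil-mode max pool)
# with 32/64/128 feature maps, a single linear map to 2 logits, and a
# softmax output. Trained with Adam on the summed softmax cross-entropy.

BN_EPS <- 1e-5
PROB_FLOOR <- 1e-12
CHANNELS <- c(32L, 64L, 128L)

#' Training configuration
#'
#' Defaults follow the published setup: batch size 45, Adam with
#' `alpha = 0.001`, `beta1 = 0.9`, `beta2 = 0.999`, `epsilon = 1e-8`, and
#' truncated-normal weight initialization with SD 0.1.
#'
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param epsilon Adam stabilizer.
#' @param init_sd Weight init SD (truncated at +/- 2 SD).
#' @param epochs Training epochs.
#' @param seed Integer seed controlling init and shuffling.
#' @return Object of class `training_config`.
#' @export
training_config <- function(batch_size = 45L, learning_rate = 0.001,
                            beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                            init_sd = 0.1, epochs = 50L, seed = 1L) {
  stopifnot(batch_size >= 1, learning_rate > 0, beta1 > 0, beta2 > 0,
            epsilon > 0, init_sd > 0, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, init_sd = init_sd,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "training_config")
}

# Truncated normal: resample-beyond-2-SD via the inverse-CDF restriction.
rtruncnorm2 <- function(n, sd) {
  qnorm(runif(n, pnorm(-2), pnorm(2))) * sd
}

#' Build an untrained 3D CNN
#'
#' Weights are drawn from a truncated normal (SD `config$init_sd`, cut at
#' +/- 2 SD), biases start at 0, batch-norm scale/shift at 1/0 and running
#' moments at 0/1. SAME convolutions preserve spatial dimensions; each
#' pooled layer halves them (ceil mode). The linear layer maps the flattened
#' final feature maps to 2 logits.
#'
#' @param input_shape Spatial input shape `(d, w, h)` (a trailing channel of
#'   1 may be included); every dimension must be >= 8.
#' @param config A [training_config()]; supplies `init_sd` and `seed`.
#' @param pool Logical triple: whether each hidden layer pools (the per-ROI
#'   pipeline drops the third pool for small inputs).
#' @return Object of class `cnn3d_model`.
#' @export
build_cnn3d <- function(input_shape, config = training_config(),
                        pool = c(TRUE, TRUE, TRUE)) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) == 4) {
    if (input_shape[4] != 1) stop("only single-channel input is supported")
    input_shape <- input_shape[1:3]
  }
  if (length(input_shape) != 3) stop("input_shape must be (d, w, h)")
  if (any(input_shape < 8))
    stop("input spatial dimensions must all be >= 8, got ",
         paste(input_shape, collapse = "x"))
  cur <- input_shape
  spatial <- vector("list", 3)
  for (l in 1:3) {
    if (pool[l]) {
      if (any(cur < 2))
        stop(sprintf("input too small at hidden layer %d (spatial %s before pooling)",
                     l, paste(cur, collapse = "x")))
      cur <- as.integer(ceiling(cur / 2))
    }
    spatial[[l]] <- cur
  }
  flat <- prod(cur) * CHANNELS[3]
  cin <- c(1L, CHANNELS[1], CHANNELS[2])
  params <- with_seed(config$seed, {
    p <- list()
    for (l in 1:3) {
      p[[paste0("W", l)]] <- matrix(
        rtruncnorm2(27 * cin[l] * CHANNELS[l], config$init_sd),
        27 * cin[l], CHANNELS[l])
      p[[paste0("b", l)]] <- numeric(CHANNELS[l])
      p[[paste0("g", l)]] <- rep(1, CHANNELS[l])
      p[[paste0("be", l)]] <- numeric(CHANNELS[l])
    }
    p$Wl <- matrix(rtruncnorm2(flat * 2, config$init_sd), flat, 2)
    p$bl <- numeric(2)
    p
  })
  running <- list()
  for (l in 1:3) {
    running[[paste0("rm", l)]] <- numeric(CHANNELS[l])
    running[[paste0("rv", l)]] <- rep(1, CHANNELS[l])
  }
  structure(list(
    arch = list(input_shape = input_shape, channels = CHANNELS,
                pool = pool, spatial = spatial, flat_size = flat,
                n_classes = 2L),
    params = params, running = running), class = "cnn3d_model")
}

#' Parameter count of a model
#' @param model A `cnn3d_model`.
#' @return Named vector of per-tensor parameter counts.
#' @export
parameter_counts <- function(model) {
  vapply(model$params, length, 0L)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Softmax cross-entropy cost
#'
#' Sum over the batch of `-log` probability assigned to the true class,
#' with probabilities clipped to `[1e-12, 1]`. Zero exactly when every
#' prediction equals its one-hot label.
#'
#' @param predictions `N x 2` matrix of class probabilities (or a length-2
#'   vector for a single sample).
#' @param labels Matching `N x 2` one-hot matrix (or length-2 vector).
#' @return Nonnegative scalar.
#' @export
cross_entropy_cost <- function(predictions, labels) {
  if (is.null(dim(predictions))) predictions <- matrix(predictions, 1)
  if (is.null(dim(labels))) labels <- matrix(labels, 1)
  if (!all(dim(predictions) == dim(labels)))
    stop("predictions and labels must have matching dimensions")
  p <- pmin(pmax(predictions, PROB_FLOOR), 1)
  -sum(labels * log(p))
}

# One training-mode forward pass; returns probabilities, cost and the cache
# needed by .backward. x: (D,W,H,1,nb); y: nb x 2.
.forward_train <- function(model, x, y) {
  p <- model$params
  cache <- list()
  a <- x
  for (l in 1:3) {
    cache[[paste0("convin", l)]] <- a
    cv <- .conv3d_forward(a, p[[paste0("W", l)]], p[[paste0("b", l)]])
    bn <- .bn_forward_train(cv, p[[paste0("g", l)]], p[[paste0("be", l)]], BN_EPS)
    rm(cv)
    r <- .relu_forward(bn$y)
    cache[[paste0("xhat", l)]] <- bn$xhat
    cache[[paste0("var", l)]] <- bn$var
    cache[[paste0("mean", l)]] <- bn$mean
    cache[[paste0("relu", l)]] <- r
    if (model$arch$pool[l]) {
      pl <- .maxpool3d_forward(r)
      cache[[paste0("idx", l)]] <- pl$idx
      cache[[paste0("indim", l)]] <- dim(r)
      a <- pl$y
    } else a <- r
  }
  cache$out3 <- dim(a)
  nb <- dim(x)[5]
  flat <- matrix(a, model$arch$flat_size, nb)
  cache$flat <- flat
  logits <- crossprod(p$Wl, flat) + p$bl   # 2 x nb
  probs <- softmax_cols(logits)
  cache$probs <- probs
  cost <- cross_entropy_cost(t(probs), y)
  list(probs = t(probs), cost = cost, cache = cache)
}

# Gradients for all parameters given a forward cache. y: nb x 2.
.backward <- function(model, cache, y) {
  p <- model$params
  g <- list()
  dlog <- cache$probs - t(y)                     # 2 x nb
  g$Wl <- cache$flat %*% t(dlog)
  g$bl <- rowSums(dlog)
  da <- p$Wl %*% dlog                            # flat x nb
  dim(da) <- cache$out3
  for (l in 3:1) {
    if (model$arch$pool[l])
      da <- .maxpool3d_backward(cache[[paste0("idx", l)]], da,
                                cache[[paste0("indim", l)]])
    da <- .relu_backward(cache[[paste0("relu", l)]], da)
    bn <- .bn_backward(cache[[paste0("xhat", l)]], da, p[[paste0("g", l)]],
                       cache[[paste0("var", l)]], BN_EPS)
    g[[paste0("g", l)]] <- bn$dgamma
    g[[paste0("be", l)]] <- bn$dbeta
    xin <- cache[[paste0("convin", l)]]
    cb <- .conv3d_backward(xin, p[[paste0("W", l)]], bn$dx, l > 1)
    g[[paste0("W", l)]] <- cb$dw
    g[[paste0("b", l)]] <- cb$db
    da <- cb$dx
  }
  g
}

# Inference-mode forward through the conv stack; returns the flattened
# features (flat x n) or, if `upto` is given, the activations after that
# hidden layer.
.forward_infer_stack <- function(model, x, upto = 3L) {
  p <- model$params; r <- model$running
  a <- x
  for (l in seq_len(upto)) {
    a <- .conv3d_forward(a, p[[paste0("W", l)]], p[[paste0("b", l)]])
    a <- .bn_forward_infer(a, p[[paste0("g", l)]], p[[paste0("be", l)]],
                           r[[paste0("rm", l)]], r[[paste0("rv", l)]], BN_EPS)
    a <- .relu_forward(a)
    if (model$arch$pool[l]) a <- .maxpool3d_forward(a)$y
  }
  a
}

#' Forward pass: class probabilities
#'
#' Inference mode: batch normalization uses the stored running moments, so
#' the prediction for a volume does not depend on what else is in the batch.
#'
#' @param model A `cnn3d_model`.
#' @param batch Volumes as a `(d, w, h, n)` or `(d, w, h, 1, n)` array (a
#'   single 3D volume is also accepted).
#' @param batch_size Internal chunk size.
#' @return `n x 2` matrix of class probabilities (rows sum to 1).
#' @export
forward <- function(model, batch, batch_size = 45L) {
  d <- model$arch$input_shape
  b <- batch
  if (length(dim(b)) == 3) dim(b) <- c(dim(b), 1L)
  if (length(dim(b)) == 4) {
    n <- dim(b)[4]
    dim(b) <- c(dim(b)[1:3], 1L, n)
  } else n <- dim(b)[5]
  if (!identical(as.integer(dim(b)[1:3]), d) || dim(b)[4] != 1L)
    stop("batch shape ", paste(dim(b), collapse = "x"),
         " does not match model input ", paste(d, collapse = "x"))
  out <- matrix(0, n, 2)
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1, n)
    xb <- b[, , , , s:e, drop = FALSE]
    out[s:e, ] <- .cnn_infer(xb, model$params, model$running,
                             model$arch$pool, BN_EPS, 3L, TRUE)
  }
  out
}

#' Predicted group labels
#'
#' @inheritParams forward
#' @return Character vector of `"A"` / `"B"` (ties go to `"A"`, the first
#'   one-hot class).
#' @export
predict_groups <- function(model, batch, batch_size = 45L) {
  pr <- forward(model, batch, batch_size)
  ifelse(pr[, 1] >= pr[, 2], "A", "B")
}

#' Train the 3D CNN
#'
#' Adam on the summed softmax cross-entropy, mini-batches of
#' `config$batch_size` (last partial batch kept), per-epoch seeded
#' shuffling. Batch-norm running moments are updated with an EMA (momentum
#' 0.9). After each epoch the model is scored on the validation set; the
#' returned model is the parameter snapshot with the highest validation
#' accuracy (earliest epoch on ties).
#'
#' @param model An untrained (or warm) `cnn3d_model`.
#' @param train_set,val_set [prepared_dataset()]s (or lists with `volumes`
#'   `(d,w,h,n)` and one-hot `labels`).
#' @param config A [training_config()].
#' @return List of class `cnn3d_fit`: `model` (best snapshot), `history`
#'   (data frame: epoch, train_cost, val_accuracy), `best_epoch`.
#' @export
train_cnn3d <- function(model, train_set, val_set, config) {
  xs <- train_set$volumes; ys <- train_set$labels
  n <- dim(xs)[4]
  if (n < 1 || is.null(val_set$volumes) || dim(val_set$volumes)[4] < 1)
    stop("train and validation sets must be nonempty")
  d <- model$arch$input_shape
  if (!identical(as.integer(dim(xs)[1:3]), d))
    stop("training volumes do not match model input shape")
  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$bn_batches <- 0
  # private copies: the fused Adam step updates these in place
  st$params <- lapply(model$params, function(p) p + 0)
  st$m <- lapply(model$params, function(p) p * 0)
  st$v <- lapply(model$params, function(p) p * 0)
  # the cumulative batch-moment mean starts from the first batch, not from
  # the (0, 1) initialization
  for (l in 1:3) {
    model$running[[paste0("rm", l)]] <- model$running[[paste0("rm", l)]] * 0
    model$running[[paste0("rv", l)]] <- model$running[[paste0("rv", l)]] * 0
  }
  truth_val <- ifelse(val_set$labels[, 1] == 1, "A", "B")
  hist_cost <- hist_acc <- numeric(config$epochs)
  best_acc <- -Inf; best <- model; best_epoch <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, "epoch", ep), sample(n))
    total_cost <- 0
    for (s in seq(1, n, by = config$batch_size)) {
      ids <- ord[s:min(s + config$batch_size - 1, n)]
      xb <- xs[, , , ids, drop = FALSE]
      dim(xb) <- c(d, 1L, length(ids))
      yb <- ys[ids, , drop = FALSE]
      stp <- .cnn_step(xb, yb, st$params, model$arch$pool, BN_EPS)
      if (!is.finite(stp$cost))
        stop(sprintf("training diverged (non-finite cost) at epoch %d, batch %d",
                     ep, (s - 1) %/% config$batch_size + 1))
      total_cost <- total_cost + stp$cost
      st$t <- st$t + 1
      .adam_step_inplace(st$params, stp$grads, st$m, st$v, st$t,
                         config$learning_rate, config$beta1, config$beta2,
                         config$epsilon)
      # inference moments: cumulative mean of the batch statistics over all
      # training batches (the batch-norm inference estimate; robust for the
      # short schedules used at desk scale, where an EMA would still be
      # dominated by its initialization)
      nbn <- st$bn_batches + 1
      for (l in 1:3) {
        model$running[[paste0("rm", l)]] <-
          model$running[[paste0("rm", l)]] * ((nbn - 1) / nbn) +
          stp$means[[l]] / nbn
        model$running[[paste0("rv", l)]] <-
          model$running[[paste0("rv", l)]] * ((nbn - 1) / nbn) +
          stp$vars[[l]] / nbn
      }
      st$bn_batches <- nbn
    }
    hist_cost[ep] <- total_cost / n
    model$params <- st$params
    pred <- predict_groups(model, val_set$volumes, config$batch_size)
    hist_acc[ep] <- accuracy(pred, truth_val)
    if (hist_acc[ep] > best_acc) {
      best_acc <- hist_acc[ep]
      best_epoch <- ep
      best <- model
      best$params <- lapply(st$params, function(p) p + 0)  # deep snapshot
    }
  }
  structure(list(model = best,
                 history = data.frame(epoch = seq_len(config$epochs),
                                      train_cost = hist_cost,
                                      val_accuracy = hist_acc),
                 best_epoch = best_epoch),
            class = "cnn3d_fit")
}

#' Extract hidden-layer feature maps for one volume
#'
#' Runs the inference-mode stack up to `layer_index` and returns that
#' layer's post-activation, post-pooling feature maps.
#'
#' @param model A trained `cnn3d_model`.
#' @param volume 3D array matching the model input shape.
#' @param layer_index Hidden layer, 1..3 (layer 1 yields 32 maps, layer 2
#'   yields 64, layer 3 yields 128).
#' @return List of 3D arrays, one per feature map.
#' @export
extract_feature_maps <- function(model, volume, layer_index) {
  if (!layer_index %in% 1:3) stop("layer_index must be 1, 2 or 3")
  x <- volume
  dim(x) <- c(model$arch$input_shape, 1L, 1L)
  a <- .cnn_infer(x, model$params, model$running, model$arch$pool, BN_EPS,
                  as.integer(layer_index), FALSE)
  d <- dim(a)
  lapply(seq_len(d[4]), function(c) array(a[, , , c, 1], dim = d[1:3]))
}

# Batched layer-1 maps for a whole dataset: (Do,Wo,Ho,32,N).
.layer1_maps <- function(model, volumes, batch_size = 45L) {
  n <- dim(volumes)[4]
  out <- NULL
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1, n)
    xb <- volumes[, , , s:e, drop = FALSE]
    dim(xb) <- c(dim(xb)[1:3], 1L, e - s + 1)
    a <- .cnn_infer(xb, model$params, model$running, model$arch$pool, BN_EPS,
                    1L, FALSE)
    if (is.null(out)) out <- array(0, dim = c(dim(a)[1:4], n))
    out[, , , , s:e] <- a
  }
  out
}

#' Save / load a model checkpoint
#'
#' Parameters and running moments go into an HDF5 file; the architecture
#' descriptor is stored as a JSON attribute-style dataset.
#'
#' @param model A `cnn3d_model`.
#' @param path Output `.h5` path.
#' @return `path` invisibly; `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "params")
  rhdf5::h5createGroup(path, "running")
  for (k in names(model$params))
    rhdf5::h5write(model$params[[k]], path, paste0("params/", k))
  for (k in names(model$running))
    rhdf5::h5write(model$running[[k]], path, paste0("running/", k))
  rhdf5::h5write(as.character(jsonlite::toJSON(model$arch, auto_unbox = TRUE)),
                 path, "arch_json")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  arch <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, "arch_json")))
  arch$input_shape <- as.integer(arch$input_shape)
  arch$channels <- as.integer(arch$channels)
  arch$spatial <- lapply(seq_len(nrow(arch$spatial)),
                         function(i) as.integer(arch$spatial[i, ]))
  params <- rhdf5::h5read(path, "params")
  running <- rhdf5::h5read(path, "running")
  rhdf5::h5closeAll()
  params <- lapply(params, function(p) if (is.array(p) && length(dim(p)) == 2)
    p else as.numeric(p))
  running <- lapply(running, as.numeric)
  structure(list(arch = arch, params = params, running = running),
            class = "cnn3d_model")
}
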