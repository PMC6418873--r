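# Shared fixtures, all generated in code.

# Two constant-intensity classes with mild noise: linearly separable.
make_separable_dataset <- function(n = 20, shape = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  vols <- array(0, c(shape, n))
  labs <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    a <- i %% 2 == 1
    vols[, , , i] <- array(rnorm(prod(shape), mean = ifelse(a, 0.3, 0.7),
                                 sd = 0.05), shape)
    labs[i, ] <- if (a) c(1, 0) else c(0, 1)
  }
  prepared_dataset(vols, labs, sprintf("sub%03d", seq_len(n)))
}

# Pure noise with labels independent of content.
make_noise_dataset <- function(n = 40, shape = c(10, 10, 10), seed = 1) {
  set.seed(seed)
  vols <- array(rnorm(prod(shape) * n), c(shape, n))
  labs <- matrix(0, n, 2)
  labs[cbind(seq_len(n), rep(c(1, 2), length.out = n))] <- 1
  prepared_dataset(vols, labs, sprintf("sub%03d", seq_len(n)))
}

# Random symmetric positive-definite 3x3 via a random rotation of a
# positive diagonal.
random_spd <- function(lambda = sort(runif(3, 0.1, 3), decreasing = TRUE)) {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  q %*% diag(lambda) %*% t(q)
}

# A tiny label volume: one cubic ROI inside a larger grid.
cube_label_volume <- function(grid = c(12, 12, 12), lo = 2, hi = 11) {
  labels <- array(0L, grid)
  labels[lo:hi, lo:hi, lo:hi] <- 1L
  structure(list(labels = labels,
                 roi_table = data.frame(roi_id = 1L, name = "cube",
                                        tissue = "gray",
                                        stringsAsFactors = FALSE)),
            class = "label_volume")
}
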