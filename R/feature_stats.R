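# First-hidden-layer feature statistics: per-subject mean voxel values and
# Shannon entropy of 256-level quantized maps, compared between groups with
# Welch two-sample t-tests under Bonferroni correction (alpha / 32).

#' Quantize a map to the 0..255 alphabet
#'
#' Per-map min-max scaling to [0, 255] followed by rounding to the nearest
#' integer; constant maps quantize to all zeros.
#'
#' @param map Numeric array with finite values.
#' @return Integer array of the same shape, values in 0..255.
#' @export
quantize_map <- function(map) {
  if (any(!is.finite(map))) stop("map contains non-finite values")
  lo <- min(map); hi <- max(map)
  q <- if (hi > lo) as.integer(round((map - lo) / (hi - lo) * 255)) else
    rep(0L, length(map))
  array(q, dim = dim(map) %||% length(map))
}

#' Shannon entropy of a quantized map
#'
#' `H = -sum(p_i log p_i)` over the empirical frequencies of the 256 symbol
#' values (natural log; empty bins contribute 0), so `0 <= H <= log(256)`.
#'
#' @param qmap Integer array with values in 0..255 (see [quantize_map()]).
#' @return Nonnegative scalar.
#' @export
map_entropy <- function(qmap) {
  if (length(qmap) == 0) stop("empty map")
  if (any(qmap < 0 | qmap > 255)) stop("values outside 0..255")
  p <- tabulate(as.integer(qmap) + 1L, nbins = 256L) / length(qmap)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Welch two-sample t-test
#'
#' Two-sided Welch test (unequal variances); antisymmetric under a group
#' swap. Degenerate input (all values identical across both groups) is an
#' error.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return Named vector `c(t =, p =)`.
#' @export
two_sample_ttest <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  if (var(values_a) + var(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      stop("degenerate input: zero variance in both groups")
    stop("degenerate input: zero combined variance with distinct means")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
  c(t = unname(ht$statistic), p = ht$p.value)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Group analysis of the 32 first-hidden-layer features
#'
#' For every feature map of the first hidden layer (post-activation,
#' post-pooling) and every subject, computes (a) the mean voxel value and
#' (b) the Shannon entropy of the quantized map; then compares groups with
#' Welch t-tests, flagging significance at `alpha / 32`. Features whose
#' statistic is constant across all subjects (e.g. a dead ReLU feature) get
#' `t = 0`, `p = 1`.
#'
#' @param model A trained `cnn3d_model`.
#' @param data A [prepared_dataset()] containing both groups.
#' @param alpha Family-wise level before Bonferroni correction.
#' @return Data frame of class `feature_stats_table` with 32 rows and
#'   columns feature, mean_A, mean_B, t_mean, p_mean, sig_mean, H_A, H_B,
#'   t_H, p_H, sig_H; the threshold and log base are attached as attributes.
#' @export
feature_group_analysis <- function(model, data, alpha = 0.05) {
  grp <- ifelse(data$labels[, 1] == 1, "A", "B")
  if (length(unique(grp)) < 2) stop("both groups must be present")
  maps <- .layer1_maps(model, data$volumes)
  nfeat <- dim(maps)[4]
  n <- dim(maps)[5]
  mv <- matrix(0, n, nfeat)
  hv <- matrix(0, n, nfeat)
  for (i in seq_len(n)) {
    for (f in seq_len(nfeat)) {
      m <- maps[, , , f, i]
      mv[i, f] <- mean(m)
      hv[i, f] <- map_entropy(quantize_map(m))
    }
  }
  thr <- bonferroni_threshold(alpha, nfeat)
  test_or_null <- function(a, b) {
    if (var(a) + var(b) == 0) c(t = 0, p = 1) else two_sample_ttest(a, b)
  }
  rows <- lapply(seq_len(nfeat), function(f) {
    tm <- test_or_null(mv[grp == "A", f], mv[grp == "B", f])
    th <- test_or_null(hv[grp == "A", f], hv[grp == "B", f])
    data.frame(feature = f,
               mean_A = mean(mv[grp == "A", f]),
               mean_B = mean(mv[grp == "B", f]),
               t_mean = tm["t"], p_mean = tm["p"],
               sig_mean = tm["p"] < thr,
               H_A = mean(hv[grp == "A", f]),
               H_B = mean(hv[grp == "B", f]),
               t_H = th["t"], p_H = th["p"],
               sig_H = th["p"] < thr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "log_base") <- "natural"
  attr(out, "maps") <- "layer1 post-activation post-pooling"
  class(out) <- c("feature_stats_table", class(out))
  out
}
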