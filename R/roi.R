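# Per-region discriminability: repeat the classification on each atlas ROI
# and recolor the parcellation by its mean test accuracy.

#' Extract an ROI subvolume
#'
#' Tight bounding box of the ROI mask with voxels outside the mask zeroed,
#' then symmetric zero-padding of every dimension up to at least 8 (the
#' model's minimum input size).
#'
#' @param volume 3D array on the atlas grid.
#' @param labels A `label_volume`.
#' @param roi_id ROI id present in the atlas.
#' @param min_dim Padding floor per dimension.
#' @return 3D array of shape `pmax(bounding box, min_dim)`.
#' @export
extract_roi_volume <- function(volume, labels, roi_id, min_dim = 8L) {
  if (!roi_id %in% labels$roi_table$roi_id)
    stop("unknown roi_id: ", roi_id)
  mask <- labels$labels == roi_id
  if (!any(mask)) stop("ROI ", roi_id, " has no voxels")
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  sub <- volume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msk <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub[!msk] <- 0
  d <- dim(sub)
  outd <- pmax(d, as.integer(min_dim))
  if (all(outd == d)) return(sub)
  out <- array(0, dim = outd)
  off <- (outd - d) %/% 2
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <- sub
  out
}

#' Per-ROI classification accuracy
#'
#' Crops every subject's volume to the ROI, builds a CNN for the padded crop
#' shape (dropping the third pooling stage when any dimension is below 16),
#' and runs the same nested cross-validation as the whole-brain analysis
#' with the *same* fold plan, so per-ROI accuracies are directly comparable.
#'
#' @param data A [prepared_dataset()] of volumes on the atlas grid.
#' @param labels A `label_volume`.
#' @param roi_id ROI id.
#' @param config A [training_config()].
#' @param plan A [make_fold_plan()] shared across ROIs.
#' @return Object of class `roi_result`: roi_id, roi_name, tissue,
#'   mean_accuracy, fold_accuracies.
#' @export
per_roi_accuracy <- function(data, labels, roi_id, config, plan) {
  row <- labels$roi_table[labels$roi_table$roi_id == roi_id, ]
  if (nrow(row) != 1) stop("unknown roi_id: ", roi_id)
  n <- dim(data$volumes)[4]
  first <- extract_roi_volume(data$volumes[, , , 1], labels, roi_id)
  crop_dim <- dim(first)
  vols <- array(0, dim = c(crop_dim, n))
  vols[, , , 1] <- first
  for (i in seq(2, length.out = n - 1))
    vols[, , , i] <- extract_roi_volume(data$volumes[, , , i], labels, roi_id)
  crop_data <- prepared_dataset(vols, data$labels, data$subject_ids)
  pool <- if (any(crop_dim < 16)) c(TRUE, TRUE, FALSE) else c(TRUE, TRUE, TRUE)
  cv <- tryCatch(
    run_nested_cv(crop_data, config, plan, pool = pool, keep_best_model = FALSE),
    error = function(e) stop("ROI ", roi_id, ": ", conditionMessage(e)))
  structure(list(roi_id = as.integer(roi_id), roi_name = row$name,
                 tissue = row$tissue, mean_accuracy = cv$mean_accuracy,
                 fold_accuracies = cv$fold_accuracies),
            class = "roi_result")
}

#' Recolor the atlas by per-ROI accuracy
#'
#' @param labels A `label_volume`.
#' @param results List of `roi_result`, one per atlas ROI.
#' @return 3D array: each foreground voxel carries its ROI's mean accuracy,
#'   background is 0.
#' @export
build_accuracy_map <- function(labels, results) {
  ids <- vapply(results, function(r) r$roi_id, 0L)
  missing <- setdiff(labels$roi_table$roi_id, ids)
  if (length(missing) > 0)
    stop("missing ROI result(s): ", paste(missing, collapse = ", "))
  acc <- vapply(results, function(r) r$mean_accuracy, 0)
  lut <- numeric(max(labels$roi_table$roi_id) + 1)
  lut[ids + 1] <- acc
  array(lut[labels$labels + 1L], dim = dim(labels$labels))
}

#' Rank ROIs by mean accuracy
#'
#' Descending by mean accuracy, ties broken by ascending roi_id; ranked
#' separately per tissue class and clamped to the available ROI count.
#'
#' @param results List of `roi_result`.
#' @param k Top-k cutoff (>= 1).
#' @return Data frame: tissue, rank, roi_id, name, mean_accuracy.
#' @export
rank_rois <- function(results, k) {
  if (length(results) == 0) stop("no results")
  if (k < 1) stop("k must be >= 1")
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(roi_id = r$roi_id, name = r$roi_name, tissue = r$tissue,
               mean_accuracy = r$mean_accuracy, stringsAsFactors = FALSE)))
  out <- do.call(rbind, lapply(split(df, df$tissue), function(part) {
    part <- part[order(-part$mean_accuracy, part$roi_id), ]
    part <- head(part, k)
    part$rank <- seq_len(nrow(part))
    part
  }))
  rownames(out) <- NULL
  out[, c("tissue", "rank", "roi_id", "name", "mean_accuracy")]
}
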