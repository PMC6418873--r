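test_that("ROI extraction: bounding box, padding floor, sum conservation", {
  lv <- cube_label_volume(c(12, 12, 12), 2, 11)       # 10^3 cube ROI
  set.seed(41)
  v <- array(rnorm(12 * 12 * 12), c(12, 12, 12))
  sub <- extract_roi_volume(v, lv, 1)
  expect_equal(dim(sub), c(10L, 10L, 10L))
  expect_equal(sub, v[2:11, 2:11, 2:11], ignore_attr = TRUE)
  # single-voxel ROI pads to the 8^3 floor with one nonzero voxel
  lv1 <- cube_label_volume(c(12, 12, 12), 5, 5)
  sub1 <- extract_roi_volume(v, lv1, 1)
  expect_equal(dim(sub1), c(8L, 8L, 8L))
  expect_equal(sum(sub1 != 0), 1)
  expect_equal(sum(sub1), v[5, 5, 5])
  # masked-sum conservation for irregular ROIs
  at <- generate_atlas(c(16, 16, 16), 3, 2, seed = 6)
  for (r in 1:5) {
    vv <- array(rnorm(16^3), c(16, 16, 16))
    for (id in 1:5)
      expect_equal(sum(extract_roi_volume(vv, at, id)),
                   sum(vv[at$labels == id]), tolerance = 1e-10)
  }
  expect_error(extract_roi_volume(v, lv, 3), "unknown roi_id")
})

test_that("accuracy map recolors the atlas exactly", {
  at <- generate_atlas(c(16, 16, 16), 3, 2, seed = 8)
  results <- lapply(1:5, function(id)
    structure(list(roi_id = id, roi_name = at$roi_table$name[id],
                   tissue = at$roi_table$tissue[id],
                   mean_accuracy = 0.5, fold_accuracies = rep(0.5, 10)),
              class = "roi_result"))
  amap <- build_accuracy_map(at, results)
  expect_true(all(amap[at$labels > 0] == 0.5))
  expect_true(all(amap[at$labels == 0] == 0))
  # voxel census: count at each accuracy value equals the ROI sizes
  for (i in 1:5) results[[i]]$mean_accuracy <- 0.1 * i
  amap2 <- build_accuracy_map(at, results)
  for (i in 1:5)
    expect_equal(sum(amap2 == 0.1 * i), sum(at$labels == i))
  # NIfTI round trip is bitwise
  p <- tempfile(fileext = ".nii.gz")
  write_nifti(amap2, p)
  expect_identical(as.vector(read_nifti(p)), as.vector(amap2))
  expect_error(build_accuracy_map(at, results[1:4]), "missing ROI")
})

test_that("ROI ranking: order, ties, clamping, permutation invariance", {
  mk <- function(id, tissue, acc)
    structure(list(roi_id = id, roi_name = paste0("r", id), tissue = tissue,
                   mean_accuracy = acc, fold_accuracies = rep(acc, 10)),
              class = "roi_result")
  res <- list(mk(1, "gray", 0.7), mk(2, "gray", 0.9), mk(3, "gray", 0.9),
              mk(4, "white", 0.6), mk(5, "white", 0.8))
  rk <- rank_rois(res, 2)
  gray <- rk[rk$tissue == "gray", ]
  expect_equal(gray$roi_id, c(2, 3))      # tie broken by ascending roi_id
  expect_equal(gray$rank, c(1, 2))
  white <- rk[rk$tissue == "white", ]
  expect_equal(white$roi_id[1], 5)
  # k beyond the count clamps to the full sorted list
  expect_equal(nrow(rank_rois(res, 50)), 5)
  # input order is irrelevant
  expect_equal(rank_rois(rev(res), 2), rk)
  expect_error(rank_rois(res, 0), "k")
  expect_error(rank_rois(list(), 1), "no results")
})

test_that("per-ROI pipeline bookkeeping on a tiny cohort", {
  sp <- cohort_spec(20, 0.5, c(16, 16, 16), seed = 14, n_gray = 2, n_white = 1)
  co <- simulate_cohort(sp)
  ds <- dticnn:::prepare_cohort(co)
  plan <- make_fold_plan(ds$subject_ids, seed = 15)
  cfg <- training_config(batch_size = 16, epochs = 1, seed = 16)
  rr <- per_roi_accuracy(ds, co$atlas, 2, cfg, plan)
  expect_s3_class(rr, "roi_result")
  expect_length(rr$fold_accuracies, 10)
  expect_equal(rr$mean_accuracy, mean(rr$fold_accuracies))
  expect_equal(rr$tissue, "gray")
  expect_error(per_roi_accuracy(ds, co$atlas, 9, cfg, plan), "unknown roi_id")
})
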