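test_that("atlas generation: label census, determinism, connectivity", {
  at <- generate_atlas(c(24, 28, 24), 6, 4, seed = 7)
  expect_setequal(sort(unique(as.vector(at$labels))), 0:10)
  # every ROI nonempty, by exhaustive voxel census
  counts <- tabulate(at$labels[at$labels > 0], nbins = 10)
  expect_true(all(counts >= 1))
  # deterministic
  at2 <- generate_atlas(c(24, 28, 24), 6, 4, seed = 7)
  expect_identical(at$labels, at2$labels)
  # each ROI is 6-connected: flood fill from one voxel must reach all of it
  flood_size <- function(labels, id) {
    mask <- labels == id
    seed <- which(mask)[1]
    seen <- array(FALSE, dim(labels))
    seen[seed] <- TRUE
    frontier <- matrix(arrayInd(seed, dim(labels)), ncol = 3)
    offs <- rbind(c(-1,0,0), c(1,0,0), c(0,-1,0), c(0,1,0), c(0,0,-1), c(0,0,1))
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (o in 1:6) {
        nc <- sweep(frontier, 2, offs[o, ], `+`)
        ok <- nc[,1] >= 1 & nc[,1] <= dim(labels)[1] &
              nc[,2] >= 1 & nc[,2] <= dim(labels)[2] &
              nc[,3] >= 1 & nc[,3] <= dim(labels)[3]
        nc <- nc[ok, , drop = FALSE]
        if (nrow(nc) == 0) next
        keep <- mask[nc] & !seen[nc]
        nc <- nc[keep, , drop = FALSE]
        if (nrow(nc) == 0) next
        seen[nc] <- TRUE
        nxt <- rbind(nxt, nc)
      }
      frontier <- if (is.null(nxt)) matrix(0, 0, 3) else unique(nxt)
    }
    sum(seen)
  }
  at3 <- generate_atlas(c(16, 16, 16), 3, 2, seed = 5)
  for (id in 1:5)
    expect_equal(flood_size(at3$labels, id), sum(at3$labels == id))
  expect_error(generate_atlas(c(8, 8, 8), 500, 500, 1), "too small")
})

test_that("tensor fields hit FA targets exactly and stay PSD", {
  at <- generate_atlas(c(12, 12, 12), 2, 1, seed = 3)
  tf <- generate_tensor_field(c(12, 12, 12), at, c(gray = 0.2, white = 0.55),
                              noise_sd = 0, seed = 11)
  sm <- scalar_maps_from_field(tf)
  gm <- at$labels %in% 1:2
  wm <- at$labels == 3
  expect_lt(max(abs(sm$FA[gm] - 0.2)), 1e-10)
  expect_lt(max(abs(sm$FA[wm] - 0.55)), 1e-10)
  # with noise: symmetric PSD everywhere, checked voxel by voxel
  tfn <- generate_tensor_field(c(12, 12, 12), at, c(gray = 0.2, white = 0.55),
                               noise_sd = 0.2, seed = 11)
  for (v in which(at$labels > 0)[seq(1, sum(at$labels > 0), by = 17)]) {
    idx <- arrayInd(v, c(12, 12, 12))
    comp <- tfn[idx[1], idx[2], idx[3], ]
    t3 <- matrix(c(comp[1], comp[2], comp[3],
                   comp[2], comp[4], comp[5],
                   comp[3], comp[5], comp[6]), 3)
    ev <- eigendecompose_voxel(t3)
    expect_gte(min(ev), -1e-12)
  }
  # determinism is bitwise
  tfn2 <- generate_tensor_field(c(12, 12, 12), at, c(gray = 0.2, white = 0.55),
                                noise_sd = 0.2, seed = 11)
  expect_identical(tfn, tfn2)
  expect_error(generate_tensor_field(c(12, 12, 12), at, c(gray = 0.2, white = 0.55),
                                     noise_sd = -1, seed = 1), "nonnegative")
})

test_that("mean-shift injection realizes the requested Cohen's d", {
  sp <- cohort_spec(200, 0.5, c(16, 16, 16),
                    effects = list(group_effect("mean_shift", 1, 1.0, 1)),
                    noise_sd = 0.1, seed = 5, n_gray = 3, n_white = 2)
  co <- simulate_cohort(sp)
  region <- co$atlas$labels == 1
  rm_ <- vapply(co$volumes, function(v) mean(v[region]), 0)
  g <- co$subjects$group
  pooled <- sqrt((var(rm_[g == "A"]) * 99 + var(rm_[g == "B"]) * 99) / 198)
  d_hat <- (mean(rm_[g == "A"]) - mean(rm_[g == "B"])) / pooled
  expect_gte(d_hat, 0.8)
  expect_lte(d_hat, 1.2)
})

test_that("zero-magnitude effects leave the cohort untouched", {
  base <- cohort_spec(12, 0.5, c(12, 12, 12), seed = 9, n_gray = 2, n_white = 1)
  sp0 <- cohort_spec(12, 0.5, c(12, 12, 12),
                     effects = list(group_effect("mean_shift", 1, 0, 1)),
                     seed = 9, n_gray = 2, n_white = 1)
  expect_identical(simulate_cohort(base)$volumes, simulate_cohort(sp0)$volumes)
})

test_that("texture effect lowers the smoothed group's entropy", {
  sp <- cohort_spec(60, 0.5, c(16, 16, 16),
                    effects = list(group_effect("texture_complexity",
                                                magnitude = 1.5, direction = 1)),
                    noise_sd = 0.1, seed = 6, n_gray = 3, n_white = 2)
  co <- simulate_cohort(sp)
  H <- vapply(co$volumes, function(v) map_entropy(quantize_map(v)), 0)
  g <- co$subjects$group
  expect_gt(mean(H[g == "A"]), mean(H[g == "B"]))  # direction +1: A larger
  tt <- two_sample_ttest(H[g == "A"], H[g == "B"])
  expect_lt(tt["p"], 0.01)
})

test_that("effect validation errors", {
  expect_error(group_effect("mean_shift", integer(), 1, 1), "nonempty")
  expect_error(group_effect("implode", 1, 1, 1))
  expect_error(group_effect("mean_shift", 1, -2, 1), ">= 0")
  co <- simulate_cohort(cohort_spec(4, 0.5, c(12, 12, 12), seed = 1,
                                    n_gray = 2, n_white = 1))
  expect_error(inject_group_effect(co, group_effect("mean_shift", 99, 1, 1)),
               "absent from atlas")
})

test_that("generate_cohort writes a consistent, reproducible bundle", {
  dir1 <- file.path(tempdir(), "coh1"); dir2 <- file.path(tempdir(), "coh2")
  sp <- cohort_spec(20, 0.5, c(12, 12, 12), seed = 4, n_gray = 2, n_white = 1)
  co <- generate_cohort(sp, dir1)
  man <- read.delim(co$manifest_path)
  expect_equal(nrow(man), 20)
  expect_equal(sum(man$group == "A"), 10)
  expect_true(all(file.exists(man$path)))
  # 21 subjects: A gets the floor
  sp21 <- cohort_spec(21, 0.5, c(12, 12, 12), seed = 4, n_gray = 2, n_white = 1)
  co21 <- simulate_cohort(sp21)
  expect_equal(sum(co21$subjects$group == "A"), 10)
  expect_equal(sum(co21$subjects$group == "B"), 11)
  # bytewise reproducibility of everything written (the manifest differs
  # only in its absolute paths, so compare its content columns instead)
  co2 <- generate_cohort(sp, dir2)
  man2 <- read.delim(co2$manifest_path)
  expect_identical(man[, c("subject_id", "group")],
                   man2[, c("subject_id", "group")])
  f1 <- sort(list.files(dir1)); f2 <- sort(list.files(dir2))
  expect_identical(f1, f2)
  for (f in setdiff(f1, "manifest.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = paste("md5 of", f))
  }
  # the atlas round-trips through NIfTI
  at <- read_nifti(co$atlas_path)
  expect_identical(as.integer(at), as.integer(co$atlas$labels))
})
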