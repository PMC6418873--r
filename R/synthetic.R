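# Synthetic diffusion-tensor cohorts with controlled group differences.
#
# The generator builds a stylized "brain": a central ellipsoid mask filled
# with axially symmetric diffusion tensors whose fractional anisotropy hits a
# per-tissue target exactly in the noiseless limit, partitioned into
# connected gray- and white-matter ROIs by seeded region growth. Group
# effects are injected on the rendered FA maps: a calibrated mean shift
# inside target ROIs (Cohen's d) and/or a texture-complexity difference
# (one group smoothed, lowering its quantized-map entropy).

#' Cohort specification
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param group_fraction Fraction of subjects in group A; group A size is
#'   `floor(n_subjects * group_fraction)`.
#' @param volume_shape Integer triple (depth, width, height), each >= 8.
#' @param effects List of [group_effect()] objects.
#' @param noise_sd Eigenvalue perturbation scale (nonnegative; tensors have
#'   mean diffusivity 1 in arbitrary units).
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @param n_gray,n_white Number of gray-/white-matter ROIs in the atlas.
#' @param base_fa Named vector of noiseless FA targets per tissue class.
#' @param subject_sd Between-subject SD of a global FA offset added to every
#'   subject's tissue targets; this is the biological variability against
#'   which mean-shift effect sizes (Cohen's d) are expressed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, group_fraction = 0.5,
                        volume_shape = c(24L, 28L, 24L), effects = list(),
                        noise_sd = 0.1, seed = 1L, n_gray = 6L, n_white = 4L,
                        base_fa = c(gray = 0.25, white = 0.55),
                        subject_sd = 0.02) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (group_fraction < 0 || group_fraction > 1) stop("group_fraction must be in [0,1]")
  if (length(volume_shape) != 3 || any(volume_shape < 8))
    stop("volume_shape must be an integer triple with every dimension >= 8")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!all(c("gray", "white") %in% names(base_fa)) ||
      any(base_fa < 0) || any(base_fa >= 1))
    stop("base_fa must name gray and white targets in [0,1)")
  for (e in effects) if (!inherits(e, "group_effect"))
    stop("effects must be a list of group_effect objects")
  structure(list(n_subjects = as.integer(n_subjects),
                 group_fraction = group_fraction,
                 volume_shape = as.integer(volume_shape), effects = effects,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 n_gray = as.integer(n_gray), n_white = as.integer(n_white),
                 base_fa = base_fa, subject_sd = subject_sd),
            class = "cohort_spec")
}

#' Group effect specification
#'
#' @param kind `"mean_shift"` (FA level difference inside target ROIs, sized
#'   in Cohen's d against the between-subject SD of per-subject ROI-mean FA)
#'   or `"texture_complexity"` (one group's maps are Gaussian-smoothed inside
#'   the target region, lowering their quantized-map entropy; `magnitude` is
#'   the smoothing-width difference in voxels).
#' @param target_roi_ids ROI ids carrying the effect. Required nonempty for
#'   `mean_shift`; empty for `texture_complexity` means the whole brain mask.
#' @param magnitude Nonnegative effect magnitude.
#' @param direction `+1` if group A ("man" analog) has the larger value
#'   (mean FA, or entropy), `-1` otherwise.
#' @return Object of class `group_effect`.
#' @export
group_effect <- function(kind = c("mean_shift", "texture_complexity"),
                         target_roi_ids = integer(), magnitude, direction = 1) {
  kind <- match.arg(kind)
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  if (kind == "mean_shift" && length(target_roi_ids) == 0)
    stop("mean_shift requires nonempty target_roi_ids")
  structure(list(kind = kind, target_roi_ids = as.integer(target_roi_ids),
                 magnitude = magnitude, direction = direction),
            class = "group_effect")
}

# Normalized ellipsoidal radius of every voxel; the brain mask is r < 1 with
# semi-axes at 30% of each dimension (a skull-stripped map: zero background).
.ellipsoid_radius <- function(shape) {
  ctr <- (shape + 1) / 2
  semi <- 0.3 * shape
  i <- (seq_len(shape[1]) - ctr[1]) / semi[1]
  j <- (seq_len(shape[2]) - ctr[2]) / semi[2]
  k <- (seq_len(shape[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  sqrt(r2)
}

brain_mask <- function(shape) .ellipsoid_radius(shape) < 1

#' Generate a synthetic atlas parcellation
#'
#' Partitions a central ellipsoidal brain mask into connected, mutually
#' exclusive ROIs by multi-source region growth (6-connected breadth-first)
#' from seeded random voxels: white-matter seeds in the ellipsoid core,
#' gray-matter seeds in the outer shell. Every in-mask voxel receives a
#' label; background is 0.
#'
#' @param shape Integer triple.
#' @param n_gray,n_white ROI counts per tissue class (ids 1..n_gray are gray,
#'   then n_gray+1..n_gray+n_white white).
#' @param seed Integer seed; the result is deterministic in (shape, seeds).
#' @return A `label_volume`: list with integer array `labels` and data frame
#'   `roi_table` (roi_id, name, tissue).
#' @export
generate_atlas <- function(shape, n_gray, n_white, seed) {
  shape <- as.integer(shape)
  r <- .ellipsoid_radius(shape)
  mask <- r < 1
  n_roi <- n_gray + n_white
  if (n_roi < 1) stop("need at least one ROI")
  if (n_roi > sum(mask))
    stop("shape too small: ", sum(mask), " brain voxels for ", n_roi, " ROIs")
  core <- which(mask & r < 0.55)
  shell <- which(mask & r >= 0.55)
  if (length(core) < n_white || length(shell) < n_gray)
    stop("shape too small to host ", n_gray, " gray and ", n_white, " white ROIs")
  labels <- array(0L, dim = shape)
  seeds <- with_seed(seed, {
    c(sample(shell, n_gray), sample(core, n_white))
  })
  labels[seeds] <- seq_len(n_roi)
  # multi-source BFS over the mask, deterministic offset order
  D <- shape[1]; W <- shape[2]; H <- shape[3]
  coord <- arrayInd(seeds, shape)
  frontier_idx <- seeds
  frontier_coord <- coord
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  while (length(frontier_idx) > 0) {
    nxt_idx <- integer(0); nxt_coord <- NULL
    for (o in seq_len(6)) {
      nc <- sweep(frontier_coord, 2, offs[o, ], `+`)
      ok <- nc[, 1] >= 1 & nc[, 1] <= D & nc[, 2] >= 1 & nc[, 2] <= W &
            nc[, 3] >= 1 & nc[, 3] <= H
      if (!any(ok)) next
      nc <- nc[ok, , drop = FALSE]
      src <- frontier_idx[ok]
      ni <- nc[, 1] + D * (nc[, 2] - 1L) + D * W * (nc[, 3] - 1L)
      free <- mask[ni] & labels[ni] == 0L
      if (!any(free)) next
      ni <- ni[free]; src <- src[free]; nc <- nc[free, , drop = FALSE]
      first <- !duplicated(ni)
      ni <- ni[first]; src <- src[first]; nc <- nc[first, , drop = FALSE]
      labels[ni] <- labels[src]
      nxt_idx <- c(nxt_idx, ni)
      nxt_coord <- rbind(nxt_coord, nc)
    }
    if (length(nxt_idx) > 0) {
      keep <- !duplicated(nxt_idx)
      frontier_idx <- nxt_idx[keep]
      frontier_coord <- nxt_coord[keep, , drop = FALSE]
    } else frontier_idx <- integer(0)
  }
  tissue <- c(rep("gray", n_gray), rep("white", n_white))
  roi_table <- data.frame(
    roi_id = seq_len(n_roi),
    name = sprintf("%s_%02d", tissue, c(seq_len(n_gray), seq_len(n_white))),
    tissue = tissue, stringsAsFactors = FALSE)
  structure(list(labels = labels, roi_table = roi_table), class = "label_volume")
}

# FA target -> anisotropy parameter of an axially symmetric eigenvalue triple
# (l1, l2, l2) with fixed mean m: l1 = m(1+2a), l2 = l3 = m(1-a), and
# FA = sqrt(3) a / sqrt(1 + 2 a^2), inverted in closed form.
.fa_to_aniso <- function(fa) fa / sqrt(3 - 2 * fa^2)

# Build a tensor field from a voxelwise FA-target array. Voxels outside
# `inside` get the zero tensor. Principal axes are seeded-random unit
# vectors; eigenvalue noise is additive, clipped to >= 0.
tensor_field_from_targets <- function(fa_target, inside, noise_sd, seed,
                                      mean_diff = 1) {
  shape <- dim(fa_target)
  v <- which(inside)
  nv <- length(v)
  tf <- array(0, dim = c(shape, 6))
  if (nv == 0) return(tf)
  a <- .fa_to_aniso(fa_target[v])
  l1 <- mean_diff * (1 + 2 * a)
  l2 <- mean_diff * (1 - a)
  lam <- cbind(l1, l2, l2)
  with_seed(seed, {
    if (noise_sd > 0)
      lam <- lam + matrix(rnorm(3 * nv, sd = noise_sd * mean_diff), nv, 3)
    u <- matrix(rnorm(3 * nv), nv, 3)
    h <- matrix(rnorm(3 * nv), nv, 3)
    lam <- pmax(lam, 0)
    u <- u / sqrt(rowSums(u^2))
    h <- h - rowSums(h * u) * u
    h <- h / sqrt(rowSums(h^2))
    w <- cbind(u[, 2] * h[, 3] - u[, 3] * h[, 2],
               u[, 3] * h[, 1] - u[, 1] * h[, 3],
               u[, 1] * h[, 2] - u[, 2] * h[, 1])
    comp <- function(p, q)
      lam[, 1] * u[, p] * u[, q] + lam[, 2] * h[, p] * h[, q] +
        lam[, 3] * w[, p] * w[, q]
    V <- prod(shape)
    tf[v]         <- comp(1, 1)
    tf[v + V]     <- comp(1, 2)
    tf[v + 2 * V] <- comp(1, 3)
    tf[v + 3 * V] <- comp(2, 2)
    tf[v + 4 * V] <- comp(2, 3)
    tf[v + 5 * V] <- comp(3, 3)
  })
  tf
}

#' Generate a tensor field for an atlas
#'
#' Axially symmetric per-voxel tensors whose noiseless FA equals the tissue
#' base target; background (label 0) voxels get the zero tensor.
#'
#' @param shape Integer triple (must match the atlas).
#' @param labels A `label_volume` from [generate_atlas()].
#' @param base_fa_by_tissue Named vector with `gray` and `white` FA targets
#'   in [0, 1).
#' @param noise_sd Nonnegative additive eigenvalue noise scale.
#' @param seed Integer seed.
#' @return `(D, W, H, 6)` tensor array.
#' @export
generate_tensor_field <- function(shape, labels, base_fa_by_tissue, noise_sd,
                                  seed) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (any(base_fa_by_tissue < 0) || any(base_fa_by_tissue >= 1))
    stop("base FA targets must lie in [0,1)")
  if (!identical(as.integer(shape), as.integer(dim(labels$labels))))
    stop("shape does not match atlas labels")
  fa_target <- array(0, dim = shape)
  tis <- labels$roi_table$tissue[match(labels$labels, labels$roi_table$roi_id)]
  inside <- labels$labels > 0
  fa_target[inside] <- base_fa_by_tissue[tis[inside]]
  tensor_field_from_targets(fa_target, inside, noise_sd, seed)
}

#' Inject a group effect into a rendered cohort
#'
#' Modifies the cohort's FA maps in place (functionally). `mean_shift` adds a
#' constant inside the target ROIs, with opposite sign per group; the
#' constant is calibrated as `magnitude * s` where `s` is the pooled
#' within-group SD of per-subject ROI-mean FA estimated from the cohort, so
#' the realized Cohen's d matches `magnitude`. `texture_complexity` smooths
#' the lower-entropy group's maps with a Gaussian kernel of width `magnitude`
#' voxels inside the target region (whole brain mask when no ROIs given).
#'
#' @param cohort A `dti_cohort` (see [generate_cohort()]).
#' @param effect A [group_effect()].
#' @param seed Unused at present (effects are deterministic given the
#'   cohort); kept for interface stability.
#' @return The modified cohort.
#' @export
inject_group_effect <- function(cohort, effect, seed = 0L) {
  stopifnot(inherits(cohort, "dti_cohort"), inherits(effect, "group_effect"))
  labels <- cohort$atlas$labels
  known <- cohort$atlas$roi_table$roi_id
  if (length(effect$target_roi_ids) > 0 &&
      !all(effect$target_roi_ids %in% known))
    stop("ROI id(s) absent from atlas: ",
         paste(setdiff(effect$target_roi_ids, known), collapse = ", "))
  grp <- cohort$subjects$group
  if (effect$magnitude == 0) return(cohort)
  if (effect$kind == "mean_shift") {
    region <- labels %in% effect$target_roi_ids
    roi_means <- vapply(cohort$volumes, function(v) mean(v[region]), 0)
    sa <- sd(roi_means[grp == "A"]); sb <- sd(roi_means[grp == "B"])
    na <- sum(grp == "A"); nb <- sum(grp == "B")
    s <- sqrt(((na - 1) * sa^2 + (nb - 1) * sb^2) / (na + nb - 2))
    if (!is.finite(s) || s == 0) {
      warning("zero between-subject variability; mean_shift not injected")
      return(cohort)
    }
    delta <- effect$magnitude * s * effect$direction
    for (i in seq_along(cohort$volumes)) {
      sgn <- if (grp[i] == "A") 0.5 else -0.5
      v <- cohort$volumes[[i]]
      v[region] <- pmin(pmax(v[region] + sgn * delta, 0), 1)
      cohort$volumes[[i]] <- v
    }
  } else if (effect$kind == "texture_complexity") {
    region <- if (length(effect$target_roi_ids) > 0)
      array(labels %in% effect$target_roi_ids, dim(labels)) else labels > 0
    smoothed_group <- if (effect$direction > 0) "B" else "A"
    # mask-normalized (region-weighted) smoothing: no bleed across the region
    # boundary, so within-tissue variance drops and quantized entropy falls
    rmask <- array(as.double(region), dim(region))
    wsum <- .gaussian_smooth3d(rmask, effect$magnitude)
    for (i in seq_along(cohort$volumes)) {
      if (grp[i] != smoothed_group) next
      v <- cohort$volumes[[i]]
      sm <- .gaussian_smooth3d(v * rmask, effect$magnitude) / pmax(wsum, 1e-9)
      v[region] <- sm[region]
      cohort$volumes[[i]] <- v
    }
  } else stop("unknown effect kind: ", effect$kind)
  cohort
}

#' Generate a full synthetic cohort on disk
#'
#' Builds the atlas, renders one FA map per subject (axially symmetric
#' tensors with seeded noise and a per-subject global FA offset, then the
#' tensor-to-scalar pipeline), injects the spec's group effects, and writes
#' everything under `output_dir`: per-subject NIfTI maps, the atlas, an ROI
#' table and a tab-separated manifest (`subject_id`, `group`, `path`).
#'
#' @param spec A [cohort_spec()].
#' @param output_dir Writable output directory (created if needed).
#' @param maps Which scalar maps to write per subject (effects apply to FA
#'   only; the manifest points at the FA map).
#' @return A `dti_cohort`: list with `subjects` (data frame: subject_id,
#'   group, path), `atlas`, `volumes` (list of FA arrays, post-effects),
#'   `manifest_path`, `atlas_path`.
#' @export
generate_cohort <- function(spec, output_dir, maps = "FA") {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", output_dir)
  cohort <- simulate_cohort(spec)
  shape <- spec$volume_shape
  paths <- character(spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    id <- cohort$subjects$subject_id[i]
    fa_path <- file.path(output_dir, sprintf("%s_FA.nii.gz", id))
    write_nifti(cohort$volumes[[i]], fa_path, datatype = "float64")
    if (length(setdiff(maps, "FA")) > 0) {
      for (k in setdiff(maps, c("FA"))) {
        write_nifti(cohort$extra_maps[[i]][[k]],
                    file.path(output_dir, sprintf("%s_%s.nii.gz", id, k)),
                    datatype = "float64")
      }
    }
    paths[i] <- fa_path
  }
  cohort$subjects$path <- paths
  atlas_path <- file.path(output_dir, "atlas.nii.gz")
  write_nifti(array(as.double(cohort$atlas$labels), dim = shape), atlas_path,
              datatype = "int32")
  write.table(cohort$atlas$roi_table, file.path(output_dir, "roi_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_path <- file.path(output_dir, "manifest.tsv")
  write.table(cohort$subjects[, c("subject_id", "group", "path")],
              manifest_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cohort$manifest_path <- manifest_path
  cohort$atlas_path <- atlas_path
  cohort$extra_maps <- NULL
  cohort
}

#' Render a cohort in memory (no I/O)
#'
#' The computational core of [generate_cohort()]; useful for tests and for
#' pipelines that do not need files.
#'
#' @inheritParams generate_cohort
#' @return A `dti_cohort` without `manifest_path`.
#' @export
simulate_cohort <- function(spec, maps = "FA") {
  stopifnot(inherits(spec, "cohort_spec"))
  shape <- spec$volume_shape
  atlas <- generate_atlas(shape, spec$n_gray, spec$n_white,
                          derive_seed(spec$seed, "atlas"))
  n <- spec$n_subjects
  n_a <- floor(n * spec$group_fraction)
  group <- c(rep("A", n_a), rep("B", n - n_a))
  subjects <- data.frame(
    subject_id = sprintf("sub%04d", seq_len(n)),
    group = group, stringsAsFactors = FALSE)
  offsets <- with_seed(derive_seed(spec$seed, "offsets"),
                       rnorm(n, sd = spec$subject_sd))
  inside <- atlas$labels > 0
  tis <- atlas$roi_table$tissue[match(atlas$labels, atlas$roi_table$roi_id)]
  base <- array(0, dim = shape)
  base[inside] <- spec$base_fa[tis[inside]]
  volumes <- vector("list", n)
  extra <- if (length(setdiff(maps, "FA")) > 0) vector("list", n) else NULL
  for (i in seq_len(n)) {
    fa_target <- base
    fa_target[inside] <- pmin(pmax(fa_target[inside] + offsets[i], 0.02), 0.95)
    tf <- tensor_field_from_targets(fa_target, inside, spec$noise_sd,
                                    derive_seed(spec$seed, "tensor", i))
    sm <- scalar_maps_from_field(tf)
    volumes[[i]] <- sm$FA
    if (!is.null(extra)) extra[[i]] <- sm[setdiff(maps, "FA")]
  }
  cohort <- structure(list(subjects = subjects, volumes = volumes,
                           atlas = atlas, spec = spec, extra_maps = extra),
                      class = "dti_cohort")
  for (k in seq_along(spec$effects))
    cohort <- inject_group_effect(cohort, spec$effects[[k]],
                                  derive_seed(spec$seed, "effect", k))
  cohort
}
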