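# Volume loading, rescaling to the model grid, label encoding and the
# HDF5-backed record store used for training.

#' Load a 3D scalar volume
#'
#' @param path NIfTI path.
#' @return 3D array with voxel sizes in the `"pixdim"` attribute.
#' @export
load_volume <- function(path) {
  x <- read_nifti(path)
  if (length(dim(x)) != 3)
    stop("expected a 3D volume, got shape ",
         paste(dim(x), collapse = "x"), ": ", path)
  x
}

#' Rescale a volume to a target grid
#'
#' Separable cubic-convolution (Catmull-Rom) interpolation with mirrored
#' boundaries and pixel-center coordinate mapping; `order = 1` selects
#' trilinear interpolation. Interpolation overshoot is clipped to the input
#' range, so constant volumes stay constant and the output range never
#' exceeds the input's.
#'
#' @param volume 3D numeric array, each dimension >= 2.
#' @param target_shape Integer triple of positive output dimensions.
#' @param order Interpolation order, 3 (cubic, default) or 1 (linear).
#' @return 3D array with `dim == target_shape`.
#' @export
rescale_volume <- function(volume, target_shape, order = 3) {
  if (length(dim(volume)) != 3 || any(dim(volume) < 2))
    stop("volume must be 3D with all dimensions >= 2")
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3 || any(target_shape < 1))
    stop("target_shape must be a positive integer triple")
  .resample3d(volume, target_shape, as.integer(order))
}

#' One-hot label encoding
#'
#' Group A ("man" analog) maps to `c(1, 0)`, group B ("woman" analog) to
#' `c(0, 1)`.
#'
#' @param group `"A"`/`"man"` or `"B"`/`"woman"`.
#' @return Length-2 one-hot vector.
#' @export
encode_label <- function(group) {
  switch(as.character(group),
         A = , man = c(1, 0),
         B = , woman = c(0, 1),
         stop("unknown group: ", group))
}

#' @rdname encode_label
#' @param onehot Length-2 one-hot vector.
#' @return `decode_label`: the group string `"A"` or `"B"`.
#' @export
decode_label <- function(onehot) {
  if (identical(as.numeric(onehot), c(1, 0))) return("A")
  if (identical(as.numeric(onehot), c(0, 1))) return("B")
  stop("not a one-hot pair: ", paste(onehot, collapse = ", "))
}

#' In-memory prepared dataset
#'
#' @param volumes 4D array `(D, W, H, N)` of same-shape volumes.
#' @param labels `N x 2` one-hot matrix.
#' @param subject_ids Character vector of length N.
#' @return Object of class `prepared_dataset`.
#' @export
prepared_dataset <- function(volumes, labels, subject_ids) {
  d <- dim(volumes)
  stopifnot(length(d) == 4, nrow(labels) == d[4],
            length(subject_ids) == d[4], ncol(labels) == 2)
  if (!all(rowSums(labels) == 1) || !all(labels %in% c(0, 1)))
    stop("labels must be one-hot rows")
  structure(list(volumes = volumes, labels = labels,
                 subject_ids = as.character(subject_ids),
                 target_shape = d[1:3]),
            class = "prepared_dataset")
}

#' Build an HDF5 record store from a manifest
#'
#' Reads the tab-separated manifest (`subject_id`, `group`, `path`), loads
#' each subject's volume, rescales it to `target_shape`, one-hot encodes the
#' group, and writes a single HDF5 container with datasets `volumes`
#' (D x W x H x N), `labels` (N x 2) and `subject_ids`, in manifest order.
#'
#' @param manifest Path to the manifest TSV.
#' @param target_shape Integer triple; the model input grid.
#' @param out Output `.h5` path.
#' @param order Interpolation order passed to [rescale_volume()].
#' @return `out`, invisibly.
#' @export
build_record_store <- function(manifest, target_shape, out, order = 3) {
  rows <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group", "path") %in% names(rows)))
    stop("manifest must have columns subject_id, group, path")
  n <- nrow(rows)
  target_shape <- as.integer(target_shape)
  vols <- array(0, dim = c(target_shape, n))
  labs <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    v <- tryCatch(load_volume(rows$path[i]), error = function(e)
      stop("subject ", rows$subject_id[i], ": ", conditionMessage(e)))
    vols[, , , i] <- rescale_volume(v, target_shape, order)
    labs[i, ] <- encode_label(rows$group[i])
  }
  if (file.exists(out)) unlink(out)
  rhdf5::h5createFile(out)
  rhdf5::h5write(vols, out, "volumes")
  rhdf5::h5write(labs, out, "labels")
  rhdf5::h5write(rows$subject_id, out, "subject_ids")
  rhdf5::h5closeAll()
  invisible(out)
}

#' Open a record store for streaming reads
#'
#' @param path `.h5` store written by [build_record_store()].
#' @return A `record_store` handle with `$n`, `$target_shape`.
#' @export
open_record_store <- function(path) {
  if (!file.exists(path)) stop("record store not found: ", path)
  info <- rhdf5::h5ls(path)
  dims <- as.integer(strsplit(info$dim[info$name == "volumes"], " x ")[[1]])
  structure(list(path = path, n = dims[4], target_shape = dims[1:3]),
            class = "record_store")
}

#' Read one record from a store
#'
#' @param store A `record_store`.
#' @param i Record index (1-based, stored order).
#' @return List with `volume`, `label`, `subject_id`.
#' @export
read_record <- function(store, i) {
  stopifnot(inherits(store, "record_store"), i >= 1, i <= store$n)
  ts <- store$target_shape
  v <- rhdf5::h5read(store$path, "volumes",
                     index = list(NULL, NULL, NULL, i))
  lab <- rhdf5::h5read(store$path, "labels", index = list(i, NULL))
  id <- rhdf5::h5read(store$path, "subject_ids", index = list(i))
  rhdf5::h5closeAll()
  list(volume = array(v, dim = ts), label = as.numeric(lab),
       subject_id = as.character(id))
}

#' Seeded shuffled record order
#'
#' @param store A `record_store` (or anything with `$n`).
#' @param seed Integer seed.
#' @return Permutation of `1:n`, deterministic for a given seed.
#' @export
record_order <- function(store, seed) {
  with_seed(seed, sample(store$n))
}

#' Load an entire record store into memory
#'
#' @param path `.h5` store path.
#' @return A [prepared_dataset()].
#' @export
load_prepared <- function(path) {
  vols <- rhdf5::h5read(path, "volumes")
  labs <- rhdf5::h5read(path, "labels")
  ids <- as.character(rhdf5::h5read(path, "subject_ids"))
  rhdf5::h5closeAll()
  prepared_dataset(vols, labs, ids)
}

#' Prepared dataset directly from an in-memory cohort (no files touched)
#'
#' @param cohort A `dti_cohort` from [simulate_cohort()] or [generate_cohort()].
#' @param target_shape Model input grid (defaults to the cohort's native shape).
#' @param order Interpolation order for [rescale_volume()].
#' @return A [prepared_dataset()].
#' @export
prepare_cohort <- function(cohort, target_shape = NULL, order = 3) {
  shape <- target_shape %||% cohort$spec$volume_shape
  n <- nrow(cohort$subjects)
  vols <- array(0, dim = c(as.integer(shape), n))
  labs <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    v <- cohort$volumes[[i]]
    if (!identical(dim(v), as.integer(shape)))
      v <- rescale_volume(v, shape, order)
    vols[, , , i] <- v
    labs[i, ] <- encode_label(cohort$subjects$group[i])
  }
  prepared_dataset(vols, labs, cohort$subjects$subject_id)
}
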