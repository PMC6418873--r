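# Tensor-derived scalar maps: FA, MD, AD, RD.
#
# Diffusion tensors are symmetric positive-semidefinite 3x3 matrices per
# voxel. A tensor field is stored as a (D, W, H, 6) array in upper-triangle
# order Dxx, Dxy, Dxz, Dyy, Dyz, Dzz (the NIfTI 6-component convention).

EIG_TOL <- 1e-9  # relative tolerance for symmetry checks and eigenvalue clipping

#' Eigendecompose a single diffusion tensor
#'
#' @param tensor Symmetric 3x3 matrix (asymmetry beyond `1e-9` of the largest
#'   entry is an error).
#' @return Eigenvalues sorted descending, `c(l1, l2, l3)`.
#' @export
eigendecompose_voxel <- function(tensor) {
  if (!is.matrix(tensor) || any(dim(tensor) != c(3, 3)))
    stop("tensor must be a 3x3 matrix")
  scale <- max(abs(tensor), 1e-300)
  if (max(abs(tensor - t(tensor))) > EIG_TOL * scale)
    stop("tensor is asymmetric beyond tolerance")
  ev <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sort(ev, decreasing = TRUE)
}

#' Fractional anisotropy from an eigenvalue triple
#'
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||, the standard
#' scale-invariant anisotropy index in [0, 1]. The all-zero tensor maps to 0
#' by convention so background voxels stay 0.
#'
#' @param lambda Numeric triple of eigenvalues (any order).
#' @return FA in [0, 1].
#' @export
fa_from_eigenvalues <- function(lambda) {
  stopifnot(length(lambda) == 3)
  lmax <- max(abs(lambda))
  if (any(lambda < -EIG_TOL * max(lmax, 1e-300)))
    stop("negative eigenvalue beyond tolerance: ", min(lambda))
  lambda <- pmax(lambda, 0)
  nrm2 <- sum(lambda^2)
  if (nrm2 == 0) return(0)
  m <- mean(lambda)
  fa <- sqrt(1.5 * sum((lambda - m)^2) / nrm2)
  min(max(fa, 0), 1)
}

#' Mean, axial and radial diffusivity from a sorted eigenvalue triple
#'
#' @param lambda Eigenvalues sorted descending (`l1 >= l2 >= l3`).
#' @return Named vector `c(MD, AD, RD)` with MD the eigenvalue mean, AD the
#'   largest eigenvalue and RD the mean of the two smaller ones.
#' @export
md_ad_rd_from_eigenvalues <- function(lambda) {
  stopifnot(length(lambda) == 3)
  if (is.unsorted(rev(lambda))) stop("eigenvalues must be sorted descending")
  c(MD = mean(lambda), AD = lambda[1], RD = (lambda[2] + lambda[3]) / 2)
}

# Vectorized FA over an eigenvalue field (D,W,H,3); used by scalar_maps_from_field.
fa_from_eigenvalue_field <- function(ev) {
  d <- dim(ev)[1:3]
  l1 <- ev[, , , 1]; l2 <- ev[, , , 2]; l3 <- ev[, , , 3]
  m <- (l1 + l2 + l3) / 3
  num <- (l1 - m)^2 + (l2 - m)^2 + (l3 - m)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5 * ifelse(den > 0, num / den, 0))
  array(pmin(pmax(fa, 0), 1), dim = d)
}

#' Compute the four scalar maps from a tensor field
#'
#' Voxelwise eigendecomposition followed by the FA/MD/AD/RD formulas.
#' All-zero (background) tensors map to 0 in all four volumes. Eigenvalues
#' more negative than `-1e-9` of the voxel's largest eigenvalue raise an
#' error naming the voxel; smaller negative slop is clipped to 0.
#'
#' @param field Tensor field: `(D, W, H, 6)` array, upper-triangle order.
#' @return Named list of 3D arrays `FA`, `MD`, `AD`, `RD`, each carrying a
#'   `"kind"` attribute.
#' @export
scalar_maps_from_field <- function(field) {
  d <- dim(field)
  if (length(d) != 4 || d[4] != 6) stop("tensor field must be a (D,W,H,6) array")
  ev <- .eig_sym_field(field)
  l1 <- ev[, , , 1]
  bad <- ev[, , , 3] < -EIG_TOL * pmax(abs(l1), 1e-300)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("negative eigenvalue beyond tolerance at voxel (%d,%d,%d)",
                 w[1], w[2], w[3]))
  }
  ev <- pmax(ev, 0)
  dim(ev) <- c(d[1:3], 3)
  fa <- fa_from_eigenvalue_field(ev)
  md <- (ev[, , , 1] + ev[, , , 2] + ev[, , , 3]) / 3
  ad <- ev[, , , 1]
  rd <- (ev[, , , 2] + ev[, , , 3]) / 2
  out <- list(FA = fa, MD = array(md, d[1:3]), AD = array(ad, d[1:3]),
              RD = array(rd, d[1:3]))
  for (k in names(out)) attr(out[[k]], "kind") <- k
  out
}

#' Write / read a tensor field as a 6-component NIfTI
#'
#' Components are stored along the fourth dimension in upper-triangle order
#' Dxx, Dxy, Dxz, Dyy, Dyz, Dzz.
#'
#' @param field `(D, W, H, 6)` array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path` invisibly (write); the array (read).
#' @export
write_tensor_field <- function(field, path) {
  d <- dim(field)
  if (length(d) != 4 || d[4] != 6) stop("tensor field must be (D,W,H,6)")
  write_nifti(field, path, datatype = "float64")
}

#' @rdname write_tensor_field
#' @export
read_tensor_field <- function(path) {
  x <- read_nifti(path)
  d <- dim(x)
  if (length(d) != 4 || d[4] != 6)
    stop("not a 6-component tensor NIfTI: ", path)
  x
}
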