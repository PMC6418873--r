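# Minimal NIfTI-1 I/O.
#
# The installed R stack ships no NIfTI reader, so the package carries a small
# one covering exactly what the pipeline writes and reads: single-file .nii /
# .nii.gz, 3D or 4D, little-endian, datatypes uint8/int16/int32/float32/float64,
# diagonal affine (pixdim voxel sizes), no extensions.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE, r = "integer"),
  `4`  = list(what = "integer", size = 2, signed = TRUE,  r = "integer"),
  `8`  = list(what = "integer", size = 4, signed = TRUE,  r = "integer"),
  `16` = list(what = "double",  size = 4, signed = TRUE,  r = "double"),
  `64` = list(what = "double",  size = 8, signed = TRUE,  r = "double")
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzipped). Only the subset of
#' the format written by this package is supported: 3D or 4D images with
#' datatype uint8, int16, int32, float32 or float64.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A numeric array with the on-disk dimensions; voxel sizes are
#'   attached as the `"pixdim"` attribute.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = "little")
  swap <- sizeof_hdr != 348L
  endian <- if (swap) "big" else "little"
  if (swap && .bitswap_int(sizeof_hdr) != 348L)
    stop("not a NIfTI-1 file (bad header size): ", path)
  readBin(con, "raw", 36)                                  # unused fields
  dim0 <- readBin(con, "integer", 8, 2, endian = endian)   # dim[0..7]
  ndim <- dim0[1]
  if (!(ndim %in% c(3L, 4L))) stop("unsupported NIfTI dimensionality ", ndim,
                                   " (shape ", paste(dim0[-1][seq_len(max(ndim, 1))], collapse = "x"),
                                   "): only 3D/4D supported")
  readBin(con, "raw", 14)                                  # intent fields
  datatype <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "raw", 4)                                   # bitpix, slice_start
  pixdim <- readBin(con, "double", 8, 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, 4, endian = endian)
  readBin(con, "raw", 348 - 112)                           # rest of header
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  nvox <- prod(dim0[2:(ndim + 1)])
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, dt$what, nvox, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) != nvox) stop("truncated NIfTI data in ", path)
  arr <- array(as.double(vals), dim = dim0[2:(ndim + 1)])
  attr(arr, "pixdim") <- pixdim[2:(ndim + 1)]
  arr
}

.bitswap_int <- function(x) {
  b <- packBits(intToBits(x), "raw")
  readBin(rev(b), "integer", 1, 4, endian = "little")
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D or 4D numeric array as a single-file NIfTI-1 image with a
#' diagonal voxel-size affine.
#'
#' @param x 3D or 4D numeric array.
#' @param path Output path; written gzipped when it ends in `.gz`.
#' @param pixdim Voxel sizes, one per dimension (default 1).
#' @param datatype One of `"float64"`, `"float32"`, `"int32"`, `"int16"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, pixdim = NULL,
                        datatype = c("float64", "float32", "int32", "int16")) {
  datatype <- match.arg(datatype)
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("write_nifti: array must be 3D or 4D")
  if (is.null(pixdim)) pixdim <- rep(1, length(d))
  code <- switch(datatype, float64 = 64L, float32 = 16L, int32 = 8L, int16 = 4L)
  bitpix <- switch(datatype, float64 = 64L, float32 = 32L, int32 = 32L, int16 = 16L)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, 4, endian = "little")
  writeBin(raw(36), con)
  dim8 <- integer(8)
  dim8[1] <- length(d)
  dim8[2:(length(d) + 1)] <- d
  dim8[dim8 == 0L] <- 1L
  dim8[1] <- length(d)
  writeBin(as.integer(dim8), con, 2, endian = "little")
  writeBin(raw(14), con)
  writeBin(code, con, 2, endian = "little")
  writeBin(as.integer(bitpix), con, 2, endian = "little")
  writeBin(raw(2), con)                                   # slice_start
  pd8 <- numeric(8)
  pd8[1] <- 1
  pd8[2:(length(d) + 1)] <- pixdim
  writeBin(pd8, con, 4, endian = "little")
  writeBin(352, con, 4, endian = "little")                # vox_offset
  writeBin(c(1, 0), con, 4, endian = "little")            # scl_slope, scl_inter
  writeBin(raw(344 - 120), con)                           # up to magic at 344
  # sform/qform zero; readers fall back to pixdim. magic at offset 344.
  writeBin(charToRaw("n+1"), con)
  writeBin(raw(1), con)
  writeBin(raw(4), con)                                   # extension flag
  vals <- as.vector(x)
  if (datatype %in% c("int32", "int16")) {
    writeBin(as.integer(round(vals)), con, bitpix / 8, endian = "little")
  } else {
    writeBin(as.double(vals), con, bitpix / 8, endian = "little")
  }
  invisible(path)
}
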