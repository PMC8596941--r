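## Minimal NIfTI-1 (.nii, single-file) IO in base R.
##
## No NIfTI-capable R package is available in this toolchain, so the
## package carries a small codec for the subset it needs: 3D/4D float32
## or int16 images with an affine stored in the srow_* fields
## (sform code 1). Round-trips were checked against nibabel during
## development. Not a general-purpose NIfTI implementation.

NIFTI_HDR_SIZE <- 348L

#' Write a 3D or 4D array as a NIfTI-1 file
#'
#' Data are stored as little-endian float32 with the voxel-to-world
#' affine in the sform rows.
#'
#' @param data numeric 3D array (one volume) or 4D array with the 4th
#'   dimension indexing volumes/subjects.
#' @param path output `.nii` path.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices, as is
#'   conventional for the format); default diagonal from `voxel_size_mm`.
#' @param voxel_size_mm length-3 voxel dimensions, used when `affine` is
#'   not given.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = NULL, voxel_size_mm = c(1, 1, 1)) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop_validation("write_nifti expects a 3D or 4D array")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  stopifnot(all(dim(affine) == c(4, 4)))
  dims <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  w_i <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  w_f <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_i(NIFTI_HDR_SIZE, 4)                       # sizeof_hdr
  writeBin(raw(36), con)                       # data_type..dim_info (unused)
  dimfield <- c(nd, dims, rep(1L, 7 - nd))
  w_i(dimfield, 2)                             # dim[8]
  w_f(c(0, 0, 0))                              # intent_p1..p3
  w_i(0, 2)                                    # intent_code
  w_i(16, 2)                                   # datatype = NIFTI_TYPE_FLOAT32
  w_i(32, 2)                                   # bitpix
  w_i(0, 2)                                    # slice_start
  pix <- sqrt(colSums(affine[1:3, 1:3]^2))
  w_f(c(1, pix, rep(1, 7 - nd), 0)[1:8])       # pixdim[8] (qfac=1)
  w_f(NIFTI_HDR_SIZE + 4)                      # vox_offset = 352
  w_f(c(1, 0))                                 # scl_slope, scl_inter
  w_i(0, 2); writeBin(raw(2), con)             # slice_end, slice_code, xyzt_units
  w_f(c(0, 0, 0))                              # cal_max, cal_min, slice_duration
  w_f(0)                                       # toffset
  w_i(c(0, 0), 4)                              # glmax, glmin (unused)
  writeBin(raw(80 + 24), con)                  # descrip, aux_file
  w_i(0, 2)                                    # qform_code = 0
  w_i(1, 2)                                    # sform_code = 1
  w_f(rep(0, 6))                               # quatern b,c,d + qoffset x,y,z
  w_f(affine[1, ]); w_f(affine[2, ]); w_f(affine[3, ])   # srow_x/y/z
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)                        # extension flag
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by this package (or compatible)
#'
#' Supports single-file `.nii`, float32/float64/int16/uint8 data,
#' 3D or 4D, either endianness, with scl_slope/scl_inter applied.
#'
#' @param path `.nii` path.
#' @return list: `data` (array), `affine` (4x4), `voxel_size_mm`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sz <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sz != NIFTI_HDR_SIZE) {
    endian <- "big"
    seek(con, 0)
    sz <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (sz != NIFTI_HDR_SIZE) stop_validation("%s is not a NIfTI-1 file", path)
  }
  readBin(con, "raw", 36)
  dimfield <- readBin(con, "integer", 8, size = 2, endian = endian)
  nd <- dimfield[1]
  if (!nd %in% c(3L, 4L)) stop_validation("unsupported NIfTI dimensionality %d", nd)
  dims <- dimfield[2:(1 + nd)]
  readBin(con, "numeric", 3, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 2, size = 2, endian = endian)     # bitpix, slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl <- readBin(con, "numeric", 2, size = 4, endian = endian)
  seek(con, 252)
  readBin(con, "integer", 1, size = 2, endian = endian)     # qform_code
  sform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "numeric", 6, size = 4, endian = endian)
  srow <- matrix(readBin(con, "numeric", 12, size = 4, endian = endian),
                 3, 4, byrow = TRUE)
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (sform_code == 0) affine <- diag(c(pixdim[2:4], 1))
  seek(con, vox_offset)
  nvox <- prod(dims)
  data <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", nvox, size = 1, signed = FALSE, endian = endian)),
    "4"  = as.numeric(readBin(con, "integer", nvox, size = 2, endian = endian)),
    "16" = readBin(con, "numeric", nvox, size = 4, endian = endian),
    "64" = readBin(con, "numeric", nvox, size = 8, endian = endian),
    stop_validation("unsupported NIfTI datatype %d", datatype))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) data <- data * scl[1] + scl[2]
  dim(data) <- dims
  list(data = data, affine = affine,
       voxel_size_mm = sqrt(colSums(affine[1:3, 1:3]^2)))
}
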