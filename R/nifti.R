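# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O in base R.
# Only the fields this package needs are interpreted: dim, datatype,
# pixdim, scl_slope/scl_inter, vox_offset, sform. Data are written as
# float64 so that round-trips are bit-exact.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352L

# datatype codes we can read
.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into an
#' array together with the voxel size and repetition time stored in
#' `pixdim`. Both endiannesses are handled; data scaling (`scl_slope`,
#' `scl_inter`) is applied when present.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array of the stored
#'   dimensionality), `voxel_size_mm` (length-3 numeric), `tr_s` (numeric
#'   scalar, `pixdim[5]`), and `affine` (4x4 sform matrix, if stored).
#' @export
read_nifti <- function(path) {
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != NIFTI_HDR_SIZE) {
    endian <- "big"
    if (.swap_int32(sizeof_hdr) != NIFTI_HDR_SIZE) {
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
    }
  }
  readBin(con, "raw", 36L)                              # skip to dim
  dim8 <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                              # intent_p1..3, intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 160L)                             # through qoffset_z
  srow <- matrix(readBin(con, "double", 12L, size = 4L, endian = endian),
                 nrow = 3L, byrow = TRUE)
  readBin(con, "raw", 16L)                              # intent_name
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1")) {
    stop("unsupported NIfTI variant (magic != 'n+1'): ", path)
  }
  ndim <- dim8[1L]
  if (ndim < 1L || ndim > 7L) stop("corrupt NIfTI dim[0]: ", ndim)
  dims <- dim8[seq_len(ndim) + 1L]
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  skip <- as.integer(vox_offset) - NIFTI_HDR_SIZE
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  affine <- rbind(srow, c(0, 0, 0, 1))
  list(data = array(as.double(vals), dim = dims),
       voxel_size_mm = abs(pixdim[2:4]),
       tr_s = pixdim[5L],
       affine = affine)
}

#' Write a NIfTI-1 image
#'
#' Writes a 3D or 4D numeric array as a little-endian single-file NIfTI-1
#' image with float64 storage (lossless round-trip). The sform encodes a
#' diagonal RAS+ affine built from the voxel size; `pixdim[5]` carries the
#' repetition time in seconds.
#'
#' @param data Numeric array with 3 or 4 dimensions.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param voxel_size_mm Voxel edge lengths in mm (scalar or length 3).
#' @param tr_s Repetition time in seconds (stored in `pixdim[5]`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size_mm = 3, tr_s = 0) {
  dims <- dim(data)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L))) {
    stop("`data` must be a 3D or 4D array")
  }
  voxel_size_mm <- rep_len(as.double(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  dim8 <- integer(8L)
  dim8[1L] <- length(dims)
  dim8[seq_along(dims) + 1L] <- dims
  dim8[dim8 == 0L] <- 1L
  pixdim <- c(1, voxel_size_mm, tr_s, 0, 0, 0)

  w_i32(NIFTI_HDR_SIZE)                 # sizeof_hdr
  w_raw(36L)                            # data_type..dim_info
  w_i16(dim8)                           # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)          # intent_p*, intent_code
  w_i16(64L); w_i16(64L); w_i16(0L)     # datatype float64, bitpix, slice_start
  w_f32(pixdim)                         # pixdim[8]
  w_f32(NIFTI_VOX_OFFSET)               # vox_offset
  w_f32(1); w_f32(0)                    # scl_slope, scl_inter
  w_i16(0L); w_raw(1L)                  # slice_end, slice_code
  writeBin(as.raw(0x0AL), con)          # xyzt_units: mm | sec
  w_f32(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                      # glmax, glmin
  w_raw(104L)                           # descrip[80] + aux_file[24]
  w_i16(0L); w_i16(1L)                  # qform_code = 0, sform_code = 1
  w_f32(numeric(6L))                    # quatern_b/c/d, qoffset_x/y/z
  w_f32(c(voxel_size_mm[1L], 0, 0, 0))  # srow_x
  w_f32(c(0, voxel_size_mm[2L], 0, 0))  # srow_y
  w_f32(c(0, 0, voxel_size_mm[3L], 0))  # srow_z
  w_raw(16L)                            # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  w_raw(4L)                             # extension flag
  writeBin(as.double(data), con, size = 8L, endian = "little")
  invisible(path)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  readBin(rev(b), "integer", 1L, size = 4L, endian = "little")
}
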