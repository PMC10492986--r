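# Minimal single-file NIfTI-1 (.nii) I/O.
#
# Only what the package needs: 3-D volumes, float32 or uint8, little-endian,
# scl_slope/inter honoured on read. No R NIfTI package ships with this image's
# library set, so the 348-byte header is assembled here by hand.

NIFTI_DTYPES <- list(uint8 = list(code = 2L, bitpix = 8L, what = "integer", size = 1L),
                     float32 = list(code = 16L, bitpix = 32L, what = "double", size = 4L))

#' Write a 3-D array as a NIfTI-1 volume
#'
#' @param img 3-D numeric array (x, y, slice).
#' @param path output file, conventionally `.nii`.
#' @param voxel_dims numeric length-3 voxel size in mm.
#' @param datatype `"float32"` (images) or `"uint8"` (label maps).
#' @param description free-text tag stored in the header (max 79 chars).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxel_dims = c(1, 1, 1),
                        datatype = c("float32", "uint8"), description = "bodycomp3") {
  datatype <- match.arg(datatype)
  if (length(dim(img)) != 3L) stop_validation("img must be a 3-D array")
  check_positive(voxel_dims, "voxel_dims")
  if (length(voxel_dims) != 3L) stop_validation("voxel_dims must have length 3")
  dt <- NIFTI_DTYPES[[datatype]]

  con <- file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_chr <- function(s, n) {
    b <- charToRaw(substr(s, 1L, n))
    writeBin(c(b, raw(n - length(b))), con)
  }

  w_i32(348L)                       # sizeof_hdr
  w_raw(36L)                        # data_type, db_name, extents, session_error, regular, dim_info
  w_i16(c(3L, dim(img), 1L, 1L, 1L, 1L))  # dim[8]
  w_f32(c(0, 0, 0))                 # intent_p1..p3
  w_i16(0L)                         # intent_code
  w_i16(dt$code)                    # datatype
  w_i16(dt$bitpix)                  # bitpix
  w_i16(0L)                         # slice_start
  w_f32(c(1, voxel_dims, 1, 1, 1, 1))     # pixdim[8]
  w_f32(352)                        # vox_offset
  w_f32(c(1, 0))                    # scl_slope, scl_inter
  w_i16(0L)                         # slice_end
  w_raw(2L)                         # slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_chr(description, 80L)           # descrip
  w_raw(24L)                        # aux_file
  w_i16(c(0L, 1L))                  # qform_code, sform_code
  w_f32(rep(0, 6))                  # quatern b,c,d, qoffset x,y,z
  w_f32(c(voxel_dims[1], 0, 0, 0))  # srow_x
  w_f32(c(0, voxel_dims[2], 0, 0))  # srow_y
  w_f32(c(0, 0, voxel_dims[3], 0))  # srow_z
  w_chr("", 16L)                    # intent_name
  w_chr("n+1", 4L)                  # magic
  w_raw(4L)                         # extension flag

  if (datatype == "uint8") {
    writeBin(as.integer(img), con, size = 1L, endian = "little")
  } else {
    writeBin(as.double(img), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()] (or any plain
#' little-endian single-file uint8/float32 volume)
#'
#' @param path `.nii` file.
#' @return list with `img` (3-D array) and `voxel_dims`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r_i32 <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  r_i16 <- function(n) readBin(con, "integer", n, size = 2L, endian = "little")
  r_f32 <- function(n) readBin(con, "double", n, size = 4L, endian = "little")

  if (r_i32(1L) != 348L) stop_validation("not a little-endian NIfTI-1 file: ", path)
  readBin(con, "raw", 36L)
  dims <- r_i16(8L)
  if (dims[1] < 3L) stop_validation("expected a 3-D volume")
  shape <- dims[2:4]
  r_f32(3L); r_i16(1L)
  dtcode <- r_i16(1L)
  r_i16(2L)                                # bitpix, slice_start
  pixdim <- r_f32(8L)
  vox_offset <- r_f32(1L)
  scl <- r_f32(2L)
  seek(con, vox_offset)
  n <- prod(shape)
  img <- switch(as.character(dtcode),
    "2" = readBin(con, "integer", n, size = 1L, signed = FALSE, endian = "little"),
    "16" = readBin(con, "double", n, size = 4L, endian = "little"),
    stop_validation("unsupported NIfTI datatype code ", dtcode))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) img <- img * scl[1] + scl[2]
  list(img = array(img, dim = shape), voxel_dims = pixdim[2:4])
}
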