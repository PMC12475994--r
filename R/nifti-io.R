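#' Read a NIfTI-1 volume
#'
#' Minimal NIfTI-1 reader covering the single-file (`.nii`, `.nii.gz`) layout
#' used throughout this package: 3D volumes in the common datatypes (uint8,
#' int16, int32, float32, float64), little- or big-endian, with `scl_slope` /
#' `scl_inter` scaling applied when it is value-altering. Integer label
#' volumes with identity scaling are returned exactly as stored, which is what
#' atlas handling requires.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list of class `nifti_volume` with elements `data` (3D array),
#'   `affine` (4x4 voxel-to-world matrix), `pixdim` (length-3 voxel size) and
#'   `datatype` (NIfTI datatype code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) {
    stop_morphnet("NIfTI file not found: %s", path, class = "morphnet_io_error")
  }
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L) {
    stop_morphnet("truncated NIfTI header in %s", path,
                  class = "morphnet_io_error")
  }
  endian <- "little"
  sz <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) {
      stop_morphnet("not a NIfTI-1 file (sizeof_hdr != 348): %s", path,
                    class = "morphnet_io_error")
    }
  }
  rd_i16 <- function(off, n) readBin(raw_hdr[(off + 1):(off + 2L * n)],
                                     "integer", n = n, size = 2L,
                                     endian = endian)
  rd_f32 <- function(off, n) readBin(raw_hdr[(off + 1):(off + 4L * n)],
                                     "double", n = n, size = 4L,
                                     endian = endian)
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop_morphnet("unsupported NIfTI magic '%s' in %s", magic, path,
                  class = "morphnet_io_error")
  }
  dims <- rd_i16(40L, 8L)
  ndim <- dims[1]
  extent <- dims[2:8]
  if (ndim < 1L || ndim > 7L) {
    stop_morphnet("invalid dim[0] = %d in %s", ndim, path,
                  class = "morphnet_io_error")
  }
  extent <- extent[seq_len(ndim)]
  if (ndim > 3L && any(extent[4:ndim] > 1L)) {
    stop_morphnet(
      "volume in %s is %dD (dim = %s); only 3D volumes are supported",
      path, ndim, paste(extent, collapse = "x"),
      class = "morphnet_dim_error")
  }
  shape <- c(extent, rep(1L, 3L - length(extent)))[1:3]
  datatype <- rd_i16(70L, 1L)
  pixdim <- rd_f32(76L, 8L)[2:4]
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  sform_code <- rd_i16(254L, 1L)
  srow <- matrix(rd_f32(280L, 12L), nrow = 3L, byrow = TRUE)

  type <- switch(as.character(datatype),
    "2"  = list(what = "integer", size = 1L, signed = FALSE),
    "4"  = list(what = "integer", size = 2L, signed = TRUE),
    "8"  = list(what = "integer", size = 4L, signed = TRUE),
    "16" = list(what = "double",  size = 4L, signed = TRUE),
    "64" = list(what = "double",  size = 8L, signed = TRUE),
    stop_morphnet("unsupported NIfTI datatype code %d in %s", datatype, path,
                  class = "morphnet_io_error"))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  nvox <- prod(shape)
  vals <- readBin(con, type$what, n = nvox, size = type$size,
                  signed = type$signed, endian = endian)
  if (length(vals) < nvox) {
    stop_morphnet("truncated NIfTI data in %s", path,
                  class = "morphnet_io_error")
  }
  # scl_slope == 0 means "no scaling"; identity scaling is skipped so that
  # integer label volumes survive exactly
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1:3, ] <- srow
  } else {
    diag(affine)[1:3] <- ifelse(pixdim > 0, pixdim, 1)
  }
  structure(
    list(data = array(vals, dim = shape), affine = affine,
         pixdim = pixdim, datatype = datatype),
    class = "nifti_volume")
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D array as a single-file little-endian NIfTI-1 volume with an
#' sform affine. Integer datatypes are stored without scaling.
#'
#' @param data 3D numeric array.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param affine 4x4 voxel-to-world matrix (default: identity with unit
#'   voxel size).
#' @param datatype one of `"auto"`, `"float64"`, `"float32"`, `"int32"`,
#'   `"int16"`, `"uint8"`. `"auto"` picks `int32` for integer-valued data and
#'   `float64` otherwise.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = "auto") {
  if (length(dim(data)) != 3L) {
    stop_morphnet("write_nifti() requires a 3D array",
                  class = "morphnet_dim_error")
  }
  if (identical(datatype, "auto")) {
    datatype <- if (is.integer(data) ||
                    all(data == round(data))) "int32" else "float64"
  }
  code <- switch(datatype,
    uint8 = c(2L, 8L), int16 = c(4L, 16L), int32 = c(8L, 32L),
    float32 = c(16L, 32L), float64 = c(64L, 64L),
    stop_morphnet("unknown datatype '%s'", datatype,
                  class = "morphnet_io_error"))
  pixdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                          # sizeof_hdr
  w_raw(36L)                           # data_type..dim_info
  w_i16(c(3L, dim(data), 1L, 1L, 1L, 1L))  # dim[8]
  w_f32(c(0, 0, 0))                    # intent_p1..p3
  w_i16(0L)                            # intent_code
  w_i16(code[1])                       # datatype
  w_i16(code[2])                       # bitpix
  w_i16(0L)                            # slice_start
  w_f32(c(1, pixdim, 1, 1, 1, 1))      # pixdim[8]
  w_f32(352)                           # vox_offset
  w_f32(c(1, 0))                       # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                 # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                 # cal_max..toffset
  w_i32(c(0L, 0L))                     # glmax, glmin
  w_raw(104L)                          # descrip, aux_file
  w_i16(c(0L, 2L))                     # qform_code, sform_code (aligned)
  w_f32(rep(0, 6))                     # quaternion fields
  w_f32(t(affine[1:3, ]))              # srow_x, srow_y, srow_z
  w_raw(16L)                           # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  w_raw(4L)                            # extension flag
  vals <- as.vector(data)
  if (code[1] %in% c(2L, 4L, 8L)) {
    writeBin(as.integer(vals), con, size = code[2] / 8L, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = code[2] / 8L, endian = "little")
  }
  invisible(path)
}

#' Load a NIfTI volume as data + affine (alias used by the extraction stage)
#'
#' @param path path to a NIfTI-1 file.
#' @return see [read_nifti()].
#' @export
load_nifti <- read_nifti
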