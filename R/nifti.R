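# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package ships with the supported toolchain, and the subset of the
# format this package needs is small: single-file .nii / .nii.gz, 3D images,
# common datatypes, pixdim spacing and an sform affine. The first array axis
# is the slice (depth) axis throughout the package; volumes are stored with
# nifti dim = (D, H, W) accordingly and round-trip exactly.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D array as a NIfTI-1 file
#'
#' @param x numeric or integer 3D array, axes (depth, height, width)
#' @param path output path (.nii or .nii.gz)
#' @param spacing voxel spacing in mm per axis
#' @param affine optional 4x4 matrix written as the sform; defaults to
#'   diag(spacing)
#' @param datatype one of "float32", "float64", "int16", "int32", "uint8"
#' @return invisibly, the path
#' @export
write_nifti <- function(x, path, spacing = c(1, 1, 1), affine = NULL,
                        datatype = "float32") {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("write_nifti: expected a 3D array")
  code <- NIFTI_DT[[datatype]]
  if (is.null(code)) stop("write_nifti: unsupported datatype ", datatype)
  bitpix <- switch(datatype, uint8 = 8L, int16 = 16L, int32 = 32L,
                   float32 = 32L, float64 = 64L)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wi <- function(v, size = 4L) writeBin(as.integer(v), con, size = size,
                                        endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wc <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }
  wi(348L)                          # sizeof_hdr
  writeBin(raw(28), con)            # data_type[10], db_name[18]
  wi(0L); writeBin(raw(2), con)     # extents, session_error
  writeBin(charToRaw("r"), con)     # regular
  writeBin(as.raw(0L), con)         # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)  # dim[8]
  wf(c(0, 0, 0))                    # intent_p1..p3
  wi(0L, 2L)                        # intent_code
  wi(code, 2L)                      # datatype
  wi(bitpix, 2L)                    # bitpix
  wi(0L, 2L)                        # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))     # pixdim[8] (qfac = 1)
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2L)                        # slice_end
  writeBin(as.raw(c(0L, 0L)), con)  # slice_code, xyzt_units
  wf(c(0, 0, 0))                    # cal_max, cal_min, slice_duration
  wf(0)                             # toffset
  wi(c(0L, 0L))                     # glmax, glmin
  wc("spineseg", 80L)               # descrip
  wc("", 24L)                       # aux_file
  wi(0L, 2L); wi(1L, 2L)            # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))           # quatern b,c,d, qoffset x,y,z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])
  wc("", 16L)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  writeBin(raw(4), con)             # extension flag
  v <- as.vector(x)
  if (datatype %in% c("float32", "float64"))
    writeBin(as.numeric(v), con, size = bitpix / 8L, endian = "little")
  else
    writeBin(as.integer(v), con, size = bitpix / 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by this package (or any single-file 3D NIfTI)
#'
#' @param path .nii or .nii.gz file
#' @return list with `data` (3D array), `spacing`, `affine`
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("read_nifti: no such file: ", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352L)
  if (length(hdr) < 348L) stop("read_nifti: truncated header")
  ri <- function(off, n = 1L, size = 4L)
    readBin(hdr[(off + 1L):(off + n * size)], "integer", n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + n * 4L)], "numeric", n, size = 4L,
            endian = "little")
  if (ri(0L) != 348L) stop("read_nifti: not a little-endian NIfTI-1 file")
  dims <- ri(40L, 8L, 2L)
  ndim <- dims[1]
  if (ndim < 3L || (ndim > 3L && any(dims[5:(ndim + 1L)] > 1L)))
    stop("read_nifti: expected a 3D image, got dim = ", ndim)
  d <- dims[2:4]
  datatype <- ri(70L, 1L, 2L)
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L)
  scl_slope <- rf(112L); scl_inter <- rf(116L)
  sform_code <- ri(254L, 1L, 2L)
  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1, ] <- rf(280L, 4L)
    affine[2, ] <- rf(296L, 4L)
    affine[3, ] <- rf(312L, 4L)
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }
  skip <- vox_offset - 352L
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  data <- switch(as.character(datatype),
                 "2"  = readBin(con, "integer", n, size = 1L, signed = FALSE),
                 "4"  = readBin(con, "integer", n, size = 2L, endian = "little"),
                 "8"  = readBin(con, "integer", n, size = 4L, endian = "little"),
                 "16" = readBin(con, "numeric", n, size = 4L, endian = "little"),
                 "64" = readBin(con, "numeric", n, size = 8L, endian = "little"),
                 stop("read_nifti: unsupported datatype code ", datatype))
  if (length(data) < n) stop("read_nifti: truncated data section")
  data <- as.numeric(data)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  dim(data) <- d
  list(data = data, spacing = pixdim[2:4], affine = affine)
}
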