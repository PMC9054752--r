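# Minimal NIfTI-1 I/O (single-file .nii / .nii.gz, float32, little-endian).
# Only what the pipeline needs: 3-D volumes with an sform affine. No scaling
# (scl_slope/inter ignored on write, honoured on read), no extensions.

nifti_pad <- function(raw_vec, n) {
  out <- raw(n)
  if (length(raw_vec)) out[seq_along(raw_vec)] <- raw_vec
  out
}

#' Write a volume as NIfTI-1
#'
#' Writes \code{vol$data} as a single-file NIfTI-1 image (float32,
#' little-endian, sform affine). The mask is not stored; repositories write
#' it as a companion image.
#'
#' @param vol a \code{nnod_volume}.
#' @param path output path; a \code{.gz} suffix triggers gzip compression.
#' @return \code{path}, invisibly.
#' @export
write_nifti <- function(vol, path) {
  shape <- dim(vol$data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  ws <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(x, n) writeBin(nifti_pad(charToRaw(x), n), con)

  voxdim <- sqrt(colSums(vol$affine[1:3, 1:3]^2))

  wi(348)                               # sizeof_hdr
  wc("", 10); wc("", 18)                # data_type, db_name (unused)
  wi(0); ws(0); wc("r", 1); wc("", 1)   # extents, session_error, regular, dim_info
  ws(c(3L, shape, 1L, 1L, 1L, 1L))      # dim[8]
  wf(c(0, 0, 0)); ws(0)                 # intent_p1..3, intent_code
  ws(16); ws(32)                        # datatype float32, bitpix
  ws(0)                                 # slice_start
  wf(c(1, voxdim, 1, 1, 1, 1))          # pixdim[8] (qfac 1)
  wf(352); wf(0); wf(0)                 # vox_offset, scl_slope, scl_inter
  ws(0); wc("", 1); wc("", 1)           # slice_end, slice_code, xyzt_units
  wf(0); wf(0); wf(0); wf(0)            # cal_max, cal_min, slice_duration, toffset
  wi(0); wi(0)                          # glmax, glmin
  wc("nnod", 80); wc("", 24)            # descrip, aux_file
  ws(0); ws(1)                          # qform_code 0, sform_code 1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))        # quaternion, qoffset
  wf(vol$affine[1, ]); wf(vol$affine[2, ]); wf(vol$affine[3, ])
  wc("", 16)                            # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)                 # extension flag: none
  wf(as.numeric(vol$data))
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the subset this package writes plus common variants (any numeric
#' datatype among uint8/int16/int32/float32/float64, gzipped or plain,
#' little- or big-endian). The returned mask is all-\code{TRUE}; repository
#' readers attach the shared brain mask separately.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return A \code{nnod_volume}.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  rd_i <- function(off, n = 1L, size = 4L, endian = "little") {
    readBin(hdr[(off + 1):(off + n * size)], "integer", n = n, size = size,
            endian = endian)
  }
  endian <- "little"
  if (rd_i(0) != 348L) {
    if (rd_i(0, endian = "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  rd_f <- function(off, n = 1L) {
    readBin(hdr[(off + 1):(off + n * 4L)], "numeric", n = n, size = 4L,
            endian = endian)
  }
  dims <- rd_i(40, n = 8L, size = 2L, endian = endian)
  ndim <- dims[1]
  if (ndim < 3L) stop("expected a 3-D image: ", path, call. = FALSE)
  shape <- dims[2:4]
  if (ndim > 3L && any(dims[5:(1 + ndim)] > 1L)) {
    stop("4-D+ images are not supported: ", path, call. = FALSE)
  }
  datatype <- rd_i(70, size = 2L, endian = endian)
  vox_offset <- rd_f(108)
  scl_slope <- rd_f(112); scl_inter <- rd_f(116)
  sform_code <- rd_i(254, size = 2L, endian = endian)
  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1, ] <- rd_f(280, 4L); affine[2, ] <- rd_f(296, 4L)
    affine[3, ] <- rd_f(312, 4L)
  } else {
    pixdim <- rd_f(76, 8L)
    affine <- diag(c(pixdim[2:4], 1))
  }
  # skip to data
  readBin(con, "raw", n = max(0L, as.integer(round(vox_offset)) - 348L))
  nvox <- prod(shape)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", nvox, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", nvox, size = 2L, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", nvox, size = 4L, endian = endian)),
    "16" = readBin(con, "numeric", nvox, size = 4L, endian = endian),
    "64" = readBin(con, "numeric", nvox, size = 8L, endian = endian),
    stop("unsupported NIfTI datatype ", datatype, call. = FALSE))
  if (length(vals) != nvox) stop("truncated NIfTI data: ", path, call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  volume(array(vals, dim = shape), affine,
         array(TRUE, dim = shape))
}
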