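# Minimal NIfTI-1 input/output.
#
# The analysis environment provides no R NIfTI reader, so the package
# carries a small single-file codec for the subset of NIfTI-1 it needs:
# uncompressed .nii, 3-D or 4-D, little- or big-endian, datatypes uint8 /
# int16 / int32 / float32 / float64, with scl_slope/scl_inter honored on
# read. Written files use float64 (float32 on request), little-endian,
# magic "n+1", vox_offset 352. Spatial units are left unspecified;
# pixdim[5] carries the repetition time in seconds for 4-D series.

NIFTI_DT <- list(`2`  = list(what = "integer", size = 1, signed = FALSE),
                 `4`  = list(what = "integer", size = 2, signed = TRUE),
                 `8`  = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "double",  size = 4, signed = TRUE),
                 `64` = list(what = "double",  size = 8, signed = TRUE))

#' Read a NIfTI-1 volume
#'
#' Supports uncompressed single-file `.nii` (3-D or 4-D) in the common
#' scalar datatypes; see the codec notes in the source for scope.
#'
#' @param path file path.
#' @return List with `data` (3-D or 4-D array, scaling applied), `tr`
#'   (seconds, from `pixdim[5]`, `NA` for 3-D files), `pixdim`, `datatype`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    seek(con, 0)
    endian <- "big"
    if (readBin(con, "integer", 1, size = 4, endian = "big") != 348L)
      stop_gbl("not a NIfTI-1 file: ", path)
  }
  invisible(readBin(con, "raw", 36))                   # unused header fields
  dim0 <- readBin(con, "integer", 8, size = 2, endian = endian)
  invisible(readBin(con, "raw", 14))                   # intent params etc.
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  invisible(readBin(con, "integer", 1, size = 2, endian = endian)) # bitpix
  invisible(readBin(con, "integer", 1, size = 2, endian = endian)) # slice_start
  pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, size = 4, endian = endian)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop_gbl("unsupported NIfTI datatype code ", datatype)
  nd <- dim0[1]
  if (!nd %in% c(3L, 4L)) stop_gbl("only 3-D or 4-D volumes are supported")
  dims <- dim0[2:(1 + nd)]
  seek(con, where = vox_offset, origin = "start")
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop_gbl("truncated NIfTI data in ", path)
  if (scl_slope != 0) vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dims),
       tr = if (nd == 4L) pixdim[5] else NA_real_,
       pixdim = pixdim, datatype = datatype)
}

#' Write a NIfTI-1 volume
#'
#' @param data 3-D or 4-D numeric (or logical) array.
#' @param path output path (uncompressed `.nii`).
#' @param tr repetition time in seconds, stored in `pixdim[5]` for 4-D
#'   data.
#' @param datatype `"float64"` (default) or `"float32"`; logical input is
#'   written as uint8.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(data, path, tr = 1, datatype = c("float64", "float32")) {
  datatype <- match.arg(datatype)
  is_logical <- is.logical(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop_gbl("data must be a 3-D or 4-D array")
  dims <- dim(data)
  dim0 <- integer(8); dim0[1] <- nd; dim0[2:(1 + nd)] <- dims
  dim0[(2 + nd):8] <- 1L
  code <- if (is_logical) 2L else if (datatype == "float32") 16L else 64L
  bitpix <- c(`2` = 8L, `16` = 32L, `64` = 64L)[[as.character(code)]]
  pixdim <- rep(1, 8); pixdim[1] <- 1
  if (nd == 4L) pixdim[5] <- tr
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")
  writeBin(raw(36), con)
  writeBin(dim0, con, size = 2, endian = "little")
  writeBin(raw(14), con)
  writeBin(code, con, size = 2, endian = "little")
  writeBin(bitpix, con, size = 2, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")               # slice_start
  writeBin(pixdim, con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")              # vox_offset
  writeBin(1, con, size = 4, endian = "little")                # scl_slope
  writeBin(0, con, size = 4, endian = "little")                # scl_inter
  # remaining header bytes up to xyzt_units..magic; fill with zeros except
  # xyzt_units (sec for time) and magic
  writeBin(raw(3), con)                                        # slice_end etc.
  writeBin(as.integer(8L), con, size = 1, endian = "little")   # xyzt_units: sec
  writeBin(raw(24), con)                                       # cal/slice/toffset etc.
  writeBin(raw(2 * 80 - 80), con)                              # descrip (80)
  writeBin(raw(24), con)                                       # aux_file (24)
  writeBin(c(0L, 0L), con, size = 2, endian = "little")        # qform/sform codes
  writeBin(rep(0, 18), con, size = 4, endian = "little")       # quatern + srows
  writeBin(raw(16), con)                                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)                # magic
  writeBin(raw(4), con)                                        # extension flag
  vals <- as.numeric(data)
  if (is_logical) writeBin(as.integer(vals), con, size = 1)
  else writeBin(vals, con, size = if (code == 16L) 4 else 8, endian = "little")
  invisible(path)
}

#' Read a 4-D BOLD file straight into a [volume4d()]
#'
#' @param bold_path 4-D `.nii` path.
#' @param mask_path optional 3-D `.nii` path (nonzero = in mask).
#' @param tr repetition time override in seconds; default uses the file's
#'   `pixdim[5]`.
#' @return A `volume4d`.
#' @export
read_volume4d <- function(bold_path, mask_path = NULL, tr = NULL) {
  nii <- read_nifti(bold_path)
  mask <- if (!is.null(mask_path)) read_nifti(mask_path)$data != 0
  volume4d(nii$data, tr %||% nii$tr, mask)
}
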