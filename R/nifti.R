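# Minimal NIfTI-1 reader/writer.
#
# Only the subset of the format needed for volumes, masks and label maps is
# supported: single-file .nii / .nii.gz, 3D images, datatypes uint8 (2),
# int16 (4), int32 (8), float32 (16), float64 (64) and uint16 (512), sform
# affine. Header extensions are ignored on read and never written.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352

nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into an array plus
#' its 4x4 voxel-to-world affine. Intended for skull-stripped volumes, brain
#' masks and integer label maps; only scalar 3D images are supported.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array), `affine` (4x4 matrix)
#'   and `pixdim` (voxel sizes).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con), add = TRUE)

  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (sizeof_hdr != NIFTI_HDR_SIZE) {
    if (sizeof_hdr == 1543569408L) endian <- "big"  # 348 byte-swapped
    else stop("not a NIfTI-1 file (sizeof_hdr = ", sizeof_hdr, "): ", path)
  }
  readBin(con, "raw", 36L)                                   # unused fields
  dim    <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                                   # intent fields
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope  <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter  <- readBin(con, "double", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 132L)                                  # display fields
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # qform_code
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "double", 6L, size = 4L, endian = endian)     # quaternion
  srow <- matrix(readBin(con, "double", 12L, size = 4L, endian = endian),
                 nrow = 3L, byrow = TRUE)
  readBin(con, "raw", 16L)                                   # intent_name
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1"))
    stop("unsupported NIfTI magic (two-file .hdr/.img not supported): ", path)

  ndim <- dim[1L]
  if (ndim > 3L && all(dim[seq(5L, 1L + ndim)] <= 1L)) ndim <- 3L
  if (ndim != 3L)
    stop("expected a 3D image, got ", dim[1L], "D: ", path)
  shape <- dim[2:4]
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)

  skip <- round(vox_offset) - NIFTI_HDR_SIZE
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  affine <- if (sform_code > 0L) rbind(srow, c(0, 0, 0, 1))
            else diag(c(pixdim[2:4], 1))
  list(data = array(vals, dim = shape), affine = affine, pixdim = pixdim[2:4])
}

#' Write a NIfTI-1 image
#'
#' Writes a 3D array as a single-file NIfTI-1 image. Label maps and masks
#' should be written with `datatype = "int16"` (lossless for integer labels);
#' intensity volumes default to `float32`.
#'
#' @param data 3D numeric array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param affine 4x4 voxel-to-world matrix, stored as the sform.
#' @param datatype One of `"float32"`, `"float64"`, `"int16"`, `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4),
                        datatype = c("float32", "float64", "int16", "uint8")) {
  datatype <- match.arg(datatype)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  code <- switch(datatype, uint8 = 2L, int16 = 4L, float32 = 16L, float64 = 64L)
  size <- switch(datatype, uint8 = 1L, int16 = 2L, float32 = 4L, float64 = 8L)
  shape <- dim(data)
  pixdim <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- tryCatch(nifti_connection(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con), add = TRUE)
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wflt <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")

  wint(NIFTI_HDR_SIZE, 4L)
  writeBin(raw(36L), con)
  wint(c(3L, shape, 1L, 1L, 1L, 1L), 2L)                     # dim[8]
  wflt(c(0, 0, 0)); wint(0L, 2L)                             # intent
  wint(code, 2L); wint(8L * size, 2L); wint(0L, 2L)          # datatype/bitpix
  wflt(c(1, pixdim, 1, 1, 1, 1))                             # pixdim[8]
  wflt(NIFTI_VOX_OFFSET); wflt(1); wflt(0)                   # offset, scl
  wint(0L, 2L); writeBin(raw(2L), con)                       # slice_end/code
  wflt(c(0, 0, 0, 0)); wint(c(0L, 0L), 4L)                   # cal/glmax etc.
  writeBin(raw(104L), con)                                   # descrip/aux
  wint(0L, 2L); wint(1L, 2L)                                 # qform, sform
  wflt(rep(0, 6))                                            # quaternion
  wflt(t(affine[1:3, ]))                                     # srow_x/y/z
  writeBin(raw(16L), con)                                    # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  writeBin(raw(4L), con)                                     # pad to 352

  vals <- as.vector(data)
  if (datatype %in% c("int16", "uint8")) {
    if (max(abs(vals - round(vals))) > 1e-6)
      warning("non-integer values rounded for integer datatype")
    writeBin(as.integer(round(vals)), con, size = size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = size, endian = "little")
  }
  invisible(path)
}
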