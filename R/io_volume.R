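# Volume and LabelMap containers.
#
# A Volume holds a 3D intensity array, a 4x4 affine and a logical brain mask
# of the same shape. A LabelMap holds integer tissue labels on the same grid:
# 0 = background, 1 = CSF, 2 = GM, 3 = WM (repository convention; T1 contrast
# orders mean intensity CSF < GM < WM). Linear voxel indices are 1-based in
# R's native column-major order, i.e. x-fastest.

#' Tissue label coding
#'
#' Integer coding used for label maps throughout the package.
#' @return Named integer vector `c(CSF = 1, GM = 2, WM = 3)`.
#' @export
tissue_labels <- function() c(CSF = 1L, GM = 2L, WM = 3L)

#' Construct a Volume
#'
#' @param data 3D numeric array of intensities.
#' @param affine 4x4 voxel-to-world transform (carried, never used in
#'   computation).
#' @param mask Logical 3D array marking brain voxels, same shape as `data`.
#'   Defaults to strict positivity `data > 0` (skull-stripped volumes have
#'   zero background).
#' @return An object of class `somseg_volume`.
#' @export
as_volume <- function(data, affine = diag(4), mask = NULL) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ",
         length(dim(data)), " dimensions")
  if (is.null(mask)) mask <- data > 0
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), dim(data)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match data shape ", paste(dim(data), collapse = "x"))
  structure(list(data = data, affine = affine, mask = mask),
            class = "somseg_volume")
}

is_volume <- function(x) inherits(x, "somseg_volume")

#' @export
print.somseg_volume <- function(x, ...) {
  cat("<somseg_volume> ", paste(dim(x$data), collapse = " x "),
      " | ", sum(x$mask), " brain voxels",
      if (!is.null(attr(x$data, "levels")))
        paste0(" | quantized to ", attr(x$data, "levels"), " levels"),
      "\n", sep = "")
  invisible(x)
}

#' Construct a LabelMap
#'
#' @param labels 3D integer array with values in {0, 1, 2, 3}
#'   (background/CSF/GM/WM).
#' @param affine 4x4 voxel-to-world transform.
#' @return An object of class `somseg_labelmap`.
#' @export
label_map <- function(labels, affine = diag(4)) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad))
    stop("label values outside {0,1,2,3}: ", paste(bad, collapse = ", "))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, affine = affine), class = "somseg_labelmap")
}

is_labelmap <- function(x) inherits(x, "somseg_labelmap")

#' @export
print.somseg_labelmap <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = c("bg", "CSF", "GM", "WM")))
  cat("<somseg_labelmap> ", paste(dim(x$labels), collapse = " x "), " | ",
      paste(names(tab), tab, sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Read a volumetric image
#'
#' Reads a 3D NIfTI-1 image as a [as_volume()] Volume. When no mask file is
#' given, the brain mask defaults to strictly positive intensities.
#'
#' @param path Path to the intensity image (`.nii`/`.nii.gz`).
#' @param mask_path Optional path to a mask image; nonzero voxels are brain.
#' @return A `somseg_volume`.
#' @export
read_volume <- function(path, mask_path = NULL) {
  img <- read_nifti(path)
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- read_nifti(mask_path)
    if (!identical(dim(m$data), dim(img$data)))
      stop("mask shape ", paste(dim(m$data), collapse = "x"),
           " does not match volume shape ",
           paste(dim(img$data), collapse = "x"))
    mask <- m$data != 0
  }
  as_volume(img$data, img$affine, mask)
}

#' Write a Volume to NIfTI
#'
#' @param vol A `somseg_volume`.
#' @param path Output path.
#' @param datatype Storage type, default `"float32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float32") {
  stopifnot(is_volume(vol))
  write_nifti(vol$data, path, vol$affine, datatype = datatype)
}

#' Read a label map
#'
#' @param path Path to an integer-valued NIfTI image with labels in {0,1,2,3}.
#' @return A `somseg_labelmap`.
#' @export
read_labelmap <- function(path) {
  img <- read_nifti(path)
  label_map(round(img$data), img$affine)
}

#' Write a label map to NIfTI
#'
#' Labels are validated against the {0,1,2,3} coding before anything is
#' written and stored as int16, so the round trip is exact.
#'
#' @param seg A `somseg_labelmap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(seg, path) {
  stopifnot(is_labelmap(seg))
  write_nifti(seg$labels, path, seg$affine, datatype = "int16")
}

#' Convert between linear voxel indices and (x, y, z) coordinates
#'
#' Linear indices are 1-based, x-fastest (R's native array order), so the
#' mapping is a bijection over the grid.
#'
#' @param idx Integer vector of linear indices.
#' @param dim Length-3 grid dimensions.
#' @return `voxel_coords`: an n x 3 integer matrix of 1-based coordinates;
#'   `voxel_index`: an integer vector of linear indices.
#' @export
voxel_coords <- function(idx, dim) {
  stopifnot(length(dim) == 3L)
  arrayInd(idx, .dim = dim)
}

#' @param coords n x 3 matrix of 1-based (x, y, z) coordinates.
#' @rdname voxel_coords
#' @export
voxel_index <- function(coords, dim) {
  stopifnot(length(dim) == 3L)
  coords <- rbind(coords)
  as.integer(coords[, 1L] + dim[1L] * (coords[, 2L] - 1L) +
             dim[1L] * dim[2L] * (coords[, 3L] - 1L))
}
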