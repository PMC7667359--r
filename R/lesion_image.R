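#' Construct a 3D binary lesion image
#'
#' The unit of analysis: a binary lesion mask on an anisotropic voxel grid.
#' Arrays are indexed `[row, col, slice]`; `spacing` gives the physical edge
#' lengths `c(row_mm, col_mm, slice_mm)` of one voxel.
#'
#' @param mask 3D array, logical or containing only 0/1.
#' @param spacing numeric length-3, voxel spacing in mm (row, col, slice),
#'   all strictly positive.
#' @param patient_id character label carried through to result rows.
#' @return An object of class `lesion_image` with elements `mask` (logical
#'   array), `spacing` and `patient_id`.
#' @export
lesion_image <- function(mask, spacing, patient_id = "lesion") {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  if (is.logical(mask)) {
    m <- mask
  } else {
    u <- unique(as.vector(mask))
    if (!all(u %in% c(0, 1))) stop("`mask` must contain only 0 and 1")
    m <- array(mask != 0, dim = dim(mask))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive lengths in mm")
  structure(
    list(mask = m, spacing = spacing, patient_id = as.character(patient_id)),
    class = "lesion_image"
  )
}

#' @export
print.lesion_image <- function(x, ...) {
  cat(sprintf(
    "<lesion_image> %s: %s voxels on %s grid, spacing %s mm, %.2f ml\n",
    x$patient_id, sum(x$mask), paste(dim(x$mask), collapse = "x"),
    paste(signif(x$spacing, 3), collapse = "x"), volumetric_volume(x)
  ))
  invisible(x)
}

#' Read a lesion mask from a NIfTI file
#'
#' Any nonzero voxel is treated as lesion. The slice axis is taken as the
#' lowest-resolution axis (largest spacing) by default and moved to the third
#' array dimension; pass `slice_axis` to override.
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param slice_axis integer in 1..3, or `NULL` to autodetect.
#' @param patient_id label; defaults to the file name without extension.
#' @return A [lesion_image].
#' @export
read_lesion_image <- function(path, slice_axis = NULL, patient_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- array(arr, dim = dim(arr)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  if (is.null(slice_axis)) slice_axis <- which.max(sp)
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("`slice_axis` must be 1, 2 or 3")
  perm <- c(setdiff(1:3, slice_axis), slice_axis)
  arr <- aperm(arr, perm)
  sp <- sp[perm]
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lesion_image(arr != 0, sp, patient_id)
}

#' Write a lesion mask to a NIfTI file
#'
#' Stores the mask as 0/1 with the image spacing in the header `pixdim`.
#'
#' @param image a [lesion_image].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_lesion_image <- function(image, path) {
  stopifnot(inherits(image, "lesion_image"))
  arr <- array(as.integer(image$mask), dim = dim(image$mask))
  nim <- RNifti::asNifti(arr)
  RNifti::pixdim(nim) <- image$spacing
  ok <- try(RNifti::writeNifti(nim, path, datatype = "uint8"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write NIfTI mask to: ", path)
  invisible(path)
}

#' Split a lesion image into per-slice masks
#'
#' @param image a [lesion_image].
#' @return A list with one `slice_mask` per slice (1-based `slice_index`),
#'   each carrying the in-plane spacing and an `empty` flag.
#' @export
slice_masks <- function(image) {
  stopifnot(inherits(image, "lesion_image"))
  lapply(seq_len(dim(image$mask)[3]), function(k)
    slice_mask(image$mask[, , k], image$spacing[1:2], k))
}

#' Construct a single 2D slice mask
#'
#' @param mask 2D logical (or 0/1) matrix `[row, col]`.
#' @param spacing in-plane spacing `c(row_mm, col_mm)`.
#' @param slice_index 1-based index of the slice within its volume.
#' @return An object of class `slice_mask`.
#' @export
slice_mask <- function(mask, spacing, slice_index = 1L) {
  if (length(dim(mask)) != 2L) stop("`mask` must be a 2D matrix")
  m <- if (is.logical(mask)) mask else mask != 0
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("`spacing` must be two strictly positive lengths in mm")
  structure(
    list(mask = m, spacing = spacing, slice_index = as.integer(slice_index),
         empty = !any(m)),
    class = "slice_mask"
  )
}

#' Count slices showing lesion
#'
#' Number of slices containing at least one lesion voxel; inter-slice gaps
#' are not interpolated.
#'
#' @param image a [lesion_image].
#' @return Integer count (0 for an empty mask).
#' @export
count_lesion_slices <- function(image) {
  stopifnot(inherits(image, "lesion_image"))
  sum(apply(image$mask, 3, any))
}

#' Gold-standard voxel volumetry
#'
#' The volumetric reference against which the diameter-based estimators are
#' judged: lesion voxel count times voxel volume.
#'
#' @param image a [lesion_image].
#' @return Volume in ml (1 ml = 1000 mm^3); 0 for an empty mask.
#' @export
volumetric_volume <- function(image) {
  stopifnot(inherits(image, "lesion_image"))
  sum(image$mask) * prod(image$spacing) / 1000
}
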