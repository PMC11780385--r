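#' Voxel grid geometry
#'
#' An `image_grid` describes the 3D voxel lattice shared by a CT volume and
#' its lesion segmentation: the number of voxels per axis, the physical
#' voxel spacing in millimetres, and which array axis runs
#' inferior-superior. Slices perpendicular to that axis are the transaxial
#' (axial) planes on which RECIST diameters are measured. Voxel indices are
#' 1-based; the physical position of a voxel is its centre, at
#' `(index - 1) * spacing` along each axis.
#'
#' @param shape Integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing Numeric vector of length 3, mm per voxel along each axis
#'   (all > 0). CT slice thickness in the clinic typically spans 0.5-5 mm,
#'   with sub-millimetre in-plane pixel spacing.
#' @param axial_axis Which axis (1, 2 or 3) is inferior-superior. Default 3,
#'   the NIfTI convention for axially acquired scans.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(64, 64, 32), spacing = c(0.78, 0.78, 5))
#' voxel_volume(g)  # 3.042 mm^3
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), axial_axis = 3L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three positive integers", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)", call. = FALSE)
  axial_axis <- as.integer(axial_axis)
  if (length(axial_axis) != 1L || is.na(axial_axis) || !axial_axis %in% 1:3)
    stop("`axial_axis` must be 1, 2 or 3", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, axial_axis = axial_axis),
            class = "image_grid")
}

#' @rdname image_grid
#' @param grid An `image_grid`.
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  prod(grid$spacing)
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %s voxels, spacing %s mm, axial axis %d\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = " x "), x$axial_axis))
  invisible(x)
}

grids_match <- function(a, b, tol = 1e-3) {
  identical(a$shape, b$shape) && all(abs(a$spacing - b$spacing) <= tol)
}

#' CT volumes and lesion masks
#'
#' A `ct_volume` couples a grid with a scalar attenuation field in
#' Hounsfield units (HU); a `lesion_mask` couples a grid with a binary
#' volume of interest (VOI) in which 1 marks tumour. Any nonzero value in
#' `voxels` is binarized to 1, so masks saved by other tools with label
#' values such as 255 are accepted.
#'
#' @param grid An [image_grid()].
#' @param intensities Numeric 3D array in HU, dimensions equal to
#'   `grid$shape`.
#' @return A `ct_volume` or `lesion_mask` object.
#' @export
ct_volume <- function(grid, intensities) {
  stopifnot(inherits(grid, "image_grid"))
  intensities <- as.array(intensities)
  if (!identical(as.integer(dim(intensities)), grid$shape))
    stop(sprintf("intensity array is %s but grid is %s",
                 paste(dim(intensities), collapse = "x"),
                 paste(grid$shape, collapse = "x")), call. = FALSE)
  structure(list(grid = grid, intensities = intensities), class = "ct_volume")
}

#' @rdname ct_volume
#' @param voxels 3D array, nonzero = tumour; stored as integer 0/1.
#' @export
lesion_mask <- function(grid, voxels) {
  stopifnot(inherits(grid, "image_grid"))
  voxels <- as.array(voxels)
  if (!identical(as.integer(dim(voxels)), grid$shape))
    stop(sprintf("mask array is %s but grid is %s",
                 paste(dim(voxels), collapse = "x"),
                 paste(grid$shape, collapse = "x")), call. = FALSE)
  if (any(is.na(voxels)))
    stop("mask contains missing values", call. = FALSE)
  storage.mode(voxels) <- "integer"
  voxels <- (voxels != 0L) * 1L
  structure(list(grid = grid, voxels = voxels), class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d tumour voxels on %s grid\n",
              sum(x$voxels), paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

grid_from_nifti <- function(img, path) {
  dm <- dim(img)
  if (length(dm) != 3L)
    stop(sprintf("'%s' is %d-dimensional; a 3D image is required",
                 path, length(dm)), call. = FALSE)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("'%s' has non-positive voxel spacing (%s)",
                 path, paste(format(spacing), collapse = ", ")),
         call. = FALSE)
  image_grid(dm, spacing, axial_axis = infer_axial_axis(img, path))
}

# The NIfTI xform encodes how array axes map to anatomical directions;
# RNifti::orientation() reduces it to one letter per axis, and the axis
# closest to inferior-superior carries "I" or "S". Without a stored xform
# there is nothing to infer from, so fall back to axis 3 (the usual axial
# acquisition layout) with a warning.
infer_axial_axis <- function(img, path = "<image>") {
  xf <- RNifti::xform(img)
  if (is.null(attr(xf, "code")) || attr(xf, "code") == 0L) {
    warning(sprintf("'%s' carries no orientation metadata; assuming axis 3 is inferior-superior",
                    path), call. = FALSE)
    return(3L)
  }
  letters3 <- strsplit(RNifti::orientation(img), "")[[1]]
  ax <- which(letters3 %in% c("I", "S"))
  if (length(ax) != 1L) {
    warning(sprintf("'%s' has ambiguous orientation '%s'; assuming axis 3 is inferior-superior",
                    paste(letters3, collapse = "")), call. = FALSE)
    return(3L)
  }
  as.integer(ax)
}

#' Read a CT volume from NIfTI
#'
#' Reads a 3D NIfTI image as a [ct_volume()], taking voxel spacing from the
#' header and inferring the inferior-superior axis from the header
#' orientation (falling back to axis 3, with a warning, when the file
#' carries no orientation metadata).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `ct_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img, path)
  ct_volume(grid, array(as.numeric(img), dim = grid$shape))
}

#' Read a lesion mask from NIfTI
#'
#' Reads a binary VOI and checks it lives on the same grid as a reference
#' image (shape identical, spacing equal within `tol` mm). Nonzero voxel
#' values are binarized to 1.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param reference An [image_grid()] the mask must match, typically from
#'   the CT volume it was drawn on. `NULL` skips the check.
#' @param tol Spacing tolerance in mm (default `1e-3`).
#' @return A `lesion_mask`.
#' @export
read_mask <- function(path, reference = NULL, tol = 1e-3) {
  if (!file.exists(path))
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img, path)
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "image_grid"))
    if (!grids_match(grid, reference, tol))
      stop(sprintf(
        "mask grid (%s voxels at %s mm) does not match reference (%s voxels at %s mm)",
        paste(grid$shape, collapse = "x"),
        paste(format(grid$spacing), collapse = ", "),
        paste(reference$shape, collapse = "x"),
        paste(format(reference$spacing), collapse = ", ")), call. = FALSE)
    grid <- reference
  }
  lesion_mask(grid, array(as.numeric(img), dim = grid$shape))
}

#' Write a mask or volume to NIfTI
#'
#' Round-tripping through [read_mask()] / [read_volume()] reproduces voxels
#' exactly and spacing to within 1e-6 mm. The axial axis is encoded through
#' an RAS-permuted affine so that it is recovered on read.
#'
#' @param mask A `lesion_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  write_nifti_on_grid(mask$voxels, mask$grid, path)
}

#' @rdname write_mask
#' @param ct A `ct_volume`.
#' @export
write_volume <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  write_nifti_on_grid(ct$intensities, ct$grid, path)
}

write_nifti_on_grid <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  # scaled permutation affine sending the axial array axis to anatomical S
  perm <- switch(grid$axial_axis,
                 `1` = c(3L, 1L, 2L), `2` = c(1L, 3L, 2L), `3` = c(1L, 2L, 3L))
  aff <- matrix(0, 4, 4)
  aff[4, 4] <- 1
  for (ax in 1:3) aff[perm[ax], ax] <- grid$spacing[ax]
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
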