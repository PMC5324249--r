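#' Construct a voxel image
#'
#' A scalar grid (grey values) with voxel spacing and world origin; the
#' container consumed by threshold segmentation.  Coordinates follow the
#' usual convention: voxel `[i, j, k]` is centred at
#' `origin + (i-1, j-1, k-1) * spacing` (mm).
#'
#' @param values 3D numeric array of grey values.
#' @param spacing length-3 positive numeric, mm per voxel.
#' @param origin length-3 numeric, world position of the first voxel centre.
#' @return a `voxel_image`.
#' @export
voxel_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (any(dim(values) < 1L)) stop("empty grid")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("voxel_image: %s voxels, spacing %s mm\n",
              paste(dim(x$values), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' Read a voxel image from a NIfTI file
#' @param path a .nii or .nii.gz file.
#' @return a `voxel_image` (spacing from the NIfTI pixdim; origin at 0).
#' @export
read_nifti_image <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_image(array(as.numeric(img), dim = dim(img)),
              spacing = RNifti::pixdim(img)[1:3])
}

#' Write a voxel image to a NIfTI file
#' @param image a `voxel_image`.
#' @param path output .nii or .nii.gz path.
#' @return `path`, invisibly.
#' @export
write_nifti_image <- function(image, path) {
  nii <- RNifti::asNifti(image$values)
  RNifti::pixdim(nii) <- image$spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Segmentation parameters for window thresholding
#' @param lower_threshold,upper_threshold grey-value window (inclusive).
#' @param min_component_voxels connected components (26-connectivity)
#'   smaller than this are discarded; 0 keeps everything.
#' @return a `segmentation_params` object.
#' @export
segmentation_params <- function(lower_threshold = 310,
                                upper_threshold = 640,
                                min_component_voxels = 0L) {
  if (lower_threshold > upper_threshold)
    stop("lower_threshold must be <= upper_threshold")
  structure(list(lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold,
                 min_component_voxels = as.integer(min_component_voxels)),
            class = "segmentation_params")
}

#' Threshold segmentation of a voxel image
#'
#' A voxel is foreground when its grey value lies inside the closed window
#' `[lower, upper]`; connected components (26-connectivity) smaller than
#' `min_component_voxels` are then removed.
#'
#' @param image a `voxel_image`.
#' @param params a `segmentation_params` (default window 310-640 GV, the
#'   documented default for bright-blood lumen; scanner-specific).
#' @return a `voxel_mask`: logical array plus the grid's spacing/origin.
#' @export
threshold_segment <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "voxel_image"))
  mask <- image$values >= params$lower_threshold &
    image$values <= params$upper_threshold
  if (!any(mask))
    stop("threshold window [", params$lower_threshold, ", ",
         params$upper_threshold,
         "] selects no voxels; adjust the thresholds")
  if (params$min_component_voxels > 0L) {
    labels <- .cpp_label_components(as.vector(mask), dim(mask))
    sizes <- tabulate(labels)
    keep <- which(sizes >= params$min_component_voxels)
    mask <- array(labels %in% keep & labels > 0L, dim = dim(mask))
    if (!any(mask))
      stop("all components smaller than min_component_voxels; ",
           "adjust the thresholds or the size filter")
  }
  structure(list(mask = mask, spacing = image$spacing,
                 origin = image$origin),
            class = "voxel_mask")
}

#' Extract an isosurface mesh from a binary mask
#'
#' The binary mask is optionally anti-aliased with a small Gaussian
#' (default sigma of 1 voxel) and the 0.5 level set extracted by
#' tetrahedral marching with linear interpolation, scaled by the voxel
#' spacing and shifted by the origin.  The surface is closed whenever the
#' foreground stays off the grid border; otherwise it is open at the
#' border and a warning is raised.
#'
#' @param mask a `voxel_mask`, or a logical/numeric 3D array.
#' @param spacing,origin grid geometry, taken from the `voxel_mask` when
#'   one is given.
#' @param smooth_sigma Gaussian pre-smoothing in voxels (0 disables);
#'   anti-aliases the staircase of the binary field so areas of smooth
#'   solids converge with grid refinement.
#' @return a validated `surface_mesh` in mm coordinates.
#' @export
extract_surface <- function(mask, spacing = NULL, origin = NULL,
                            smooth_sigma = 1) {
  if (inherits(mask, "voxel_mask")) {
    spacing <- spacing %||% mask$spacing
    origin <- origin %||% mask$origin
    mask <- mask$mask
  }
  spacing <- as.numeric(spacing %||% c(1, 1, 1))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  origin <- as.numeric(origin %||% c(0, 0, 0))
  d <- dim(mask)
  field <- as.numeric(mask)
  if (!any(field > 0)) stop("mask has no foreground voxels")
  touches <- any(mask[c(1, d[1]), , ] != 0) || any(mask[, c(1, d[2]), ] != 0) ||
    any(mask[, , c(1, d[3])] != 0)
  if (touches)
    warning("foreground touches the grid boundary; surface will be open")
  if (smooth_sigma > 0)
    field <- .cpp_gaussian_smooth3(field, d, smooth_sigma)
  iso <- .cpp_isosurface(field, d, 0.5, spacing, origin)
  if (nrow(iso$faces) == 0L)
    stop("no isosurface found at level 0.5")
  surface_mesh(iso$vertices, iso$faces)
}
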