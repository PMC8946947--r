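#' 3D image volume
#'
#' A `Volume` is the basic image container of the package: a 3D scalar array
#' together with its voxel spacing (mm), a voxel-to-world affine (NIfTI
#' convention, 0-based voxel indices), and a modality tag.
#'
#' @param data 3D numeric array of voxel intensities (all finite).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal scaling by
#'   `spacing` with zero origin.
#' @param modality one of `"T1w"`, `"SWI"`, `"HC"`, `"template"`, or `"other"`.
#' @return An object of class `iron_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                   modality = "other") {
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly 3 axes, got ", length(dim(data)))
  if (!all(is.finite(data)))
    stop("volume contains non-finite voxel values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- unclass(affine)[1:4, 1:4]
  modality <- match.arg(modality, c("T1w", "SWI", "HC", "template", "other"))
  structure(list(data = data, spacing = spacing, affine = affine,
                 modality = modality),
            class = "iron_volume")
}

#' @export
print.iron_volume <- function(x, ...) {
  cat(sprintf("<iron_volume> %s  %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "iron_volume")

#' @export
dim.iron_volume <- function(x) dim(x$data)

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data %||% a$labels), dim(b$data %||% b$labels)))
    stop(what, " are not on the same grid (dimensions differ)")
  sa <- a$spacing %||% a$grid$spacing
  sb <- b$spacing %||% b$grid$spacing
  if (max(abs(sa - sb)) > 1e-6)
    stop(what, " are not on the same grid (spacing differs)")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integer-labeled mask on a reference grid
#'
#' @param labels 3D array of non-negative integer labels; 0 is background.
#' @param grid a `Volume` (or list with `spacing`/`affine`) defining the grid.
#' @param legend named integer vector mapping structure names to label values;
#'   must include entries for the structures the pipeline uses (putamen,
#'   globus pallidus, white matter) when the mask is meant for them.
#' @return An object of class `iron_labelmask`.
#' @export
label_mask <- function(labels, grid, legend) {
  if (length(dim(labels)) != 3L)
    stop("label array must have exactly 3 axes")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  if (is.null(names(legend)) || any(!nzchar(names(legend))))
    stop("legend must be a named integer vector (structure -> label)")
  if (anyDuplicated(names(legend)) || anyDuplicated(legend))
    stop("legend names and label values must be unique")
  if (!is.null(grid$data) && !identical(dim(labels), dim(grid$data)))
    stop("label array does not match its reference grid")
  spacing <- grid$spacing %||% c(1, 1, 1)
  grid_desc <- list(dim = dim(labels), spacing = spacing,
                    affine = grid$affine %||% diag(c(spacing, 1)))
  present <- legend %in% unique(as.integer(labels))
  structure(list(labels = labels, grid = grid_desc,
                 legend = legend, empty = names(legend)[!present]),
            class = "iron_labelmask")
}

#' @export
print.iron_labelmask <- function(x, ...) {
  cat(sprintf("<iron_labelmask> %s voxels; structures: %s\n",
              paste(dim(x$labels), collapse = "x"),
              paste(sprintf("%s=%d%s", names(x$legend), x$legend,
                            ifelse(names(x$legend) %in% x$empty, " (empty)", "")),
                    collapse = ", ")))
  invisible(x)
}

#' Logical mask of one structure
#'
#' @param mask an `iron_labelmask`.
#' @param structure structure name, looked up in the legend.
#' @return logical 3D array.
#' @export
structure_mask <- function(mask, structure) {
  if (!structure %in% names(mask$legend))
    stop("structure '", structure, "' not in mask legend")
  mask$labels == mask$legend[[structure]]
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param modality modality tag to attach.
#' @return A [volume()].
#' @export
read_volume <- function(path, modality = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " axes in ", path)
  arr <- array(as.numeric(img), dim = d)   # strip RNifti attributes
  if (!all(is.finite(arr)))
    stop("non-finite voxel values in ", path)
  volume(arr, spacing = RNifti::pixdim(img)[1:3],
         affine = unclass(RNifti::xform(img))[1:4, 1:4],
         modality = modality)
}

#' Write a volume to NIfTI
#'
#' @param vol a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label mask from NIfTI
#'
#' @inheritParams read_volume
#' @param legend named integer vector (structure -> label value).
#' @return An [label_mask()].
#' @export
read_mask <- function(path, legend) {
  vol <- read_volume(path)
  label_mask(array(as.integer(round(vol$data)), dim(vol$data)),
             grid = vol, legend = legend)
}

#' Write a label mask to NIfTI
#'
#' @param mask an [label_mask()].
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  vol <- volume(mask$labels + 0, spacing = mask$grid$spacing,
                affine = mask$grid$affine)
  write_volume(vol, path)
}
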