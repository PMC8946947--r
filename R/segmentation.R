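#' Deformation providers for label propagation
#'
#' Template-to-subject spatial correspondence is abstracted behind a
#' provider so that externally computed non-linear deformations (e.g. a
#' diffeomorphic registration run elsewhere) can drive label transport,
#' while the in-repo default is the package's own affine engine.
#'
#' `deformation_affine()` wraps an affine transform mapping template world
#' coordinates to subject world coordinates; with `transform = NULL` the
#' transform is estimated by [register_affine()] when labels are propagated.
#'
#' `deformation_field()` wraps a dense displacement field sampled on the
#' template grid: a template world point `x` maps to subject world
#' `x + u(x)` (mm). The field must be invertible in practice; the inverse
#' map is recovered by fixed-point iteration.
#'
#' @param transform an [affine_transform()] (template world -> subject
#'   world) or `NULL` to estimate it.
#' @param control [registration_control()] used when estimating.
#' @return a provider object of class `iron_deformation`.
#' @export
deformation_affine <- function(transform = NULL,
                               control = registration_control()) {
  structure(list(kind = "affine-internal", transform = transform,
                 control = control),
            class = "iron_deformation")
}

#' @rdname deformation_affine
#' @param field 4D array `dim x 3` of displacements (mm) on the template
#'   grid, or a list of three 3D arrays.
#' @param template_grid grid descriptor (a [volume()]) the field lives on.
#' @export
deformation_field <- function(field, template_grid) {
  if (is.list(field)) field <- array(unlist(field), dim = c(dim(field[[1]]), 3))
  if (length(dim(field)) != 4L || dim(field)[4] != 3L)
    stop("displacement field must be a dim x 3 array on the template grid")
  structure(list(kind = "external-field", field = field,
                 grid = list(dim = dim(field)[1:3],
                             spacing = template_grid$spacing,
                             affine = template_grid$affine)),
            class = "iron_deformation")
}

sample_field <- function(provider, pts) {
  # trilinear sample of the displacement at world points (3 x n)
  g <- provider$grid
  vox <- solve(g$affine[1:3, 1:3]) %*% (pts - g$affine[1:3, 4])
  u <- vapply(1:3, function(k)
    trilinear_sample(provider$field[, , , k], vox, background = 0),
    numeric(ncol(pts)))
  t(u)
}

invert_field_map <- function(provider, y, iters = 20L) {
  # solve x + u(x) = y for template points x, given subject points y (3 x n)
  x <- y
  for (i in seq_len(iters)) x <- y - sample_field(provider, x)
  x
}

#' Propagate template labels to a subject
#'
#' Registers (or accepts) a template-to-subject correspondence and carries
#' the template's deep-gray-matter labels into the subject grid by
#' nearest-neighbor transport through the inverse mapping, so every output
#' label existed in the template legend.
#'
#' @param hc subject [volume()] (typically the hybrid-contrast image).
#' @param template template [volume()].
#' @param template_labels [label_mask()] on the template grid.
#' @param provider an `iron_deformation` (default: internal affine engine).
#' @param required structure names that must be non-empty in the result.
#' @return subject-space [label_mask()] with the template legend. The
#'   estimated transform (if any) is attached as attribute `transform`.
#' @export
propagate_labels <- function(hc, template, template_labels,
                             provider = deformation_affine(),
                             required = "putamen") {
  if (!inherits(provider, "iron_deformation")) stop("invalid provider")
  if (!identical(dim(template_labels$labels), dim(template$data)))
    stop("template labels are not on the template grid")
  gdim <- dim(hc$data)
  y <- world_coords(hc$affine, gdim)  # subject world points
  est <- NULL
  if (provider$kind == "affine-internal") {
    t <- provider$transform
    if (is.null(t)) {
      # register the subject (moving) to the template (fixed); the result
      # maps template world -> subject world, so its inverse is the
      # subject -> template map used for inverse label warping
      t <- register_affine(hc, template, provider$control)
      est <- t
    }
    x <- apply_transform(invert_transform(t), y)
  } else {
    if (!identical(provider$grid$dim, dim(template$data)))
      stop("displacement field is not on the template grid")
    x <- invert_field_map(provider, y)
  }
  vox <- solve(template_labels$grid$affine[1:3, 1:3]) %*%
    (x - template_labels$grid$affine[1:3, 4])
  vals <- as.integer(nearest_sample(template_labels$labels, vox,
                                    background = 0L))
  dim(vals) <- gdim
  out <- label_mask(vals, grid = hc, legend = template_labels$legend)
  for (s in required) {
    if (s %in% out$empty)
      stop("propagated mask has no voxels for required structure '", s, "'")
  }
  attr(out, "transform") <- est
  out
}

#' Overlap quality report between two label masks
#'
#' Per-structure Dice coefficient `2|A&B| / (|A|+|B|)`, voxel counts, and
#' centroid displacement in mm.
#'
#' @param pred,truth [label_mask()] objects on the same grid.
#' @return data frame with one row per structure in the union of legends.
#' @export
mask_quality_report <- function(pred, truth) {
  stopifnot_same_grid(pred, truth, "masks")
  structures <- union(names(pred$legend), names(truth$legend))
  spacing <- truth$grid$spacing
  rows <- lapply(structures, function(s) {
    a <- if (s %in% names(pred$legend)) structure_mask(pred, s) else
      array(FALSE, dim(pred$labels))
    b <- if (s %in% names(truth$legend)) structure_mask(truth, s) else
      array(FALSE, dim(truth$labels))
    na <- sum(a); nb <- sum(b)
    dice <- if (na + nb == 0) NA_real_ else 2 * sum(a & b) / (na + nb)
    cdisp <- if (na == 0 || nb == 0) NA_real_ else {
      ca <- colMeans(which(a, arr.ind = TRUE)) * spacing
      cb <- colMeans(which(b, arr.ind = TRUE)) * spacing
      sqrt(sum((ca - cb)^2))
    }
    data.frame(structure = s, dice = dice, n_pred = na, n_truth = nb,
               centroid_shift_mm = cdisp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
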