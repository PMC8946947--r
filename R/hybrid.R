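#' Mean intensity of a volume over one labeled structure
#'
#' @param vol a [volume()].
#' @param mask a [label_mask()] on the same grid.
#' @param structure structure name in the mask legend.
#' @return scalar mean intensity.
#' @export
roi_mean <- function(vol, mask, structure) {
  sel <- structure_mask(mask, structure)
  if (!identical(dim(sel), dim(vol$data)))
    stop("mask is not on the volume grid")
  n <- sum(sel)
  if (n == 0) stop("structure '", structure, "' has no voxels")
  sum(vol$data[sel]) / n
}

#' ROI-mean system for the hybrid-contrast weight solve
#'
#' Collects the six mean intensities that drive the weight optimization:
#' subject T1w and SWI means in the putamen and globus pallidus, and the
#' template's target means in the same two structures.
#'
#' @param t1w,swi subject volumes on one grid.
#' @param init_mask initial deep-gray-matter [label_mask()] (T1w-derived)
#'   with `putamen` and `globus pallidus` in its legend.
#' @param template template [volume()].
#' @param template_mask template [label_mask()] with the same two structures.
#' @return a list of class `iron_roisystem` with elements `put_t1w`,
#'   `put_swi`, `pall_t1w`, `pall_swi`, `put_mni`, `pall_mni`.
#' @export
roi_mean_system <- function(t1w, swi, init_mask, template, template_mask) {
  stopifnot_same_grid(t1w, swi)
  sys <- list(put_t1w = roi_mean(t1w, init_mask, "putamen"),
              put_swi = roi_mean(swi, init_mask, "putamen"),
              pall_t1w = roi_mean(t1w, init_mask, "globus pallidus"),
              pall_swi = roi_mean(swi, init_mask, "globus pallidus"),
              put_mni = roi_mean(template, template_mask, "putamen"),
              pall_mni = roi_mean(template, template_mask, "globus pallidus"))
  if (!all(vapply(sys, is.finite, logical(1))))
    stop("non-finite ROI mean in the weight system")
  structure(sys, class = "iron_roisystem")
}

#' Solve the hybrid-contrast weights
#'
#' Finds the weighting coefficients (w1, w2) of the hybrid contrast
#' `HC = w1 * T1w + w2 * SWI` that minimize the squared difference between
#' the HC and template mean intensities in the putamen and globus pallidus:
#' the least-squares solution of the 2x2 system whose rows are the two
#' structures and whose columns are the two modalities. For a non-singular
#' square system this is the exact linear solve with zero residual.
#'
#' @param sys an `iron_roisystem` (see [roi_mean_system()]), or any list
#'   carrying its six fields.
#' @param cond_tol reciprocal-condition threshold below which the system is
#'   rejected as collinear.
#' @param nonneg if `TRUE`, clamp the solution to the non-negative quadrant
#'   (off by default; the weights are unconstrained).
#' @return list of class `iron_hcweights`: `w1`, `w2`, `residual` (value of
#'   the squared-difference objective at the solution) and `system`.
#' @export
solve_weights <- function(sys, cond_tol = 1e-10, nonneg = FALSE) {
  A <- matrix(c(sys$put_t1w, sys$put_swi,
                sys$pall_t1w, sys$pall_swi), 2, 2, byrow = TRUE)
  b <- c(sys$put_mni, sys$pall_mni)
  if (rcond(A) < cond_tol)
    stop("ROI-mean system is singular or ill-conditioned ",
         "(SWI column collinear with T1w column); cannot solve weights")
  w <- as.numeric(solve(A, b))
  if (nonneg) w <- pmax(w, 0)
  res <- sum((A %*% w - b)^2)
  structure(list(w1 = w[1], w2 = w[2], residual = res, system = sys),
            class = "iron_hcweights")
}

#' @export
print.iron_hcweights <- function(x, ...) {
  cat(sprintf("<iron_hcweights> w1 = %.6g, w2 = %.6g, residual = %.3g\n",
              x$w1, x$w2, x$residual))
  invisible(x)
}

#' Fuse T1w and SWI into a hybrid-contrast volume
#'
#' Voxelwise linear combination `HC = w1 * T1w + w2 * SWI` on a shared grid.
#'
#' @param t1w,swi [volume()] objects on the identical grid (SWI already
#'   resampled to T1w space).
#' @param w an `iron_hcweights` (or list with `w1`, `w2`).
#' @return the hybrid-contrast [volume()] (modality `"HC"`).
#' @export
fuse <- function(t1w, swi, w) {
  stopifnot_same_grid(t1w, swi)
  out <- t1w
  out$data <- w$w1 * t1w$data + w$w2 * swi$data
  out$modality <- "HC"
  out
}
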