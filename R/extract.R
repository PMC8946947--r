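#' Radiomic extraction settings
#'
#' @param bin_width fixed bin width for intensity discretization (default
#'   25, the de-facto standard for radiomics pipelines).
#' @param distances neighbor distances (voxels) for the distance-
#'   parameterized families (GLCM, NGTDM); default `c(1, 4, 7)`.
#' @param gldm_alpha dependence tolerance for GLDM.
#' @param merge_lateral kept for configurability: when the mask legend has
#'   `putamen left`/`putamen right` entries they are merged into one ROI.
#' @param exclude_signal unprefixed first-order names dropped by the
#'   texture-safe filter.
#' @export
extraction_control <- function(bin_width = 25, distances = c(1, 4, 7),
                               gldm_alpha = 0, merge_lateral = TRUE,
                               exclude_signal = signal_based_names()) {
  list(bin_width = bin_width, distances = distances,
       gldm_alpha = gldm_alpha, merge_lateral = merge_lateral,
       exclude_signal = exclude_signal)
}

merged_structure_mask <- function(mask, structure, merge_lateral) {
  nm <- names(mask$legend)
  parts <- nm[nm == structure |
                (merge_lateral & nm %in% paste(structure, c("left", "right")))]
  if (length(parts) == 0) stop("structure '", structure, "' not in legend")
  sel <- array(FALSE, dim(mask$labels))
  for (p in parts) sel <- sel | structure_mask(mask, p)
  sel
}

#' Extract the full radiomic feature vector of one ROI
#'
#' Computes all 178 features of the standard families: 19 first-order, 16
#' 3D shape, 10 2D shape, 24 GLCM per distance, 16 GLRLM, 16 GLSZM, 5 NGTDM
#' per distance, and 14 GLDM, with GLCM and NGTDM evaluated at neighbor
#' distances 1, 4 and 7 voxels. Left/right parts of the structure are
#' merged into a single ROI before extraction.
#'
#' A distance at which the ROI supports no voxel pair for any direction is
#' recorded in the `flagged_distances` attribute (its features are `NA`),
#' never silently dropped.
#'
#' @param swi SWI [volume()].
#' @param mask [label_mask()] on the same grid.
#' @param structure structure to extract from (default `"putamen"`).
#' @param control an [extraction_control()] list.
#' @return named numeric vector of 178 features with attributes
#'   `signal_based` and `flagged_distances`.
#' @export
extract_all <- function(swi, mask, structure = "putamen",
                        control = extraction_control()) {
  sel <- merged_structure_mask(mask, structure, control$merge_lateral)
  if (!identical(dim(sel), dim(swi$data)))
    stop("SWI volume and mask are not on the same grid")
  if (!any(sel)) stop("structure '", structure, "' has no voxels")
  d <- discretize(swi, sel, width = control$bin_width)
  fo <- first_order_features(swi, sel, width = control$bin_width)
  sh <- shape_features(label_mask(sel + 0L, grid = list(spacing = swi$spacing,
                                                        affine = swi$affine),
                                  legend = c(roi = 1L)), "roi")
  flagged <- integer(0)
  glcm_all <- ngtdm_all <- numeric(0)
  for (delta in control$distances) {
    g <- compute_glcm(d, delta)
    if (all(vapply(g$matrices, is.null, logical(1)))) {
      flagged <- c(flagged, delta)
      gf <- stats::setNames(rep(NA_real_, 24),
                            paste0("glcm_", names(glcm_features_one(matrix(1), 1)),
                                   delta))
    } else {
      gf <- glcm_features(g)
    }
    glcm_all <- c(glcm_all, gf)
    nf <- tryCatch(compute_ngtdm_features(d, delta), error = function(e) {
      stats::setNames(rep(NA_real_, 5),
                      paste0("ngtdm_", c("Coarseness", "Contrast", "Busyness",
                                         "Complexity", "Strength"), delta))
    })
    if (all(is.na(nf))) flagged <- c(flagged, delta)
    ngtdm_all <- c(ngtdm_all, nf)
  }
  out <- c(fo, sh, glcm_all,
           compute_glrlm_features(d),
           compute_glszm_features(d),
           ngtdm_all,
           compute_gldm_features(d, control$gldm_alpha))
  if (anyDuplicated(names(out))) stop("internal error: duplicate feature names")
  attr(out, "signal_based") <- attr(fo, "signal_based")
  attr(out, "flagged_distances") <- sort(unique(flagged))
  out
}

#' Extract a feature table for a cohort of subjects
#'
#' @param subjects list of lists with at least `swi` ([volume()]), `mask`
#'   ([label_mask()]), `id` and `class`.
#' @param structure,control passed to [extract_all()].
#' @return a `data.frame` with `subject_id`, `class`, and one column per
#'   feature.
#' @export
extract_cohort <- function(subjects, structure = "putamen",
                           control = extraction_control()) {
  rows <- lapply(subjects, function(s) {
    fv <- extract_all(s$swi, s$mask, structure, control)
    cbind(data.frame(subject_id = s$id, class = s$class,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  do.call(rbind, rows)
}
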