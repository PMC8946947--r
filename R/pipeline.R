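# End-to-end orchestration: preprocess -> fuse -> segment -> extract ->
# select -> classify, both file-based (NIfTI in, artifacts out, driven by a
# YAML config + manifest) and in-memory for generated cohorts.

#' Shift and dilate a mask (T1w-only segmentation surrogate)
#'
#' Produces a deliberately degraded mask: rigidly shifted by whole voxels
#' and dilated, so the ROI includes adjacent tissue without iron contrast,
#' emulating an atlas mask propagated without iron-reflecting contrast.
#'
#' @param mask a [label_mask()].
#' @param shift integer voxel shift (length 3).
#' @param dilate number of 26-neighborhood dilation passes.
#' @return the degraded [label_mask()].
#' @export
misalign_mask <- function(mask, shift = c(3, 2, 0), dilate = 1) {
  L <- mask$labels
  d <- dim(L)
  out <- array(0L, d)
  src <- lapply(1:3, function(k) {
    i <- seq_len(d[k]) - shift[k]
    i[i >= 1 & i <= d[k]]
  })
  dst <- lapply(1:3, function(k) {
    i <- seq_len(d[k])
    i[i - shift[k] >= 1 & i - shift[k] <= d[k]]
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- L[src[[1]], src[[2]], src[[3]]]
  if (dilate > 0) {
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
    for (pass in seq_len(dilate)) {
      grown <- out
      for (k in seq_len(nrow(offs))) {
        o <- offs[k, ]
        src <- lapply(1:3, function(j) {
          i <- seq_len(d[j]) - o[j]; i[i >= 1 & i <= d[j]]
        })
        dst <- lapply(1:3, function(j) {
          i <- seq_len(d[j]); i[i - o[j] >= 1 & i - o[j] <= d[j]]
        })
        nb <- array(0L, d)
        nb[dst[[1]], dst[[2]], dst[[3]]] <- out[src[[1]], src[[2]], src[[3]]]
        grown[grown == 0L & nb > 0L] <- nb[grown == 0L & nb > 0L]
      }
      out <- grown
    }
  }
  label_mask(out, grid = list(spacing = mask$grid$spacing,
                              affine = mask$grid$affine),
             legend = mask$legend)
}

#' Process one subject into an iron-reflecting DGM mask
#'
#' The per-subject segmentation pipeline: white-matter normalization of the
#' T1w, hybrid-contrast weight solve from the initial DGM mask, fusion, and
#' template label propagation driven by the hybrid image.
#'
#' @param t1w,swi subject volumes on one grid (SWI already registered).
#' @param init_mask initial (T1w-derived) DGM [label_mask()] with putamen,
#'   globus pallidus and white matter.
#' @param template,template_labels the registration target and its labels.
#' @param wm_target white-matter normalization target (default 110).
#' @param provider deformation provider for the propagation.
#' @return list: `hc` volume, `mask` (propagated), `weights`, `t1w_norm`.
#' @export
segment_subject <- function(t1w, swi, init_mask, template, template_labels,
                            wm_target = 110,
                            provider = deformation_affine()) {
  t1n <- normalize_t1w_wm(t1w, init_mask, target = wm_target)
  sys <- roi_mean_system(t1n, swi, init_mask, template, template_labels)
  w <- solve_weights(sys)
  hc <- fuse(t1n, swi, w)
  mask <- propagate_labels(hc, template, template_labels, provider)
  list(hc = hc, mask = mask, weights = w, t1w_norm = t1n)
}

#' Feature table of a phantom cohort under a mask policy
#'
#' Runs the segmentation pipeline over generated subjects and extracts the
#' putamen feature table from SWI. `mask_source` selects the ROI policy:
#' the propagated hybrid-contrast mask (`"hc"`), the exact truth mask
#' (`"truth"`), or a shifted/dilated surrogate of a T1w-only atlas mask
#' (`"misaligned"`).
#'
#' @param subjects list from [generate_cohort()].
#' @param mask_source one of `"hc"`, `"truth"`, `"misaligned"`.
#' @param template output of [phantom_template()] (required for `"hc"`).
#' @param control an [extraction_control()].
#' @param reg_control [registration_control()] for the `"hc"` propagation.
#' @param misalign_shift,misalign_dilate parameters of the surrogate.
#' @return feature `data.frame` (see [extract_cohort()]).
#' @export
cohort_features <- function(subjects,
                            mask_source = c("hc", "truth", "misaligned"),
                            template = phantom_template(),
                            control = extraction_control(),
                            reg_control = registration_control(),
                            misalign_shift = c(3, 2, 0),
                            misalign_dilate = 1) {
  mask_source <- match.arg(mask_source)
  rows <- lapply(subjects, function(s) {
    mask <- switch(mask_source,
      truth = s$truth,
      misaligned = misalign_mask(s$truth, misalign_shift, misalign_dilate),
      hc = segment_subject(s$t1w, s$swi, s$truth, template$volume,
                           template$labels,
                           provider = deformation_affine(control = reg_control))$mask)
    list(swi = s$swi, mask = mask, id = s$id, class = s$class)
  })
  extract_cohort(rows, "putamen", control)
}

default_legend <- function()
  c("putamen" = 1L, "globus pallidus" = 2L, "white matter" = 3L)

#' Load a pipeline run configuration
#'
#' @param path YAML file, or a named list of overrides.
#' @return config list with defaults filled in.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- list(manifest = NULL, out_dir = "ironmap_run", seed = 1,
              wm_target = 110, bin_width = 25, distances = c(1, 4, 7),
              template_path = NULL, template_mask_path = NULL,
              register_swi = FALSE, pair = NULL, n_repeats = 100,
              k_features = 10, structure = "putamen",
              legend = as.list(default_legend()), resume = FALSE)
  over <- if (is.character(path)) yaml::read_yaml(path) else path
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg$legend <- unlist(cfg$legend)
  storage.mode(cfg$legend) <- "integer"
  cfg
}

#' Run the full pipeline from a manifest
#'
#' Executes preprocess -> fuse -> segment -> extract (-> select -> classify
#' when `pair` is configured) for every subject of the manifest, writing
#' per-stage artifacts under `out_dir` and a run manifest with every
#' parameter and seed. With `resume = TRUE`, subjects whose stage outputs
#' already exist are not recomputed.
#'
#' @param config a [pipeline_config()] list or YAML path. The manifest CSV
#'   must have columns `subject_id`, `class`, `t1w_path`, `swi_path`,
#'   `wm_mask_path`, `init_dgm_mask_path`.
#' @return run manifest list (also written as `run_manifest.json`).
#' @export
run_all <- function(config) {
  cfg <- if (is.list(config) && !is.null(config$legend)) config else
    pipeline_config(config)
  if (is.null(cfg$manifest)) stop("config$manifest is required")
  man <- utils::read.csv(cfg$manifest, stringsAsFactors = FALSE)
  needed <- c("subject_id", "class", "t1w_path", "swi_path",
              "wm_mask_path", "init_dgm_mask_path")
  if (!all(needed %in% names(man)))
    stop("manifest must have columns: ", paste(needed, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$template_path)) {
    tpl <- phantom_template()
  } else {
    tpl <- list(volume = read_volume(cfg$template_path, "template"),
                labels = read_mask(cfg$template_mask_path, cfg$legend))
  }
  ctl <- extraction_control(bin_width = cfg$bin_width,
                            distances = cfg$distances)
  feat_rows <- list()
  for (i in seq_len(nrow(man))) {
    id <- man$subject_id[i]
    for (col in c("t1w_path", "swi_path", "wm_mask_path",
                  "init_dgm_mask_path")) {
      if (!file.exists(man[[col]][i]))
        stop("stage preprocess, subject ", id, ": missing file ",
             man[[col]][i], " (", col, ")")
    }
    hc_path <- file.path(cfg$out_dir, paste0("hc_", id, ".nii.gz"))
    mask_path <- file.path(cfg$out_dir, paste0("dgm_", id, ".nii.gz"))
    w_path <- file.path(cfg$out_dir, paste0("weights_", id, ".json"))
    done <- cfg$resume && all(file.exists(hc_path, mask_path, w_path))
    res <- tryCatch({
      if (done) {
        list(mask = read_mask(mask_path, cfg$legend))
      } else {
        t1w <- read_volume(man$t1w_path[i], "T1w")
        swi <- read_volume(man$swi_path[i], "SWI")
        init <- read_mask(man$init_dgm_mask_path[i], cfg$legend)
        if (cfg$register_swi) {
          tr <- register_affine(swi, t1w)
          swi <- resample(swi, tr, grid = t1w)
        }
        out <- segment_subject(t1w, swi, init, tpl$volume, tpl$labels,
                               wm_target = cfg$wm_target)
        write_volume(out$hc, hc_path)
        write_mask(out$mask, mask_path)
        jsonlite::write_json(c(list(w1 = out$weights$w1, w2 = out$weights$w2,
                                    residual = out$weights$residual),
                               unclass(out$weights$system)),
                             w_path, auto_unbox = TRUE, digits = NA)
        out
      }
    }, error = function(e)
      stop("stage segment, subject ", id, ": ", conditionMessage(e),
           call. = FALSE))
    swi <- read_volume(man$swi_path[i], "SWI")
    fv <- tryCatch(extract_all(swi, res$mask, cfg$structure, ctl),
                   error = function(e)
                     stop("stage extract, subject ", id, ": ",
                          conditionMessage(e), call. = FALSE))
    feat_rows[[i]] <- cbind(data.frame(subject_id = id, class = man$class[i],
                                       stringsAsFactors = FALSE),
                            as.data.frame(as.list(fv), check.names = FALSE))
  }
  features <- do.call(rbind, feat_rows)
  feat_path <- file.path(cfg$out_dir, "features.csv")
  utils::write.csv(features, feat_path, row.names = FALSE)
  result <- list(features = feat_path)
  if (!is.null(cfg$pair)) {
    keep <- c("subject_id", "class",
              names(texture_safe_features(
                stats::setNames(numeric(ncol(features) - 2),
                                names(features)[-(1:2)]))))
    tab <- features[, keep]
    pairtab <- tab[tab$class %in% cfg$pair, ]
    ranking <- fisher_score(pairtab)
    sel <- select_top_k(ranking, cfg$k_features)
    sel_path <- file.path(cfg$out_dir, "selected.json")
    jsonlite::write_json(list(features = sel,
                              scores = ranking$scores[sel],
                              rank = seq_along(sel)),
                         sel_path, auto_unbox = TRUE, digits = NA)
    report <- run_task(tab, cfg$pair, n_repeats = cfg$n_repeats,
                       k_features = cfg$k_features, seed = cfg$seed)
    rep_path <- file.path(cfg$out_dir, "report.csv")
    utils::write.csv(report$summary, rep_path, row.names = FALSE)
    result$selected <- sel_path
    result$report <- rep_path
  }
  cfg_path <- file.path(cfg$out_dir, "run_config.yaml")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], cfg_path)
  manifest <- list(config = cfg_path,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed, n_subjects = nrow(man),
                   outputs = result)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
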