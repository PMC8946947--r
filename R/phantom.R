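# Seeded paired T1w/SWI phantoms with ground-truth deep-gray-matter masks
# and class-specific iron-deposition topographies: posterolateral putaminal
# hypointensity with a lateral-to-medial gradient (MSA-P), anteromedial
# pallidal hypointensity (PSP), a slit-like lateral putaminal rim (PD), and
# mild diffuse putaminal change (MSA-C).

#' Effect sizes of the phantom iron topographies
#'
#' Depths are SWI hypointensity magnitudes in intensity units (the phantom
#' SWI baseline is ~100 in gray nuclei against white matter ~120).
#'
#' @param msap_depth posterolateral putaminal depth for MSA-P.
#' @param psp_depth anteromedial pallidal depth for PSP.
#' @param pd_depth lateral slit depth for PD (added to the common slit).
#' @param msac_depth mild diffuse putaminal depth for MSA-C.
#' @param common_slit depth of the class-independent slit-like lateral
#'   putaminal hypointensity: the generic, age-related mineralization sign
#'   rendered in every class, which is what makes intensity alone
#'   insufficient to separate MSA-P from PD.
#' @param gradient exponent of the lateral-to-medial gradient in MSA-P.
#' @param slit_frac thickness of the slit as a fraction of the putamen
#'   ellipsoid radius.
#' @param scale global multiplier on all depths (0 gives a null cohort in
#'   which classes differ only by noise).
#' @export
phantom_effects <- function(msap_depth = 30, psp_depth = 25, pd_depth = 10,
                            msac_depth = 8, common_slit = 10, gradient = 1,
                            slit_frac = 0.25, scale = 1) {
  list(msap_depth = msap_depth * scale, psp_depth = psp_depth * scale,
       pd_depth = pd_depth * scale, msac_depth = msac_depth * scale,
       common_slit = common_slit * scale,
       gradient = gradient, slit_frac = slit_frac)
}

#' Phantom specification
#'
#' Defines one subject: grid, bilateral parametric geometry (putamen and
#' globus pallidus ellipsoids inside a white-matter brain ellipsoid),
#' disease class, effect sizes, noise model, geometric jitter, and seed.
#' Identical spec + seed render bit-identical phantoms.
#'
#' @param class one of `"MSA-P"`, `"MSA-C"`, `"PSP"`, `"PD"`.
#' @param dim grid size (default 64^3).
#' @param spacing voxel size mm.
#' @param effects a [phantom_effects()] list.
#' @param noise_sd Gaussian noise sd on SWI (intensity units).
#' @param t1w_noise_sd Gaussian noise sd on T1w.
#' @param t1w_iron_frac fraction of the SWI deposit field added to T1w
#'   (brightening toward white matter, eroding the nucleus boundary);
#'   small by default: the phantom T1w is nearly iron-insensitive.
#' @param t1w_scale global T1w intensity scale (the raw scanner scale the
#'   white-matter normalization removes).
#' @param jitter list with `translation` (voxels, length 3) and `scale`
#'   (relative semi-axis change) applied to the whole geometry, plus an
#'   optional `dgm_translation` (voxels) moving the deep nuclei relative
#'   to the brain, emulating anatomical variability of DGM position that
#'   global alignment cannot absorb.
#' @param seed RNG seed for the noise.
#' @export
phantom_spec <- function(class = "PD", dim = c(64, 64, 64),
                         spacing = c(1, 1, 1),
                         effects = phantom_effects(),
                         noise_sd = 8, t1w_noise_sd = 5,
                         t1w_iron_frac = 0.1, t1w_scale = 1,
                         jitter = list(translation = c(0, 0, 0), scale = 0),
                         seed = 1L) {
  class <- match.arg(class, c("MSA-P", "MSA-C", "PSP", "PD"))
  list(class = class, dim = dim, spacing = spacing, effects = effects,
       noise_sd = noise_sd, t1w_noise_sd = t1w_noise_sd,
       t1w_iron_frac = t1w_iron_frac, t1w_scale = t1w_scale,
       jitter = jitter, seed = as.integer(seed))
}

phantom_geometry <- function(spec) {
  d <- spec$dim
  mid <- (d[1] + 1) / 2
  tr <- spec$jitter$translation
  dg <- spec$jitter$dgm_translation %||% c(0, 0, 0)
  sc <- 1 + spec$jitter$scale
  g <- list(
    mid = mid,
    brain = list(c = c(mid, (d[2] + 1) / 2, (d[3] + 1) / 2) + tr,
                 a = c(0.42, 0.45, 0.38) * d * sc),
    put = list(dx = 15 * sc,
               c = c(NA, (d[2] + 1) / 2 + 2, (d[3] + 1) / 2) +
                 c(0, tr[2] + dg[2], tr[3] + dg[3]),
               a = c(5, 10, 8) * sc),
    pall = list(dx = 6 * sc,
                c = c(NA, (d[2] + 1) / 2, (d[3] + 1) / 2) +
                  c(0, tr[2] + dg[2], tr[3] + dg[3]),
                a = c(3, 5, 5) * sc),
    tr1 = tr[1] + dg[1])
  if (g$put$dx - g$put$a[1] <= g$pall$dx + g$pall$a[1])
    stop("phantom nuclei overlap; reduce jitter or semi-axes")
  if (mid + g$put$dx + g$put$a[1] + abs(g$tr1) >= d[1])
    stop("phantom nuclei exceed the grid")
  g
}

ellipsoid_rho <- function(X, Y, Z, c, a) {
  sqrt(((X - c[1]) / a[1])^2 + ((Y - c[2]) / a[2])^2 + ((Z - c[3]) / a[3])^2)
}

#' Per-voxel iron-deposit field of a phantom
#'
#' The class-specific hypointensity field (intensity units, >= 0) on the
#' phantom grid, evaluated analytically from the geometry; the rendered SWI
#' is `baseline - field` plus noise, so tests can verify the topography in
#' closed form.
#'
#' @param spec a [phantom_spec()].
#' @return 3D array of deposit magnitudes.
#' @export
phantom_deposit_field <- function(spec) {
  d <- spec$dim
  g <- phantom_geometry(spec)
  X <- array(rep(seq_len(d[1]), times = prod(d[2:3])), d)
  Y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  Z <- array(rep(seq_len(d[3]), each = prod(d[1:2])), d)
  ef <- spec$effects
  field <- array(0, d)
  for (h in c(-1, 1)) {
    pc <- g$put$c; pc[1] <- g$mid + h * g$put$dx + g$tr1
    rho_p <- ellipsoid_rho(X, Y, Z, pc, g$put$a)
    in_put <- rho_p <= 1
    lc <- g$pall$c; lc[1] <- g$mid + h * g$pall$dx + g$tr1
    rho_g <- ellipsoid_rho(X, Y, Z, lc, g$pall$a)
    in_pall <- rho_g <= 1
    lat <- pmin(pmax((h * (X - pc[1]) / g$put$a[1] + 1) / 2, 0), 1)
    post <- (Y - pc[2]) / g$put$a[2]   # >0 towards posterior
    slit <- in_put & rho_p >= 1 - ef$slit_frac &
      h * (X - pc[1]) > 0.3 * g$put$a[1]
    w <- switch(spec$class,
      "MSA-P" = {
        # posterolateral wedge penetrating from the putaminal margin with a
        # lateral-to-medial gradient; the distinguishing structure sits
        # within a few voxels of the margin, so ROI precision matters
        pen <- 2 * ef$slit_frac
        shell <- pmax(0, (rho_p - (1 - pen)) / pen) * (rho_p <= 1)
        postw <- ifelse(post > 0, 1, pmax(0.2, 1 + post))
        wp <- in_put * ef$msap_depth * shell^ef$gradient * postw *
          (lat > 0.5)
        # companion deposit in the lateral pallidum adjacent to the putamen
        wl <- in_pall * 0.5 * ef$msap_depth *
          pmax(0, h * (X - lc[1]) / g$pall$a[1])
        wp + wl
      },
      "PSP" = {
        antmed <- pmax(0, -(Y - lc[2]) / g$pall$a[2]) *
          pmax(0, -h * (X - lc[1]) / g$pall$a[1] + 0.5)
        in_pall * ef$psp_depth * pmin(1, antmed)
      },
      "PD" = slit * ef$pd_depth,
      "MSA-C" = in_put * ef$msac_depth)
    # generic age-related mineralization: slit-like lateral hypointensity
    # present in every class
    field <- field + w + slit * ef$common_slit
  }
  field
}

smooth3 <- function(arr) {
  k <- c(0.25, 0.5, 0.25)
  d <- dim(arr)
  pad_conv <- function(a, axis) {
    idx <- function(sh) {
      i <- seq_len(d[axis]) + sh
      pmin(pmax(i, 1L), d[axis])
    }
    slice <- function(i) {
      switch(axis,
             a[i, , , drop = FALSE],
             a[, i, , drop = FALSE],
             a[, , i, drop = FALSE])
    }
    k[1] * slice(idx(-1L)) + k[2] * slice(idx(0L)) + k[3] * slice(idx(1L))
  }
  for (ax in 1:3) arr <- pad_conv(arr, ax)
  arr
}

#' Generate one phantom subject
#'
#' Renders paired T1w and SWI volumes plus the exact truth mask. SWI
#' encodes iron as hypointensity (`baseline - deposit field`); the T1w
#' carries only a small fraction of the field (brightening), so fusing the
#' two has genuine added value for iron-reflecting segmentation. Noise is
#' smoothed with a small separable kernel (a point-spread-function
#' surrogate) and added to the crisp structural image, keeping the deposit
#' topography analytically exact.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `iron_phantom`: `t1w`, `swi` ([volume()]s),
#'   `truth` ([label_mask()]), `class`, `spec`.
#' @export
generate_subject <- function(spec) {
  d <- spec$dim
  g <- phantom_geometry(spec)
  X <- array(rep(seq_len(d[1]), times = prod(d[2:3])), d)
  Y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  Z <- array(rep(seq_len(d[3]), each = prod(d[1:2])), d)
  labs <- array(0L, d)
  in_brain <- ellipsoid_rho(X, Y, Z, g$brain$c, g$brain$a) <= 1
  labs[in_brain] <- 3L
  for (h in c(-1, 1)) {
    pc <- g$put$c; pc[1] <- g$mid + h * g$put$dx + g$tr1
    labs[ellipsoid_rho(X, Y, Z, pc, g$put$a) <= 1] <- 1L
    lc <- g$pall$c; lc[1] <- g$mid + h * g$pall$dx + g$tr1
    labs[ellipsoid_rho(X, Y, Z, lc, g$pall$a) <= 1] <- 2L
  }
  field <- phantom_deposit_field(spec)
  t1_base <- c(0, 110, 105, 150)[labs + 1L]
  sw_base <- c(0, 100, 95, 120)[labs + 1L]
  t1_struct <- (t1_base + spec$t1w_iron_frac * field) * spec$t1w_scale
  sw_struct <- sw_base - field
  noise <- with_seed(spec$seed, list(
    t1 = array(stats::rnorm(prod(d), sd = spec$t1w_noise_sd), d),
    sw = array(stats::rnorm(prod(d), sd = spec$noise_sd), d)))
  t1 <- t1_struct + if (spec$t1w_noise_sd > 0) smooth3(noise$t1) * spec$t1w_scale else 0
  sw <- sw_struct + if (spec$noise_sd > 0) smooth3(noise$sw) else 0
  dim(t1) <- d; dim(sw) <- d
  grid <- volume(array(0, d), spacing = spec$spacing)
  truth <- label_mask(labs, grid = grid,
                      legend = c("putamen" = 1L, "globus pallidus" = 2L,
                                 "white matter" = 3L))
  structure(list(t1w = volume(t1, spec$spacing, modality = "T1w"),
                 swi = volume(sw, spec$spacing, modality = "SWI"),
                 truth = truth, class = spec$class, spec = spec),
            class = "iron_phantom")
}

#' Noise- and disease-free phantom template
#'
#' The reference anatomy (no jitter, no iron, no noise) with a typical
#' T1w-like contrast, plus its label mask: the registration target and the
#' source of the template ROI means for the weight solve.
#'
#' @param dim,spacing grid of the template.
#' @return list with `volume` (modality `"template"`) and `labels`.
#' @export
phantom_template <- function(dim = c(64, 64, 64), spacing = c(1, 1, 1)) {
  spec <- phantom_spec("PD", dim = dim, spacing = spacing,
                       effects = phantom_effects(scale = 0),
                       noise_sd = 0, t1w_noise_sd = 0, seed = 0L)
  subj <- generate_subject(spec)
  tpl <- subj$t1w
  # template DGM contrast: darker nuclei than subject T1w, as in a
  # typical T1w atlas with strong structural delineation
  tpl$data[subj$truth$labels == 1L] <- 95
  tpl$data[subj$truth$labels == 2L] <- 88
  tpl$modality <- "template"
  list(volume = tpl, labels = subj$truth)
}

#' Generate a phantom cohort
#'
#' Independent seeded subjects with per-subject geometric jitter (random
#' translation and isotropic scale of the whole geometry). Default class
#' counts are 34 MSA-P, 21 MSA-C, 17 PSP and 56 PD.
#'
#' @param counts named integer vector of subjects per class.
#' @param spec template [phantom_spec()] (its class/jitter/seed fields are
#'   overridden per subject).
#' @param master_seed seed controlling all per-subject seeds and jitter.
#' @param jitter_translation max absolute translation jitter (voxels).
#' @param jitter_scale max absolute relative scale jitter.
#' @param severity_range uniform range of the per-subject disease-severity
#'   factor multiplying the class-specific deposit depth; the lower end
#'   models early disease whose deposit is close to the noise floor, which
#'   is what keeps the phantom tasks from being trivially separable.
#' @param mineralization_range uniform range of the per-subject multiplier
#'   on the class-independent slit component (age-related variability).
#' @return list of `iron_phantom` subjects with `id` fields `S001`, ...
#' @export
generate_cohort <- function(counts = c("MSA-P" = 34, "MSA-C" = 21,
                                       "PSP" = 17, "PD" = 56),
                            spec = phantom_spec(),
                            master_seed = 1,
                            jitter_translation = 2, jitter_scale = 0.03,
                            severity_range = c(0.1, 1),
                            mineralization_range = c(0, 1.5)) {
  stopifnot(all(counts >= 0), !is.null(names(counts)))
  classes <- rep(names(counts), counts)
  n <- length(classes)
  jit <- with_seed(master_seed, list(
    tr = matrix(stats::runif(3 * n, -jitter_translation, jitter_translation),
                ncol = 3),
    sc = stats::runif(n, -jitter_scale, jitter_scale),
    # raw scanner intensity scale, removed by white-matter normalization
    t1sc = stats::runif(n, 0.8, 1.2),
    sev = stats::runif(n, severity_range[1], severity_range[2]),
    mine = stats::runif(n, mineralization_range[1], mineralization_range[2])))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ef <- spec$effects
    ef$msap_depth <- ef$msap_depth * jit$sev[i]
    ef$psp_depth <- ef$psp_depth * jit$sev[i]
    ef$pd_depth <- ef$pd_depth * jit$sev[i]
    ef$msac_depth <- ef$msac_depth * jit$sev[i]
    ef$common_slit <- ef$common_slit * jit$mine[i]
    subj <- generate_subject(phantom_spec(class = classes[i], dim = spec$dim,
                                          spacing = spec$spacing,
                                          effects = ef,
                                          noise_sd = spec$noise_sd,
                                          t1w_noise_sd = spec$t1w_noise_sd,
                                          t1w_iron_frac = spec$t1w_iron_frac,
                                          t1w_scale = spec$t1w_scale * jit$t1sc[i],
                                          jitter = list(translation = jit$tr[i, ],
                                                        scale = jit$sc[i]),
                                          seed = as.integer(master_seed * 10000 + i)))
    subj$id <- sprintf("S%03d", i)
    subj$severity <- jit$sev[i]
    out[[i]] <- subj
  }
  out
}
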