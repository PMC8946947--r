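#' Normalize T1w white-matter intensity
#'
#' Globally rescales a T1w volume so that its mean intensity over the
#' white-matter mask equals a predefined target (110 by default), the
#' standard intensity normalization step preceding hybrid-contrast fusion.
#' One scale factor is applied to the whole volume.
#'
#' @param vol a T1w [volume()].
#' @param wm a [label_mask()] whose legend contains `"white matter"`, or a
#'   logical array on the same grid.
#' @param target desired WM mean (default 110).
#' @return the rescaled [volume()].
#' @export
normalize_t1w_wm <- function(vol, wm, target = 110) {
  sel <- if (is.logical(wm)) wm else structure_mask(wm, "white matter")
  if (!identical(dim(sel), dim(vol$data)))
    stop("WM mask is not on the volume grid")
  n <- sum(sel)
  if (n == 0) stop("white-matter mask is empty")
  m <- sum(vol$data[sel]) / n
  if (m == 0) stop("white-matter mean intensity is zero; cannot rescale")
  out <- vol
  out$data <- vol$data * (target / m)
  out
}

#' Affine transform in world (mm) coordinates
#'
#' Represents `x_moving = matrix %*% x_fixed + translation`: the resampling
#' convention, mapping points of the fixed image's world space into the
#' moving image's world space.
#'
#' @param matrix 3x3 linear part (invertible).
#' @param translation length-3 vector in mm.
#' @return An object of class `iron_affine`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- unname(unclass(matrix)[1:3, 1:3])
  if (abs(det(matrix)) < 1e-12)
    stop("affine matrix is singular (|det| < 1e-12)")
  structure(list(matrix = matrix, translation = as.numeric(translation)[1:3]),
            class = "iron_affine")
}

#' @export
print.iron_affine <- function(x, ...) {
  cat("<iron_affine>\n")
  m <- cbind(x$matrix, x$translation)
  dimnames(m) <- list(NULL, c("", "", "", "t"))
  print(signif(m, 6))
  invisible(x)
}

#' @rdname affine_transform
#' @export
identity_transform <- function() affine_transform()

#' Invert an affine transform
#' @param t an [affine_transform()].
#' @return the inverse transform.
#' @export
invert_transform <- function(t) {
  m <- solve(t$matrix)
  affine_transform(m, -m %*% t$translation)
}

#' Compose two affine transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`
#' (i.e. `compose(a, b)(x) = a(b(x))`).
#' @param a,b [affine_transform()] objects.
#' @export
compose_transforms <- function(a, b) {
  affine_transform(a$matrix %*% b$matrix,
                   a$matrix %*% b$translation + a$translation)
}

apply_transform <- function(t, pts) {
  # pts: 3 x n matrix of world coordinates
  t$matrix %*% pts + t$translation
}

#' Serialize / read a transform as a plain-text 4x4 matrix
#' @param t an [affine_transform()].
#' @param path text file path.
#' @export
write_transform <- function(t, path) {
  m <- rbind(cbind(t$matrix, t$translation), c(0, 0, 0, 1))
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  affine_transform(m[1:3, 1:3], m[1:3, 4])
}

world_coords <- function(affine, dims) {
  # world coordinates of every voxel (0-based indices), 3 x n
  idx <- as.matrix(expand.grid(seq_len(dims[1]) - 1L,
                               seq_len(dims[2]) - 1L,
                               seq_len(dims[3]) - 1L))
  affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4]
}

trilinear_sample <- function(arr, vox, background = NA_real_) {
  # vox: 3 x n 0-based continuous voxel coordinates
  d <- dim(arr)
  x <- vox[1, ]; y <- vox[2, ]; z <- vox[3, ]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  ok <- x0 >= 0 & y0 >= 0 & z0 >= 0 &
    x0 <= d[1] - 1 & y0 <= d[2] - 1 & z0 <= d[3] - 1
  # clamp the upper corner so voxels exactly on the far face interpolate flat
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  out <- rep(background, length(x))
  if (any(ok)) {
    g <- function(i, j, k) arr[cbind(i[ok] + 1, j[ok] + 1, k[ok] + 1)]
    wx <- fx[ok]; wy <- fy[ok]; wz <- fz[ok]
    out[ok] <-
      g(x0, y0, z0) * (1 - wx) * (1 - wy) * (1 - wz) +
      g(x1, y0, z0) * wx * (1 - wy) * (1 - wz) +
      g(x0, y1, z0) * (1 - wx) * wy * (1 - wz) +
      g(x1, y1, z0) * wx * wy * (1 - wz) +
      g(x0, y0, z1) * (1 - wx) * (1 - wy) * wz +
      g(x1, y0, z1) * wx * (1 - wy) * wz +
      g(x0, y1, z1) * (1 - wx) * wy * wz +
      g(x1, y1, z1) * wx * wy * wz
  }
  out
}

nearest_sample <- function(arr, vox, background = 0) {
  d <- dim(arr)
  i <- round(vox[1, ]); j <- round(vox[2, ]); k <- round(vox[3, ])
  ok <- i >= 0 & j >= 0 & k >= 0 & i <= d[1] - 1 & j <= d[2] - 1 & k <= d[3] - 1
  out <- rep(background, ncol(vox))
  out[ok] <- arr[cbind(i[ok] + 1, j[ok] + 1, k[ok] + 1)]
  out
}

#' Resample a volume or mask through an affine transform
#'
#' Maps every voxel of the target grid to world space, through `t` into the
#' moving image's world space, and interpolates. `nearest` never invents
#' label values; `linear` output is bounded by the input range.
#'
#' @param vol a [volume()] or [label_mask()] (masks force nearest).
#' @param t an [affine_transform()] (fixed world -> moving world).
#' @param grid target grid: a [volume()], [label_mask()], or list with
#'   `dim`, `spacing`, `affine`.
#' @param interp `"linear"` or `"nearest"`.
#' @param background fill value outside the moving image (default 0).
#' @return object of the same class as `vol`, on the target grid.
#' @export
resample <- function(vol, t = identity_transform(), grid = vol,
                     interp = c("linear", "nearest"), background = 0) {
  interp <- match.arg(interp)
  gdim <- grid$dim %||% dim(grid$data %||% grid$labels)
  gspacing <- grid$spacing %||% grid$grid$spacing
  gaffine <- grid$affine %||% grid$grid$affine
  if (is.null(gdim) || any(gdim < 1)) stop("degenerate target grid")
  is_mask <- inherits(vol, "iron_labelmask")
  arr <- if (is_mask) vol$labels else vol$data
  src_affine <- if (is_mask) vol$grid$affine else vol$affine
  w <- world_coords(gaffine, gdim)           # fixed world
  wm <- apply_transform(t, w)                # moving world
  vox <- solve(src_affine[1:3, 1:3]) %*% (wm - src_affine[1:3, 4])
  if (is_mask || interp == "nearest") {
    vals <- nearest_sample(arr, vox, background = if (is_mask) 0 else background)
  } else {
    vals <- trilinear_sample(arr, vox, background = NA_real_)
    vals[is.na(vals)] <- background
  }
  dim(vals) <- gdim
  if (is_mask) {
    storage.mode(vals) <- "integer"
    label_mask(vals, grid = list(spacing = gspacing, affine = gaffine),
               legend = vol$legend)
  } else {
    volume(vals, spacing = gspacing, affine = gaffine, modality = vol$modality)
  }
}

downsample_volume <- function(vol, f) {
  if (f == 1) return(vol)
  d <- dim(vol$data); nd <- d %/% f
  a <- vol$data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
                drop = FALSE]
  dim(a) <- c(f, nd[1], f, nd[2], f, nd[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(f^3, prod(nd))
  out <- colMeans(a)
  dim(out) <- nd
  aff <- vol$affine
  shift <- aff[1:3, 1:3] %*% rep((f - 1) / 2, 3)
  aff[1:3, 1:3] <- aff[1:3, 1:3] * f
  aff[1:3, 4] <- aff[1:3, 4] + shift
  volume(out, spacing = vol$spacing * f, affine = aff, modality = vol$modality)
}

#' Registration settings
#'
#' @param metric similarity criterion: `"nmi"` (normalized mutual
#'   information, default), `"ncc"` (normalized cross-correlation) or
#'   `"mse"`.
#' @param type transform family: `"affine"` (12 dof), `"similarity"`,
#'   `"rigid"`, or `"translation"`.
#' @param levels integer downsampling factors of the multi-resolution
#'   pyramid, coarse to fine.
#' @param maxit per-level budget of metric evaluations per free parameter.
#' @param nbins joint-histogram bins for the MI metric.
#' @param min_overlap minimum fraction of fixed voxels that must map inside
#'   the moving image at the solution.
#' @param init `"identity"` (header alignment) initialization.
#' @param seed RNG seed fixed during optimization for reproducibility.
#' @export
registration_control <- function(metric = c("nmi", "ncc", "mse"),
                                 type = c("affine", "similarity", "rigid",
                                          "translation"),
                                 levels = c(4, 2), maxit = c(300, 150),
                                 nbins = 32, min_overlap = 0.1,
                                 init = "identity", seed = 0L) {
  list(metric = match.arg(metric), type = match.arg(type),
       levels = levels, maxit = rep_len(maxit, length(levels)),
       nbins = nbins, min_overlap = min_overlap, init = init,
       seed = as.integer(seed))
}

params_to_transform <- function(par, type, center) {
  tr <- par[1:3]
  rot <- if (type %in% c("rigid", "similarity", "affine")) par[4:6] else c(0, 0, 0)
  logs <- switch(type,
                 affine = par[7:9],
                 similarity = rep(par[7], 3),
                 c(0, 0, 0))
  shear <- if (type == "affine") par[10:12] else c(0, 0, 0)
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Sh <- diag(3); Sh[1, 2] <- shear[1]; Sh[1, 3] <- shear[2]; Sh[2, 3] <- shear[3]
  M <- Rz %*% Ry %*% Rx %*% Sh %*% diag(exp(logs))
  affine_transform(M, center - M %*% center + tr)
}

n_params <- function(type)
  switch(type, translation = 3L, rigid = 6L, similarity = 7L, affine = 12L)

similarity_metric <- function(fixed_vals, moving_vals, metric, nbins) {
  ok <- !is.na(moving_vals)
  n <- sum(ok)
  if (n < 16) return(list(value = -Inf, overlap = n))
  f <- fixed_vals[ok]; m <- moving_vals[ok]
  val <- switch(metric,
    mse = -mean((f - m)^2),
    ncc = {
      sf <- stats::sd(f); sm <- stats::sd(m)
      if (sf == 0 || sm == 0) 0 else abs(stats::cor(f, m))
    },
    nmi = {
      fb <- pmin(pmax(floor((f - min(f)) / ((max(f) - min(f)) / nbins + 1e-300)),
                      0), nbins - 1)
      mb <- pmin(pmax(floor((m - min(m)) / ((max(m) - min(m)) / nbins + 1e-300)),
                      0), nbins - 1)
      joint <- tabulate(fb * nbins + mb + 1, nbins * nbins) / n
      pf <- tabulate(fb + 1, nbins) / n
      pm <- tabulate(mb + 1, nbins) / n
      h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
      hj <- h(joint)
      if (hj == 0) 2 else (h(pf) + h(pm)) / hj
    })
  list(value = val, overlap = n)
}

#' Affine registration of one volume to another
#'
#' Multi-resolution maximization of an intensity-similarity criterion: a
#' whole-voxel translation scan captures the basin at each level, then
#' deterministic coordinate descent with step halving refines to sub-voxel
#' precision (the binned-histogram metric is piecewise-flat, which defeats
#' purely local simplex search). The returned transform maps fixed-image
#' world coordinates to moving-image world coordinates (so
#' `resample(moving, t, grid = fixed)` aligns the moving image onto the
#' fixed grid). At the coarsest level only the translation is optimized;
#' the full requested transform family is optimized at the finer levels.
#'
#' @param moving,fixed [volume()] objects.
#' @param control a [registration_control()] list.
#' @return an [affine_transform()] with attributes `similarity` (final
#'   metric value) and `overlap` (voxel overlap fraction at the solution).
#' @export
register_affine <- function(moving, fixed, control = registration_control()) {
  ctl <- control
  center <- fixed$affine[1:3, 1:3] %*% ((dim(fixed$data) - 1) / 2) +
    fixed$affine[1:3, 4]
  np <- n_params(ctl$type)
  par <- rep(0, np)
  best <- list(par = par, value = -Inf, overlap = 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(ctl$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (li in seq_along(ctl$levels)) {
    f <- ctl$levels[li]
    # metric values are not comparable across resolutions: keep the warm
    #-start parameters but restart the best-value tracking per level
    best$value <- -Inf
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    w <- world_coords(fx$affine, dim(fx$data))
    inv_src <- solve(mv$affine[1:3, 1:3])
    src_t <- mv$affine[1:3, 4]
    fvals <- as.vector(fx$data)
    active <- if (li == 1 && ctl$type != "translation") 1:3 else seq_len(np)
    objective <- function(p_active) {
      p <- best$par
      p[active] <- p_active
      t <- params_to_transform(p, ctl$type, center)
      vox <- inv_src %*% (apply_transform(t, w) - src_t)
      mvals <- trilinear_sample(mv$data, vox, background = NA_real_)
      s <- similarity_metric(fvals, mvals, ctl$metric, ctl$nbins)
      if (s$value > best$value ||
          (s$value == best$value && identical(p, best$par))) {
        best <<- list(par = p, value = s$value, overlap = s$overlap / length(fvals))
      }
      if (!is.finite(s$value)) 1e10 else -s$value
    }
    objective(best$par[active])  # evaluate the warm start so it can win ties
    # capture the basin with a whole-voxel translation scan around the
    # warm start: the binned-histogram metric is near-flat at sub-voxel
    # steps, so a purely local search can stall far from the optimum
    span <- if (li == 1) 3 else 2
    vstep <- max(fx$spacing)
    offs <- as.matrix(expand.grid(-span:span, -span:span, -span:span)) * vstep
    start <- best$par
    for (k in seq_len(nrow(offs))) {
      p <- start
      p[1:3] <- p[1:3] + offs[k, ]
      objective(p[active])
    }
    # deterministic coordinate descent with step halving, robust on the
    # piecewise-flat metric surface
    steps <- c(rep(vstep, 3), rep(0.04, 3), rep(0.04, 3), rep(0.04, 3))[active]
    min_step <- c(rep(0.05 * min(fx$spacing), 3), rep(0.002, 9))[active]
    evals <- 0L
    while (evals < ctl$maxit[li] * length(active) &&
           any(steps > min_step)) {
      improved <- FALSE
      for (i in seq_along(active)) {
        for (sgn in c(1, -1)) {
          p <- best$par[active]
          p[i] <- p[i] + sgn * steps[i]
          prev <- best$value
          objective(p)
          evals <- evals + 1L
          if (best$value > prev) improved <- TRUE
        }
      }
      if (!improved) steps <- steps / 2
    }
  }
  if (best$overlap < ctl$min_overlap || !is.finite(best$value))
    stop(sprintf(paste0("registration failed to converge: overlap fraction ",
                        "%.3f below %.3f (final similarity %.4g)"),
                 best$overlap, ctl$min_overlap, best$value))
  out <- params_to_transform(best$par, ctl$type, center)
  attr(out, "similarity") <- best$value
  attr(out, "overlap") <- best$overlap
  out
}
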