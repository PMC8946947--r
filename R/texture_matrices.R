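# Texture-matrix machinery: discretization and the GLCM / GLRLM / GLSZM /
# GLDM / NGTDM builders. All matrices are computed on the cropped bounding
# box of the ROI with level 0 marking out-of-ROI voxels.

#' The 13 unique 3D direction vectors
#'
#' One representative of each +-pair of the 26 neighbors of a voxel; the
#' angle set used for co-occurrence and run-length accumulation.
#' @return 13 x 3 integer matrix.
#' @export
texture_angles_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  unname(g[keep, , drop = FALSE])
}

crop_to_roi <- function(arr, sel) {
  ix <- range(which(apply(sel, 1, any)))
  iy <- range(which(apply(sel, 2, any)))
  iz <- range(which(apply(sel, 3, any)))
  list(arr = arr[ix[1]:ix[2], iy[1]:iy[2], iz[1]:iz[2], drop = FALSE],
       sel = sel[ix[1]:ix[2], iy[1]:iy[2], iz[1]:iz[2], drop = FALSE],
       offset = c(ix[1], iy[1], iz[1]) - 1L)
}

#' Discretize intensities within an ROI
#'
#' Fixed-bin-width rule: `level = floor((x - min) / width) + 1`; a constant
#' ROI maps to a single level. With `bins` given instead, the range is split
#' into that many equal bins (the top edge maps to the last bin).
#'
#' @param vol a [volume()].
#' @param mask a [label_mask()] on the same grid, or a logical array.
#' @param structure structure name (ignored when `mask` is logical).
#' @param width fixed bin width in intensity units (default 25).
#' @param bins fixed bin count (overrides `width` when non-NULL).
#' @return `iron_droi`: list with `levels` (3D integer array on the ROI
#'   bounding box, 0 outside the ROI), `Ng`, `mask`, `spacing`, `binning`.
#' @export
discretize <- function(vol, mask, structure = "putamen", width = 25,
                       bins = NULL) {
  sel <- if (is.logical(mask)) mask else structure_mask(mask, structure)
  if (!identical(dim(sel), dim(vol$data)))
    stop("mask is not on the volume grid")
  if (!any(sel)) stop("empty ROI")
  x <- vol$data[sel]
  if (!all(is.finite(x))) stop("non-finite intensities inside the ROI")
  cr <- crop_to_roi(vol$data, sel)
  lo <- min(x); hi <- max(x)
  if (is.null(bins)) {
    if (width <= 0) stop("bin width must be positive")
    lev <- floor((cr$arr - lo) / width) + 1
    ng <- floor((hi - lo) / width) + 1
    binning <- list(rule = "width", width = width)
  } else {
    if (bins < 1) stop("bin count must be >= 1")
    w <- (hi - lo) / bins
    lev <- if (w == 0) array(1, dim(cr$arr)) else
      pmin(floor((cr$arr - lo) / w) + 1, bins)
    ng <- bins
    binning <- list(rule = "count", bins = bins)
  }
  lev[!cr$sel] <- 0
  structure(list(levels = array(as.integer(lev), dim(cr$arr)),
                 Ng = as.integer(ng), mask = cr$sel,
                 spacing = vol$spacing, binning = binning),
            class = "iron_droi")
}

#' @export
print.iron_droi <- function(x, ...) {
  cat(sprintf("<iron_droi> %d in-ROI voxels in a %s box, Ng = %d\n",
              sum(x$mask), paste(dim(x$levels), collapse = "x"), x$Ng))
  invisible(x)
}

shifted_pairs <- function(L, off) {
  # level pairs (a at voxel, b at voxel + off) fully inside the box
  d <- dim(L)
  r <- lapply(1:3, function(k) {
    lo <- max(1L, 1L - off[k]); hi <- min(d[k], d[k] - off[k])
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(vapply(r, length, 1L) < 1)) return(NULL)
  a <- L[r[[1]], r[[2]], r[[3]], drop = FALSE]
  b <- L[r[[1]] + off[1], r[[2]] + off[2], r[[3]] + off[3], drop = FALSE]
  list(a = as.integer(a), b = as.integer(b))
}

#' Gray-level co-occurrence matrices
#'
#' For each direction, counts in-ROI voxel pairs separated by
#' `delta * angle`, accumulated symmetrically and normalized per angle.
#' Angles with no valid pair are flagged empty.
#'
#' @param d an `iron_droi` from [discretize()].
#' @param delta neighbor distance in voxels (>= 1).
#' @param angles direction matrix (default [texture_angles_3d()]).
#' @return list of class `iron_glcm_set`: `matrices` (per-angle Ng x Ng
#'   normalized matrices, `NULL` when empty), `delta`, `Ng`.
#' @export
compute_glcm <- function(d, delta, angles = texture_angles_3d()) {
  if (delta < 1) stop("delta must be >= 1")
  ng <- d$Ng
  mats <- vector("list", nrow(angles))
  for (ai in seq_len(nrow(angles))) {
    p <- shifted_pairs(d$levels, angles[ai, ] * delta)
    if (is.null(p)) next
    keep <- p$a > 0L & p$b > 0L
    if (!any(keep)) next
    counts <- tabulate((p$a[keep] - 1L) * ng + p$b[keep], ng * ng)
    m <- matrix(counts, ng, ng, byrow = TRUE)
    m <- m + t(m)                     # symmetric accumulation
    mats[[ai]] <- m / sum(m)
  }
  structure(list(matrices = mats, delta = delta, Ng = ng,
                 angles = angles), class = "iron_glcm_set")
}

run_lengths <- function(L, dir) {
  # maximal same-level runs along one direction; returns matrix of
  # (level, length) rows including level-0 runs (dropped by the caller)
  d <- dim(L)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  ax <- which(dir != 0)[1]
  t <- idx[, ax] * sign(dir[ax])
  line <- idx - outer(t, dir)         # constant along each line
  B <- 3 * max(d) + 1                 # exceeds the span of any line coord
  key <- (line[, 1] - min(line[, 1])) +
    (line[, 2] - min(line[, 2])) * B +
    (line[, 3] - min(line[, 3])) * B^2
  o <- order(key, t)
  lv <- as.integer(L)[o]
  newrun <- c(TRUE, key[o][-1] != key[o][-length(o)] |
                lv[-1] != lv[-length(lv)])
  starts <- which(newrun)
  lens <- diff(c(starts, length(lv) + 1L))
  cbind(level = lv[starts], len = lens)
}

#' Gray-level run-length matrices over the 13 directions
#'
#' @inheritParams compute_glcm
#' @return list of class `iron_glrlm_set`: per-direction count matrices
#'   (levels x run length).
#' @export
compute_glrlm <- function(d, angles = texture_angles_3d()) {
  ng <- d$Ng
  maxlen <- max(dim(d$levels))
  mats <- vector("list", nrow(angles))
  for (ai in seq_len(nrow(angles))) {
    rl <- run_lengths(d$levels, angles[ai, ])
    rl <- rl[rl[, "level"] > 0L, , drop = FALSE]
    if (nrow(rl) == 0) next
    counts <- tabulate((rl[, "level"] - 1L) * maxlen + rl[, "len"],
                       ng * maxlen)
    mats[[ai]] <- matrix(counts, ng, maxlen, byrow = TRUE)
  }
  structure(list(matrices = mats, Ng = ng, Np = sum(d$mask),
                 angles = angles), class = "iron_glrlm_set")
}

neighbor_offsets_26 <- function(dpad) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  g[, 1] + g[, 2] * dpad[1] + g[, 3] * dpad[1] * dpad[2]
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal level within the ROI.
#'
#' @inheritParams compute_glcm
#' @return list of class `iron_glszm`: `matrix` (levels x zone size counts),
#'   `Ng`, `Np`.
#' @export
compute_glszm <- function(d) {
  dm <- dim(d$levels)
  dpad <- dm + 2L
  P <- array(0L, dpad)
  P[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- d$levels
  offs <- neighbor_offsets_26(dpad)
  np <- sum(d$mask)
  zones <- list()
  for (g in sort(unique(d$levels[d$levels > 0]))) {
    A <- P == g
    todo <- which(A)
    A2 <- A
    for (seed in todo) {
      if (!A2[seed]) next
      A2[seed] <- FALSE
      frontier <- seed
      size <- 1L
      while (length(frontier)) {
        cand <- unique(as.vector(outer(frontier, offs, `+`)))
        cand <- cand[cand >= 1 & cand <= length(A2)]
        cand <- cand[A2[cand]]
        A2[cand] <- FALSE
        size <- size + length(cand)
        frontier <- cand
      }
      zones[[length(zones) + 1L]] <- c(g, size)
    }
  }
  z <- do.call(rbind, zones)
  maxsz <- max(z[, 2])
  counts <- tabulate((z[, 1] - 1L) * maxsz + z[, 2], d$Ng * maxsz)
  structure(list(matrix = matrix(counts, d$Ng, maxsz, byrow = TRUE),
                 Ng = d$Ng, Np = np), class = "iron_glszm")
}

#' Gray-level dependence matrix
#'
#' The dependence of a voxel is the number of its 26-neighbors (inside the
#' ROI) whose level differs from the center by at most `alpha`.
#'
#' @inheritParams compute_glcm
#' @param alpha dependence tolerance (default 0).
#' @return list of class `iron_gldm`: `matrix` with rows = levels and
#'   columns indexed by dependence + 1, `Ng`, `Np`.
#' @export
compute_gldm <- function(d, alpha = 0) {
  L <- d$levels
  dep <- array(0L, dim(L))
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  for (k in seq_len(nrow(g))) {
    p <- shifted_pairs(L, g[k, ])
    if (is.null(p)) next
    ok <- p$a > 0L & p$b > 0L & abs(p$a - p$b) <= alpha
    inc <- array(0L, dim(L))
    dd <- dim(L); off <- g[k, ]
    r <- lapply(1:3, function(j) {
      lo <- max(1L, 1L - off[j]); hi <- min(dd[j], dd[j] - off[j])
      lo:hi
    })
    block <- array(0L, vapply(r, length, 1L))
    block[ok] <- 1L
    inc[r[[1]], r[[2]], r[[3]]] <- block
    dep <- dep + inc
  }
  sel <- L > 0L
  maxdep <- max(dep[sel]) + 1L
  counts <- tabulate((L[sel] - 1L) * maxdep + dep[sel] + 1L, d$Ng * maxdep)
  structure(list(matrix = matrix(counts, d$Ng, maxdep, byrow = TRUE),
                 Ng = d$Ng, Np = sum(sel), alpha = alpha),
            class = "iron_gldm")
}

box_sum <- function(arr, r) {
  # sum of arr over the Chebyshev-radius-r window around every voxel
  d <- dim(arr)
  cum_axis <- function(a, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, d[axis], prod(d[-axis]))
    m <- matrix(apply(m, 2, cumsum), d[axis])
    aperm(array(m, d[perm]), order(perm))
  }
  cs <- cum_axis(cum_axis(cum_axis(arr, 1), 2), 3)
  Z <- array(0, d + 1L)
  Z[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- cs
  hi <- lapply(1:3, function(k) pmin(seq_len(d[k]) + r, d[k]) + 1L)
  lo <- lapply(1:3, function(k) pmax(seq_len(d[k]) - r, 1L))
  Z[hi[[1]], hi[[2]], hi[[3]]] - Z[lo[[1]], hi[[2]], hi[[3]]] -
    Z[hi[[1]], lo[[2]], hi[[3]]] - Z[hi[[1]], hi[[2]], lo[[3]]] +
    Z[lo[[1]], lo[[2]], hi[[3]]] + Z[lo[[1]], hi[[2]], lo[[3]]] +
    Z[hi[[1]], lo[[2]], lo[[3]]] - Z[lo[[1]], lo[[2]], lo[[3]]]
}

#' Neighboring gray-tone difference matrix
#'
#' For each level i, `s_i` sums |i - mean of in-ROI neighbors| over ROI
#' voxels of level i, the neighborhood being the Chebyshev ball of radius
#' `delta` minus the center. Voxels with no in-ROI neighbor are excluded.
#'
#' @inheritParams compute_glcm
#' @return list of class `iron_ngtdm`: data frame with `i`, `n`, `p`, `s`
#'   per occupied level, plus `Nvp` (valid voxels) and `delta`.
#' @export
compute_ngtdm <- function(d, delta) {
  if (delta < 1) stop("delta must be >= 1")
  L <- d$levels
  m <- (L > 0L) + 0
  sums <- box_sum(L + 0, delta) - L
  cnts <- box_sum(m, delta) - m
  valid <- L > 0L & cnts > 0
  nvp <- sum(valid)
  if (nvp == 0) {
    tab <- data.frame(i = integer(), n = integer(), p = numeric(),
                      s = numeric())
  } else {
    i <- L[valid]
    a <- sums[valid] / cnts[valid]
    sdiff <- abs(i - a)
    n <- tabulate(i, d$Ng)
    s <- vapply(seq_len(d$Ng), function(g) sum(sdiff[i == g]), numeric(1))
    occ <- which(n > 0)
    tab <- data.frame(i = occ, n = n[occ], p = n[occ] / nvp, s = s[occ])
  }
  structure(list(table = tab, Nvp = nvp, Ng = d$Ng, delta = delta),
            class = "iron_ngtdm")
}
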