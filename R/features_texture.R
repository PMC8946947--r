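# Feature definitions over the texture matrices. Per-angle families (GLCM,
# GLRLM) compute features for each direction and average; angles without a
# valid matrix are skipped from the average.

.eps <- 2.2e-16

glcm_features_one <- function(P, ng) {
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * P); muy <- sum(j * P)
  sigx <- sqrt(sum((i - mux)^2 * P)); sigy <- sqrt(sum((j - muy)^2 * P))
  # diagonal (difference) and cross-diagonal (sum) probabilities
  k_diff <- 0:(ng - 1)
  pdiff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  psum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(k_diff * pdiff)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy <- -sum(P[P > 0] * log2(P[P > 0]))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxy + .eps))
  hxy2 <- -sum(pxy * log2(pxy + .eps))
  imc1 <- if (max(hx, hy) == 0) 0 else (hxy - hxy1) / max(hx, hy)
  imc2 <- if (ng == 1 || hxy2 < hxy) 0 else sqrt(1 - exp(-2 * (hxy2 - hxy)))
  mcc <- if (ng == 1) 0 else {
    # Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) py(k))
    Q <- (P / pmax(px, .eps)) %*% t(sweep(P, 2, pmax(py, .eps), "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  corr <- if (sigx * sigy == 0) 1 else (sum(i * j * P) - mux * muy) / (sigx * sigy)
  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0])),
    DifferenceVariance = sum((k_diff - da)^2 * pdiff),
    Id = sum(pdiff / (1 + k_diff)),
    Idm = sum(pdiff / (1 + k_diff^2)),
    Idmn = sum(pdiff / (1 + (k_diff / ng)^2)),
    Idn = sum(pdiff / (1 + k_diff / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (ng == 1) 0 else sum(pdiff[-1] / k_diff[-1]^2),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * psum),
    SumEntropy = -sum(psum[psum > 0] * log2(psum[psum > 0])),
    SumSquares = sum((i - mux)^2 * P))
}

#' GLCM features averaged over angles
#'
#' Computes the 24-feature co-occurrence set for every non-empty per-angle
#' matrix and averages feature values over angles. Names carry the class
#' prefix and the neighbor distance as suffix (e.g. `glcm_Autocorrelation7`).
#'
#' @param mats an `iron_glcm_set` from [compute_glcm()].
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(mats) {
  keep <- !vapply(mats$matrices, is.null, logical(1))
  if (!any(keep)) stop("all angle matrices are empty at delta = ", mats$delta)
  vals <- vapply(mats$matrices[keep], glcm_features_one, numeric(24),
                 ng = mats$Ng)
  out <- rowMeans(vals)
  names(out) <- paste0("glcm_", rownames(vals), mats$delta)
  out
}

rlm_features_one <- function(P, np) {
  nr <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / nr
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(ShortRunEmphasis = sum(P / j^2) / nr,
    LongRunEmphasis = sum(P * j^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nr^2,
    RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    RunVariance = sum((j - mu_j)^2 * p),
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr)
}

#' GLRLM features averaged over the 13 directions
#'
#' @param d an `iron_droi` from [discretize()].
#' @return named numeric vector of 16 features, prefix `glrlm_`.
#' @export
compute_glrlm_features <- function(d) {
  set <- compute_glrlm(d)
  keep <- !vapply(set$matrices, is.null, logical(1))
  if (!any(keep)) stop("empty ROI: no runs found")
  vals <- vapply(set$matrices[keep], rlm_features_one, numeric(16),
                 np = set$Np)
  out <- rowMeans(vals)
  names(out) <- paste0("glrlm_", rownames(vals))
  out
}

#' GLSZM features
#'
#' @inheritParams compute_glrlm_features
#' @return named numeric vector of 16 features, prefix `glszm_`.
#' @export
compute_glszm_features <- function(d) {
  z <- compute_glszm(d)
  P <- z$matrix
  nz <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  out <- c(SmallAreaEmphasis = sum(P / j^2) / nz,
           LargeAreaEmphasis = sum(P * j^2) / nz,
           GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
           GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nz^2,
           SizeZoneNonUniformity = sum(colSums(P)^2) / nz,
           SizeZoneNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
           ZonePercentage = nz / z$Np,
           GrayLevelVariance = sum((i - mu_i)^2 * p),
           ZoneVariance = sum((j - mu_j)^2 * p),
           ZoneEntropy = -sum(p[p > 0] * log2(p[p > 0])),
           LowGrayLevelZoneEmphasis = sum(P / i^2) / nz,
           HighGrayLevelZoneEmphasis = sum(P * i^2) / nz,
           SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
           SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
           LargeAreaLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
           LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz)
  names(out) <- paste0("glszm_", names(out))
  out
}

#' GLDM features
#'
#' @inheritParams compute_glrlm_features
#' @param alpha dependence tolerance (default 0).
#' @return named numeric vector of 14 features, prefix `gldm_`.
#' @export
compute_gldm_features <- function(d, alpha = 0) {
  g <- compute_gldm(d, alpha)
  P <- g$matrix
  nz <- sum(P)
  i <- row(P); j <- col(P)   # j = dependence + 1
  p <- P / nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  out <- c(SmallDependenceEmphasis = sum(P / j^2) / nz,
           LargeDependenceEmphasis = sum(P * j^2) / nz,
           GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
           DependenceNonUniformity = sum(colSums(P)^2) / nz,
           DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
           GrayLevelVariance = sum((i - mu_i)^2 * p),
           DependenceVariance = sum((j - mu_j)^2 * p),
           DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
           LowGrayLevelEmphasis = sum(P / i^2) / nz,
           HighGrayLevelEmphasis = sum(P * i^2) / nz,
           SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
           SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
           LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
           LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz)
  names(out) <- paste0("gldm_", names(out))
  out
}

#' NGTDM features at one neighbor distance
#'
#' The five-feature neighboring gray-tone difference set (Coarseness,
#' Contrast, Busyness, Complexity, Strength), suffixed with the distance.
#'
#' @inheritParams compute_glrlm_features
#' @param delta Chebyshev neighborhood radius in voxels.
#' @return named numeric vector of 5 features, prefix `ngtdm_`.
#' @export
compute_ngtdm_features <- function(d, delta) {
  m <- compute_ngtdm(d, delta)
  tb <- m$table
  if (nrow(tb) == 0) stop("empty ROI for NGTDM at delta = ", delta)
  nvp <- m$Nvp
  ngp <- nrow(tb)
  i <- tb$i; p <- tb$p; s <- tb$s; n <- tb$n
  coarse <- 1 / max(sum(p * s), 1e-30)
  contrast <- if (ngp == 1) 0 else {
    (sum(outer(p, p) * outer(i, i, `-`)^2) / (ngp * (ngp - 1))) *
      (sum(s) / nvp)
  }
  busy_den <- sum(abs(outer(i * p, i * p, `-`)))
  busy <- if (busy_den == 0) 0 else sum(p * s) / busy_den
  cplx <- sum(abs(outer(i, i, `-`)) *
                (outer(p * s, p * s, `+`)) / outer(p, p, `+`)) / nvp
  strength <- if (sum(s) == 0) 0 else
    sum(outer(p, p, `+`) * outer(i, i, `-`)^2) / sum(s)
  out <- c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
           Complexity = cplx, Strength = strength)
  names(out) <- paste0("ngtdm_", names(out), delta)
  out
}
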