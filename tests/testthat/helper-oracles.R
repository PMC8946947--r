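# Independent brute-force oracles for the texture matrices: plain nested
# loops over voxels, written without reference to the package internals.

make_droi <- function(levels, spacing = c(1, 1, 1)) {
  structure(list(levels = array(as.integer(levels), dim(levels)),
                 Ng = max(levels), mask = levels > 0L,
                 spacing = spacing, binning = list(rule = "direct")),
            class = "iron_droi")
}

rand_droi <- function(seed, dims, ng) {
  set.seed(seed)
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  lev[array(runif(prod(dims)) < 0.25, dims)] <- 0L  # carve out non-ROI holes
  if (!any(lev > 0)) lev[1] <- 1L
  make_droi(lev)
}

all_angles <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  unname(g[keep, , drop = FALSE])
}

bf_glcm <- function(L, ng, delta, angle) {
  d <- dim(L)
  M <- matrix(0, ng, ng)
  off <- angle * delta
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- L[x, y, z]
    if (a == 0) next
    p <- c(x, y, z) + off
    if (any(p < 1) || any(p > d)) next
    b <- L[p[1], p[2], p[3]]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1
  }
  M <- M + t(M)
  if (sum(M) == 0) NULL else M / sum(M)
}

bf_glrlm <- function(L, ng, dir) {
  d <- dim(L)
  maxlen <- max(d)
  M <- matrix(0, ng, maxlen)
  seen <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (seen[x, y, z] || L[x, y, z] == 0) next
    prev <- c(x, y, z) - dir
    if (all(prev >= 1) && all(prev <= d) &&
        L[prev[1], prev[2], prev[3]] == L[x, y, z]) next  # not a run start
    len <- 0
    p <- c(x, y, z)
    while (all(p >= 1) && all(p <= d) && L[p[1], p[2], p[3]] == L[x, y, z]) {
      seen[p[1], p[2], p[3]] <- TRUE
      len <- len + 1
      p <- p + dir
    }
    M[L[x, y, z], len] <- M[L[x, y, z], len] + 1
  }
  M
}

bf_zones <- function(L) {
  # 26-connected equal-level components; returns (level, size) rows
  d <- dim(L)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- NULL
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (seen[x, y, z] || L[x, y, z] == 0) next
    g <- L[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        if (!seen[q[1], q[2], q[3]] && L[q[1], q[2], q[3]] == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones <- rbind(zones, c(g, size))
  }
  zones
}

bf_gldm <- function(L, ng, alpha = 0) {
  d <- dim(L)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  deps <- NULL
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (L[x, y, z] == 0) next
    dep <- 0
    for (k in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[k, ]
      if (any(q < 1) || any(q > d)) next
      b <- L[q[1], q[2], q[3]]
      if (b > 0 && abs(b - L[x, y, z]) <= alpha) dep <- dep + 1
    }
    deps <- rbind(deps, c(L[x, y, z], dep))
  }
  maxdep <- max(deps[, 2]) + 1
  M <- matrix(0, ng, maxdep)
  for (i in seq_len(nrow(deps)))
    M[deps[i, 1], deps[i, 2] + 1] <- M[deps[i, 1], deps[i, 2] + 1] + 1
  M
}

bf_ngtdm <- function(L, ng, delta) {
  d <- dim(L)
  s <- numeric(ng); n <- integer(ng); nvp <- 0
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- L[x, y, z]
    if (i == 0) next
    nb <- c()
    for (dx in -delta:delta) for (dy in -delta:delta) for (dz in -delta:delta) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (any(q < 1) || any(q > d)) next
      b <- L[q[1], q[2], q[3]]
      if (b > 0) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    nvp <- nvp + 1
    n[i] <- n[i] + 1L
    s[i] <- s[i] + abs(i - mean(nb))
  }
  list(s = s, n = n, nvp = nvp)
}

# independent re-derivation of the 24 co-occurrence features from a
# normalized symmetric matrix, written directly from the textbook formulas
ref_glcm_features <- function(P) {
  ng <- nrow(P)
  eps <- 2.2e-16
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; for (i in 1:ng) for (j in 1:ng) mux <- mux + i * P[i, j]
  muy <- 0; for (i in 1:ng) for (j in 1:ng) muy <- muy + j * P[i, j]
  sx2 <- 0; sy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    sx2 <- sx2 + (i - mux)^2 * P[i, j]
    sy2 <- sy2 + (j - muy)^2 * P[i, j]
  }
  pd <- numeric(ng); ps <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j] <- ps[i + j] + P[i, j]
  }
  kd <- 0:(ng - 1); ks <- 2:(2 * ng); psv <- ps[ks]
  ac <- sum(outer(1:ng, 1:ng) * P)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- h(P); hx <- h(px); hy <- h(py)
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxpy + eps))
  hxy2 <- -sum(pxpy * log2(pxpy + eps))
  Q <- matrix(0, ng, ng)
  for (i in 1:ng) for (j in 1:ng) {
    acc <- 0
    for (k in 1:ng) acc <- acc + P[i, k] * P[j, k] /
        max(px[i] * py[k], eps)
    Q[i, j] <- acc
  }
  evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  da <- sum(kd * pd)
  c(Autocorrelation = ac,
    ClusterProminence = sum(outer(1:ng, 1:ng, function(i, j)
      (i + j - mux - muy)^4) * P),
    ClusterShade = sum(outer(1:ng, 1:ng, function(i, j)
      (i + j - mux - muy)^3) * P),
    ClusterTendency = sum(outer(1:ng, 1:ng, function(i, j)
      (i + j - mux - muy)^2) * P),
    Contrast = sum(outer(1:ng, 1:ng, function(i, j) (i - j)^2) * P),
    Correlation = if (sx2 * sy2 == 0) 1 else
      (ac - mux * muy) / sqrt(sx2 * sy2),
    DifferenceAverage = da,
    DifferenceEntropy = h(pd),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = sum(pd / (1 + kd)),
    Idm = sum(pd / (1 + kd^2)),
    Idmn = sum(pd / (1 + (kd / ng)^2)),
    Idn = sum(pd / (1 + kd / ng)),
    Imc1 = if (max(hx, hy) == 0) 0 else (hxy - hxy1) / max(hx, hy),
    Imc2 = if (ng == 1 || hxy2 < hxy) 0 else sqrt(1 - exp(-2 * (hxy2 - hxy))),
    InverseVariance = if (ng == 1) 0 else sum(pd[-1] / kd[-1]^2),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = if (ng == 1) 0 else sqrt(max(0, min(1, evq[2]))),
    MaximumProbability = max(P),
    SumAverage = sum(ks * psv),
    SumEntropy = h(psv),
    SumSquares = sx2)
}
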