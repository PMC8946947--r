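test_that("fixed-bin-width discretization follows the floor rule", {
  dims <- c(4, 4, 4)
  sel <- array(TRUE, dims)
  # constant ROI: single level
  d <- discretize(volume(array(42, dims)), sel)
  expect_true(all(d$levels[d$mask] == 1L))
  expect_identical(d$Ng, 1L)
  # values {0, 25, 50} at width 25 map to levels {1, 2, 3}
  v <- volume(array(rep(c(0, 25, 50), length.out = prod(dims)), dims))
  d3 <- discretize(v, sel, width = 25)
  expect_identical(sort(unique(as.vector(d3$levels))), c(1L, 2L, 3L))
  expect_identical(d3$levels[v$data == 25], rep(2L, sum(v$data == 25)))
  # random ROI: level histogram equals an independent binning oracle
  set.seed(31)
  vr <- volume(array(runif(prod(dims), 0, 213), dims))
  mask <- array(runif(prod(dims)) < 0.6, dims)
  dr <- discretize(vr, mask, width = 25)
  x <- vr$data[mask]
  oracle <- tabulate(floor((x - min(x)) / 25) + 1)
  expect_identical(tabulate(dr$levels[dr$mask], length(oracle)), oracle)
  # errors
  expect_error(discretize(vr, mask, width = 0), "positive")
  expect_error(discretize(vr, array(FALSE, dims)), "empty")
})

test_that("co-occurrence matrices match hand-computable cases", {
  # constant 3^3 ROI at distance 1: single entry, normalized to 1
  d <- make_droi(array(1L, c(3, 3, 3)))
  g <- compute_glcm(d, 1)
  for (M in g$matrices) {
    expect_equal(dim(M), c(1, 1))
    expect_equal(M[1, 1], 1)
  }
  # two voxels [1, 2] along x: symmetric entries 0.5 / 0.5
  lev <- array(0L, c(2, 1, 1)); lev[, 1, 1] <- c(1L, 2L)
  d2 <- make_droi(lev)
  g2 <- compute_glcm(d2, 1)
  ax <- which(apply(texture_angles_3d(), 1, function(a)
    all(a == c(1, 0, 0))))
  expect_equal(g2$matrices[[ax]],
               matrix(c(0, 0.5, 0.5, 0), 2, 2))
  # angles without pairs are flagged empty, not fabricated
  empties <- vapply(g2$matrices, is.null, logical(1))
  expect_true(any(empties))
  expect_error(compute_glcm(d2, 0), "delta")
})

test_that("texture matrices equal brute-force enumeration on seeded ROIs", {
  angles <- all_angles()
  for (seed in 1:8) {
    dims <- c(sample(3:6, 1), sample(3:6, 1), sample(3:6, 1))
    d <- rand_droi(seed * 100, dims, ng = 4)
    ng <- d$Ng
    for (delta in c(1, 2)) {
      g <- compute_glcm(d, delta)
      for (ai in seq_len(nrow(angles))) {
        expect_equal(g$matrices[[ai]],
                     bf_glcm(d$levels, ng, delta, angles[ai, ]),
                     tolerance = 1e-12,
                     info = sprintf("glcm seed %d delta %d angle %d",
                                    seed, delta, ai))
      }
    }
    rl <- compute_glrlm(d)
    for (ai in seq_len(nrow(angles))) {
      M <- rl$matrices[[ai]]
      B <- bf_glrlm(d$levels, ng, angles[ai, ])
      expect_equal(M[, seq_len(ncol(B)), drop = FALSE] + 0, B,
                   info = sprintf("glrlm seed %d angle %d", seed, ai))
    }
    z <- compute_glszm(d)
    zb <- bf_zones(d$levels)
    Mb <- matrix(0, ng, max(zb[, 2]))
    for (i in seq_len(nrow(zb))) Mb[zb[i, 1], zb[i, 2]] <-
        Mb[zb[i, 1], zb[i, 2]] + 1
    expect_equal(z$matrix[, seq_len(ncol(Mb)), drop = FALSE] + 0, Mb,
                 info = paste("glszm seed", seed))
    gd <- compute_gldm(d, 0)
    Db <- bf_gldm(d$levels, ng, 0)
    expect_equal(gd$matrix[, seq_len(ncol(Db)), drop = FALSE] + 0, Db,
                 info = paste("gldm seed", seed))
    for (delta in c(1, 2)) {
      nm <- compute_ngtdm(d, delta)
      ob <- bf_ngtdm(d$levels, ng, delta)
      occ <- which(ob$n > 0)
      expect_equal(nm$table$i, occ)
      expect_equal(nm$table$s, ob$s[occ], tolerance = 1e-10)
      expect_equal(nm$Nvp, ob$nvp)
    }
  }
})

test_that("zones follow 26-connectivity", {
  # checkerboard: the two levels are diagonally 26-connected into 2 zones
  dims <- c(4, 4, 4)
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  lev <- array(1L + (rowSums(idx) %% 2L), dims)
  z <- compute_glszm(make_droi(lev))
  zb <- bf_zones(lev)
  expect_equal(sum(z$matrix), nrow(zb))
  expect_equal(nrow(zb), 2)
  # two separated blobs of one level: two zones of that level
  lev2 <- array(0L, c(7, 3, 3))
  lev2[1:2, 1:2, 1:2] <- 2L
  lev2[6:7, 1:2, 1:2] <- 2L
  z2 <- compute_glszm(make_droi(lev2))
  expect_equal(z2$matrix[2, 8], 2)
  expect_equal(sum(z2$matrix), 2)
})

test_that("dependence counts behave at the degenerate extremes", {
  d <- make_droi(array(1L, c(3, 3, 3)))
  gd <- compute_gldm(d, 0)
  expect_equal(gd$matrix[1, 27], 1)   # the center voxel has 26 dependents
  single <- make_droi(array(1L, c(1, 1, 1)))
  g1 <- compute_gldm(single, 0)
  expect_equal(dim(g1$matrix), c(1, 1))
  expect_equal(g1$matrix[1, 1], 1)    # dependence 0
})

test_that("gray-tone differences match direct enumeration in 1D", {
  lev <- array(0L, c(3, 1, 1)); lev[, 1, 1] <- c(1L, 3L, 1L)
  nm <- compute_ngtdm(make_droi(lev), 1)
  # voxel 1: neighbor {3} -> |1-3| = 2; voxel 2: neighbors {1,1} -> 2;
  # voxel 3: neighbor {3} -> 2. s_1 = 4, s_3 = 2.
  expect_equal(nm$table$i, c(1, 3))
  expect_equal(nm$table$s, c(4, 2))
  expect_equal(nm$table$n, c(2, 1))
})

test_that("normalized matrices are symmetric with unit mass per angle", {
  d <- rand_droi(77, c(5, 5, 5), ng = 5)
  g <- compute_glcm(d, 1)
  for (M in g$matrices) {
    expect_equal(sum(M), 1, tolerance = 1e-12)
    expect_equal(M, t(M), tolerance = 1e-12)
  }
})

test_that("texture features are invariant to whole-voxel translation", {
  set.seed(41)
  base <- array(0L, c(9, 9, 9))
  base[2:6, 2:6, 2:6] <- array(sample.int(4, 125, TRUE), c(5, 5, 5))
  shifted <- array(0L, c(9, 9, 9))
  shifted[4:8, 3:7, 4:8] <- base[2:6, 2:6, 2:6]
  fb <- c(glcm_features(compute_glcm(make_droi(base), 1)),
          compute_glrlm_features(make_droi(base)),
          compute_glszm_features(make_droi(base)),
          compute_gldm_features(make_droi(base)),
          compute_ngtdm_features(make_droi(base), 1))
  fs <- c(glcm_features(compute_glcm(make_droi(shifted), 1)),
          compute_glrlm_features(make_droi(shifted)),
          compute_glszm_features(make_droi(shifted)),
          compute_gldm_features(make_droi(shifted)),
          compute_ngtdm_features(make_droi(shifted), 1))
  expect_identical(fb, fs)
})

test_that("contrast grows with distance on a smooth gradient", {
  # linear ramp: voxels delta apart differ by delta levels
  dims <- c(10, 10, 10)
  lev <- array(rep(1:10, prod(dims) / 10), dims)
  d <- make_droi(lev)
  c1 <- glcm_features(compute_glcm(d, 1))[["glcm_Contrast1"]]
  c7 <- glcm_features(compute_glcm(d, 7))[["glcm_Contrast7"]]
  expect_gte(c7, c1)
})
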