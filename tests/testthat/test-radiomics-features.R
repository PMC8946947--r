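test_that("single-level co-occurrence features take their closed forms", {
  # a constant ROI discretized to level g: the matrix is the single entry
  # (g, g), so Autocorrelation = g^2, JointAverage = g, SumAverage = 2g
  for (g in c(1L, 3L)) {
    P <- matrix(0, g, g); P[g, g] <- 1
    mats <- structure(list(matrices = list(P), delta = 1, Ng = g,
                           angles = matrix(c(1, 0, 0), 1)),
                      class = "iron_glcm_set")
    f <- glcm_features(mats)
    expect_equal(f[[paste0("glcm_Autocorrelation", 1)]], g^2)
    expect_equal(f[[paste0("glcm_JointAverage", 1)]], g)
    expect_equal(f[[paste0("glcm_SumAverage", 1)]], 2 * g)
    expect_equal(f[[paste0("glcm_ClusterShade", 1)]], 0)
  }
})

test_that("Imc2 and MCC stay within their bounds", {
  for (seed in c(3, 14, 25)) {
    d <- rand_droi(seed, c(5, 5, 5), ng = 6)
    f <- glcm_features(compute_glcm(d, 1))
    expect_gte(f[["glcm_Imc21"]], 0)
    expect_lte(f[["glcm_Imc21"]], 1)
    expect_gte(f[["glcm_MCC1"]], 0)
    expect_lte(f[["glcm_MCC1"]], 1 + 1e-9)
  }
})

test_that("co-occurrence features match an independent formula oracle", {
  angles <- all_angles()
  for (seed in c(8, 19)) {
    d <- rand_droi(seed, c(6, 6, 6), ng = 5)
    for (delta in c(1, 2)) {
      f <- glcm_features(compute_glcm(d, delta))
      mats <- lapply(seq_len(nrow(angles)), function(ai)
        bf_glcm(d$levels, d$Ng, delta, angles[ai, ]))
      mats <- mats[!vapply(mats, is.null, logical(1))]
      ref <- rowMeans(vapply(mats, ref_glcm_features, numeric(24)))
      nm <- sub("^glcm_", "", sub("([0-9])$", "", names(f)))
      expect_equal(unname(f), unname(ref[nm]), tolerance = 1e-6)
    }
  }
})

test_that("run features behave on degenerate runs", {
  # one straight run of length 5 at level 2 (uses the aligned direction)
  lev <- array(0L, c(5, 1, 1)); lev[, 1, 1] <- 2L
  d <- make_droi(lev)
  rl <- compute_glrlm(d)
  ax <- which(apply(texture_angles_3d(), 1, function(a)
    all(a == c(1, 0, 0))))
  M <- rl$matrices[[ax]]
  expect_equal(sum(M), 1)            # a single run in total
  expect_equal(M[2, 5], 1)           # at level 2, length 5
  nr <- sum(M)
  expect_equal(sum(rowSums(M)^2) / nr, 1)  # GrayLevelNonUniformity = 1
  p <- M / nr
  expect_equal(-sum(p[p > 0] * log2(p[p > 0])), 0)  # RunEntropy = 0
})

test_that("first-order features match independent statistics", {
  dims <- c(6, 6, 6)
  sel <- array(TRUE, dims)
  # constant ROI: variance and entropy are 0
  fc <- first_order_features(volume(array(9, dims)), sel)
  expect_equal(fc[["firstorder_Variance"]], 0)
  expect_equal(fc[["firstorder_Entropy"]], 0)
  expect_equal(fc[["firstorder_Skewness"]], 0)
  # the texture-safe view contains no signal-scale feature
  filtered <- texture_safe_features(fc)
  banned <- paste0("firstorder_", c("Minimum", "Maximum", "Mean", "Median",
                                    "10Percentile", "90Percentile", "Range"))
  expect_false(any(banned %in% names(filtered)))
  expect_equal(length(fc), 19L)
  # moments against an independent routine
  set.seed(51)
  v <- volume(array(rgamma(prod(dims), 2, 0.1), dims))
  f <- first_order_features(v, sel)
  x <- as.vector(v$data)
  expect_equal(f[["firstorder_Skewness"]], e1071::skewness(x, type = 1),
               tolerance = 1e-9)
  expect_equal(f[["firstorder_Kurtosis"]], e1071::kurtosis(x, type = 1) + 3,
               tolerance = 1e-9)
  expect_equal(f[["firstorder_Variance"]], mean((x - mean(x))^2),
               tolerance = 1e-9)
})

test_that("shape features are exact on boxes and calibrated on balls", {
  grid <- list(spacing = c(1, 1, 1))
  # single voxel of 1 mm spacing: voxel volume 1 mm^3
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  f1 <- shape_features(label_mask(one, grid, legend = c(roi = 1L)), "roi")
  expect_equal(f1[["shape_VoxelVolume"]], 1)
  expect_true(all(is.finite(f1)))
  # a x b x c box
  box <- array(0L, c(20, 20, 20)); box[5:10, 5:12, 5:9] <- 1L
  fb <- shape_features(label_mask(box, grid, legend = c(roi = 1L)), "roi")
  expect_equal(fb[["shape_VoxelVolume"]], 6 * 8 * 5)
  expect_equal(fb[["shape_Maximum3DDiameter"]], sqrt(5^2 + 7^2 + 4^2),
               tolerance = 1e-9)
  # anisotropic spacing scales the voxel volume
  fb2 <- shape_features(label_mask(box, list(spacing = c(0.75, 0.75, 2)),
                                   legend = c(roi = 1L)), "roi")
  expect_equal(fb2[["shape_VoxelVolume"]], 6 * 8 * 5 * 0.75 * 0.75 * 2)
  # digitized ball of radius 8: sphericity within 5% of 1
  dims <- c(24, 24, 24); ctr <- 12.5
  X <- array(rep(1:24, 24 * 24), dims)
  Y <- array(rep(rep(1:24, each = 24), 24), dims)
  Z <- array(rep(1:24, each = 24 * 24), dims)
  ball <- (X - ctr)^2 + (Y - ctr)^2 + (Z - ctr)^2 <= 64
  fs <- shape_features(label_mask(ball + 0L, grid, legend = c(roi = 1L)),
                       "roi")
  expect_lt(abs(fs[["shape_Sphericity"]] - 1), 0.05)
  expect_equal(fs[["shape_MeshVolume"]], 4 / 3 * pi * 512, tolerance = 0.05)
  expect_equal(length(grep("^shape_", names(fs))), 16L)
  expect_equal(length(grep("^shape2D_", names(fs))), 10L)
})

test_that("the full extraction emits 178 uniquely named features", {
  s <- generate_subject(phantom_spec("MSA-P", seed = 3))
  fv <- extract_all(s$swi, s$truth)
  expect_length(fv, 178L)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_true(all(is.finite(fv)))
  # GLCM names: 24 base names x 3 distance suffixes
  glcm_names <- grep("^glcm_", names(fv), value = TRUE)
  expect_length(glcm_names, 72L)
  # the distance suffix is the single last digit (Imc1/Imc2 keep theirs)
  bases <- unique(sub("([0-9])$", "", glcm_names))
  expect_length(bases, 24L)
  expect_setequal(unique(sub(".*([0-9])$", "\\1", glcm_names)),
                  c("1", "4", "7"))
  # determinism: identical inputs give bitwise-identical vectors
  fv2 <- extract_all(s$swi, s$truth)
  expect_identical(fv, fv2)
})

test_that("an ROI too small for a distance is flagged, never dropped", {
  dims <- c(16, 16, 16)
  labs <- array(0L, dims); labs[7:9, 7:9, 7:9] <- 1L
  m <- label_mask(labs, grid = list(spacing = c(1, 1, 1)),
                  legend = c("putamen" = 1L))
  set.seed(61)
  v <- volume(array(runif(prod(dims), 0, 100), dims))
  fv <- extract_all(v, m)
  expect_length(fv, 178L)
  flagged <- attr(fv, "flagged_distances")
  expect_true(all(c(4, 7) %in% flagged))
  expect_true(all(is.na(fv[grep("^glcm_.*4$", names(fv))])))
  expect_true(all(is.finite(fv[grep("^glcm_.*1$", names(fv))])))
})

test_that("laterality parts merge into one ROI before extraction", {
  dims <- c(16, 16, 16)
  labs <- array(0L, dims)
  labs[3:5, 7:9, 7:9] <- 1L
  labs[12:14, 7:9, 7:9] <- 2L
  m_lr <- label_mask(labs, grid = list(spacing = c(1, 1, 1)),
                     legend = c("putamen left" = 1L, "putamen right" = 2L))
  merged <- label_mask((labs > 0) + 0L, grid = list(spacing = c(1, 1, 1)),
                       legend = c("putamen" = 1L))
  set.seed(62)
  v <- volume(array(runif(prod(dims), 0, 100), dims))
  expect_identical(extract_all(v, m_lr), extract_all(v, merged))
})
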