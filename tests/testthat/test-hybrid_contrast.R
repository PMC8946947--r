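make_mask <- function(labs, legend = c("putamen" = 1L,
                                       "globus pallidus" = 2L,
                                       "white matter" = 3L)) {
  label_mask(labs, grid = list(spacing = c(1, 1, 1)), legend = legend)
}

test_that("roi_mean is an exact masked arithmetic mean", {
  labs <- array(0L, c(6, 6, 6))
  labs[2:4, 2:4, 2:4] <- 1L
  m <- make_mask(labs)
  # constant volume
  v <- volume(array(7.5, c(6, 6, 6)))
  expect_equal(roi_mean(v, m, "putamen"), 7.5)
  # two-voxel structure, values 3 and 5
  labs2 <- array(0L, c(6, 6, 6)); labs2[c(1, 2)] <- 2L
  v2 <- volume(array(0, c(6, 6, 6))); v2$data[1] <- 3; v2$data[2] <- 5
  expect_equal(roi_mean(v2, make_mask(labs2), "globus pallidus"), 4)
  # random volume against a brute-force sum/count oracle
  set.seed(5)
  vr <- volume(array(rnorm(6^3), c(6, 6, 6)))
  sel <- labs == 1L
  oracle <- sum(vr$data[sel]) / sum(sel)
  expect_equal(roi_mean(vr, m, "putamen"), oracle, tolerance = 1e-12)
  # empty structure errors
  expect_error(roi_mean(v, m, "white matter"), "no voxels")
})

test_that("the weight solve is the exact least-squares solution", {
  # T1w already matches the template: (w1, w2) = (1, 0)
  sys1 <- list(put_t1w = 110, put_swi = 40, pall_t1w = 95, pall_swi = 80,
               put_mni = 110, pall_mni = 95)
  w <- solve_weights(sys1)
  expect_equal(c(w$w1, w$w2), c(1, 0), tolerance = 1e-12)
  expect_equal(w$residual, 0, tolerance = 1e-20)

  # proportional columns: singularity identified
  sys2 <- list(put_t1w = 100, put_swi = 50, pall_t1w = 80, pall_swi = 40,
               put_mni = 110, pall_mni = 95)
  expect_error(solve_weights(sys2), "singular|collinear")

  # general system against an independent least-squares oracle
  sys3 <- list(put_t1w = 100, put_swi = 50, pall_t1w = 80, pall_swi = 90,
               put_mni = 110, pall_mni = 95)
  w3 <- solve_weights(sys3)
  oracle <- qr.solve(matrix(c(100, 50, 80, 90), 2, 2, byrow = TRUE),
                     c(110, 95))
  expect_equal(c(w3$w1, w3$w2), unname(oracle), tolerance = 1e-10)
  expect_equal(w3$residual, 0, tolerance = 1e-16)
})

test_that("perturbing the solved weights never decreases the objective", {
  sys <- list(put_t1w = 100, put_swi = 50, pall_t1w = 80, pall_swi = 90,
              put_mni = 110, pall_mni = 95)
  w <- solve_weights(sys)
  A <- matrix(c(sys$put_t1w, sys$put_swi, sys$pall_t1w, sys$pall_swi),
              2, 2, byrow = TRUE)
  b <- c(sys$put_mni, sys$pall_mni)
  obj <- function(ww) sum((A %*% ww - b)^2)
  base <- obj(c(w$w1, w$w2))
  offsets <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)) * 1e-4
  for (k in seq_len(nrow(offsets))) {
    expect_gte(obj(c(w$w1, w$w2) + offsets[k, ]), base)
  }
})

test_that("fusion is the voxelwise linear combination", {
  set.seed(6)
  dims <- c(8, 8, 8)
  t1w <- volume(array(runif(prod(dims), 50, 150), dims), modality = "T1w")
  swi <- volume(array(runif(prod(dims), 20, 120), dims), modality = "SWI")
  # w = (1, 0): HC equals T1w
  hc <- fuse(t1w, swi, list(w1 = 1, w2 = 0))
  expect_equal(hc$data, t1w$data, tolerance = 1e-12)
  expect_identical(hc$modality, "HC")
  # w = (0.5, 0.5) on identical inputs: HC equals both
  hc2 <- fuse(t1w, t1w, list(w1 = 0.5, w2 = 0.5))
  expect_equal(hc2$data, t1w$data, tolerance = 1e-12)
  # grid mismatch is an error
  small <- volume(array(0, c(4, 4, 4)))
  expect_error(fuse(t1w, small, list(w1 = 1, w2 = 0)), "grid")
})

test_that("solved weights close the loop: fused ROI means hit the targets", {
  set.seed(7)
  dims <- c(10, 10, 10)
  labs <- array(0L, dims)
  labs[2:4, 2:4, 2:4] <- 1L
  labs[6:8, 6:8, 6:8] <- 2L
  m <- make_mask(labs)
  t1w <- volume(array(runif(prod(dims), 80, 120), dims), modality = "T1w")
  swi <- volume(array(runif(prod(dims), 40, 90), dims), modality = "SWI")
  tpl <- volume(array(0, dims), modality = "template")
  tpl$data[labs == 1L] <- 95
  tpl$data[labs == 2L] <- 88
  sys <- roi_mean_system(t1w, swi, m, tpl, m)
  w <- solve_weights(sys)
  hc <- fuse(t1w, swi, w)
  expect_equal(roi_mean(hc, m, "putamen"), sys$put_mni, tolerance = 1e-6)
  expect_equal(roi_mean(hc, m, "globus pallidus"), sys$pall_mni,
               tolerance = 1e-6)
})

test_that("rescaling SWI rescales w2 and leaves the HC image unchanged", {
  set.seed(8)
  dims <- c(10, 10, 10)
  labs <- array(0L, dims)
  labs[2:4, 2:4, 2:4] <- 1L
  labs[6:8, 6:8, 6:8] <- 2L
  m <- make_mask(labs)
  t1w <- volume(array(runif(prod(dims), 80, 120), dims))
  swi <- volume(array(runif(prod(dims), 40, 90), dims))
  tpl <- volume(array(100, dims))
  tpl$data[labs == 2L] <- 88
  sys <- roi_mean_system(t1w, swi, m, tpl, m)
  w <- solve_weights(sys)
  for (c_ in c(0.5, 3)) {
    swi_c <- swi; swi_c$data <- swi$data * c_
    sys_c <- roi_mean_system(t1w, swi_c, m, tpl, m)
    w_c <- solve_weights(sys_c)
    expect_equal(w_c$w2, w$w2 / c_, tolerance = 1e-9)
    expect_equal(w_c$w1, w$w1, tolerance = 1e-9)
    hc <- fuse(t1w, swi, w)
    hc_c <- fuse(t1w, swi_c, w_c)
    expect_lt(max(abs(hc$data - hc_c$data)), 1e-9)
  }
})
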