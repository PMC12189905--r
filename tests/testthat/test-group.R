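test_that("the GLM t equals the pooled two-sample t for intercept+group designs", {
  set.seed(71)
  n <- 16; V <- 30
  clin <- data.frame(group = rep(c("patient", "control"), each = n / 2))
  stack <- matrix(rnorm(n * V), n, V)
  design <- build_design(clin, covariates = character(0))
  fit <- fit_glm_voxelwise(stack, design)
  for (v in sample(V, 5)) {
    tt <- t.test(stack[clin$group == "patient", v],
                 stack[clin$group == "control", v], var.equal = TRUE)
    expect_equal(fit$t[v], unname(tt$statistic), tolerance = 1e-10)
  }
  expect_equal(fit$df, n - 2)
})

test_that("degenerate designs are refused with informative errors", {
  set.seed(72)
  stack <- matrix(rnorm(10 * 5), 10, 5)
  clin <- data.frame(group = rep("patient", 10))
  design <- build_design(clin, covariates = character(0))
  expect_error(fit_glm_voxelwise(stack, design), "group")

  clin2 <- data.frame(group = rep(c("patient", "control"), each = 5),
                      age = rnorm(10))
  d2 <- build_design(clin2, covariates = "age")
  d2 <- cbind(d2, age2 = d2[, "age"])
  attr(d2, "contrast") <- c(0, 1, 0, 0)
  expect_error(fit_glm_voxelwise(stack, d2), "age2")
})

test_that("pure covariate effects do not inflate the group test", {
  set.seed(73)
  n <- 40; V <- 4000
  clin <- data.frame(group = rep(c("patient", "control"), each = n / 2),
                     age = rnorm(n))
  stack <- outer(clin$age, rnorm(V)) + matrix(rnorm(n * V), n, V)
  design <- build_design(clin, covariates = "age")
  fit <- fit_glm_voxelwise(stack, design)
  p_thresh <- 0.01
  t_crit <- qt(1 - p_thresh / 2, fit$df)
  rate <- mean(abs(fit$t) > t_crit)
  band <- qbinom(c(0.005, 0.995), V, p_thresh) / V
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("thresholding labels constructed blobs at the stated connectivity", {
  d <- c(10, 10, 6)
  mask <- array(TRUE, d)
  tarr <- array(0, d)
  expect_equal(nrow(threshold_and_cluster(tarr[mask], 20, 0.001, mask)), 0)

  # one 5-voxel face-connected blob
  tarr[3, 3, 3] <- 8; tarr[4, 3, 3] <- 8; tarr[5, 3, 3] <- 8
  tarr[3, 4, 3] <- 8; tarr[3, 3, 4] <- 8
  cl <- threshold_and_cluster(tarr[mask], 20, 0.001, mask)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$extent_voxels, 5)
  expect_equal(cl$sign, 1)

  # two blobs touching only at a corner
  tarr2 <- array(0, d)
  tarr2[2:3, 2:3, 2] <- 8
  tarr2[4:5, 4:5, 3] <- 8          # corner contact at (3,3,2)-(4,4,3)
  c26 <- threshold_and_cluster(tarr2[mask], 20, 0.001, mask,
                               connectivity = 26)
  c6 <- threshold_and_cluster(tarr2[mask], 20, 0.001, mask,
                              connectivity = 6)
  expect_equal(nrow(c26), 1)
  expect_equal(nrow(c6), 2)

  # signed clusters are kept separately
  tarr3 <- array(0, d)
  tarr3[2:3, 2, 2] <- 8
  tarr3[7:8, 7, 4] <- -8
  c3 <- threshold_and_cluster(tarr3[mask], 20, 0.001, mask)
  expect_equal(sort(c3$sign), c(-1, 1))
})

test_that("peak MNI coordinates are consistent with the affine", {
  d <- c(10, 10, 6)
  mask <- array(TRUE, d)
  tarr <- array(0, d)
  tarr[4, 5, 3] <- 9
  aff <- rehodyn:::default_affine(d, c(3, 3, 3))
  cl <- threshold_and_cluster(tarr[mask], 20, 0.001, mask, affine = aff)
  expect_equal(c(cl$peak_x_mni, cl$peak_y_mni, cl$peak_z_mni),
               voxel_to_world(c(4, 5, 3), aff))
})

test_that("residual smoothness estimation recovers the applied kernel", {
  d <- c(30, 30, 20); vox <- c(2, 2, 2)
  mask <- array(TRUE, d)
  set.seed(74)
  n <- 8
  res_sm <- matrix(NA_real_, n, prod(d))
  res_raw <- matrix(NA_real_, n, prod(d))
  for (s in seq_len(n)) {
    noise <- array(rnorm(prod(d)), d)
    res_raw[s, ] <- noise
    sm <- gaussian_smooth(scalar_map(noise, voxel_mm = vox), 6,
                          use_mask = FALSE)
    res_sm[s, ] <- sm$data
  }
  est <- estimate_smoothness(res_sm, mask, vox)
  expect_equal(est$fwhm_mm, rep(6, 3), tolerance = 0.15)

  est0 <- estimate_smoothness(res_raw, mask, vox)
  expect_equal(est0$fwhm_mm, vox, tolerance = 0.05)

  expect_error(estimate_smoothness(res_sm[1, , drop = FALSE], mask, vox),
               "at least 2")
  expect_error(estimate_smoothness(matrix(1, 3, prod(d)), mask, vox),
               "constant")
})

test_that("GRF cluster p-values behave as a survival function of extent", {
  p0 <- rehodyn:::grf_cluster_p(0, zt = 3.1, resels = 100,
                                n_mask_voxels = 9216)
  expect_equal(p0, 1)
  ext <- c(1, 5, 10, 50, 100, 500)
  pv <- vapply(ext, rehodyn:::grf_cluster_p, numeric(1), zt = 3.1,
               resels = 100, n_mask_voxels = 9216)
  expect_true(all(diff(pv) <= 0))
  expect_true(all(pv >= 0 & pv <= 1))
  # large clusters on a smooth field are rare under the null
  expect_lt(pv[6], 0.01)
})

test_that("permutation cluster p-values are reproducible and monotone in extent", {
  set.seed(75)
  n <- 16
  d <- c(12, 12, 8)
  mask <- array(TRUE, d)
  clin <- data.frame(group = rep(c("patient", "control"), each = n / 2))
  mk <- function(seed) {
    set.seed(seed)
    zscore_map(gaussian_smooth(scalar_map(array(rnorm(prod(d)), d)), 6))
  }
  maps <- lapply(1:n, function(i) mk(1000 + i))
  # inject a strong patient-specific blob
  for (i in 1:(n / 2)) maps[[i]]$data[4:6, 4:6, 3:5] <-
    maps[[i]]$data[4:6, 4:6, 3:5] + 3
  stack <- rehodyn:::stack_maps(maps, mask)
  design <- build_design(clin, covariates = character(0))
  fit <- fit_glm_voxelwise(stack, design)
  cand <- threshold_and_cluster(fit$t, fit$df, 0.001, mask)
  expect_gte(nrow(cand), 1)
  tab1 <- cluster_pvalues(cand, fit, mask, method = "permutation",
                          stack = stack, design = design, n_perm = 200,
                          seed = 3)
  tab2 <- cluster_pvalues(cand, fit, mask, method = "permutation",
                          stack = stack, design = design, n_perm = 200,
                          seed = 3)
  expect_identical(tab1$cluster_p, tab2$cluster_p)
  ord <- order(tab1$extent_voxels)
  expect_true(all(diff(tab1$cluster_p[ord]) <= 1e-12))
  expect_error(cluster_pvalues(cand, fit, mask, method = "permutation",
                               stack = stack, design = design, n_perm = 0),
               "positive")
  expect_warning(cluster_pvalues(cand, fit, mask, method = "permutation",
                                 stack = stack, design = design,
                                 n_perm = 50), "100")
})

test_that("GRF and permutation agree on an obvious cluster", {
  set.seed(76)
  n <- 16
  d <- c(16, 16, 10)
  mask <- array(TRUE, d)
  clin <- data.frame(group = rep(c("patient", "control"), each = n / 2))
  maps <- lapply(1:n, function(i) {
    set.seed(2000 + i)
    zscore_map(gaussian_smooth(scalar_map(array(rnorm(prod(d)), d)), 6))
  })
  for (i in 1:(n / 2)) maps[[i]]$data[6:9, 6:9, 4:6] <-
    maps[[i]]$data[6:9, 6:9, 4:6] + 3
  stack <- rehodyn:::stack_maps(maps, mask)
  design <- build_design(clin, covariates = character(0))
  fit <- fit_glm_voxelwise(stack, design)
  cand <- threshold_and_cluster(fit$t, fit$df, 0.001, mask)
  big <- which.max(cand$extent_voxels)
  p_perm <- cluster_pvalues(cand, fit, mask, method = "permutation",
                            stack = stack, design = design,
                            n_perm = 300, seed = 4)$cluster_p[big]
  p_grf <- cluster_pvalues(cand, fit, mask, method = "grf")$cluster_p[big]
  expect_lt(p_perm, 0.05)
  expect_lt(p_grf, 0.05)
})

test_that("Dice coefficient counts overlap symmetrically", {
  a <- array(FALSE, c(4, 4, 1)); b <- a
  a[1:2, 1, 1] <- TRUE
  b[2:3, 1, 1] <- TRUE
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(a, a), 1)
  expect_true(is.na(dice_coefficient(a & FALSE, b & FALSE)))
})
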