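test_that("configuration invariants are enforced", {
  expect_error(cohort_config(grid_shape = c(8, 24, 16)), ">= 9")
  expect_error(cohort_config(n_volumes = 50), "window")
  expect_error(tiny_config(clinical_effects = list(
    list(roi = "sync_down", covariate = "thi_score", rho = 1.0))),
    "magnitude must be < 1")
  expect_error(tiny_config(clinical_effects = list(
    list(roi = "nowhere", covariate = "thi_score", rho = 0.3))),
    "unknown region")
  # region that does not fit the grid
  expect_error(cohort_config(
    grid_shape = c(10, 10, 10),
    effect_regions = list(list(name = "big", kind = "reho_up",
                               center = c(9, 5, 5), radius = 3,
                               magnitude = 0.2))),
    "grid too small")
})

test_that("identical seeds reproduce the cohort bit for bit, on disk too", {
  cfg <- tiny_config(n_patients = 1, n_controls = 1, seed = 55)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$subjects[[1]]$bold$data, c2$subjects[[1]]$bold$data)
  expect_identical(c1$subjects[[2]]$motion6, c2$subjects[[2]]$motion6)
  expect_identical(c1$clinical, c2$clinical)

  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  md5_1 <- tools::md5sum(file.path(d1, f1))
  md5_2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(md5_1), unname(md5_2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("NIfTI and motion files round-trip through the readers", {
  cfg <- tiny_config(n_patients = 1, n_controls = 0, seed = 56)
  coh <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "cohRT")
  write_cohort(coh, dir)
  s <- coh$subjects[[1]]
  b <- read_bold(file.path(dir, sprintf("bold_%s.nii.gz", s$subject_id)))
  expect_equal(dim(b), dim(s$bold))
  expect_equal(unclass(b$data), s$bold$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(b$voxel_mm, s$bold$voxel_mm, tolerance = 1e-6)
  expect_equal(b$tr_s, s$bold$tr_s, tolerance = 1e-6)
  m <- as.matrix(read.table(file.path(dir, sprintf("rp_%s.txt", s$subject_id))))
  expect_equal(unname(m), unname(s$motion6), tolerance = 1e-6)
  cl <- read.csv(file.path(dir, "clinical.csv"))
  expect_equal(cl$subject_id, coh$clinical$subject_id)
  unlink(dir, recursive = TRUE)
})

test_that("perfect local synchronization without noise gives ReHo near 1", {
  cfg <- tiny_config(n_patients = 1, n_controls = 1, seed = 57,
                     sync_base = 1, noise_sd = 0,
                     effect_regions = list(), clinical_effects = list())
  s <- generate_subject_bold(cfg, "control", seed = 58)
  pp <- preprocess_bold(s$bold, s$motion6, s$wm, s$csf)
  rh <- reho_map(pp$bold)
  w <- rh$w$data[!is.na(rh$w$data)]
  expect_gt(min(w), 0.999)
})

test_that("zero synchronization reproduces the independent-noise null level", {
  cfg <- tiny_config(n_patients = 1, n_controls = 1, seed = 59,
                     sync_base = 0, effect_regions = list(),
                     clinical_effects = list())
  s <- generate_subject_bold(cfg, "control", seed = 60)
  # ReHo on the raw series (preprocessing filters induce autocorrelation
  # but leave cross-series independence, and the null mean of W depends
  # only on K and n)
  rh <- reho_map(preprocess_bold(s$bold, s$motion6, s$wm, s$csf)$bold)
  w <- rh$w$data[!is.na(rh$w$data)]
  null_level <- null_w_mc(27, cfg$n_volumes - 10, B = 300)
  # bandpass-induced autocorrelation widens the spread of the map mean
  # (~1e-3 across subjects) but not its null expectation
  expect_lt(abs(mean(w) - null_level), 0.004)
})

test_that("expected ReHo increases monotonically with the sync weight", {
  levels <- c(0.2, 0.5, 0.8)
  means <- vapply(seq_along(levels), function(i) {
    cfg <- tiny_config(n_patients = 1, n_controls = 1, seed = 61,
                       sync_base = levels[i], effect_regions = list(),
                       clinical_effects = list())
    m <- vapply(1:3, function(j) {
      s <- generate_subject_bold(cfg, "control", seed = 500 + j)
      pp <- preprocess_bold(s$bold, s$motion6, s$wm, s$csf)
      rh <- reho_map(pp$bold)
      mean(rh$w$data, na.rm = TRUE)
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("effect regions shift regional ReHo and CV in the stated directions", {
  cfg <- tiny_config(seed = 62, n_volumes = 240)
  s <- generate_subject_bold(cfg, "patient", seed = 63)
  pp <- preprocess_bold(s$bold, s$motion6, s$wm, s$csf)
  rh <- reho_map(pp$bold)
  bg <- s$truth$region_labels == 0
  expect_lt(mean(rh$w$data[region_mask(cfg, "sync_down")], na.rm = TRUE),
            mean(rh$w$data[bg], na.rm = TRUE))
  expect_gt(mean(rh$w$data[region_mask(cfg, "sync_up")], na.rm = TRUE),
            mean(rh$w$data[bg], na.rm = TRUE))
  # controls carry no effect
  sc <- generate_subject_bold(cfg, "control", seed = 64)
  expect_equal(sc$truth$sync[region_mask(cfg, "sync_down")][1],
               cfg$sync_base, tolerance = 0.5)
  expect_true(all(sc$truth$modamp == 0))
})

test_that("regional ReHo ordering follows the effect magnitude", {
  mags <- c(0.1, 0.25, 0.4)
  means <- vapply(mags, function(m) {
    cfg <- tiny_config(seed = 70,
                       effect_regions = list(
                         list(name = "up", kind = "reho_up",
                              center = c(6, 6, 5), radius = 1,
                              magnitude = m)),
                       clinical_effects = list())
    s <- generate_subject_bold(cfg, "patient", seed = 71)
    pp <- preprocess_bold(s$bold, s$motion6, s$wm, s$csf)
    rh <- reho_map(pp$bold)
    mean(rh$w$data[region_mask(cfg, "up")], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("a null clinical link stays inside the Fisher null band", {
  cfg <- tiny_config(
    n_patients = 80, n_controls = 0, seed = 65,
    clinical_effects = list(list(roi = "sync_down",
                                 covariate = "thi_score", rho = 0)))
  cl <- generate_clinical(cfg)
  r <- cor(cl$truth_roi$sync_down[1:80], cl$clinical$thi_score[1:80])
  expect_lt(abs(atanh(r)), qnorm(0.975) / sqrt(80 - 3))
})

test_that("a strong configured link is recovered at large n", {
  cfg <- tiny_config(
    n_patients = 200, n_controls = 0, seed = 66,
    clinical_effects = list(list(roi = "sync_down",
                                 covariate = "thi_score", rho = 0.8)))
  cl <- generate_clinical(cfg)
  r <- cor(cl$truth_roi$sync_down[1:200], cl$clinical$thi_score[1:200])
  expect_lt(abs(atanh(r) - atanh(0.8)), qnorm(0.975) / sqrt(200 - 3))
})

test_that("configured links are covered by the Fisher 95% interval across repetitions", {
  hits <- matrix(NA, 100, 2)
  for (b in seq_len(100)) {
    cfg <- cohort_config(n_patients = 102, n_controls = 73, seed = 9000 + b)
    cl <- generate_clinical(cfg)
    pat <- cl$clinical$group == "patient"
    halfw <- qnorm(0.975) / sqrt(102 - 3)
    r1 <- cor(cl$truth_roi$sync_down[pat], cl$clinical$thi_score[pat])
    r2 <- cor(cl$truth_roi$dyn_up[pat], cl$clinical$duration_days[pat])
    hits[b, 1] <- abs(atanh(r1) - atanh(0.39)) <= halfw
    hits[b, 2] <- abs(atanh(r2) - atanh(-0.35)) <= halfw
  }
  expect_gte(mean(hits[, 1]), 0.9)
  expect_gte(mean(hits[, 2]), 0.9)
})

test_that("a patient-free cohort is refused by the group contrast", {
  cfg <- tiny_config(n_patients = 0, n_controls = 3, seed = 67)
  coh <- generate_cohort(cfg, imaging = FALSE)
  expect_true(all(coh$clinical$group == "control"))
  expect_error(analyze_cohort(coh), "both groups|no imaging")
})

test_that("clinical marginals match the configured targets", {
  cfg <- cohort_config(n_patients = 1500, n_controls = 1000, seed = 68)
  cl <- generate_clinical(cfg)$clinical
  pat <- cl[cl$group == "patient", ]
  expect_equal(mean(pat$age), 38.89, tolerance = 0.05)
  expect_equal(mean(pat$pta_db), 73.66, tolerance = 0.02)
  expect_equal(mean(pat$duration_days), 9.03, tolerance = 0.05)
  expect_equal(sd(pat$thi_score), 26.37, tolerance = 0.1)
  ctl <- cl[cl$group == "control", ]
  expect_equal(mean(ctl$pta_db), 13.25, tolerance = 0.05)
  expect_true(all(is.na(ctl$thi_score)))
  expect_true(all(pat$duration_days > 0))
  expect_true(all(pat$thi_score >= 0 & pat$thi_score <= 100))
})
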