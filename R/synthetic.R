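#' Configuration for a synthetic resting-state cohort
#'
#' Defines the ground-truth structure of a simulated two-group study:
#' grid geometry, acquisition timing, where local synchronization is
#' raised/lowered in patients, where it is modulated in time (driving
#' dynamic ReHo), how strongly clinical covariates are tied to regional
#' synchronization, and the marginal distributions of the clinical table.
#'
#' The signal model is a shared-source construction: every voxel's series
#' is `w * g(t) + noise_sd * e(t)` with `g` a source signal common to the
#' neighborhood (here, the whole subject), `w` the voxel's local
#' synchronization weight in [0, 1], and `e` independent noise. Expected
#' ReHo is monotone in `w`. Inside `dreho_up` regions the weight is
#' modulated slowly in time by a sinusoid of period
#' `nonstationarity_period_s`, producing window-to-window ReHo
#' variability. Low-frequency drift, WM/CSF-like signals and a small
#' motion-coupled component are added on top and are recoverable by the
#' preprocessing chain.
#'
#' @param n_patients,n_controls group sizes (defaults 20 + 20, a
#'   desk-scale stand-in for the 102 + 73 cohort the defaults emulate).
#' @param grid_shape voxels per axis (each >= 9).
#' @param voxel_size_mm,tr_s,n_volumes acquisition geometry and timing.
#' @param effect_regions list of regions, each
#'   `list(name, kind, center, radius, magnitude)` with kind one of
#'   `"reho_up"`, `"reho_down"` (additive shift of the sync weight in
#'   patients) or `"dreho_up"` (fractional sinusoidal modulation depth in
#'   patients). Regions are cubes of half-width `radius` voxels.
#' @param sync_base baseline local-synchronization weight in [0, 1].
#' @param noise_sd independent noise SD (signal units; source SD is 1).
#' @param nonstationarity_period_s period of the sync modulation, seconds.
#' @param clinical_effects list of `list(roi, covariate, rho)` links: the
#'   subject's ground-truth regional value and the named covariate share a
#'   latent factor so their population correlation is exactly `rho`
#'   (|rho| < 1). Applied to patients (covariates are patient-only).
#' @param subject_sync_sd between-subject SD of the regional sync weight.
#' @param seed integer seed governing the whole cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20, n_controls = 20,
                          grid_shape = c(24, 24, 16), voxel_size_mm = 3,
                          tr_s = 2, n_volumes = 240,
                          effect_regions = default_effect_regions(),
                          sync_base = 0.5, noise_sd = 0.6,
                          nonstationarity_period_s = 200,
                          clinical_effects = default_clinical_effects(),
                          subject_sync_sd = 0.08, seed = 1) {
  cfg <- structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    tr_s = tr_s, n_volumes = as.integer(n_volumes),
    effect_regions = effect_regions, sync_base = sync_base,
    noise_sd = noise_sd, nonstationarity_period_s = nonstationarity_period_s,
    clinical_effects = clinical_effects, subject_sync_sd = subject_sync_sd,
    seed = as.integer(seed)), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' Default patient-vs-control effect layout
#'
#' Three cubic regions on the 24 x 24 x 16 default grid: lowered
#' synchronization (sensorimotor-like deficit), raised synchronization
#' (cerebellar-like compensation), and time-modulated synchronization
#' (frontal-like dynamic variability), each roughly 100-150 voxels as in
#' typical significant clusters.
#' @export
default_effect_regions <- function() {
  list(
    list(name = "sync_down", kind = "reho_down", center = c(7, 7, 8),
         radius = 2, magnitude = 0.3),
    list(name = "sync_up", kind = "reho_up", center = c(17, 17, 8),
         radius = 2, magnitude = 0.3),
    list(name = "dyn_up", kind = "dreho_up", center = c(7, 17, 8),
         radius = 2, magnitude = 0.8))
}

#' Default ROI-covariate links
#'
#' Ties tinnitus severity (THI) positively to the lowered-synchronization
#' region and hearing-loss duration negatively to the dynamically
#' modulated region, at the correlation strengths used as simulation
#' targets (0.39 and -0.35).
#' @export
default_clinical_effects <- function() {
  list(list(roi = "sync_down", covariate = "thi_score", rho = 0.39),
       list(roi = "dyn_up", covariate = "duration_days", rho = -0.35))
}

validate_cohort_config <- function(cfg) {
  if (any(cfg$grid_shape < 9))
    stop("configuration error: each grid axis must be >= 9")
  if (cfg$n_volumes < 55)
    stop("configuration error: n_volumes must cover at least one window plus step (>= 55)")
  if (cfg$sync_base < 0 || cfg$sync_base > 1)
    stop("configuration error: sync_base must lie in [0, 1]")
  for (r in cfg$effect_regions) {
    if (!r$kind %in% c("reho_up", "reho_down", "dreho_up"))
      stop("configuration error: unknown effect kind ", r$kind)
    if (any(r$center - r$radius < 1) || any(r$center + r$radius > cfg$grid_shape))
      stop("configuration error: grid too small for region ", r$name)
  }
  for (ce in cfg$clinical_effects) {
    if (abs(ce$rho) >= 1)
      stop("configuration error: target correlation magnitude must be < 1")
    if (!ce$roi %in% vapply(cfg$effect_regions, `[[`, "", "name"))
      stop("configuration error: clinical effect refers to unknown region ", ce$roi)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d patients + %d controls, grid %s, %d volumes @ TR %.3g s\n",
              x$n_patients, x$n_controls,
              paste(x$grid_shape, collapse = "x"), x$n_volumes, x$tr_s))
  for (r in x$effect_regions)
    cat(sprintf("  region %-10s %-9s center (%s) radius %d magnitude %.2g\n",
                r$name, r$kind, paste(r$center, collapse = ","), r$radius,
                r$magnitude))
  invisible(x)
}

#' Voxel mask of a configured effect region
#' @param config a [cohort_config()].
#' @param name region name.
#' @return 3D logical array.
#' @export
region_mask <- function(config, name) {
  r <- Filter(function(z) z$name == name, config$effect_regions)
  if (length(r) == 0) stop("no region named ", name)
  r <- r[[1]]
  m <- array(FALSE, config$grid_shape)
  ix <- lapply(1:3, function(a) (r$center[a] - r$radius):(r$center[a] + r$radius))
  m[ix[[1]], ix[[2]], ix[[3]]] <- TRUE
  m
}

region_label_array <- function(config) {
  lab <- array(0L, config$grid_shape)
  for (i in seq_along(config$effect_regions))
    lab[region_mask(config, config$effect_regions[[i]]$name)] <- i
  lab
}

subject_seed <- function(config, idx) {
  as.integer((as.numeric(config$seed) * 10007 + idx * 7919) %% 2147483629)
}

# Clinical marginals: patients scanned in the acute phase of sudden
# hearing loss vs audiometrically normal controls. Units: years (age,
# education), days (duration), dB HL (PTA), THI points (0-100), cm^3 (gmv).
clinical_marginals <- function() {
  list(
    patient = list(age = c(38.89, 12.11), education_years = c(12.67, 3.20),
                   duration_days = c(9.03, 4.27), pta_db = c(73.66, 10.38),
                   thi_score = c(47.54, 26.37), gmv = c(620, 55),
                   p_male = 52 / 102, p_left = 56 / 102),
    control = list(age = c(38.01, 16.52), education_years = c(12.74, 2.93),
                   pta_db = c(13.25, 5.08), gmv = c(625, 55),
                   p_male = 37 / 73))
}

#' Generate the clinical table and latent regional deviations
#'
#' Draws the per-subject clinical covariates and the standard-normal
#' latent factors `z` that perturb each subject's regional ground truth.
#' A configured link `(roi, covariate, rho)` makes the patient covariate
#' `mu + sd * (rho * z_roi + sqrt(1 - rho^2) * eta)`, so the population
#' correlation between the ground-truth regional value and the covariate
#' is exactly `rho`.
#'
#' This is the fast path used when only clinical structure is needed
#' (e.g. correlation-recovery studies at full cohort size); [generate_cohort()]
#' reuses the same draws so imaging and clinical stay consistent.
#'
#' @param config a [cohort_config()].
#' @return List: `clinical` (data frame, one row per subject), `latent`
#'   (subjects x regions matrix of z-scores), `truth_roi` (data frame of
#'   ground-truth regional values: sync weight for `reho_*` regions,
#'   modulation depth for `dreho_up` regions).
#' @export
generate_clinical <- function(config) {
  set.seed(config$seed)
  marg <- clinical_marginals()
  n <- config$n_patients + config$n_controls
  group <- rep(c("patient", "control"), c(config$n_patients, config$n_controls))
  id <- sprintf("S%03d", seq_len(n))
  rnames <- vapply(config$effect_regions, `[[`, "", "name")
  latent <- matrix(stats::rnorm(n * length(rnames)), n, length(rnames),
                   dimnames = list(id, rnames))

  draw <- function(par, k) stats::rnorm(k, par[1], par[2])
  np <- config$n_patients; nc <- config$n_controls
  age <- c(draw(marg$patient$age, np), draw(marg$control$age, nc))
  edu <- c(draw(marg$patient$education_years, np),
           draw(marg$control$education_years, nc))
  pta <- c(draw(marg$patient$pta_db, np), draw(marg$control$pta_db, nc))
  sex <- c(stats::rbinom(np, 1, marg$patient$p_male),
           stats::rbinom(nc, 1, marg$control$p_male))
  gmv <- c(draw(marg$patient$gmv, np), draw(marg$control$gmv, nc))
  side <- c(ifelse(stats::rbinom(np, 1, marg$patient$p_left) == 1,
                   "left", "right"), rep(NA_character_, nc))

  linked <- vapply(config$clinical_effects, `[[`, "", "covariate")
  covs <- list(duration_days = marg$patient$duration_days,
               thi_score = marg$patient$thi_score)
  pat_cov <- list()
  for (cv in names(covs)) {
    mu <- covs[[cv]][1]; sdv <- covs[[cv]][2]
    eff <- Filter(function(e) e$covariate == cv, config$clinical_effects)
    if (length(eff) > 0 && np > 0) {
      e <- eff[[1]]
      z <- latent[seq_len(np), e$roi]
      val <- mu + sdv * (e$rho * z +
                           sqrt(1 - e$rho^2) * stats::rnorm(np))
    } else {
      val <- mu + sdv * stats::rnorm(np)
    }
    if (cv == "duration_days") val <- pmax(val, 0.5)
    if (cv == "thi_score") val <- pmin(pmax(val, 0), 100)
    pat_cov[[cv]] <- c(val, rep(NA_real_, nc))
  }

  clinical <- data.frame(
    subject_id = id, group = group, age = age, sex = sex,
    education_years = edu, duration_days = pat_cov$duration_days,
    pta_db = pta, thi_score = pat_cov$thi_score, affected_side = side,
    gmv = gmv, stringsAsFactors = FALSE)

  truth <- data.frame(subject_id = id, stringsAsFactors = FALSE)
  for (i in seq_along(config$effect_regions)) {
    r <- config$effect_regions[[i]]
    is_pat <- group == "patient"
    if (r$kind == "dreho_up") {
      base <- ifelse(is_pat, r$magnitude, 0)
      val <- pmax(base * (1 + 0.3 * latent[, r$name]), 0)
      val[!is_pat] <- 0
    } else {
      shift <- if (r$kind == "reho_up") r$magnitude else -r$magnitude
      val <- config$sync_base + ifelse(is_pat, shift, 0) +
        config$subject_sync_sd * latent[, r$name]
      val <- pmin(pmax(val, 0), 1)
    }
    truth[[r$name]] <- val
  }
  list(clinical = clinical, latent = latent, truth_roi = truth)
}

#' Simulate a bounded-random-walk motion trace
#'
#' @param n_volumes number of rows.
#' @param spiky inject a large mid-scan jump that violates the standard
#'   exclusion thresholds (for testing the screening logic).
#' @return n x 6 matrix: translations (mm) then rotations (rad).
#' @export
simulate_motion <- function(n_volumes, spiky = FALSE) {
  steps <- cbind(matrix(stats::rnorm(n_volumes * 3, 0, 0.02), ncol = 3),
                 matrix(stats::rnorm(n_volumes * 3, 0, 2e-4), ncol = 3))
  m <- apply(steps, 2, cumsum)
  m[, 1:3] <- pmin(pmax(m[, 1:3], -0.6), 0.6)
  m[, 4:6] <- pmin(pmax(m[, 4:6], -0.006), 0.006)
  if (spiky) {
    at <- floor(n_volumes / 2) + 0:2
    m[at, 1] <- m[at, 1] + 2.5
    m[at, 5] <- m[at, 5] + 0.04
  }
  m
}

#' Generate one subject's BOLD data with ground truth
#'
#' @param config a [cohort_config()].
#' @param group `"patient"` or `"control"`.
#' @param subject_id label.
#' @param sync_dev named numeric vector of latent z-scores, one per effect
#'   region (defaults to zeros).
#' @param seed integer seed for this subject.
#' @param spiky generate an exclusion-violating motion trace.
#' @return A `subject_record`: `subject_id`, `group`, `bold`
#'   ([bold_series]), `motion6`, nuisance signals `wm`/`csf`, and `truth`
#'   (per-voxel `sync` weights, `dreho_mask`, `region_labels`).
#' @export
generate_subject_bold <- function(config, group = c("patient", "control"),
                                  subject_id = "S001", sync_dev = NULL,
                                  seed = config$seed, spiky = FALSE) {
  group <- match.arg(group)
  validate_cohort_config(config)
  set.seed(seed)
  d <- config$grid_shape
  V <- prod(d)
  nt <- config$n_volumes
  rnames <- vapply(config$effect_regions, `[[`, "", "name")
  if (is.null(sync_dev)) sync_dev <- stats::setNames(numeric(length(rnames)), rnames)

  w <- array(config$sync_base, d)
  modamp <- array(0, d)
  labels <- region_label_array(config)
  is_pat <- group == "patient"
  for (r in config$effect_regions) {
    m <- region_mask(config, r$name)
    z <- sync_dev[[r$name]]
    if (r$kind == "dreho_up") {
      if (is_pat) modamp[m] <- max(r$magnitude * (1 + 0.3 * z), 0)
    } else {
      shift <- if (r$kind == "reho_up") r$magnitude else -r$magnitude
      w[m] <- config$sync_base + (if (is_pat) shift else 0) +
        config$subject_sync_sd * z
    }
  }
  w <- pmin(pmax(w, 0), 1)

  g <- stats::rnorm(nt)
  W <- matrix(w, nrow = nt, ncol = V, byrow = TRUE)
  dyn <- which(modamp > 0)
  if (length(dyn) > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    tt <- seq_len(nt) * config$tr_s
    for (v in dyn) {
      W[, v] <- W[, v] * (1 + modamp[v] * sin(2 * pi * tt /
                                                config$nonstationarity_period_s + phase))
    }
    W <- pmin(pmax(W, 0), 1)
  }
  X <- W * g + config$noise_sd * matrix(stats::rnorm(nt * V), nt, V)

  # nuisance structure, recoverable by preprocessing
  trend <- seq(-1, 1, length.out = nt)
  drift_coef <- stats::rnorm(V, 0, 0.5)
  wm <- as.numeric(scale(stats::filter(stats::rnorm(nt), 0.9,
                                       method = "recursive")))
  csf <- as.numeric(scale(stats::filter(stats::rnorm(nt), 0.9,
                                        method = "recursive")))
  motion6 <- simulate_motion(nt, spiky = spiky)
  m1 <- as.numeric(scale(motion6[, 1]))
  if (any(!is.finite(m1))) m1 <- numeric(nt)
  X <- X + outer(trend, drift_coef) +
    outer(wm, stats::rnorm(V, 0, 0.3)) +
    outer(csf, stats::rnorm(V, 0, 0.3)) +
    outer(m1, stats::rnorm(V, 0, 0.2))

  bold <- bold_series(array(t(X), dim = c(d, nt)),
                      voxel_mm = rep(config$voxel_size_mm, 3),
                      tr_s = config$tr_s)
  structure(list(
    subject_id = subject_id, group = group, bold = bold, motion6 = motion6,
    wm = wm, csf = csf,
    truth = list(sync = w, modamp = modamp, dreho_mask = modamp > 0,
                 region_labels = labels)),
    class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s)\n", x$subject_id, x$group))
  print(x$bold)
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Draws the clinical table and latent factors, then one BOLD subject per
#' row with a deterministically derived per-subject seed, so the same
#' configuration always produces an identical cohort.
#'
#' @param config a [cohort_config()].
#' @param imaging generate BOLD data (`TRUE`) or clinical-only (`FALSE`).
#' @return List of class `cohort`: `subjects` (list of `subject_record`,
#'   empty when `imaging = FALSE`), `clinical`, `truth_roi`, `config`.
#' @export
generate_cohort <- function(config, imaging = TRUE) {
  cl <- generate_clinical(config)
  subjects <- list()
  if (imaging) {
    n <- nrow(cl$clinical)
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      subjects[[i]] <- generate_subject_bold(
        config, group = cl$clinical$group[i],
        subject_id = cl$clinical$subject_id[i],
        sync_dev = cl$latent[i, , drop = TRUE],
        seed = subject_seed(config, i))
    }
    names(subjects) <- cl$clinical$subject_id
  }
  structure(list(subjects = subjects, clinical = cl$clinical,
                 truth_roi = cl$truth_roi, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$clinical$group)
  cat(sprintf("<cohort> %s (%d subjects with imaging)\n",
              paste(names(tab), tab, sep = "=", collapse = ", "),
              length(x$subjects)))
  invisible(x)
}

#' Write a cohort to disk in standard formats
#'
#' BOLD as NIfTI-1 (`bold_<id>.nii.gz`), motion as SPM-style
#' `rp_<id>.txt` (6 whitespace-separated columns: mm, mm, mm, rad, rad,
#' rad), the clinical table as `clinical.csv`, ground-truth region labels
#' as `truth_regions.nii.gz`, and ground-truth regional values as
#' `truth_roi.csv`.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    write_bold(s$bold, file.path(dir, sprintf("bold_%s.nii.gz", s$subject_id)))
    utils::write.table(format(s$motion6, digits = 8),
                       file.path(dir, sprintf("rp_%s.txt", s$subject_id)),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth_roi, file.path(dir, "truth_roi.csv"),
                   row.names = FALSE)
  lab <- region_label_array(cohort$config)
  write_map(scalar_map(array(as.numeric(lab), dim(lab)),
                       voxel_mm = rep(cohort$config$voxel_size_mm, 3)),
            file.path(dir, "truth_regions.nii.gz"))
  invisible(dir)
}
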