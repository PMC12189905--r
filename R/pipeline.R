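#' Per-subject ReHo maps from raw BOLD
#'
#' Runs the standard chain for one subject: preprocessing (volume
#' discard, nuisance regression, bandpass), static ReHo (Kendall's W,
#' Fisher z, 6 mm smoothing) and, optionally, dynamic ReHo (CV of
#' windowed W, z-standardized, smoothed).
#'
#' @param subject a `subject_record` (or any list with `bold`, `motion6`,
#'   `wm`, `csf`).
#' @param mask 3D logical analysis mask (`NULL` = whole grid).
#' @param window_length_tr,window_step_tr sliding-window settings
#'   (defaults 50 and 5 TRs).
#' @param fwhm_mm smoothing kernel FWHM (default 6 mm).
#' @param dynamic also compute dynamic ReHo (default `TRUE`).
#' @param n_discard leading volumes to drop (default 10).
#' @return List: `static` (smoothed Fisher-z [scalar_map]), `dynamic`
#'   (smoothed z-scored CV map or `NULL`), `motion` (motion summary),
#'   `excluded` (logical).
#' @export
subject_maps <- function(subject, mask = NULL, window_length_tr = 50,
                         window_step_tr = 5, fwhm_mm = 6, dynamic = TRUE,
                         n_discard = 10) {
  pp <- preprocess_bold(subject$bold, motion6 = subject$motion6,
                        wm = subject$wm, csf = subject$csf,
                        n_discard = n_discard)
  rh <- reho_map(pp$bold, mask)
  st <- gaussian_smooth(standardize_reho(rh, "fisher"), fwhm_mm)
  dy <- NULL
  if (dynamic) {
    win <- sliding_windows(n_volumes(pp$bold), window_length_tr,
                           window_step_tr)
    dcv <- dynamic_reho_cv(pp$bold, mask, windows = win)
    dy <- gaussian_smooth(zscore_map(dcv$cv), fwhm_mm)
  }
  list(static = st, dynamic = dy, motion = pp$motion,
       excluded = if (is.null(pp$exclusion)) FALSE else pp$exclusion$excluded)
}

#' End-to-end analysis of a synthetic (or loaded) cohort
#'
#' Computes per-subject static and dynamic ReHo maps, screens for motion,
#' appends mean FD to the clinical table, and runs the group GLM with
#' cluster-level correction for both metrics.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param mask analysis mask (`NULL` = whole grid).
#' @param method cluster inference method (default `"permutation"`).
#' @param n_perm,seed permutation settings.
#' @param voxel_p,cluster_alpha thresholds (defaults 0.001, 0.01).
#' @param dynamic analyse dynamic ReHo too (default `TRUE`).
#' @return List of class `cohort_analysis`: `static_glm`, `dynamic_glm`,
#'   `static_maps`, `dynamic_maps`, `clinical` (with `mean_fd`),
#'   `excluded` (subject ids dropped by motion screening).
#' @export
analyze_cohort <- function(cohort, mask = NULL, method = "permutation",
                           n_perm = 500, seed = 1, voxel_p = 0.001,
                           cluster_alpha = 0.01, dynamic = TRUE) {
  if (length(cohort$subjects) == 0)
    stop("cohort has no imaging data")
  if (length(unique(cohort$clinical$group)) < 2)
    stop("group contrast needs both groups present")
  maps <- lapply(cohort$subjects, subject_maps, mask = mask,
                 dynamic = dynamic)
  clin <- cohort$clinical
  clin$mean_fd <- vapply(maps, function(m) m$motion$mean_fd, numeric(1))
  keep <- !vapply(maps, `[[`, logical(1), "excluded")
  excluded <- clin$subject_id[!keep]
  maps <- maps[keep]
  clin <- clin[keep, , drop = FALSE]
  st_maps <- lapply(maps, `[[`, "static")
  # restrict to voxels defined for every subject (3x3x3 neighborhoods are
  # clipped at the grid/mask edge, where ReHo is flagged undefined)
  defined_mask <- function(ms) {
    Reduce(`&`, lapply(ms, function(m) m$mask & !is.na(m$data)))
  }
  st_mask <- defined_mask(st_maps)
  st_glm <- reho_group_glm(st_maps, clin, mask = st_mask, method = method,
                           n_perm = n_perm, seed = seed, voxel_p = voxel_p,
                           cluster_alpha = cluster_alpha)
  dy_glm <- dy_maps <- NULL
  if (dynamic) {
    dy_maps <- lapply(maps, `[[`, "dynamic")
    dy_glm <- reho_group_glm(dy_maps, clin, mask = defined_mask(dy_maps),
                             method = method,
                             n_perm = n_perm, seed = seed + 1,
                             voxel_p = voxel_p,
                             cluster_alpha = cluster_alpha)
  }
  structure(list(static_glm = st_glm, dynamic_glm = dy_glm,
                 static_maps = st_maps, dynamic_maps = dy_maps,
                 clinical = clin, excluded = excluded),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d subjects analysed (%d excluded for motion)\n",
              nrow(x$clinical), length(x$excluded)))
  cat("static ReHo: "); print(x$static_glm)
  if (!is.null(x$dynamic_glm)) { cat("dynamic ReHo: "); print(x$dynamic_glm) }
  invisible(x)
}
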