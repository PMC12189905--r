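#' Sliding-window specification
#'
#' Rectangular windows of `length_tr` volumes shifted by `step_tr`,
#' starting at volume 0 and continuing while the window fits:
#' `n_windows = floor((T - L) / S) + 1`. Starts are reported 0-based.
#'
#' @param n_timepoints total number of volumes T.
#' @param length_tr window length L in TRs.
#' @param step_tr window step S in TRs.
#' @return An object of class `window_spec` with fields `length_tr`,
#'   `step_tr`, `n_windows`, `starts`.
#' @export
sliding_windows <- function(n_timepoints, length_tr = 50, step_tr = 5) {
  if (length_tr <= 0 || length_tr > n_timepoints)
    stop("window length must satisfy 0 < L <= T")
  if (step_tr < 1) stop("step must be >= 1")
  n <- floor((n_timepoints - length_tr) / step_tr) + 1
  structure(list(length_tr = as.integer(length_tr),
                 step_tr = as.integer(step_tr),
                 n_windows = as.integer(n),
                 n_timepoints = as.integer(n_timepoints),
                 starts = as.integer(seq(0, by = step_tr, length.out = n))),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %d windows of %d TRs, step %d, over %d volumes\n",
              x$n_windows, x$length_tr, x$step_tr, x$n_timepoints))
  invisible(x)
}

#' Dynamic ReHo: coefficient of variation of windowed ReHo
#'
#' Static ReHo is recomputed inside each sliding window and the
#' per-voxel variability across windows is summarized by the coefficient
#' of variation
#'
#' \deqn{CV_i = \frac{\sqrt{\sum_{t=1}^{n}(x_t - \bar x)^2 / n}}{\bar x}}
#'
#' with \eqn{x_t} the raw (untransformed) Kendall's W of voxel i in window
#' t and n the number of windows. The SD is the population form (divide by
#' n). Voxels whose window-mean W is not positive are flagged undefined.
#'
#' @param bold a preprocessed [bold_series].
#' @param mask 3D logical array or `NULL`.
#' @param spec a [neighborhood_spec()].
#' @param windows a `window_spec` from [sliding_windows()]; `NULL` uses
#'   the defaults (50-TR windows, step 5).
#' @param transform_windows if `TRUE`, apply the Fisher transform to each
#'   window's W before the CV (sensitivity analysis; default `FALSE`).
#' @param keep_stack keep the per-window ReHo stack (windows x voxels).
#' @return A `dreho_map`: list with `cv` ([scalar_map]), `windows`, and
#'   optionally `window_reho`.
#' @export
dynamic_reho_cv <- function(bold, mask = NULL, spec = neighborhood_spec(),
                            windows = NULL, transform_windows = FALSE,
                            keep_stack = FALSE) {
  nt <- n_volumes(bold)
  if (is.null(windows)) windows <- sliding_windows(nt)
  if (windows$n_timepoints != nt)
    stop("window spec was built for a different series length")
  f_min <- 0.01
  if (windows$length_tr * bold$tr_s < 1 / f_min)
    warning(sprintf(
      "window length %.0f s is shorter than 1/f_min = %.0f s; windowed ReHo may be unstable",
      windows$length_tr * bold$tr_s, 1 / f_min))
  d <- dim(bold$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!any(mask)) stop("mask is empty")
  nb <- neighborhood_index(mask)
  Y <- as_timeseries_matrix(bold)[, nb$vox, drop = FALSE]
  nwin <- windows$n_windows
  stack <- matrix(NA_real_, nwin, length(nb$vox))
  for (i in seq_len(nwin)) {
    rows <- (windows$starts[i] + 1):(windows$starts[i] + windows$length_tr)
    rt <- rank_cols_ties(Y[rows, , drop = FALSE])
    kc <- kcc_neighbors(rt$ranks, rt$ties, nb$nb_idx, nb$nb_ptr)
    w <- kc$W
    w[kc$K < spec$min_in_mask] <- NA_real_
    stack[i, ] <- w
  }
  vals <- if (transform_windows) atanh(pmin(stack, 1 - 1e-7)) else stack
  mu <- colMeans(vals)
  sdp <- sqrt(colMeans(sweep(vals, 2, mu)^2))
  cv <- sdp / mu
  cv[!is.finite(cv) | is.na(mu) | mu <= 0] <- NA_real_
  arr <- array(NA_real_, d)
  arr[nb$vox] <- cv
  structure(list(cv = scalar_map(arr, mask, bold$voxel_mm, bold$affine),
                 windows = windows,
                 window_reho = if (keep_stack) stack else NULL),
            class = "dreho_map")
}

#' @export
print.dreho_map <- function(x, ...) {
  cat("<dreho_map> CV of windowed ReHo\n")
  print(x$windows)
  print(x$cv)
  invisible(x)
}

#' Population-SD CV of a numeric vector (the windowed-ReHo summary)
#'
#' Exposed so the variability summary can be checked in isolation:
#' population standard deviation (divide by n) over the mean.
#' @param x numeric vector of windowed values.
#' @return The coefficient of variation, or `NA` if the mean is not
#'   positive.
#' @export
cv_population <- function(x) {
  mu <- mean(x)
  if (!is.finite(mu) || mu <= 0) return(NA_real_)
  sqrt(mean((x - mu)^2)) / mu
}

#' Z-standardize a scalar map over its mask
#'
#' Centres to mask mean 0 and scales to mask SD 1, using the population SD
#' convention (divide by the number of voxels).
#'
#' @param map a [scalar_map].
#' @return The standardized [scalar_map].
#' @export
zscore_map <- function(map) {
  v <- map$data[map$mask]
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 defined in-mask voxels")
  mu <- mean(v)
  sdp <- sqrt(mean((v - mu)^2))
  if (sdp == 0) stop("constant map: z-scoring undefined")
  scalar_map((map$data - mu) / sdp, map$mask, map$voxel_mm, map$affine)
}
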