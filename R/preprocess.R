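#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes of a BOLD series, the usual guard
#' against T1 saturation effects at the start of an EPI run.
#'
#' @param bold a [bold_series].
#' @param n_discard number of leading volumes to drop.
#' @return A [bold_series] with `n_volumes - n_discard` time points.
#' @export
discard_initial_volumes <- function(bold, n_discard = 10) {
  nt <- n_volumes(bold)
  if (n_discard < 0 || n_discard >= nt)
    stop(sprintf("n_discard must be in [0, %d)", nt))
  if (n_discard == 0) return(bold)
  bold_series(bold$data[, , , (n_discard + 1):nt, drop = FALSE],
              voxel_mm = bold$voxel_mm, tr_s = bold$tr_s, affine = bold$affine)
}

#' Friston-24 motion regressors
#'
#' Expands a 6-parameter rigid-body motion trace into the 24-parameter
#' autoregressive model: the 6 parameters, their one-volume-lagged copies
#' (first row zero), and the squares of both sets.
#'
#' @param motion6 numeric matrix with 6 columns (3 translations in mm,
#'   3 rotations in radians) and one row per volume.
#' @return A matrix with 24 named columns and the same number of rows.
#' @export
friston24 <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) stop("motion trace must have exactly 6 columns")
  lagged <- rbind(0, motion6[-nrow(motion6), , drop = FALSE])
  out <- cbind(motion6, lagged, motion6^2, lagged^2)
  colnames(out) <- c(paste0("rp", 1:6), paste0("rp", 1:6, "_lag"),
                     paste0("rp", 1:6, "_sq"), paste0("rp", 1:6, "_lag_sq"))
  if (all(out == 0)) attr(out, "degenerate") <- TRUE
  out
}

#' Build a nuisance confound matrix
#'
#' Assembles the standard resting-state nuisance set: a linear trend
#' (detrending is folded into the regression), mean white-matter and CSF
#' signals, and the Friston-24 motion expansion. WM/CSF signals are taken
#' as precomputed columns; tissue segmentation is out of scope here.
#'
#' @param n_timepoints number of retained volumes.
#' @param motion6 6-column motion trace over the retained volumes, or `NULL`.
#' @param wm,csf optional nuisance signal vectors (length `n_timepoints`).
#' @return Numeric matrix with uniquely named columns.
#' @export
confound_matrix <- function(n_timepoints, motion6 = NULL, wm = NULL,
                            csf = NULL) {
  cols <- list(trend = seq_len(n_timepoints) - (n_timepoints + 1) / 2)
  if (!is.null(wm)) {
    stopifnot(length(wm) == n_timepoints)
    cols$wm <- as.numeric(wm)
  }
  if (!is.null(csf)) {
    stopifnot(length(csf) == n_timepoints)
    cols$csf <- as.numeric(csf)
  }
  out <- do.call(cbind, cols)
  if (!is.null(motion6)) {
    if (nrow(motion6) != n_timepoints)
      stop("motion trace length must equal the number of retained volumes")
    out <- cbind(out, friston24(motion6))
  }
  out
}

#' Regress nuisance signals out of a BOLD series
#'
#' Per-voxel ordinary least squares against the confound columns plus an
#' internally added intercept; the residuals replace the data. A
#' rank-deficient confound matrix is handled by dropping dependent columns
#' via a pivoted QR decomposition, with a warning naming them.
#'
#' @param bold a [bold_series].
#' @param confounds confound matrix, rows matching time points.
#' @return A [bold_series] of residuals (orthogonal to every confound).
#' @export
regress_nuisance <- function(bold, confounds) {
  confounds <- as.matrix(confounds)
  nt <- n_volumes(bold)
  if (nrow(confounds) != nt)
    stop("confound rows must equal the number of time points")
  if (is.null(colnames(confounds)))
    colnames(confounds) <- paste0("c", seq_len(ncol(confounds)))
  X <- cbind(intercept = 1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("dropping linearly dependent confound column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  Y <- as_timeseries_matrix(bold)
  res <- qr.resid(qx, Y)
  matrix_to_bold(res, bold)
}

#' FFT-domain bandpass filter
#'
#' Ideal (brick-wall) frequency-domain filter: Fourier coefficients whose
#' frequency falls outside `[low_hz, high_hz]` are zeroed, including the DC
#' term, and the series is inverse-transformed. This matches the
#' REST/DPABI convention and is idempotent by construction.
#'
#' @param bold a [bold_series].
#' @param low_hz,high_hz passband edges in Hz; `0 <= low < high < Nyquist`.
#' @return The filtered [bold_series] (zero mean by construction).
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.08) {
  nyq <- 1 / (2 * bold$tr_s)
  if (low_hz < 0 || low_hz >= high_hz) stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyq)
    stop(sprintf("high_hz must be below the Nyquist frequency (%.4g Hz)", nyq))
  Y <- as_timeseries_matrix(bold)
  nt <- nrow(Y)
  freqs <- seq_len(nt) - 1
  freqs <- pmin(freqs, nt - freqs) / (nt * bold$tr_s)
  keep <- freqs >= low_hz & freqs <= high_hz
  F <- stats::mvfft(Y)
  F[!keep, ] <- 0
  out <- Re(stats::mvfft(F, inverse = TRUE)) / nt
  matrix_to_bold(out, bold)
}

#' Jenkinson framewise displacement and motion summary
#'
#' For each consecutive pair of volumes, builds the rigid-body transforms
#' from the 6 realignment parameters (SPM convention: translations in mm,
#' rotations in radians, applied as Rx Ry Rz), takes the relative
#' transform, and reports the RMS displacement of the points of a solid
#' sphere of radius `radius_mm` centred at the origin:
#' \code{sqrt(r^2/5 * tr(A'A) + t't)} with `A` the linear part minus the
#' identity and `t` the translation of the relative transform.
#'
#' @param motion6 6-column motion trace (mm, mm, mm, rad, rad, rad).
#' @param radius_mm sphere radius in mm (default 50, the usual head proxy).
#' @return An object of class `motion_summary`: `fd_series` (length
#'   volumes - 1), `mean_fd`, `max_abs_translation` (mm),
#'   `max_abs_rotation` (degrees).
#' @export
framewise_displacement_jenkinson <- function(motion6, radius_mm = 50) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) stop("motion trace must have exactly 6 columns")
  nt <- nrow(motion6)
  if (nt < 2) stop("need at least 2 rows of motion parameters")
  mats <- lapply(seq_len(nt), function(i) rigid_transform(motion6[i, ]))
  fd <- vapply(2:nt, function(i) {
    M <- mats[[i]] %*% solve(mats[[i - 1]])
    A <- M[1:3, 1:3] - diag(3)
    tt <- M[1:3, 4]
    sqrt(radius_mm^2 / 5 * sum(A * A) + sum(tt * tt))
  }, numeric(1))
  structure(list(fd_series = fd,
                 mean_fd = mean(fd),
                 max_abs_translation = max(abs(motion6[, 1:3])),
                 max_abs_rotation = max(abs(motion6[, 4:6])) * 180 / pi,
                 radius_mm = radius_mm),
            class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf("<motion_summary> mean FD %.4f mm, max |trans| %.3f mm, max |rot| %.3f deg\n",
              x$mean_fd, x$max_abs_translation, x$max_abs_rotation))
  invisible(x)
}

# SPM-style rigid body matrix: translation then Rx Ry Rz (radians)
rigid_transform <- function(p) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  M <- diag(4)
  M[1:3, 1:3] <- Rx %*% Ry %*% Rz
  M[1:3, 4] <- p[1:3]
  M
}

#' Apply motion exclusion rules
#'
#' A subject is excluded iff any criterion is *strictly* exceeded
#' ("exceeding" is read literally, so a value exactly at the threshold is
#' retained): maximum absolute translation over `max_mm`, maximum absolute
#' rotation over `max_deg` degrees, or mean framewise displacement over
#' `max_mean_fd`.
#'
#' @param summary a `motion_summary` from
#'   [framewise_displacement_jenkinson()].
#' @param max_mm,max_deg,max_mean_fd thresholds (defaults 1.5 mm, 1.5
#'   degrees, 0.2 mm).
#' @return List with `excluded` (logical) and `reasons` (character vector,
#'   subset of `"translation"`, `"rotation"`, `"mean_fd"`).
#' @export
apply_exclusion <- function(summary, max_mm = 1.5, max_deg = 1.5,
                            max_mean_fd = 0.2) {
  stopifnot(max_mm > 0, max_deg > 0, max_mean_fd > 0)
  reasons <- character(0)
  if (summary$max_abs_translation > max_mm) reasons <- c(reasons, "translation")
  if (summary$max_abs_rotation > max_deg) reasons <- c(reasons, "rotation")
  if (summary$mean_fd > max_mean_fd) reasons <- c(reasons, "mean_fd")
  list(excluded = length(reasons) > 0, reasons = reasons)
}

#' Run the full in-scope preprocessing chain on one subject
#'
#' Fixed order: discard leading volumes, regress nuisance covariates
#' (linear trend, WM/CSF signals, Friston-24 motion terms), then FFT
#' bandpass. Motion screening is reported but exclusion is left to the
#' caller.
#'
#' @param bold a [bold_series].
#' @param motion6 6-column motion trace aligned with the *original* series.
#' @param wm,csf optional nuisance signal vectors aligned with the original
#'   series.
#' @param n_discard leading volumes to drop (default 10).
#' @param low_hz,high_hz passband (default 0.01-0.08 Hz).
#' @param fd_radius_mm Jenkinson sphere radius.
#' @return List with `bold` (preprocessed), `confounds`, `motion` (a
#'   `motion_summary` over the retained volumes), `exclusion`.
#' @export
preprocess_bold <- function(bold, motion6 = NULL, wm = NULL, csf = NULL,
                            n_discard = 10, low_hz = 0.01, high_hz = 0.08,
                            fd_radius_mm = 50) {
  bold <- discard_initial_volumes(bold, n_discard)
  nt <- n_volumes(bold)
  keep <- function(x) if (is.null(x)) NULL else utils::tail(x, nt)
  m6 <- if (is.null(motion6)) NULL else
    motion6[(nrow(motion6) - nt + 1):nrow(motion6), , drop = FALSE]
  conf <- confound_matrix(nt, motion6 = m6, wm = keep(wm), csf = keep(csf))
  bold <- regress_nuisance(bold, conf)
  bold <- bandpass(bold, low_hz, high_hz)
  motion <- if (is.null(m6)) NULL else
    framewise_displacement_jenkinson(m6, fd_radius_mm)
  list(bold = bold, confounds = conf, motion = motion,
       exclusion = if (is.null(motion)) NULL else apply_exclusion(motion))
}
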