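#' Kendall's coefficient of concordance (KCC)
#'
#' The agreement statistic at the heart of regional homogeneity: each of
#' the K series is ranked over its n time points (midranks for ties) and
#'
#' \deqn{W = \frac{12 \sum_t (R_t - \bar R)^2}{K^2 (n^3 - n) - K \sum_j T_j}}
#'
#' where \eqn{R_t} is the rank sum across series at time t and
#' \eqn{T_j = \sum (g^3 - g)} over tie groups of series j. W lies in
#' [0, 1]; 1 means identical rank orderings. W is invariant under strictly
#' monotone transforms of any single series. If every series is constant
#' the statistic is undefined and `NA` is returned.
#'
#' @param series_block numeric matrix, one column per series (n x K).
#' @return Kendall's W, or `NA` when undefined.
#' @export
kendalls_w <- function(series_block) {
  x <- as.matrix(series_block)
  K <- ncol(x); n <- nrow(x)
  if (K < 2) stop("need at least 2 series")
  if (n < 3) stop("need at least 3 time points")
  rt <- rank_cols_ties(x)
  kc <- kcc_neighbors(rt$ranks, rt$ties,
                      nb_idx = seq_len(K) - 1L, nb_ptr = c(0L, K))
  kc$W[1]
}

#' Neighborhood specification for ReHo
#'
#' The standard ReHo neighborhood is the full 3x3x3 cube of 27 voxels
#' including the centre. Voxels whose in-mask neighborhood has fewer than
#' `min_in_mask` members are flagged undefined rather than computed from a
#' degenerate set.
#'
#' @param kind only `"cube27"` is provided.
#' @param min_in_mask minimum in-mask neighborhood size, in [2, 27].
#' @export
neighborhood_spec <- function(kind = "cube27", min_in_mask = 27) {
  kind <- match.arg(kind)
  if (min_in_mask < 2 || min_in_mask > 27)
    stop("min_in_mask must be in [2, 27]")
  structure(list(kind = kind, min_in_mask = as.integer(min_in_mask)),
            class = "neighborhood_spec")
}

# Neighbor bookkeeping for every in-mask voxel: 0-based column indices into
# the in-mask voxel set, in compressed (idx, ptr) form for the C++ kernel.
neighborhood_index <- function(mask) {
  d <- dim(mask)
  vox <- which(mask)                       # linear indices, 1-based
  col_of <- integer(prod(d))               # map linear index -> column no.
  col_of[vox] <- seq_along(vox)
  co <- arrayInd(vox, d)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb_list <- vector("list", length(vox))
  for (m in seq_along(vox)) {
    nb <- sweep(offsets, 2, co[m, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    nb_list[[m]] <- col_of[lin[mask[lin]]] - 1L
  }
  list(vox = vox,
       nb_idx = as.integer(unlist(nb_list)),
       nb_ptr = c(0L, cumsum(lengths(nb_list))))
}

#' Voxelwise static ReHo map
#'
#' Computes Kendall's W between each in-mask voxel's time series and those
#' of its 3x3x3 neighborhood (in-mask members only), on preprocessed,
#' *unsmoothed* data. Spatial smoothing belongs after standardization.
#'
#' @param bold a preprocessed [bold_series].
#' @param mask 3D logical array; `NULL` means whole grid.
#' @param spec a [neighborhood_spec()].
#' @param nb_index optional precomputed neighborhood index (internal reuse
#'   across sliding windows).
#' @return A `reho_map`: list with `w` ([scalar_map] of W),
#'   `n_neighbors` ([scalar_map] of counts used), `mask`.
#' @export
reho_map <- function(bold, mask = NULL, spec = neighborhood_spec(),
                     nb_index = NULL) {
  d <- dim(bold$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!any(mask)) stop("mask is empty")
  if (is.null(nb_index)) nb_index <- neighborhood_index(mask)
  Y <- as_timeseries_matrix(bold)[, nb_index$vox, drop = FALSE]
  rt <- rank_cols_ties(Y)
  kc <- kcc_neighbors(rt$ranks, rt$ties, nb_index$nb_idx, nb_index$nb_ptr)
  w <- kc$W
  w[kc$K < spec$min_in_mask] <- NA_real_
  warr <- array(NA_real_, d)
  warr[nb_index$vox] <- w
  karr <- array(NA_real_, d)
  karr[nb_index$vox] <- kc$K
  structure(list(
    w = scalar_map(warr, mask, bold$voxel_mm, bold$affine),
    n_neighbors = scalar_map(karr, mask, bold$voxel_mm, bold$affine),
    mask = mask, spec = spec), class = "reho_map")
}

#' @export
print.reho_map <- function(x, ...) {
  cat("<reho_map> Kendall's W\n")
  print(x$w)
  invisible(x)
}

#' Standardize a ReHo map
#'
#' Two conventions are provided. `"fisher"` applies the Fisher r-to-z
#' transform `atanh(W)` (with W clipped at `1 - eps` so perfect concordance
#' stays finite); `"zscore"` centres and scales by the in-mask mean and SD.
#'
#' @param map a `reho_map` or [scalar_map].
#' @param method `"fisher"` (default) or `"zscore"`.
#' @param eps clipping distance from 1 for `atanh` (default 1e-7).
#' @return A [scalar_map] of standardized values.
#' @export
standardize_reho <- function(map, method = c("fisher", "zscore"),
                             eps = 1e-7) {
  method <- match.arg(method)
  if (inherits(map, "reho_map")) map <- map$w
  arr <- map$data
  if (method == "fisher") {
    arr <- atanh(pmin(arr, 1 - eps))
  } else {
    v <- arr[map$mask]
    mu <- mean(v, na.rm = TRUE)
    sdv <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) stop("constant map: z-scoring undefined")
    arr <- (arr - mu) / sdv
  }
  scalar_map(arr, map$mask, map$voxel_mm, map$affine)
}

gaussian_kernel_1d <- function(fwhm_mm, voxel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm  # in voxels
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# zero-padded shift of a 3D array along one axis
shift_array3 <- function(a, s, axis) {
  if (s == 0) return(a)
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  ix_src <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  ix_dst <- ix_src
  ix_src[[axis]] <- src
  ix_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), ix_dst,
                          list(do.call(`[`, c(list(a), ix_src)))))
  out
}

conv_axis <- function(a, w, axis) {
  r <- (length(w) - 1) / 2
  out <- array(0, dim(a))
  for (i in seq_along(w)) {
    out <- out + w[i] * shift_array3(a, i - r - 1, axis)
  }
  out
}

#' Gaussian spatial smoothing of a scalar map
#'
#' Separable Gaussian convolution with `sigma = FWHM / (2 sqrt(2 ln 2))`
#' per axis, in voxel units. When the map carries a mask, out-of-mask
#' voxels are excluded and kernel weights renormalized within the mask
#' (smoothing of `x * mask` divided by smoothing of `mask`), so values
#' never bleed across the mask edge.
#'
#' @param map a [scalar_map].
#' @param fwhm_mm kernel full width at half maximum, mm (default 6).
#' @param use_mask renormalize within the mask (default `TRUE`); with
#'   `FALSE` a plain zero-padded convolution is used.
#' @return The smoothed [scalar_map].
#' @export
gaussian_smooth <- function(map, fwhm_mm = 6, use_mask = TRUE) {
  stopifnot(fwhm_mm > 0)
  arr <- map$data
  valid <- map$mask & !is.na(arr)
  x <- arr
  x[!valid] <- 0
  m <- array(as.numeric(valid), dim(arr))
  for (axis in 1:3) {
    w <- gaussian_kernel_1d(fwhm_mm, map$voxel_mm[axis])
    x <- conv_axis(x, w, axis)
    if (use_mask) m <- conv_axis(m, w, axis)
  }
  out <- if (use_mask) {
    res <- array(NA_real_, dim(arr))
    res[valid] <- x[valid] / m[valid]
    res
  } else x
  mask_out <- if (use_mask) map$mask else array(TRUE, dim(arr))
  scalar_map(out, mask_out, map$voxel_mm, map$affine)
}
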