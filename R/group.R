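#' Build a group-comparison design matrix
#'
#' Intercept, a 0/1 group indicator (patient = 1), and mean-centred
#' covariates taken from the clinical table. Sex is expected coded 0/1.
#'
#' @param clinical data frame with a `group` column (`"patient"` /
#'   `"control"`) and the covariate columns.
#' @param covariates covariate column names (default age, sex, mean FD,
#'   education and gray-matter volume, when present).
#' @return Numeric matrix with named columns; attribute `"contrast"`
#'   holds the unit contrast vector selecting the group column.
#' @export
build_design <- function(clinical,
                         covariates = intersect(
                           c("age", "sex", "mean_fd", "education_years", "gmv"),
                           names(clinical))) {
  g <- as.integer(clinical$group == "patient")
  X <- cbind(intercept = 1, group = g)
  for (cv in covariates) {
    v <- as.numeric(clinical[[cv]])
    if (anyNA(v)) stop("covariate ", cv, " contains missing values")
    X <- cbind(X, scale(v, scale = FALSE))
    colnames(X)[ncol(X)] <- cv
  }
  contrast <- as.numeric(colnames(X) == "group")
  attr(X, "contrast") <- contrast
  X
}

#' Mass-univariate GLM over a map stack
#'
#' Ordinary least squares at every voxel of a subjects-by-voxels stack,
#' returning the t statistic for a contrast plus the residuals needed for
#' smoothness estimation.
#'
#' @param stack numeric matrix, subjects x voxels (e.g. from
#'   `stack_maps()`), or a list of [scalar_map]s.
#' @param design design matrix (subjects x predictors), e.g. from
#'   [build_design()].
#' @param contrast numeric contrast vector (defaults to the design's
#'   `"contrast"` attribute).
#' @return List: `t` (voxel t values), `beta` (contrast effect),
#'   `residuals` (subjects x voxels), `df`.
#' @export
fit_glm_voxelwise <- function(stack, design, contrast = attr(design, "contrast")) {
  if (is.list(stack) && !is.matrix(stack)) stack <- stack_maps(stack)
  X <- as.matrix(design)
  if (nrow(X) != nrow(stack)) stop("design rows must match the map stack")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- nrow(X) - qx$rank
  if (df < 1) stop("no residual degrees of freedom")
  if (is.null(contrast)) stop("no contrast supplied")
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, stack)        # p x V
  res <- stack - X %*% B
  sigma2 <- colSums(res^2) / df
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  eff <- drop(contrast %*% B)
  tval <- eff / sqrt(sigma2 * cvar)
  list(t = tval, beta = eff, residuals = res, df = df)
}

#' Threshold a t map and label candidate clusters
#'
#' Signed cluster-forming: by default two one-tailed analyses at
#' `voxel_p` each (the usual convention for signed neuroimaging
#' contrasts), i.e. voxels with `t > t_crit` and voxels with
#' `t < -t_crit` are labelled into connected components separately.
#' `tail = "two.sided"` instead uses `|t| > t_crit(voxel_p / 2)`.
#'
#' @param tmap numeric vector of t values over the in-mask voxels, or a
#'   [scalar_map].
#' @param df residual degrees of freedom.
#' @param voxel_p cluster-forming voxel p threshold (default 0.001).
#' @param mask 3D logical array locating the voxels (required when `tmap`
#'   is a vector).
#' @param connectivity 6, 18 or 26 (default 26: faces, edges, corners).
#' @param tail `"one.sided.both"` (default) or `"two.sided"`.
#' @param affine optional voxel-to-world matrix for peak coordinates.
#' @param voxel_mm voxel size for the default affine.
#' @return data frame of candidate clusters: `cluster_id`, `sign`,
#'   `extent_voxels`, `peak_t`, peak voxel indices and world (MNI-style)
#'   coordinates; attribute `"labels"` carries the signed label array and
#'   `"t_crit"` the threshold used.
#' @export
threshold_and_cluster <- function(tmap, df, voxel_p = 0.001, mask = NULL,
                                  connectivity = 26,
                                  tail = c("one.sided.both", "two.sided"),
                                  affine = NULL, voxel_mm = c(3, 3, 3)) {
  tail <- match.arg(tail)
  if (inherits(tmap, "scalar_map")) {
    if (is.null(mask)) mask <- tmap$mask
    if (is.null(affine)) affine <- tmap$affine
    voxel_mm <- tmap$voxel_mm
    tvec <- tmap$data[mask]
  } else {
    if (is.null(mask)) stop("a mask is required when tmap is a vector")
    tvec <- tmap
  }
  stopifnot(voxel_p > 0, voxel_p < 1, connectivity %in% c(6, 18, 26))
  if (is.null(affine)) affine <- default_affine(dim(mask), voxel_mm)
  t_crit <- stats::qt(1 - if (tail == "two.sided") voxel_p / 2 else voxel_p, df)

  d <- dim(mask)
  tarr <- array(0, d)
  tarr[mask] <- ifelse(is.na(tvec), 0, tvec)
  out <- list()
  labarr <- array(0L, d)
  next_id <- 0L
  for (sgn in c(1, -1)) {
    supra <- (sgn * tarr) > t_crit & mask
    if (!any(supra)) next
    lab <- label_clusters_cpp(as.logical(supra), d, as.integer(connectivity))
    for (k in seq_len(max(lab))) {
      vox <- which(lab == k)
      pk <- vox[which.max(sgn * tarr[vox])]
      pk_ix <- arrayInd(pk, d)[1, ]
      next_id <- next_id + 1L
      labarr[vox] <- sgn * next_id
      mni <- voxel_to_world(pk_ix, affine)
      out[[next_id]] <- data.frame(
        cluster_id = next_id, sign = sgn, extent_voxels = length(vox),
        peak_t = tarr[pk], peak_i = pk_ix[1], peak_j = pk_ix[2],
        peak_k = pk_ix[3], peak_x_mni = mni[1], peak_y_mni = mni[2],
        peak_z_mni = mni[3])
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(cluster_id = integer(0), sign = numeric(0),
               extent_voxels = integer(0), peak_t = numeric(0),
               peak_i = integer(0), peak_j = integer(0), peak_k = integer(0),
               peak_x_mni = numeric(0), peak_y_mni = numeric(0),
               peak_z_mni = numeric(0))
  attr(res, "labels") <- labarr
  attr(res, "t_crit") <- t_crit
  attr(res, "connectivity") <- connectivity
  res
}

#' Estimate residual spatial smoothness (FWHM and RESELs)
#'
#' Per-axis FWHM from the spatial autocorrelation of standardized GLM
#' residuals: for a unit-variance Gaussian field the lag-1 correlation is
#' `rho = exp(-2 ln 2 (dx / FWHM)^2)`, so
#' `FWHM = dx * sqrt(-2 ln 2 / ln rho)` with `rho = 1 - var(diff) / 2`.
#' The estimate is floored at one voxel (a sampled field cannot be
#' rougher than its grid). The RESEL count is the mask volume divided by
#' the FWHM product.
#'
#' @param residuals subjects x voxels residual matrix (over the mask).
#' @param mask 3D logical array.
#' @param voxel_mm voxel size in mm.
#' @return List: `fwhm_mm` (length 3), `resels`, `n_mask_voxels`.
#' @export
estimate_smoothness <- function(residuals, mask, voxel_mm = c(3, 3, 3)) {
  if (nrow(residuals) < 2) stop("need at least 2 residual maps")
  voxel_mm <- rep_len(voxel_mm, 3)
  d <- dim(mask)
  sds <- apply(residuals, 1, stats::sd)
  if (any(sds == 0)) stop("constant residual map: smoothness undefined")
  fwhm <- numeric(3)
  for (axis in 1:3) {
    num <- 0; den <- 0
    for (s in seq_len(nrow(residuals))) {
      arr <- array(NA_real_, d)
      arr[mask] <- residuals[s, ] / sds[s]
      ix_lo <- ix_hi <- list(quote(expr = ), quote(expr = ), quote(expr = ))
      ix_lo[[axis]] <- 1:(d[axis] - 1)
      ix_hi[[axis]] <- 2:d[axis]
      a <- do.call(`[`, c(list(arr), ix_lo))
      b <- do.call(`[`, c(list(arr), ix_hi))
      dd <- (b - a)[!is.na(a) & !is.na(b)]
      num <- num + sum(dd^2)
      den <- den + length(dd)
    }
    vdiff <- num / den
    rho <- 1 - vdiff / 2
    fwhm[axis] <- if (rho <= exp(-2 * log(2))) voxel_mm[axis] else
      voxel_mm[axis] * sqrt(-2 * log(2) / log(rho))
  }
  nvox <- sum(mask)
  resels <- nvox * prod(voxel_mm) / prod(fwhm)
  list(fwhm_mm = fwhm, resels = resels, n_mask_voxels = nvox)
}

# Expected number of clusters (Euler characteristic, 3D) and expected
# cluster size for a Gaussianized threshold zt on a field with the given
# resel count; the classical random-field approximation.
grf_cluster_p <- function(extent, zt, resels, n_mask_voxels) {
  if (extent <= 0) return(1)
  em <- resels * (4 * log(2))^(3 / 2) / (2 * pi)^2 * (zt^2 - 1) *
    exp(-zt^2 / 2)
  em <- max(em, 1e-12)
  p0 <- stats::pnorm(zt, lower.tail = FALSE)
  en_vox <- n_mask_voxels * p0 / em        # expected cluster size, voxels
  beta <- (gamma(5 / 2) / en_vox)^(2 / 3)
  1 - exp(-em * exp(-beta * extent^(2 / 3)))
}

#' Cluster-level p-values (permutation or Gaussian random field)
#'
#' `method = "permutation"` (the reference method here) builds the null
#' distribution of the maximum cluster extent by the Freedman-Lane
#' scheme: residuals from the reduced model (design without the contrast
#' column) are permuted across subjects, the reduced fit is added back,
#' the full model is refit, and the permuted t map is thresholded and
#' clustered exactly like the observed one. `method = "grf"` uses the
#' classical Gaussian-random-field expected-cluster approximation with
#' the smoothness estimated from the residuals; its exactness is not
#' guaranteed on coarse or mildly non-Gaussian fields, so permutation is
#' the default for inference and GRF is provided for comparability with
#' common neuroimaging pipelines.
#'
#' @param clusters candidate clusters from [threshold_and_cluster()].
#' @param fit the [fit_glm_voxelwise()] result (for df and residuals).
#' @param mask 3D logical array.
#' @param voxel_p the cluster-forming voxel p used for `clusters`.
#' @param method `"permutation"` or `"grf"`.
#' @param cluster_alpha retained-cluster threshold (default 0.01).
#' @param stack,design needed for permutation: the map stack and design
#'   matrix used in the fit.
#' @param contrast contrast vector (defaults to the design attribute).
#' @param n_perm number of permutations (default 500; < 100 warns, 0 errors).
#' @param seed RNG seed for the permutations.
#' @param voxel_mm voxel size (for GRF smoothness).
#' @param tail passed through to the permuted thresholding.
#' @return A `cluster_table` data frame: the candidate clusters with
#'   `cluster_p` and `significant` columns; attributes `"labels"` (signed
#'   label array of all candidates) and `"sig_mask"` (logical array of
#'   significant voxels).
#' @export
cluster_pvalues <- function(clusters, fit, mask, voxel_p = 0.001,
                            method = c("permutation", "grf"),
                            cluster_alpha = 0.01, stack = NULL, design = NULL,
                            contrast = NULL, n_perm = 500, seed = 1,
                            voxel_mm = c(3, 3, 3),
                            tail = "one.sided.both") {
  method <- match.arg(method)
  labs <- attr(clusters, "labels")
  conn <- attr(clusters, "connectivity")
  if (is.null(conn)) conn <- 26
  if (nrow(clusters) == 0) {
    clusters$cluster_p <- numeric(0)
    clusters$significant <- logical(0)
    attr(clusters, "labels") <- labs
    attr(clusters, "sig_mask") <- array(FALSE, dim(mask))
    class(clusters) <- c("cluster_table", "data.frame")
    return(clusters)
  }
  if (method == "grf") {
    sm <- estimate_smoothness(fit$residuals, mask, voxel_mm)
    t_crit <- attr(clusters, "t_crit")
    zt <- stats::qnorm(stats::pt(t_crit, fit$df))
    pv <- vapply(clusters$extent_voxels, grf_cluster_p, numeric(1),
                 zt = zt, resels = sm$resels,
                 n_mask_voxels = sm$n_mask_voxels)
  } else {
    if (is.null(stack) || is.null(design))
      stop("permutation inference needs the map stack and design matrix")
    if (n_perm == 0) stop("n_perm must be positive")
    if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
    if (is.null(contrast)) contrast <- attr(design, "contrast")
    max_null <- perm_max_extent(stack, design, contrast, fit$df, mask,
                                voxel_p, conn, n_perm, seed, tail)
    pv <- vapply(clusters$extent_voxels, function(k)
      (1 + sum(max_null >= k)) / (1 + n_perm), numeric(1))
  }
  clusters$cluster_p <- pv
  clusters$significant <- pv < cluster_alpha
  sig <- array(FALSE, dim(mask))
  for (i in which(clusters$significant))
    sig[abs(labs) == clusters$cluster_id[i] & (sign(labs) == clusters$sign[i])] <- TRUE
  attr(clusters, "labels") <- labs
  attr(clusters, "sig_mask") <- sig
  class(clusters) <- c("cluster_table", "data.frame")
  clusters
}

# Freedman-Lane max-cluster-extent null
perm_max_extent <- function(stack, design, contrast, df, mask, voxel_p,
                            connectivity, n_perm, seed, tail) {
  X <- as.matrix(design)
  n <- nrow(X)
  keep <- contrast == 0
  Z <- X[, keep, drop = FALSE]
  qz <- qr(Z)
  Ez <- qr.resid(qz, stack)                 # reduced-model residuals
  Yz <- stack - Ez                          # reduced-model fit
  XtXinv <- chol2inv(chol(crossprod(X)))
  H <- XtXinv %*% t(X)                      # p x n
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  t_crit <- stats::qt(1 - if (tail == "two.sided") voxel_p / 2 else voxel_p, df)
  d <- dim(mask)
  set.seed(seed)
  out <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    Yp <- Yz + Ez[sample.int(n), , drop = FALSE]
    B <- H %*% Yp
    res <- Yp - X %*% B
    sigma2 <- colSums(res^2) / df
    tval <- drop(contrast %*% B) / sqrt(sigma2 * cvar)
    mx <- 0L
    for (sgn in c(1, -1)) {
      supra_vec <- (sgn * tval) > t_crit
      if (!any(supra_vec)) next
      supra <- array(FALSE, d)
      supra[mask] <- supra_vec
      lab <- label_clusters_cpp(as.logical(supra), d,
                                as.integer(connectivity))
      if (max(lab) > 0) mx <- max(mx, max(tabulate(lab[lab > 0L])))
    }
    out[b] <- mx
  }
  out
}

#' Group comparison of ReHo-type maps with cluster-level correction
#'
#' One-call wrapper around the mass-univariate chain: build the design
#' from the clinical table, fit the voxelwise GLM, threshold and label
#' clusters, and attach cluster-level p-values.
#'
#' @param maps list of per-subject [scalar_map]s (same order as
#'   `clinical` rows) or a subjects x voxels matrix.
#' @param clinical clinical data frame with `group` and covariates.
#' @param mask 3D logical array (defaults to the first map's mask).
#' @param covariates covariate names, passed to [build_design()].
#' @param voxel_p,cluster_alpha voxel and cluster thresholds
#'   (defaults 0.001 and 0.01).
#' @param method `"permutation"` (default) or `"grf"`.
#' @param connectivity cluster connectivity (default 26).
#' @param n_perm,seed permutation settings.
#' @param voxel_mm,affine geometry, when `maps` is a bare matrix.
#' @return An object of class `reho_glm`: the fit, candidate clusters
#'   with p-values (`$clusters`), the t map as a [scalar_map] (`$tmap`)
#'   and the significant-voxel mask (`$sig_mask`).
#' @export
reho_group_glm <- function(maps, clinical, mask = NULL, covariates = NULL,
                           voxel_p = 0.001, cluster_alpha = 0.01,
                           method = c("permutation", "grf"),
                           connectivity = 26, n_perm = 500, seed = 1,
                           voxel_mm = c(3, 3, 3), affine = NULL) {
  method <- match.arg(method)
  if (length(unique(clinical$group)) < 2)
    stop("group contrast needs both groups present")
  if (is.list(maps) && !is.matrix(maps)) {
    if (is.null(mask)) mask <- maps[[1]]$mask
    voxel_mm <- maps[[1]]$voxel_mm
    if (is.null(affine)) affine <- maps[[1]]$affine
    stack <- stack_maps(maps, mask)
  } else stack <- maps
  if (is.null(mask)) stop("a mask is required")
  if (is.null(affine)) affine <- default_affine(dim(mask), voxel_mm)
  design <- if (is.null(covariates)) build_design(clinical) else
    build_design(clinical, covariates)
  fit <- fit_glm_voxelwise(stack, design)
  cand <- threshold_and_cluster(fit$t, fit$df, voxel_p, mask,
                                connectivity, affine = affine,
                                voxel_mm = voxel_mm)
  tab <- cluster_pvalues(cand, fit, mask, voxel_p, method, cluster_alpha,
                         stack = stack, design = design, n_perm = n_perm,
                         seed = seed, voxel_mm = voxel_mm)
  tarr <- array(NA_real_, dim(mask))
  tarr[mask] <- fit$t
  structure(list(clusters = tab, fit = fit, design = design,
                 tmap = scalar_map(tarr, mask, voxel_mm, affine),
                 sig_mask = attr(tab, "sig_mask"), method = method,
                 voxel_p = voxel_p, cluster_alpha = cluster_alpha),
            class = "reho_glm")
}

#' @export
print.reho_glm <- function(x, ...) {
  cat(sprintf("<reho_glm> %s inference, voxel p < %g, cluster alpha %g\n",
              x$method, x$voxel_p, x$cluster_alpha))
  cat(sprintf("  %d candidate cluster(s), %d significant\n",
              nrow(x$clusters), sum(x$clusters$significant)))
  invisible(x)
}

#' @export
summary.reho_glm <- function(object, ...) {
  print(object)
  if (nrow(object$clusters) > 0) {
    cols <- c("cluster_id", "sign", "extent_voxels", "peak_x_mni",
              "peak_y_mni", "peak_z_mni", "peak_t", "cluster_p",
              "significant")
    print(as.data.frame(object$clusters)[, cols], row.names = FALSE)
  }
  invisible(object$clusters)
}

#' Write a cluster table as TSV
#' @param clusters a `cluster_table`.
#' @param path output path.
#' @export
write_cluster_table <- function(clusters, path) {
  cols <- intersect(c("cluster_id", "extent_voxels", "peak_x_mni",
                      "peak_y_mni", "peak_z_mni", "peak_t", "cluster_p",
                      "sign", "significant"), names(clusters))
  utils::write.table(as.data.frame(clusters)[, cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dice overlap between two masks
#' @param a,b logical arrays of equal dimension.
#' @return 2|A and B| / (|A| + |B|); `NA` when both are empty.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}
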