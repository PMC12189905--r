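#' Mean map value inside an ROI
#'
#' @param map a [scalar_map].
#' @param roi_mask 3D logical array (e.g. a significant-cluster mask).
#' @return Arithmetic mean over in-ROI voxels with defined values.
#' @export
extract_roi_means <- function(map, roi_mask) {
  if (!any(roi_mask)) stop("ROI mask is empty")
  if (!identical(dim(roi_mask), dim(map$data)))
    stop("ROI mask is not aligned with the map")
  v <- map$data[roi_mask]
  mean(v, na.rm = TRUE)
}

#' Build a subjects-by-ROI feature table from map stacks
#'
#' @param maps list of per-subject [scalar_map]s.
#' @param rois named list of 3D logical ROI masks.
#' @return Data frame, one row per subject, one column per ROI.
#' @export
roi_feature_table <- function(maps, rois) {
  out <- as.data.frame(lapply(rois, function(m)
    vapply(maps, extract_roi_means, numeric(1), roi_mask = m)))
  names(out) <- names(rois)
  out
}

#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] that enforces the
#' preconditions used in ROI-clinical analyses (n >= 3, non-constant
#' inputs) and returns a compact result.
#'
#' @param x,y numeric vectors (pairs with missing values are dropped).
#' @return List with `r`, `p` (t-based, n - 2 df), `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' ROI-clinical correlation table
#'
#' @param features ROI feature data frame (rows = subjects).
#' @param clinical clinical data frame aligned to the same subjects.
#' @param covariates clinical column names to correlate against.
#' @param adjust multiplicity adjustment across the table
#'   (`"none"` by default, reflecting ROI preselection; `"bonferroni"`
#'   available).
#' @return Data frame with `roi`, `covariate`, `r`, `p`, `p_adj`, `n`.
#' @export
correlate_clinical <- function(features, clinical, covariates,
                               adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  rows <- list()
  for (roi in names(features)) {
    for (cv in covariates) {
      res <- pearson_corr(features[[roi]], as.numeric(clinical[[cv]]))
      rows[[length(rows) + 1]] <- data.frame(
        roi = roi, covariate = cv, r = res$r, p = res$p, n = res$n)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}

# Ridge-penalized logistic fit via iteratively reweighted least squares.
# A small fixed L2 penalty on the slopes (never the intercept) keeps the
# fit finite under perfect separation.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100, tol = 1e-10) {
  X <- cbind(1, X)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wgt <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X, y - mu) - pen %*% beta
    Hmat <- crossprod(X * wgt, X) + pen
    step <- solve(Hmat, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = drop(beta), prob = stats::plogis(drop(X %*% beta)),
       iterations = it)
}

#' Predictive probabilities from binary logistic regression
#'
#' Maximum-likelihood logistic fit with intercept on the supplied ROI
#' features; returns the in-sample predicted probability of the positive
#' class (the "predictive probability" used as the ROC score). Exactly
#' duplicated or aliased feature columns are dropped before fitting. If
#' the classes are perfectly separated the ML estimate diverges, so the
#' fit falls back to a weakly ridge-penalized solution and warns.
#'
#' @param features data frame or matrix of features.
#' @param labels binary labels (factor, logical, or 0/1; "patient" is the
#'   positive class for a patient/control factor).
#' @return Numeric vector of probabilities with attributes `"model"`
#'   (`"ml"` or `"ridge"`) and `"coefficients"`.
#' @export
logistic_predictive_prob <- function(features, labels) {
  X <- as.matrix(as.data.frame(features))
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("features must be finite")
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  # drop aliased columns
  kept <- seq_len(ncol(X))
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    keepcols <- qx$pivot[seq_len(qx$rank)] - 1L
    kept <- sort(keepcols[keepcols > 0])
    X <- X[, kept, drop = FALSE]
  }
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                         family = stats::binomial()))
  separated <- !fit$converged || any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8)
  if (separated) {
    warning("quasi-separation detected: using ridge-penalized logistic fit")
    rf <- ridge_logistic(X, y)
    prob <- rf$prob
    attr(prob, "model") <- "ridge"
    attr(prob, "coefficients") <- rf$beta
  } else {
    prob <- fit$fitted.values
    attr(prob, "model") <- "ml"
    attr(prob, "coefficients") <- fit$coefficients
  }
  attr(prob, "kept_features") <- kept
  prob
}

as_binary_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.character(labels)
    lv <- sort(unique(labels))
    if ("patient" %in% lv) as.integer(labels == "patient")
    else as.integer(labels == lv[length(lv)])
  } else as.integer(labels != 0)
}

#' ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney probability that a random
#' positive scores above a random negative, with ties counted 1/2; the
#' curve is traced over all score thresholds and (by construction) its
#' trapezoidal integral equals the same quantity.
#'
#' @param scores numeric classifier scores (higher = more "positive").
#' @param labels binary labels; see [logistic_predictive_prob()].
#' @return An object of class `roc_result`: `auc`, `curve` (data frame
#'   with `fpr`, `tpr` from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  pos <- scores[y == 1]; neg <- scores[y == 0]
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord] == 1) / sum(y == 1)
  fp <- cumsum(y[ord] == 0) / sum(y == 0)
  # collapse tied thresholds so the curve is a function of the threshold
  keep <- c(diff(scores[ord]) != 0, TRUE)
  curve <- data.frame(fpr = c(0, fp[keep]), tpr = c(0, tp[keep]))
  structure(list(auc = auc, curve = curve, n_pos = sum(y == 1),
                 n_neg = sum(y == 0)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    folds[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  folds
}

#' Compare classifiers on ROI features
#'
#' Evaluates a fixed set of classifiers (RBF-kernel SVM with unit cost,
#' CART decision tree, random forest with 500 trees, k-nearest
#' neighbours with k = 5, and logistic regression) on the feature table
#' under stratified k-fold cross-validation: fold-wise held-out scores
#' are pooled before a single ROC per model. `scheme = "insample"`
#' instead scores the training data itself (comparable to reporting
#' apparent accuracy). Hyperparameters are fixed so results are
#' deterministic under a fixed seed.
#'
#' @param features data frame or matrix of features.
#' @param labels binary labels.
#' @param models subset of `c("svm", "decision_tree", "random_forest",
#'   "knn", "logistic")`.
#' @param scheme `"cv"` (default) or `"insample"`.
#' @param k folds (default 5; reduced with a warning if a class has
#'   fewer members than folds).
#' @param seed RNG seed controlling folds and the stochastic learners.
#' @return Data frame with `model`, `auc`, `scheme`; attribute
#'   `"scores"` holds the per-subject pooled scores by model.
#' @export
compare_classifiers <- function(features, labels,
                                models = c("svm", "decision_tree",
                                           "random_forest", "knn",
                                           "logistic"),
                                scheme = c("cv", "insample"), k = 5,
                                seed = 1) {
  scheme <- match.arg(scheme)
  models <- match.arg(models, several.ok = TRUE)
  X <- as.data.frame(features)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  ntab <- min(table(y))
  if (scheme == "cv" && ntab < k) {
    warning(sprintf("smallest class has %d members; reducing folds to %d",
                    ntab, ntab))
    k <- ntab
  }
  set.seed(seed)
  folds <- if (scheme == "cv") stratified_folds(y, k) else
    rep(1L, length(y))
  scores <- matrix(NA_real_, length(y), length(models),
                   dimnames = list(NULL, models))
  for (f in sort(unique(folds))) {
    test <- if (scheme == "cv") folds == f else rep(TRUE, length(y))
    train <- if (scheme == "cv") !test else rep(TRUE, length(y))
    for (m in models) {
      scores[test, m] <- fit_score_model(m, X[train, , drop = FALSE],
                                         y[train], X[test, , drop = FALSE])
    }
  }
  out <- data.frame(model = models,
                    auc = vapply(models, function(m)
                      roc_auc(scores[, m], y)$auc, numeric(1)),
                    scheme = scheme, row.names = NULL)
  attr(out, "scores") <- scores
  out
}

fit_score_model <- function(model, Xtr, ytr, Xte) {
  yf <- factor(ytr, levels = c(0, 1))
  switch(model,
    svm = {
      fit <- e1071::svm(Xtr, yf, kernel = "radial", cost = 1,
                        probability = TRUE)
      pr <- attr(stats::predict(fit, Xte, probability = TRUE),
                 "probabilities")
      pr[, "1"]
    },
    decision_tree = {
      dtr <- cbind(Xtr, .y = yf)
      fit <- rpart::rpart(.y ~ ., data = dtr, method = "class")
      stats::predict(fit, Xte)[, "1"]
    },
    random_forest = {
      fit <- randomForest::randomForest(Xtr, yf, ntree = 500)
      stats::predict(fit, Xte, type = "prob")[, "1"]
    },
    knn = {
      kk <- min(5, nrow(Xtr))
      pred <- class::knn(scale_to(Xtr, Xtr), scale_to(Xte, Xtr), yf,
                         k = kk, prob = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "1", pr, 1 - pr)
    },
    logistic = {
      prtr <- suppressWarnings(logistic_predictive_prob(Xtr, ytr))
      beta <- attr(prtr, "coefficients")
      cols <- attr(prtr, "kept_features")
      stats::plogis(drop(cbind(1, as.matrix(Xte)[, cols, drop = FALSE]) %*% beta))
    },
    stop("unknown model ", model))
}

scale_to <- function(X, ref) {
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, stats::sd)
  sdv[sdv == 0] <- 1
  scale(as.matrix(X), center = mu, scale = sdv)
}
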