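# Independent oracles, deliberately plain-R and separate from the package's
# computation paths.

# Kendall's W by direct evaluation of the rank-sum formula with midranks
# and tie correction.
kcc_formula_R <- function(block) {
  block <- as.matrix(block)
  n <- nrow(block); K <- ncol(block)
  R <- apply(block, 2, rank)
  tiecorr <- sum(apply(block, 2, function(col) {
    g <- table(col)
    sum(g^3 - g)
  }))
  S <- sum((rowSums(R) - K * (n + 1) / 2)^2)
  12 * S / (K^2 * (n^3 - n) - K * tiecorr)
}

# Kendall's W from the mean pairwise Spearman correlation (valid without
# ties): W = ((K - 1) * mean_rho + 1) / K.
kcc_spearman_oracle <- function(block) {
  block <- as.matrix(block)
  K <- ncol(block)
  C <- stats::cor(apply(block, 2, rank))
  rho_bar <- mean(C[upper.tri(C)])
  ((K - 1) * rho_bar + 1) / K
}

# Monte-Carlo null level of W for K independent series of length n.
null_w_mc <- function(K, n, B = 1000, seed = 99) {
  set.seed(seed)
  mean(replicate(B, kcc_formula_R(matrix(stats::runif(n * K), n, K))))
}

# small BOLD series filled with iid noise
noise_bold <- function(d = c(9, 9, 9), nt = 60, tr = 2, seed = 1) {
  set.seed(seed)
  bold_series(array(stats::rnorm(prod(d) * nt), dim = c(d, nt)), tr_s = tr)
}

# single-frequency sinusoid BOLD (one voxel line), for filter checks
sinusoid_series <- function(f_hz, nt = 230, tr = 2) {
  sin(2 * pi * f_hz * (0:(nt - 1)) * tr)
}

rms <- function(x) sqrt(mean(x^2))

# desk-scale config small enough for per-test use; any cohort_config
# argument can be overridden
tiny_config <- function(...) {
  defaults <- list(
    n_patients = 2, n_controls = 2, grid_shape = c(12, 12, 10),
    n_volumes = 120,
    effect_regions = list(
      list(name = "sync_down", kind = "reho_down", center = c(4, 4, 5),
           radius = 1, magnitude = 0.3),
      list(name = "sync_up", kind = "reho_up", center = c(9, 9, 5),
           radius = 1, magnitude = 0.3),
      list(name = "dyn_up", kind = "dreho_up", center = c(4, 9, 5),
           radius = 1, magnitude = 0.8)))
  dots <- list(...)
  args <- defaults
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}
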