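# Shared fixture builders; everything is generated in code at test time.

# absolute-tolerance comparison (expect_equal's tolerance is relative)
expect_near <- function(object, expected, tol) {
  testthat::expect_lt(max(abs(object - expected)), tol)
}

# balanced design: n pairs per zygosity group
design_per_group <- function(n, seed, ...) {
  cohort_design(n, n, n, n, n, seed = seed, ...)
}

# MZ/DZ-balanced large design used for convergence-in-n checks
design_mzdz <- function(n_mz, n_dz, seed, ...) {
  a <- ceiling(n_mz / 2)
  c1 <- floor(n_dz / 3)
  cohort_design(a, n_mz - a, c1, c1, n_dz - 2 * c1, seed = seed, ...)
}

# the six-indicator common pathway generator used across tests: common
# factor 64/8/28 with loadings spanning 0.54-0.75; indicator residuals
# mostly nonshared environment with a modest genetic part
cp_gen6 <- function() {
  common_pathway_gen(variance_components(0.64, 0.08, 0.28),
                     loadings = c(0.54, 0.58, 0.63, 0.67, 0.71, 0.75),
                     specific_ace = variance_components(0.20, 0.05, 0.75),
                     phenotypes = c("sc", "pt", "nd", "rm", "mr", "nl"))
}

# 16-indicator hierarchical AE generator: second-order factor 84% genetic,
# first-order loadings giving R2 = 0.79 / 0.69 / 1.00, factor-level
# residual genetic variances 0.05 / 0.27 / 0
hier_gen16 <- function() {
  hierarchical_gen(
    common_ace = variance_components(0.84, 0, 0.16),
    factor_loadings = c(sqrt(0.79), 0.81, 1.0),
    factor_specific_ace = list(
      variance_components(0.05 / 0.21, 0, 1 - 0.05 / 0.21),
      variance_components(0.27 / 0.3439, 0, 1 - 0.27 / 0.3439),
      variance_components(0.5, 0, 0.5)),
    loadings = c(0.75, 0.72, 0.70, 0.65, 0.60, 0.54,
                 0.74, 0.70, 0.68, 0.65, 0.62, 0.58,
                 0.72, 0.68, 0.64, 0.60),
    factor_map = rep(1:3, c(6, 6, 4)),
    specific_ace = variance_components(0.25, 0, 0.75),
    phenotypes = c(paste0("nav", 1:6), paste0("obj", 1:6), paste0("vis", 1:4)),
    factor_names = c("Navigation", "ObjectManipulation", "Visualization"))
}

# bivariate AE Cholesky: general ability (70% genetic) entered first,
# spatial factor 84% genetic with 55% of its genetic variance shared
chol_gen_g <- function() {
  LA <- matrix(c(sqrt(0.70), 0,
                 sqrt(0.55 * 0.84), sqrt(0.45 * 0.84)), 2, byrow = TRUE)
  LE <- matrix(c(sqrt(0.30), 0,
                 sqrt(0.20 * 0.16), sqrt(0.80 * 0.16)), 2, byrow = TRUE)
  cholesky_gen(LA, LE, phenotypes = c("g", "spatial"))
}

# closed-form multivariate-normal -2 log-likelihood of complete rows,
# written independently of the package's sufficient-statistic path
m2ll_closed_form <- function(Y, mu, Sigma) {
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  ch <- chol(Sigma)
  logdet <- 2 * sum(log(diag(ch)))
  Z <- backsolve(ch, t(Y) - mu, transpose = TRUE)
  nrow(Y) * (logdet + ncol(Y) * log(2 * pi)) + sum(Z^2)
}

# cross-twin covariance block (p x p) of a cohort restricted to given rows
cross_twin_cov <- function(cohort, rows = TRUE) {
  ph <- phenotypes(cohort)
  p <- length(ph)
  Y1 <- as.matrix(as.data.frame(cohort)[rows, paste0(ph, "_t1"), drop = FALSE])
  Y2 <- as.matrix(as.data.frame(cohort)[rows, paste0(ph, "_t2"), drop = FALSE])
  stats::cov(Y1, Y2, use = "pairwise.complete.obs")
}
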