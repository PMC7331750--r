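# Maximum-likelihood CFA fitting and fit statistics.

# ML discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - p
f_ml <- function(S, Sigma, logdetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(BIG_PENALTY)
  2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S) - logdetS - nrow(S)
}

cfa_start <- function(spec, S) {
  v <- diag(S)
  lo <- rep(sqrt(mean(v)) * 0.6, spec$n_load)
  if (spec$structure == "bifactor") lo <- rep(sqrt(mean(v)) * 0.45, spec$n_load)
  st <- switch(spec$structure, correlated = rep(0.5, spec$n_struct),
               second_order = rep(0.7, spec$n_struct), numeric(0))
  c(lo, st, v * 0.5)
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p` over the model's free
#' parameters and reports the chi-squared statistic `T = (N - 1) F`, fit
#' indices against the independence baseline, and AIC. Residual variances
#' are unbounded by default, so inadmissible (Heywood) solutions are
#' allowed but flagged; `bounded = TRUE` re-parameterizes them on the log
#' scale.
#'
#' @param S Sample covariance matrix (symmetric positive definite).
#' @param N Number of observations behind `S`.
#' @param spec A [cfa_model()].
#' @param start Optional start values.
#' @param multistart Jittered restarts on non-convergence.
#' @param bounded Constrain residual variances to be positive.
#' @return An object of class `cfa_fit`: estimates, `T` statistic, df,
#'   CFI/TLI/RMSEA/SRMR, `m2ll`, `aic`, convergence and Heywood flags.
#' @examples
#' spec <- cfa_model(list(F1 = c("a", "b", "c")))
#' Sig <- implied_covariance(spec, c(0.7, 0.8, 0.6, 0.51, 0.36, 0.64))
#' fit_cfa(Sig, N = 500, spec = spec)
#' @export
fit_cfa <- function(S, N, spec, start = NULL, multistart = 10L,
                    bounded = FALSE) {
  stopifnot(inherits(spec, "cfa_model"))
  S <- as.matrix(S)
  p <- spec$p
  if (nrow(S) != p) stop("S does not match the model's indicators", call. = FALSE)
  if (!is.null(rownames(S)) && !identical(rownames(S), spec$indicators)) {
    if (!setequal(rownames(S), spec$indicators))
      stop("S row names do not match the model's indicators", call. = FALSE)
    S <- S[spec$indicators, spec$indicators]
  }
  if (N <= p) stop("N must exceed the number of indicators", call. = FALSE)
  if (spec$df < 0)
    stop("model has negative degrees of freedom (unidentified)", call. = FALSE)
  chS <- tryCatch(chol(S), error = function(e)
    stop("S must be positive definite", call. = FALSE))
  logdetS <- 2 * sum(log(diag(chS)))

  theta_idx <- spec$n_load + spec$n_struct + seq_len(p)
  to_natural <- function(par) {
    if (bounded) par[theta_idx] <- exp(par[theta_idx])
    par
  }
  start <- start %||% cfa_start(spec, S)
  if (bounded) start[theta_idx] <- log(pmax(start[theta_idx], 1e-4))
  fn <- function(par) f_ml(S, implied_covariance(spec, to_natural(par)), logdetS)
  opt <- minimize_m2ll(fn, start, multistart = multistart)
  est <- to_natural(opt$par)
  pp <- cfa_unpack(spec, est)
  Sigma <- implied_covariance(spec, est)
  Fmin <- max(opt$value, 0)
  T_stat <- (N - 1) * Fmin
  # independence baseline: free variances, zero covariances (closed form)
  T_base <- (N - 1) * (sum(log(diag(S))) - logdetS)
  df_base <- p * (p - 1) / 2
  idx <- fit_indices(T_stat, spec$df, T_base, df_base, N, S = S, Sigma = Sigma)
  m2ll <- (N - 1) * (determinant(Sigma)$modulus[1] +
                       sum(chol2inv(chol(Sigma)) * S) + p * log(2 * pi))
  heywood <- any(pp$theta < 0) ||
    (!is.null(pp$corr) && any(abs(pp$corr) > 1)) ||
    (!is.null(pp$gamma) && any(abs(pp$gamma) > 1))

  loads <- stats::setNames(numeric(p), spec$indicators)
  loads[] <- if (spec$structure == "bifactor") est[p + seq_len(p)] else est[seq_len(p)]
  structure(list(spec = spec, estimates = est, loadings = loads,
                 general_loadings = if (spec$structure == "bifactor")
                   stats::setNames(est[seq_len(p)], spec$indicators),
                 gamma = if (!is.null(pp$gamma))
                   stats::setNames(pp$gamma, names(spec$factors)),
                 phi = pp$Phi, theta = stats::setNames(pp$theta, spec$indicators),
                 implied = Sigma, S = S, N = N,
                 F_ml = Fmin, T = T_stat, df = spec$df,
                 T_baseline = T_base, df_baseline = df_base,
                 cfi = idx$cfi, tli = idx$tli, rmsea = idx$rmsea,
                 srmr = idx$srmr, m2ll = m2ll, npar = spec$npar,
                 aic = m2ll + 2 * spec$npar,
                 convergence = opt$convergence, restarts = opt$restarts,
                 heywood = heywood),
            class = "cfa_fit")
}

#' Covariance-structure fit indices
#'
#' CFI, TLI (clipped to `[0, 1]`), RMSEA and, when the sample and implied
#' matrices are supplied, SRMR over the unique elements including the
#' diagonal. `RMSEA = 0` whenever `T <= df` (including `df = 0`).
#'
#' @param T,df Model chi-squared statistic and degrees of freedom.
#' @param T_baseline,df_baseline Independence-baseline statistic and df.
#' @param N Sample size.
#' @param S,Sigma Optional sample and implied covariance matrices for SRMR.
#' @return List with `cfi`, `tli`, `rmsea` and `srmr` (NA if no matrices).
#' @export
fit_indices <- function(T, df, T_baseline, df_baseline, N,
                        S = NULL, Sigma = NULL) {
  num <- max(T - df, 0)
  den <- max(T_baseline - df_baseline, T - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (df == 0 || df_baseline == 0) 1 else {
    rb <- T_baseline / df_baseline
    if (rb <= 1) 1 else min(1, max(0, (rb - T / df) / (rb - 1)))
  }
  rmsea <- if (df == 0 || T <= df) 0 else sqrt((T - df) / (df * (N - 1)))
  srmr <- NA_real_
  if (!is.null(S) && !is.null(Sigma)) {
    d <- sqrt(diag(S))
    R <- (S - Sigma) / tcrossprod(d)
    srmr <- sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
  }
  list(cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr)
}

#' Akaike weights for a set of models
#'
#' Normalized evidence weights `w_i = exp(-Delta_i / 2) / sum_j
#' exp(-Delta_j / 2)` with `Delta_i = AIC_i - min(AIC)`; invariant to
#' adding a constant to every AIC.
#'
#' @param aic Numeric vector of AIC values for models fitted to the same
#'   data.
#' @return Weights summing to 1, preserving names.
#' @examples
#' aic_weights(c(one = 100, two = 102))
#' @export
aic_weights <- function(aic) {
  if (length(aic) < 2L) stop("need at least 2 models", call. = FALSE)
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Variance in a first-order factor explained by the general factor
#'
#' For a hierarchical (second-order) model with standardized factors this
#' is the squared second-order loading of the first-order factor.
#'
#' @param fit A [fit_cfa()] result with `structure = "second_order"`, or a
#'   hierarchical twin-model fit.
#' @param factor First-order factor name.
#' @return R-squared in `[0, ...]`.
#' @export
factor_r2 <- function(fit, factor) UseMethod("factor_r2")

#' @export
factor_r2.cfa_fit <- function(fit, factor) {
  if (is.null(fit$gamma))
    stop("factor_r2 requires a second-order model", call. = FALSE)
  unname(fit$gamma[factor]^2)
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("CFA fit (%s): T = %.3f, df = %d, CFI = %.3f, TLI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$spec$structure, x$T, x$df, x$cfi, x$tli, x$rmsea, x$srmr))
  cat(sprintf("  AIC = %.2f (npar = %d)%s%s\n", x$aic, x$npar,
              if (x$convergence == 0) "" else " [NOT CONVERGED]",
              if (x$heywood) " [Heywood case]" else ""))
  invisible(x)
}

#' @export
summary.cfa_fit <- function(object, ...) {
  print(object)
  cat("Standardized loadings:\n")
  std <- object$loadings / sqrt(diag(object$implied))
  print(round(std, 3))
  if (!is.null(object$gamma)) {
    cat("Second-order loadings:\n")
    print(round(object$gamma, 3))
  }
  invisible(object)
}

#' @export
coef.cfa_fit <- function(object, ...) object$estimates

#' @export
logLik.cfa_fit <- function(object, ...) {
  structure(-object$m2ll / 2, df = object$npar, class = "logLik")
}
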