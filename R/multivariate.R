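# Multivariate biometric models fitted by FIML: common pathway,
# hierarchical second-order, and Cholesky decomposition.
#
# Latent factor variances are identified by the spherical share
# parameterization (see utils.R): a factor's A/C/E paths live on the unit
# sphere, so its total variance is exactly 1 and the squared paths are the
# standardized components.

#' Path-tracing share of genetic variance captured by a common factor
#'
#' For a trait (or first-order factor) receiving genetic variance both
#' through a common factor and from a specific source, the proportion
#' attributable to the common factor is
#' `(common_a2 * loading^2) / (common_a2 * loading^2 + specific_a2)`.
#'
#' @param common_a2 Standardized genetic variance of the common factor.
#' @param loading Standardized path from the common factor to the trait.
#' @param specific_a2 Trait-specific genetic variance.
#' @return Proportion in `[0, 1]`.
#' @examples
#' path_trace_genetic_share(0.84, 0.81, 0.27)
#' @export
path_trace_genetic_share <- function(common_a2, loading, specific_a2) {
  if (common_a2 < 0 || specific_a2 < 0 || abs(loading) > 1)
    stop("inadmissible inputs", call. = FALSE)
  num <- common_a2 * loading^2
  tot <- num + specific_a2
  if (tot <= 0) stop("zero total genetic variance", call. = FALSE)
  num / tot
}

# assemble MZ/DZ pair covariance from phenotypic component matrices
pair_sigmas <- function(A, C, E, groups) {
  W <- A + C + E
  out <- lapply(groups, function(r) {
    X <- r * A + C
    rbind(cbind(W, X), cbind(t(X), W))
  })
  names(out) <- names(groups)
  out
}

fit_biometric <- function(gs, build_ACE, start, n_means, multistart = 10L) {
  # generic driver: build_ACE(par) -> list(A, C, E); means are the last
  # n_means parameters, equated over twin order and zygosity
  rg <- c(MZ = 1, DZ = 0.5)[names(gs)]
  fn <- function(par) {
    cm <- build_ACE(par)
    mu <- rep(par[length(par) - n_means + seq_len(n_means)], 2)
    sig <- pair_sigmas(cm$A, cm$C, cm$E, rg)
    models <- lapply(names(gs), function(g) list(mu = mu, Sigma = sig[[g]]))
    names(models) <- names(gs)
    fiml_m2ll_groups(gs, models)
  }
  minimize_m2ll(fn, start, multistart = multistart)
}

group_means_start <- function(cohort, phenos) {
  vapply(phenos, function(p) mean(pair_scores(cohort, p), na.rm = TRUE),
         numeric(1))
}

#' Common pathway twin model
#'
#' One latent factor, itself decomposed into A/C/E (variance fixed to 1),
#' drives all indicators through free loadings; every indicator residual
#' carries its own A/C/E (AE when `components = "AE"`) paths. Fitted by
#' FIML over MZ and DZ pair groups. Reports the common factor's
#' standardized components, standardized loadings, and the per-indicator
#' share of genetic variance captured by the common factor.
#'
#' @param cohort A [twin_cohort()] with both MZ and DZ pairs.
#' @param indicators Phenotypes to analyse (at least 3).
#' @param components `"ACE"` or `"AE"` for the factor and the residuals.
#' @param multistart Jittered restarts on non-convergence.
#' @return An object of class `c("common_pathway_fit", "twin_fit")`.
#' @export
fit_common_pathway <- function(cohort, indicators = phenotypes(cohort),
                               components = c("ACE", "AE"),
                               multistart = 10L) {
  components <- match.arg(components)
  p <- length(indicators)
  if (p < 3L) stop("need at least 3 indicators", call. = FALSE)
  gs <- twin_group_stats(cohort, indicators, scheme = "two")
  if (length(gs) < 2L) stop("need both MZ and DZ pairs", call. = FALSE)
  nc <- if (components == "ACE") 3L else 2L  # components per source
  n_ang <- nc - 1L

  # layout: factor angles | lambda (p) | specific paths (nc * p) | means (p)
  unpack <- function(par) {
    ang <- par[seq_len(n_ang)]
    lam <- par[n_ang + seq_len(p)]
    sp <- matrix(par[n_ang + p + seq_len(nc * p)], nrow = nc)
    fp <- angles_to_paths(ang)  # factor a, (c,) e paths; squares sum to 1
    if (components == "AE") { fpc <- 0; spc <- rep(0, p) }
    else { fpc <- fp[2]; spc <- sp[2, ] }
    fpa <- fp[1]; fpe <- fp[nc]
    spa <- sp[1, ]; spe <- sp[nc, ]
    ll <- tcrossprod(lam)
    list(lam = lam, f = c(a = fpa, c = fpc, e = fpe),
         spec = rbind(a = spa, c = spc, e = spe),
         A = fpa^2 * ll + diag(spa^2, p),
         C = fpc^2 * ll + diag(spc^2, p),
         E = fpe^2 * ll + diag(spe^2, p))
  }
  start <- c(shares_to_angles(if (components == "ACE") c(0.5, 0.2, 0.3)
                              else c(0.5, 0.5)),
             rep(0.6, p), rep(sqrt(0.64 / nc), nc * p),
             group_means_start(cohort, indicators))
  opt <- fit_biometric(gs, function(par) unpack(par), start, p, multistart)
  pp <- unpack(opt$par)
  common <- pp$f^2  # sums to 1 by construction
  tot_var <- diag(pp$A + pp$C + pp$E)
  std_load <- pp$lam / sqrt(tot_var)
  gshare <- (common[["a"]] * pp$lam^2) /
    (common[["a"]] * pp$lam^2 + pp$spec["a", ]^2)
  npar <- length(start)
  structure(list(indicators = indicators, components = components,
                 common = c(a2 = unname(common[["a"]]),
                            c2 = unname(common[["c"]]),
                            e2 = unname(common[["e"]])),
                 loadings = stats::setNames(pp$lam, indicators),
                 std_loadings = stats::setNames(std_load, indicators),
                 specific = structure(pp$spec^2,
                                      dimnames = list(c("a2", "c2", "e2"),
                                                      indicators)),
                 genetic_shares = stats::setNames(gshare, indicators),
                 total_variance = stats::setNames(tot_var, indicators),
                 m2ll = opt$value, npar = npar, aic = opt$value + 2 * npar,
                 convergence = opt$convergence, restarts = opt$restarts),
            class = c("common_pathway_fit", "twin_fit"))
}

#' @export
print.common_pathway_fit <- function(x, ...) {
  cat(sprintf("Common pathway model (%s), %d indicators\n", x$components,
              length(x$indicators)))
  cat(sprintf("  common factor: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$common["a2"], x$common["c2"], x$common["e2"]))
  cat("  standardized loadings:",
      paste(sprintf("%s %.2f", x$indicators, x$std_loadings), collapse = ", "),
      "\n")
  cat(sprintf("  -2lnL = %.3f, AIC = %.3f, npar = %d%s\n", x$m2ll, x$aic,
              x$npar, if (x$convergence == 0) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.common_pathway_fit <- function(object, ...) object$common

#' Hierarchical second-order biometric model
#'
#' A second-order general factor with its own A/E (or A/C/E) decomposition
#' loads on K first-order factors; first-order factor residuals and
#' indicator residuals carry their own components. All latent variances
#' are fixed to 1 through the spherical parameterization, so second-order
#' loadings `gamma_k`, factor residual paths and their squares are
#' standardized. Reports the second-order components, per-factor genetic
#' shares obtained by path tracing, and the factor R-squared on the
#' general factor.
#'
#' @param cohort A [twin_cohort()].
#' @param factors Named list mapping first-order factor names to indicator
#'   names; at least 3 factors with at least 2 indicators each.
#' @param components `"AE"` (default, no shared-environment paths) or
#'   `"ACE"`.
#' @param multistart Jittered restarts.
#' @return An object of class `c("hierarchical_twin_fit", "twin_fit")`.
#' @export
fit_hierarchical_model <- function(cohort, factors,
                                   components = c("AE", "ACE"),
                                   multistart = 10L) {
  components <- match.arg(components)
  K <- length(factors)
  if (K < 3L)
    stop("need at least 3 first-order factors for an identified hierarchy",
         call. = FALSE)
  if (any(lengths(factors) < 2L))
    stop("every first-order factor needs at least 2 indicators", call. = FALSE)
  indicators <- unlist(factors, use.names = FALSE)
  p <- length(indicators)
  map <- rep(seq_len(K), lengths(factors))
  gs <- twin_group_stats(cohort, indicators, scheme = "two")
  if (length(gs) < 2L) stop("need both MZ and DZ pairs", call. = FALSE)
  nc <- if (components == "ACE") 3L else 2L
  n_ang <- nc - 1L

  # layout: G angles (nc-1) | per-factor angles (nc each: the paths
  # (gamma_k, a_res, [c_res,] e_res) are a point on the unit sphere) |
  # lambda (p) | indicator specific paths (nc*p) | means (p)
  unpack <- function(par) {
    i <- 0L
    gpath <- angles_to_paths(par[i + seq_len(n_ang)]); i <- i + n_ang
    fmat <- matrix(0, nc + 1L, K)  # rows: gamma, a, (c,) e
    for (k in seq_len(K)) {
      fmat[, k] <- angles_to_paths(par[i + seq_len(nc)])
      i <- i + nc
    }
    lam <- par[i + seq_len(p)]; i <- i + p
    sp <- matrix(par[i + seq_len(nc * p)], nrow = nc)
    gam <- fmat[1L, ]
    gg <- tcrossprod(gam)
    Lam <- matrix(0, p, K)
    Lam[cbind(seq_len(p), map)] <- lam
    comp_mat <- function(g2, fres, spec) {
      AF <- g2 * gg + diag(fres^2, K)
      Lam %*% AF %*% t(Lam) + diag(spec^2, p)
    }
    if (components == "AE") {
      A <- comp_mat(gpath[1]^2, fmat[2L, ], sp[1L, ])
      C <- matrix(0, p, p)
      E <- comp_mat(gpath[2]^2, fmat[3L, ], sp[2L, ])
      g_shares <- c(a2 = gpath[1]^2, c2 = 0, e2 = gpath[2]^2)
      fres_a <- fmat[2L, ]
    } else {
      A <- comp_mat(gpath[1]^2, fmat[2L, ], sp[1L, ])
      C <- comp_mat(gpath[2]^2, fmat[3L, ], sp[2L, ])
      E <- comp_mat(gpath[3]^2, fmat[4L, ], sp[3L, ])
      g_shares <- c(a2 = gpath[1]^2, c2 = gpath[2]^2, e2 = gpath[3]^2)
      fres_a <- fmat[2L, ]
    }
    list(A = A, C = C, E = E, gamma = gam, g_shares = g_shares,
         fres_a = fres_a, fmat = fmat, lam = lam, spec = sp)
  }
  start <- c(shares_to_angles(if (components == "AE") c(0.7, 0.3)
                              else c(0.6, 0.1, 0.3)),
             rep(shares_to_angles(if (components == "AE") c(0.7, 0.15, 0.15)
                                  else c(0.65, 0.15, 0.05, 0.15)), K),
             rep(0.7, p), rep(sqrt(0.5 / nc), nc * p),
             group_means_start(cohort, indicators))
  opt <- fit_biometric(gs, function(par) unpack(par), start, p, multistart)
  pp <- unpack(opt$par)
  # per-factor share of genetic variance captured by the general factor
  fshare <- vapply(seq_len(K), function(k)
    path_trace_genetic_share(pp$g_shares[["a2"]], pp$gamma[k], pp$fres_a[k]^2),
    numeric(1))
  npar <- length(start)
  structure(list(factors = factors, indicators = indicators,
                 components = components,
                 second_order = pp$g_shares,
                 gamma = stats::setNames(pp$gamma, names(factors)),
                 factor_r2 = stats::setNames(pp$gamma^2, names(factors)),
                 factor_residual_a2 = stats::setNames(pp$fres_a^2, names(factors)),
                 factor_genetic_shares = stats::setNames(fshare, names(factors)),
                 loadings = stats::setNames(pp$lam, indicators),
                 specific = structure(pp$spec^2, dimnames = list(
                   if (components == "AE") c("a2", "e2") else c("a2", "c2", "e2"),
                   indicators)),
                 m2ll = opt$value, npar = npar, aic = opt$value + 2 * npar,
                 convergence = opt$convergence, restarts = opt$restarts),
            class = c("hierarchical_twin_fit", "twin_fit"))
}

#' @export
print.hierarchical_twin_fit <- function(x, ...) {
  cat(sprintf("Hierarchical %s biometric model: %d indicators, %d first-order factors\n",
              x$components, length(x$indicators), length(x$factors)))
  cat(sprintf("  general factor: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$second_order["a2"], x$second_order["c2"], x$second_order["e2"]))
  for (k in seq_along(x$factors))
    cat(sprintf("  %-16s gamma = %.2f (R2 = %.2f), genetic share from general = %.2f\n",
                names(x$factors)[k], x$gamma[k], x$factor_r2[k],
                x$factor_genetic_shares[k]))
  cat(sprintf("  -2lnL = %.3f, AIC = %.3f, npar = %d%s\n", x$m2ll, x$aic,
              x$npar, if (x$convergence == 0) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.hierarchical_twin_fit <- function(object, ...) object$second_order

#' @export
factor_r2.hierarchical_twin_fit <- function(fit, factor) {
  unname(fit$factor_r2[factor])
}

#' Cholesky decomposition of twin data
#'
#' Triangular genetic and environmental path matrices over explicitly
#' ordered phenotypes, fitted by FIML; the implied A (and C, E) covariance
#' matrices are positive semidefinite for every parameter value. Reports,
#' for each trait, the proportion of its genetic variance accounted for by
#' each preceding trait's genetic factor versus the variance unique to it.
#'
#' @param cohort A [twin_cohort()].
#' @param phenos Phenotypes in Cholesky order (the conditioning trait, for
#'   example a general cognitive ability composite, first).
#' @param components `"AE"` (default) or `"ACE"`.
#' @param multistart Jittered restarts.
#' @return An object of class `c("cholesky_fit", "twin_fit")` with path
#'   matrices and the per-trait `genetic_shares` matrix (rows sum to 1).
#' @export
fit_cholesky <- function(cohort, phenos = phenotypes(cohort),
                         components = c("AE", "ACE"), multistart = 10L) {
  components <- match.arg(components)
  p <- length(phenos)
  gs <- twin_group_stats(cohort, phenos, scheme = "two")
  if (length(gs) < 2L) stop("need both MZ and DZ pairs", call. = FALSE)
  nl <- p * (p + 1L) / 2L
  nc <- if (components == "ACE") 3L else 2L

  unpack <- function(par) {
    LA <- vec_to_lower(par[seq_len(nl)], p)
    LE <- vec_to_lower(par[nl + seq_len(nl)], p)
    LC <- if (components == "ACE") vec_to_lower(par[2L * nl + seq_len(nl)], p)
    list(LA = LA, LC = LC, LE = LE,
         A = tcrossprod(LA),
         C = if (is.null(LC)) matrix(0, p, p) else tcrossprod(LC),
         E = tcrossprod(LE))
  }
  SW <- pooled_within_cov(cohort, phenos)
  half <- tryCatch(t(chol(SW / nc)), error = function(e) diag(sqrt(0.4), p))
  start <- c(lower_to_vec(half), lower_to_vec(half),
             if (components == "ACE") lower_to_vec(half),
             group_means_start(cohort, phenos))
  opt <- fit_biometric(gs, function(par) unpack(par), start, p, multistart)
  pp <- unpack(opt$par)
  gshare <- pp$LA^2 / rowSums(pp$LA^2)
  dimnames(gshare) <- list(phenos, paste0("A", seq_len(p)))
  npar <- length(start)
  structure(list(phenotypes = phenos, components = components,
                 a_paths = pp$LA, c_paths = pp$LC, e_paths = pp$LE,
                 A = pp$A, C = pp$C, E = pp$E,
                 genetic_shares = gshare,
                 trait_components = {
                   tot <- diag(pp$A + pp$C + pp$E)
                   cbind(a2 = diag(pp$A) / tot, c2 = diag(pp$C) / tot,
                         e2 = diag(pp$E) / tot)
                 },
                 m2ll = opt$value, npar = npar, aic = opt$value + 2 * npar,
                 convergence = opt$convergence, restarts = opt$restarts),
            class = c("cholesky_fit", "twin_fit"))
}

#' @export
print.cholesky_fit <- function(x, ...) {
  cat(sprintf("Cholesky %s decomposition over: %s\n", x$components,
              paste(x$phenotypes, collapse = " -> ")))
  cat("  per-trait genetic variance shares (by source factor):\n")
  print(round(x$genetic_shares, 3))
  cat(sprintf("  -2lnL = %.3f, AIC = %.3f, npar = %d%s\n", x$m2ll, x$aic,
              x$npar, if (x$convergence == 0) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.cholesky_fit <- function(object, ...) object$trait_components
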