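# Univariate twin analysis: intraclass correlations, Falconer estimates,
# ACE model fitting by FIML, profile-likelihood confidence intervals.

icc_anova <- function(Y) {
  # one-way random-effects intraclass correlation for pairs (k = 2)
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  n <- nrow(Y)
  if (n < 2L) return(NA_real_)
  m <- mean(Y)
  pm <- rowMeans(Y)
  msb <- 2 * sum((pm - m)^2) / (n - 1)
  msw <- sum((Y - pm)^2) / n
  (msb - msw) / (msb + msw)
}

icc_double_entry <- function(Y) {
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  if (nrow(Y) < 2L) return(NA_real_)
  stats::cor(c(Y[, 1], Y[, 2]), c(Y[, 2], Y[, 1]))
}

#' Twin intraclass correlations by zygosity
#'
#' ANOVA-based intraclass correlations per zygosity class (MZ vs DZ, with
#' opposite-sex pairs counted as DZ) and per five-level group. A
#' double-entry Pearson correlation is available as an alternative
#' estimator.
#'
#' @param cohort A [twin_cohort()].
#' @param phenotype Phenotype name.
#' @param method `"anova"` (default) or `"double_entry"`.
#' @return List with `rMZ`, `rDZ`, per-group correlations and the method
#'   used.
#' @export
intraclass_correlations <- function(cohort, phenotype,
                                    method = c("anova", "double_entry")) {
  method <- match.arg(method)
  est <- if (method == "anova") icc_anova else icc_double_entry
  Y <- pair_scores(cohort, phenotype)
  if (sum(stats::complete.cases(Y)) < 4L)
    stop("need at least 2 complete pairs per zygosity class", call. = FALSE)
  mz <- cohort$zygosity %in% c("MZm", "MZf")
  by_group <- sapply(ZYGOSITY_LEVELS, function(g) {
    rows <- cohort$zygosity == g
    if (sum(rows) < 2L) NA_real_ else est(Y[rows, , drop = FALSE])
  })
  list(rMZ = est(Y[mz, , drop = FALSE]), rDZ = est(Y[!mz, , drop = FALSE]),
       by_group = by_group, method = method)
}

#' Falconer variance-component estimates
#'
#' Closed-form decomposition from twin intraclass correlations:
#' `h2 = 2 (rMZ - rDZ)`, `c2 = 2 rDZ - rMZ`, `e2 = 1 - rMZ`. Values are
#' returned unclipped; `admissible` flags whether all three lie in
#' `[0, 1]`.
#'
#' @param rMZ,rDZ Intraclass correlations in `[-1, 1]`.
#' @return List with `a2`, `c2`, `e2` and logical `admissible`.
#' @examples
#' falconer_estimates(0.55, 0.35)
#' @export
falconer_estimates <- function(rMZ, rDZ) {
  if (abs(rMZ) > 1 || abs(rDZ) > 1)
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  a2 <- 2 * (rMZ - rDZ)
  c2 <- 2 * rDZ - rMZ
  e2 <- 1 - rMZ
  list(a2 = a2, c2 = c2, e2 = e2,
       admissible = all(c(a2, c2, e2) >= 0 & c(a2, c2, e2) <= 1))
}

ACE_SUBMODELS <- list(ACE = c("a", "c", "e"), AE = c("a", "e"),
                      CE = c("c", "e"), E = "e")

# Sigma for one univariate group: within variance a2+c2+e2, cross-twin
# r_g a2 + c2 (paths enter squared, so negative paths are admissible)
uni_sigma <- function(a, c, e, r_g) {
  v <- a^2 + c^2 + e^2
  x <- r_g * a^2 + c^2
  matrix(c(v, x, x, v), 2, 2)
}

#' Univariate ACE model by full-information maximum likelihood
#'
#' Fits the classical twin variance decomposition (or a nested submodel) to
#' one phenotype, maximizing the multivariate-normal likelihood restricted
#' to each pair's observed scores, with a single mean equated over twin
#' order and zygosity. Components are parameterized as unconstrained paths
#' `a`, `c`, `e` (reported as squares), so no bound constraints are needed.
#'
#' @param cohort A [twin_cohort()]; both MZ and DZ pairs must be present.
#' @param phenotype Phenotype name.
#' @param submodel One of `"ACE"`, `"AE"`, `"CE"`, `"E"`.
#' @param multistart Number of jittered restarts on non-convergence.
#' @return An object of class `c("ace_fit", "twin_fit")` with standardized
#'   components (summing to 1), raw paths, `m2ll` (-2 log-likelihood),
#'   `aic`, parameter count and convergence diagnostics. Use [confint()]
#'   for profile-likelihood intervals and [lrt()] for nested comparisons.
#' @examples
#' cohort <- simulate_univariate_cohort(
#'   cohort_design(200, 200, 200, 200, 200, seed = 7),
#'   variance_components(0.5, 0.1, 0.4))
#' fit <- fit_univariate_ace(cohort, "trait")
#' fit
#' @export
fit_univariate_ace <- function(cohort, phenotype,
                               submodel = c("ACE", "AE", "CE", "E"),
                               multistart = 10L) {
  submodel <- match.arg(submodel)
  comps <- ACE_SUBMODELS[[submodel]]
  Y <- pair_scores(cohort, phenotype)
  if (all(is.na(Y))) stop("all-missing phenotype", call. = FALSE)
  gs <- twin_group_stats(cohort, phenotype, scheme = "two")
  if (length(gs) < 2L && submodel != "E")
    stop("need both MZ and DZ pairs", call. = FALSE)
  rg <- c(MZ = 1, DZ = 0.5)[names(gs)]

  v0 <- stats::var(c(Y), na.rm = TRUE)
  m0 <- mean(Y, na.rm = TRUE)
  start <- c(m0, rep(sqrt(v0 / length(comps)), length(comps)))

  unpack <- function(par) {
    paths <- c(a = 0, c = 0, e = 0)
    paths[comps] <- par[-1L]
    list(mu = par[1L], paths = paths)
  }
  fn <- function(par) {
    pp <- unpack(par)
    models <- lapply(rg, function(r)
      list(mu = rep(pp$mu, 2),
           Sigma = uni_sigma(pp$paths["a"], pp$paths["c"], pp$paths["e"], r)))
    names(models) <- names(gs)
    fiml_m2ll_groups(gs, models)
  }
  opt <- minimize_m2ll(fn, start, multistart = multistart)
  pp <- unpack(opt$par)
  sq <- pp$paths^2
  shares <- sq / sum(sq)
  npar <- length(start)
  structure(list(phenotype = phenotype, submodel = submodel,
                 mean = pp$mu, paths = pp$paths,
                 components = c(a2 = unname(shares["a"]),
                                c2 = unname(shares["c"]),
                                e2 = unname(shares["e"])),
                 total_variance = sum(sq),
                 m2ll = opt$value, npar = npar, aic = opt$value + 2 * npar,
                 n_pairs = vapply(gs, function(s) sum(vapply(s, `[[`, 0, "n")),
                                  numeric(1)),
                 convergence = opt$convergence, restarts = opt$restarts,
                 group_stats = gs, r_g = rg),
            class = c("ace_fit", "twin_fit"))
}

#' Likelihood-ratio test between nested twin or factor model fits
#'
#' @param full,reduced Two fits of the same data, `reduced` nested in
#'   `full`.
#' @return List with `chisq`, `df` and `p`.
#' @export
lrt <- function(full, reduced) {
  chisq <- max(reduced$m2ll - full$m2ll, 0)
  df <- full$npar - reduced$npar
  if (df <= 0) stop("'reduced' must have fewer parameters", call. = FALSE)
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

# profile -2lnL of a univariate fit with one standardized share fixed at t;
# shares are re-parameterized as (mu, log total variance, free split) so
# the constraint "shares sum to 1" is built in
profile_m2ll_share <- function(fit, comp, t) {
  comps <- ACE_SUBMODELS[[fit$submodel]]
  others <- setdiff(comps, comp)
  gs <- fit$group_stats
  rg <- fit$r_g
  obj <- function(par) {
    mu <- par[1L]; V <- exp(par[2L])
    shares <- c(a = 0, c = 0, e = 0)
    shares[comp] <- t
    if (length(others) == 1L) {
      shares[others] <- 1 - t
    } else {
      u <- stats::plogis(par[3L])
      shares[others[1L]] <- (1 - t) * u
      shares[others[2L]] <- (1 - t) * (1 - u)
    }
    models <- lapply(rg, function(r) {
      Sw <- V
      Sx <- V * (r * shares["a"] + shares["c"])
      list(mu = rep(mu, 2), Sigma = matrix(c(Sw, Sx, Sx, Sw), 2, 2))
    })
    names(models) <- names(gs)
    fiml_m2ll_groups(gs, models)
  }
  start <- c(fit$mean, log(fit$total_variance), if (length(others) == 2L) 0)
  minimize_m2ll(obj, start, multistart = 4L)$value
}

#' Profile-likelihood confidence interval for a standardized component
#'
#' Bounds are found where -2 log-likelihood rises by the chi-squared(1)
#' quantile above its minimum, profiling out the mean, the total variance
#' and the remaining variance split. Bounds are clipped to the admissible
#' range `[0, 1]`; a bound stuck at the boundary is reported as one-sided.
#'
#' @param fit An [fit_univariate_ace()] result.
#' @param parameter One of `"a2"`, `"c2"`, `"e2"` (must be part of the
#'   fitted submodel).
#' @param level Confidence level.
#' @return Named numeric `c(lower, upper)` with attribute `one_sided`.
#' @export
likelihood_ci <- function(fit, parameter = c("a2", "c2", "e2"), level = 0.95) {
  stopifnot(inherits(fit, "ace_fit"))
  parameter <- match.arg(parameter)
  comp <- substr(parameter, 1, 1)
  if (!comp %in% ACE_SUBMODELS[[fit$submodel]])
    stop(parameter, " is not free in submodel ", fit$submodel, call. = FALSE)
  est <- fit$components[[parameter]]
  target <- fit$m2ll + stats::qchisq(level, 1)
  f <- function(t) profile_m2ll_share(fit, comp, t) - target
  eps <- 1e-6
  one_sided <- c(lower = FALSE, upper = FALSE)
  lower <- if (est <= eps || f(eps) < 0) {
    one_sided["lower"] <- TRUE; 0
  } else stats::uniroot(f, c(eps, est), tol = 1e-5)$root
  upper <- if (est >= 1 - eps || f(1 - eps) < 0) {
    one_sided["upper"] <- TRUE; 1
  } else stats::uniroot(f, c(est, 1 - eps), tol = 1e-5)$root
  structure(c(lower = lower, upper = upper), one_sided = one_sided,
            level = level, parameter = parameter)
}

#' @export
confint.ace_fit <- function(object, parm = c("a2", "c2", "e2"), level = 0.95,
                            ...) {
  parm <- intersect(parm, paste0(ACE_SUBMODELS[[object$submodel]], "2"))
  out <- t(vapply(parm, function(p) likelihood_ci(object, p, level),
                  numeric(2)))
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("%s model for '%s' (FIML over %s pairs)\n", x$submodel,
              x$phenotype, paste(names(x$n_pairs), x$n_pairs, collapse = ", ")))
  cat(sprintf("  standardized components: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$components["a2"], x$components["c2"], x$components["e2"]))
  cat(sprintf("  -2lnL = %.3f, AIC = %.3f, npar = %d%s\n", x$m2ll, x$aic,
              x$npar, if (x$convergence == 0) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.ace_fit <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  out <- data.frame(estimate = object$components[rownames(ci)], ci)
  cat(sprintf("%s fit for '%s': -2lnL = %.3f, AIC = %.3f\n",
              object$submodel, object$phenotype, object$m2ll, object$aic))
  print(round(out, 3))
  invisible(out)
}

#' @export
coef.ace_fit <- function(object, ...) object$components

#' @export
logLik.twin_fit <- function(object, ...) {
  structure(-object$m2ll / 2, df = object$npar, class = "logLik")
}

#' @export
plot.ace_fit <- function(x, ci = FALSE, level = 0.95, ...) {
  est <- x$components
  b <- graphics::barplot(est, ylim = c(0, 1), col = c("#33669988", "#99333388",
                                                      "#33993388"),
                         ylab = "standardized variance share",
                         main = sprintf("%s decomposition of '%s'",
                                        x$submodel, x$phenotype), ...)
  if (ci) {
    cis <- confint(x, level = level)
    keep <- match(rownames(cis), names(est))
    graphics::arrows(b[keep], cis[, 1], b[keep], cis[, 2], angle = 90,
                     code = 3, length = 0.06)
  }
  invisible(x)
}

#' @export
simulate.ace_fit <- function(object, nsim = 1, seed = NULL, design = NULL,
                             ...) {
  if (is.null(design))
    stop("supply a cohort_design describing the cohorts to simulate",
         call. = FALSE)
  if (!is.null(seed)) design$seed <- check_seed(seed)
  sh <- pmax(object$components, 0)
  vc <- variance_components(sh["a2"] / sum(sh), sh["c2"] / sum(sh),
                            sh["e2"] / sum(sh))
  out <- lapply(seq_len(nsim), function(i) {
    design$seed <- design$seed + i - 1L
    simulate_univariate_cohort(design, vc, object$phenotype)
  })
  if (nsim == 1L) out[[1L]] else out
}
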