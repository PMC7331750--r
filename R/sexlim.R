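# Five-group sex-limitation modelling.
#
# Nested sequence, each model fitted by FIML over the five sex/zygosity
# groups (MZm, MZf, DZm, DZf, DOS; opposite-sex pairs reordered male
# first):
#   qualitative  - sex-specific a, c, e and means, DOS additive-genetic
#                  correlation free in (0, 0.5)
#   quantitative - sex-specific a, c, e and means, DOS r_g fixed at 0.5
#   scalar       - equal standardized components, male variance scaled
#   homogeneity  - all parameters equated across sexes
SEXLIM_MODELS <- c("qualitative", "quantitative", "scalar", "homogeneity")

sexlim_sigma <- function(pm, pf, r_g, group) {
  # pm/pf: c(a, c, e) paths for males and females
  vm <- sum(pm^2); vf <- sum(pf^2)
  switch(group,
         MZm = uni_sigma(pm[1], pm[2], pm[3], 1),
         DZm = uni_sigma(pm[1], pm[2], pm[3], 0.5),
         MZf = uni_sigma(pf[1], pf[2], pf[3], 1),
         DZf = uni_sigma(pf[1], pf[2], pf[3], 0.5),
         DOS = {
           x <- r_g * pm[1] * pf[1] + pm[2] * pf[2]
           matrix(c(vm, x, x, vf), 2, 2)
         })
}

sexlim_build <- function(model, par, groups) {
  # returns list per group of list(mu, Sigma)
  get <- switch(model,
    qualitative = function(par) list(mum = par[1], muf = par[2],
                                     pm = par[3:5], pf = par[6:8],
                                     rg = 0.5 * stats::plogis(par[9])),
    quantitative = function(par) list(mum = par[1], muf = par[2],
                                      pm = par[3:5], pf = par[6:8], rg = 0.5),
    scalar = function(par) list(mum = par[1], muf = par[2],
                                pm = par[6] * par[3:5], pf = par[3:5],
                                rg = 0.5),
    homogeneity = function(par) list(mum = par[1], muf = par[1],
                                     pm = par[2:4], pf = par[2:4], rg = 0.5))
  pp <- get(par)
  out <- lapply(groups, function(g) {
    mu <- switch(g, MZm = , DZm = rep(pp$mum, 2), MZf = , DZf = rep(pp$muf, 2),
                 DOS = c(pp$mum, pp$muf))
    list(mu = mu, Sigma = sexlim_sigma(pp$pm, pp$pf, pp$rg, g))
  })
  names(out) <- groups
  out
}

sexlim_npar <- c(qualitative = 9L, quantitative = 8L, scalar = 6L,
                 homogeneity = 4L)

#' Five-group sex-limitation model sequence
#'
#' Fits the nested sex-limitation sequence (qualitative, quantitative,
#' scalar, homogeneity) to one phenotype by FIML across the five
#' sex-by-zygosity groups, and reports chi-squared difference tests between
#' successive models. Qualitative sex differences are modelled by freeing
#' the opposite-sex pairs' additive-genetic correlation below 0.5; without
#' opposite-sex pairs the qualitative model is skipped with a warning.
#'
#' @param cohort A [twin_cohort()] containing the five zygosity groups.
#' @param phenotype Phenotype name.
#' @param models Which models of the nested sequence to fit.
#' @param multistart Jittered restarts on non-convergence.
#' @return An object of class `sexlim_fit`: per-model fits (standardized
#'   male/female components, -2lnL, AIC) and the likelihood-ratio table.
#' @export
fit_sex_limitation <- function(cohort, phenotype, models = SEXLIM_MODELS,
                               multistart = 10L) {
  models <- match.arg(models, SEXLIM_MODELS, several.ok = TRUE)
  gs <- twin_group_stats(cohort, phenotype, scheme = "five",
                         male_first_dos = TRUE)
  if (!("DOS" %in% names(gs)) && "qualitative" %in% models) {
    warning("no opposite-sex pairs: qualitative sex-limitation model skipped")
    models <- setdiff(models, "qualitative")
  }
  groups <- names(gs)
  Y <- pair_scores(cohort, phenotype)
  v0 <- stats::var(c(Y), na.rm = TRUE)
  m0 <- mean(Y, na.rm = TRUE)
  p0 <- sqrt(v0 / 3)
  starts <- list(qualitative = c(m0, m0, rep(p0, 6), 2),
                 quantitative = c(m0, m0, rep(p0, 6)),
                 scalar = c(m0, m0, rep(p0, 3), 1),
                 homogeneity = c(m0, rep(p0, 3)))

  # fit the sequence restrictive-to-rich, warm-starting every richer model
  # from the nested solution so -2lnL is monotone to optimizer tolerance
  opts <- list()
  for (mod in rev(SEXLIM_MODELS)) {
    if (!mod %in% models) next
    prev <- switch(mod, scalar = opts$homogeneity,
                   quantitative = opts$scalar, qualitative = opts$quantitative)
    start <- starts[[mod]]
    if (!is.null(prev)) {
      p <- prev$par
      start <- switch(mod,
        scalar = c(p[1], p[1], p[2:4], 1),
        quantitative = c(p[1], p[2], p[6] * p[3:5], p[3:5]),
        qualitative = c(p, 6))  # r_g starts just below 0.5
    }
    fn <- local({
      mod_ <- mod
      function(par) fiml_m2ll_groups(gs, sexlim_build(mod_, par, groups))
    })
    opt <- minimize_m2ll(fn, start, multistart = multistart)
    if (!is.null(prev) && opt$value > prev$value)
      opt$value <- prev$value  # boundary solution: inherit the nested optimum
    opts[[mod]] <- opt
  }

  fits <- lapply(models, function(mod) {
    opt <- opts[[mod]]
    built <- sexlim_build(mod, opt$par, groups)
    std <- function(paths) { s <- paths^2; s / sum(s) }
    pm <- switch(mod, qualitative = , quantitative = opt$par[3:5],
                 scalar = opt$par[6] * opt$par[3:5], homogeneity = opt$par[2:4])
    pf <- switch(mod, qualitative = , quantitative = opt$par[6:8],
                 scalar = , homogeneity = opt$par[if (mod == "scalar") 3:5 else 2:4])
    list(model = mod,
         male = stats::setNames(std(pm), c("a2", "c2", "e2")),
         female = stats::setNames(std(pf), c("a2", "c2", "e2")),
         r_dos = if (mod == "qualitative") 0.5 * stats::plogis(opt$par[9]) else 0.5,
         m2ll = opt$value, npar = sexlim_npar[[mod]],
         aic = opt$value + 2 * sexlim_npar[[mod]],
         convergence = opt$convergence)
  })
  names(fits) <- models

  # chi-squared difference tests between successive fitted models
  lrt_tab <- NULL
  if (length(models) > 1L) {
    lrt_tab <- do.call(rbind, lapply(seq_len(length(models) - 1L), function(i) {
      f1 <- fits[[i]]; f0 <- fits[[i + 1L]]
      chisq <- max(f0$m2ll - f1$m2ll, 0)
      df <- f1$npar - f0$npar
      data.frame(comparison = paste(f0$model, "vs", f1$model),
                 chisq = chisq, df = df,
                 p = stats::pchisq(chisq, df, lower.tail = FALSE))
    }))
  }
  structure(list(phenotype = phenotype, fits = fits, lrt = lrt_tab,
                 n_pairs = vapply(gs, function(s)
                   sum(vapply(s, `[[`, 0, "n")), numeric(1))),
            class = "sexlim_fit")
}

#' @export
print.sexlim_fit <- function(x, ...) {
  cat(sprintf("Sex-limitation sequence for '%s' (%s)\n", x$phenotype,
              paste(names(x$n_pairs), x$n_pairs, collapse = ", ")))
  for (f in x$fits)
    cat(sprintf("  %-12s male a2/c2/e2 = %.2f/%.2f/%.2f  female = %.2f/%.2f/%.2f  -2lnL = %.2f\n",
                f$model, f$male[1], f$male[2], f$male[3],
                f$female[1], f$female[2], f$female[3], f$m2ll))
  if (!is.null(x$lrt)) {
    cat("Likelihood-ratio tests:\n")
    print(transform(x$lrt, chisq = round(chisq, 3), p = signif(p, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.sexlim_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$fits, function(f)
    data.frame(model = f$model, male_a2 = f$male[1], female_a2 = f$female[1],
               r_dos = f$r_dos, m2ll = f$m2ll, aic = f$aic, npar = f$npar)))
  rownames(tab) <- NULL
  tab
}
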