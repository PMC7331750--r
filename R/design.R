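#' Standardized variance components
#'
#' Bundle of standardized additive-genetic (`a2`), shared-environment (`c2`)
#' and nonshared-environment (`e2`) variance shares for one phenotype or one
#' latent factor. The three shares must be non-negative and sum to one (the
#' phenotype is taken as standardized).
#'
#' @param a2,c2,e2 Variance shares in `[0, 1]`, summing to 1 within `1e-8`.
#' @return An object of class `variance_components`.
#' @examples
#' variance_components(0.4, 0.15, 0.45)
#' @export
variance_components <- function(a2, c2 = 0, e2 = 1 - a2 - c2) {
  x <- c(a2 = a2, c2 = c2, e2 = e2)
  check_prob(x, "a2/c2/e2")
  if (abs(sum(x) - 1) > 1e-8)
    stop("a2 + c2 + e2 must equal 1 (within 1e-8)", call. = FALSE)
  structure(as.list(x), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("ACE variance shares: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$a2, x$c2, x$e2))
  invisible(x)
}

as_vc_list <- function(x, p, name) {
  # recycle a single variance_components over p indicators
  if (inherits(x, "variance_components")) x <- rep(list(x), p)
  if (!is.list(x) || length(x) != p ||
      !all(vapply(x, inherits, TRUE, "variance_components")))
    stop(sprintf("'%s' must be one variance_components or a list of %d", name, p),
         call. = FALSE)
  x
}

#' Twin cohort design
#'
#' Describes the sampling frame of a simulated twin cohort: pair counts for
#' the five zygosity groups (MZ male, MZ female, DZ male, DZ female, and DZ
#' opposite-sex), the age distribution, covariate effect sizes, the
#' missing-data rate, and the random seed that fully determines the cohort.
#'
#' The default group sizes reproduce a large UK young-adult twin register
#' wave (178 MZm, 169 MZf, 325 DZm, 260 DZf and 398 opposite-sex pairs,
#' ages centred on 21.2 years).
#'
#' @param n_mzm,n_mzf,n_dzm,n_dzf,n_dos Pair counts per zygosity group.
#' @param seed Integer seed; the same seed always yields a byte-identical
#'   cohort.
#' @param age_mean,age_sd Age distribution of pairs, in years.
#' @param sex_effect Standardized male-minus-female mean difference added to
#'   each phenotype by [apply_covariates_and_missingness()]; scalar or one
#'   value per phenotype.
#' @param age_effect Standardized slope of each phenotype on z-scored age;
#'   scalar or per phenotype.
#' @param missing_rate Probability that any single phenotype value is
#'   missing, independently per twin and per test (MCAR); scalar or per
#'   phenotype.
#' @return An object of class `cohort_design`.
#' @examples
#' cohort_design(178, 169, 325, 260, 398, seed = 1)
#' @export
cohort_design <- function(n_mzm = 178, n_mzf = 169, n_dzm = 325, n_dzf = 260,
                          n_dos = 398, seed, age_mean = 21.2, age_sd = 0.53,
                          sex_effect = 0, age_effect = 0, missing_rate = 0) {
  n <- c(MZm = n_mzm, MZf = n_mzf, DZm = n_dzm, DZf = n_dzf, DOS = n_dos)
  if (any(n < 0) || any(n != round(n)))
    stop("group sizes must be non-negative integers", call. = FALSE)
  check_prob(missing_rate, "missing_rate")
  if (age_sd <= 0) stop("'age_sd' must be positive", call. = FALSE)
  structure(list(group_sizes = n, seed = check_seed(seed),
                 age_mean = age_mean, age_sd = age_sd,
                 sex_effect = sex_effect, age_effect = age_effect,
                 missing_rate = missing_rate),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Twin cohort design\n")
  cat("  pairs:", paste(names(x$group_sizes), x$group_sizes, collapse = ", "),
      sprintf("(total %d)\n", sum(x$group_sizes)))
  cat(sprintf("  age ~ N(%.2f, %.2f); seed %d\n", x$age_mean, x$age_sd, x$seed))
  if (any(x$sex_effect != 0) || any(x$age_effect != 0) || any(x$missing_rate != 0))
    cat(sprintf("  covariates: sex d = %s, age beta = %s, missing = %s\n",
                paste(x$sex_effect, collapse = "/"),
                paste(x$age_effect, collapse = "/"),
                paste(x$missing_rate, collapse = "/")))
  invisible(x)
}

#' Common pathway generating model
#'
#' Generating structure for a one-common-factor common pathway model: a
#' latent factor with its own A/C/E decomposition drives all indicators
#' through standardized loadings, and each indicator's residual variance
#' (`1 - lambda^2`) has its own A/C/E composition.
#'
#' @param common_ace [variance_components()] of the latent common factor.
#' @param loadings Standardized indicator loadings, each in `[-1, 1]`.
#' @param specific_ace A/C/E composition of each indicator's residual
#'   variance: one [variance_components()] (recycled) or a list, one per
#'   indicator. The shares apply to the residual variance `1 - lambda_i^2`,
#'   so every indicator has total variance 1.
#' @param phenotypes Optional indicator names.
#' @return An object of class `common_pathway_gen`.
#' @examples
#' common_pathway_gen(variance_components(0.64, 0.08, 0.28),
#'                    loadings = c(0.54, 0.6, 0.75),
#'                    specific_ace = variance_components(0.2, 0.05, 0.75))
#' @export
common_pathway_gen <- function(common_ace, loadings, specific_ace,
                               phenotypes = NULL) {
  stopifnot(inherits(common_ace, "variance_components"))
  if (any(abs(loadings) > 1))
    stop("loadings must lie in [-1, 1]", call. = FALSE)
  p <- length(loadings)
  specific_ace <- as_vc_list(specific_ace, p, "specific_ace")
  phenotypes <- phenotypes %||% paste0("y", seq_len(p))
  stopifnot(length(phenotypes) == p)
  structure(list(common_ace = common_ace, loadings = loadings,
                 specific_ace = specific_ace, phenotypes = phenotypes),
            class = "common_pathway_gen")
}

#' Cholesky (triangular decomposition) generating model
#'
#' Generating structure in which ordered phenotypes receive their genetic
#' and environmental variance through lower-triangular path matrices, so the
#' implied A (and C, E) covariance matrices `L %*% t(L)` are positive
#' semidefinite by construction.
#'
#' @param a_paths,e_paths Lower-triangular genetic and nonshared-environment
#'   path matrices (p x p).
#' @param c_paths Optional lower-triangular shared-environment path matrix;
#'   omitted for an AE structure.
#' @param phenotypes Optional phenotype names, in Cholesky order.
#' @return An object of class `cholesky_gen`.
#' @export
cholesky_gen <- function(a_paths, e_paths, c_paths = NULL, phenotypes = NULL) {
  as_lower <- function(m, nm) {
    m <- as.matrix(m)
    if (nrow(m) != ncol(m) || any(m[upper.tri(m)] != 0))
      stop(sprintf("'%s' must be square lower-triangular", nm), call. = FALSE)
    m
  }
  a_paths <- as_lower(a_paths, "a_paths")
  e_paths <- as_lower(e_paths, "e_paths")
  p <- nrow(a_paths)
  stopifnot(nrow(e_paths) == p)
  if (!is.null(c_paths)) {
    c_paths <- as_lower(c_paths, "c_paths")
    stopifnot(nrow(c_paths) == p)
  }
  phenotypes <- phenotypes %||% paste0("y", seq_len(p))
  stopifnot(length(phenotypes) == p)
  structure(list(a_paths = a_paths, c_paths = c_paths, e_paths = e_paths,
                 phenotypes = phenotypes),
            class = "cholesky_gen")
}

#' Hierarchical (second-order) biometric generating model
#'
#' Generating structure for a hierarchical factor model of twin data: a
#' second-order general factor with its own A/C/E decomposition loads on K
#' first-order factors; each first-order factor's residual variance
#' (`1 - gamma_k^2`) and each indicator's residual variance
#' (`1 - lambda_i^2`) carry their own A/C/E composition. All latent factors
#' and indicators are standardized to unit variance.
#'
#' @param common_ace [variance_components()] of the second-order factor
#'   (set `c2 = 0` for an AE structure).
#' @param factor_loadings Standardized second-order loadings `gamma_k`, one
#'   per first-order factor, each in `[-1, 1]`.
#' @param factor_specific_ace Composition of each first-order factor's
#'   residual variance; one [variance_components()] (recycled) or a list.
#' @param loadings Standardized first-order indicator loadings `lambda_i`.
#' @param factor_map Integer or character vector assigning each indicator to
#'   a first-order factor.
#' @param specific_ace Composition of each indicator's residual variance.
#' @param phenotypes Optional indicator names.
#' @param factor_names Optional first-order factor names.
#' @return An object of class `hierarchical_gen`.
#' @export
hierarchical_gen <- function(common_ace, factor_loadings, factor_specific_ace,
                             loadings, factor_map, specific_ace,
                             phenotypes = NULL, factor_names = NULL) {
  stopifnot(inherits(common_ace, "variance_components"))
  K <- length(factor_loadings)
  p <- length(loadings)
  if (any(abs(factor_loadings) > 1) || any(abs(loadings) > 1))
    stop("all standardized loadings must lie in [-1, 1]", call. = FALSE)
  factor_names <- factor_names %||% paste0("F", seq_len(K))
  if (is.character(factor_map)) factor_map <- match(factor_map, factor_names)
  if (length(factor_map) != p || any(is.na(factor_map)) ||
      any(factor_map < 1) || any(factor_map > K))
    stop("'factor_map' must assign every indicator to a first-order factor",
         call. = FALSE)
  structure(list(common_ace = common_ace,
                 factor_loadings = factor_loadings,
                 factor_specific_ace = as_vc_list(factor_specific_ace, K,
                                                  "factor_specific_ace"),
                 loadings = loadings, factor_map = as.integer(factor_map),
                 specific_ace = as_vc_list(specific_ace, p, "specific_ace"),
                 phenotypes = phenotypes %||% paste0("y", seq_len(p)),
                 factor_names = factor_names),
            class = "hierarchical_gen")
}

vc_vec <- function(vcs, field) vapply(vcs, `[[`, numeric(1), field)

#' Phenotypic A, C and E component matrices of a generating model
#'
#' Exact matrix algebra for the phenotypic covariance components implied by
#' a generating model: `A`, `C` and `E` are p x p matrices such that the
#' within-twin phenotypic covariance is `A + C + E`.
#'
#' @param gen A generating model ([variance_components()],
#'   [common_pathway_gen()], [cholesky_gen()] or [hierarchical_gen()]).
#' @return List with matrices `A`, `C`, `E` and the phenotype names.
#' @keywords internal
#' @export
ace_component_matrices <- function(gen) UseMethod("ace_component_matrices")

#' @export
ace_component_matrices.variance_components <- function(gen) {
  list(A = matrix(gen$a2), C = matrix(gen$c2), E = matrix(gen$e2),
       phenotypes = "trait")
}

#' @export
ace_component_matrices.common_pathway_gen <- function(gen) {
  lam <- gen$loadings
  p <- length(lam)
  resid <- 1 - lam^2
  ll <- tcrossprod(lam)
  list(A = gen$common_ace$a2 * ll + diag(vc_vec(gen$specific_ace, "a2") * resid, p),
       C = gen$common_ace$c2 * ll + diag(vc_vec(gen$specific_ace, "c2") * resid, p),
       E = gen$common_ace$e2 * ll + diag(vc_vec(gen$specific_ace, "e2") * resid, p),
       phenotypes = gen$phenotypes)
}

#' @export
ace_component_matrices.cholesky_gen <- function(gen) {
  p <- nrow(gen$a_paths)
  C <- if (is.null(gen$c_paths)) matrix(0, p, p) else tcrossprod(gen$c_paths)
  list(A = tcrossprod(gen$a_paths), C = C, E = tcrossprod(gen$e_paths),
       phenotypes = gen$phenotypes)
}

#' @export
ace_component_matrices.hierarchical_gen <- function(gen) {
  gam <- gen$factor_loadings
  K <- length(gam)
  p <- length(gen$loadings)
  fres <- 1 - gam^2
  gg <- tcrossprod(gam)
  AF <- gen$common_ace$a2 * gg + diag(vc_vec(gen$factor_specific_ace, "a2") * fres, K)
  CF <- gen$common_ace$c2 * gg + diag(vc_vec(gen$factor_specific_ace, "c2") * fres, K)
  EF <- gen$common_ace$e2 * gg + diag(vc_vec(gen$factor_specific_ace, "e2") * fres, K)
  Lam <- matrix(0, p, K)
  Lam[cbind(seq_len(p), gen$factor_map)] <- gen$loadings
  ires <- 1 - gen$loadings^2
  list(A = Lam %*% AF %*% t(Lam) + diag(vc_vec(gen$specific_ace, "a2") * ires, p),
       C = Lam %*% CF %*% t(Lam) + diag(vc_vec(gen$specific_ace, "c2") * ires, p),
       E = Lam %*% EF %*% t(Lam) + diag(vc_vec(gen$specific_ace, "e2") * ires, p),
       phenotypes = gen$phenotypes)
}

#' Expected twin-pair covariance matrices by zygosity
#'
#' Assembles the model-implied 2p x 2p twin-pair covariance matrix for MZ
#' and DZ pairs from a generating model's phenotypic A, C, E components:
#' the within-twin block is `A + C + E` and the cross-twin block is
#' `r_g * A + C`, with additive-genetic correlation `r_g = 1` for MZ pairs
#' and 0.5 for DZ pairs under the standard biometrical assumptions.
#'
#' @param gen A generating model object (see [ace_component_matrices()]).
#' @param r_dz DZ additive-genetic correlation; 0.5 unless a qualitative
#'   sex-difference scenario frees it.
#' @return List with the component matrices `A`, `C`, `E`, the within-twin
#'   block `within`, and the pair matrices `MZ` and `DZ`. Rows/columns are
#'   ordered twin-1 phenotypes first, then twin-2 phenotypes.
#' @examples
#' expected_twin_covariance(variance_components(0.4, 0.15, 0.45))
#' @export
expected_twin_covariance <- function(gen, r_dz = 0.5) {
  cm <- ace_component_matrices(gen)
  W <- cm$A + cm$C + cm$E
  pair <- function(X) rbind(cbind(W, X), cbind(t(X), W))
  nm <- c(paste0(cm$phenotypes, "_t1"), paste0(cm$phenotypes, "_t2"))
  mz <- pair(cm$A + cm$C)
  dz <- pair(r_dz * cm$A + cm$C)
  dimnames(mz) <- dimnames(dz) <- list(nm, nm)
  list(A = cm$A, C = cm$C, E = cm$E, within = W, MZ = mz, DZ = dz)
}
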