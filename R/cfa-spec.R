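# Declarative confirmatory factor model specification and implied
# covariance algebra.

#' Confirmatory factor model specification
#'
#' Declares a CFA structure: which indicators load on which factors, and
#' how the factors relate. Factor scale is set by fixing every latent
#' variance to 1, so all loadings are standardized. Supported structures:
#'
#' * `"correlated"` - first-order factors with freely estimated
#'   correlations;
#' * `"orthogonal"` - uncorrelated first-order factors;
#' * `"second_order"` - a single general factor above the first-order
#'   factors, with free second-order loadings `gamma_k`; the factor
#'   covariance is `gamma gamma' + diag(1 - gamma^2)`;
#' * `"bifactor"` - one general factor loading on every indicator plus
#'   orthogonal group factors.
#'
#' @param factors Named list mapping each factor name to its indicator
#'   names. Each indicator may appear in exactly one factor.
#' @param structure Factor covariance structure (see above).
#' @param indicators Optional indicator ordering; defaults to order of
#'   appearance.
#' @return An object of class `cfa_model`.
#' @examples
#' cfa_model(list(Nav = c("nd", "nl", "mr"), Obj = c("rot", "pf", "pa")),
#'           structure = "second_order")
#' @export
cfa_model <- function(factors,
                      structure = c("correlated", "orthogonal",
                                    "second_order", "bifactor"),
                      indicators = NULL) {
  structure <- match.arg(structure)
  stopifnot(is.list(factors), length(factors) >= 1L,
            !is.null(names(factors)))
  all_ind <- unlist(factors, use.names = FALSE)
  if (anyDuplicated(all_ind))
    stop("each indicator may load on exactly one declared factor", call. = FALSE)
  if (any(lengths(factors) < 2L))
    stop("every factor needs at least 2 indicators", call. = FALSE)
  if (structure == "second_order" && length(factors) < 3L)
    stop("a second-order structure needs at least 3 first-order factors ",
         "to be identified", call. = FALSE)
  indicators <- indicators %||% all_ind
  stopifnot(setequal(indicators, all_ind))
  p <- length(indicators)
  K <- length(factors)
  map <- integer(p)
  for (k in seq_len(K)) map[match(factors[[k]], indicators)] <- k
  n_load <- if (structure == "bifactor") 2L * p else p
  n_struct <- switch(structure, correlated = K * (K - 1L) / 2L,
                     orthogonal = 0L, second_order = K, bifactor = 0L)
  npar <- n_load + n_struct + p
  df <- p * (p + 1L) / 2L - npar
  structure(list(factors = factors, structure = structure,
                 indicators = indicators, map = map, p = p, K = K,
                 n_load = n_load, n_struct = n_struct, npar = npar, df = df),
            class = "cfa_model")
}

#' @export
print.cfa_model <- function(x, ...) {
  cat(sprintf("CFA model (%s): %d indicators, %d factor(s), %d free parameters, df = %d\n",
              x$structure, x$p, x$K, x$npar, x$df))
  for (k in seq_len(x$K))
    cat(sprintf("  %s: %s\n", names(x$factors)[k],
                paste(x$factors[[k]], collapse = ", ")))
  invisible(x)
}

# parameter vector layout: loadings, structure parameters, residual
# variances (all on the natural scale)
cfa_unpack <- function(spec, params) {
  p <- spec$p; K <- spec$K
  lo <- params[seq_len(spec$n_load)]
  st <- params[spec$n_load + seq_len(spec$n_struct)]
  th <- params[spec$n_load + spec$n_struct + seq_len(p)]
  if (spec$structure == "bifactor") {
    Lam <- matrix(0, p, K + 1L)
    Lam[, 1L] <- lo[seq_len(p)]
    Lam[cbind(seq_len(p), spec$map + 1L)] <- lo[p + seq_len(p)]
    Phi <- diag(K + 1L)
  } else {
    Lam <- matrix(0, p, K)
    Lam[cbind(seq_len(p), spec$map)] <- lo
    Phi <- switch(spec$structure,
      orthogonal = diag(K),
      correlated = {
        Ph <- diag(K)
        Ph[lower.tri(Ph)] <- st
        Ph[upper.tri(Ph)] <- t(Ph)[upper.tri(Ph)]
        Ph
      },
      second_order = tcrossprod(st) + diag(1 - st^2, K))
  }
  list(Lambda = Lam, Phi = Phi, theta = th,
       gamma = if (spec$structure == "second_order") st else NULL,
       corr = if (spec$structure == "correlated") st else NULL)
}

#' Model-implied covariance matrix of a CFA specification
#'
#' Computes `Sigma = Lambda Phi Lambda' + Theta`, expanding any
#' second-order structure into the factor covariance first.
#'
#' @param spec A [cfa_model()].
#' @param params Parameter vector: free loadings (indicator order; for a
#'   bifactor model the general-factor loadings first), then structure
#'   parameters (factor correlations in column-major lower-triangular
#'   order, or second-order loadings), then residual variances.
#' @return The p x p implied covariance matrix.
#' @export
implied_covariance <- function(spec, params) {
  stopifnot(inherits(spec, "cfa_model"))
  if (length(params) != spec$npar)
    stop(sprintf("expected %d parameters, got %d", spec$npar, length(params)),
         call. = FALSE)
  pp <- cfa_unpack(spec, params)
  S <- pp$Lambda %*% pp$Phi %*% t(pp$Lambda) + diag(pp$theta, spec$p)
  dimnames(S) <- list(spec$indicators, spec$indicators)
  S
}

#' Simulate person-level scores from a CFA model
#'
#' Draws factor scores and residuals from the generating structure implied
#' by `params` (standard-normal latents) and returns one row per person.
#'
#' @param spec A [cfa_model()].
#' @param params Parameter vector as in [implied_covariance()]; residual
#'   variances must be non-negative.
#' @param n Number of persons.
#' @param seed Integer seed.
#' @return An n x p matrix of scores.
#' @export
simulate_cfa_sample <- function(spec, params, n, seed) {
  stopifnot(inherits(spec, "cfa_model"))
  set.seed(check_seed(seed))
  pp <- cfa_unpack(spec, params)
  if (any(pp$theta < 0))
    stop("residual variances must be non-negative for simulation", call. = FALSE)
  ch <- chol(pp$Phi)  # factor scores with covariance Phi
  Fsc <- matrix(stats::rnorm(n * nrow(ch)), n) %*% ch
  Y <- Fsc %*% t(pp$Lambda) +
    matrix(stats::rnorm(n * spec$p), n) %*% diag(sqrt(pp$theta), spec$p)
  colnames(Y) <- spec$indicators
  Y
}
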