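# Generative twin-cohort simulation.
#
# All generators draw the latent A, C and E variables directly (rather than
# sampling from the model-implied pair covariance), so the implied-covariance
# algebra in expected_twin_covariance() remains an independent oracle:
#   - additive-genetic scores are correlated r_g between co-twins
#     (1 for MZ, 0.5 for DZ/DOS),
#   - shared-environment scores are identical within a pair,
#   - nonshared-environment scores are independent.

# n pairs of standardized ACE scores with twin correlation r_g on A
draw_twin_ace <- function(n, shares, r_g) {
  a <- sqrt(shares[1]); cc <- sqrt(shares[2]); e <- sqrt(shares[3])
  Ag <- stats::rnorm(n)
  A1 <- sqrt(r_g) * Ag + sqrt(1 - r_g) * stats::rnorm(n)
  A2 <- sqrt(r_g) * Ag + sqrt(1 - r_g) * stats::rnorm(n)
  Cg <- stats::rnorm(n)
  cbind(a * A1 + cc * Cg + e * stats::rnorm(n),
        a * A2 + cc * Cg + e * stats::rnorm(n))
}

group_rg <- c(MZm = 1, MZf = 1, DZm = 0.5, DZf = 0.5, DOS = 0.5)

# frame of pair_id / zygosity / sexes / age; consumes RNG in a fixed order
cohort_frame <- function(design) {
  n <- design$group_sizes
  zyg <- rep(names(n), n)
  total <- sum(n)
  age <- stats::rnorm(total, design$age_mean, design$age_sd)
  sex1 <- c(MZm = "M", MZf = "F", DZm = "M", DZf = "F", DOS = "M")[zyg]
  sex2 <- sex1
  # opposite-sex pairs: twin order is exchangeable, so randomize which
  # member is male
  dos <- which(zyg == "DOS")
  if (length(dos)) {
    flip <- stats::runif(length(dos)) < 0.5
    sex1[dos] <- ifelse(flip, "F", "M")
    sex2[dos] <- ifelse(flip, "M", "F")
  }
  data.frame(pair_id = seq_len(total), zygosity = zyg,
             sex1 = unname(sex1), sex2 = unname(sex2), age = age)
}

# run a per-group bivariate-pair generator and bind the phenotype columns
simulate_groups <- function(design, phenotypes, draw_group) {
  set.seed(design$seed)
  frame <- cohort_frame(design)
  p <- length(phenotypes)
  cols <- matrix(NA_real_, nrow(frame), 2L * p)
  for (g in ZYGOSITY_LEVELS) {
    idx <- which(frame$zygosity == g)
    if (!length(idx)) next
    Y <- draw_group(length(idx), group_rg[[g]])  # n x 2p: t1 block then t2
    cols[idx, ] <- Y
  }
  out <- frame
  for (i in seq_len(p)) {
    out[[paste0(phenotypes[i], "_t1")]] <- cols[, i]
    out[[paste0(phenotypes[i], "_t2")]] <- cols[, p + i]
  }
  twin_cohort(out, phenotypes)
}

#' Simulate a univariate twin cohort
#'
#' Draws one standardized phenotype per twin from the classical ACE model:
#' unit variances, cross-twin covariance `a2 + c2` for MZ pairs and
#' `0.5 * a2 + c2` for DZ pairs. The cohort is fully determined by
#' `design$seed`.
#'
#' @param design A [cohort_design()].
#' @param vc A [variance_components()] object.
#' @param phenotype Name of the simulated test score.
#' @return A [twin_cohort()].
#' @examples
#' cohort <- simulate_univariate_cohort(
#'   cohort_design(seed = 1), variance_components(0.4, 0.15, 0.45))
#' @export
simulate_univariate_cohort <- function(design, vc, phenotype = "trait") {
  stopifnot(inherits(design, "cohort_design"), inherits(vc, "variance_components"))
  shares <- c(vc$a2, vc$c2, vc$e2)
  simulate_groups(design, phenotype, function(n, r_g)
    draw_twin_ace(n, shares, r_g))
}

#' Simulate a common pathway twin cohort
#'
#' The latent common factor is drawn with its own A/C/E structure; each
#' indicator is `lambda_i * F` plus a residual with the indicator's specific
#' A/C/E composition, giving unit-variance indicators.
#'
#' @param design A [cohort_design()].
#' @param gen A [common_pathway_gen()].
#' @return A [twin_cohort()].
#' @export
simulate_common_pathway_cohort <- function(design, gen) {
  stopifnot(inherits(design, "cohort_design"), inherits(gen, "common_pathway_gen"))
  lam <- gen$loadings
  p <- length(lam)
  com <- with(gen$common_ace, c(a2, c2, e2))
  spec <- lapply(gen$specific_ace, function(v) c(v$a2, v$c2, v$e2))
  simulate_groups(design, gen$phenotypes, function(n, r_g) {
    Fac <- draw_twin_ace(n, com, r_g)
    Y <- matrix(0, n, 2L * p)
    for (i in seq_len(p)) {
      R <- draw_twin_ace(n, spec[[i]], r_g)
      s <- sqrt(1 - lam[i]^2)
      Y[, i] <- lam[i] * Fac[, 1] + s * R[, 1]
      Y[, p + i] <- lam[i] * Fac[, 2] + s * R[, 2]
    }
    Y
  })
}

#' Simulate a Cholesky-structured twin cohort
#'
#' Latent standardized genetic, shared- and nonshared-environment factors
#' (one per phenotype, with the appropriate twin correlations) are combined
#' through the generating model's lower-triangular path matrices.
#'
#' @param design A [cohort_design()].
#' @param gen A [cholesky_gen()].
#' @return A [twin_cohort()].
#' @export
simulate_cholesky_cohort <- function(design, gen) {
  stopifnot(inherits(design, "cohort_design"), inherits(gen, "cholesky_gen"))
  p <- nrow(gen$a_paths)
  simulate_groups(design, gen$phenotypes, function(n, r_g) {
    draw_block <- function(shares) {
      U1 <- matrix(0, n, p); U2 <- matrix(0, n, p)
      for (j in seq_len(p)) {
        u <- draw_twin_ace(n, shares, r_g)
        U1[, j] <- u[, 1]; U2[, j] <- u[, 2]
      }
      list(U1, U2)
    }
    UA <- draw_block(c(1, 0, 0))
    UE <- draw_block(c(0, 0, 1))
    Y1 <- UA[[1]] %*% t(gen$a_paths) + UE[[1]] %*% t(gen$e_paths)
    Y2 <- UA[[2]] %*% t(gen$a_paths) + UE[[2]] %*% t(gen$e_paths)
    if (!is.null(gen$c_paths)) {
      UC <- draw_block(c(0, 1, 0))
      Y1 <- Y1 + UC[[1]] %*% t(gen$c_paths)
      Y2 <- Y2 + UC[[2]] %*% t(gen$c_paths)
    }
    cbind(Y1, Y2)
  })
}

#' Simulate a hierarchical second-order twin cohort
#'
#' A second-order general factor (with its own A/C/E structure) drives K
#' first-order factors through loadings `gamma_k`; first-order factor
#' residuals and indicator residuals carry their own A/C/E compositions.
#'
#' @param design A [cohort_design()].
#' @param gen A [hierarchical_gen()].
#' @return A [twin_cohort()].
#' @export
simulate_hierarchical_cohort <- function(design, gen) {
  stopifnot(inherits(design, "cohort_design"), inherits(gen, "hierarchical_gen"))
  gam <- gen$factor_loadings
  K <- length(gam)
  lam <- gen$loadings
  p <- length(lam)
  com <- with(gen$common_ace, c(a2, c2, e2))
  fspec <- lapply(gen$factor_specific_ace, function(v) c(v$a2, v$c2, v$e2))
  ispec <- lapply(gen$specific_ace, function(v) c(v$a2, v$c2, v$e2))
  simulate_groups(design, gen$phenotypes, function(n, r_g) {
    G <- draw_twin_ace(n, com, r_g)
    F1 <- matrix(0, n, K); F2 <- matrix(0, n, K)
    for (k in seq_len(K)) {
      R <- draw_twin_ace(n, fspec[[k]], r_g)
      s <- sqrt(1 - gam[k]^2)
      F1[, k] <- gam[k] * G[, 1] + s * R[, 1]
      F2[, k] <- gam[k] * G[, 2] + s * R[, 2]
    }
    Y <- matrix(0, n, 2L * p)
    for (i in seq_len(p)) {
      R <- draw_twin_ace(n, ispec[[i]], r_g)
      s <- sqrt(1 - lam[i]^2)
      k <- gen$factor_map[i]
      Y[, i] <- lam[i] * F1[, k] + s * R[, 1]
      Y[, p + i] <- lam[i] * F2[, k] + s * R[, 2]
    }
    Y
  })
}

#' Simulate a univariate cohort with sex-specific variance components
#'
#' Males and females receive their own A/C/E structure; in opposite-sex
#' pairs the male twin follows the male paths and the female twin the
#' female paths, with cross-twin covariance
#' `r_dos * a_m * a_f + c_m * c_f`. Freeing `r_dos` below 0.5 emulates
#' qualitative sex differences.
#'
#' @param design A [cohort_design()].
#' @param vc_male,vc_female [variance_components()] per sex.
#' @param r_dos Additive-genetic correlation of opposite-sex pairs.
#' @param phenotype Name of the simulated score.
#' @return A [twin_cohort()].
#' @export
simulate_sexlim_cohort <- function(design, vc_male, vc_female, r_dos = 0.5,
                                   phenotype = "trait") {
  stopifnot(inherits(design, "cohort_design"),
            inherits(vc_male, "variance_components"),
            inherits(vc_female, "variance_components"))
  check_prob(r_dos, "r_dos")
  shm <- c(vc_male$a2, vc_male$c2, vc_male$e2)
  shf <- c(vc_female$a2, vc_female$c2, vc_female$e2)
  set.seed(design$seed)
  frame <- cohort_frame(design)
  y <- matrix(NA_real_, nrow(frame), 2L)
  for (g in ZYGOSITY_LEVELS) {
    idx <- which(frame$zygosity == g)
    if (!length(idx)) next
    n <- length(idx)
    if (g == "DOS") {
      Zg <- stats::rnorm(n)
      Am <- sqrt(r_dos) * Zg + sqrt(1 - r_dos) * stats::rnorm(n)
      Af <- sqrt(r_dos) * Zg + sqrt(1 - r_dos) * stats::rnorm(n)
      Cg <- stats::rnorm(n)
      ym <- sqrt(shm[1]) * Am + sqrt(shm[2]) * Cg + sqrt(shm[3]) * stats::rnorm(n)
      yf <- sqrt(shf[1]) * Af + sqrt(shf[2]) * Cg + sqrt(shf[3]) * stats::rnorm(n)
      male1 <- frame$sex1[idx] == "M"
      y[idx, 1L] <- ifelse(male1, ym, yf)
      y[idx, 2L] <- ifelse(male1, yf, ym)
    } else {
      sh <- if (g %in% c("MZm", "DZm")) shm else shf
      y[idx, ] <- draw_twin_ace(n, sh, group_rg[[g]])
    }
  }
  out <- frame
  out[[paste0(phenotype, "_t1")]] <- y[, 1L]
  out[[paste0(phenotype, "_t2")]] <- y[, 2L]
  twin_cohort(out, phenotype)
}

#' Add covariate effects and missingness to a simulated cohort
#'
#' Adds the design's sex and age effects to every phenotype and then masks
#' scores missing-completely-at-random at the design's `missing_rate`. Sex
#' effects are applied as +/- half the standardized male-minus-female
#' difference; age enters through the z-scored pair age. Missing values are
#' recorded as `NA` in the returned cohort.
#'
#' @param cohort A [twin_cohort()] produced by one of the `simulate_*`
#'   generators.
#' @param design The [cohort_design()]; `sex_effect`, `age_effect` and
#'   `missing_rate` are recycled over phenotypes.
#' @param seed Seed for the missingness mask; defaults to `design$seed + 1`
#'   so a design fully determines the final cohort.
#' @return A [twin_cohort()].
#' @export
apply_covariates_and_missingness <- function(cohort, design,
                                             seed = design$seed + 1L) {
  stopifnot(inherits(cohort, "twin_cohort"), inherits(design, "cohort_design"))
  ph <- phenotypes(cohort)
  p <- length(ph)
  dsex <- rep_len(design$sex_effect, p)
  dage <- rep_len(design$age_effect, p)
  miss <- rep_len(design$missing_rate, p)
  check_prob(miss, "missing_rate")
  set.seed(check_seed(seed))
  zage <- (cohort$age - design$age_mean) / design$age_sd
  out <- cohort
  for (i in seq_len(p)) {
    for (m in 1:2) {
      col <- paste0(ph[i], "_t", m)
      shift <- dsex[i] * ifelse(cohort[[paste0("sex", m)]] == "M", 0.5, -0.5)
      y <- cohort[[col]] + shift + dage[i] * zage
      if (miss[i] > 0) y[stats::runif(length(y)) < miss[i]] <- NA
      out[[col]] <- y
    }
  }
  out
}
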