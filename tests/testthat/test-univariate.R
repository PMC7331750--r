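# Univariate twin modelling: intraclass correlations, Falconer estimates,
# FIML ACE fits and profile-likelihood intervals.

test_that("intraclass correlations behave at the degenerate limits", {
  n <- 300
  base <- data.frame(pair_id = 1:(2 * n),
                     zygosity = rep(c("MZm", "DZm"), each = n),
                     sex1 = "M", sex2 = "M", age = 20)
  set.seed(51)
  same <- base
  same$trait_t1 <- same$trait_t2 <- rnorm(2 * n)
  r1 <- intraclass_correlations(twin_cohort(same, "trait"), "trait")
  expect_equal(r1$rMZ, 1, tolerance = 1e-10)
  expect_equal(r1$rDZ, 1, tolerance = 1e-10)
  indep <- base
  indep$trait_t1 <- rnorm(2 * n); indep$trait_t2 <- rnorm(2 * n)
  r0 <- intraclass_correlations(twin_cohort(indep, "trait"), "trait")
  expect_lt(abs(r0$rMZ), 0.1)
  expect_lt(abs(r0$rDZ), 0.1)
})

test_that("Falconer estimates are the definitional algebra, flagged when inadmissible", {
  f <- falconer_estimates(0.55, 0.35)
  expect_equal(f[c("a2", "c2", "e2")], list(a2 = 0.40, c2 = 0.15, e2 = 0.45))
  expect_true(f$admissible)
  expect_equal(falconer_estimates(0.42, 0.42)$a2, 0)
  g <- falconer_estimates(0.8, 0.2)
  expect_equal(g$a2, 1.2)
  expect_false(g$admissible)
})

test_that("FIML recovers generating components and equals the closed-form likelihood", {
  vc <- variance_components(0.64, 0.08, 0.28)
  cohort <- simulate_univariate_cohort(design_mzdz(2000, 2000, seed = 52), vc)
  fit <- fit_univariate_ace(cohort, "trait")
  expect_equal(fit$convergence, 0)
  expect_near(unname(fit$components["a2"]), 0.64, 0.05)
  expect_near(unname(fit$components["c2"]), 0.08, 0.05)
  expect_equal(sum(fit$components), 1, tolerance = 1e-6)

  # complete data: the FIML objective must equal the closed-form grouped
  # multivariate-normal -2 log-likelihood at the fitted parameters
  v <- fit$total_variance
  sig <- function(r) {
    x <- v * (r * fit$components[["a2"]] + fit$components[["c2"]])
    matrix(c(v, x, x, v), 2)
  }
  Ymz <- pair_scores(cohort, "trait")[cohort$zygosity %in% c("MZm", "MZf"), ]
  Ydz <- pair_scores(cohort, "trait")[!cohort$zygosity %in% c("MZm", "MZf"), ]
  closed <- m2ll_closed_form(Ymz, rep(fit$mean, 2), sig(1)) +
    m2ll_closed_form(Ydz, rep(fit$mean, 2), sig(0.5))
  expect_equal(fit$m2ll, closed, tolerance = 1e-6)
})

test_that("nested submodels respect the likelihood ordering", {
  cohort <- simulate_univariate_cohort(design_mzdz(600, 600, seed = 53),
                                       variance_components(0.5, 0.1, 0.4))
  ace <- fit_univariate_ace(cohort, "trait", "ACE")
  ae <- fit_univariate_ace(cohort, "trait", "AE")
  e <- fit_univariate_ace(cohort, "trait", "E")
  expect_lte(ace$m2ll, ae$m2ll + 1e-6)
  expect_lte(ae$m2ll, e$m2ll + 1e-6)
  expect_equal(e$components[["a2"]], 0)
  expect_gte(lrt(ace, e)$chisq, 0)
  expect_gte(lrt(ace, ae)$chisq, 0)
})

test_that("estimates are invariant to twin-order permutation", {
  cohort <- simulate_univariate_cohort(design_per_group(300, seed = 54),
                                       variance_components(0.45, 0.2, 0.35))
  flipped <- as.data.frame(cohort)
  swap <- seq(1, nrow(flipped), by = 2)
  tmp <- flipped$trait_t1[swap]
  flipped$trait_t1[swap] <- flipped$trait_t2[swap]
  flipped$trait_t2[swap] <- tmp
  f1 <- fit_univariate_ace(cohort, "trait")
  f2 <- fit_univariate_ace(twin_cohort(flipped, "trait"), "trait")
  expect_equal(f1$components, f2$components, tolerance = 1e-6)
  expect_equal(f1$m2ll, f2$m2ll, tolerance = 1e-6)
})

test_that("FIML agrees with Falconer estimates at large n", {
  vc <- variance_components(0.4, 0.15, 0.45)
  cohort <- simulate_univariate_cohort(design_mzdz(30000, 30000, seed = 55), vc)
  r <- intraclass_correlations(cohort, "trait")
  fal <- falconer_estimates(r$rMZ, r$rDZ)
  fit <- fit_univariate_ace(cohort, "trait")
  expect_near(unname(fit$components["a2"]), fal$a2, 0.02)
  expect_near(unname(fit$components["c2"]), fal$c2, 0.02)
})

test_that("FIML handles missing scores through per-pattern likelihoods", {
  d <- design_mzdz(2000, 2000, seed = 56, missing_rate = 0.25)
  cohort <- apply_covariates_and_missingness(
    simulate_univariate_cohort(d, variance_components(0.6, 0.1, 0.3)), d)
  fit <- fit_univariate_ace(cohort, "trait")
  expect_equal(fit$convergence, 0)
  expect_near(unname(fit$components["a2"]), 0.6, 0.07)
})

test_that("profile-likelihood intervals contain the estimate and shrink with n", {
  vc <- variance_components(0.5, 0.1, 0.4)
  widths <- sapply(c(400, 1600, 6400), function(n) {
    fit <- fit_univariate_ace(
      simulate_univariate_cohort(design_mzdz(n, n, seed = 57 + n), vc), "trait")
    ci <- likelihood_ci(fit, "a2")
    expect_lte(ci[["lower"]], fit$components[["a2"]] + 1e-6)
    expect_gte(ci[["upper"]], fit$components[["a2"]] - 1e-6)
    ci[["upper"]] - ci[["lower"]]
  })
  expect_true(all(diff(widths) < 0))
})
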