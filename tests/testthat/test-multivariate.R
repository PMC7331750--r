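# Multivariate biometric models: implied covariance algebra, common
# pathway, hierarchical and Cholesky fits, path tracing.

test_that("path tracing apportions genetic variance correctly", {
  expect_equal(path_trace_genetic_share(0.84, 0.81, 0.27), 0.671,
               tolerance = 5e-4)
  expect_equal(path_trace_genetic_share(0.3, 1, 0), 1)
  expect_equal(path_trace_genetic_share(0.5, sqrt(0.5), 0.25), 0.5)
  expect_error(path_trace_genetic_share(0, 0.5, 0), "zero total")
})

test_that("expected twin covariance follows the biometrical block algebra", {
  # no genetic paths: MZ and DZ cross-twin blocks both equal C
  gen0 <- common_pathway_gen(variance_components(0, 0.4, 0.6),
                             loadings = c(0.6, 0.7, 0.5),
                             specific_ace = variance_components(0, 0.3, 0.7))
  ex0 <- expected_twin_covariance(gen0)
  expect_equal(ex0$MZ[1:3, 4:6], ex0$DZ[1:3, 4:6])
  expect_equal(unname(ex0$MZ[1:3, 4:6]), unname(ex0$C))

  # purely genetic common factor, loadings 0.54 / 0.75: cross-twin
  # cross-trait entries 0.405 (MZ) and 0.2025 (DZ)
  gen1 <- common_pathway_gen(variance_components(1, 0, 0),
                             loadings = c(0.54, 0.75),
                             specific_ace = variance_components(0, 0, 1))
  ex1 <- expected_twin_covariance(gen1)
  expect_equal(ex1$MZ[1, 4], 0.54 * 0.75)
  expect_equal(ex1$DZ[1, 4], 0.5 * 0.54 * 0.75)

  # symmetry and MZ >= DZ cross-block dominance for non-negative A, C
  gen2 <- cp_gen6()
  ex2 <- expected_twin_covariance(gen2)
  expect_equal(ex2$MZ, t(ex2$MZ))
  expect_true(all(ex2$MZ[1:6, 7:12] >= ex2$DZ[1:6, 7:12] - 1e-12))
})

test_that("implied covariance matches a brute-force Monte-Carlo estimate", {
  # full ACE trivariate Cholesky generator, 200k pairs per zygosity class
  LA <- matrix(c(0.7, 0, 0, 0.3, 0.6, 0, 0.2, 0.25, 0.5), 3, byrow = TRUE)
  LC <- matrix(c(0.3, 0, 0, 0.1, 0.25, 0, 0.15, 0.1, 0.2), 3, byrow = TRUE)
  LE <- matrix(c(0.55, 0, 0, 0.2, 0.5, 0, 0.1, 0.2, 0.6), 3, byrow = TRUE)
  gen <- cholesky_gen(LA, LE, LC)
  cohort <- simulate_cholesky_cohort(design_mzdz(200000, 200000, seed = 81), gen)
  implied <- expected_twin_covariance(gen)
  ph <- phenotypes(cohort)
  cols <- c(paste0(ph, "_t1"), paste0(ph, "_t2"))
  mz <- cohort$zygosity %in% c("MZm", "MZf")
  emp_mz <- cov(as.matrix(as.data.frame(cohort)[mz, cols]))
  emp_dz <- cov(as.matrix(as.data.frame(cohort)[!mz, cols]))
  expect_lt(max(abs(emp_mz - implied$MZ)), 0.01)
  expect_lt(max(abs(emp_dz - implied$DZ)), 0.01)
})

test_that("common pathway fit recovers a boundary case: no specific genetics", {
  # indicator 1 has zero specific genetic variance: its genetic share from
  # the common factor should approach 1
  gen <- common_pathway_gen(
    variance_components(0.64, 0.08, 0.28),
    loadings = c(0.54, 0.58, 0.63, 0.67, 0.71, 0.75),
    specific_ace = c(list(variance_components(0, 0.05, 0.95)),
                     rep(list(variance_components(0.2, 0.05, 0.75)), 5)))
  cohort <- simulate_common_pathway_cohort(design_mzdz(2000, 2000, seed = 82),
                                           gen)
  fit <- fit_common_pathway(cohort)
  expect_equal(fit$convergence, 0)
  expect_gte(fit$genetic_shares[[1]], 0.95)
  expect_true(all(fit$genetic_shares >= 0 & fit$genetic_shares <= 1))
  expect_equal(sum(fit$common), 1, tolerance = 1e-6)
})

test_that("the common pathway model never beats the Cholesky on the same data", {
  cohort <- simulate_common_pathway_cohort(design_mzdz(300, 300, seed = 83),
                                           cp_gen6())
  cp <- fit_common_pathway(cohort)
  chol <- fit_cholesky(cohort, components = "ACE")
  expect_lte(chol$m2ll, cp$m2ll + 1e-4)
})

test_that("hierarchical biometric and phenotypic CFA algebra agree", {
  gen <- hier_gen16()
  cm <- ace_component_matrices(gen)
  spec <- cfa_model(list(N = paste0("nav", 1:6), O = paste0("obj", 1:6),
                         V = paste0("vis", 1:4)), structure = "second_order")
  params <- c(gen$loadings, gen$factor_loadings, 1 - gen$loadings^2)
  expect_equal(unname(cm$A + cm$C + cm$E),
               unname(implied_covariance(spec, params)), tolerance = 1e-10)
})

test_that("hierarchical fit reports per-factor genetic shares that sum with specifics to 1", {
  gen <- hier_gen16()
  cohort <- simulate_hierarchical_cohort(design_mzdz(800, 800, seed = 84), gen)
  fit <- fit_hierarchical_model(cohort,
                                split(phenotypes(cohort), rep(1:3, c(6, 6, 4))),
                                components = "AE")
  expect_equal(fit$convergence, 0)
  expect_equal(sum(fit$second_order), 1, tolerance = 1e-6)
  expect_true(all(fit$factor_genetic_shares >= 0 &
                    fit$factor_genetic_shares <= 1))
  # share + complementary specific share = 1 by construction
  sh <- fit$factor_genetic_shares
  spec_sh <- 1 - sh
  expect_equal(unname(sh + spec_sh), rep(1, 3))
  # recovery at moderate n stays in the right region
  expect_near(unname(fit$second_order[["a2"]]), 0.84, 0.12)
})

test_that("genetically independent traits yield near-zero cross paths in the Cholesky fit", {
  gen <- cholesky_gen(diag(sqrt(0.5), 2), diag(sqrt(0.5), 2))
  cohort <- simulate_cholesky_cohort(design_mzdz(2000, 2000, seed = 85), gen)
  fit <- fit_cholesky(cohort, components = "AE")
  expect_equal(fit$convergence, 0)
  expect_lt(fit$genetic_shares[2, 1], 0.05)
  expect_equal(rowSums(fit$genetic_shares), c(g = 1, spatial = 1),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a single-trait Cholesky reduces to the univariate ACE fit", {
  cohort <- simulate_univariate_cohort(design_mzdz(800, 800, seed = 86),
                                       variance_components(0.5, 0.2, 0.3))
  chol <- fit_cholesky(cohort, "trait", components = "ACE")
  uni <- fit_univariate_ace(cohort, "trait", "ACE")
  expect_equal(unname(chol$trait_components[1, ]), unname(uni$components),
               tolerance = 1e-4)
  expect_equal(chol$m2ll, uni$m2ll, tolerance = 1e-6)
})
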