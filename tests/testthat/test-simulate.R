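# Generative properties of the twin-cohort simulators.

test_that("univariate twin correlations converge to the ACE algebra", {
  cases <- list(list(vc = variance_components(1, 0, 0), mz = 1.0, dz = 0.5),
                list(vc = variance_components(0, 0, 1), mz = 0.0, dz = 0.0),
                list(vc = variance_components(0.40, 0.15, 0.45),
                     mz = 0.55, dz = 0.35))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    cohort <- simulate_univariate_cohort(
      design_mzdz(50000, 50000, seed = 400 + i), cs$vc)
    r <- intraclass_correlations(cohort, "trait")
    expect_near(r$rMZ, cs$mz, 0.01)
    expect_near(r$rDZ, cs$dz, 0.01)
  }
})

test_that("the seed fully determines the cohort", {
  vc <- variance_components(0.4, 0.1, 0.5)
  a <- simulate_univariate_cohort(design_per_group(50, seed = 9), vc)
  b <- simulate_univariate_cohort(design_per_group(50, seed = 9), vc)
  c <- simulate_univariate_cohort(design_per_group(50, seed = 10), vc)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$trait_t1, c$trait_t1)))
})

test_that("degenerate common pathway (unit loadings, no specifics) collapses indicators", {
  gen <- common_pathway_gen(variance_components(0.6, 0.1, 0.3),
                            loadings = c(1, 1, 1),
                            specific_ace = variance_components(0, 0, 1))
  cohort <- simulate_common_pathway_cohort(design_per_group(100, seed = 3), gen)
  expect_equal(cohort$y1_t1, cohort$y2_t1, tolerance = 1e-12)
  expect_equal(cohort$y2_t1, cohort$y3_t1, tolerance = 1e-12)
})

test_that("common pathway cross-twin cross-indicator covariance follows path tracing", {
  # purely genetic common factor, loadings 0.54 and 0.75:
  # MZ cross-twin cross-indicator covariance = 0.54 * 0.75 = 0.405
  gen <- common_pathway_gen(variance_components(1, 0, 0),
                            loadings = c(0.54, 0.75),
                            specific_ace = variance_components(0, 0, 1))
  cohort <- simulate_common_pathway_cohort(design_mzdz(50000, 0, seed = 41), gen)
  cc <- cross_twin_cov(cohort)
  expect_near(cc[1, 2], 0.405, 0.01)
})

test_that("common pathway empirical covariances match the implied-covariance oracle", {
  gen <- cp_gen6()
  cohort <- simulate_common_pathway_cohort(design_mzdz(50000, 50000, seed = 42),
                                           gen)
  implied <- expected_twin_covariance(gen)
  mz_rows <- cohort$zygosity %in% c("MZm", "MZf")
  ph <- phenotypes(cohort)
  emp <- function(rows) {
    Y <- as.matrix(as.data.frame(cohort)[rows, c(paste0(ph, "_t1"),
                                                 paste0(ph, "_t2"))])
    stats::cov(Y)
  }
  expect_lt(max(abs(emp(mz_rows) - implied$MZ)), 0.02)
  expect_lt(max(abs(emp(!mz_rows) - implied$DZ)), 0.02)
})

test_that("diagonal Cholesky paths give genetically independent traits", {
  gen <- cholesky_gen(diag(sqrt(0.5), 2), diag(sqrt(0.5), 2))
  cohort <- simulate_cholesky_cohort(design_mzdz(50000, 0, seed = 7), gen)
  cc <- cross_twin_cov(cohort)
  expect_lt(abs(cc[1, 2]), 0.01)
  expect_lt(abs(cc[2, 1]), 0.01)
})

test_that("bivariate Cholesky simulation matches its implied covariance", {
  gen <- chol_gen_g()
  cohort <- simulate_cholesky_cohort(design_mzdz(50000, 50000, seed = 8), gen)
  implied <- expected_twin_covariance(gen)
  mz_rows <- cohort$zygosity %in% c("MZm", "MZf")
  emp_mz <- cross_twin_cov(cohort, mz_rows)
  emp_dz <- cross_twin_cov(cohort, !mz_rows)
  expect_lt(max(abs(emp_mz - implied$MZ[1:2, 3:4])), 0.01)
  expect_lt(max(abs(emp_dz - implied$DZ[1:2, 3:4])), 0.01)
})

test_that("single-phenotype Cholesky reduces to the univariate generator", {
  vc <- variance_components(0.4, 0.15, 0.45)
  gen1 <- cholesky_gen(matrix(sqrt(vc$a2)), matrix(sqrt(vc$e2)),
                       matrix(sqrt(vc$c2)))
  expect_equal(unname(expected_twin_covariance(gen1)$MZ),
               unname(expected_twin_covariance(vc)$MZ), tolerance = 1e-12)
  expect_equal(unname(expected_twin_covariance(gen1)$DZ),
               unname(expected_twin_covariance(vc)$DZ), tolerance = 1e-12)
  cohort <- simulate_cholesky_cohort(design_mzdz(30000, 30000, seed = 12), gen1)
  r <- intraclass_correlations(cohort, "y1")
  expect_near(r$rMZ, 0.55, 0.015)
  expect_near(r$rDZ, 0.35, 0.015)
})

test_that("covariate injection and missingness behave as designed", {
  vc <- variance_components(0.5, 0, 0.5)
  d0 <- design_per_group(200, seed = 5)
  cohort <- simulate_univariate_cohort(d0, vc)
  expect_identical(apply_covariates_and_missingness(cohort, d0)$trait_t1,
                   cohort$trait_t1)

  # sex gap of 0.85 SD: R2 = (d^2/4) / (1 + d^2/4) under equal group sizes
  d1 <- cohort_design(10000, 10000, 0, 0, 0, seed = 6, sex_effect = 0.85)
  ch1 <- apply_covariates_and_missingness(simulate_univariate_cohort(d1, vc), d1)
  persons <- cohort_persons(ch1)
  r2 <- sex_difference_r2(persons$trait, persons$sex)
  expect_near(r2$r2, 0.85^2 / 4 / (1 + 0.85^2 / 4), 0.01)
  expect_equal(r2$direction, 1)

  d2 <- design_per_group(2000, seed = 7, missing_rate = 0.2)
  ch2 <- apply_covariates_and_missingness(simulate_univariate_cohort(d2, vc), d2)
  expect_near(mean(is.na(pair_scores(ch2, "trait"))), 0.2, 0.01)
})

test_that("cohorts round-trip through the wide CSV dialect", {
  gen <- cp_gen6()
  d <- design_per_group(30, seed = 77, missing_rate = 0.15)
  cohort <- apply_covariates_and_missingness(
    simulate_common_pathway_cohort(d, gen), d)
  path <- withr::local_tempfile(fileext = ".csv")
  write_twin_cohort(cohort, path)
  back <- read_twin_cohort(path)
  expect_identical(phenotypes(back), phenotypes(cohort))
  expect_equal(as.data.frame(back), as.data.frame(cohort), tolerance = 1e-12)
})
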