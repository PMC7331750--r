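# Phenotype preparation and descriptive screening.

test_that("composite score equally weights z-scored accuracy and speed", {
  # acc (0,1,2) and lat (3,2,1) both standardize to (-1,0,1)
  expect_equal(composite_score(c(0, 1, 2), c(3, 2, 1)), c(-1, 0, 1))
  # a person at the sample mean of both scores lands at 0
  expect_equal(composite_score(c(0, 1, 2), c(3, 2, 1))[2], 0)
  # independent accuracy and latency: Var(mean of two z-scores) = 0.5
  set.seed(11)
  comp <- composite_score(rnorm(20000, 50, 8), rexp(20000) + 1)
  expect_near(var(comp), 0.5, 0.02)
  expect_error(composite_score(c(1, 1, 1), c(2, 3, 4)), "zero-variance")
  expect_error(composite_score(c(1, 2), c(0, 3)), "positive")
})

test_that("residualization removes age and sex signal, standardizes, and is idempotent", {
  d <- design_per_group(1000, seed = 21, sex_effect = 0.5, age_effect = 0.3)
  cohort <- apply_covariates_and_missingness(
    simulate_univariate_cohort(d, variance_components(0.5, 0, 0.5)), d)
  out <- residualize_standardize(cohort)
  persons <- cohort_persons(out)
  expect_equal(mean(persons$trait), 0, tolerance = 1e-8)
  expect_equal(sd(persons$trait), 1, tolerance = 1e-8)
  expect_lt(abs(cor(persons$trait, as.numeric(persons$sex == "M"))), 0.01)
  r2 <- summary(lm(trait ~ age + sex, data = persons))$r.squared
  expect_lt(r2, 1e-6)
  twice <- residualize_standardize(out)
  expect_equal(as.data.frame(twice), as.data.frame(out), tolerance = 1e-8)
})

test_that("a phenotype unrelated to age and sex is simply z-scored", {
  d <- design_per_group(500, seed = 22)
  cohort <- simulate_univariate_cohort(d, variance_components(0.4, 0.1, 0.5))
  out <- residualize_standardize(cohort)
  raw <- cohort_persons(cohort)$trait
  z <- (raw - mean(raw)) / sd(raw)
  expect_gt(cor(cohort_persons(out)$trait, z), 0.999)
  expect_near(cohort_persons(out)$trait, z, 0.1)
})

test_that("one-twin-per-pair halves are disjoint, exhaustive and seeded", {
  cohort <- simulate_univariate_cohort(design_per_group(300, seed = 23),
                                       variance_components(0.4, 0.1, 0.5))
  halves <- select_one_per_pair(cohort, seed = 99)
  expect_equal(nrow(halves$primary), nrow(cohort))
  expect_false(anyDuplicated(halves$primary$pair_id) > 0)
  key <- function(d) paste(d$pair_id, d$member)
  expect_length(intersect(key(halves$primary), key(halves$replication)), 0)
  expect_setequal(c(key(halves$primary), key(halves$replication)),
                  key(cohort_persons(cohort)))
  again <- select_one_per_pair(cohort, seed = 99)
  expect_identical(halves$primary, again$primary)
})

test_that("distribution screening matches known moments", {
  expect_equal(distribution_check(rep(c(-1, 1), 10))$skewness, 0)
  set.seed(31)
  dc <- distribution_check(rnorm(50000))
  expect_equal(dc$skewness, 0, tolerance = 0.05)
  expect_equal(dc$kurtosis, 0, tolerance = 0.1)
  expect_true(dc$pass)
  # exponential scores sit right at the screening boundary (skewness 2)
  de <- distribution_check(rexp(50000))
  expect_near(de$skewness, 2, 0.2)
  expect_identical(de$pass, abs(de$skewness) < 2 && abs(de$kurtosis) < 2)
  expect_error(distribution_check(rnorm(5)), "at least 8")
})

test_that("sex-difference R2 follows the point-biserial algebra", {
  scores <- c(1, 2, 3, 1, 2, 3)
  sex <- c("M", "M", "M", "F", "F", "F")
  expect_equal(sex_difference_r2(scores, sex)$r2, 0)
  set.seed(32)
  x <- c(rnorm(5000) + 0.9, rnorm(5000))
  sx <- rep(c("M", "F"), each = 5000)
  r <- sex_difference_r2(x, sx)
  expect_near(r$r2, 0.9^2 / 4 / (1 + 0.9^2 / 4), 0.01)
  expect_equal(r$direction, 1)
  y <- c(rnorm(5000) + 0.35, rnorm(5000))
  expect_near(sex_difference_r2(y, sx)$r2, 0.35^2 / 4 / (1 + 0.35^2 / 4),
              0.005)
  # invariant to linear rescaling
  expect_equal(sex_difference_r2(3 + 5 * x, sx)$r2, r$r2)
  expect_error(sex_difference_r2(x, rep("M", 10000)), "both sexes")
})

test_that("test-retest reliability behaves like a Pearson correlation", {
  x <- rnorm(50)
  expect_equal(test_retest(x, x), 1)
  set.seed(33)
  expect_lt(abs(test_retest(rnorm(10000), rnorm(10000))), 0.02)
  # sampling distribution at the battery's average reliability (rho = 0.74,
  # n = 100): the Fisher-z interval puts ~99% of replicates in [0.60, 0.85]
  reps <- replicate(400, {
    z <- rnorm(100)
    test_retest(z, 0.74 * z + sqrt(1 - 0.74^2) * rnorm(100))
  })
  expect_gte(mean(reps >= 0.60 & reps <= 0.85), 0.95)
  expect_error(test_retest(rep(1, 10), rnorm(10)), "zero-variance")
})
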