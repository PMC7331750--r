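# Phenotype preparation and descriptive screening.

#' Accuracy/latency composite score
#'
#' Combines a test's accuracy score with its completion latency, equally
#' weighted: the composite is the mean of the z-scored accuracy and the
#' z-scored negated latency (slower completion lowers the score), computed
#' over the analysis sample. Higher values mean better performance.
#'
#' @param accuracy Numeric accuracy scores (test-specific points).
#' @param latency Completion times in seconds; must be positive.
#' @return Numeric composite, mean 0 in the analysis sample.
#' @examples
#' composite_score(c(4, 7, 10), c(50, 40, 30))
#' @export
composite_score <- function(accuracy, latency) {
  if (length(accuracy) != length(latency))
    stop("accuracy and latency must have the same length", call. = FALSE)
  if (any(latency <= 0, na.rm = TRUE))
    stop("latency must be positive", call. = FALSE)
  (zscore(accuracy) + zscore(-latency)) / 2
}

#' Residualize phenotypes for age and sex, then standardize
#'
#' Replaces every phenotype by the z-scored residual from a linear
#' regression on age and sex, fitted over all individuals (both twins) with
#' available data. A constant-age or single-sex sample drops the offending
#' term with a warning. The operation is idempotent.
#'
#' @param cohort A [twin_cohort()].
#' @return The cohort with residualized, standardized phenotypes.
#' @export
residualize_standardize <- function(cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  persons <- cohort_persons(cohort)
  use_age <- stats::sd(persons$age) > 0
  use_sex <- length(unique(persons$sex)) > 1L
  if (!use_age) warning("constant age: age term dropped")
  if (!use_sex) warning("single-sex sample: sex term dropped")
  terms <- c(if (use_age) "age", if (use_sex) "sex")
  out <- cohort
  for (p in phenotypes(cohort)) {
    y <- persons[[p]]
    if (all(is.na(y))) next
    if (length(terms)) {
      fml <- stats::reformulate(terms, response = "y")
      fit <- stats::lm(fml, data = cbind(persons, y = y),
                       na.action = stats::na.exclude)
      r <- stats::residuals(fit)
    } else r <- y - mean(y, na.rm = TRUE)
    z <- r / stats::sd(r, na.rm = TRUE)
    n <- nrow(cohort)
    out[[paste0(p, "_t1")]] <- z[seq_len(n)]
    out[[paste0(p, "_t2")]] <- z[n + seq_len(n)]
  }
  out
}

#' Randomly select one twin per pair
#'
#' Draws one member from every pair (for analyses requiring independent
#' observations) and returns both the selected half and the complementary
#' replication half. The split is fully determined by `seed`.
#'
#' @param cohort A [twin_cohort()].
#' @param seed Integer seed.
#' @return List with person-level data.frames `primary` and `replication`
#'   (columns as in [cohort_persons()]).
#' @export
select_one_per_pair <- function(cohort, seed) {
  stopifnot(inherits(cohort, "twin_cohort"))
  set.seed(check_seed(seed))
  pick <- sample(c(1L, 2L), nrow(cohort), replace = TRUE)
  persons <- cohort_persons(cohort)
  n <- nrow(cohort)
  sel <- ifelse(pick == 1L, seq_len(n), n + seq_len(n))
  list(primary = persons[sel, , drop = FALSE],
       replication = persons[-sel, , drop = FALSE])
}

#' Distributional screening: skewness and excess kurtosis
#'
#' Bias-adjusted sample skewness and excess kurtosis with a pass flag using
#' the conventional screening rule that both must be smaller than 2 in
#' absolute value.
#'
#' @param x Numeric scores; at least 8 non-missing values.
#' @return List with `skewness`, `kurtosis` (excess) and logical `pass`.
#' @export
distribution_check <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 8) stop("need at least 8 non-missing values", call. = FALSE)
  sk <- e1071::skewness(x, type = 2)
  ku <- e1071::kurtosis(x, type = 2)
  list(skewness = sk, kurtosis = ku, pass = abs(sk) < 2 && abs(ku) < 2)
}

#' Sex-difference effect size
#'
#' R-squared from the regression of a score on a male/female indicator,
#' with the direction of the male-minus-female mean difference.
#'
#' @param scores Numeric scores.
#' @param sex `"M"`/`"F"` per person; both sexes must be present.
#' @return List with `r2` and `direction` (+1 if males score higher).
#' @export
sex_difference_r2 <- function(scores, sex) {
  ok <- !is.na(scores) & !is.na(sex)
  scores <- scores[ok]; sex <- sex[ok]
  if (!all(sex %in% c("M", "F")))
    stop("sex must be coded 'M'/'F'", call. = FALSE)
  if (length(unique(sex)) < 2L)
    stop("both sexes must be present", call. = FALSE)
  fit <- stats::lm(scores ~ sex)
  diff <- mean(scores[sex == "M"]) - mean(scores[sex == "F"])
  list(r2 = summary(fit)$r.squared, direction = sign(diff))
}

#' Test-retest reliability
#'
#' Pearson correlation between first and second administrations, pairwise
#' deletion of incomplete pairs.
#'
#' @param first,second Paired scores.
#' @return Pearson r.
#' @export
test_retest <- function(first, second) {
  ok <- !is.na(first) & !is.na(second)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(first[ok]) == 0 || stats::sd(second[ok]) == 0)
    stop("zero-variance scores", call. = FALSE)
  stats::cor(first[ok], second[ok])
}
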