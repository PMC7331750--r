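# Full-information maximum likelihood engine for grouped twin-pair data.
#
# Pairs are grouped by zygosity and, within a group, by missing-data
# pattern. For each pattern we keep sufficient statistics (n, mean, MLE
# covariance of the observed entries), so the -2 log-likelihood
#
#   sum_k n_k [ log|S_k(theta)| + tr(Sbar_k S_k(theta)^-1)
#               + (xbar_k - mu_k)' S_k(theta)^-1 (xbar_k - mu_k)
#               + p_k log(2 pi) ]
#
# is exact FIML under multivariate normality and costs O(p^3) per pattern
# regardless of sample size. Complete data collapse to one pattern per
# group, which is what makes the large replicate suites affordable.

BIG_PENALTY <- 1e12

fiml_stats <- function(Y) {
  # Y: n x d numeric matrix, NA = missing. Returns list of patterns.
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0L
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  lapply(split(seq_len(nrow(Y)), key), function(rows) {
    idx <- which(obs[rows[1L], ])
    X <- Y[rows, idx, drop = FALSE]
    n <- nrow(X)
    xbar <- colMeans(X)
    Xc <- sweep(X, 2L, xbar)
    list(idx = idx, n = n, xbar = xbar, S = crossprod(Xc) / n)
  })
}

fiml_m2ll_stats <- function(stats, mu, Sigma) {
  tot <- 0
  for (st in stats) {
    Sg <- Sigma[st$idx, st$idx, drop = FALSE]
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(BIG_PENALTY)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    d <- st$xbar - mu[st$idx]
    tot <- tot + st$n * (logdet + sum(Sinv * st$S) +
                           drop(crossprod(d, Sinv %*% d)) +
                           length(st$idx) * log(2 * pi))
  }
  tot
}

# pair-data matrices per zygosity group; columns are t1 phenotypes then t2
# phenotypes (matching expected_twin_covariance ordering)
twin_group_matrices <- function(cohort, phenos, scheme = c("two", "five"),
                                male_first_dos = FALSE) {
  scheme <- match.arg(scheme)
  p <- length(phenos)
  build <- function(rows) {
    Y <- matrix(NA_real_, length(rows), 2L * p)
    for (i in seq_len(p)) {
      Y[, i] <- cohort[[paste0(phenos[i], "_t1")]][rows]
      Y[, p + i] <- cohort[[paste0(phenos[i], "_t2")]][rows]
    }
    Y
  }
  if (scheme == "two") {
    groups <- list(MZ = which(cohort$zygosity %in% c("MZm", "MZf")),
                   DZ = which(cohort$zygosity %in% c("DZm", "DZf", "DOS")))
    groups <- Filter(length, groups)
    lapply(groups, build)
  } else {
    out <- list()
    for (g in ZYGOSITY_LEVELS) {
      rows <- which(cohort$zygosity == g)
      if (!length(rows)) next
      Y <- build(rows)
      if (g == "DOS" && male_first_dos) {
        swap <- cohort$sex1[rows] == "F"
        if (any(swap)) {
          tmp <- Y[swap, seq_len(p), drop = FALSE]
          Y[swap, seq_len(p)] <- Y[swap, p + seq_len(p), drop = FALSE]
          Y[swap, p + seq_len(p)] <- tmp
        }
      }
      out[[g]] <- Y
    }
    out
  }
}

twin_group_stats <- function(cohort, phenos, scheme = "two",
                             male_first_dos = FALSE) {
  mats <- twin_group_matrices(cohort, phenos, scheme, male_first_dos)
  lapply(mats, fiml_stats)
}

# total -2 lnL over groups; `models` is a named list (parallel to
# group_stats) of list(mu=, Sigma=)
fiml_m2ll_groups <- function(group_stats, models) {
  tot <- 0
  for (g in names(group_stats)) {
    v <- fiml_m2ll_stats(group_stats[[g]], models[[g]]$mu, models[[g]]$Sigma)
    if (v >= BIG_PENALTY) return(BIG_PENALTY)
    tot <- tot + v
  }
  tot
}

# quasi-Newton minimization with jittered multistarts on failure;
# restarts draw from the session RNG stream so a seeded pipeline stays
# reproducible
minimize_m2ll <- function(fn, start, multistart = 10L, maxit = 2000L,
                          jitter = 0.3) {
  run <- function(par) {
    tryCatch(stats::optim(par, fn, method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-12)),
             error = function(e) NULL)
  }
  best <- run(start)
  tries <- 0L
  while ((is.null(best) || best$convergence != 0 || best$value >= BIG_PENALTY) &&
         tries < multistart) {
    tries <- tries + 1L
    cand <- run(start + stats::rnorm(length(start), 0, jitter))
    if (is.null(best) ||
        (!is.null(cand) && cand$convergence == 0 && cand$value < best$value))
      best <- cand
  }
  if (is.null(best)) stop("optimization failed after multistart", call. = FALSE)
  # polish: one extra pass never hurts and often tightens the optimum
  pol <- run(best$par)
  if (!is.null(pol) && pol$value <= best$value) best <- pol
  best$restarts <- tries
  best
}

# pooled within-twin sample covariance (complete persons), used for starts
pooled_within_cov <- function(cohort, phenos) {
  persons <- cohort_persons(cohort)
  X <- as.matrix(persons[, phenos, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < length(phenos) + 2L) return(diag(length(phenos)))
  stats::cov(X)
}
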