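# Confirmatory factor model engine.

test_that("implied covariance reproduces direct path-tracing algebra", {
  spec <- cfa_model(list(F1 = c("a", "b")))
  # zero loadings: Sigma is the residual diagonal
  expect_equal(unname(implied_covariance(spec, c(0, 0, 0.3, 0.7))),
               diag(c(0.3, 0.7)))
  # lambda = (0.6, 0.6), theta = 0.64: off-diagonal 0.36, diagonal 1
  S <- implied_covariance(spec, c(0.6, 0.6, 0.64, 0.64))
  expect_equal(unname(S), matrix(c(1, 0.36, 0.36, 1), 2))

  # hierarchical: covariance of two indicators of the same first-order
  # factor is lambda_i lambda_j (gamma^2 + (1 - gamma^2)) = lambda_i
  # lambda_j; across factors it is lambda_i lambda_j gamma_k gamma_l
  spec2 <- cfa_model(list(A = c("a1", "a2"), B = c("b1", "b2"),
                          C = c("c1", "c2")), structure = "second_order")
  lam <- c(0.7, 0.6, 0.8, 0.5, 0.65, 0.75)
  gam <- c(0.9, 0.8, 0.85)
  th <- 1 - lam^2
  S2 <- implied_covariance(spec2, c(lam, gam, th))
  expect_equal(S2["a1", "a2"], 0.7 * 0.6 * (0.9^2 + (1 - 0.9^2)))
  expect_equal(S2["a1", "b1"], 0.7 * 0.8 * 0.9 * 0.8)
  expect_equal(S2["b2", "c1"], 0.5 * 0.65 * 0.8 * 0.85)
  expect_equal(diag(S2), setNames(rep(1, 6), colnames(S2)))
})

test_that("a just-identified model fits exactly (F = 0, T = 0)", {
  spec <- cfa_model(list(F1 = c("a", "b", "c")))
  S <- matrix(c(1, 0.42, 0.35, 0.42, 1, 0.3, 0.35, 0.3, 1), 3)
  dimnames(S) <- list(c("a", "b", "c"), c("a", "b", "c"))
  fit <- fit_cfa(S, 500, spec)
  expect_equal(fit$df, 0)
  expect_equal(fit$T, 0, tolerance = 1e-6)
  expect_equal(fit$rmsea, 0)
  expect_equal(fit$srmr, 0, tolerance = 1e-5)
})

test_that("fitting the population implied matrix recovers generating parameters", {
  spec <- cfa_model(list(F1 = c("a", "b", "c", "d")))
  true <- c(0.7, 0.8, 0.6, 0.5, 0.51, 0.36, 0.64, 0.75)
  fit <- fit_cfa(implied_covariance(spec, true), 1000, spec)
  expect_equal(abs(fit$loadings), true[1:4], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(unname(fit$theta), true[5:8], tolerance = 1e-4)
  expect_equal(fit$F_ml, 0, tolerance = 1e-8)
})

test_that("correlated three-factor model recovers factor correlations from data", {
  fac <- list(A = paste0("a", 1:5), B = paste0("b", 1:5), C = paste0("c", 1:6))
  spec <- cfa_model(fac, structure = "correlated")
  lam <- rep(c(0.75, 0.7, 0.65, 0.6, 0.55), length.out = 16)
  phi <- c(0.75, 0.80, 0.90)  # strongly correlated factors
  Y <- simulate_cfa_sample(spec, c(lam, phi, 1 - lam^2), 1300, seed = 61)
  fit <- fit_cfa(cov(Y), nrow(Y), spec)
  est <- fit$phi[lower.tri(fit$phi)]
  expect_near(est, phi, 0.05)
  expect_equal(fit$convergence, 0)
})

test_that("fit indices match hand-computed arithmetic", {
  idx <- fit_indices(T = 20, df = 5, T_baseline = 100, df_baseline = 3, N = 101)
  expect_equal(idx$cfi, 1 - 15 / 97)
  expect_equal(idx$rmsea, sqrt(15 / 500))
  # exact fit: CFI 1, RMSEA 0
  idx0 <- fit_indices(T = 5, df = 5, T_baseline = 100, df_baseline = 3, N = 101)
  expect_equal(idx0$cfi, 1)
  expect_equal(idx0$rmsea, 0)
  # SRMR = 0 when the implied matrix equals the sample matrix
  S <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(fit_indices(0, 0, 10, 1, 100, S = S, Sigma = S)$srmr, 0)
})

test_that("Akaike weights normalize evidence and ignore constants", {
  expect_equal(unname(aic_weights(c(10, 10))), c(0.5, 0.5))
  w <- aic_weights(c(0, 2))
  expect_equal(unname(w), c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_lt(aic_weights(c(0, 20))[2], 1e-4)
  expect_equal(aic_weights(c(0, 2, 7)), aic_weights(c(100, 102, 107)))
  expect_equal(sum(aic_weights(c(3, 1, 4, 1, 5))), 1)
})

test_that("factor R2 on the general factor is the squared second-order loading", {
  fac <- list(A = c("a1", "a2"), B = c("b1", "b2"), C = c("c1", "c2"))
  spec <- cfa_model(fac, structure = "second_order")
  lam <- rep(0.7, 6)
  for (g in c(1, 0.889)) {
    Sg <- implied_covariance(spec, c(lam, c(g, 0.8, 0.85), 1 - lam^2))
    fit <- fit_cfa(Sg, 2000, spec)
    expect_equal(factor_r2(fit, "A"), g^2, tolerance = 1e-3)
  }
})

test_that("freeing parameters never worsens the ML discrepancy (nesting)", {
  fac <- list(A = paste0("a", 1:5), B = paste0("b", 1:5), C = paste0("c", 1:6))
  spec3 <- cfa_model(fac, structure = "correlated")
  spec1 <- cfa_model(list(G = unlist(fac, use.names = FALSE)))
  lam <- rep(0.65, 16)
  Y <- simulate_cfa_sample(spec3, c(lam, c(0.75, 0.8, 0.9), 1 - lam^2),
                           800, seed = 62)
  f3 <- fit_cfa(cov(Y), nrow(Y), spec3)
  f1 <- fit_cfa(cov(Y), nrow(Y), spec1)
  expect_lte(f3$F_ml, f1$F_ml + 1e-8)
})
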