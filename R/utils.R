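# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

zscore <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot standardize a zero-variance vector")
  (x - m) / s
}

# Spherical parameterization of K standardized variance shares.
# K-1 unconstrained angles map to K path coefficients on the unit sphere,
# so the squared paths always sum to exactly 1. Used wherever a latent
# factor's total variance is fixed to 1 (common pathway, hierarchical).
angles_to_paths <- function(ang) {
  K <- length(ang) + 1L
  p <- numeric(K)
  s <- 1
  for (k in seq_len(K - 1L)) {
    p[k] <- s * cos(ang[k])
    s <- s * sin(ang[k])
  }
  p[K] <- s
  p
}

shares_to_angles <- function(shares) {
  K <- length(shares)
  stopifnot(K >= 2L)
  paths <- sqrt(pmax(shares, 0))
  ang <- numeric(K - 1L)
  rem <- 1
  for (k in seq_len(K - 1L)) {
    val <- if (rem <= 1e-12) 0 else min(1, max(-1, paths[k] / sqrt(rem)))
    ang[k] <- acos(val)
    rem <- rem * (1 - val^2)
  }
  ang
}

# lower-triangular matrix from packed column-major vector of its p(p+1)/2
# free entries, and the inverse
vec_to_lower <- function(x, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- x
  L
}

lower_to_vec <- function(L) L[lower.tri(L, diag = TRUE)]

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed) ||
      abs(seed) >= 2^31)
    stop("'seed' must be a single integer below 2^31", call. = FALSE)
  as.integer(seed)
}
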