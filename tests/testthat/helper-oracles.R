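# Independent oracles and fixture builders shared across the suite.
# These deliberately take different code paths from the package: the ILR
# oracle builds its contrast matrix by Gram-Schmidt, the regression oracle
# solves the normal equations directly, and the cluster-covariance oracle
# assembles the sandwich by summing per-cluster score outer products.

# Orthonormal pivot contrast matrix via Gram-Schmidt on the raw
# part-vs-mean-of-rest contrasts; returns (D-1) x D acting on log parts.
oracle_contrast_matrix <- function(D) {
  raw <- matrix(0, D - 1, D)
  for (k in seq_len(D - 1)) {
    raw[k, k] <- 1
    raw[k, (k + 1):D] <- -1 / (D - k)
  }
  L <- matrix(0, D - 1, D)
  for (k in seq_len(D - 1)) {
    v <- raw[k, ]
    if (k > 1) for (j in seq_len(k - 1)) v <- v - sum(v * L[j, ]) * L[j, ]
    L[k, ] <- v / sqrt(sum(v^2))
  }
  L
}

# ILR coordinates of one composition through the contrast matrix.
oracle_ilr <- function(x, order) {
  L <- oracle_contrast_matrix(length(order))
  drop(L %*% log(x[order]))
}

# OLS point estimates by explicit normal equations.
oracle_ols <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# Stata-style CR1 cluster sandwich: G/(G-1) * (n-1)/(n-k) adjustment.
oracle_cluster_vcov <- function(X, resid, cluster) {
  n <- nrow(X); k <- ncol(X)
  G <- length(unique(cluster))
  bread <- solve(crossprod(X))
  meat <- matrix(0, k, k)
  for (g in unique(cluster)) {
    s <- colSums(X[cluster == g, , drop = FALSE] * resid[cluster == g])
    meat <- meat + tcrossprod(s)
  }
  (G / (G - 1)) * ((n - 1) / (n - k)) * bread %*% meat %*% bread
}

# Random strictly-positive compositions closed to 1440.
random_compositions <- function(n, parts = mb_parts(), sd = 1) {
  m <- exp(matrix(rnorm(n * length(parts), sd = sd), n,
                  dimnames = list(NULL, parts)))
  close_composition(m)
}

# Small deterministic cohort for model tests.
toy_cohort <- function(n = 60, seed = 101, ...) {
  generate_cohort(cohort_config(n = n, seed = seed, ...))
}

# Complete questionnaire response rows.
toy_responses <- function(values) {
  stopifnot(length(values) == 20)
  as.data.frame(as.list(stats::setNames(values, sprintf("item_%02d", 1:20))))
}
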