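# Shared fixtures, all generated in code.

# small default-structure cohort for fast tests
small_cohort <- function(seed = 1L, ...) {
  generate_cohort(cohort_config(seed = seed, ...))
}

# complete-case standardized matrix + fitted PPCA at the true dimension
fitted_space <- function(cohort, D = 4L) {
  std <- standardize(cohort$features)
  cc <- rowSums(std$X$mask) == 0
  model <- fit_ppca(std$X$values[cc, , drop = FALSE], D)
  list(std = std, cc = cc, model = model)
}

# noiseless rank-D factor data with known loadings
noiseless_factor_data <- function(n = 60, p = 12, D = 3, seed = 42) {
  set.seed(seed)
  W <- matrix(rnorm(p * D), p, D)
  Z <- matrix(rnorm(n * D), n, D)
  list(X = Z %*% t(W), W = W, Z = Z)
}

# independent multivariate normal log density (direct solve/determinant),
# used as an oracle against the eigen-based model likelihoods
mvn_loglik_oracle <- function(X, mu, Sigma) {
  X <- as.matrix(X)
  p <- ncol(X)
  sum(apply(X, 1, function(x) {
    d <- x - mu
    -0.5 * (p * log(2 * pi) + determinant(Sigma, logarithm = TRUE)$modulus +
              drop(t(d) %*% solve(Sigma, d)))
  }))
}

# largest principal angle (degrees) between column spaces
principal_angle_deg <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s)))) * 180 / pi
}

# adjusted Rand index between two hard labelings (small-n closed form)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
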