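test_that("standardization centers and scales on the complete cases", {
  co <- small_cohort(seed = 2)
  std <- standardize(co$features)
  cc <- rowSums(std$X$mask) == 0
  V <- std$X$values[cc, , drop = FALSE]
  expect_lt(max(abs(colMeans(V))), 1e-10)
  expect_lt(max(abs(apply(V, 2, sd) - 1)), 1e-10)
  # masked cells stay masked
  expect_identical(std$X$mask, co$features$mask)
  expect_true(all(is.na(std$X$values[std$X$mask])))
  # idempotence: re-applying on already standardized data changes nothing
  std2 <- standardize(std$X)
  expect_lt(max(abs(std2$X$values - std$X$values), na.rm = TRUE), 1e-12)
})

test_that("standardization uses the n-1 denominator and rejects constants", {
  fm <- feature_matrix(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_error(standardize(fm), "b")
  fm2 <- feature_matrix(cbind(a = c(1, 2, 3), b = c(0, 1, 4)))
  std <- standardize(fm2)
  expect_equal(unname(std$X$values[, "a"]), c(-1, 0, 1))
})

test_that("stored standardization parameters transfer to new subjects", {
  co <- small_cohort(seed = 9)
  std <- standardize(co$features)
  redo <- standardize(co$features, params = std$params)
  expect_identical(redo$X$values, std$X$values)
})

test_that("PPCA ML solution matches its closed-form properties", {
  nf <- noiseless_factor_data(n = 200, p = 10, D = 3)
  X <- nf$X + matrix(rnorm(2000, sd = 0.1), 200, 10)
  m <- fit_ppca(X, 3)
  expect_s3_class(m, "ppca_model")
  # sigma2 = mean of discarded eigenvalues
  expect_equal(m$sigma2, mean(m$eigenvalues[4:10]))
  # boundary case D = p - 1: sigma2 is the smallest eigenvalue
  mb <- fit_ppca(X, 9)
  expect_equal(mb$sigma2, m$eigenvalues[10])
  # W columns orthogonal at the canonical solution
  G <- crossprod(m$W)
  expect_lt(max(abs(G[lower.tri(G)])), 1e-8)
  expect_error(fit_ppca(X, 10), "D must")
  expect_error(fit_ppca(X * NA, 2), "non-finite")
})

test_that("PPCA recovers a known 4-factor model at large n", {
  set.seed(31)
  p <- 20; D <- 4; n <- 5000
  W <- matrix(rnorm(p * D), p, D)
  Z <- matrix(rnorm(n * D), n, D)
  sigma <- 0.6
  X <- Z %*% t(W) + matrix(rnorm(n * p, sd = sigma), n, p)
  m <- fit_ppca(X, D)
  expect_lt(abs(m$sigma2 - sigma^2) / sigma^2, 0.05)
  expect_lt(principal_angle_deg(m$W, W), 5)
})

test_that("model log-likelihood agrees with a direct density oracle", {
  set.seed(8)
  X <- matrix(rnorm(15), 5, 3)
  m <- fit_ppca(X, 2)
  C <- tcrossprod(m$W) + diag(m$sigma2, 3)
  expect_equal(m$loglik, mvn_loglik_oracle(X, m$mu, C), tolerance = 1e-8)
  expect_equal(ppca_loglik(m, X), m$loglik, tolerance = 1e-8)
})

test_that("AIC formula and penalty behave as documented", {
  # equal log-likelihood, D = 3 vs 4: AIC difference = 2 (p - 3)
  p <- 45
  m3 <- structure(list(D = 3L, loglik = -100, mu = rep(0, p)),
                  class = "ppca_model")
  m4 <- structure(list(D = 4L, loglik = -100, mu = rep(0, p)),
                  class = "ppca_model")
  expect_equal(ppca_aic(m4) - ppca_aic(m3), 2 * (p - 3))
  expect_equal(ppca_n_params(45, 4), 45 * 4 - 6 + 45 + 1)
})

test_that("AIC is invariant to orthogonal rotation of the loadings", {
  set.seed(12)
  X <- matrix(rnorm(40 * 6), 40, 6)
  m <- fit_ppca(X, 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  mrot <- m
  mrot$W <- m$W %*% Q
  mrot$loglik <- ppca_loglik(mrot, X)
  expect_equal(ppca_aic(mrot), ppca_aic(m), tolerance = 1e-8)
})

test_that("AIC prefers the grid minimum on isotropic noise", {
  hits <- sapply(1:25, function(s) {
    set.seed(s)
    X <- matrix(rnorm(80 * 15), 80, 15)
    select_dimension(X, 2:8)$selected_D == 2L
  })
  expect_gte(mean(hits), 0.9)
})

test_that("dimension selection returns the full curve with correct argmin", {
  co <- small_cohort(seed = 1, missing_subject_rate = 0)
  std <- standardize(co$features)
  # drop to the study's complete-case size
  X <- std$X$values[1:92, ]
  # the default grid spans 2 .. min(p, n) - 1; D = p is not estimable for
  # an isotropic-noise factor model, so the study design yields 43 entries
  cur <- select_dimension(X)
  expect_length(cur$aic, 43L)
  expect_error(select_dimension(X, 2:45), "grid")
  expect_identical(cur$selected_D,
                   cur$D_grid[which.min(cur$aic)])
  # log-likelihood is non-decreasing in D on the same data
  ll <- vapply(cur$models, `[[`, numeric(1), "loglik")
  expect_true(all(diff(ll) > -1e-6))
  # AIC curve is not monotone (penalty bites after the true dimension)
  expect_gt(cur$aic[length(cur$aic)], min(cur$aic))
  # grid of length 1 returns that D
  expect_identical(select_dimension(X, 5L)$selected_D, 5L)
  expect_error(select_dimension(X, integer(0)), "empty")
})

test_that("fitting is deterministic with a fixed eigen sign convention", {
  co <- small_cohort(seed = 14, missing_subject_rate = 0)
  std <- standardize(co$features)
  m1 <- fit_ppca(std$X$values, 4)
  m2 <- fit_ppca(std$X$values, 4)
  expect_identical(m1$W, m2$W)
  # sign convention: largest-magnitude element of each column's
  # eigenvector is positive, so projections are platform-reproducible
  expect_true(all(apply(m1$W, 2, function(w) w[which.max(abs(w))] > 0)))
})

test_that("projection is the latent posterior mean", {
  nf <- noiseless_factor_data(n = 80, p = 12, D = 3)
  m <- fit_ppca(nf$X, 3)
  # x = mu projects to the origin
  expect_equal(unname(drop(project(m, matrix(m$mu, 1)))), rep(0, 3),
               tolerance = 1e-10)
  # round trip on noiseless rank-D data recovers x
  Z <- project(m, nf$X)
  Xrec <- Z %*% t(m$W) + matrix(m$mu, 80, 12, byrow = TRUE)
  expect_lt(max(abs(Xrec - nf$X)), 1e-6)
  # sigma2 -> 0 limit: model reconstruction equals rank-D PCA reconstruction
  Xc <- sweep(nf$X, 2, colMeans(nf$X))
  U <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)$vectors[, 1:3]
  Xpca <- Xc %*% U %*% t(U)
  expect_lt(max(abs((Xrec - matrix(m$mu, 80, 12, byrow = TRUE)) - Xpca)), 1e-6)
  expect_error(project(m, matrix(0, 2, 5)), "mismatch")
})
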