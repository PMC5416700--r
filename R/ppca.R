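#' Standardize features to zero mean and unit variance
#'
#' Per-feature mean and sample s.d. (denominator n-1) are estimated on the
#' complete-case subjects (rows without missing cells) and applied to all
#' subjects, so subjects that later enter through imputation are scaled with
#' the same statistics as the fitting sample. Masked cells are untouched.
#'
#' @param X a [feature_matrix()].
#' @param params optionally, previously estimated standardization parameters
#'   (list with `mean` and `sd`) to apply instead of re-estimating.
#' @return list with `X` (standardized feature_matrix) and `params`
#'   (list: `mean`, `sd`, `n_used`).
#' @export
standardize <- function(X, params = NULL) {
  stopifnot(inherits(X, "feature_matrix"))
  if (is.null(params)) {
    cc <- complete_rows(X)
    if (sum(cc) < 2L) abort("standardize: fewer than 2 complete cases")
    V <- X$values[cc, , drop = FALSE]
    mu <- colMeans(V)
    s <- apply(V, 2, sd)
    bad <- !is.finite(s) | s <= 0
    if (any(bad))
      abort("standardize: constant feature(s): ",
            paste(X$feature_names[bad], collapse = ", "))
    params <- list(mean = mu, sd = s, n_used = sum(cc))
  }
  X$values <- sweep(sweep(X$values, 2, params$mean), 2, params$sd, "/")
  list(X = X, params = params)
}

#' Fit maximum-likelihood probabilistic PCA
#'
#' Closed-form ML solution for the isotropic Gaussian factor model
#' x = W z + mu + eps, eps ~ N(0, sigma^2 I), z ~ N(0, I): with sample
#' covariance eigenvalues lambda_1 >= ... >= lambda_p (ML covariance,
#' denominator n) and eigenvectors U, sigma^2 is the mean of the p - D
#' smallest eigenvalues and W = U_D (Lambda_D - sigma^2 I)^{1/2}. The
#' eigenvector sign convention (largest-magnitude element positive) makes
#' the fit bit-reproducible across platforms.
#'
#' @param Xs numeric complete-case matrix (n x p), typically standardized, or
#'   a [feature_matrix()] without missing cells.
#' @param D latent dimension, 1 <= D < min(p, n).
#' @return object of class `"ppca_model"`: list with `D`, `W` (p x D),
#'   `sigma2`, `mu`, `n_fit`, `loglik`, `eigenvalues`.
#' @export
fit_ppca <- function(Xs, D) {
  if (inherits(Xs, "feature_matrix")) {
    if (any(Xs$mask)) abort("fit_ppca: input has missing cells")
    Xs <- Xs$values
  }
  Xs <- as.matrix(Xs)
  if (!all(is.finite(Xs))) abort("fit_ppca: non-finite values in input")
  n <- nrow(Xs); p <- ncol(Xs)
  if (D < 1 || D >= p) abort("fit_ppca: D must satisfy 1 <= D < p")
  if (n <= D) abort("fit_ppca: need more fitting subjects than dimensions")
  mu <- colMeans(Xs)
  Xc <- sweep(Xs, 2, mu)
  S <- crossprod(Xc) / n                    # ML covariance (denominator n)
  eg <- eigen(S, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  ## fixed sign convention for reproducibility
  for (j in seq_len(ncol(U))) {
    k <- which.max(abs(U[, j]))
    if (U[k, j] < 0) U[, j] <- -U[, j]
  }
  sigma2 <- mean(lam[(D + 1):p])
  W <- U[, seq_len(D), drop = FALSE] %*%
    diag(sqrt(pmax(lam[seq_len(D)] - sigma2, 0)), D, D)
  rownames(W) <- colnames(Xs)
  ## log|C| and tr(C^-1 S) from the eigenvalues of C = W W' + sigma^2 I:
  ## lambda_j for j <= D, sigma^2 for j > D
  logdetC <- sum(log(lam[seq_len(D)])) + (p - D) * log(sigma2)
  trCinvS <- D + sum(lam[(D + 1):p]) / sigma2
  loglik <- -n / 2 * (p * log(2 * pi) + logdetC + trCinvS)
  structure(list(D = as.integer(D), W = W, sigma2 = sigma2, mu = mu,
                 n_fit = n, loglik = loglik, eigenvalues = lam),
            class = "ppca_model")
}

#' Log-likelihood of data under a fitted PPCA model
#'
#' Evaluates the Gaussian log-density with covariance C = W W' + sigma^2 I
#' and mean `mu` at the rows of `Xs`, summed. Used for model audit and for
#' rotation-invariance checks; `fit_ppca()` stores the same quantity for the
#' fitting data.
#'
#' @param model a `"ppca_model"`.
#' @param Xs numeric matrix, columns matching the model.
#' @return total log-likelihood (scalar).
#' @export
ppca_loglik <- function(model, Xs) {
  stopifnot(inherits(model, "ppca_model"))
  Xs <- as.matrix(Xs)
  p <- length(model$mu)
  if (ncol(Xs) != p) abort("ppca_loglik: dimension mismatch")
  C <- tcrossprod(model$W) + diag(model$sigma2, p)
  ch <- chol(C)
  Xc <- sweep(Xs, 2, model$mu)
  Q <- backsolve(ch, t(Xc), transpose = TRUE)
  -0.5 * (nrow(Xs) * (p * log(2 * pi) + 2 * sum(log(diag(ch)))) +
            sum(Q^2))
}

#' Akaike information criterion of a PPCA model
#'
#' AIC = -2 loglik + 2 m with the free-parameter count
#' m = pD - D(D-1)/2 + p + 1: the loading matrix minus its rotational gauge
#' freedom, plus the p mean parameters, plus the noise variance. Used as an
#' analytic stand-in for cross-validated deviance when choosing the latent
#' dimension.
#'
#' @param model a `"ppca_model"`.
#' @return numeric AIC value.
#' @export
ppca_aic <- function(model) {
  stopifnot(inherits(model, "ppca_model"))
  -2 * model$loglik + 2 * ppca_n_params(length(model$mu), model$D)
}

#' PPCA free-parameter count used in the AIC penalty
#' @param p number of features.
#' @param D latent dimension.
#' @return integer parameter count.
#' @export
ppca_n_params <- function(p, D) p * D - D * (D - 1) / 2 + p + 1

#' Select the PPCA latent dimension by AIC
#'
#' Fits the model for every dimension in `D_grid` and returns the AIC curve
#' with the arg-min; ties are broken toward the smaller dimension. The
#' computation is deterministic given the input.
#'
#' @param Xs complete-case matrix or [feature_matrix()].
#' @param D_grid integer vector of candidate dimensions (default 2 up to
#'   min(p, n) - 1, capped at 45).
#' @return object of class `"aic_curve"`: list with `D_grid`, `aic`,
#'   `selected_D`, `models` (the per-D fits).
#' @export
select_dimension <- function(Xs, D_grid = NULL) {
  if (inherits(Xs, "feature_matrix")) {
    if (any(Xs$mask)) abort("select_dimension: input has missing cells")
    Xs <- Xs$values
  }
  n <- nrow(Xs); p <- ncol(Xs)
  if (is.null(D_grid)) D_grid <- 2:(min(p, n) - 1L)
  D_grid <- as.integer(D_grid)
  if (length(D_grid) == 0L) abort("select_dimension: empty dimension grid")
  if (any(D_grid < 1L) || any(D_grid >= min(p, n)))
    abort("select_dimension: grid must lie in [1, min(p, n) - 1]")
  models <- lapply(D_grid, function(D) fit_ppca(Xs, D))
  aic <- vapply(models, ppca_aic, numeric(1))
  sel <- D_grid[which.min(aic)]   # which.min takes the first = smallest D
  structure(list(D_grid = D_grid, aic = aic, selected_D = sel,
                 models = models),
            class = "aic_curve")
}

#' @export
print.aic_curve <- function(x, ...) {
  cat(sprintf("AIC over D = %d..%d: selected D = %d (AIC %.1f)\n",
              min(x$D_grid), max(x$D_grid), x$selected_D, min(x$aic)))
  invisible(x)
}

#' Project complete subjects into the latent space
#'
#' Posterior mean of the latent scores, E\[z | x\] = M^{-1} W' (x - mu) with
#' M = W'W + sigma^2 I. Axes inherit the eigen ordering of the fit, so the
#' first column explains the most variance. Subjects with missing cells must
#' go through the imputation stage instead.
#'
#' @param model a `"ppca_model"`.
#' @param Xs numeric matrix or [feature_matrix()] with no missing cells
#'   among its rows, columns matching the model.
#' @return subjects x D matrix of latent scores.
#' @export
project <- function(model, Xs) {
  stopifnot(inherits(model, "ppca_model"))
  if (inherits(Xs, "feature_matrix")) {
    if (any(Xs$mask)) abort("project: input has missing cells; use the imputation stage")
    Xs <- Xs$values
  }
  if (is.null(dim(Xs))) Xs <- matrix(Xs, nrow = 1)
  ids <- rownames(Xs)
  Xs <- matrix(as.numeric(Xs), ncol = ncol(Xs),
               dimnames = list(ids, NULL))
  if (ncol(Xs) != nrow(model$W)) abort("project: dimension mismatch")
  M <- crossprod(model$W) + diag(model$sigma2, model$D)
  Z <- t(solve(M, t(model$W) %*% t(sweep(Xs, 2, model$mu))))
  colnames(Z) <- paste0("PC", seq_len(model$D))
  Z
}
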