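## Gaussian mixture subgrouping in the latent space.
##
## EM with full, unshared covariances, a diagonal ridge `reg` added at every
## M-step, k-means++-style initialization, and multiple restarts. Model
## selection over K uses leave-one-out cross-validated held-out negative
## log-likelihood, the estimator that generalizes to unseen subjects even at
## small n.

## internal: per-point log densities under each component -> n x K matrix
gmm_log_dens <- function(Z, weights, means, covs) {
  n <- nrow(Z); K <- length(weights); D <- ncol(Z)
  L <- matrix(0, n, K)
  tZ <- t(Z)
  for (k in seq_len(K)) {
    ch <- tryCatch(chol(covs[[k]]), error = function(e) NULL)
    if (is.null(ch)) abort("gmm: covariance not positive-definite")
    Q <- backsolve(ch, tZ - means[[k]], transpose = TRUE)
    L[, k] <- log(weights[k]) - 0.5 * (D * log(2 * pi) +
                                         2 * sum(log(diag(ch))) + colSums(Q^2))
  }
  L
}

logsumexp_rows <- function(L) {
  m <- L[, 1L]
  for (k in seq_len(ncol(L))[-1L]) m <- pmax(m, L[, k])
  m + log(rowSums(exp(L - m)))
}

## internal: squared Euclidean distances rows(Z) x rows(C)
pairwise_d2 <- function(Z, C) {
  d2 <- outer(rowSums(Z^2), rowSums(C^2), "+") - 2 * tcrossprod(Z, C)
  pmax(d2, 0)
}

## internal: k-means++ style seeding of K centres
kmeanspp_centres <- function(Z, K) {
  n <- nrow(Z)
  idx <- sample.int(n, 1L)
  d2min <- rep(Inf, n)
  for (k in seq_len(K - 1L)) {
    d2min <- pmin(d2min, pairwise_d2(Z, Z[idx[k], , drop = FALSE])[, 1L])
    pr <- if (sum(d2min) > 0 && all(is.finite(d2min))) d2min / sum(d2min)
    else rep(1 / n, n)
    idx <- c(idx, sample.int(n, 1L, prob = pr))
  }
  Z[idx, , drop = FALSE]
}

gmm_em_once <- function(Z, K, reg, max_iter, tol, min_mass) {
  n <- nrow(Z); D <- ncol(Z)
  centres <- kmeanspp_centres(Z, K)
  ## hard assignment to nearest centre -> initial responsibilities
  dist2 <- pairwise_d2(Z, centres)
  R <- matrix(1e-6, n, K)
  R[cbind(seq_len(n), max.col(-dist2))] <- 1
  R <- R / rowSums(R)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    Nk <- colSums(R)
    if (any(Nk < min_mass)) return(list(collapsed = TRUE))
    weights <- Nk / n
    M <- crossprod(R, Z) / Nk                 # K x D component means
    means <- lapply(seq_len(K), function(k) M[k, ])
    covs <- lapply(seq_len(K), function(k) {
      Zc <- Z - rep(M[k, ], each = n)
      (crossprod(Zc * R[, k], Zc)) / Nk[k] + diag(reg, D)
    })
    L <- gmm_log_dens(Z, weights, means, covs)
    lse <- logsumexp_rows(L)
    ll <- sum(lse)
    trace <- c(trace, ll)
    R <- exp(L - lse)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) {
      return(list(collapsed = FALSE, weights = weights, means = means,
                  covs = covs, loglik = ll, n_iter = it, converged = TRUE,
                  loglik_trace = trace))
    }
    ll_old <- ll
  }
  list(collapsed = FALSE, weights = weights, means = means, covs = covs,
       loglik = ll_old, n_iter = max_iter, converged = FALSE,
       loglik_trace = trace)
}

#' Fit a Gaussian mixture model by EM
#'
#' Full, unshared covariances with a diagonal regularizer `reg` added at
#' every M-step (keeps 4-D fits positive-definite even in n = 43 CV folds
#' with K up to 10). Each of `n_restarts` runs starts from a
#' k-means++-style seeding; the best training log-likelihood wins. A restart
#' in which a component's responsibility mass drops below `min_mass` points
#' is discarded as collapsed; if all restarts collapse an error is raised.
#' The training log-likelihood is non-decreasing across EM iterations (the
#' full trace is kept in `loglik_trace`).
#'
#' The default `min_mass = D + 1` matters at small n: selecting the best
#' restart by training likelihood otherwise latches onto degenerate "spike"
#' solutions -- a near-singular component wrapped around a handful of
#' points has arbitrarily high training likelihood but generalizes
#' terribly. A full D-dimensional covariance needs at least D + 1 points
#' to be non-degenerate, so restarts below that mass are rejected.
#'
#' @param Z numeric n x D matrix of latent scores.
#' @param K number of components (>= 1).
#' @param n_restarts number of random initializations (default 20).
#' @param reg diagonal covariance regularizer (default 1e-4).
#' @param seed integer seed; restarts are seeded deterministically from it.
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood change falls below `tol` (default 1e-8) or after
#'   `max_iter` (default 500) iterations.
#' @param min_mass minimum responsibility mass per component before a
#'   restart counts as collapsed (default `ncol(Z) + 1`).
#' @return object of class `"gmm_model"`: `K`, `weights`, `means` (list of
#'   length-D vectors), `covs` (list of D x D matrices), `loglik`,
#'   `converged`, `n_iter`, `loglik_trace`.
#' @export
fit_gmm <- function(Z, K, n_restarts = 20L, reg = 1e-4, seed = 1L,
                    max_iter = 500L, tol = 1e-8, min_mass = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (K < 1L) abort("fit_gmm: K must be >= 1")
  if (n < K) abort("fit_gmm: need at least K points")
  if (reg < 0) abort("fit_gmm: reg must be >= 0")
  if (is.null(min_mass)) min_mass <- ncol(Z) + 1
  if (K == 1L) {
    ## closed form: no EM needed
    mu <- colMeans(Z)
    Zc <- sweep(Z, 2, mu)
    Sg <- crossprod(Zc) / n + diag(reg, ncol(Z))
    L <- gmm_log_dens(Z, 1, list(mu), list(Sg))
    return(structure(list(K = 1L, weights = 1, means = list(mu),
                          covs = list(Sg), loglik = sum(L),
                          converged = TRUE, n_iter = 0L,
                          loglik_trace = sum(L)),
                     class = "gmm_model"))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, 100L + r))
    fit <- gmm_em_once(Z, K, reg, max_iter, tol, min_mass)
    if (fit$collapsed) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    abort("fit_gmm: all restarts collapsed (K too large for the data?)")
  structure(c(list(K = as.integer(K)), best[c("weights", "means", "covs",
                                              "loglik", "converged", "n_iter",
                                              "loglik_trace")]),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d, loglik = %.3f (%s after %d iterations)\n",
              x$K, x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Held-out negative log-likelihood of points under a mixture
#'
#' -log sum_k pi_k N(z; mu_k, Sigma_k), evaluated with log-sum-exp
#' stabilization. Vectorized over the rows of `z`.
#'
#' @param model a `"gmm_model"`.
#' @param z numeric vector (one point) or matrix (rows = points).
#' @return numeric vector of per-point negative log-likelihoods.
#' @export
heldout_nll <- function(model, z) {
  stopifnot(inherits(model, "gmm_model"))
  z <- if (is.null(dim(z))) matrix(z, nrow = 1) else as.matrix(z)
  L <- gmm_log_dens(z, model$weights, model$means, model$covs)
  -logsumexp_rows(L)
}

#' Select the number of mixture components by leave-one-out CV
#'
#' For every K in the grid and every subject, fits the mixture on the n - 1
#' remaining subjects and records the held-out negative log-likelihood of
#' the left-out subject; the CV curve is the per-K mean and the selected K
#' its arg-min (ties broken to the smaller K within tolerance 1e-9). A fold
#' whose fit fails is recorded as `NaN` with a warning; a K with more than
#' 10% failed folds is marked invalid and excluded from selection.
#'
#' @param Z n x D latent scores (patients only, in the intended use).
#' @param K_grid integer grid (default 1:10).
#' @param n_restarts,reg,min_mass EM settings per fold fit, see
#'   [fit_gmm()].
#' @param seed integer; fold/K fits are seeded deterministically from it.
#' @return object of class `"cv_curve"`: `K_grid`, `mean_nll`, `se_nll`,
#'   `fold_nll` (n x length(K_grid)), `valid`, `selected_K`.
#' @export
loo_select_k <- function(Z, K_grid = 1:10, n_restarts = 20L, reg = 1e-4,
                         seed = 1L, min_mass = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  K_grid <- as.integer(K_grid)
  if (length(K_grid) == 0L) abort("loo_select_k: empty K grid")
  if (n < max(K_grid) + 1L)
    abort("loo_select_k: need at least max(K_grid) + 1 subjects")
  fold_nll <- matrix(NA_real_, n, length(K_grid),
                     dimnames = list(NULL, paste0("K", K_grid)))
  for (j in seq_along(K_grid)) {
    K <- K_grid[j]
    for (i in seq_len(n)) {
      fit <- tryCatch(
        fit_gmm(Z[-i, , drop = FALSE], K, n_restarts = n_restarts,
                reg = reg, seed = derive_seed(seed, 1000L * K + i),
                min_mass = min_mass),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning(sprintf("loo_select_k: fit failed for K=%d fold %d", K, i))
        fold_nll[i, j] <- NaN
      } else {
        fold_nll[i, j] <- heldout_nll(fit, Z[i, ])
      }
    }
  }
  failed <- colMeans(is.nan(fold_nll))
  valid <- failed <= 0.10
  mean_nll <- colMeans(fold_nll, na.rm = TRUE)
  se_nll <- apply(fold_nll, 2, function(v) sd(v[!is.nan(v)]) /
                    sqrt(sum(!is.nan(v))))
  cand <- which(valid)
  if (length(cand) == 0L) abort("loo_select_k: no valid K in the grid")
  best <- min(mean_nll[cand])
  sel <- K_grid[cand[mean_nll[cand] <= best + 1e-9][1L]]
  structure(list(K_grid = K_grid, mean_nll = unname(mean_nll),
                 se_nll = unname(se_nll), fold_nll = fold_nll,
                 valid = unname(valid), selected_K = sel),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("LOO-CV held-out NLL over K = %s: selected K = %d\n",
              paste(range(x$K_grid), collapse = ".."), x$selected_K))
  print(data.frame(K = x$K_grid, mean_nll = x$mean_nll, se = x$se_nll,
                   valid = x$valid), row.names = FALSE)
  invisible(x)
}

#' Posterior subgroup assignment
#'
#' Responsibilities by Bayes' rule and hard labels by maximum
#' responsibility. Components are renumbered by descending size (total
#' responsibility mass) so "subgroup 1" is always the largest, giving
#' reproducible naming across fits.
#'
#' @param model a `"gmm_model"`.
#' @param Z n x D matrix of latent scores.
#' @return object of class `"subgroup_assignment"`: list with
#'   `responsibilities` (n x K, rows sum to 1), `labels` (integer per
#'   subject), `sizes` (hard-label counts per component).
#' @export
assign_subgroups <- function(model, Z) {
  stopifnot(inherits(model, "gmm_model"))
  Z <- if (is.null(dim(Z))) matrix(Z, nrow = 1) else as.matrix(Z)
  if (ncol(Z) != length(model$means[[1L]]))
    abort("assign_subgroups: dimension mismatch")
  L <- gmm_log_dens(Z, model$weights, model$means, model$covs)
  R <- exp(L - logsumexp_rows(L))
  ord <- order(colSums(R), decreasing = TRUE)
  R <- R[, ord, drop = FALSE]
  colnames(R) <- paste0("responsibility_", seq_len(model$K))
  rownames(R) <- rownames(Z)
  labels <- max.col(R, ties.method = "first")
  names(labels) <- rownames(Z)
  structure(list(responsibilities = R, labels = labels,
                 sizes = tabulate(labels, nbins = model$K),
                 component_order = ord),
            class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat(sprintf("Subgroup assignment: %d subjects, %d components, sizes %s\n",
              length(x$labels), ncol(x$responsibilities),
              paste(x$sizes, collapse = " / ")))
  invisible(x)
}
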