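#' Imputation configuration
#'
#' Controls the model-based imputation of subjects with missing features.
#' A subject is imputed into the latent space through the conditional
#' posterior of the fitted PPCA model; its expected imputation error is
#' estimated by replaying its missingness pattern on every complete-case
#' donor and similarity-weighting the donors' realized latent errors.
#' Latent axes are rescaled so each has s.d. `pc_sd_scale` over the complete
#' cases before errors are measured, making the `threshold` comparable
#' across cohorts; with the defaults the gate 0.05 equals half a (rescaled)
#' standard deviation.
#'
#' @param threshold inclusion gate: a subject is included iff its estimated
#'   error is strictly below this value (default 0.05).
#' @param pc_sd_scale per-axis s.d. after rescaling (default 0.1).
#' @param bandwidth Gaussian similarity-kernel bandwidth on the donor-target
#'   distance over mutually observed features; `NULL` (default) uses the
#'   median donor-target distance, a scale-free choice.
#' @return list of class `"imputation_config"`.
#' @export
imputation_config <- function(threshold = 0.05, pc_sd_scale = 0.1,
                              bandwidth = NULL) {
  if (threshold <= 0) abort("imputation_config: threshold must be > 0")
  if (pc_sd_scale <= 0) abort("imputation_config: pc_sd_scale must be > 0")
  if (!is.null(bandwidth) && bandwidth <= 0)
    abort("imputation_config: bandwidth must be > 0")
  structure(list(threshold = threshold, pc_sd_scale = pc_sd_scale,
                 bandwidth = bandwidth),
            class = "imputation_config")
}

#' Conditional latent projection from partially observed features
#'
#' Posterior mean of the latent score given only the observed coordinates:
#' E[z | x_obs] = (W_o' W_o + sigma^2 I)^{-1} W_o' (x_obs - mu_o), where the
#' subscript o restricts the loading rows and mean entries to observed
#' features. With an empty mask this equals [project()] exactly.
#'
#' @param model a `"ppca_model"`.
#' @param x numeric length-p vector (values at masked positions are ignored).
#' @param mask logical length-p vector, `TRUE` = missing.
#' @return length-D latent score vector.
#' @export
conditional_project <- function(model, x, mask) {
  stopifnot(inherits(model, "ppca_model"))
  p <- nrow(model$W)
  if (length(x) != p || length(mask) != p)
    abort("conditional_project: x and mask must have length p")
  obs <- !mask
  if (sum(obs) < model$D)
    abort("conditional_project: fewer observed features than latent dimensions")
  Wo <- model$W[obs, , drop = FALSE]
  M <- crossprod(Wo) + diag(model$sigma2, model$D)
  drop(solve(M, crossprod(Wo, x[obs] - model$mu[obs])))
}

## internal: conditional projection of many rows sharing one mask pattern
conditional_project_rows <- function(model, X, mask) {
  obs <- !mask
  Wo <- model$W[obs, , drop = FALSE]
  M <- crossprod(Wo) + diag(model$sigma2, model$D)
  t(solve(M, crossprod(Wo, t(sweep(X[, obs, drop = FALSE], 2, model$mu[obs])))))
}

#' Estimate the latent-space imputation error for one missingness pattern
#'
#' For every complete-case donor, the target's missingness pattern is masked
#' onto the donor's feature vector; the donor's conditional projection is
#' compared with its complete-data projection, giving a realized latent
#' Euclidean error (on axes rescaled to s.d. `pc_sd_scale`). The returned
#' estimate is the similarity-weighted mean of these donor errors, with
#' Gaussian-kernel weights on the donor-target distance over the features
#' the target actually observed.
#'
#' @param model a `"ppca_model"`.
#' @param complete_scores complete-case latent scores (donors x D), as from
#'   [project()] on the complete cases.
#' @param complete_X complete-case standardized feature matrix (donors x p).
#' @param x_target numeric length-p vector for the target subject
#'   (masked entries may be `NA`).
#' @param mask logical length-p missingness pattern of the target.
#' @param config an [imputation_config()].
#' @return non-negative scalar error estimate.
#' @export
estimate_error <- function(model, complete_scores, complete_X, x_target,
                           mask, config = imputation_config()) {
  stopifnot(inherits(model, "ppca_model"))
  if (!any(mask)) return(0)
  complete_X <- as.matrix(complete_X)
  if (nrow(complete_X) < 10L)
    abort("estimate_error: need at least 10 complete-case donors")
  axis_sd <- apply(complete_scores, 2, sd)
  scale_fac <- config$pc_sd_scale / axis_sd
  Zc <- conditional_project_rows(model, complete_X, mask)
  Zf <- complete_scores
  err <- sqrt(rowSums((sweep(Zc - Zf, 2, scale_fac, "*"))^2))
  obs <- !mask
  d <- sqrt(rowSums(sweep(complete_X[, obs, drop = FALSE], 2,
                          x_target[obs])^2))
  h <- config$bandwidth
  if (is.null(h)) h <- median(d)
  w <- if (is.finite(h) && h > 0) exp(-d^2 / (2 * h^2)) else rep(1, length(d))
  if (sum(w) <= 0 || !is.finite(sum(w))) {
    warning("estimate_error: zero total similarity weight; using unweighted mean")
    w <- rep(1, length(d))
  }
  sum(w * err) / sum(w)
}

#' Impute subjects with missing features into the latent space
#'
#' Runs [conditional_project()] and [estimate_error()] for every subject
#' with at least one missing cell, and applies the inclusion gate: a subject
#' is included iff its estimated error is strictly below
#' `config$threshold`. Subjects failing the projection preconditions (fewer
#' observed features than latent dimensions) are excluded with a reason.
#'
#' @param X standardized [feature_matrix()] for the whole cohort (complete
#'   and incomplete subjects).
#' @param model the `"ppca_model"` fitted on the complete cases.
#' @param config an [imputation_config()].
#' @return object of class `"imputation_report"`: data.frame with columns
#'   subject_id, n_missing_cells, estimated_error, included, reason, and an
#'   attribute `"scores"` holding the imputed latent scores of included
#'   subjects.
#' @export
impute_cohort <- function(X, model, config = imputation_config()) {
  stopifnot(inherits(X, "feature_matrix"), inherits(model, "ppca_model"))
  cc <- complete_rows(X)
  Xcc <- X$values[cc, , drop = FALSE]
  Zcc <- project(model, Xcc)
  todo <- which(!cc)
  res <- data.frame(subject_id = X$subject_ids[todo],
                    n_missing_cells = rowSums(X$mask)[todo],
                    estimated_error = NA_real_, included = FALSE,
                    reason = "", stringsAsFactors = FALSE)
  scores <- matrix(NA_real_, length(todo), model$D,
                   dimnames = list(X$subject_ids[todo],
                                   paste0("PC", seq_len(model$D))))
  for (k in seq_along(todo)) {
    i <- todo[k]
    mask_i <- X$mask[i, ]
    if (sum(!mask_i) < model$D) {
      res$reason[k] <- "fewer observed features than latent dimensions"
      next
    }
    scores[k, ] <- conditional_project(model, X$values[i, ], mask_i)
    res$estimated_error[k] <-
      estimate_error(model, Zcc, Xcc, X$values[i, ], mask_i, config)
    res$included[k] <- res$estimated_error[k] < config$threshold
    res$reason[k] <- if (res$included[k]) "included" else
      "estimated error at or above threshold"
  }
  attr(res, "scores") <- scores[res$included, , drop = FALSE]
  attr(res, "threshold") <- config$threshold
  class(res) <- c("imputation_report", "data.frame")
  res
}

#' @export
print.imputation_report <- function(x, ...) {
  cat(sprintf("Imputation report: %d subjects with missing cells; %d included, %d excluded (gate < %.3g)\n",
              nrow(x), sum(x$included), sum(!x$included),
              attr(x, "threshold")))
  print.data.frame(x, ...)
  invisible(x)
}
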