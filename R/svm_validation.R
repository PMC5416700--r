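## External validation of discovered subgroups from clinical scores:
## linear soft-margin SVM (C = 100), leave-one-out accuracy against the
## majority-class baseline, and a label-permutation significance test.

#' Train a linear soft-margin SVM
#'
#' Standard primal: minimize 0.5 ||w||^2 + C sum hinge. Features are
#' standardized to training mean/s.d. by default before fitting because a
#' fixed C = 100 on raw clinical scores is scale-sensitive; the scaling
#' parameters are stored and re-applied at prediction. The optimization is
#' delegated to the libsvm solver with a tight tolerance, so the fit is
#' deterministic.
#'
#' @param X numeric n x q feature matrix (no missing values).
#' @param y binary labels (factor or coercible); both classes must occur.
#' @param C soft-margin penalty (default 100).
#' @param scale standardize features on the training set (default TRUE).
#' @param tolerance solver termination tolerance (libsvm default 1e-3;
#'   tighten when the exact optimum matters more than speed).
#' @return object of class `"svm_model"`: `w` (length q), `b`, `C`,
#'   `levels` (class names; the first is predicted on a tied decision value
#'   of exactly zero), `center`, `scale_sd`.
#' @export
train_svm <- function(X, y, C = 100, scale = TRUE, tolerance = 1e-3) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) abort("train_svm: missing or non-finite features")
  y <- factor(y)
  if (nlevels(y) != 2L) abort("train_svm: need exactly two classes present")
  if (scale) {
    center <- colMeans(X)
    scale_sd <- apply(X, 2, sd)
    scale_sd[scale_sd == 0 | !is.finite(scale_sd)] <- 1
  } else {
    center <- rep(0, ncol(X))
    scale_sd <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale_sd, "/")
  fit <- e1071::svm(Xs, y, kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  ## libsvm orients the decision value toward its internal first label;
  ## align so that positive decision values mean levels(y)[1]
  if (fit$labels[1L] != 1L) { w <- -w; b <- -b }
  structure(list(w = w, b = b, C = C, levels = levels(y),
                 center = center, scale_sd = scale_sd),
            class = "svm_model")
}

#' Decision values of a linear SVM
#' @param model a `"svm_model"`.
#' @param X numeric matrix on the original feature scale.
#' @return numeric vector w . x_scaled + b; positive values predict the
#'   first class level.
#' @export
svm_decision <- function(model, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale_sd, "/")
  drop(Xs %*% model$w + model$b)
}

#' Predict class labels with a linear SVM
#' @inheritParams svm_decision
#' @return character vector of predicted labels; a decision value of exactly
#'   zero predicts the first class level.
#' @export
svm_predict <- function(model, X) {
  d <- svm_decision(model, X)
  ifelse(d >= 0, model$levels[1L], model$levels[2L])
}

#' SVM primal objective value
#'
#' 0.5 ||w||^2 + C sum max(0, 1 - y_i f(x_i)) on the model's scaled
#' features, with y in {+1, -1} for the first/second class level. Used to
#' compare the fit against an independent optimizer.
#'
#' @param model a `"svm_model"`.
#' @param X,y the training data.
#' @return scalar objective value.
#' @export
svm_objective <- function(model, X, y) {
  y <- factor(y, levels = model$levels)
  s <- ifelse(y == model$levels[1L], 1, -1)
  f <- svm_decision(model, X)
  0.5 * sum(model$w^2) + model$C * sum(pmax(0, 1 - s * f))
}

#' Leave-one-out cross-validated accuracy
#'
#' n fits on n - 1 subjects, each predicting the held-out subject; feature
#' scaling is re-estimated inside every training fold. If a fold loses one
#' class entirely, the remaining class is predicted with a warning.
#'
#' @inheritParams train_svm
#' @return list with `accuracy`, `confusion` (actual x predicted),
#'   `predicted` (character per subject).
#' @export
loo_accuracy <- function(X, y, C = 100, scale = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  if (n < 3L) abort("loo_accuracy: need at least 3 subjects")
  pred <- character(n)
  lev <- levels(y)
  yi_int <- as.integer(y)
  for (i in seq_len(n)) {
    yi <- y[-i]
    tab <- tabulate(yi_int[-i], nbins = length(lev))
    if (any(tab == 0L)) {
      warning("loo_accuracy: single-class training fold; predicting that class")
      pred[i] <- lev[which.max(tab)]
      next
    }
    Xi <- X[-i, , drop = FALSE]
    if (scale) {
      center <- colMeans(Xi)
      sds <- sqrt(colSums(Xi * Xi) / (n - 2) - colSums(Xi)^2 / ((n - 1) * (n - 2)))
      sds[sds == 0 | !is.finite(sds)] <- 1
    } else {
      center <- rep(0, ncol(X)); sds <- rep(1, ncol(X))
    }
    Xs <- sweep(sweep(Xi, 2, center), 2, sds, "/")
    fit <- e1071::svm(Xs, yi, kernel = "linear", cost = C, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    if (fit$labels[1L] != 1L) { w <- -w; b <- -b }
    d <- sum(((X[i, ] - center) / sds) * w) + b
    pred[i] <- if (d >= 0) lev[1L] else lev[2L]
  }
  conf <- table(actual = y, predicted = factor(pred, levels = levels(y)))
  list(accuracy = mean(pred == as.character(y)), confusion = conf,
       predicted = pred)
}

#' Majority-class baseline accuracy
#'
#' Accuracy of the simplest classification rule: always predict the most
#' frequent class.
#'
#' @param y label vector (any type).
#' @return fraction in (0, 1].
#' @export
majority_baseline <- function(y) {
  if (length(y) == 0L) abort("majority_baseline: empty label vector")
  max(table(y)) / length(y)
}

#' Permutation test of subgroup predictability
#'
#' Computes the observed LOO accuracy once, then recomputes the full LOO
#' accuracy under `B` random permutations of the labels; the p-value uses
#' the add-one formula p = (1 + #\{null >= observed\}) / (1 + B), which can
#' never be exactly zero.
#'
#' @inheritParams train_svm
#' @param B number of permutations (default 1000).
#' @param seed integer seed for the permutation engine.
#' @return object of class `"validation_result"`: `loo_accuracy`,
#'   `baseline_accuracy`, `p_value`, `null_accuracies` (length B),
#'   `confusion`, `n`, `B`, `seed`.
#' @export
permutation_test <- function(X, y, C = 100, B = 1000L, seed = 1L,
                             scale = TRUE) {
  if (B < 1L) abort("permutation_test: B must be >= 1")
  X <- as.matrix(X)
  y <- factor(y)
  obs <- loo_accuracy(X, y, C = C, scale = scale)
  set.seed(seed)
  null_acc <- vapply(seq_len(B), function(b) {
    yp <- y[sample.int(length(y))]
    loo_accuracy(X, yp, C = C, scale = scale)$accuracy
  }, numeric(1))
  p <- (1 + sum(null_acc >= obs$accuracy)) / (1 + B)
  structure(list(loo_accuracy = obs$accuracy,
                 baseline_accuracy = majority_baseline(y),
                 p_value = p, null_accuracies = null_acc,
                 confusion = obs$confusion, n = length(y),
                 B = as.integer(B), seed = as.integer(seed)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("LOO accuracy %.1f%% vs majority baseline %.1f%% (n = %d)\n",
              100 * x$loo_accuracy, 100 * x$baseline_accuracy, x$n))
  cat(sprintf("permutation p = %.4g (B = %d)\n", x$p_value, x$B))
  print(x$confusion)
  invisible(x)
}
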