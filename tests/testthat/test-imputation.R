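test_that("conditional projection equals full projection when all observed", {
  co <- small_cohort(seed = 1, missing_subject_rate = 0)
  fs <- fitted_space(co)
  X <- fs$std$X$values
  z_full <- drop(project(fs$model, X[3, , drop = FALSE]))
  z_cond <- conditional_project(fs$model, X[3, ], rep(FALSE, 45))
  expect_equal(unname(z_cond), unname(z_full), tolerance = 1e-10)
})

test_that("conditional projection recovers the score on noiseless data", {
  nf <- noiseless_factor_data(n = 50, p = 12, D = 3)
  m <- fit_ppca(nf$X, 3)
  z_full <- drop(project(m, nf$X[7, , drop = FALSE]))
  mask <- rep(FALSE, 12); mask[5] <- TRUE
  z_cond <- conditional_project(m, nf$X[7, ], mask)
  expect_equal(unname(z_cond), unname(z_full), tolerance = 1e-6)
  # too few observed features is an error
  expect_error(conditional_project(m, nf$X[7, ], rep(TRUE, 12)), "observed")
})

test_that("latent error grows with the number of masked features", {
  co <- small_cohort(seed = 6, missing_subject_rate = 0)
  fs <- fitted_space(co)
  X <- fs$std$X$values
  m <- fs$model
  err_for <- function(k) {
    mean(sapply(1:30, function(i) {
      set.seed(1000 + 37 * k + i)
      mask <- rep(FALSE, 45); mask[sample.int(45, k)] <- TRUE
      sqrt(sum((conditional_project(m, X[i, ], mask) -
                  drop(project(m, X[i, , drop = FALSE])))^2))
    }))
  }
  errs <- sapply(c(1, 5, 15, 30), err_for)
  expect_true(all(diff(errs) > 0))
})

test_that("error estimate is zero for complete subjects and donor-order invariant", {
  co <- small_cohort(seed = 2, missing_subject_rate = 0)
  fs <- fitted_space(co)
  X <- fs$std$X$values
  Z <- project(fs$model, X)
  cfgi <- imputation_config()
  expect_identical(estimate_error(fs$model, Z, X, X[1, ], rep(FALSE, 45), cfgi), 0)
  mask <- rep(FALSE, 45); mask[c(3, 17, 40)] <- TRUE
  e1 <- estimate_error(fs$model, Z, X, X[1, ], mask, cfgi)
  ord <- sample(nrow(X))
  e2 <- estimate_error(fs$model, Z[ord, ], X[ord, ], X[1, ], mask, cfgi)
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_gt(e1, 0)
})

test_that("infinite bandwidth reduces to the unweighted donor mean", {
  co <- small_cohort(seed = 3, missing_subject_rate = 0)
  fs <- fitted_space(co)
  X <- fs$std$X$values
  Z <- project(fs$model, X)
  mask <- rep(FALSE, 45); mask[c(2, 9)] <- TRUE
  est <- estimate_error(fs$model, Z, X, X[5, ], mask,
                        imputation_config(bandwidth = Inf))
  # brute-force oracle: loop over donors, unweighted mean of latent errors
  sds <- apply(Z, 2, sd)
  errs <- sapply(seq_len(nrow(X)), function(j) {
    zc <- conditional_project(fs$model, X[j, ], mask)
    sqrt(sum(((zc - Z[j, ]) * 0.1 / sds)^2))
  })
  expect_equal(est, mean(errs), tolerance = 1e-10)
})

test_that("a vanishing kernel bandwidth selects the coinciding donor", {
  set.seed(5)
  W <- matrix(rnorm(30), 10, 3)
  Xd <- matrix(rnorm(120), 40, 3) %*% t(W) +
    matrix(rnorm(400, sd = .3), 40, 10)
  m <- fit_ppca(Xd, 3)
  Zd <- project(m, Xd)
  mask <- rep(FALSE, 10); mask[4] <- TRUE
  # target identical to donor 1: with bandwidth -> 0 all kernel weight
  # concentrates there and the estimate equals that donor's own error
  est <- estimate_error(m, Zd, Xd, Xd[1, ], mask,
                        imputation_config(bandwidth = 1e-9))
  zc <- conditional_project(m, Xd[1, ], mask)
  sds <- apply(Zd, 2, sd)
  e1 <- sqrt(sum(((zc - Zd[1, ]) * 0.1 / sds)^2))
  expect_equal(est, e1, tolerance = 1e-10)
})

test_that("the inclusion gate is strict at the threshold", {
  co <- small_cohort(seed = 4)
  fs <- fitted_space(co)
  # lenient threshold: everyone with enough observed features included
  rep_inf <- impute_cohort(fs$std$X, fs$model,
                           imputation_config(threshold = Inf))
  expect_true(all(rep_inf$included | rep_inf$n_missing_cells > 41))
  # the gate is exactly estimated_error < threshold
  expect_identical(rep_inf$included,
                   rep_inf$estimated_error < Inf & !is.na(rep_inf$estimated_error))
  tiny <- impute_cohort(fs$std$X, fs$model,
                        imputation_config(threshold = 1e-12))
  expect_false(any(tiny$included))
  mid <- impute_cohort(fs$std$X, fs$model, imputation_config())
  expect_identical(mid$included,
                   !is.na(mid$estimated_error) &
                     mid$estimated_error < attr(mid, "threshold"))
  # imputed scores returned only for included subjects
  expect_identical(rownames(attr(mid, "scores")),
                   mid$subject_id[mid$included])
})

test_that("estimated error tracks the true latent error across subjects", {
  # calibration: over ~200 incomplete subjects the similarity-weighted
  # estimate must rank subjects like their realized latent error
  # patterns span 1..15 masked cells so imputation difficulty varies enough
  # for a rank correlation to be informative
  cfg <- cohort_config(n_patients = 150, n_controls = 150, seed = 8,
                       missing_subject_rate = 0.6, cells_per_subject = 1:15)
  co <- generate_cohort(cfg)
  std <- standardize(co$features)
  cc <- rowSums(std$X$mask) == 0
  m <- fit_ppca(std$X$values[cc, , drop = FALSE], 4)
  Zcc <- project(m, std$X$values[cc, , drop = FALSE])
  Xcc <- std$X$values[cc, , drop = FALSE]
  icfg <- imputation_config()
  sds <- apply(Zcc, 2, sd)
  # standardize the complete ground-truth values with the same params
  full <- standardize(feature_matrix(
    co$complete_values, feature_names = co$features$feature_names,
    modality = co$features$modality, subject_ids = co$features$subject_ids,
    group = co$features$group), params = std$params)$X$values
  idx <- which(!cc)
  res <- t(sapply(idx, function(i) {
    mask <- std$X$mask[i, ]
    est <- estimate_error(m, Zcc, Xcc, std$X$values[i, ], mask, icfg)
    z_imp <- conditional_project(m, std$X$values[i, ], mask)
    z_true <- drop(project(m, full[i, , drop = FALSE]))
    c(est = est, true = sqrt(sum(((z_imp - z_true) * 0.1 / sds)^2)))
  }))
  expect_gte(nrow(res), 150)
  expect_gt(cor(res[, "est"], res[, "true"], method = "spearman"), 0.5)
})
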