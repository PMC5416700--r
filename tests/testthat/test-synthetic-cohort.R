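test_that("default cohort has the study's dimensions and subgroup structure", {
  co <- small_cohort(seed = 1)
  expect_identical(dim(co$features$values), c(97L, 45L))
  expect_identical(sum(co$features$group == "patient"), 44L)
  expect_identical(sum(co$features$group == "control"), 53L)
  # subgroup labels only for patients, binary
  expect_length(co$true_subgroup, 44L)
  expect_true(all(co$true_subgroup %in% 1:2))
  # expected sizes 26/18: binomial(44, 26/44) within a generous 99.9% band
  expect_gt(sum(co$true_subgroup == 1L), 26 - 11)
  expect_lt(sum(co$true_subgroup == 1L), 26 + 11)
  expect_identical(co$features$modality,
                   c(rep("cognitive", 26), rep("electrophysiological", 19)))
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- small_cohort(seed = 7)
  b <- small_cohort(seed = 7)
  expect_identical(a$features$values, b$features$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$true_subgroup, b$true_subgroup)
  c2 <- small_cohort(seed = 8)
  expect_false(identical(a$features$values, c2$features$values))
})

test_that("zero mean shift collapses the patient mixture to one Gaussian", {
  co <- small_cohort(seed = 3, subgroup_mean_shift = rep(0, 4),
                     missing_subject_rate = 0)
  Zp <- co$true_latent[co$features$group == "patient", ]
  g1 <- co$true_subgroup == 1L
  # latent group means coincide up to sampling noise
  expect_lt(max(abs(colMeans(Zp[g1, ]) - colMeans(Zp[!g1, ]))), 1)
})

test_that("noiseless cohort has feature covariance of the latent rank", {
  co <- generate_cohort(cohort_config(seed = 5, noise_sd = 1e-8,
                                      missing_subject_rate = 0))
  ev <- eigen(cov(co$features$values), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(ev[4], 1e-3)
  expect_lt(ev[5], 1e-10)
})

test_that("feature covariance converges to W W' + sigma^2 I", {
  cfg <- cohort_config(n_patients = 2500, n_controls = 2500, seed = 2,
                       missing_subject_rate = 0)
  co <- generate_cohort(cfg)
  # compare against the generator's own parameters, holding out the latent
  # mean structure (centering within patient/control x subgroup cells)
  W <- co$loadings
  grp <- co$features$group
  lab <- rep(3L, nrow(co$features$values))
  lab[grp == "patient"] <- co$true_subgroup
  Xc <- co$features$values
  for (g in unique(lab)) {
    i <- lab == g
    Xc[i, ] <- sweep(Xc[i, , drop = FALSE], 2, colMeans(Xc[i, , drop = FALSE]))
  }
  S <- crossprod(Xc) / nrow(Xc)
  target <- tcrossprod(W) + diag(cfg$noise_sd^2, nrow(W))
  rel_frob <- norm(S - target, "F") / norm(target, "F")
  expect_lt(rel_frob, 0.1)
})

test_that("missingness injection is MCAR at the requested subject rate", {
  co <- small_cohort(seed = 4)
  # rate 0: nothing masked, values untouched
  c0 <- inject_missingness(co, 0, seed = 1)
  expect_false(any(c0$features$mask))
  expect_identical(c0$features$values, co$complete_values)
  # rate 1 with exactly one cell: every subject masked once
  c1 <- inject_missingness(co, 1, cells_per_subject = 1L, seed = 2)
  expect_true(all(rowSums(c1$features$mask) == 1L))
  expect_true(all(is.na(c1$features$values[c1$features$mask])))
  # ground truth retained for masked cells
  expect_false(anyNA(c1$complete_values))
  # study-like rate 39/131 on a 131-subject cohort: about 39 subjects hit
  big <- generate_cohort(cohort_config(n_patients = 66, n_controls = 65,
                                       seed = 6, missing_subject_rate = 0))
  hits <- replicate(20, {
    ci <- inject_missingness(big, 39 / 131, seed = sample.int(1e6, 1))
    sum(rowSums(ci$features$mask) > 0)
  })
  expect_gt(mean(hits), 39 - 2 * sqrt(39 * (1 - 39 / 131)) / sqrt(20) - 3)
  expect_lt(mean(hits), 39 + 2 * sqrt(39 * (1 - 39 / 131)) / sqrt(20) + 3)
  expect_error(inject_missingness(co, 1.2), "rate")
})

test_that("PANSS generation matches the configured effect structure", {
  eff <- panss_effects_default(missing_baseline_rate = 0,
                               missing_followup_rate = 0,
                               missing_dose_rate = 0)
  lab <- setNames(rep(1:2, c(190, 160)), sprintf("P%03d", 1:350))
  cl <- generate_panss(lab, eff, seed = 11)
  # change = baseline - follow-up by construction
  expect_identical(cl$panss_negative_change,
                   cl$panss_negative_b - cl$panss_negative_fu)
  # subgroup-specific change means within 2 s.e. of the configured targets
  for (s in c("positive", "negative", "general")) {
    ch <- cl[[paste0("panss_", s, "_change")]]
    for (g in 1:2) {
      m <- mean(ch[lab == g])
      se <- eff$change_sd[g, s] / sqrt(sum(lab == g))
      expect_lt(abs(m - eff$change_mean[g, s]), 3 * se + 0.5)  # + rounding
    }
  }
  # legal PANSS ranges respected
  expect_true(all(cl$panss_positive_b >= 7 & cl$panss_positive_b <= 49))
  expect_true(all(cl$panss_negative_fu >= 7 & cl$panss_negative_fu <= 49))
  expect_true(all(cl$panss_general_b >= 16 & cl$panss_general_b <= 112))
  expect_error(generate_panss(setNames(3L, "x"), eff), "labels")
})

test_that("zero subgroup difference in PANSS yields chance-level prediction", {
  eff <- panss_effects_default(
    change_mean = rbind(`1` = c(6, 1.5, 9), `2` = c(6, 1.5, 9)),
    missing_baseline_rate = 0, missing_followup_rate = 0,
    missing_dose_rate = 0)
  accs <- sapply(1:5, function(s) {
    lab <- setNames(rep(1:2, c(19, 16)), sprintf("P%02d", 1:35))
    cl <- generate_panss(lab, eff, seed = 100 + s)
    X <- as.matrix(cl[, paste0("panss_", c("positive", "negative", "general"),
                               "_change")])
    loo_accuracy(X, lab)$accuracy
  })
  base <- 19 / 35
  expect_lt(abs(mean(accs) - base), 0.2)
})

test_that("huge separable PANSS difference gives perfect LOO accuracy", {
  eff <- panss_effects_default(
    change_mean = rbind(`1` = c(6, -15, 25), `2` = c(6, 20, -5)),
    change_sd = rbind(`1` = c(0.5, 0.5, 0.5), `2` = c(0.5, 0.5, 0.5)),
    missing_baseline_rate = 0, missing_followup_rate = 0,
    missing_dose_rate = 0)
  lab <- setNames(rep(1:2, c(19, 16)), sprintf("P%02d", 1:35))
  cl <- generate_panss(lab, eff, seed = 21)
  X <- as.matrix(cl[, paste0("panss_", c("positive", "negative", "general"),
                             "_change")])
  expect_equal(loo_accuracy(X, lab)$accuracy, 1.0)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(subgroup_proportion = 1.2), "proportion")
  expect_error(cohort_config(latent_dim = 50), "latent_dim")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(subgroup_mean_shift = c(1, 2)), "length")
})
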