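#' Configuration for a synthetic multimodal cohort
#'
#' Defines the statistical structure of a simulated cohort: a latent Gaussian
#' factor model with modality-blocked loadings, a two-component mixture among
#' patients in latent space, a latent mean offset for healthy controls, MCAR
#' missingness, and clinical symptom scores (PANSS positive/negative/general
#' at baseline and 6-week follow-up) whose change differs between the latent
#' patient subgroups.
#'
#' The defaults emulate a first-episode schizophrenia cohort of 44 patients
#' and 53 controls measured on 26 cognitive and 19 electrophysiological
#' continuous features, with 4 latent factors, roughly 26:18 patient subgroup
#' proportions, about 30% of subjects carrying 1-3 missing cells, and PANSS
#' effects at the scale reported for 6 weeks of amisulpride monotherapy
#' (subgroups differ mainly in negative/general symptom change).
#'
#' @param n_patients,n_controls subject counts per group.
#' @param n_cognitive,n_electro features per modality; total p = sum.
#' @param latent_dim number of latent factors (must be <= total features).
#' @param subgroup_proportion probability that a patient belongs to
#'   subgroup 1; in (0, 1).
#' @param subgroup_mean_shift numeric vector of length `latent_dim`: latent
#'   mean difference (subgroup 1 minus subgroup 2). Default signs are
#'   (-,-,-,+) with magnitude 1.5 per axis, i.e. subgroup 1 sits lower on
#'   factors 1-3 and higher on factor 4.
#' @param control_mean_offset latent mean of controls relative to the patient
#'   centre; default shifts controls up on factor 1 (general cognition).
#' @param noise_sd isotropic feature noise s.d. (> 0).
#' @param loading_jitter_sd s.d. of random jitter added to the deterministic
#'   loading template.
#' @param equalize_feature_variance rescale the loading rows so every
#'   feature has the same marginal variance (default `FALSE`). With unequal
#'   marginal variances, per-feature standardization makes the residual
#'   noise anisotropic, which biases AIC dimension selection upward at
#'   strong subgroup separations; equalized variances give the clean
#'   isotropic-noise regime in which the latent dimension is exactly
#'   recoverable.
#' @param missing_subject_rate probability a subject has >= 1 missing cell.
#' @param cells_per_subject integer vector of possible missing-cell counts
#'   for an affected subject (sampled uniformly).
#' @param panss_effects list as returned by [panss_effects_default()].
#' @param seed integer random seed.
#' @return An object of class `"cohort_config"` (a validated list).
#' @seealso [generate_cohort()], [panss_effects_default()]
#' @export
cohort_config <- function(n_patients = 44L, n_controls = 53L,
                          n_cognitive = 26L, n_electro = 19L,
                          latent_dim = 4L,
                          subgroup_proportion = 26 / 44,
                          subgroup_mean_shift = NULL,
                          control_mean_offset = NULL,
                          noise_sd = 0.5,
                          loading_jitter_sd = 0.05,
                          equalize_feature_variance = FALSE,
                          missing_subject_rate = 0.3,
                          cells_per_subject = 1:3,
                          panss_effects = panss_effects_default(),
                          seed = 1L) {
  if (n_patients < 1 || n_controls < 0 || n_cognitive < 1 || n_electro < 0)
    abort("cohort_config: subject and feature counts must be positive")
  p <- n_cognitive + n_electro
  if (latent_dim < 1 || latent_dim > p)
    abort("cohort_config: latent_dim must lie in [1, n_cognitive + n_electro]")
  if (subgroup_proportion <= 0 || subgroup_proportion >= 1)
    abort("cohort_config: subgroup_proportion must be in (0, 1)")
  if (noise_sd <= 0) abort("cohort_config: noise_sd must be > 0")
  if (missing_subject_rate < 0 || missing_subject_rate > 1)
    abort("cohort_config: missing_subject_rate must be in [0, 1]")
  if (is.null(subgroup_mean_shift)) {
    signs <- rep_len(c(-1, -1, -1, 1), latent_dim)
    subgroup_mean_shift <- 1.5 * signs
  }
  if (length(subgroup_mean_shift) != latent_dim)
    abort("cohort_config: subgroup_mean_shift must have length latent_dim")
  if (is.null(control_mean_offset)) {
    control_mean_offset <- c(0.75, rep(0, latent_dim - 1L))
  }
  if (length(control_mean_offset) != latent_dim)
    abort("cohort_config: control_mean_offset must have length latent_dim")
  check_effects(panss_effects)
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_cognitive = as.integer(n_cognitive), n_electro = as.integer(n_electro),
    latent_dim = as.integer(latent_dim),
    subgroup_proportion = subgroup_proportion,
    subgroup_mean_shift = as.numeric(subgroup_mean_shift),
    control_mean_offset = as.numeric(control_mean_offset),
    noise_sd = noise_sd, loading_jitter_sd = loading_jitter_sd,
    equalize_feature_variance = isTRUE(equalize_feature_variance),
    missing_subject_rate = missing_subject_rate,
    cells_per_subject = as.integer(cells_per_subject),
    panss_effects = panss_effects,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default PANSS effect structure
#'
#' Baseline subscore distributions are subgroup-independent; change scores
#' (baseline minus 6-week follow-up) are subgroup-specific, with the subgroup
#' difference concentrated on the negative and general subscales. Values are
#' on the PANSS scale (positive/negative range 7-49, general 16-112).
#' Follow-up is baseline minus change, truncated to the legal range. The
#' amisulpride dose (mg/day at follow-up) is subgroup-independent.
#'
#' @param baseline_mean,baseline_sd named length-3 vectors
#'   (positive, negative, general).
#' @param change_mean,change_sd 2x3 matrices, rows = subgroups 1 and 2,
#'   columns = subscales.
#' @param dose_mean,dose_sd amisulpride dose distribution.
#' @param missing_baseline_rate,missing_followup_rate,missing_dose_rate
#'   per-patient probabilities that the corresponding clinical block is
#'   absent (independent MCAR).
#' @return list of class `"panss_effects"`.
#' @export
panss_effects_default <- function(
    baseline_mean = c(positive = 20.1, negative = 20.9, general = 40.6),
    baseline_sd = c(positive = 4.3, negative = 7.1, general = 8.8),
    change_mean = rbind(`1` = c(6.42, -0.37, 10.47),
                        `2` = c(5.13, 3.31, 7.13)),
    change_sd = rbind(`1` = c(4.90, 5.20, 6.82),
                      `2` = c(3.95, 5.79, 7.88)),
    dose_mean = 280, dose_sd = 160,
    missing_baseline_rate = 1 / 44,
    missing_followup_rate = 8 / 44,
    missing_dose_rate = 11 / 44) {
  colnames(change_mean) <- colnames(change_sd) <-
    c("positive", "negative", "general")
  out <- list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              change_mean = change_mean, change_sd = change_sd,
              dose_mean = dose_mean, dose_sd = dose_sd,
              missing_baseline_rate = missing_baseline_rate,
              missing_followup_rate = missing_followup_rate,
              missing_dose_rate = missing_dose_rate)
  class(out) <- "panss_effects"
  out
}

check_effects <- function(eff) {
  if (!inherits(eff, "panss_effects"))
    abort("panss_effects must be built with panss_effects_default()")
  if (any(eff$baseline_sd <= 0) || any(eff$change_sd <= 0) || eff$dose_sd <= 0)
    abort("panss_effects: all s.d. must be > 0")
  invisible(eff)
}

## Deterministic loading template: factor 1 loads all cognitive features
## (general cognitive capacity), factor 2 primarily electrophysiological
## ones, higher factors are mixed-modality signed contrasts. The contrasts
## use Walsh-style alternating sign patterns of increasing period, so they
## are near-orthogonal to the constant modality patterns and to each other;
## without that, the mixed factors would be almost collinear with factors
## 1-2 in feature space and unrecoverable.
loading_template <- function(n_cog, n_el, d) {
  p <- n_cog + n_el
  W <- matrix(0, p, d)
  cog <- seq_len(n_cog)
  el <- n_cog + seq_len(n_el)
  W[cog, 1] <- 0.8
  if (d >= 2 && n_el > 0) {
    W[el, 2] <- 0.75
    W[cog, 2] <- 0.10
  }
  if (d >= 3) {
    walsh <- function(idx, period) (-1)^(floor((idx - 1) / period))
    for (j in seq_len(d - 2L)) {
      period <- 2^(j - 1L)
      W[cog, 2L + j] <- 0.55 * walsh(cog, period)
      if (n_el > 0) W[el, 2L + j] <- 0.55 * walsh(seq_len(n_el), period)
    }
  }
  W
}

#' Generate a synthetic multimodal cohort
#'
#' Draws latent factor scores (patients from a two-component Gaussian
#' mixture separated by `subgroup_mean_shift`; controls from a single
#' Gaussian offset by `control_mean_offset`), maps them through a
#' modality-blocked loading matrix with small random jitter, adds isotropic
#' Gaussian noise, injects MCAR missingness, and simulates the clinical
#' table. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return An object of class `"synthetic_cohort"`: a list with
#'   \describe{
#'     \item{features}{a [feature_matrix()] (missing cells are `NA`)}
#'     \item{complete_values}{the noise-free-of-missingness value matrix,
#'       for imputation-error ground truth (tests only)}
#'     \item{metadata}{data.frame: subject_id, group, gender, age,
#'       substance-use flags}
#'     \item{clinical}{data.frame of PANSS records and dose (patients only)}
#'     \item{true_subgroup}{integer 1/2 per patient}
#'     \item{true_latent}{subjects x latent_dim matrix of true scores}
#'     \item{loadings, noise_sd}{the generating parameters}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$seed, 1L))
  n_pat <- config$n_patients; n_con <- config$n_controls
  n <- n_pat + n_con
  d <- config$latent_dim
  p <- config$n_cognitive + config$n_electro

  W <- loading_template(config$n_cognitive, config$n_electro, d)
  W <- W + matrix(rnorm(p * d, sd = config$loading_jitter_sd), p, d)
  if (config$equalize_feature_variance) {
    ## per-axis latent variance of the combined cohort (mixture + offset)
    f_p <- n_pat / n; f_c <- n_con / n
    pi1 <- config$subgroup_proportion; pi2 <- 1 - pi1
    mu1 <- 0.5 * config$subgroup_mean_shift
    mu2 <- -0.5 * config$subgroup_mean_shift
    oc <- config$control_mean_offset
    mbar <- f_p * (pi1 * mu1 + pi2 * mu2) + f_c * oc
    cvar <- f_p * (1 + pi1 * mu1^2 + pi2 * mu2^2) + f_c * (1 + oc^2) - mbar^2
    sig_var <- drop(W^2 %*% cvar)
    W <- W * sqrt(mean(sig_var) / sig_var)
  }

  ## patients: two-component latent mixture centred at +/- shift/2
  sub <- 1L + rbinom(n_pat, 1L, 1 - config$subgroup_proportion)
  shift <- config$subgroup_mean_shift
  mu_pat <- outer(ifelse(sub == 1L, 0.5, -0.5), shift)
  Z_pat <- mu_pat + matrix(rnorm(n_pat * d), n_pat, d)
  Z_con <- matrix(rnorm(n_con * d), n_con, d) +
    matrix(config$control_mean_offset, n_con, d, byrow = TRUE)
  Z <- rbind(Z_pat, Z_con)

  X <- Z %*% t(W) + matrix(rnorm(n * p, sd = config$noise_sd), n, p)
  ids <- sprintf("S%03d", seq_len(n))
  feat_names <- c(sprintf("cog_%02d", seq_len(config$n_cognitive)),
                  sprintf("ephys_%02d", seq_len(config$n_electro)))
  dimnames(X) <- list(ids, feat_names)
  group <- c(rep("patient", n_pat), rep("control", n_con))
  fm <- feature_matrix(X, feature_names = feat_names,
                       modality = c(rep("cognitive", config$n_cognitive),
                                    rep("electrophysiological", config$n_electro)),
                       subject_ids = ids, group = group)

  metadata <- data.frame(
    subject_id = ids, group = group,
    gender = sample(c("m", "f"), n, replace = TRUE, prob = c(0.57, 0.43)),
    age = round(rnorm(n, 25, 6), 1),
    alcohol = runif(n) < 0.77, tobacco = runif(n) < 0.59,
    cannabis = runif(n) < 0.27, benzodiazepines = runif(n) < 0.02,
    stringsAsFactors = FALSE
  )

  clinical <- generate_panss(setNames(sub, ids[seq_len(n_pat)]),
                             config$panss_effects,
                             seed = derive_seed(config$seed, 2L))

  cohort <- structure(list(
    features = fm, complete_values = X,
    metadata = metadata, clinical = clinical,
    true_subgroup = setNames(sub, ids[seq_len(n_pat)]),
    true_latent = structure(Z, dimnames = list(ids, paste0("F", seq_len(d)))),
    loadings = W, noise_sd = config$noise_sd,
    config = config
  ), class = "synthetic_cohort")

  inject_missingness(cohort, config$missing_subject_rate,
                     config$cells_per_subject,
                     seed = derive_seed(config$seed, 3L))
}

#' Inject MCAR missingness into a synthetic cohort
#'
#' Selects subjects independently with probability `missing_subject_rate`;
#' each selected subject gets a uniformly drawn number of cells (from
#' `cells_per_subject`) masked at uniformly drawn feature positions. The
#' pre-masking values are retained in `complete_values` so imputation error
#' can be measured against ground truth.
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param missing_subject_rate probability in \[0, 1\].
#' @param cells_per_subject integer vector of candidate missing-cell counts.
#' @param seed integer seed.
#' @return the cohort with `features$values` masked (`NA`) and
#'   `features$mask` set.
#' @export
inject_missingness <- function(cohort, missing_subject_rate,
                               cells_per_subject = 1:3, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (missing_subject_rate < 0 || missing_subject_rate > 1)
    abort("inject_missingness: rate must be in [0, 1]")
  set.seed(seed)
  fm <- cohort$features
  fm$values <- cohort$complete_values
  dimnames(fm$values) <- list(fm$subject_ids, fm$feature_names)
  n <- nrow(fm$values); p <- ncol(fm$values)
  mask <- matrix(FALSE, n, p, dimnames = dimnames(fm$values))
  hit <- runif(n) < missing_subject_rate
  for (i in which(hit)) {
    k <- if (length(cells_per_subject) == 1L) cells_per_subject else
      sample(cells_per_subject, 1L)
    mask[i, sample.int(p, min(k, p))] <- TRUE
  }
  fm$values[mask] <- NA_real_
  fm$mask <- mask
  cohort$features <- fm
  cohort
}

#' Simulate PANSS clinical records for labelled patients
#'
#' Baseline subscores are drawn with subgroup-independent means; change
#' scores (baseline minus follow-up) with subgroup-dependent means;
#' follow-up is baseline minus change. Scores are truncated to legal PANSS
#' ranges (positive/negative 7-49, general 16-112) after sampling. Blocks
#' (baseline, follow-up, dose) can be missing per patient, MCAR at the rates
#' in `effects`.
#'
#' @param true_subgroup named integer vector of labels (1 or 2), names =
#'   subject ids.
#' @param effects list from [panss_effects_default()].
#' @param seed integer seed.
#' @return data.frame of class `"clinical_table"` with columns subject_id,
#'   `panss_<subscale>_b`, `panss_<subscale>_fu`, `panss_<subscale>_change`,
#'   and `dose`.
#' @export
generate_panss <- function(true_subgroup, effects = panss_effects_default(),
                           seed = 1L) {
  check_effects(effects)
  lab <- as.integer(true_subgroup)
  if (!all(lab %in% c(1L, 2L)))
    abort("generate_panss: subgroup labels must be 1 or 2")
  set.seed(seed)
  n <- length(lab)
  ids <- names(true_subgroup)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  lo <- c(positive = 7, negative = 7, general = 16)
  hi <- c(positive = 49, negative = 49, general = 112)
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  b <- fu <- matrix(NA_real_, n, 3,
                    dimnames = list(NULL, c("positive", "negative", "general")))
  for (s in c("positive", "negative", "general")) {
    bs <- rnorm(n, effects$baseline_mean[[s]], effects$baseline_sd[[s]])
    ch <- rnorm(n, effects$change_mean[lab, s], effects$change_sd[lab, s])
    b[, s] <- pmin(pmax(bs, lo[[s]]), hi[[s]])
    fu[, s] <- pmin(pmax(b[, s] - ch, lo[[s]]), hi[[s]])
  }
  miss_b <- runif(n) < effects$missing_baseline_rate
  miss_fu <- runif(n) < effects$missing_followup_rate
  miss_dose <- runif(n) < effects$missing_dose_rate
  b[miss_b, ] <- NA_real_
  fu[miss_fu, ] <- NA_real_
  for (s in c("positive", "negative", "general")) {
    out[[paste0("panss_", s, "_b")]] <- round(b[, s])
    out[[paste0("panss_", s, "_fu")]] <- round(fu[, s])
    out[[paste0("panss_", s, "_change")]] <- round(b[, s]) - round(fu[, s])
  }
  dose <- pmin(pmax(rnorm(n, effects$dose_mean, effects$dose_sd), 50), 1200)
  dose[miss_dose] <- NA_real_
  out$dose <- round(dose)
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  fm <- x$features
  cat(sprintf("Synthetic cohort: %d subjects (%d patients, %d controls), %d features\n",
              nrow(fm$values), sum(fm$group == "patient"),
              sum(fm$group == "control"), ncol(fm$values)))
  cat(sprintf("  latent dim %d; %d subjects with >=1 missing cell\n",
              ncol(x$true_latent), sum(rowSums(fm$mask) > 0)))
  cat(sprintf("  true subgroup sizes: %s\n",
              paste(table(x$true_subgroup), collapse = " / ")))
  invisible(x)
}
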