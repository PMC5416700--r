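## End-to-end orchestration and plain-text I/O. All stage artifacts are
## CSV/JSON so every module can be re-run in isolation from the manifest.

#' Write a cohort to CSV files
#'
#' Writes `features.csv` (subjects x named features, empty cell = missing),
#' `metadata.csv`, `clinical.csv` and, for synthetic cohorts, `truth.csv`
#' (true subgroup labels), all keyed by a `subject_id` column.
#'
#' @param cohort a `"synthetic_cohort"` or a list with elements `features`
#'   ([feature_matrix()]), `metadata`, `clinical`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fm <- cohort$features
  feat <- data.frame(subject_id = fm$subject_ids, group = fm$group,
                     fm$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  paths <- c(features = file.path(dir, "features.csv"),
             metadata = file.path(dir, "metadata.csv"),
             clinical = file.path(dir, "clinical.csv"))
  write.csv(feat, paths[["features"]], row.names = FALSE, na = "")
  write.csv(cohort$metadata, paths[["metadata"]], row.names = FALSE, na = "")
  write.csv(cohort$clinical, paths[["clinical"]], row.names = FALSE, na = "")
  if (!is.null(cohort$true_subgroup)) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    write.csv(data.frame(subject_id = names(cohort$true_subgroup),
                         true_subgroup = as.integer(cohort$true_subgroup)),
              paths[["truth"]], row.names = FALSE)
  }
  ## modality map so a round-trip preserves feature typing
  paths <- c(paths, modality = file.path(dir, "modality.csv"))
  write.csv(data.frame(feature = fm$feature_names, modality = fm$modality),
            paths[["modality"]], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from CSV files
#'
#' Reads the files written by [write_cohort()] (or equivalently shaped
#' files). Both empty cells and the string `"NA"` parse as missing and
#' produce the same mask. Duplicate subject ids, unknown group labels,
#' non-numeric feature cells, and subject-id mismatches across files are
#' reported as parse errors naming the offender.
#'
#' @param dir directory containing `features.csv` (required),
#'   `metadata.csv`, `clinical.csv`, `modality.csv` (optional).
#' @return list with `features` ([feature_matrix()]), `metadata`,
#'   `clinical` (either may be `NULL` when absent).
#' @export
read_cohort <- function(dir) {
  fpath <- file.path(dir, "features.csv")
  if (!file.exists(fpath)) abort("read_cohort: missing ", fpath)
  feat <- read.csv(fpath, check.names = FALSE, na.strings = c("", "NA"),
                   stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(feat))
    abort("read_cohort: features.csv has no subject_id column")
  if (anyDuplicated(feat$subject_id))
    abort("read_cohort: duplicated subject_id: ",
          paste(unique(feat$subject_id[duplicated(feat$subject_id)]),
                collapse = ", "))
  group <- if ("group" %in% names(feat)) feat$group else
    rep("patient", nrow(feat))
  if (!all(group %in% c("patient", "control")))
    abort("read_cohort: unknown group label: ",
          paste(setdiff(unique(group), c("patient", "control")),
                collapse = ", "))
  vals <- feat[, setdiff(names(feat), c("subject_id", "group")),
               drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]]))
      abort("read_cohort: non-numeric cells in feature column '",
            names(vals)[j], "'")
  }
  modality <- NULL
  mpath <- file.path(dir, "modality.csv")
  if (file.exists(mpath)) {
    mm <- read.csv(mpath, stringsAsFactors = FALSE)
    modality <- mm$modality[match(names(vals), mm$feature)]
  }
  fm <- feature_matrix(as.matrix(vals), feature_names = names(vals),
                       modality = modality,
                       subject_ids = feat$subject_id, group = group)
  read_opt <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) return(NULL)
    df <- read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
    extra <- setdiff(df$subject_id, fm$subject_ids)
    if (length(extra))
      abort("read_cohort: ", name, " has subject ids absent from features.csv: ",
            paste(extra, collapse = ", "))
    df
  }
  metadata <- read_opt("metadata.csv")
  clinical <- read_opt("clinical.csv")
  if (!is.null(clinical)) class(clinical) <- c("clinical_table", "data.frame")
  list(features = fm, metadata = metadata, clinical = clinical)
}

#' Pipeline configuration
#'
#' @param cohort either a [cohort_config()] (the cohort is simulated) or a
#'   directory path readable by [read_cohort()].
#' @param D_grid candidate latent dimensions (default 2:45, capped by the
#'   data at run time).
#' @param K_grid candidate subgroup counts (default 1:10).
#' @param imputation an [imputation_config()].
#' @param C SVM penalty (default 100).
#' @param B permutations for the validation test (default 1000).
#' @param gmm_restarts,cv_restarts,gmm_reg EM settings for the final fit
#'   and the CV folds.
#' @param seed master seed; every stage derives its own seed from it.
#' @param out_dir optional directory: when given, all stage artifacts and a
#'   manifest are written there.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            D_grid = 2:45, K_grid = 1:10,
                            imputation = imputation_config(),
                            C = 100, B = 1000L,
                            gmm_restarts = 20L, cv_restarts = 20L,
                            gmm_reg = 1e-4,
                            seed = 1L, out_dir = NULL) {
  if (length(D_grid) == 0L || length(K_grid) == 0L)
    abort("pipeline_config: grids must be non-empty")
  structure(list(cohort = cohort, D_grid = D_grid, K_grid = K_grid,
                 imputation = imputation, C = C, B = as.integer(B),
                 gmm_restarts = gmm_restarts, cv_restarts = cv_restarts,
                 gmm_reg = gmm_reg, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full stratification pipeline
#'
#' Executes the stages in order: standardize on complete cases; fit PPCA
#' over the dimension grid and select D by AIC; project complete subjects;
#' impute incomplete subjects with the error gate; LOO-CV selection of the
#' number of patient subgroups and final GMM fit (patients only); external
#' validation by SVM + permutation test on each available clinical block
#' (baseline, follow-up, change); univariate subgroup characterization.
#'
#' @param config a [pipeline_config()].
#' @return object of class `"run_report"`: list with `aic_curve`,
#'   `ppca_model`, `scores` (all analyzed subjects), `imputation`,
#'   `cv_curve`, `gmm_model`, `assignment`, `validation` (named list per
#'   clinical block), `table1`, `log` (per-stage n), and `manifest` when
#'   `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  ## stage 0: obtain cohort
  if (inherits(config$cohort, "cohort_config")) {
    cohort <- generate_cohort(config$cohort)
  } else {
    cohort <- read_cohort(config$cohort)
  }
  fm <- cohort$features
  log$n_subjects <- nrow(fm$values)
  log$n_features <- ncol(fm$values)

  ## stage 1: standardize on complete cases, apply to all
  std <- standardize(fm)
  Xs <- std$X
  cc <- complete_rows(Xs)
  log$n_complete <- sum(cc)

  ## stage 2: PPCA + AIC dimension selection on complete cases
  Xcc <- Xs$values[cc, , drop = FALSE]
  D_grid <- config$D_grid
  D_grid <- D_grid[D_grid >= 1 & D_grid < min(ncol(Xcc), nrow(Xcc))]
  curve <- select_dimension(Xcc, D_grid)
  model <- curve$models[[match(curve$selected_D, curve$D_grid)]]
  log$selected_D <- curve$selected_D

  ## stage 3: project complete cases, impute the rest with the error gate
  Zcc <- project(model, Xcc)
  imp <- impute_cohort(Xs, model, config$imputation)
  Zimp <- attr(imp, "scores")
  scores <- rbind(Zcc, Zimp)
  scores <- scores[order(match(rownames(scores), fm$subject_ids)), ,
                   drop = FALSE]
  log$n_imputed_included <- if (nrow(imp)) sum(imp$included) else 0L
  log$n_imputed_excluded <- if (nrow(imp)) sum(!imp$included) else 0L
  log$n_analyzed <- nrow(scores)

  ## stage 4: GMM subgrouping on patients only
  pat_ids <- fm$subject_ids[fm$group == "patient"]
  Zpat <- scores[rownames(scores) %in% pat_ids, , drop = FALSE]
  log$n_patients_analyzed <- nrow(Zpat)
  cv <- loo_select_k(Zpat, config$K_grid, n_restarts = config$cv_restarts,
                     reg = config$gmm_reg,
                     seed = derive_seed(config$seed, 4L))
  gmm <- fit_gmm(Zpat, cv$selected_K, n_restarts = config$gmm_restarts,
                 reg = config$gmm_reg, seed = derive_seed(config$seed, 5L))
  assignment <- assign_subgroups(gmm, Zpat)
  log$selected_K <- cv$selected_K
  log$subgroup_sizes <- assignment$sizes

  ## stage 5: external validation on the clinical blocks
  validation <- list()
  if (!is.null(cohort$clinical) && cv$selected_K >= 2L) {
    labels <- assignment$labels
    cl <- cohort$clinical[match(names(labels), cohort$clinical$subject_id), ,
                          drop = FALSE]
    blocks <- list(
      baseline = paste0("panss_", c("positive", "negative", "general"), "_b"),
      followup = paste0("panss_", c("positive", "negative", "general"), "_fu"),
      change = paste0("panss_", c("positive", "negative", "general"), "_change"))
    for (bn in names(blocks)) {
      Xb <- as.matrix(cl[, blocks[[bn]], drop = FALSE])
      ok <- rowSums(is.na(Xb)) == 0
      yb <- factor(ifelse(labels[ok] == 1L, "subgroup1", "subgroup2"))
      if (sum(ok) >= 3 && nlevels(droplevels(yb)) == 2L) {
        validation[[bn]] <- permutation_test(
          Xb[ok, , drop = FALSE], yb, C = config$C, B = config$B,
          seed = derive_seed(config$seed, 6L + match(bn, names(blocks))))
      }
      log[[paste0("n_", bn)]] <- sum(ok)
    }
  }

  ## stage 6: univariate characterization
  table1 <- NULL
  if (!is.null(cohort$metadata) && !is.null(cohort$clinical) &&
      cv$selected_K >= 1L) {
    table1 <- characterize_subgroups(assignment$labels, cohort$metadata,
                                     cohort$clinical)
  }

  report <- structure(list(aic_curve = curve, ppca_model = model,
                           standardization = std$params,
                           scores = scores, imputation = imp,
                           cv_curve = cv, gmm_model = gmm,
                           assignment = assignment,
                           validation = validation, table1 = table1,
                           log = log, config = config),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

## internal: persist all stage artifacts as CSV/JSON plus a manifest
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  curve <- report$aic_curve
  write.csv(data.frame(D = curve$D_grid, AIC = curve$aic),
            file.path(dir, "aic_curve.csv"), row.names = FALSE)
  m <- report$ppca_model
  jsonlite::write_json(list(D = m$D, W = m$W, sigma2 = m$sigma2, mu = m$mu,
                            n_fit = m$n_fit, loglik = m$loglik),
                       file.path(dir, "ppca_model.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(subject_id = rownames(report$scores), report$scores),
            file.path(dir, "scores.csv"), row.names = FALSE)
  write.csv(as.data.frame(report$imputation),
            file.path(dir, "imputation_report.csv"), row.names = FALSE)
  cv <- report$cv_curve
  write.csv(data.frame(K = cv$K_grid, mean_nll = cv$mean_nll,
                       se = cv$se_nll, valid = cv$valid),
            file.path(dir, "cv_curve.csv"), row.names = FALSE)
  asg <- report$assignment
  write.csv(data.frame(subject_id = names(asg$labels), label = asg$labels,
                       asg$responsibilities, check.names = FALSE),
            file.path(dir, "subgroups.csv"), row.names = FALSE)
  for (bn in names(report$validation)) {
    v <- report$validation[[bn]]
    jsonlite::write_json(
      list(block = bn, loo_accuracy = v$loo_accuracy,
           baseline_accuracy = v$baseline_accuracy, p_value = v$p_value,
           confusion = as.data.frame(v$confusion), n = v$n, B = v$B,
           seed = v$seed),
      file.path(dir, paste0("validation_", bn, ".json")),
      auto_unbox = TRUE, digits = NA)
    write.csv(data.frame(accuracy = v$null_accuracies),
              file.path(dir, paste0("null_accuracies_", bn, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(report$table1))
    write.csv(as.data.frame(report$table1),
              file.path(dir, "table1_report.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mixstrat")),
    seed = report$config$seed,
    log = report$log,
    outputs = list.files(dir))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Stratification pipeline run\n")
  cat(sprintf("  %d subjects (%d complete), %d features\n",
              x$log$n_subjects, x$log$n_complete, x$log$n_features))
  cat(sprintf("  latent dimension D = %d (AIC); %d imputed subjects included, %d excluded\n",
              x$log$selected_D, x$log$n_imputed_included,
              x$log$n_imputed_excluded))
  cat(sprintf("  subgroups K = %d (LOO-CV), sizes %s\n", x$log$selected_K,
              paste(x$log$subgroup_sizes, collapse = " / ")))
  for (bn in names(x$validation)) {
    v <- x$validation[[bn]]
    cat(sprintf("  %s: LOO accuracy %.1f%% vs baseline %.1f%%, p = %.4g (n = %d)\n",
                bn, 100 * v$loo_accuracy, 100 * v$baseline_accuracy,
                v$p_value, v$n))
  }
  invisible(x)
}
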