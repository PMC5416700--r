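#' Construct a subjects x features matrix with metadata
#'
#' The common container passed between pipeline stages: a numeric matrix with
#' a missingness mask, feature modality labels, and subject group labels.
#' Missing cells are `NA` in `values` and `TRUE` in `mask`; `NA` never occurs
#' outside the mask.
#'
#' @param values numeric subjects x features matrix (`NA` = missing).
#' @param feature_names character, one per column, unique.
#' @param modality character per feature: `"cognitive"` or
#'   `"electrophysiological"`.
#' @param subject_ids character, one per row, unique.
#' @param group character per subject: `"patient"` or `"control"`.
#' @param mask optional logical matrix; defaults to `is.na(values)`.
#' @return object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(values, feature_names = colnames(values),
                           modality = NULL,
                           subject_ids = rownames(values),
                           group = NULL, mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); p <- ncol(values)
  if (is.null(feature_names)) feature_names <- sprintf("f%03d", seq_len(p))
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  if (anyDuplicated(subject_ids))
    abort("feature_matrix: duplicated subject_id: ",
          paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (anyDuplicated(feature_names))
    abort("feature_matrix: duplicated feature names")
  if (length(feature_names) != p || length(subject_ids) != n)
    abort("feature_matrix: name lengths do not match matrix dimensions")
  if (is.null(modality)) modality <- rep("cognitive", p)
  if (!all(modality %in% c("cognitive", "electrophysiological")))
    abort("feature_matrix: modality must be 'cognitive' or 'electrophysiological'")
  if (is.null(group)) group <- rep("patient", n)
  if (!all(group %in% c("patient", "control")))
    abort("feature_matrix: group must be 'patient' or 'control'")
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values)))
    abort("feature_matrix: mask dimensions do not match values")
  if (any(is.na(values) & !mask))
    abort("feature_matrix: NA cell outside the missingness mask")
  dimnames(values) <- dimnames(mask) <- list(subject_ids, feature_names)
  structure(list(values = values, mask = mask,
                 feature_names = feature_names, modality = modality,
                 subject_ids = subject_ids, group = group),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d subjects x %d features (%d cognitive, %d electrophysiological)\n",
              nrow(x$values), ncol(x$values),
              sum(x$modality == "cognitive"),
              sum(x$modality == "electrophysiological")))
  cat(sprintf("  %d missing cells in %d subjects\n",
              sum(x$mask), sum(rowSums(x$mask) > 0)))
  invisible(x)
}

## internal: logical index of rows with no missing cells
complete_rows <- function(fm) rowSums(fm$mask) == 0L
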