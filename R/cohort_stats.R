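## Univariate subgroup characterization from summary statistics:
## Welch t-tests, 2x2 chi-squared tests, exact recombination of per-group
## summaries, and a full demographic/clinical characterization table.

#' Summary statistic triple
#' @param n count (>= 1).
#' @param mean group mean.
#' @param sd sample standard deviation (denominator n - 1); requires n >= 2.
#' @return list of class `"summary_stat"`.
#' @export
summary_stat <- function(n, mean, sd = NA_real_) {
  if (n < 1) abort("summary_stat: n must be >= 1")
  if (!is.na(sd) && sd < 0) abort("summary_stat: sd must be >= 0")
  if (!is.na(sd) && n < 2) abort("summary_stat: sd requires n >= 2")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "summary_stat")
}

#' Two-sample t-test from summary statistics
#'
#' Welch's unequal-variance statistic with Satterthwaite degrees of freedom
#' (default), or the pooled-variance Student statistic, computed from group
#' summaries alone.
#'
#' @param s1,s2 [summary_stat()] objects with n >= 2 and sd > 0.
#' @param pooled use the pooled-variance test instead of Welch.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(s1, s2, pooled = FALSE) {
  stopifnot(inherits(s1, "summary_stat"), inherits(s2, "summary_stat"))
  if (s1$n < 2 || s2$n < 2) abort("welch_t: both groups need n >= 2")
  if (is.na(s1$sd) || is.na(s2$sd) || s1$sd <= 0 || s2$sd <= 0)
    abort("welch_t: both groups need sd > 0")
  if (pooled) {
    sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / (s1$n + s2$n - 2)
    se <- sqrt(sp2 * (1 / s1$n + 1 / s2$n))
    df <- s1$n + s2$n - 2
  } else {
    v1 <- s1$sd^2 / s1$n
    v2 <- s2$sd^2 / s2$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (s1$n - 1) + v2^2 / (s2$n - 1))
  }
  t <- (s1$mean - s2$mean) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Continuity correction is off by default. Requires all expected counts to
#' be positive (no zero marginals).
#'
#' @param tab 2x2 numeric matrix or table of non-negative counts.
#' @param correction apply the Yates continuity correction.
#' @return list with `chi2`, `df` (= 1), `p`.
#' @export
chi2_2x2 <- function(tab, correction = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) abort("chi2_2x2: need a 2x2 table")
  if (any(tab < 0)) abort("chi2_2x2: negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("chi2_2x2: zero marginal")
  ct <- suppressWarnings(chisq.test(tab, correct = correction))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Exact pooling of group summary statistics
#'
#' Recombines per-group (n, mean, sd) into the summary of the concatenated
#' raw data via the total-sum-of-squares decomposition (within + between);
#' exact, order-invariant and associative. The pooled sd uses the sample
#' (n - 1) denominator.
#'
#' @param parts list of [summary_stat()] objects (total n >= 2).
#' @return a [summary_stat()] for the combined sample.
#' @export
pool_summaries <- function(parts) {
  if (inherits(parts, "summary_stat")) parts <- list(parts)
  if (length(parts) == 0L) abort("pool_summaries: no parts")
  stopifnot(all(vapply(parts, inherits, logical(1), "summary_stat")))
  n <- sum(vapply(parts, `[[`, numeric(1), "n"))
  if (n < 2) abort("pool_summaries: total n must be >= 2")
  m <- sum(vapply(parts, function(s) s$n * s$mean, numeric(1))) / n
  tss <- sum(vapply(parts, function(s) {
    within <- if (s$n >= 2 && !is.na(s$sd)) (s$n - 1) * s$sd^2 else 0
    within + s$n * (s$mean - m)^2
  }, numeric(1)))
  summary_stat(n, m, sqrt(tss / (n - 1)))
}

## internal: summary_stat from a raw vector, NA dropped; NULL if empty
stat_from_raw <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NULL)
  summary_stat(length(v), mean(v), if (length(v) >= 2) sd(v) else NA_real_)
}

## internal: one numeric row of the characterization table
numeric_row <- function(measure, v1, v2) {
  s1 <- stat_from_raw(v1); s2 <- stat_from_raw(v2)
  p <- if (!is.null(s1) && !is.null(s2) && s1$n >= 2 && s2$n >= 2 &&
           !is.na(s1$sd) && !is.na(s2$sd) && s1$sd > 0 && s2$sd > 0)
    welch_t(s1, s2)$p else NA_real_
  data.frame(measure = measure, type = "numeric",
             n_1 = if (is.null(s1)) NA_integer_ else s1$n,
             mean_1 = if (is.null(s1)) NA_real_ else s1$mean,
             sd_1 = if (is.null(s1)) NA_real_ else s1$sd,
             n_2 = if (is.null(s2)) NA_integer_ else s2$n,
             mean_2 = if (is.null(s2)) NA_real_ else s2$mean,
             sd_2 = if (is.null(s2)) NA_real_ else s2$sd,
             p = p, stringsAsFactors = FALSE)
}

## internal: one categorical (2x2) row; count = "positive" cases per group
categorical_row <- function(measure, x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  tab <- rbind(c(sum(x1), length(x1) - sum(x1)),
               c(sum(x2), length(x2) - sum(x2)))
  p <- tryCatch(chi2_2x2(tab)$p, error = function(e) NA_real_)
  data.frame(measure = measure, type = "categorical",
             n_1 = length(x1), mean_1 = sum(x1), sd_1 = NA_real_,
             n_2 = length(x2), mean_2 = sum(x2), sd_2 = NA_real_,
             p = p, stringsAsFactors = FALSE)
}

#' Univariate characterization of patient subgroups
#'
#' Builds the standard demographic/clinical comparison table for two
#' discovered subgroups: gender and substance-use items (alcohol, tobacco,
#' cannabis, benzodiazepines) by uncorrected chi-squared; age, the three
#' PANSS subscores at baseline, follow-up and change (baseline - follow-up),
#' and drug dose by Welch t-test. Missing clinical blocks shrink the
#' per-cell n rather than erroring; with a single subgroup the comparison
#' p-values are `NA` but the table is still produced.
#'
#' @param labels named integer vector (1/2) of subgroup labels per patient;
#'   names are subject ids.
#' @param metadata data.frame with subject_id, gender (`"m"`/`"f"`), age,
#'   and logical user flags alcohol, tobacco, cannabis, benzodiazepines.
#' @param clinical a `"clinical_table"` data.frame as from
#'   [generate_panss()] (or the same columns read from file).
#' @return data.frame of class `"table1_report"`, 16 rows (one per
#'   measure).
#' @export
characterize_subgroups <- function(labels, metadata, clinical) {
  ids <- names(labels)
  if (is.null(ids)) abort("characterize_subgroups: labels must be named by subject id")
  md <- metadata[match(ids, metadata$subject_id), , drop = FALSE]
  cl <- clinical[match(ids, clinical$subject_id), , drop = FALSE]
  if (anyNA(md$subject_id))
    abort("characterize_subgroups: metadata missing for some labelled patients")
  g1 <- labels == 1L; g2 <- labels == 2L
  rows <- list()
  rows[[1]] <- categorical_row("gender_m", md$gender[g1] == "m",
                               md$gender[g2] == "m")
  rows[[2]] <- numeric_row("age", md$age[g1], md$age[g2])
  k <- 3L
  for (blk in c("b", "fu", "change")) {
    for (s in c("positive", "negative", "general")) {
      col <- paste0("panss_", s, "_", blk)
      rows[[k]] <- numeric_row(col, cl[[col]][g1], cl[[col]][g2])
      k <- k + 1L
    }
  }
  rows[[k]] <- numeric_row("dose", cl$dose[g1], cl$dose[g2]); k <- k + 1L
  for (u in c("alcohol", "tobacco", "cannabis", "benzodiazepines")) {
    rows[[k]] <- categorical_row(u, md[[u]][g1], md[[u]][g2])
    k <- k + 1L
  }
  out <- do.call(rbind, rows)
  class(out) <- c("table1_report", "data.frame")
  out
}
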