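new_numt_test <- function(statistic, p_value, method, tails, n,
                          degenerate = FALSE, extra = list()) {
  structure(c(list(statistic = as.numeric(statistic),
                   p_value = as.numeric(p_value), method = method,
                   tails = tails, n = n, degenerate = degenerate), extra),
            class = "numt_test")
}

#' @export
print.numt_test <- function(x, ...) {
  cat("<numt_test> ", x$method, " (", x$tails, "-tailed)\n", sep = "")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate input (zero variance); no p-value\n")
  } else {
    cat(sprintf("  statistic = %.4g, p = %.4g, n = %s\n", x$statistic,
                x$p_value, paste(unlist(x$n), collapse = "/")))
  }
  invisible(x)
}

#' Paired t-test on log-transformed NUMT proportions
#'
#' Tests whether tumor genomes carry more NUMTs than their matched
#' blood-derived healthy genomes by a paired t-test on the log-transformed
#' proportions, i.e. a one-sample t-test on the per-participant log fold
#' changes. The statistic and p-value are identical for any log base (a base
#' change rescales the differences by a positive constant); log2 is used so
#' the mean difference reads as a log2 fold change. One-tailed tests are in
#' the tumor-excess direction.
#'
#' @param p_t,p_h Positive proportion vectors of equal length (>= 2),
#'   matched by participant.
#' @param tails `"two"` or `"one"`.
#' @return A `numt_test` with `statistic`, `p_value`, `df`; degenerate
#'   (zero-variance differences) inputs return a flagged result with no
#'   p-value rather than an infinite statistic.
#' @export
paired_t_log <- function(p_t, p_h, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(p_t) != length(p_h)) stopf("p_t and p_h must have equal length")
  if (length(p_t) < 2L) stopf("need at least 2 pairs")
  if (any(p_t <= 0) || any(p_h <= 0))
    stopf("log transform undefined for non-positive proportions")
  d <- log2(p_t) - log2(p_h)
  n <- length(d)
  if (stats::sd(d) == 0 && mean(d) == 0)  # no change at all: no evidence
    return(new_numt_test(0, 1, "paired t on log2 proportions", tails, n,
                         extra = list(df = n - 1L, mean_log2_fc = 0)))
  tt <- tryCatch(
    stats::t.test(d, alternative = if (tails == "one") "greater"
                                   else "two.sided"),
    error = function(e) NULL)
  if (is.null(tt))  # constant nonzero differences: singular, flagged
    return(new_numt_test(NA, NA, "paired t on log2 proportions", tails, n,
                         degenerate = TRUE, extra = list(df = n - 1L)))
  new_numt_test(unname(tt$statistic), tt$p.value,
                "paired t on log2 proportions", tails, n,
                extra = list(df = n - 1L, mean_log2_fc = mean(d)))
}

#' Welch unequal-variance t-test
#'
#' Two-sample t-test without the equal-variance assumption
#' (Welch–Satterthwaite degrees of freedom), as used for the
#' tumor-versus-blood group comparison and for sex- and disease-stratified
#' contrasts.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param tails `"two"` or `"one"` (one-tailed: `group_a > group_b`).
#' @return A `numt_test`; zero variance in both groups yields a flagged
#'   degenerate result.
#' @export
welch_t <- function(group_a, group_b, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stopf("each group needs at least 2 observations")
  n <- list(n1 = length(group_a), n2 = length(group_b))
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
    return(new_numt_test(NA, NA, "Welch t", tails, n, degenerate = TRUE))
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = if (tails == "one") "greater"
                                    else "two.sided")
  new_numt_test(unname(tt$statistic), tt$p.value, "Welch t", tails, n,
                extra = list(df = unname(tt$parameter)))
}

#' Mann–Whitney U test
#'
#' Rank-sum comparison of two groups (used for the alive-versus-deceased
#' vital-status contrast). The p-value is exact when the smaller group has at
#' most 8 observations and there are no ties; otherwise the tie-corrected
#' normal approximation (with continuity correction) is used. The statistic
#' is the U of the first group; tied observations receive midranks.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A `numt_test` with the U statistic and two-sided p-value.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- min(length(group_a), length(group_b)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = TRUE))
  new_numt_test(unname(wt$statistic), wt$p.value,
                if (exact) "Mann-Whitney U (exact)"
                else "Mann-Whitney U (normal approx., tie-corrected)",
                "two", list(n1 = length(group_a), n2 = length(group_b)))
}

#' Regression of log2 tumor proportion on log2 healthy proportion
#'
#' Ordinary least squares of `log2(p_t)` on `log2(p_h)`, quantifying how
#' well NUMT abundance in blood predicts NUMT abundance in the matched
#' tumor. The slope p-value is the usual t-test with n-2 degrees of freedom.
#'
#' @param p_t,p_h Positive proportion vectors, length >= 3.
#' @return List of class `numt_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
regress_log2 <- function(p_t, p_h) {
  if (length(p_t) != length(p_h)) stopf("vectors must have equal length")
  if (length(p_t) < 3L) stopf("need at least 3 pairs")
  if (any(p_t <= 0) || any(p_h <= 0)) stopf("log2 undefined at <= 0")
  ols_result(stats::lm(log2(p_t) ~ log2(p_h)),
             "OLS of log2 tumor on log2 healthy proportion")
}

ols_result <- function(fit, method) {
  x <- stats::model.matrix(fit)[, 2L]
  if (stats::var(x) == 0) stopf("zero variance in predictor")
  y <- stats::model.frame(fit)[[1L]]
  n <- length(y)
  if (stats::var(y) == 0)  # constant response: flat line, no fit quality
    return(structure(list(slope = 0, intercept = mean(y), r_squared = 0,
                          p_value = 1, n = n, method = method),
                     class = "numt_regression"))
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2L, 4L]),
                 n = n, method = method),
            class = "numt_regression")
}

#' @export
print.numt_regression <- function(x, ...) {
  cat("<numt_regression> ", x$method, "\n", sep = "")
  cat(sprintf("  slope = %.4g, intercept = %.4g, R^2 = %.4g, p = %.4g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Arm-level fold change versus mapped read count
#'
#' Linear regression of the rescaled arm-level fold change on the arm's
#' mapped read count (no log transform), probing whether NUMT transposition
#' is coincident with aneuploidy: large copy-number shifts move arm-level
#' mapped counts, so a systematic relationship would confound the NUMT
#' signal with dosage.
#'
#' @param rescaled_arm Rescaled fold changes per arm.
#' @param mapped_arm Mapped read counts per arm.
#' @return A `numt_regression`.
#' @export
arm_aneuploidy_regression <- function(rescaled_arm, mapped_arm) {
  if (length(rescaled_arm) != length(mapped_arm))
    stopf("vectors must have equal length")
  if (length(rescaled_arm) < 3L) stopf("need at least 3 arms")
  ols_result(stats::lm(rescaled_arm ~ mapped_arm),
             "OLS of rescaled arm fold change on mapped reads")
}

#' Window-level fold change versus GC content
#'
#' Pearson and Spearman correlation of the rescaled window-level fold change
#' with window GC content, probing whether gene-dense (GC-rich, open
#' chromatin) regions are preferred NUMT landing sites.
#'
#' @param rescaled_win Rescaled fold changes per window.
#' @param gc_win GC fractions per window (same order).
#' @return List of class `numt_correlation`: `pearson`, `pearson_p`,
#'   `spearman`, `spearman_p`, `n`; constant input yields a flagged
#'   degenerate result.
#' @export
gc_association <- function(rescaled_win, gc_win) {
  if (length(rescaled_win) != length(gc_win))
    stopf("vectors must have equal length")
  keep <- is.finite(rescaled_win) & is.finite(gc_win)
  x <- rescaled_win[keep]; g <- gc_win[keep]
  if (length(x) < 3L) stopf("need at least 3 windows")
  if (stats::var(x) == 0 || stats::var(g) == 0)
    return(structure(list(pearson = NA_real_, pearson_p = NA_real_,
                          spearman = NA_real_, spearman_p = NA_real_,
                          n = length(x), degenerate = TRUE),
                     class = "numt_correlation"))
  pe <- stats::cor.test(x, g, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, g, method = "spearman"))
  structure(list(pearson = unname(pe$estimate), pearson_p = pe$p.value,
                 spearman = unname(sp$estimate), spearman_p = sp$p.value,
                 n = length(x), degenerate = FALSE),
            class = "numt_correlation")
}

#' @export
print.numt_correlation <- function(x, ...) {
  cat("<numt_correlation> n =", x$n, "\n")
  if (isTRUE(x$degenerate)) cat("  degenerate (constant input)\n")
  else cat(sprintf("  Pearson r = %.3f (p = %.3g); Spearman rho = %.3f (p = %.3g)\n",
                   x$pearson, x$pearson_p, x$spearman, x$spearman_p))
  invisible(x)
}

#' Per-Giemsa-group summary of cytoband fold changes
#'
#' Summarizes rescaled cytoband-level fold changes within the five Giemsa
#' stain groups (gneg, gpos25, gpos50, gpos75, gpos100); centromeric (acen),
#' variable (gvar) and stalk bands are excluded. For each group the band
#' count, quartiles, mean, and the number of bands at or above a fold-change
#' threshold (default 4.2) are reported. Empty groups are omitted.
#'
#' @param ratio_records Cytoband-level ratio table ([ratio_table()]).
#' @param cytobands Cytoband partition carrying the `stain` column.
#' @param threshold Fold-change threshold for the exceedance count.
#' @return Data frame: `stain`, `n`, `q1`, `median`, `q3`, `mean`,
#'   `n_above_threshold`.
#' @export
giemsa_group_summary <- function(ratio_records, cytobands, threshold = 4.2) {
  groups <- c("gneg", "gpos25", "gpos50", "gpos75", "gpos100")
  stain <- cytobands$stain[match(ratio_records$interval_id,
                                 cytobands$interval_id)]
  out <- lapply(groups, function(g) {
    v <- ratio_records$rescaled[which(stain == g)]
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(stain = g, n = length(v), q1 = q[1L], median = q[2L],
               q3 = q[3L], mean = mean(v),
               n_above_threshold = sum(v >= threshold),
               stringsAsFactors = FALSE)
  })
  empty <- groups[vapply(out, is.null, TRUE)]
  if (length(empty))
    message("empty Giemsa group(s) omitted: ", paste(empty, collapse = ", "))
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Covariate-stratified summary of per-sample fold change
#'
#' Splits the cohort by a covariate and reports each group's median, minimum
#' and maximum per-sample genome-level fold change, plus the group contrast
#' the analysis design pairs with that covariate: a Welch unequal-variance
#' t-test for sex and disease, a Mann–Whitney U test for vital status.
#' Alternatively `values` can select the raw tumor or healthy proportions
#' (the sex contrast on raw proportions stratified by genome type).
#'
#' @param cohort A cohort table ([cohort_table()] or any data frame with the
#'   covariate column and the value column).
#' @param by Covariate: `"sex"`, `"disease"`, `"vital_status"`, or `"stage"`.
#' @param values Column to summarize: `"fold_change"` (default), `"p_t"`, or
#'   `"p_h"`.
#' @return List with `summary` (per-group data frame) and `test` (a
#'   `numt_test`, or NULL when the covariate has other than 2 groups).
#' @export
stratified_summary <- function(cohort,
                               by = c("sex", "disease", "vital_status",
                                      "stage"),
                               values = c("fold_change", "p_t", "p_h")) {
  by <- match.arg(by)
  values <- match.arg(values)
  if (!by %in% names(cohort)) stopf("covariate '%s' missing", by)
  if (!values %in% names(cohort)) stopf("value column '%s' missing", values)
  v <- cohort[[values]]
  g <- as.character(cohort[[by]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  groups <- unique(g)
  smry <- do.call(rbind, lapply(groups, function(gr) {
    x <- v[g == gr]
    data.frame(group = gr, n = length(x), median = stats::median(x),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }))
  test <- NULL
  if (length(groups) == 2L) {
    a <- v[g == groups[1L]]; b <- v[g == groups[2L]]
    test <- if (by == "vital_status") mann_whitney(a, b)
            else if (length(a) >= 2L && length(b) >= 2L) welch_t(a, b)
            else NULL
  }
  list(summary = smry, test = test, by = by, values = values)
}

#' Benjamini–Hochberg adjustment for window-level scans
#'
#' Convenience wrapper around [stats::p.adjust()] for multiple-testing
#' control when a test is applied across many windows. No correction is
#' applied anywhere by default; this is an opt-in extension.
#'
#' @param p Vector of p-values.
#' @return BH-adjusted p-values.
#' @export
adjust_window_p <- function(p) stats::p.adjust(p, method = "BH")
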