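#' Condition vocabulary for cohort tables
#'
#' The fixed set of culture-condition labels used in cohort tables:
#' flat glass coverslips ("Flat"), the 3D microscaffold ("Nichoid"), and
#' their cytochalasin-D and puromycin treated variants.
#'
#' @export
conditionLevels <- function() {
  c("Flat", "Flat+CD", "Nichoid", "Nichoid+CD", "Flat+Puro", "Nichoid+Puro")
}

#' Validate a cohort table
#'
#' A cohort table has one row per (cell, metric): columns cell_id,
#' condition (from [conditionLevels()]), metric, value. Duplicate
#' (cell_id, metric) pairs and unknown condition labels are rejected.
#'
#' @param table data.frame.
#' @return the table, invisibly, after validation.
#' @export
validateCohortTable <- function(table) {
  need <- c("cell_id", "condition", "metric", "value")
  if (!all(need %in% names(table)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(table$condition), conditionLevels())
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  key <- paste(table$cell_id, table$metric)
  if (anyDuplicated(key))
    stop("duplicate (cell_id, metric) rows in cohort table")
  invisible(table)
}

#' Non-parametric group comparison for a cohort metric
#'
#' Dispatches the two-sided Mann-Whitney (Wilcoxon rank-sum) test for two
#' groups and the Kruskal-Wallis test for three or more, following the
#' convention of reporting raw non-parametric p-values with significance
#' stars (* p<0.05, ** p<0.01, *** p<0.001, **** p<0.0001).
#'
#' @param table a cohort table (see [validateCohortTable()]).
#' @param metric metric name to compare.
#' @param conditions character vector of condition labels (>= 2).
#' @param adjust optional p-adjustment method passed to [stats::p.adjust()]
#'   when several metrics are compared via [compareAllMetrics()]; unused
#'   here, reserved for symmetry.
#' @return data.frame with metric, test, statistic, df, p.value, stars and
#'   the group sizes.
#' @export
compareGroups <- function(table, metric, conditions, adjust = "none") {
  validateCohortTable(table)
  bad <- setdiff(conditions, conditionLevels())
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  if (length(conditions) < 2L) stop("need at least 2 conditions")
  sub <- table[table$metric == metric & table$condition %in% conditions, ]
  ns <- table(factor(sub$condition, levels = conditions))
  if (any(ns < 3L))
    stop("need at least 3 observations per group for metric ", metric)
  if (length(conditions) == 2L) {
    ht <- wilcox.test(value ~ factor(condition, levels = conditions),
                      data = sub, exact = FALSE, correct = TRUE)
    test <- "Mann-Whitney"
    df <- NA_real_
  } else {
    ht <- kruskal.test(value ~ factor(condition, levels = conditions),
                       data = sub)
    test <- "Kruskal-Wallis"
    df <- unname(ht$parameter)
  }
  p <- ht$p.value
  if (!is.finite(p)) stop("test returned a non-finite p-value")
  data.frame(metric = metric, test = test,
             statistic = unname(ht$statistic), df = df, p.value = p,
             stars = .stars(p), n = paste(as.integer(ns), collapse = "/"),
             groups = paste(conditions, collapse = " vs "))
}

.stars <- function(p) {
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 1e-2) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Compare all metrics of a cohort table across conditions
#'
#' Runs [compareGroups()] for every metric present in the table. No
#' multiple-testing correction is applied by default (raw non-parametric
#' p-values with star thresholds); Benjamini-Hochberg adjustment is
#' available via \code{adjust = "BH"}.
#'
#' @param table a cohort table.
#' @param conditions condition labels to compare.
#' @param adjust p-adjustment method (default "none").
#' @return data.frame, one row per metric.
#' @export
compareAllMetrics <- function(table, conditions, adjust = "none") {
  mets <- sort(unique(table$metric))
  out <- do.call(rbind, lapply(mets, function(m)
    compareGroups(table, m, conditions)))
  if (adjust != "none") {
    out$p.adjusted <- stats::p.adjust(out$p.value, method = adjust)
    out$stars <- vapply(out$p.adjusted, .stars, character(1))
  }
  rownames(out) <- NULL
  out
}
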