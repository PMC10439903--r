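# Statistical reporting layer: the tests and summary artifacts used for
# cohort comparisons. Test machinery is delegated to base R (wilcox.test,
# chisq.test, p.adjust); this layer fixes the conventions (two-sided, exact
# for small tie-free samples, no continuity correction for chi-squared) and
# returns a uniform result record.

new_test_result <- function(statistic, p_value, method, n,
                            adjusted_p = NA_real_) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 adjusted_p = adjusted_p, method = method, n = n),
            class = "conformap_test")
}

#' @export
print.conformap_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.3g%s\n", x$method, x$statistic,
              x$p_value,
              if (!is.na(x$adjusted_p)) sprintf(" (adj %.3g)", x$adjusted_p)
              else ""))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when `length(x) + length(y) <= 12` and the pooled data
#' carry no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return A `conformap_test` with the rank-sum statistic `W`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  no_ties <- !anyDuplicated(c(x, y))
  exact <- (length(x) + length(y)) <= 12 && no_ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  new_test_result(wt$statistic, wt$p.value,
                  if (exact) "wilcoxon_exact" else "wilcoxon_normal_approx",
                  n = c(length(x), length(y)))
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction; `df = (R - 1)(C - 1)`.
#'
#' @param table Matrix of counts (R x C).
#' @return A `conformap_test`.
#' @export
chi_squared_independence <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-squared table has an empty row or column")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  new_test_result(ct$statistic, ct$p.value, "chi_squared",
                  n = sum(table))
}

#' Multiplicity adjustment of p-values
#'
#' Holm step-down by default (monotone, capped at 1); Bonferroni available.
#'
#' @param pvals Numeric vector of raw p-values.
#' @param method `"holm"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, elementwise `>=` the raw ones.
#' @export
adjust_pvalues <- function(pvals, method = c("holm", "bonferroni")) {
  p.adjust(pvals, method = match.arg(method))
}

#' Significance stars for an adjusted p-value
#'
#' Bands: `n.s.` above 0.05, `*` <= 0.05, `**` <= 0.01, `***` <= 0.001,
#' `****` <= 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  cut_lab <- function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp <= 1e-4) "****" else if (pp <= 1e-3) "***"
    else if (pp <= 1e-2) "**" else if (pp <= 0.05) "*" else "n.s."
  }
  vapply(p, cut_lab, "")
}

#' Position frequency matrix of aligned sequences
#'
#' @param aligned Character vector of equal-length strings, or a character
#'   matrix (rows = sequences, columns = positions). `NA` and `"-"` entries
#'   are excluded from the column denominator.
#' @return Matrix of per-column frequencies (rows = observed symbols,
#'   columns = positions); each column with observations sums to 1.
#' @export
position_frequency_matrix <- function(aligned) {
  if (is.character(aligned) && is.null(dim(aligned))) {
    lens <- nchar(aligned)
    if (length(unique(lens)) != 1L) stop("sequences must be equal length")
    aligned <- do.call(rbind, strsplit(aligned, ""))
  }
  aligned[aligned == "-"] <- NA_character_
  symbols <- sort(unique(as.vector(aligned[!is.na(aligned)])))
  pfm <- matrix(0, length(symbols), ncol(aligned),
                dimnames = list(symbols,
                                colnames(aligned) %||% seq_len(ncol(aligned))))
  for (j in seq_len(ncol(aligned))) {
    col <- aligned[, j]
    col <- col[!is.na(col)]
    if (length(col) == 0L) next
    tb <- table(col) / length(col)
    pfm[names(tb), j] <- as.numeric(tb)
  }
  pfm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a cohort report bundle
#'
#' Gathers the main analysis outputs into one list and optionally writes it
#' as JSON plus TSV tables.
#'
#' @param angles Data frame from [classify_cohort()] (stem-angle scatter
#'   data), or `NULL`.
#' @param paratope Output of [cohort_paratope_summary()], or `NULL`.
#' @param repertoire Output of [cohort_summaries()], or `NULL`.
#' @param funnel Funnel count list from [run_repertoire()], or `NULL`.
#' @param dir Output directory; when given, `report.json` and TSV tables are
#'   written there.
#' @return The report list, invisibly when written.
#' @export
build_report <- function(angles = NULL, paratope = NULL, repertoire = NULL,
                         funnel = NULL, dir = NULL) {
  report <- list()
  if (!is.null(angles)) {
    tab <- table(factor(angles$label,
                        levels = c("kinked", "extended", "other")))
    report$classification <- list(
      n = nrow(angles),
      counts = as.list(tab),
      percent = as.list(round(100 * as.numeric(tab) / nrow(angles), 2) |>
                          setNames(names(tab))),
      mean_cdr3_length = lapply(split(angles$cdr3_len, angles$label), mean))
    report$angles <- angles
  }
  if (!is.null(paratope)) report$paratope <- paratope
  if (!is.null(repertoire)) report$repertoire <- repertoire
  if (!is.null(funnel)) report$funnel <- funnel
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report[setdiff(names(report), "angles")],
      file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    if (!is.null(angles))
      write.table(angles, file.path(dir, "angles.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(paratope)) {
      write.table(paratope$usage, file.path(dir, "paratope_usage.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(paratope$area, file.path(dir, "paratope_area.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(report))
  }
  report
}
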