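## Differential feature detection: the protein-array F-test, the
## expression t-test, Benjamini-Hochberg adjustment, and threshold
## selection.

.differential_result <- function(feature_id, effect, statistic, p_value,
                                 fdr, flagged, selected, threshold_spec,
                                 test) {
  df <- data.frame(
    feature_id = feature_id, effect = effect, statistic = statistic,
    p_value = p_value, fdr = fdr, flagged = flagged,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(df,
            selected = selected, threshold_spec = threshold_spec,
            test = test,
            class = c("DifferentialResult", "data.frame"))
}

#' @export
print.DifferentialResult <- function(x, ...) {
  cat(sprintf(
    "DifferentialResult (%s): %d features, %d selected, %d flagged\n",
    attr(x, "test"), nrow(x), length(attr(x, "selected")), sum(x$flagged)
  ))
  invisible(x)
}

#' Selected feature ids of a differential result
#' @param result a `DifferentialResult`
#' @return character vector
#' @export
selected_features <- function(result) attr(result, "selected")

#' Per-feature F-test from a two-group linear model
#'
#' Fits, per feature, a mean-plus-group-effect linear model and tests the
#' group effect with an F statistic on (1, n - 2) degrees of freedom -
#' the selection rule used for differentially regulated proteins (DRPs)
#' on protein-array data. Features with `p < alpha` form the selected
#' set; the FDR column is left unpopulated because DRP selection operates
#' on raw p-values.
#'
#' Features with zero residual variance have an undefined p-value: they
#' are flagged, excluded from selection, and reported with `NA`
#' statistics (a warning counts them).
#'
#' @param matrix an `ExpressionMatrix`.
#' @param design a two-group [sample_design()], each group >= 2 samples.
#' @param alpha raw p-value selection threshold (default 0.05).
#' @return a `DifferentialResult` with columns `feature_id`, `effect`
#'   (mean group2 - mean group1, groups ordered lexicographically),
#'   `statistic` (F), `p_value`, `fdr` (`NA`), `flagged`.
#' @examples
#' m <- matrix(c(0, 1, 2, 3), 1, 4,
#'             dimnames = list("P1", paste0("s", 1:4)))
#' d <- sample_design(paste0("s", 1:4), c("a", "a", "b", "b"))
#' group_ftest_table(expression_matrix(m), d)$statistic  # F = 8
#' @export
group_ftest_table <- function(matrix, design, alpha = 0.05) {
  idx <- .design_indices(matrix, design)
  tt <- .row_ttest(matrix$values, idx[[1L]], idx[[2L]], "pooled")
  f <- tt$statistic^2
  p <- stats::pf(f, 1, tt$df, lower.tail = FALSE)
  if (any(tt$flagged)) {
    .warnf("%d feature(s) with zero residual variance flagged and excluded",
           sum(tt$flagged))
  }
  ids <- feature_ids(matrix)
  sel <- ids[!tt$flagged & !is.na(p) & p < alpha]
  .differential_result(
    ids, tt$effect, f, p, rep(NA_real_, length(ids)), tt$flagged,
    selected = sel,
    threshold_spec = list(rule = "p", cutoff = alpha, test = "ftest"),
    test = "ftest"
  )
}

#' Per-feature two-sample t-test with BH adjustment
#'
#' Two-sided two-sample t-test per gene between the two design groups,
#' with Benjamini-Hochberg false discovery rates computed over all
#' non-flagged genes - the detection step for differentially expressed
#' genes (DEGs) whose FDR later gates the random walk.
#'
#' @param matrix an `ExpressionMatrix`.
#' @param design a two-group [sample_design()].
#' @param variant `"pooled"` (default; the form implied by the two-group
#'   linear model, satisfying F = t^2) or `"welch"`.
#' @return a `DifferentialResult`; `statistic` follows the
#'   `t.test(group1, group2)` orientation, `effect` is
#'   mean(group2) - mean(group1).
#' @export
two_sample_ttest_table <- function(matrix, design,
                                   variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  idx <- .design_indices(matrix, design)
  tt <- .row_ttest(matrix$values, idx[[1L]], idx[[2L]], variant)
  if (any(tt$flagged)) {
    .warnf("%d feature(s) with zero residual variance flagged and excluded",
           sum(tt$flagged))
  }
  fdr <- rep(NA_real_, length(tt$p_value))
  fdr[!tt$flagged] <- bh_adjust(tt$p_value[!tt$flagged])
  .differential_result(
    feature_ids(matrix), tt$effect, tt$statistic, tt$p_value, fdr,
    tt$flagged, selected = character(0L),
    threshold_spec = NULL, test = paste0("ttest_", variant)
  )
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, clipped at 1
#' and mapped back to input order (stable under ties).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of FDR values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0L))
  if (anyNA(p_values) || !is.numeric(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    .stopf("p-values must all lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Select significant features
#'
#' Features whose raw p-value or FDR falls strictly below a cutoff,
#' ordered by ascending value. Flagged features never qualify.
#'
#' @param result a `DifferentialResult`.
#' @param rule `"p"` or `"fdr"`.
#' @param cutoff threshold; values strictly below are selected.
#' @param name name for the returned list (default derived from the rule).
#' @return a [gene_list()] (possibly empty symbol handling: an error if
#'   nothing passes and `allow_empty = FALSE`).
#' @param allow_empty return `NULL` instead of erroring when nothing
#'   passes (default `FALSE` errors).
#' @export
select_significant <- function(result, rule = c("p", "fdr"), cutoff,
                               name = NULL, allow_empty = FALSE) {
  rule <- match.arg(rule)
  stopifnot(inherits(result, "DifferentialResult"))
  vals <- if (rule == "p") result$p_value else result$fdr
  if (all(is.na(vals))) {
    .stopf("column '%s' is unpopulated in this result", rule)
  }
  ok <- !result$flagged & !is.na(vals) & vals < cutoff
  ids <- result$feature_id[ok][order(vals[ok])]
  if (length(ids) == 0L) {
    if (allow_empty) return(NULL)
    .stopf("no feature passes %s < %g", rule, cutoff)
  }
  if (is.null(name)) name <- sprintf("%s<%g", rule, cutoff)
  gene_list(name, ids, normalize_case = FALSE)
}
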