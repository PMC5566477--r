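## Kaplan-Meier curves, the two-group log-rank test, and the percentile
## cutoff scan that dichotomizes a continuous marker (e.g. an RPPA
## protein level) against survival. The scan mirrors the original
## procedure: every percentile cutpoint in a band is tried, the
## cutpoint with the smallest log-rank p is recorded, and no
## multiplicity correction is applied by default - the resulting
## minimum-p inflation is real, measurable, and an optional
## permutation adjustment is provided.

#' Survival data container
#'
#' @param sample_id sample identifiers (unique).
#' @param time follow-up time, non-negative (months).
#' @param event 1 = event observed, 0 = censored.
#' @param marker optional numeric marker per sample (unitless).
#' @return data frame of class `SurvivalData`.
#' @export
survival_data <- function(sample_id, time, event, marker = NULL) {
  if (anyDuplicated(sample_id)) .stopf("duplicate sample ids")
  time <- as.numeric(time)
  if (any(!is.finite(time)) || any(time < 0)) {
    .stopf("times must be finite and >= 0")
  }
  if (!all(event %in% c(0, 1))) .stopf("events must be 0/1")
  df <- data.frame(sample_id = as.character(sample_id), time = time,
                   event = as.integer(event), stringsAsFactors = FALSE)
  if (!is.null(marker)) {
    if (length(marker) != nrow(df)) .stopf("marker length mismatch")
    df$marker <- as.numeric(marker)
  }
  structure(df, class = c("SurvivalData", "data.frame"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator via `survival::survfit`; censored subjects
#' reduce the risk set without producing steps. The returned step
#' function starts at S(0) = 1, is non-increasing and right-continuous.
#'
#' @param data a [survival_data()] frame.
#' @param group optional logical vector or sample-id subset restricting
#'   the curve to one group.
#' @return data frame `time`, `n_risk`, `n_event`, `surv`, including the
#'   `time = 0, surv = 1` anchor; the `survfit` object is attached as
#'   attribute `fit`.
#' @export
km_curve <- function(data, group = NULL) {
  stopifnot(inherits(data, "SurvivalData"))
  d <- data
  if (!is.null(group)) {
    keep <- if (is.logical(group)) group else d$sample_id %in% group
    d <- d[keep, , drop = FALSE]
  }
  if (nrow(d) == 0L) .stopf("no subjects in requested group")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(nrow(d), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    surv = c(1, fit$surv))
  attr(out, "fit") <- fit
  out
}

#' Two-group log-rank test
#'
#' Standard aggregated-risk-set log-rank statistic with a 1-df
#' chi-square p-value, via `survival::survdiff`.
#'
#' @param data a [survival_data()] frame.
#' @param groups two-level grouping: a logical vector, a factor/character
#'   vector (length = subjects), or a list of two sample-id sets.
#' @return list with `chi_square` and `p_value`.
#' @export
logrank_test <- function(data, groups) {
  stopifnot(inherits(data, "SurvivalData"))
  g <- if (is.list(groups)) {
    ifelse(data$sample_id %in% groups[[1L]], "g1",
           ifelse(data$sample_id %in% groups[[2L]], "g2", NA))
  } else if (is.logical(groups)) {
    ifelse(groups, "g1", "g2")
  } else {
    as.character(groups)
  }
  if (anyNA(g)) .stopf("every subject must belong to one of the two groups")
  tab <- table(g)
  if (length(tab) != 2L || any(tab == 0L)) {
    .stopf("log-rank test needs two non-empty groups")
  }
  d <- data.frame(time = data$time, event = data$event, g = g)
  if (sum(d$event) == 0L || length(unique(d$time[d$event == 1])) == 0L) {
    return(list(chi_square = 0, p_value = 1))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  chisq <- unname(sd_$chisq)
  list(chi_square = chisq,
       p_value = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Percentile cutoff scan against survival
#'
#' Dichotomizes the marker at every percentile cutpoint in
#' `percentile_band` (default 10th-90th by 1) and runs the log-rank
#' test at each; the cutpoint with the smallest p-value is recorded as
#' the marker's cutoff. The `significant` flag reports whether the
#' minimum p falls below `alpha` with NO multiplicity correction (the
#' original procedure); the inflation this causes is the classical
#' minimum-p phenomenon and can be corrected with the optional min-p
#' permutation adjustment.
#'
#' Dichotomies compare `marker > quantile(marker, pct/100)`, which is
#' invariant under strictly monotone transforms of the marker.
#'
#' @param data a [survival_data()] frame with a `marker` column.
#' @param percentile_band `(low, high)` percentile limits (default
#'   `c(10, 90)`), keeping at least roughly 10% of subjects per side.
#' @param step grid step in percentile points (default 1).
#' @param alpha significance level for the flag (default 0.05).
#' @param adjust `"none"` (default) or `"minp_permutation"`.
#' @param n_perm permutations for the adjustment (default 200).
#' @return list of class `CutoffScanResult`: `grid` (data frame
#'   `percentile`, `cutoff`, `chi_square`, `p_value`), `best_percentile`,
#'   `best_cutoff` (marker value at the selected cutpoint), `best_p`,
#'   `significant`, and `adjusted_p` (`NA` unless adjusted).
#' @export
scan_cutoff <- function(data, percentile_band = c(10, 90), step = 1,
                        alpha = 0.05, adjust = c("none", "minp_permutation"),
                        n_perm = 200L) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(data, "SurvivalData"))
  if (is.null(data$marker)) .stopf("scan_cutoff needs a marker column")
  marker <- data$marker
  if (length(unique(marker)) < 2L) .stopf("degenerate marker: constant")
  stopifnot(length(percentile_band) == 2L,
            percentile_band[1L] < percentile_band[2L],
            percentile_band[1L] > 0, percentile_band[2L] < 100)
  grid_pct <- seq(percentile_band[1L], percentile_band[2L], by = step)

  scan_once <- function(mk) {
    cuts <- stats::quantile(mk, grid_pct / 100, type = 7, names = FALSE)
    vapply(seq_along(grid_pct), function(i) {
      upper <- mk > cuts[i]
      if (sum(upper) < 2L || sum(!upper) < 2L) {
        return(c(cuts[i], NA_real_, NA_real_))
      }
      lr <- logrank_test(data, upper)
      c(cuts[i], lr$chi_square, lr$p_value)
    }, numeric(3L))
  }

  obs <- scan_once(marker)
  grid <- data.frame(percentile = grid_pct, cutoff = obs[1L, ],
                     chi_square = obs[2L, ], p_value = obs[3L, ])
  if (all(is.na(grid$p_value))) .stopf("no admissible cutpoint in the band")
  best <- which(grid$p_value == min(grid$p_value, na.rm = TRUE))[1L]
  adjusted_p <- NA_real_
  if (adjust == "minp_permutation") {
    obs_min <- grid$p_value[best]
    perm_min <- vapply(seq_len(n_perm), function(b) {
      min(scan_once(sample(marker))[3L, ], na.rm = TRUE)
    }, numeric(1L))
    adjusted_p <- (1 + sum(perm_min <= obs_min)) / (n_perm + 1)
  }
  structure(
    list(grid = grid,
         best_percentile = grid$percentile[best],
         best_cutoff = grid$cutoff[best],
         best_p = grid$p_value[best],
         significant = grid$p_value[best] < alpha,
         adjusted_p = adjusted_p,
         alpha = alpha),
    class = "CutoffScanResult"
  )
}

#' @export
print.CutoffScanResult <- function(x, ...) {
  cat(sprintf(
    "CutoffScanResult: best cutoff %.4g (%gth percentile), log-rank p = %.3g%s\n",
    x$best_cutoff, x$best_percentile, x$best_p,
    if (x$significant) " *" else ""
  ))
  if (!is.na(x$adjusted_p)) {
    cat(sprintf("  min-p permutation adjusted p = %.3g\n", x$adjusted_p))
  }
  invisible(x)
}
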