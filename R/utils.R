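#' @keywords internal
"_PACKAGE"

## Shared internal helpers. No science in this file beyond the pooled /
## Welch two-sample t computed row-wise, which several stages reuse.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Case-normalize gene/protein symbols
#' @param x character vector of symbols
#' @param normalize_case upper-case symbols (default TRUE)
#' @return character vector
#' @keywords internal
.norm_symbols <- function(x, normalize_case = TRUE) {
  x <- trimws(as.character(x))
  if (normalize_case) toupper(x) else x
}

## Row-wise two-sample t over a features x samples matrix.
## Orientation: statistic = (mean1 - mean2) / se, the stats::t.test(x = g1,
## y = g2) convention; effect = mean2 - mean1 (treated minus reference).
## Features with zero standard error are flagged (statistic/p set NA).
.row_ttest <- function(values, idx1, idx2, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  n1 <- length(idx1)
  n2 <- length(idx2)
  x1 <- values[, idx1, drop = FALSE]
  x2 <- values[, idx2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  ## zero residual variance: p undefined, feature flagged (never "p = 0")
  flagged <- !is.finite(se) | se == 0
  stat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(stat), df)
  stat[flagged] <- NA_real_
  p[flagged] <- NA_real_
  list(
    mean1 = m1, mean2 = m2, effect = m2 - m1,
    statistic = stat, se = se, df = df, p_value = p, flagged = flagged
  )
}

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    .stopf("`seed` must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}
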