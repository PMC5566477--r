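## Compound covariate predictor (CCP): each sample is scored by a
## t-statistic-weighted sum of signature-gene expression and classified
## against the midpoint of the class-mean scores. The classical
## formulation: per signature gene g the weight is the pooled two-sample
## t statistic t_g (class2 - class1, classes ordered lexicographically),
## the compound covariate of sample i is c_i = sum_g t_g x_gi, and the
## threshold is (mean c | class1 + mean c | class2) / 2. Because
## c_bar2 - c_bar1 = sum_g t_g (m2g - m1g) >= 0, class2 always sits on
## the upper side of the threshold.

.ccp_weights <- function(values, idx1, idx2) {
  tt <- .row_ttest(values, idx1, idx2, "pooled")
  w <- -tt$statistic                    # class2 - class1 orientation
  w[tt$flagged] <- 0                    # constant genes carry no signal
  list(weights = w, n_flagged = sum(tt$flagged))
}

.ccp_stats <- function(cc, idx1, idx2) {
  m1 <- mean(cc[idx1]); m2 <- mean(cc[idx2])
  s1 <- stats::sd(cc[idx1]); s2 <- stats::sd(cc[idx2])
  n1 <- length(idx1); n2 <- length(idx2)
  pooled_sd <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  list(mean = c(m1, m2), sd = c(s1, s2), pooled_sd = pooled_sd,
       threshold = (m1 + m2) / 2)
}

.zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  z
}

#' Fit a compound covariate predictor
#'
#' Trains the CCP on a labeled two-class cohort: pooled t-statistic
#' weights per signature gene, compound covariates, midpoint threshold,
#' and per-class score statistics for the probability estimate.
#' Signature genes absent from the training matrix are dropped with a
#' message; a model in which every weight is zero (identical classes) is
#' degenerate and raises an error.
#'
#' @param train training `ExpressionMatrix`.
#' @param design two-class [sample_design()], each class >= 2 samples.
#' @param signature a `GeneList` of signature genes.
#' @return a list of class `SignatureModel`: `genes`, `weights`,
#'   `threshold`, `class_stats` (per-class mean/sd and the pooled sd of
#'   the compound covariate), `classes` (sorted labels), `zscore`
#'   (threshold/stats recomputed on per-gene standardized training
#'   data, used for cross-cohort application), `gene_means`,
#'   `dropped`, `loocv_error` (`NA` until [loocv_ccp()]).
#' @examples
#' m <- matrix(c(0, 1, 2, 3), 1, 4,
#'             dimnames = list("G1", paste0("s", 1:4)))
#' d <- sample_design(paste0("s", 1:4), c("a", "a", "b", "b"))
#' fit_ccp(expression_matrix(m), d, gene_list("sig", "G1"))$threshold
#' @export
fit_ccp <- function(train, design, signature) {
  stopifnot(inherits(train, "ExpressionMatrix"))
  idx <- .design_indices(train, design)
  classes <- names(idx)
  sig <- .as_symbols(signature)
  present <- intersect(sig, feature_ids(train))
  dropped <- length(sig) - length(present)
  if (length(present) == 0L) {
    .stopf("no signature gene present in the training matrix")
  }
  if (dropped > 0L) {
    message(sprintf("fit_ccp: %d signature gene(s) absent from training data",
                    dropped))
  }
  x <- train$values[present, , drop = FALSE]
  w <- .ccp_weights(x, idx[[1L]], idx[[2L]])
  if (all(w$weights == 0)) {
    .stopf("degenerate model: every signature weight is zero")
  }
  cc <- as.vector(crossprod(x, w$weights))
  raw <- .ccp_stats(cc, idx[[1L]], idx[[2L]])
  z <- .zscore_rows(x)
  ccz <- as.vector(crossprod(z, w$weights))
  zs <- .ccp_stats(ccz, idx[[1L]], idx[[2L]])
  structure(
    list(
      genes = gene_list("ccp_signature", present, normalize_case = FALSE),
      weights = stats::setNames(w$weights, present),
      threshold = raw$threshold,
      class_stats = raw,
      classes = classes,
      zscore = zs,
      gene_means = stats::setNames(rowMeans(x), present),
      dropped = dropped,
      n_flagged = w$n_flagged,
      loocv_error = NA_real_
    ),
    class = "SignatureModel"
  )
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat(sprintf(
    "SignatureModel (CCP): %d genes, classes %s | %s, threshold %.4g%s\n",
    length(x$genes), x$classes[1L], x$classes[2L], x$threshold,
    if (is.na(x$loocv_error)) "" else sprintf(", LOOCV error %.3f",
                                              x$loocv_error)
  ))
  invisible(x)
}

#' Leave-one-out cross-validated CCP error
#'
#' For every training sample, refits the weights and threshold on the
#' remaining samples and classifies the held-out sample; the returned
#' rate is errors / n. Each class needs >= 3 samples so every fold
#' retains two.
#'
#' @param train training `ExpressionMatrix`.
#' @param design two-class [sample_design()].
#' @param signature a `GeneList`.
#' @return misclassification rate (numeric scalar) with attributes
#'   `n_folds` and `errors`.
#' @export
loocv_ccp <- function(train, design, signature) {
  idx <- .design_indices(train, design, min_per_group = 3L)
  classes <- names(idx)
  sig <- intersect(.as_symbols(signature), feature_ids(train))
  if (length(sig) == 0L) .stopf("no signature gene present in training data")
  x <- train$values[sig, , drop = FALSE]
  samples <- c(idx[[1L]], idx[[2L]])
  truth <- rep(classes, times = lengths(idx))
  errors <- 0L
  for (k in seq_along(samples)) {
    hold <- samples[k]
    i1 <- setdiff(idx[[1L]], hold)
    i2 <- setdiff(idx[[2L]], hold)
    if (length(i1) < 2L || length(i2) < 2L) {
      .stopf("a leave-one-out fold leaves a class with < 2 samples")
    }
    w <- .ccp_weights(x, i1, i2)
    cc <- as.vector(crossprod(x, w$weights))
    st <- .ccp_stats(cc, i1, i2)
    pred <- if (cc[hold] >= st$threshold) classes[2L] else classes[1L]
    if (pred != truth[k]) errors <- errors + 1L
  }
  message(sprintf("loocv_ccp: %d refits performed", length(samples)))
  rate <- errors / length(samples)
  attr(rate, "n_folds") <- length(samples)
  attr(rate, "errors") <- errors
  rate
}

#' Apply a CCP model to a test cohort
#'
#' Computes compound covariates for the test cohort and stratifies it.
#' With the default `"zscore_per_cohort"` harmonization, the signature
#' gene rows of the test cohort are standardized against the test
#' cohort's own per-gene mean and sd, and compared against the model's
#' standardized-scale threshold - the minimal platform-bridging choice
#' when training and test cohorts come from different platforms. With
#' `"none"`, raw values and the raw threshold are used.
#'
#' The class probability is a Gaussian posterior with equal priors and a
#' common (pooled) within-class sd, which makes "posterior >= 0.5"
#' exactly the midpoint-threshold rule; threshold-exact samples go to
#' the second (alphabetically later) class.
#'
#' Model genes absent from the test cohort contribute at the neutral
#' value (cohort mean under z-scoring, training mean otherwise) and are
#' counted in a message.
#'
#' @param model a [fit_ccp()] model.
#' @param test test `ExpressionMatrix`.
#' @param normalization `"zscore_per_cohort"` (default) or `"none"`.
#' @param covariate optional named numeric per-sample clinical covariate
#'   (e.g. platelet count, 1e9/L) carried into the result.
#' @return a data frame of class `CohortStratification` with columns
#'   `sample_id`, `label`, `probability` (posterior probability of the
#'   second class; labels are the second class iff probability >= 0.5),
#'   and `covariate` when supplied. Attribute `classes` stores the
#'   label pair.
#' @export
apply_ccp <- function(model, test,
                      normalization = c("zscore_per_cohort", "none"),
                      covariate = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(model, "SignatureModel"),
            inherits(test, "ExpressionMatrix"))
  genes <- model$genes$symbols
  present <- intersect(genes, feature_ids(test))
  if (length(present) == 0L) .stopf("no model gene present in test cohort")
  missing <- setdiff(genes, present)
  if (length(missing)) {
    message(sprintf("apply_ccp: %d model gene(s) absent from test cohort",
                    length(missing)))
  }
  n <- ncol(test$values)
  x <- matrix(0, length(genes), n, dimnames = list(genes, sample_ids(test)))
  if (normalization == "zscore_per_cohort") {
    x[present, ] <- .zscore_rows(test$values[present, , drop = FALSE])
    stats_used <- model$zscore
  } else {
    x[present, ] <- test$values[present, , drop = FALSE]
    if (length(missing)) x[missing, ] <- model$gene_means[missing]
    stats_used <- model$class_stats
  }
  cc <- as.vector(crossprod(x, model$weights[genes]))
  sdp <- stats_used$pooled_sd
  if (!is.finite(sdp) || sdp == 0) {
    .stopf("degenerate class statistics: zero pooled sd")
  }
  ## equal-variance Gaussian posterior reduces to a logistic in c
  delta <- (stats_used$mean[2L] - stats_used$mean[1L]) / sdp^2
  prob2 <- stats::plogis(delta * (cc - stats_used$threshold))
  label <- ifelse(prob2 >= 0.5, model$classes[2L], model$classes[1L])
  out <- data.frame(sample_id = sample_ids(test), label = label,
                    probability = prob2, stringsAsFactors = FALSE)
  if (!is.null(covariate)) {
    if (is.null(names(covariate))) .stopf("covariate must be named by sample")
    out$covariate <- as.numeric(covariate[out$sample_id])
  }
  structure(out, classes = model$classes,
            normalization = normalization,
            class = c("CohortStratification", "data.frame"))
}

#' Compare a clinical covariate between predicted strata
#'
#' Pooled two-sample (Student) t-test of the covariate between the two
#' predicted groups - e.g. platelet counts between samples with and
#' without the activation signature.
#'
#' @param strat a [apply_ccp()] stratification with a `covariate` column
#'   (or supply `covariate` separately, named by sample).
#' @param covariate optional named numeric vector overriding the column.
#' @return list with `statistic` (t), `p_value`, `df`, `means` (named
#'   per-group), and `n` (per-group sizes).
#' @export
compare_groups_covariate <- function(strat, covariate = NULL) {
  stopifnot(inherits(strat, "CohortStratification"))
  if (is.null(covariate)) {
    if (is.null(strat$covariate)) .stopf("no covariate available")
    covariate <- stats::setNames(strat$covariate, strat$sample_id)
  }
  v <- as.numeric(covariate[strat$sample_id])
  classes <- attr(strat, "classes")
  g1 <- v[strat$label == classes[1L]]
  g2 <- v[strat$label == classes[2L]]
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  if (length(g1) < 2L || length(g2) < 2L) {
    .stopf("each predicted stratum needs >= 2 covariate values")
  }
  if (stats::var(g1) == 0 && stats::var(g2) == 0 && mean(g1) == mean(g2)) {
    ## degenerate but well-defined: no group difference at all
    ht <- list(statistic = 0, p.value = 1,
               parameter = length(g1) + length(g2) - 2)
  } else {
    ht <- stats::t.test(g1, g2, var.equal = TRUE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       means = stats::setNames(c(mean(g1), mean(g2)), classes),
       n = stats::setNames(c(length(g1), length(g2)), classes))
}
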