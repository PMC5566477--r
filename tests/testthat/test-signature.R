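test_that("CCP fit reproduces the hand-computed single-gene model", {
  ## class a = (0, 1), class b = (2, 3): weight t = +2.8284 (b - a),
  ## c-means 2.8284 * 0.5 and 2.8284 * 2.5, threshold = 4.2426
  fx <- two_group_matrix(c(0, 1), c(2, 3), "G1")
  model <- fit_ccp(fx$matrix, fx$design, gene_list("sig", "G1"))
  t_exp <- 2 / sqrt(0.5 * (1 / 2 + 1 / 2))
  expect_equal(unname(model$weights), t_exp, tolerance = 1e-10)
  expect_equal(model$threshold, t_exp * 1.5, tolerance = 1e-10)
  expect_equal(model$threshold, 4.2426, tolerance = 1e-4)
  expect_identical(model$classes, c("a", "b"))
  ## class 2 always sits above the threshold
  expect_gt(model$class_stats$mean[2], model$threshold)

  ## identical classes -> degenerate
  fx0 <- two_group_matrix(c(1, 2), c(1, 2), "G1")
  expect_error(fit_ccp(fx0$matrix, fx0$design, gene_list("sig", "G1")),
               "degenerate")

  ## absent signature gene dropped with a message
  expect_message(
    m2 <- fit_ccp(fx$matrix, fx$design, gene_list("sig", c("G1", "NOPE"))),
    "1 signature gene"
  )
  expect_identical(m2$dropped, 1L)
  expect_error(fit_ccp(fx$matrix, fx$design, gene_list("sig", "NOPE")),
               "no signature gene")
})

test_that("fit is invariant to sample order and gene order", {
  set.seed(61)
  m <- matrix(rnorm(8 * 20), 8,
              dimnames = list(sprintf("G%d", 1:8), sprintf("s%d", 1:20)))
  m[1:4, 11:20] <- m[1:4, 11:20] + 2
  d <- sample_design(colnames(m), rep(c("x", "y"), each = 10))
  sig <- gene_list("sig", sprintf("G%d", 1:4))
  base <- fit_ccp(expression_matrix(m), d, sig)
  perm_s <- sample(20)
  perm_g <- sample(8)
  shuf <- fit_ccp(expression_matrix(m[perm_g, perm_s]), d[perm_s], sig)
  expect_equal(shuf$weights[names(base$weights)], base$weights,
               tolerance = 1e-12)
  expect_equal(shuf$threshold, base$threshold, tolerance = 1e-12)
})

test_that("LOOCV is exact on separable data and counts its refits", {
  fx <- two_group_matrix(c(0, 0.1, 0.2), c(10, 10.1, 10.2), "G1")
  expect_message(rate <- loocv_ccp(fx$matrix, fx$design, gene_list("s", "G1")),
                 "6 refits")
  expect_identical(as.numeric(rate), 0)
  expect_identical(attr(rate, "n_folds"), 6L)
})

test_that("LOOCV concentrates near 0.5 under label permutation", {
  set.seed(62)
  sig <- gene_list("sig", sprintf("SG%02d", 1:20))
  coh <- simulate_cohorts(sig, n_train = 40, n_test = 8, class_effect = 2,
                          seed = 62)
  rates <- vapply(1:30, function(i) {
    d <- sample_design(names(coh$train_design),
                       sample(unclass(coh$train_design)))
    as.numeric(suppressMessages(loocv_ccp(coh$train, d, sig)))
  }, numeric(1))
  expect_gt(mean(rates), 0.40)
  expect_lt(mean(rates), 0.60)
})

test_that("application classifies centroids, boundaries, and scales correctly", {
  fx <- two_group_matrix(c(0, 1), c(2, 3), "G1")
  model <- fit_ccp(fx$matrix, fx$design, gene_list("sig", "G1"))
  mk_test <- function(vals) {
    expression_matrix(matrix(vals, 1,
                             dimnames = list("G1", sprintf("t%d", seq_along(vals)))))
  }
  ## class-1 centroid (0.5), boundary sample (1.5), class-2 centroid (2.5)
  strat <- apply_ccp(model, mk_test(c(0.5, 1.5, 2.5)), normalization = "none")
  expect_identical(strat$label, c("a", "b", "b"))    # boundary -> class 2
  expect_lt(strat$probability[1], 0.5)
  expect_equal(strat$probability[2], 0.5, tolerance = 1e-12)
  expect_gt(strat$probability[3], 0.5)

  ## positive rescaling of all expression never changes labels
  set.seed(63)
  vals <- rnorm(50, 1.5, 2)
  s1 <- apply_ccp(model, mk_test(vals), normalization = "none")
  model_scaled <- fit_ccp(
    expression_matrix(fx$matrix$values * 7), fx$design, gene_list("sig", "G1")
  )
  s2 <- apply_ccp(model_scaled, mk_test(vals * 7), normalization = "none")
  expect_identical(s1$label, s2$label)
  ## z-scored application is itself scale-free
  z1 <- apply_ccp(model, mk_test(vals))
  z2 <- apply_ccp(model_scaled, mk_test(vals * 7))
  expect_equal(z1$probability, z2$probability, tolerance = 1e-12)

  expect_error(apply_ccp(model, expression_matrix(
    matrix(1, 1, 2, dimnames = list("OTHER", c("t1", "t2")))
  )), "no model gene")
})

test_that("synthetic cohorts are recovered at high accuracy", {
  sig <- gene_list("sig", sprintf("SG%02d", 1:50))
  coh <- simulate_cohorts(sig, n_train = 40, n_test = 200, class_effect = 2,
                          covariate_shift = 1, seed = 64)
  model <- fit_ccp(coh$train, coh$train_design, sig)
  strat <- apply_ccp(model, coh$test, covariate = coh$covariate)
  acc <- mean(strat$label == coh$truth$true_classes[strat$sample_id])
  expect_gte(acc, 0.95)
  cmp <- compare_groups_covariate(strat)
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$means[["active"]], cmp$means[["inactive"]])
})

test_that("covariate comparison matches the pooled-t hand computation", {
  strat <- structure(
    data.frame(sample_id = sprintf("s%d", 1:4),
               label = c("a", "a", "b", "b"),
               probability = c(0.1, 0.2, 0.9, 0.8),
               covariate = c(300, 310, 450, 460)),
    classes = c("a", "b"),
    class = c("CohortStratification", "data.frame")
  )
  cmp <- compare_groups_covariate(strat)
  expect_equal(abs(cmp$statistic), 21.2132, tolerance = 1e-4)
  expect_equal(unname(cmp$means), c(305, 455))

  strat$covariate <- rep(5, 4)
  same <- compare_groups_covariate(strat)
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  strat2 <- strat[-1, ]
  attr(strat2, "classes") <- c("a", "b")
  class(strat2) <- c("CohortStratification", "data.frame")
  expect_error(compare_groups_covariate(strat2), ">= 2")
})
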