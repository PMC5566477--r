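test_that("simulated network plants the axis and is seed-deterministic", {
  sim <- simulate_network(n_nodes = 500, n_pathways = 20, path_length = 3,
                          deg_cluster_size = 10, seed = 1)
  net <- build_union_network(sim$collection)
  truth <- sim$truth
  expect_length(truth$planted_path, 15)
  expect_true(all(truth$planted_path %in% net$nodes))
  ## planted edges present: chain S - c1 - ... - hub, hub - each DEG
  path <- c(truth$seed_protein, truth$signaling, truth$hub)
  ekey <- paste(net$edges$from, net$edges$to)
  has_edge <- function(a, b) {
    paste(pmin(a, b), pmax(a, b)) %in% ekey
  }
  for (i in seq_len(length(path) - 1)) {
    expect_true(has_edge(path[i], path[i + 1]))
  }
  expect_true(all(has_edge(truth$hub, truth$true_degs$symbols)))
  ## seed and chain only touch the planted axis
  axis_nodes <- c(truth$seed_protein, truth$signaling)
  touching <- net$edges$from %in% axis_nodes | net$edges$to %in% axis_nodes
  prov <- unique(unlist(net$edges$provenance[touching]))
  expect_identical(prov, "planted_axis")

  again <- simulate_network(seed = 1)
  expect_identical(again$collection, sim$collection)
  other <- simulate_network(seed = 2)
  expect_false(identical(other$collection, sim$collection))
})

test_that("expression generator plants detectable shifts and is deterministic", {
  genes <- gene_list("g", sprintf("G%03d", 1:400))
  de <- gene_list("de", sprintf("G%03d", 1:10))
  sim <- simulate_expression(genes, n_per_group = 10, de_genes = de,
                             effect = 3, seed = 3)
  expect_identical(dim(sim$matrix), c(400L, 20L))
  res <- two_sample_ttest_table(sim$matrix, sim$design)
  hits <- select_significant(res, "fdr", 0.05)$symbols
  expect_gte(mean(de$symbols %in% hits), 0.99)
  ## DE genes shift in the stated direction
  expect_true(all(res$effect[1:10] > 1))

  again <- simulate_expression(genes, n_per_group = 10, de_genes = de,
                               effect = 3, seed = 3)
  expect_identical(again$matrix$values, sim$matrix$values)

  null <- simulate_expression(genes, n_per_group = 10, effect = 0, seed = 4)
  nres <- two_sample_ttest_table(null$matrix, null$design)
  frac <- mean(nres$p_value < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
  expect_error(simulate_expression(genes, de_genes = gene_list("x", "NOPE")),
               "subset")
})

test_that("protein generator shifts only the designated DRP", {
  panel <- gene_list("panel", sprintf("P%02d", 1:20))
  sim <- simulate_rppa(panel, "P01", n_per_group = 4, effect = -3, seed = 5)
  expect_identical(sim$matrix$platform_tag, "rppa")
  res <- group_ftest_table(sim$matrix, sim$design)
  expect_true("P01" %in% selected_features(res))
  expect_lt(res$effect[res$feature_id == "P01"], 0)  # downshifted
  expect_error(simulate_rppa(panel, "NOPE"), "absent")
  expect_identical(simulate_rppa(panel, "P01", seed = 6)$matrix$values,
                   simulate_rppa(panel, "P01", seed = 6)$matrix$values)
})

test_that("cohort generator links classes to signature and covariate", {
  sig <- gene_list("sig", sprintf("SG%02d", 1:30))
  coh <- simulate_cohorts(sig, n_train = 20, n_test = 60, class_effect = 2,
                          covariate_shift = 1, seed = 7)
  expect_identical(dim(coh$train), c(60L, 20L))  # signature + background rows
  expect_identical(sort(unique(unclass(coh$train_design))),
                   c("active", "inactive"))
  active <- names(coh$truth$true_classes)[coh$truth$true_classes == "active"]
  inactive <- setdiff(names(coh$truth$true_classes), active)
  gap <- mean(coh$test$values[sig$symbols, active]) -
    mean(coh$test$values[sig$symbols, inactive])
  expect_gt(gap, 1.5)
  expect_gt(mean(coh$covariate[active]) - mean(coh$covariate[inactive]), 20)
  again <- simulate_cohorts(sig, n_train = 20, n_test = 60, class_effect = 2,
                            covariate_shift = 1, seed = 7)
  expect_identical(again$covariate, coh$covariate)
})

test_that("survival generator plants the changepoint and hits the censor rate", {
  sim <- simulate_survival(n = 2000, hazard_ratio = 3,
                           changepoint_percentile = 40, censor_rate = 0.3,
                           seed = 8)
  d <- sim$data
  expect_true(all(d$time >= 0))
  expect_true(all(d$event %in% c(0, 1)))
  cens <- mean(d$event == 0)
  expect_gt(cens, 0.2)
  expect_lt(cens, 0.4)
  hi <- d$marker > sim$truth$changepoint_value
  ## empirical event rate above the changepoint is markedly higher
  expect_gt(sum(d$event[hi]) / sum(d$time[hi]),
            2 * sum(d$event[!hi]) / sum(d$time[!hi]))
  expect_error(simulate_survival(changepoint_percentile = 0), "0, 100")
  expect_error(simulate_survival(censor_rate = 1), "censor_rate")
})

test_that("generated matrices round-trip losslessly through the writers", {
  sim <- simulate_expression(gene_list("g", sprintf("G%02d", 1:12)),
                             n_per_group = 3, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(sim$matrix, path)
  back <- read_expression_matrix(path, "microarray")
  expect_lt(max(abs(back$values - sim$matrix$values)), 1e-12)
  expect_identical(feature_ids(back), feature_ids(sim$matrix))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_network(seed = 99))
  after <- runif(1)
  expect_identical(before, after)
})
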