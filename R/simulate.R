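## Synthetic-data generators with planted ground truth. Every stage of
## the pipeline can be exercised, and benchmarked against known truth,
## without any external download. All generators are deterministic
## under their `seed` and return a `SyntheticTruth` record alongside
## the data.

.truth <- function(...) structure(list(...), class = "SyntheticTruth")

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a pathway collection with a planted crosstalk axis
#'
#' Background: `n_pathways` random connected pathways (a random spanning
#' tree per pathway plus extra edges) over a shared symbol pool.
#' Planted structure: a seed protein S, a chain of `path_length`
#' signaling nodes, a hub, and `deg_cluster_size` DEG-cluster genes,
#' wired S - chain - hub - cluster and stored as its own pathway. The
#' seed and the chain belong only to the planted axis (they model a
#' phospho-protein and signaling intermediates that transcript-level
#' pathway projections touch once), while the hub and the DEG genes are
#' also eligible for background pathways - this keeps the planted truth
#' identifiable, so benchmark failures indict the method rather than an
#' unrecoverable instance.
#'
#' @param n_nodes symbol pool size (default 500).
#' @param n_pathways background pathways (default 20).
#' @param pathway_size nodes per background pathway (default 15; each
#'   contributes `pathway_size - 1` tree edges plus
#'   `ceiling(pathway_size/2)` extra edges before deduplication).
#' @param path_length signaling-chain length (default 3).
#' @param deg_cluster_size DEG cluster size (default 10).
#' @param seed RNG seed.
#' @return list with `collection` (a `PathwayCollection` including the
#'   `planted_axis` pathway) and `truth` (`SyntheticTruth` with
#'   `seed_protein`, `signaling`, `hub`, `true_degs`, `planted_path`).
#' @export
simulate_network <- function(n_nodes = 500L, n_pathways = 20L,
                             pathway_size = 15L, path_length = 3L,
                             deg_cluster_size = 10L, seed = 1L) {
  n_planted <- 1L + path_length + 1L + deg_cluster_size
  if (path_length < 1L) .stopf("path_length must be >= 1")
  if (n_nodes < n_planted + pathway_size) {
    .stopf("n_nodes too small for the requested structure")
  }
  .with_seed(seed, {
    width <- max(4L, nchar(as.character(n_nodes)))
    nodes <- sprintf(paste0("G%0", width, "d"), seq_len(n_nodes))
    planted <- sample(nodes, n_planted)
    s <- planted[1L]
    chain <- planted[seq(2L, 1L + path_length)]
    hub <- planted[path_length + 2L]
    degs <- planted[seq(path_length + 3L, n_planted)]
    axis <- cbind(c(s, chain), c(chain, hub))
    axis <- rbind(axis, cbind(hub, degs))
    colnames(axis) <- c("from", "to")
    pool <- setdiff(nodes, c(s, chain))
    pw <- vector("list", n_pathways)
    for (i in seq_len(n_pathways)) {
      v <- sample(pool, pathway_size)
      parents <- vapply(seq(2L, pathway_size),
                        function(j) v[sample.int(j - 1L, 1L)], character(1L))
      tree <- cbind(v[seq(2L, pathway_size)], parents)
      n_extra <- ceiling(pathway_size / 2)
      extra <- t(replicate(n_extra, sample(v, 2L)))
      pw[[i]] <- .dedup_edges(rbind(tree, extra))
    }
    names(pw) <- sprintf("pathway_%02d", seq_len(n_pathways))
    collection <- structure(
      c(list(planted_axis = .dedup_edges(axis)), pw),
      class = "PathwayCollection"
    )
    list(
      collection = collection,
      truth = .truth(
        seed_protein = s, signaling = chain, hub = hub,
        true_degs = gene_list("true_degs", degs, normalize_case = FALSE),
        true_drps = gene_list("true_drps", s, normalize_case = FALSE),
        planted_path = c(s, chain, hub, degs),
        rng_seed = as.integer(seed)
      )
    )
  })
}

#' Simulate a two-condition expression matrix
#'
#' Gaussian background N(0, noise_sd^2); the genes in `de_genes` are
#' shifted by `effect * noise_sd` in the second group. The default
#' group size mirrors a triplicate co-incubation design.
#'
#' @param genes a `GeneList` (or character vector) of gene symbols.
#' @param n_per_group samples per group (default 3).
#' @param de_genes genes carrying the shift (subset of `genes`); `NULL`
#'   for a null matrix.
#' @param effect shift in units of `noise_sd` (default 3).
#' @param noise_sd Gaussian noise sd (default 1).
#' @param seed RNG seed.
#' @param group_labels two labels, reference first
#'   (default `c("control", "platelet")`).
#' @return list with `matrix` (`ExpressionMatrix`), `design`
#'   (`SampleDesign`), `truth`.
#' @export
simulate_expression <- function(genes, n_per_group = 3L, de_genes = NULL,
                                effect = 3, noise_sd = 1, seed = 1L,
                                group_labels = c("control", "platelet")) {
  syms <- .as_symbols(genes)
  de <- if (is.null(de_genes)) character(0L) else .as_symbols(de_genes)
  if (!all(de %in% syms)) .stopf("de_genes must be a subset of genes")
  if (n_per_group < 2L) .stopf("need >= 2 samples per group")
  .with_seed(seed, {
    n <- 2L * n_per_group
    ids <- c(sprintf("%s_%02d", group_labels[1L], seq_len(n_per_group)),
             sprintf("%s_%02d", group_labels[2L], seq_len(n_per_group)))
    m <- matrix(stats::rnorm(length(syms) * n, 0, noise_sd),
                length(syms), n, dimnames = list(syms, ids))
    g2 <- seq(n_per_group + 1L, n)
    m[de, g2] <- m[de, g2] + effect * noise_sd
    list(
      matrix = expression_matrix(m, "microarray", normalize_case = FALSE),
      design = sample_design(ids, rep(group_labels, each = n_per_group)),
      truth = .truth(
        true_degs = if (length(de)) {
          gene_list("true_degs", de, normalize_case = FALSE)
        },
        effect = effect, noise_sd = noise_sd, rng_seed = as.integer(seed)
      )
    )
  })
}

#' Simulate a two-condition protein array
#'
#' Only the designated protein carries the group effect (negative by
#' default, mimicking a dephosphorylation read-out); every other
#' antibody is null. Defaults mirror a duplicate-array design.
#'
#' @param proteins panel symbols (`GeneList` or character).
#' @param drp the differentially regulated protein (must be in the
#'   panel).
#' @param n_per_group samples per group (default 2).
#' @param effect shift in noise-sd units (default -3).
#' @param noise_sd Gaussian noise sd (default 1).
#' @param seed RNG seed.
#' @param group_labels two labels, reference first.
#' @return list with `matrix` (`ExpressionMatrix`, platform `"rppa"`),
#'   `design`, `truth`.
#' @export
simulate_rppa <- function(proteins, drp, n_per_group = 2L, effect = -3,
                          noise_sd = 1, seed = 1L,
                          group_labels = c("control", "platelet")) {
  syms <- .as_symbols(proteins)
  drp <- .norm_symbols(drp)
  if (!drp %in% syms) .stopf("drp '%s' absent from the protein panel", drp)
  .with_seed(seed, {
    n <- 2L * n_per_group
    ids <- c(sprintf("%s_%02d", group_labels[1L], seq_len(n_per_group)),
             sprintf("%s_%02d", group_labels[2L], seq_len(n_per_group)))
    m <- matrix(stats::rnorm(length(syms) * n, 0, noise_sd),
                length(syms), n, dimnames = list(syms, ids))
    g2 <- seq(n_per_group + 1L, n)
    m[drp, g2] <- m[drp, g2] + effect * noise_sd
    list(
      matrix = expression_matrix(m, "rppa", normalize_case = FALSE),
      design = sample_design(ids, rep(group_labels, each = n_per_group)),
      truth = .truth(
        true_drps = gene_list("true_drps", drp, normalize_case = FALSE),
        effect = effect, rng_seed = as.integer(seed)
      )
    )
  })
}

#' Simulate training/test cohorts for the signature classifier
#'
#' Two cohorts from the same generative model: signature genes are
#' shifted by `class_effect` (in noise-sd units) in the "active" class;
#' an equal number of background genes is null everywhere. The test
#' cohort carries a clinical covariate resembling platelet counts
#' (1e9/L): N(mu + covariate_shift * sigma, sigma^2) for true-active
#' samples, N(mu, sigma^2) otherwise.
#'
#' @param signature signature `GeneList` (or character).
#' @param n_train,n_test cohort sizes (default 40 / 200), split evenly
#'   between classes.
#' @param class_effect signature shift in sd units (default 2).
#' @param covariate_shift covariate shift in covariate-sd units
#'   (default 1).
#' @param seed RNG seed.
#' @param covariate_mean,covariate_sd covariate moments (defaults 300
#'   and 80, platelet-count-like).
#' @param class_labels class pair, inactive first
#'   (default `c("inactive", "active")` - note labels sort so that
#'   "active" is the second class).
#' @return list with `train`, `train_design`, `test` (matrices/design),
#'   `covariate` (named numeric over test samples), `truth`
#'   (`true_classes` for the test cohort, shifts, seed).
#' @export
simulate_cohorts <- function(signature, n_train = 40L, n_test = 200L,
                             class_effect = 2, covariate_shift = 1,
                             seed = 1L, covariate_mean = 300,
                             covariate_sd = 80,
                             class_labels = c("inactive", "active")) {
  syms <- .as_symbols(signature)
  if (n_train < 8L || n_test < 8L) .stopf("need >= 4 samples per class")
  .with_seed(seed, {
    n_bg <- length(syms)
    width <- max(4L, nchar(as.character(n_bg)))
    bg <- sprintf(paste0("BG%0", width, "d"), seq_len(n_bg))
    genes <- c(syms, bg)

    gen_cohort <- function(n, prefix) {
      n_act <- n %/% 2L
      cls <- rep(class_labels, times = c(n - n_act, n_act))
      ids <- sprintf("%s_%03d", prefix, seq_len(n))
      m <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                  dimnames = list(genes, ids))
      act <- which(cls == class_labels[2L])
      m[syms, act] <- m[syms, act] + class_effect
      list(matrix = expression_matrix(m, "microarray",
                                      normalize_case = FALSE),
           classes = stats::setNames(cls, ids))
    }

    tr <- gen_cohort(n_train, "train")
    te <- gen_cohort(n_test, "test")
    active <- te$classes == class_labels[2L]
    covariate <- stats::rnorm(
      n_test,
      covariate_mean + ifelse(active, covariate_shift * covariate_sd, 0),
      covariate_sd
    )
    names(covariate) <- names(te$classes)
    list(
      train = tr$matrix,
      train_design = sample_design(names(tr$classes), tr$classes),
      test = te$matrix,
      covariate = covariate,
      truth = .truth(
        true_classes = te$classes, class_effect = class_effect,
        covariate_shift = covariate_shift, rng_seed = as.integer(seed)
      )
    )
  })
}

#' Simulate censored survival data with a marker changepoint
#'
#' Marker ~ Uniform(0, 1); event times are exponential with the hazard
#' multiplied by `hazard_ratio` above the marker's changepoint
#' percentile; independent exponential censoring is calibrated to an
#' approximate overall censoring fraction.
#'
#' @param n subjects (default 200).
#' @param hazard_ratio hazard multiplier above the changepoint
#'   (default 3).
#' @param changepoint_percentile marker percentile of the true
#'   changepoint, in (0, 100) (default 40).
#' @param censor_rate approximate fraction censored (default 0.3).
#' @param baseline_hazard events per month below the changepoint
#'   (default 0.05).
#' @param seed RNG seed.
#' @return list with `data` (a [survival_data()] frame with marker) and
#'   `truth` (`changepoint_percentile`, `changepoint_value`,
#'   `hazard_ratio`, seed).
#' @export
simulate_survival <- function(n = 200L, hazard_ratio = 3,
                              changepoint_percentile = 40,
                              censor_rate = 0.3, baseline_hazard = 0.05,
                              seed = 1L) {
  if (changepoint_percentile <= 0 || changepoint_percentile >= 100) {
    .stopf("changepoint_percentile must lie in (0, 100)")
  }
  if (censor_rate < 0 || censor_rate >= 1) .stopf("invalid censor_rate")
  if (hazard_ratio <= 0) .stopf("hazard_ratio must be positive")
  .with_seed(seed, {
    marker <- stats::runif(n)
    cp <- stats::quantile(marker, changepoint_percentile / 100, type = 7,
                          names = FALSE)
    rate <- baseline_hazard * ifelse(marker > cp, hazard_ratio, 1)
    t_event <- stats::rexp(n, rate)
    frac_hi <- mean(marker > cp)
    mean_rate <- baseline_hazard * ((1 - frac_hi) + frac_hi * hazard_ratio)
    out_time <- t_event
    status <- rep(1L, n)
    if (censor_rate > 0) {
      c_rate <- mean_rate * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n, c_rate)
      status <- as.integer(t_event <= t_cens)
      out_time <- pmin(t_event, t_cens)
    }
    list(
      data = survival_data(sprintf("pt_%03d", seq_len(n)), out_time,
                           status, marker),
      truth = .truth(
        changepoint_percentile = changepoint_percentile,
        changepoint_value = cp, hazard_ratio = hazard_ratio,
        censor_rate = censor_rate, rng_seed = as.integer(seed)
      )
    )
  })
}
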