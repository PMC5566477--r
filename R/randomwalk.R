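## The core computation: an FDR-weighted random walk started from the
## differentially regulated proteins (DRPs) over the pathway union
## network. Transition probabilities are p_ij = a_ij * q_j / sum_j a_ij
## * q_j, where a_ij is the 0/1 adjacency and q_j a per-node weight
## derived from the per-gene FDR. The walk iterates
## g_n = (1 - r) * g_{n-1} P + r * g_0 until the step norm drops below
## `tol`; r = 0 reproduces the plain power iteration g_n = g_{n-1} P.

#' Random-walk configuration
#'
#' @param tol convergence threshold on the step norm (default `1e-5`).
#' @param k_top number of top-probability genes to keep (default 50).
#' @param restart restart probability r in \[0, 1); 0 (default) is the
#'   plain power iteration. Note that with r = 0 an ergodic chain
#'   forgets its seeds: the result is the stationary distribution of P
#'   regardless of g0. A positive restart keeps the result anchored to
#'   the seed proteins.
#' @param max_iter iteration cap (default 10000).
#' @param weight_mode `"one_minus_fdr"` (default): q_j = max(1 - FDR_j,
#'   floor), sending the walk toward significant genes; `"fdr"`: the
#'   literal q_j = max(FDR_j, floor).
#' @param weight_floor minimum weight applied to every node (default
#'   0.01) so unmeasured connector nodes stay reachable.
#' @param force_include_seeds append absent seed proteins to the top-k
#'   list (flagged) instead of letting them compete on probability
#'   (default `FALSE`).
#' @param norm `"l1"` (default) or `"linf"` step norm.
#' @param strict treat iteration-cap exhaustion as an error instead of a
#'   flagged result (default `FALSE`).
#' @return a list of class `WalkConfig`.
#' @export
walk_config <- function(tol = 1e-5, k_top = 50L, restart = 0,
                        max_iter = 10000L,
                        weight_mode = c("one_minus_fdr", "fdr"),
                        weight_floor = 0.01,
                        force_include_seeds = FALSE,
                        norm = c("l1", "linf"),
                        strict = FALSE) {
  weight_mode <- match.arg(weight_mode)
  norm <- match.arg(norm)
  stopifnot(tol > 0, k_top >= 1L, restart >= 0, restart < 1,
            max_iter >= 1L, weight_floor > 0)
  structure(
    list(tol = tol, k_top = as.integer(k_top), restart = restart,
         max_iter = as.integer(max_iter), weight_mode = weight_mode,
         weight_floor = weight_floor,
         force_include_seeds = force_include_seeds,
         norm = norm, strict = strict),
    class = "WalkConfig"
  )
}

#' Node weights from per-gene FDR
#'
#' In the default `"one_minus_fdr"` mode q_j = max(1 - FDR_j, floor) and
#' network nodes without a measured FDR get the floor; in the literal
#' `"fdr"` mode q_j = max(FDR_j, floor) and unmeasured nodes get 1.
#'
#' @param net a `GeneNetwork`.
#' @param degs a `DifferentialResult` with a populated `fdr` column (or
#'   a named numeric vector of FDR values).
#' @param config a [walk_config()].
#' @return named numeric vector over `net$nodes`, class `NodeWeights`,
#'   with attributes `mode` and `floor`.
#' @export
compute_node_weights <- function(net, degs, config = walk_config()) {
  stopifnot(inherits(net, "GeneNetwork"))
  if (inherits(degs, "DifferentialResult")) {
    ok <- !degs$flagged & !is.na(degs$fdr)
    if (!any(ok)) .stopf("degs carries no populated fdr column")
    fdr <- stats::setNames(degs$fdr[ok], degs$feature_id[ok])
  } else {
    fdr <- degs
    if (is.null(names(fdr))) .stopf("fdr vector must be named by gene")
  }
  if (any(fdr < 0 | fdr > 1)) .stopf("FDR values must lie in [0, 1]")
  floor_ <- config$weight_floor
  q <- if (config$weight_mode == "one_minus_fdr") {
    stats::setNames(rep(floor_, length(net$nodes)), net$nodes)
  } else {
    stats::setNames(rep(1, length(net$nodes)), net$nodes)
  }
  hit <- intersect(net$nodes, names(fdr))
  q[hit] <- if (config$weight_mode == "one_minus_fdr") {
    pmax(1 - fdr[hit], floor_)
  } else {
    pmax(fdr[hit], floor_)
  }
  structure(q, mode = config$weight_mode, floor = floor_,
            class = "NodeWeights")
}

#' Row-stochastic transition matrix
#'
#' p_ij = a_ij * q_j / sum_j a_ij * q_j for rows with neighbors; isolated
#' (degree-0) nodes get a unit self-loop so stochasticity is preserved
#' without teleporting mass. Rows are renormalized exactly.
#'
#' @param net a `GeneNetwork`.
#' @param weights a [compute_node_weights()] result covering all nodes.
#' @return a list of class `TransitionMatrix` with fields `p` (matrix),
#'   `nodes`, and `isolated` (logical).
#' @export
build_transition <- function(net, weights) {
  stopifnot(inherits(net, "GeneNetwork"))
  if (!all(net$nodes %in% names(weights))) {
    .stopf("weights must cover every network node")
  }
  a <- adjacency_matrix(net)
  q <- as.numeric(weights[net$nodes])
  w <- a * rep(q, each = length(q))      # w_ij = a_ij * q_j
  rs <- rowSums(w)
  isolated <- rs == 0
  p <- w / ifelse(rs == 0, 1, rs)
  if (any(isolated)) p[cbind(which(isolated), which(isolated))] <- 1
  p <- p / rowSums(p)                    # exact renormalization
  structure(list(p = p, nodes = net$nodes, isolated = isolated),
            class = "TransitionMatrix")
}

#' Uniform seed vector over mapped DRPs
#'
#' Equal probability on every seed protein present in the network, zero
#' elsewhere. Seeds absent from the network are reported; if none maps,
#' an error lists the unmapped symbols.
#'
#' @param net a `GeneNetwork`.
#' @param drps a `GeneList` or character vector of seed proteins.
#' @return named numeric probability vector over `net$nodes`.
#' @export
seed_vector <- function(net, drps) {
  stopifnot(inherits(net, "GeneNetwork"))
  drps <- .as_symbols(drps)
  mapped <- intersect(drps, net$nodes)
  unmapped <- setdiff(drps, net$nodes)
  if (length(mapped) == 0L) {
    .stopf("no DRP maps to the network; unmapped: %s",
           paste(unmapped, collapse = ", "))
  }
  if (length(unmapped)) {
    message(sprintf("seed_vector: %d DRP(s) not in network: %s",
                    length(unmapped), paste(unmapped, collapse = ", ")))
  }
  g0 <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  g0[mapped] <- 1 / length(mapped)
  g0
}

#' Propagate the random walk to convergence
#'
#' Iterates g <- (1 - r) * g P + r * g0 from `g0` until the step norm
#' falls below `config$tol` or `config$max_iter` is reached. Failure to
#' converge (e.g. the period-2 oscillation of a bipartite graph at
#' r = 0) is reported through `converged = FALSE`, or as an error in
#' strict mode with the advice to use a positive restart.
#'
#' @param P a [build_transition()] result (or a bare row-stochastic
#'   matrix).
#' @param g0 probability vector on the simplex (rows of `P` order).
#' @param config a [walk_config()].
#' @return a list of class `WalkResult` with `g`, `g0`, `iterations`,
#'   `converged`, and the `config` used. Top-k/component fields are
#'   filled by [random_walk()] / [extract_crosstalk()].
#' @export
propagate <- function(P, g0, config = walk_config()) {
  p <- if (inherits(P, "TransitionMatrix")) P$p else P
  stopifnot(is.matrix(p), nrow(p) == ncol(p), length(g0) == nrow(p))
  if (any(g0 < 0) || abs(sum(g0) - 1) > 1e-8) {
    .stopf("g0 must be a probability vector")
  }
  if (is.null(names(g0)) && !is.null(rownames(p))) names(g0) <- rownames(p)
  r <- config$restart
  g <- g0
  converged <- FALSE
  iterations <- 0L
  for (i in seq_len(config$max_iter)) {
    gn <- as.vector(g %*% p)
    if (r > 0) gn <- (1 - r) * gn + r * g0
    step <- if (config$norm == "l1") sum(abs(gn - g)) else max(abs(gn - g))
    g <- gn
    iterations <- i
    if (step < config$tol) {
      converged <- TRUE
      break
    }
  }
  names(g) <- names(g0)
  if (!converged) {
    msg <- sprintf(
      "walk did not converge in %d iterations (use restart > 0 or a lazy step)",
      config$max_iter
    )
    if (config$strict) .stopf("%s", msg) else .warnf("%s", msg)
  }
  structure(
    list(g = g, g0 = g0, iterations = iterations, converged = converged,
         config = config, seeds = names(g0)[g0 > 0],
         top_nodes = NULL, component = NULL, connector_drps = NULL,
         node_classes = NULL),
    class = "WalkResult"
  )
}

#' @export
print.WalkResult <- function(x, ...) {
  cat(sprintf(
    "WalkResult: %d nodes, %d iterations (%s)\n", length(x$g),
    x$iterations, if (x$converged) "converged" else "NOT converged"
  ))
  if (!is.null(x$component)) {
    cat(sprintf("  crosstalk component: %d nodes; connector DRPs: %s\n",
                length(x$component$nodes),
                if (length(x$connector_drps)) {
                  paste(x$connector_drps, collapse = ", ")
                } else "none"))
  }
  invisible(x)
}

#' Top-k nodes by walk probability
#'
#' Nodes sorted by probability descending with ties broken by ascending
#' symbol; the first `k` are returned. With `force_include_seeds`, seeds
#' missing from the top-k are appended beyond k and flagged in the
#' `forced` attribute.
#'
#' @param result a `WalkResult` (or named probability vector).
#' @param k number of nodes (default the config's `k_top`).
#' @param seeds optional seed symbols for `force_include_seeds`.
#' @param force_include_seeds append absent seeds (default from config).
#' @return a `GeneList` named `"top_k"`.
#' @export
top_k_nodes <- function(result, k = NULL, seeds = NULL,
                        force_include_seeds = NULL) {
  if (inherits(result, "WalkResult")) {
    g <- result$g
    if (is.null(k)) k <- result$config$k_top
    if (is.null(seeds)) seeds <- result$seeds
    if (is.null(force_include_seeds)) {
      force_include_seeds <- result$config$force_include_seeds
    }
  } else {
    g <- result
    if (is.null(k)) .stopf("`k` required for a bare probability vector")
    if (is.null(force_include_seeds)) force_include_seeds <- FALSE
  }
  if (k > length(g)) .stopf("k = %d exceeds node count %d", k, length(g))
  ord <- order(-g, names(g))
  top <- names(g)[ord][seq_len(k)]
  forced <- character(0L)
  if (isTRUE(force_include_seeds) && length(seeds)) {
    forced <- setdiff(intersect(seeds, names(g)), top)
    top <- c(top, forced)
  }
  out <- gene_list("top_k", top, normalize_case = FALSE)
  attr(out, "forced") <- forced
  out
}

#' Extract the crosstalk component
#'
#' Induces the subgraph of the background network on the top-k genes and
#' takes its major connected component (walk-probability tie-break); the
#' component is read as the signaling route between the seed proteins
#' and the transcriptional changes. Seeds inside the component are the
#' connector DRPs. Node classes mirror the figure roles: `seed_drp`,
#' `receptor`, `transcription_factor`, `deg` (selected DEGs), and
#' `signaling` for everything else.
#'
#' @param net the background `GeneNetwork`.
#' @param top `GeneList` of top walk genes.
#' @param seeds seed DRP symbols.
#' @param degs selected DEG symbols (a `GeneList`, character vector, or
#'   a `DifferentialResult` whose selected set is used). Optional.
#' @param receptors,tfs optional `GeneList`s of node classes.
#' @param probabilities optional named walk probabilities for the
#'   component tie-break.
#' @return list with `component` (`GeneNetwork`), `connector_drps`
#'   (character), `node_classes` (named character over component nodes),
#'   and `empty` flag.
#' @export
extract_crosstalk <- function(net, top, seeds, degs = NULL,
                              receptors = NULL, tfs = NULL,
                              probabilities = NULL) {
  top_syms <- .as_symbols(top)
  if (length(top_syms) == 0L) .stopf("top gene list is empty")
  seeds <- .as_symbols(seeds)
  deg_syms <- if (is.null(degs)) {
    character(0L)
  } else if (inherits(degs, "DifferentialResult")) {
    selected_features(degs)
  } else {
    .as_symbols(degs)
  }
  sub <- suppressWarnings(induced_subgraph(net, top_syms))
  if (length(sub$nodes) == 0L || nrow(sub$edges) == 0L) {
    return(list(component = .gene_network(sub$edges[0L, , drop = FALSE]),
                connector_drps = character(0L),
                node_classes = stats::setNames(character(0L), character(0L)),
                empty = TRUE))
  }
  comp <- largest_component(sub, probabilities = probabilities)
  cls <- stats::setNames(rep("signaling", length(comp$nodes)), comp$nodes)
  cls[comp$nodes %in% deg_syms] <- "deg"
  if (!is.null(tfs)) cls[comp$nodes %in% .as_symbols(tfs)] <- "transcription_factor"
  if (!is.null(receptors)) cls[comp$nodes %in% .as_symbols(receptors)] <- "receptor"
  cls[comp$nodes %in% seeds] <- "seed_drp"
  list(component = comp,
       connector_drps = intersect(seeds, comp$nodes),
       node_classes = cls,
       empty = FALSE)
}

#' Run the full FDR-weighted random walk
#'
#' Convenience wrapper chaining [compute_node_weights()],
#' [build_transition()], [seed_vector()], [propagate()],
#' [top_k_nodes()] and [extract_crosstalk()] into one complete
#' `WalkResult`.
#'
#' @param net background `GeneNetwork`.
#' @param seeds DRP `GeneList` or symbols.
#' @param degs `DifferentialResult` with populated `fdr` (or named FDR
#'   vector).
#' @param config a [walk_config()].
#' @param deg_list selected DEG symbols for node classification
#'   (defaults to `degs`' selected set, if any).
#' @param receptors,tfs optional class lists.
#' @return a complete `WalkResult`.
#' @export
random_walk <- function(net, seeds, degs, config = walk_config(),
                        deg_list = NULL, receptors = NULL, tfs = NULL) {
  weights <- compute_node_weights(net, degs, config)
  P <- build_transition(net, weights)
  g0 <- seed_vector(net, seeds)
  res <- propagate(P, g0, config)
  res$top_nodes <- top_k_nodes(res)
  if (is.null(deg_list) && inherits(degs, "DifferentialResult")) {
    deg_list <- selected_features(degs)
  }
  ext <- extract_crosstalk(net, res$top_nodes, .as_symbols(seeds),
                           degs = deg_list, receptors = receptors,
                           tfs = tfs, probabilities = res$g)
  res$component <- ext$component
  res$connector_drps <- ext$connector_drps
  res$node_classes <- ext$node_classes
  res
}
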