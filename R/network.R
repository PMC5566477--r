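## Background gene network: union of pathway edge sets, with
## component/subgraph utilities. Edges are undirected and unweighted
## (the transition formula multiplies the 0/1 adjacency by node weights,
## so topology alone lives here); nodes are kept lexicographically
## sorted so matrix orderings and tie-breaks are reproducible.

.gene_network <- function(edges, nodes = character(0L),
                          provenance = NULL) {
  if (nrow(edges)) {
    e <- .dedup_edges(as.matrix(edges[, c("from", "to"), drop = FALSE]))
  } else {
    e <- matrix(character(0L), 0L, 2L, dimnames = list(NULL, c("from", "to")))
  }
  nodes <- sort(unique(c(nodes, as.vector(e))))
  edf <- data.frame(from = e[, 1L], to = e[, 2L],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(provenance)) {
    stopifnot(length(provenance) == nrow(edf))
    edf$provenance <- I(provenance)
  }
  ## deterministic edge ordering regardless of input order
  ord <- order(edf$from, edf$to)
  edf <- edf[ord, , drop = FALSE]
  row.names(edf) <- NULL
  structure(list(nodes = nodes, edges = edf), class = "GeneNetwork")
}

#' @export
print.GeneNetwork <- function(x, ...) {
  cat(sprintf("GeneNetwork: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build the background network as the union of pathway edge sets
#'
#' Node set is the union of all edge endpoints; duplicated edges collapse
#' to one, with the contributing pathway names retained per edge as
#' provenance.
#'
#' @param collection a `PathwayCollection` from
#'   [read_pathway_collection()] or [simulate_network()].
#' @return a `GeneNetwork` with fields `nodes` (sorted) and `edges`
#'   (data frame `from`, `to`, `provenance`).
#' @export
build_union_network <- function(collection) {
  stopifnot(inherits(collection, "PathwayCollection"))
  if (length(collection) == 0L) .stopf("empty pathway collection")
  all_edges <- do.call(rbind, lapply(names(collection), function(nm) {
    e <- collection[[nm]]
    if (nrow(e) == 0L) return(NULL)
    e <- .dedup_edges(as.matrix(e))
    if (nrow(e) == 0L) return(NULL)
    data.frame(from = e[, 1L], to = e[, 2L], pathway = nm,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_edges) || nrow(all_edges) == 0L) {
    .stopf("pathway collection contributes no edges")
  }
  key <- paste(all_edges$from, all_edges$to, sep = "\r")
  prov <- split(all_edges$pathway, key)
  uniq <- !duplicated(key)
  e <- all_edges[uniq, c("from", "to")]
  provenance <- lapply(key[uniq], function(k) unique(prov[[k]]))
  .gene_network(e, provenance = provenance)
}

#' Convert a network to an igraph object
#' @param net a `GeneNetwork`
#' @return an undirected `igraph` graph over the same nodes
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "GeneNetwork"))
  igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Dense 0/1 adjacency matrix of a network
#'
#' Rows/columns follow the sorted node order; the diagonal is zero.
#'
#' @param net a `GeneNetwork`
#' @return symmetric numeric matrix with node dimnames
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "GeneNetwork"))
  n <- length(net$nodes)
  a <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    a[cbind(i, j)] <- 1
    a[cbind(j, i)] <- 1
  }
  a
}

#' Induced subgraph on a set of symbols
#'
#' Keeps `keep` intersected with the network's nodes (symbols absent from
#' the network are ignored with a warning) and every edge whose two
#' endpoints are kept. Kept nodes with no surviving edge stay as isolated
#' nodes.
#'
#' @param net a `GeneNetwork`.
#' @param keep a `GeneList` or character vector of symbols.
#' @return a `GeneNetwork`.
#' @export
induced_subgraph <- function(net, keep) {
  stopifnot(inherits(net, "GeneNetwork"))
  keep <- .as_symbols(keep)
  absent <- setdiff(keep, net$nodes)
  if (length(absent)) {
    .warnf("%d symbol(s) not in network ignored: %s", length(absent),
           paste(utils::head(absent, 5L), collapse = ", "))
  }
  keep <- intersect(keep, net$nodes)
  sel <- net$edges$from %in% keep & net$edges$to %in% keep
  e <- net$edges[sel, , drop = FALSE]
  out <- .gene_network(e, nodes = keep)
  if (!is.null(e$provenance)) {
    m <- match(paste(out$edges$from, out$edges$to),
               paste(e$from, e$to))
    out$edges$provenance <- I(e$provenance[m])
  }
  out
}

#' Connected components of a network
#' @param net a `GeneNetwork`
#' @return list of character vectors of node names, largest first
#' @export
network_components <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups[order(-lengths(groups),
               vapply(groups, min, character(1L)))]
}

#' Largest connected component
#'
#' The component with the most nodes. Ties are broken by the larger total
#' walk probability when a probability vector is supplied, otherwise by
#' the lexicographically smallest member.
#'
#' @param net a non-empty `GeneNetwork`.
#' @param probabilities optional named numeric vector of node
#'   probabilities used for tie-breaking.
#' @return a `GeneNetwork` restricted to the winning component.
#' @export
largest_component <- function(net, probabilities = NULL) {
  stopifnot(inherits(net, "GeneNetwork"))
  if (length(net$nodes) == 0L) .stopf("empty graph has no components")
  groups <- network_components(net)
  sizes <- lengths(groups)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L && !is.null(probabilities)) {
    mass <- vapply(groups[cand], function(g) {
      sum(probabilities[intersect(g, names(probabilities))])
    }, numeric(1L))
    cand <- cand[mass == max(mass)]
  }
  if (length(cand) > 1L) {
    cand <- cand[order(vapply(groups[cand], min, character(1L)))]
  }
  suppressWarnings(induced_subgraph(net, groups[[cand[1L]]]))
}
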