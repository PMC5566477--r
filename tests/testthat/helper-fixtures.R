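## Shared fixture builders and independent oracles.

# PathwayCollection from named list of edge matrices / vectors
pw_collection <- function(...) {
  pws <- list(...)
  pws <- lapply(pws, function(e) {
    if (is.character(e) && is.null(dim(e))) e <- matrix(e, ncol = 2, byrow = TRUE)
    colnames(e) <- c("from", "to")
    e
  })
  structure(pws, class = "PathwayCollection")
}

# GeneNetwork from a flat vector of edge endpoints c("A","B", "B","C", ...)
make_net <- function(edges, nodes = character(0)) {
  e <- matrix(edges, ncol = 2, byrow = TRUE)
  net <- build_union_network(pw_collection(p = e))
  if (length(nodes)) {
    net$nodes <- sort(unique(c(net$nodes, toupper(nodes))))
  }
  net
}

# ExpressionMatrix + two-group design from per-group value lists
two_group_matrix <- function(g1, g2, features = NULL, labels = c("a", "b")) {
  g1 <- rbind(g1); g2 <- rbind(g2)
  if (is.null(features)) features <- sprintf("F%03d", seq_len(nrow(g1)))
  ids <- c(sprintf("%s%d", labels[1], seq_len(ncol(g1))),
           sprintf("%s%d", labels[2], seq_len(ncol(g2))))
  m <- cbind(g1, g2)
  dimnames(m) <- list(features, ids)
  list(
    matrix = expression_matrix(m),
    design = sample_design(ids, rep(labels, c(ncol(g1), ncol(g2))))
  )
}

# Brute-force Benjamini-Hochberg: q_(i) = min_{j>=i} p_(j) * m / j, clip 1
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  q <- vapply(seq_len(m), function(i) {
    min(pmin(po[i:m] * (m / (i:m)), 1))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Connected non-bipartite Erdos-Renyi adjacency (forced triangle on 1:3)
rand_adjacency <- function(n, p = 0.4) {
  repeat {
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
    a <- a + t(a)
    a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- a[1, 3] <- a[3, 1] <- 1
    g <- igraph::graph_from_adjacency_matrix(a, "undirected")
    if (igraph::is_connected(g)) return(a)
  }
}

# Row-normalized FDR-weighted transition matrix from adjacency + weights
transition_from <- function(a, q) {
  w <- a * rep(q, each = nrow(a))
  p <- w / rowSums(w)
  p / rowSums(p)
}

# Direct fixed point of g = (1-r) g P + r g0 (independent linear solve)
restart_fixed_point <- function(p, g0, r) {
  as.vector(solve(diag(nrow(p)) - (1 - r) * t(p), r * g0))
}

# Principal left eigenvector of P, normalized to the simplex
stationary_eigen <- function(p) {
  v <- Re(eigen(t(p))$vectors[, 1])
  v / sum(v)
}
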