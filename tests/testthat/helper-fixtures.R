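# Fixture builders and independent oracles used across the suite.

# Edge row with internally consistent statistics, as if fitted from data
# with the given means/SDs/correlation: b1_ab = r*sd_a/sd_b etc., so the
# least-squares identity b1_ab*b1_ba = r^2 holds by construction.
edge_row <- function(a, b, r, sd_a = 1, sd_b = 1, mu_a = 0, mu_b = 0,
                     n = 10L) {
  b1_ab <- r * sd_a / sd_b
  b1_ba <- r * sd_b / sd_a
  data.frame(gene_a = a, gene_b = b, r = r, n = n,
             b1_ab = b1_ab, b0_ab = mu_a - b1_ab * mu_b,
             b1_ba = b1_ba, b0_ba = mu_b - b1_ba * mu_a,
             stringsAsFactors = FALSE)
}

# Network from a simple edge list (pairs of ids), identity-like models,
# strong correlation; for topology-only tests.
toy_network <- function(pairs, r = 0.9) {
  rows <- lapply(seq_len(nrow(pairs)), function(i)
    edge_row(pairs[i, 1L], pairs[i, 2L], r))
  coexpression_network(do.call(rbind, rows), threshold = 0.75)
}

# Layered fixture matching a source separated from a target by two layers
# of two genes each, fully layer-connected, plus one source-to-layer-3
# skip edge: 5 simple paths of length <= 3.
fig1_network <- function() {
  pairs <- rbind(c("S", "a1"), c("S", "a2"),
                 c("a1", "b1"), c("a1", "b2"),
                 c("a2", "b1"), c("a2", "b2"),
                 c("b1", "T"), c("b2", "T"),
                 c("S", "b1"))             # layer-skip shortcut
  toy_network(pairs)
}

# Independent recursive enumeration of all simple paths from src to dst
# with at most max_len edges (adjacency given as a named list).
oracle_simple_paths <- function(adj, src, dst, max_len) {
  out <- list()
  recurse <- function(path) {
    node <- path[length(path)]
    if (node == dst && length(path) > 1L) {
      out[[length(out) + 1L]] <<- path
    }
    if (length(path) - 1L >= max_len) return()
    for (nb in sort(adj[[node]])) {
      if (nb %in% path) next
      recurse(c(path, nb))
    }
  }
  recurse(src)
  out
}

adjacency_of <- function(net) {
  e <- net$edges
  nodes <- network_nodes(net)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in nodes) adj[[n]] <- character()
  for (i in seq_len(nrow(e))) {
    adj[[e$gene_a[i]]] <- c(adj[[e$gene_a[i]]], e$gene_b[i])
    adj[[e$gene_b[i]]] <- c(adj[[e$gene_b[i]]], e$gene_a[i])
  }
  adj
}

# Brute-force BFS distances from one source over a named adjacency list.
oracle_bfs <- function(adj, src) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- character()
    for (node in frontier)
      for (nb in adj[[node]])
        if (!is.finite(dist[nb])) {
          dist[nb] <- d
          nxt <- c(nxt, nb)
        }
    frontier <- unique(nxt)
  }
  dist
}

# Floyd-Warshall all-pairs shortest paths over a named adjacency list.
oracle_floyd_warshall <- function(adj) {
  nodes <- names(adj)
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (a in nodes) for (b in adj[[a]]) d[a, b] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Random connected-ish undirected graph as a toy network.
random_toy_network <- function(n_nodes, p_edge, seed, r = 0.9) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  set.seed(seed)
  pairs <- t(utils::combn(ids, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  # guarantee a spanning path so the graph has no isolated vertex
  spine <- cbind(ids[-n_nodes], ids[-1L])
  all_pairs <- unique(rbind(pairs[keep, , drop = FALSE], spine))
  toy_network(all_pairs, r = r)
}
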