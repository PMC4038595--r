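#' Gene co-expression network with per-edge regression models
#'
#' A `coexpression_network` is an undirected graph over probes/genes in
#' which an edge joins every pair whose absolute Pearson correlation
#' exceeds the build threshold. Each edge carries the correlation `r`, the
#' sample count `n`, and ordinary-least-squares affine models in both
#' orientations: `b1_ab`/`b0_ab` predict `gene_a` from `gene_b`, and
#' `b1_ba`/`b0_ba` predict `gene_b` from `gene_a`. The least-squares
#' identity `b1_ab * b1_ba == r^2` holds for every edge.
#'
#' @param edges data frame with columns `gene_a`, `gene_b`, `r`, `n`,
#'   `b1_ab`, `b0_ab`, `b1_ba`, `b0_ba`. Pairs are unordered; rows are
#'   stored with `gene_a < gene_b` lexicographically.
#' @param threshold the |r| cutoff the edge set satisfies.
#' @param dropped ids of zero-variance genes excluded before correlation.
#' @param isolated ids of genes that had no edge above the threshold.
#' @return an object of class `coexpression_network`.
#' @export
coexpression_network <- function(edges, threshold,
                                 dropped = character(), isolated = character()) {
  need <- c("gene_a", "gene_b", "r", "n",
            "b1_ab", "b0_ab", "b1_ba", "b0_ba")
  if (!all(need %in% names(edges)))
    stop("edges must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  if (any(edges$gene_a == edges$gene_b))
    stop("self-loop edge(s) not allowed", call. = FALSE)
  flip <- edges$gene_a > edges$gene_b
  if (any(flip)) {
    tmp <- edges[flip, ]
    edges[flip, c("gene_a", "gene_b")] <- tmp[, c("gene_b", "gene_a")]
    edges[flip, c("b1_ab", "b0_ab", "b1_ba", "b0_ba")] <-
      tmp[, c("b1_ba", "b0_ba", "b1_ab", "b0_ab")]
  }
  key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  if (anyDuplicated(key)) stop("duplicated edge(s)", call. = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  if (any(abs(edges$r) > 1 + 1e-12)) stop("|r| > 1 on some edge",
                                          call. = FALSE)
  if (nrow(edges) && any(edges$n < 3L)) stop("edge with n < 3", call. = FALSE)
  if (nrow(edges) && any(abs(edges$r) <= threshold))
    stop("edge(s) below the stated threshold |r| > ", threshold,
         call. = FALSE)
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b"), drop = FALSE][rep(nrow(edges) > 0, nrow(edges)), ],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  net <- structure(list(edges = edges, graph = g, threshold = threshold,
                        dropped = as.character(dropped),
                        isolated = as.character(isolated)),
                   class = "coexpression_network")
  net$coefs <- build_coef_index(edges)
  net$adj <- build_adjacency(edges, nodes)
  net
}

# Directed coefficient lookup: env[["from\rto"]] = c(b1, b0) predicting
# `to` from `from`.
build_coef_index <- function(edges) {
  env <- new.env(hash = TRUE, parent = emptyenv(), size = 2L * nrow(edges) + 1L)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$gene_a[i]; b <- edges$gene_b[i]
      assign(paste(a, b, sep = "\r"),
             c(edges$b1_ba[i], edges$b0_ba[i]), envir = env)
      assign(paste(b, a, sep = "\r"),
             c(edges$b1_ab[i], edges$b0_ab[i]), envir = env)
    }
  }
  env
}

# Sorted adjacency lists keyed by node id (lexicographic neighbor order,
# the deterministic traversal order used by path enumeration).
build_adjacency <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in nodes) adj[[n]] <- character()
  if (nrow(edges)) {
    inc <- split(c(edges$gene_b, edges$gene_a),
                 c(edges$gene_a, edges$gene_b))
    for (n in names(inc)) adj[[n]] <- sort(inc[[n]], method = "radix")
  }
  adj
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("<coexpression_network> ", length(network_nodes(x)), " nodes, ",
      nrow(x$edges), " edges (|r| > ", x$threshold, ")\n", sep = "")
  if (length(x$isolated))
    cat("  ", length(x$isolated), " isolated gene(s) excluded from graph\n",
        sep = "")
  if (length(x$dropped))
    cat("  ", length(x$dropped), " zero-variance gene(s) dropped\n", sep = "")
  invisible(x)
}

#' Nodes of a co-expression network
#' @param net a [coexpression_network()].
#' @return sorted character vector of gene ids incident to at least one edge.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  names(net$adj)
}

#' Number of unordered gene pairs
#'
#' The count of pairwise correlations examined when building a network over
#' `p` probes: `p * (p - 1) / 2`.
#'
#' @param p non-negative integer number of probes/genes.
#' @return the pair count as a double (exact for p well beyond 10^5).
#' @export
pair_count <- function(p) {
  if (length(p) != 1L || !is.finite(p) || p < 0 || p != trunc(p))
    stop("`p` must be a single non-negative integer", call. = FALSE)
  p * (p - 1) / 2
}

#' Fit both affine regression orientations for one gene pair
#'
#' Computes the sample Pearson correlation and the two
#' ordinary-least-squares fits `a = b1_ab * b + b0_ab` and
#' `b = b1_ba * a + b0_ba`.
#'
#' @param x,y numeric vectors of equal length >= 3 (expression of the two
#'   genes across samples).
#' @param gene_a,gene_b ids used to label the edge.
#' @return a one-row data frame with the edge-model columns (see
#'   [coexpression_network()]).
#' @export
fit_edge <- function(x, y, gene_a = "a", gene_b = "b") {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0)
    stop("degenerate edge: zero variance in ",
         if (vx == 0) gene_a else gene_b, call. = FALSE)
  cxy <- stats::cov(x, y)
  r <- cxy / sqrt(vx * vy)
  b1_ab <- cxy / vy              # predict x (gene_a) from y (gene_b)
  b0_ab <- mean(x) - b1_ab * mean(y)
  b1_ba <- cxy / vx              # predict y (gene_b) from x (gene_a)
  b0_ba <- mean(y) - b1_ba * mean(x)
  data.frame(gene_a = gene_a, gene_b = gene_b, r = r, n = length(x),
             b1_ab = b1_ab, b0_ab = b0_ab, b1_ba = b1_ba, b0_ba = b0_ba,
             stringsAsFactors = FALSE)
}

#' Correlation p-value with Bonferroni correction
#'
#' Two-sided p-value for a Pearson correlation under the null of no
#' association, from the t statistic `t = r * sqrt((n - 2) / (1 - r^2))`
#' with `n - 2` degrees of freedom, multiplied by the number of tests `m`
#' and capped at 1. Computed on the log scale so extreme tails (e.g.
#' 1e-110) do not underflow.
#'
#' @param r Pearson correlation, |r| <= 1.
#' @param n sample count, >= 3.
#' @param m number of tests for the Bonferroni correction, >= 1.
#' @return corrected two-sided p-value in \[0, 1\].
#' @export
corr_pvalue_bonferroni <- function(r, n, m = 1) {
  if (!is.finite(r) || abs(r) > 1) stop("|r| must be <= 1", call. = FALSE)
  if (!is.finite(n) || n < 3) stop("n must be >= 3", call. = FALSE)
  if (!is.finite(m) || m < 1) stop("m must be >= 1", call. = FALSE)
  if (abs(r) == 1) return(0)
  tstat <- abs(r) * sqrt((n - 2) / (1 - r^2))
  logp <- log(2) + stats::pt(tstat, df = n - 2, lower.tail = FALSE,
                             log.p = TRUE)
  min(1, exp(logp + log(m)))
}

#' Build a co-expression network from an expression matrix
#'
#' Computes all pairwise Pearson correlations between rows, retains pairs
#' with `|r| > threshold`, and fits both regression orientations for each
#' retained pair. Zero-variance genes are dropped with a warning;
#' above-threshold computation is optionally blockwise (results are
#' independent of `block_size`).
#'
#' @param mat an [expression_matrix()] with at least 3 samples.
#' @param threshold absolute-correlation cutoff in \[0, 1); default 0.75.
#' @param pairs optional 2-column character matrix/data frame restricting
#'   the candidate pairs (used to realise a known topology, e.g. from a
#'   simulation truth); when given, `threshold` is not applied and is
#'   recorded as 0.
#' @param block_size optional gene-block size for blockwise correlation.
#' @param min_pairwise_n minimum shared samples per pair when the matrix
#'   contains NA (default 10); pairs with fewer are excluded.
#' @return a [coexpression_network()].
#' @export
build_network <- function(mat, threshold = 0.75, pairs = NULL,
                          block_size = NULL, min_pairwise_n = 10L) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (ncol(mat) < 3L)
    stop("need at least 3 samples to build a network", call. = FALSE)
  if (is.null(pairs) && (threshold < 0 || threshold >= 1))
    stop("threshold must be in [0, 1)", call. = FALSE)
  x <- t(unclass(mat))                      # samples x genes
  has_na <- anyNA(x)
  v <- apply(x, 2L, stats::var, na.rm = TRUE)
  degenerate <- colnames(x)[!is.finite(v) | v == 0]
  if (length(degenerate)) {
    warning("dropping ", length(degenerate),
            " zero-variance gene(s): ",
            paste(utils::head(degenerate, 5L), collapse = ", "),
            if (length(degenerate) > 5L) ", ...", call. = FALSE)
    x <- x[, setdiff(colnames(x), degenerate), drop = FALSE]
  }
  genes <- colnames(x)
  use <- if (has_na) "pairwise.complete.obs" else "everything"

  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    storage.mode(pairs) <- "character"
    keep <- pairs[, 1L] %in% genes & pairs[, 2L] %in% genes
    pairs <- pairs[keep, , drop = FALSE]
    rows <- lapply(seq_len(nrow(pairs)), function(i)
      fit_edge(x[, pairs[i, 1L]], x[, pairs[i, 2L]],
               pairs[i, 1L], pairs[i, 2L]))
    edges <- do.call(rbind, rows) %||%
      empty_edges()
    return(coexpression_network(edges, threshold = 0))
  }

  blocks <- if (is.null(block_size)) list(seq_along(genes)) else
    split(seq_along(genes), ceiling(seq_along(genes) / block_size))
  hits <- list()
  n_samp <- nrow(x)
  for (bi in seq_along(blocks)) {
    for (bj in bi:length(blocks)) {
      ii <- blocks[[bi]]; jj <- blocks[[bj]]
      cc <- suppressWarnings(stats::cor(x[, ii, drop = FALSE],
                                        x[, jj, drop = FALSE], use = use))
      idx <- which(abs(cc) > threshold & !is.na(cc), arr.ind = TRUE)
      if (nrow(idx)) {
        gi <- ii[idx[, 1L]]; gj <- jj[idx[, 2L]]
        keep <- gi < gj
        if (any(keep))
          hits[[length(hits) + 1L]] <- cbind(gi[keep], gj[keep])
      }
    }
  }
  hits <- if (length(hits)) unique(do.call(rbind, hits)) else
    matrix(integer(), ncol = 2L)
  rows <- vector("list", nrow(hits))
  keep <- logical(nrow(hits))
  for (k in seq_len(nrow(hits))) {
    xi <- x[, hits[k, 1L]]; yj <- x[, hits[k, 2L]]
    ok <- is.finite(xi) & is.finite(yj)
    if (has_na && sum(ok) < max(3L, min_pairwise_n)) next
    rows[[k]] <- fit_edge(xi[ok], yj[ok],
                          genes[hits[k, 1L]], genes[hits[k, 2L]])
    keep[k] <- TRUE
  }
  edges <- if (any(keep)) do.call(rbind, rows[keep]) else empty_edges()
  incident <- unique(c(edges$gene_a, edges$gene_b))
  isolated <- setdiff(genes, incident)
  coexpression_network(edges, threshold = threshold,
                       dropped = degenerate, isolated = isolated)
}

empty_edges <- function() {
  data.frame(gene_a = character(), gene_b = character(), r = numeric(),
             n = integer(), b1_ab = numeric(), b0_ab = numeric(),
             b1_ba = numeric(), b0_ba = numeric(), stringsAsFactors = FALSE)
}

#' Edge model lookup (orientation-independent)
#' @param net a [coexpression_network()].
#' @param x,y gene ids of the pair.
#' @return the one-row edge data frame, or `NULL` when no edge exists.
#' @export
edge_model <- function(net, x, y) {
  stopifnot(inherits(net, "coexpression_network"))
  a <- min(x, y); b <- max(x, y)
  i <- which(net$edges$gene_a == a & net$edges$gene_b == b)
  if (!length(i)) return(NULL)
  net$edges[i, , drop = FALSE]
}

# Directed coefficients c(b1, b0) predicting `to` from `from`; error when
# the edge is absent.
edge_coef <- function(net, from, to) {
  v <- get0(paste(from, to, sep = "\r"), envir = net$coefs,
            inherits = FALSE)
  if (is.null(v)) stop("no edge between '", from, "' and '", to, "'",
                       call. = FALSE)
  v
}

#' Degree of a gene in the network
#' @param net a [coexpression_network()].
#' @param gene gene id; must be a network node.
#' @return integer count of incident edges.
#' @export
gene_degree <- function(net, gene) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!gene %in% network_nodes(net))
    stop("gene '", gene, "' is not in the network", call. = FALSE)
  length(net$adj[[gene]])
}

#' Write a network to GraphML
#'
#' Serializes the graph with edge attributes `r`, `n`, `b1_ab`, `b0_ab`,
#' `b1_ba`, `b0_ba` and graph attribute `threshold`; round-trips through
#' [read_network_graphml()].
#'
#' @param net a [coexpression_network()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- net$graph
  e <- net$edges
  for (col in c("r", "n", "b1_ab", "b0_ab", "b1_ba", "b0_ba"))
    g <- igraph::set_edge_attr(g, col, value = as.numeric(e[[col]]))
  g <- igraph::set_graph_attr(g, "threshold", as.numeric(net$threshold))
  write_atomic(path, function(tmp)
    igraph::write_graph(g, tmp, format = "graphml"))
}

#' Read a network from GraphML
#' @param path a file written by [write_network_graphml()].
#' @return a [coexpression_network()].
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
                      stringsAsFactors = FALSE)
  for (col in c("r", "n", "b1_ab", "b0_ab", "b1_ba", "b0_ba"))
    edges[[col]] <- igraph::edge_attr(g, col)
  edges$n <- as.integer(round(edges$n))
  thr <- igraph::graph_attr(g, "threshold") %||% 0
  coexpression_network(edges, threshold = as.numeric(thr))
}

#' Write a network as a JSON-lines edge list
#'
#' One JSON object per line with fields `gene_a`, `gene_b`, `r`, `n`,
#' `b1_ab`, `b0_ab`, `b1_ba`, `b0_ba`; first line is a header object
#' holding the threshold.
#'
#' @param net a [coexpression_network()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_network_jsonl <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(jsonlite::toJSON(list(threshold = net$threshold),
                                auto_unbox = TRUE, digits = NA), con)
    e <- net$edges
    for (i in seq_len(nrow(e)))
      writeLines(jsonlite::toJSON(as.list(e[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
  })
}

#' Read a network from a JSON-lines edge list
#' @param path a file written by [write_network_jsonl()].
#' @return a [coexpression_network()].
#' @export
read_network_jsonl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("empty network file: ", path, call. = FALSE)
  hdr <- jsonlite::fromJSON(lines[1L])
  rows <- lapply(lines[-1L], function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
  edges <- if (length(rows)) do.call(rbind, rows) else empty_edges()
  edges$n <- as.integer(edges$n)
  coexpression_network(edges, threshold = hdr$threshold)
}
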