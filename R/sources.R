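#' Coverage of a source panel within a jump limit
#'
#' Breadth-first reachability of a set of source genes: which targets lie
#' within `max_jumps` edges of at least one source, how far the nearest
#' source is, and how many sources reach each target. Sources themselves
#' are excluded from the target set.
#'
#' @param net a [coexpression_network()].
#' @param sources character vector of gene ids, all network nodes.
#' @param max_jumps maximum path length in edges (default 4).
#' @return a `coverage_report` list with elements `sources`, `max_jumps`,
#'   `reachable` (sorted target ids), `per_target_min_jumps` and
#'   `per_target_source_count` (named integer vectors over `reachable`).
#' @export
reachable_set <- function(net, sources, max_jumps = 4L) {
  stopifnot(inherits(net, "coexpression_network"))
  if (max_jumps < 1L) stop("max_jumps must be >= 1", call. = FALSE)
  sources <- as.character(sources)
  miss <- setdiff(sources, network_nodes(net))
  if (length(miss))
    stop("unknown source gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!length(sources))
    return(structure(list(sources = character(), max_jumps = max_jumps,
                          reachable = character(),
                          per_target_min_jumps = integer(),
                          per_target_source_count = integer()),
                     class = "coverage_report"))
  d <- source_distances(net, sources)
  nodes <- colnames(d)
  mind <- apply(d, 2L, min)
  reach <- sort(setdiff(nodes[mind <= max_jumps], sources))
  cnt <- colSums(d[, reach, drop = FALSE] <= max_jumps)
  structure(list(sources = sources, max_jumps = as.integer(max_jumps),
                 reachable = reach,
                 per_target_min_jumps =
                   stats::setNames(as.integer(mind[reach]), reach),
                 per_target_source_count =
                   stats::setNames(as.integer(cnt), reach)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report> ", length(x$sources), " source(s), max ",
      x$max_jumps, " jumps -> ", length(x$reachable),
      " reachable target gene(s)\n", sep = "")
  invisible(x)
}

#' Shortest-path length histogram
#'
#' Distribution of shortest-path lengths (jumps) over node pairs of the
#' network; disconnected pairs are counted separately. Used to judge how
#' far a typical gene pair sits in the network (the density of the source
#' compendium peaks at 4 jumps).
#'
#' @param net a [coexpression_network()].
#' @param n_pairs optional number of node pairs to subsample (all pairs
#'   when `NULL`).
#' @param seed seed for the pair subsample.
#' @return list with `counts` (named integer vector, names = path length)
#'   and `disconnected` (pair count with no path).
#' @export
path_length_histogram <- function(net, n_pairs = NULL, seed = 1L) {
  stopifnot(inherits(net, "coexpression_network"))
  nodes <- network_nodes(net)
  if (length(nodes) < 2L)
    return(list(counts = stats::setNames(integer(), character()),
                disconnected = 0L))
  d <- igraph::distances(net$graph)
  lens <- d[upper.tri(d)]
  if (!is.null(n_pairs) && n_pairs < length(lens))
    lens <- with_seed(seed, sample(lens, n_pairs))
  fin <- lens[is.finite(lens)]
  tab <- table(factor(as.integer(fin), levels = sort(unique(as.integer(fin)))))
  list(counts = stats::setNames(as.integer(tab), names(tab)),
       disconnected = sum(!is.finite(lens)))
}

#' Candidate source genes by edge-strength criterion
#'
#' A gene qualifies as a candidate source when *any* of its incident edges
#' passes the criterion: `abs_r` keeps edges with `|r| > cutoff`,
#' `r_squared` keeps edges with `r^2 > cutoff`. Strong correlation on the
#' first jump propagates to better chained predictions, which is why
#' candidates are screened on their best edge.
#'
#' @param net a [coexpression_network()].
#' @param criterion `"abs_r"` or `"r_squared"`.
#' @param cutoff value in (0, 1).
#' @return sorted character vector of candidate gene ids.
#' @export
candidate_sources <- function(net, criterion = c("abs_r", "r_squared"),
                              cutoff = 0.95) {
  stopifnot(inherits(net, "coexpression_network"))
  criterion <- match.arg(criterion)
  if (cutoff <= 0 || cutoff >= 1)
    stop("cutoff must be in (0, 1)", call. = FALSE)
  e <- net$edges
  pass <- switch(criterion,
                 abs_r = abs(e$r) > cutoff,
                 r_squared = e$r^2 > cutoff)
  sort(unique(c(e$gene_a[pass], e$gene_b[pass])))
}

# coverage mask matrix: candidates x nodes, TRUE when node is within
# max_jumps of the candidate and is not the candidate itself
coverage_masks <- function(net, candidates, max_jumps) {
  d <- source_distances(net, candidates)
  m <- d <= max_jumps
  for (i in seq_along(candidates)) m[i, candidates[i]] <- FALSE
  m
}

#' Greedy minimal source panel
#'
#' Redundancy removal by greedy set cover: repeatedly pick the candidate
#' that covers the most not-yet-covered targets within `max_jumps` (ties
#' broken by lexicographic gene id) until no candidate adds coverage. The
#' returned panel covers exactly the same targets as the full candidate
#' set, typically with far fewer genes.
#'
#' @param net a [coexpression_network()].
#' @param candidates character vector of candidate gene ids (network
#'   nodes).
#' @param max_jumps jump limit (default 4).
#' @return character vector of selected gene ids, in selection order.
#' @export
greedy_minimal_sources <- function(net, candidates, max_jumps = 4L) {
  stopifnot(inherits(net, "coexpression_network"))
  candidates <- as.character(candidates)
  if (!length(candidates)) return(character())
  miss <- setdiff(candidates, network_nodes(net))
  if (length(miss))
    stop("candidate(s) not in network: ", paste(miss, collapse = ", "),
         call. = FALSE)
  candidates <- sort(unique(candidates))   # lexicographic tie-break order
  m <- coverage_masks(net, candidates, max_jumps)
  covered <- rep(FALSE, ncol(m))
  selected <- character()
  repeat {
    gain <- m %*% (!covered)               # marginal coverage per candidate
    best <- max(gain)
    if (best == 0) break
    pick <- which(gain == best)[1L]        # rows sorted -> lexicographic tie
    selected <- c(selected, candidates[pick])
    covered <- covered | m[pick, ]
    m[pick, ] <- FALSE
  }
  selected
}

#' Supplement a panel with high-degree genes from the uncovered set
#'
#' After redundancy removal some genes remain outside the panel's
#' `max_jumps` reach. This adds the `k` highest-degree genes (ties broken
#' lexicographically) drawn from those uncovered genes, trading a small
#' panel increase for extra coverage.
#'
#' @param net a [coexpression_network()].
#' @param selected current panel (network nodes).
#' @param k number of genes to add (default 10).
#' @param max_jumps jump limit (default 4).
#' @return `selected` followed by the added genes.
#' @export
supplement_by_degree <- function(net, selected, k = 10L, max_jumps = 4L) {
  stopifnot(inherits(net, "coexpression_network"))
  if (k < 0L) stop("k must be >= 0", call. = FALSE)
  selected <- as.character(selected)
  if (k == 0L) return(selected)
  nodes <- network_nodes(net)
  covered <- if (length(selected))
    union(selected, reachable_set(net, selected, max_jumps)$reachable)
  else character()
  uncovered <- setdiff(nodes, covered)
  if (!length(uncovered)) return(selected)
  deg <- vapply(uncovered, function(g) length(net$adj[[g]]), integer(1))
  ord <- order(-deg, uncovered, method = "radix")
  c(selected, uncovered[ord][seq_len(min(k, length(uncovered)))])
}

#' Write a coverage report as TSV
#' @param x a `coverage_report`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(x, path) {
  stopifnot(inherits(x, "coverage_report"))
  df <- data.frame(target = x$reachable,
                   min_jumps = as.integer(x$per_target_min_jumps),
                   source_count = as.integer(x$per_target_source_count),
                   stringsAsFactors = FALSE)
  write_atomic(path, function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE))
}
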