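#' Path enumeration policy
#'
#' Controls how simple paths between source and target genes are
#' enumerated. `max_len` bounds the path length in edges (jumps); the
#' default of 4 reflects the predictability limit of the chained regression
#' approach — accuracy at a 20% error threshold falls off sharply beyond 4
#' jumps. `max_paths` caps the number of paths used per source–target pair
#' (enumeration is deterministic depth-first in lexicographic neighbor
#' order and simply truncates at the cap); `sample_paths = TRUE` instead
#' draws a seeded uniform subsample of the enumerated paths.
#'
#' @param max_len maximum path length in edges (default 4).
#' @param max_paths per-pair path cap (default 10000).
#' @param sample_paths if `TRUE`, paths beyond `max_paths` are handled by
#'   seeded uniform subsampling rather than truncation.
#' @param seed seed used when `sample_paths = TRUE`.
#' @return a `path_policy` object.
#' @export
path_policy <- function(max_len = 4L, max_paths = 10000L,
                        sample_paths = FALSE, seed = 1L) {
  if (max_len < 1L) stop("max_len must be >= 1", call. = FALSE)
  if (max_paths < 1L) stop("max_paths must be >= 1", call. = FALSE)
  structure(list(max_len = as.integer(max_len),
                 max_paths = as.integer(max_paths),
                 sample_paths = isTRUE(sample_paths),
                 seed = as.integer(seed)),
            class = "path_policy")
}

# Core bounded simple-path walker. Depth-first from `source`, visiting
# neighbors in lexicographic order, never revisiting a node within a path.
# For every node reached it records either the node sequence
# (mode = "paths", restricted to `target`) or the composed affine
# coefficients of the path (mode = "affine", all terminals). A path that
# passes *through* a node and continues still contributes its prefix to
# that node. Per-terminal recording stops at `max_paths`.
walk_paths <- function(net, source, policy, mode = c("affine", "paths"),
                       target = NULL) {
  mode <- match.arg(mode)
  adj <- net$adj
  if (is.null(adj[[source]]))
    stop("source gene '", source, "' is not in the network", call. = FALSE)
  max_len <- policy$max_len
  cap <- policy$max_paths
  acc <- new.env(hash = TRUE, parent = emptyenv())
  # Recursive DFS; path state carried in vectors. Depth equals number of
  # edges walked so far.
  path_nodes <- character(max_len + 1L)
  path_nodes[1L] <- source
  on_path <- new.env(hash = TRUE, parent = emptyenv())
  assign(source, TRUE, envir = on_path)
  record <- function(node, slope, intercept, depth) {
    if (mode == "paths" && !identical(node, target)) return(invisible())
    cur <- get0(node, envir = acc, inherits = FALSE)
    if (!is.null(cur) && cur$count >= cap) return(invisible())
    if (is.null(cur)) cur <- list(count = 0L, items = list())
    cur$count <- cur$count + 1L
    cur$items[[cur$count]] <-
      if (mode == "paths") path_nodes[seq_len(depth + 1L)]
      else c(slope, intercept, depth)
    assign(node, cur, envir = acc)
    invisible()
  }
  descend <- function(node, slope, intercept, depth) {
    if (depth >= max_len) return(invisible())
    for (nb in adj[[node]]) {
      if (isTRUE(get0(nb, envir = on_path, inherits = FALSE))) next
      cf <- edge_coef(net, node, nb)
      s2 <- slope * cf[1L]
      i2 <- intercept * cf[1L] + cf[2L]
      d2 <- depth + 1L
      path_nodes[d2 + 1L] <<- nb
      assign(nb, TRUE, envir = on_path)
      record(nb, s2, i2, d2)
      descend(nb, s2, i2, d2)
      assign(nb, FALSE, envir = on_path)
    }
    invisible()
  }
  descend(source, 1, 0, 0L)
  out <- as.list(acc)
  lapply(out, function(e) e$items)
}

#' Enumerate bounded simple paths between two genes
#'
#' All simple paths (no repeated nodes) from `source` to `target` of length
#' at most `policy$max_len` edges, in deterministic depth-first
#' lexicographic order, truncated at `policy$max_paths`.
#'
#' @param net a [coexpression_network()].
#' @param source,target distinct gene ids in the network.
#' @param policy a [path_policy()].
#' @return list of character vectors (node sequences, source first); empty
#'   list when no path exists.
#' @export
enumerate_paths <- function(net, source, target, policy = path_policy()) {
  stopifnot(inherits(net, "coexpression_network"))
  if (identical(source, target))
    stop("source and target must differ", call. = FALSE)
  if (!target %in% network_nodes(net))
    stop("target gene '", target, "' is not in the network", call. = FALSE)
  res <- walk_paths(net, source, policy, mode = "paths", target = target)
  res[[target]] %||% list()
}

#' Chained prediction along one path
#'
#' Composes the directed affine model of each edge along `path`: if the
#' edge from gene X to gene Y has model `Y = b1 * X + b0`, the value is
#' propagated step by step, so the overall map is affine in `source_value`
#' with slope equal to the product of the per-edge slopes.
#'
#' @param path character vector of gene ids; consecutive entries must be
#'   network edges.
#' @param source_value expression value of the first gene in `path`.
#' @param net a [coexpression_network()].
#' @return the predicted expression value of the last gene in `path`.
#' @export
chain_predict <- function(path, source_value, net) {
  stopifnot(inherits(net, "coexpression_network"))
  if (length(path) < 2L) stop("path needs at least 2 nodes", call. = FALSE)
  v <- source_value
  for (i in seq_len(length(path) - 1L)) {
    cf <- edge_coef(net, path[i], path[i + 1L])
    v <- cf[1L] * v + cf[2L]
  }
  v
}

# Per-target path predictions from one source: returns a named list of
# numeric vectors (one predicted value per path), plus attribute "len"
# with per-path lengths. Applies seeded subsampling when the policy asks
# for it.
source_path_predictions <- function(net, source, value, policy) {
  aff <- walk_paths(net, source, policy, mode = "affine")
  preds <- lapply(aff, function(items) {
    m <- do.call(rbind, items)
    vals <- m[, 1L] * value + m[, 2L]
    attr(vals, "len") <- as.integer(m[, 3L])
    vals
  })
  if (policy$sample_paths) {
    preds <- lapply(preds, function(v) {
      if (length(v) <= policy$max_paths) return(v)
      keep <- with_seed(policy$seed,
                        sort(sample.int(length(v), policy$max_paths)))
      out <- v[keep]
      attr(out, "len") <- attr(v, "len")[keep]
      out
    })
  }
  preds
}

prediction_frame <- function(target, mean, sd, n_paths, jumps, sources_used) {
  structure(data.frame(target = target, mean = mean, sd = sd,
                       n_paths = n_paths, jumps = jumps,
                       sources_used = sources_used,
                       adjacent = jumps == 1L,
                       stringsAsFactors = FALSE),
            class = c("prediction_result", "data.frame"))
}

check_sources <- function(net, src) {
  miss <- setdiff(src, network_nodes(net))
  if (length(miss) == length(src))
    stop("no source gene is present in the network", call. = FALSE)
  if (length(miss))
    stop("source gene(s) not in network: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(src)
}

# Jump distances from each source to every node (sources x nodes matrix).
source_distances <- function(net, src) {
  d <- igraph::distances(net$graph, v = src, to = igraph::V(net$graph))
  rownames(d) <- src
  d
}

#' Single-pass transcriptome prediction
#'
#' Predicts every gene reachable within `policy$max_len` jumps of the
#' source panel. Each target is assigned exactly one source — the one at
#' minimal jump distance, ties broken by position in the source list — and
#' its expression is the arithmetic mean of the chained predictions over
#' all enumerated simple paths from that source, with the standard
#' deviation over paths as the uncertainty. Targets at 1 jump have a single
#' path, no standard deviation, and are flagged `adjacent` (they are
#' excluded from SD-based evaluation).
#'
#' @param net a [coexpression_network()].
#' @param sources a [source_values()] vector (order matters for
#'   tie-breaking).
#' @param policy a [path_policy()].
#' @return a `prediction_result` data frame with columns `target`, `mean`,
#'   `sd`, `n_paths`, `jumps`, `sources_used`, `adjacent`, ordered by
#'   target id.
#' @export
predict_single_pass <- function(net, sources, policy = path_policy()) {
  stopifnot(inherits(net, "coexpression_network"))
  src <- names(sources)
  check_sources(net, src)
  d <- source_distances(net, src)
  nodes <- colnames(d)
  targets <- setdiff(nodes[apply(d, 2L, min) <= policy$max_len], src)
  if (!length(targets))
    return(prediction_frame(character(), numeric(), numeric(), integer(),
                            integer(), character()))
  # assignment: minimal jumps, ties by source order (rows are in source
  # order so which.min picks the first)
  assign_idx <- apply(d[, targets, drop = FALSE], 2L, which.min)
  jumps <- as.integer(apply(d[, targets, drop = FALSE], 2L, min))
  rows <- vector("list", length(targets))
  for (s_i in unique(assign_idx)) {
    s <- src[s_i]
    preds <- source_path_predictions(net, s, sources[[s]], policy)
    for (t_i in which(assign_idx == s_i)) {
      tg <- targets[t_i]
      v <- preds[[tg]]
      if (is.null(v)) next          # unreachable by paths (cannot happen)
      rows[[t_i]] <- prediction_frame(
        tg, mean(v), if (length(v) > 1L) stats::sd(v) else NA_real_,
        length(v), jumps[t_i], s)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$target, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-pass transcriptome prediction
#'
#' Like [predict_single_pass()] but pools the path-level predictions of
#' *all* sources that reach a target within the jump limit, regardless of
#' source order: the reported mean and SD are over the pooled set and
#' `n_paths` is the total across sources. The reachable target set is
#' identical to single-pass; only the statistics differ.
#'
#' @inheritParams predict_single_pass
#' @return a `prediction_result` data frame; `sources_used` is a
#'   comma-separated list in source-panel order.
#' @export
predict_multi_pass <- function(net, sources, policy = path_policy()) {
  stopifnot(inherits(net, "coexpression_network"))
  src <- names(sources)
  check_sources(net, src)
  d <- source_distances(net, src)
  nodes <- colnames(d)
  targets <- setdiff(nodes[apply(d, 2L, min) <= policy$max_len], src)
  if (!length(targets))
    return(prediction_frame(character(), numeric(), numeric(), integer(),
                            integer(), character()))
  pooled <- stats::setNames(vector("list", length(targets)), targets)
  used <- stats::setNames(vector("list", length(targets)), targets)
  for (s in src) {
    preds <- source_path_predictions(net, s, sources[[s]], policy)
    reach <- intersect(targets, names(preds))
    # only pool paths from sources within the jump limit of the target
    reach <- reach[d[s, reach] <= policy$max_len]
    for (tg in reach) {
      pooled[[tg]] <- c(pooled[[tg]], as.numeric(preds[[tg]]))
      used[[tg]] <- c(used[[tg]], s)
    }
  }
  jumps <- as.integer(apply(d[, targets, drop = FALSE], 2L, min))
  rows <- lapply(seq_along(targets), function(i) {
    v <- pooled[[targets[i]]]
    prediction_frame(targets[i], mean(v),
                     if (length(v) > 1L) stats::sd(v) else NA_real_,
                     length(v), jumps[i],
                     paste(used[[targets[i]]], collapse = ","))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$target, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a prediction result as TSV
#' @param x a `prediction_result`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(x, path) {
  stopifnot(inherits(x, "prediction_result"))
  write_atomic(path, function(tmp)
    utils::write.table(x, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE))
}
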