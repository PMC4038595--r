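#' Simulate a modular expression compendium
#'
#' Generates an RMA-scale expression matrix with known co-expression
#' structure. Each module is driven by one standard-normal latent factor
#' `L_m` per sample; gene `g` in module `m` is
#' `c_g + lambda_g * (L_m + s * Z_g)` with `Z_g` iid standard normal.
#' Because signal and noise share the per-gene scale `lambda_g`, every
#' within-module gene pair has expected correlation
#' `1 / (1 + s^2) = target_r`, independent of the loadings, while
#' cross-module correlations are 0 in expectation. `target_r = 1` gives
#' the noiseless limit (every gene an exact affine transform of its
#' module's latent factor). Baselines `c_g` are drawn uniformly from
#' `[6, 12]` and loadings from `[0.5, 1.5]`, emulating RMA log2-intensity
#' compendia.
#'
#' @param module_sizes integer vector, genes per module.
#' @param n_samples number of samples (>= 3).
#' @param target_r expected within-module pairwise correlation in (0, 1].
#' @param seed RNG seed (all randomness is local to the call).
#' @param gene_prefix prefix for generated gene ids.
#' @return list with `matrix` (an [expression_matrix()]) and `truth` (a
#'   `synthetic_truth` list: `true_edges` data frame with generating
#'   slopes/intercepts per within-module pair, `module_assignment`,
#'   `loadings`, `baselines`, `noise_sd`, `target_r`, `seed`).
#' @export
simulate_transcriptomes <- function(module_sizes, n_samples = 600L,
                                    target_r = 0.85, seed = 1L,
                                    gene_prefix = "g") {
  if (any(module_sizes < 1L)) stop("module sizes must be >= 1", call. = FALSE)
  if (n_samples < 3L) stop("need n_samples >= 3", call. = FALSE)
  if (target_r <= 0 || target_r > 1)
    stop("target_r must be in (0, 1]", call. = FALSE)
  noise_sd <- sqrt(1 / target_r - 1)
  n_genes <- sum(module_sizes)
  ids <- sprintf("%s%03d", gene_prefix, seq_len(n_genes))
  module <- rep(seq_along(module_sizes), module_sizes)
  with_seed(seed, {
    lambda <- stats::runif(n_genes, 0.5, 1.5)
    base <- stats::runif(n_genes, 6, 12)
    latent <- matrix(stats::rnorm(length(module_sizes) * n_samples),
                     nrow = length(module_sizes))
    eps <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes)
    vals <- base + lambda * (latent[module, , drop = FALSE] + noise_sd * eps)
    rownames(vals) <- ids
    colnames(vals) <- sprintf("s%03d", seq_len(n_samples))
    # noiseless affine relation between within-module genes i, j:
    # gene_j = (lambda_j/lambda_i) * gene_i + (c_j - slope * c_i)
    edges <- list()
    for (m in seq_along(module_sizes)) {
      idx <- which(module == m)
      if (length(idx) < 2L) next
      cmb <- utils::combn(idx, 2L)
      slope <- lambda[cmb[2L, ]] / lambda[cmb[1L, ]]
      edges[[m]] <- data.frame(
        gene_a = ids[cmb[1L, ]], gene_b = ids[cmb[2L, ]],
        b1 = slope, b0 = base[cmb[2L, ]] - slope * base[cmb[1L, ]],
        target_r = target_r, module = m, stringsAsFactors = FALSE)
    }
    true_edges <- if (length(edges)) do.call(rbind, edges) else
      data.frame(gene_a = character(), gene_b = character(), b1 = numeric(),
                 b0 = numeric(), target_r = numeric(), module = integer(),
                 stringsAsFactors = FALSE)
    rownames(true_edges) <- NULL
    list(matrix = expression_matrix(vals),
         truth = structure(list(true_edges = true_edges,
                                module_assignment =
                                  stats::setNames(module, ids),
                                loadings = stats::setNames(lambda, ids),
                                baselines = stats::setNames(base, ids),
                                noise_sd = noise_sd, target_r = target_r,
                                seed = seed),
                           class = "synthetic_truth"))
  })
}

#' Simulate a layered chain of affinely related genes
#'
#' Builds a layered topology in the spirit of a source-to-target prediction
#' chain: a latent signal follows a stationary AR(1) process across layers,
#' `t_{k+1} = sqrt(1 - noise^2) * t_k + noise * W_k`, and every gene in
#' layer `k` is `c_g + lambda_g * (t_k + gene_noise * Z_g)`. The true edge
#' set connects all gene pairs in consecutive layers (complete bipartite),
#' plus any requested layer-skip edges. With `noise = 0` the whole chain is
#' a deterministic affine transform of the first layer's signal, so chained
#' regression recovers downstream genes exactly; with `noise > 0` the
#' adjacent-layer correlation is `sqrt(1 - noise^2) / (1 + gene_noise^2)`
#' and prediction error grows with the number of jumps.
#'
#' @param layers integer vector of genes per layer (>= 2 layers).
#' @param n_samples number of samples.
#' @param noise layer-process innovation fraction in \[0, 1).
#' @param seed RNG seed.
#' @param gene_noise per-gene measurement noise SD (default 0).
#' @param skip_edges optional 2-column matrix/data frame of extra gene-id
#'   pairs to add to the true edge set (e.g. a layer-skip shortcut).
#' @return list with `matrix` and `truth` as in
#'   [simulate_transcriptomes()]; `truth$chain_layout` maps gene id ->
#'   layer, and gene ids are `L<layer>g<index>`.
#' @export
simulate_chain_network <- function(layers, n_samples = 200L, noise = 0,
                                   seed = 1L, gene_noise = 0,
                                   skip_edges = NULL) {
  if (length(layers) < 2L) stop("need at least 2 layers", call. = FALSE)
  if (any(layers < 1L)) stop("layer sizes must be >= 1", call. = FALSE)
  if (noise < 0 || noise >= 1) stop("noise must be in [0, 1)", call. = FALSE)
  n_layers <- length(layers)
  ids <- unlist(lapply(seq_len(n_layers), function(k)
    sprintf("L%dg%d", k, seq_len(layers[k]))))
  layer_of <- rep(seq_len(n_layers), layers)
  with_seed(seed, {
    lambda <- stats::runif(length(ids), 0.5, 1.5)
    base <- stats::runif(length(ids), 6, 12)
    tt <- matrix(0, nrow = n_layers, ncol = n_samples)
    tt[1L, ] <- stats::rnorm(n_samples)
    keep <- sqrt(1 - noise^2)
    for (k in seq_len(n_layers - 1L))
      tt[k + 1L, ] <- keep * tt[k, ] + noise * stats::rnorm(n_samples)
    eps <- matrix(stats::rnorm(length(ids) * n_samples), nrow = length(ids))
    vals <- base + lambda * (tt[layer_of, , drop = FALSE] + gene_noise * eps)
    rownames(vals) <- ids
    colnames(vals) <- sprintf("s%03d", seq_len(n_samples))
    pairs <- list()
    for (k in seq_len(n_layers - 1L)) {
      a <- ids[layer_of == k]; b <- ids[layer_of == k + 1L]
      pairs[[k]] <- expand.grid(gene_a = a, gene_b = b,
                                stringsAsFactors = FALSE)
    }
    true_edges <- do.call(rbind, pairs)
    if (!is.null(skip_edges)) {
      sk <- as.data.frame(as.matrix(skip_edges), stringsAsFactors = FALSE)
      names(sk) <- c("gene_a", "gene_b")
      true_edges <- rbind(true_edges, sk)
    }
    rownames(true_edges) <- NULL
    list(matrix = expression_matrix(vals),
         truth = structure(list(true_edges = true_edges,
                                chain_layout = stats::setNames(layer_of, ids),
                                loadings = stats::setNames(lambda, ids),
                                baselines = stats::setNames(base, ids),
                                noise_sd = noise, gene_noise = gene_noise,
                                seed = seed),
                           class = "synthetic_truth"))
  })
}

#' Append simulated duplicate probes to a matrix
#'
#' For each listed gene adds a second probe such that the per-array ratio
#' original/duplicate equals a per-gene factor of fixed magnitude
#' `1 +/- target_deviation` (sign random per gene) times a small
#' mean-corrected lognormal per-array jitter. The per-gene *average* ratio
#' (original probe over duplicate, the lexicographic orientation the
#' estimator uses) therefore deviates from 1 by `target_deviation` in
#' expectation, so the intra-array variation estimator applied to the
#' result recovers the configured deviation; the jitter keeps individual
#' arrays from being exact rescalings.
#'
#' @param mat an [expression_matrix()].
#' @param genes row ids of `mat` to duplicate.
#' @param target_deviation configured mean `|avg ratio - 1|` as a percent
#'   (default 19.19, a realistic microarray intra-array noise level).
#' @param seed RNG seed.
#' @param jitter_sd SD of the per-array log-ratio jitter (default 0.05).
#' @return list with `matrix` (original plus `<gene>_dup` rows) and `map`
#'   (a [probe_gene_map()] assigning both probes of each duplicated gene to
#'   the gene, and every other probe to itself).
#' @export
simulate_duplicate_probes <- function(mat, genes, target_deviation = 19.19,
                                      seed = 1L, jitter_sd = 0.05) {
  stopifnot(inherits(mat, "expr_matrix"))
  genes <- as.character(genes)
  miss <- setdiff(genes, rownames(mat))
  if (length(miss))
    stop("gene(s) not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- target_deviation / 100
  with_seed(seed, {
    sign <- sample(c(-1, 1), length(genes), replace = TRUE)
    ratio <- 1 + sign * d
    dup <- matrix(NA_real_, nrow = length(genes), ncol = ncol(mat))
    for (i in seq_along(genes)) {
      jitter <- exp(stats::rnorm(ncol(mat), -jitter_sd^2 / 2, jitter_sd))
      # original / dup = ratio * jitter per array; E[jitter] = 1
      dup[i, ] <- unclass(mat)[genes[i], ] / (ratio[i] * jitter)
    }
    rownames(dup) <- paste0(genes, "_dup")
    colnames(dup) <- colnames(mat)
    out <- rbind(unclass(mat), dup)
    all_probes <- rownames(out)
    gene_of <- all_probes
    gene_of[match(paste0(genes, "_dup"), all_probes)] <- genes
    list(matrix = expression_matrix(out),
         map = probe_gene_map(all_probes, gene_of))
  })
}

#' Build a network over a simulation's true edge set
#'
#' Fits edge models on the simulated matrix restricted to the generator's
#' true pairs, realising the known topology exactly (no threshold applied,
#' so spurious or missing edges cannot distort topology-sensitive tests).
#'
#' @param sim a list with `matrix` and `truth`, as returned by the
#'   simulators.
#' @return a [coexpression_network()] with threshold recorded as 0.
#' @export
network_from_truth <- function(sim) {
  build_network(sim$matrix, pairs = sim$truth$true_edges[, c("gene_a",
                                                             "gene_b")])
}

#' Write simulation truth as JSON
#' @param truth a `synthetic_truth`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  write_atomic(path, function(tmp)
    jsonlite::write_json(unclass(truth), tmp, auto_unbox = TRUE,
                         digits = NA, null = "null"))
}
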