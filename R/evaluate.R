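#' Prediction accuracy report
#'
#' Compares predicted target-gene expression against actual values: the
#' per-gene percent difference `|actual - predicted| / predicted * 100`,
#' the fraction of genes whose actual value lies within +/- t% of the
#' predicted value for each threshold t, and the Pearson correlation
#' between predicted and actual. When jump counts are available the same
#' metrics are stratified by jumps.
#'
#' @param predicted a `prediction_result` or a named numeric vector of
#'   predicted values.
#' @param actual named numeric vector of actual expression values.
#' @param thresholds percent thresholds (default `c(10, 20, 30, 40)`).
#' @param jumps optional named integer vector of jump counts (taken from
#'   `predicted` when it is a `prediction_result`).
#' @return an `accuracy_report` list: `per_gene_pct_diff`,
#'   `within_threshold` (named fractions), `correlation` (`NA` with
#'   `constant_input = TRUE` when either side is constant), `n_genes`, and
#'   `by_jumps` (per-jump list of the same metrics, when jumps known).
#' @export
accuracy_within <- function(predicted, actual,
                            thresholds = c(10, 20, 30, 40), jumps = NULL) {
  if (inherits(predicted, "prediction_result")) {
    jumps <- stats::setNames(predicted$jumps, predicted$target)
    predicted <- stats::setNames(predicted$mean, predicted$target)
  }
  if (is.null(names(predicted)) || is.null(names(actual)))
    stop("predicted and actual must be named", call. = FALSE)
  shared <- intersect(names(predicted), names(actual))
  if (!length(shared))
    stop("no shared genes between predicted and actual", call. = FALSE)
  pred <- predicted[shared]
  act <- actual[shared]
  pct <- abs(act - pred) / abs(pred) * 100
  within <- vapply(thresholds, function(t) mean(pct <= t), numeric(1))
  names(within) <- as.character(thresholds)
  const <- length(shared) < 2L || stats::sd(pred) == 0 ||
    stats::sd(act) == 0
  r <- if (const) NA_real_ else stats::cor(pred, act)
  by_jumps <- NULL
  if (!is.null(jumps)) {
    j <- jumps[shared]
    by_jumps <- lapply(split(seq_along(shared), j), function(idx) {
      p2 <- pct[idx]
      w <- vapply(thresholds, function(t) mean(p2 <= t), numeric(1))
      names(w) <- as.character(thresholds)
      list(n_genes = length(idx), within_threshold = w,
           mean_pct_diff = mean(p2))
    })
  }
  structure(list(per_gene_pct_diff = pct, within_threshold = within,
                 correlation = r, constant_input = const,
                 n_genes = length(shared), by_jumps = by_jumps),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> ", x$n_genes, " gene(s)\n", sep = "")
  cat("  correlation (predicted vs actual): ",
      if (x$constant_input) "undefined (constant input)" else
        format(x$correlation, digits = 4), "\n", sep = "")
  for (t in names(x$within_threshold))
    cat("  within ", t, "%: ",
        format(100 * x$within_threshold[[t]], digits = 4), "% of genes\n",
        sep = "")
  invisible(x)
}

#' Intra-array variation from duplicate probes
#'
#' Genes measured by two probes on the same array should, in principle,
#' give identical values (ratio 1, correlation 1). Departures estimate the
#' within-array measurement noise. Per duplicated gene this computes the
#' Pearson correlation of its two probes' value vectors across arrays and
#' the per-array ratio probe1/probe2 (probes ordered lexicographically);
#' the report averages the correlations and the absolute deviations of the
#' per-gene average ratio from 1:
#' `mean_ratio_deviation = sum(|avg_ratio_g - 1|) / N * 100`.
#'
#' @param mat an [expression_matrix()] with >= 3 arrays.
#' @param dup duplicate-probe list from [duplicate_probe_genes()] or a
#'   [probe_gene_map()].
#' @return an `intra_array_report` list: `per_gene` data frame (gene,
#'   correlation, avg_ratio, abs_dev), `mean_duplicate_correlation`,
#'   `mean_ratio_deviation` (percent), `n_genes`.
#' @export
intra_array_variation <- function(mat, dup) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (ncol(mat) < 3L) stop("need at least 3 arrays", call. = FALSE)
  if (inherits(dup, "probe_gene_map")) dup <- duplicate_probe_genes(dup)
  if (!length(dup)) stop("no duplicated genes supplied", call. = FALSE)
  rows <- list()
  for (g in names(dup)) {
    probes <- sort(dup[[g]])
    if (length(probes) != 2L) {
      warning("gene '", g, "' has ", length(probes),
              " probes (need exactly 2); skipped", call. = FALSE)
      next
    }
    if (!all(probes %in% rownames(mat))) {
      warning("gene '", g, "' has probe(s) missing from the matrix; skipped",
              call. = FALSE)
      next
    }
    p1 <- unclass(mat)[probes[1L], ]
    p2 <- unclass(mat)[probes[2L], ]
    r <- if (stats::sd(p1) == 0 || stats::sd(p2) == 0) {
      if (isTRUE(all.equal(p1, p2))) 1 else NA_real_
    } else stats::cor(p1, p2)
    avg_ratio <- mean(p1 / p2)
    rows[[g]] <- data.frame(gene = g, correlation = r,
                            avg_ratio = avg_ratio,
                            abs_dev = abs(avg_ratio - 1),
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no usable duplicated gene (all skipped)", call. = FALSE)
  per_gene <- do.call(rbind, rows)
  rownames(per_gene) <- NULL
  structure(list(per_gene = per_gene,
                 mean_duplicate_correlation =
                   mean(per_gene$correlation, na.rm = TRUE),
                 mean_ratio_deviation = 100 * mean(per_gene$abs_dev),
                 n_genes = nrow(per_gene)),
            class = "intra_array_report")
}

#' @export
print.intra_array_report <- function(x, ...) {
  cat("<intra_array_report> ", x$n_genes, " duplicated gene(s)\n", sep = "")
  cat("  mean duplicate-probe correlation: ",
      format(x$mean_duplicate_correlation, digits = 4), "\n", sep = "")
  cat("  mean |avg ratio - 1|: ",
      format(x$mean_ratio_deviation, digits = 4), "%\n", sep = "")
  invisible(x)
}
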