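#' Expression matrix container
#'
#' An `expr_matrix` is a numeric matrix of RMA-scale (log2-intensity)
#' expression values with probes/genes as rows and arrays/samples as
#' columns. Row and column names must be unique; values must be finite
#' unless `allow_na = TRUE`, in which case downstream correlation uses
#' pairwise-complete observations with a minimum of 10 shared samples per
#' pair.
#'
#' Probe-level identifiers are treated as opaque strings throughout; the
#' package does not distinguish probes from genes except where a
#' probe-to-gene map is explicitly supplied.
#'
#' @param values numeric matrix with unique rownames (probe/gene ids) and
#'   unique colnames (sample ids).
#' @param allow_na allow missing values (default `FALSE`).
#' @return an object of class `expr_matrix` (a validated numeric matrix).
#' @export
expression_matrix <- function(values, allow_na = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  rid <- rownames(values)
  cid <- colnames(values)
  if (is.null(rid) || is.null(cid))
    stop("expression matrix requires rownames (probes) and colnames (samples)",
         call. = FALSE)
  if (anyDuplicated(rid))
    stop("duplicated row id(s): ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(cid))
    stop("duplicated sample id(s): ",
         paste(unique(cid[duplicated(cid)]), collapse = ", "), call. = FALSE)
  bad <- !is.finite(values)
  if (allow_na) bad <- bad & !is.na(values)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-finite value at row '", rid[w[1L]], "', sample '", cid[w[2L]],
         "'", if (!allow_na) " (use allow_na = TRUE to permit NA)",
         call. = FALSE)
  }
  structure(values, class = c("expr_matrix", "matrix", "array"))
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose header row starts with an `id` column
#' followed by sample ids; each subsequent row is a probe/gene id followed
#' by decimal expression values.
#'
#' @param path path to the TSV file.
#' @param allow_na permit NA cells (empty or `NA`).
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, allow_na = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L)
    stop("malformed header in ", path,
         ": need an id column plus at least one sample column", call. = FALSE)
  if (names(df)[1L] != "id")
    stop("malformed header in ", path, ": first column must be 'id', got '",
         names(df)[1L], "'", call. = FALSE)
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- is.na(num) & !(is.na(vals) | vals == "NA" | vals == "")
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell '", vals[w[1L], w[2L]], "' at row '", ids[w[1L]],
         "', column '", colnames(vals)[w[2L]], "' in ", path, call. = FALSE)
  }
  rownames(num) <- ids
  colnames(num) <- colnames(vals)
  expression_matrix(num, allow_na = allow_na)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; `load(save(x))` reproduces the
#' values up to the 15-significant-digit text representation.
#'
#' @param x an [expression_matrix()].
#' @param path destination path (written atomically).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(paste(c("id", colnames(x)), collapse = "\t"), con)
    body <- apply(format(unclass(x), digits = 15, trim = TRUE,
                         scientific = FALSE), 1L, paste, collapse = "\t")
    writeLines(paste(rownames(x), body, sep = "\t"), con)
  })
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x), " probes/genes x ", ncol(x), " samples\n",
      sep = "")
  cat("  values: [", format(min(x, na.rm = TRUE), digits = 4), ", ",
      format(max(x, na.rm = TRUE), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Probe-to-gene map
#'
#' A two-column mapping in which every probe maps to exactly one gene while
#' a gene may own several probes (the basis of duplicate-probe intra-array
#' analysis).
#'
#' @param probe_id,gene_id character vectors of equal length.
#' @return a `probe_gene_map` data frame with columns `probe_id`, `gene_id`.
#' @export
probe_gene_map <- function(probe_id, gene_id) {
  probe_id <- as.character(probe_id)
  gene_id <- as.character(gene_id)
  if (length(probe_id) != length(gene_id))
    stop("probe_id and gene_id must have equal length", call. = FALSE)
  if (anyDuplicated(probe_id))
    stop("probe mapped to more than one gene: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "),
         call. = FALSE)
  structure(data.frame(probe_id = probe_id, gene_id = gene_id,
                       stringsAsFactors = FALSE),
            class = c("probe_gene_map", "data.frame"))
}

#' Read a probe-to-gene map (2-column TSV, no header)
#' @param path path to the TSV file.
#' @return a [probe_gene_map()].
#' @export
read_probe_gene_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) != 2L)
    stop("probe map must have exactly 2 columns (probe_id, gene_id)",
         call. = FALSE)
  probe_gene_map(df[[1L]], df[[2L]])
}

#' Write a probe-to-gene map
#' @param x a [probe_gene_map()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_probe_gene_map <- function(x, path) {
  stopifnot(inherits(x, "probe_gene_map"))
  write_atomic(path, function(tmp)
    utils::write.table(x, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE))
}

#' Genes represented by two or more probes
#'
#' Returns the genes measured by at least two probes, each with its probe
#' set — the raw material for intra-array variation estimation.
#'
#' @param map a [probe_gene_map()].
#' @return a named list (gene id -> sorted character vector of probe ids),
#'   ordered by gene id; empty when the map is injective.
#' @export
duplicate_probe_genes <- function(map) {
  stopifnot(inherits(map, "probe_gene_map"))
  split_probes <- split(map$probe_id, map$gene_id)
  dup <- split_probes[lengths(split_probes) >= 2L]
  dup <- lapply(dup, sort)
  dup[order(names(dup))]
}

#' Source gene values
#'
#' A named vector of known expression values (RMA scale) for a panel of
#' source (marker) genes, the inputs to transcriptome prediction.
#'
#' @param values named numeric vector; names are gene ids.
#' @return a `source_values` object.
#' @export
source_values <- function(values) {
  if (!is.numeric(values) || is.null(names(values)))
    stop("`values` must be a named numeric vector", call. = FALSE)
  if (anyDuplicated(names(values)))
    stop("duplicated gene id(s) in source values: ",
         paste(unique(names(values)[duplicated(names(values))]),
               collapse = ", "), call. = FALSE)
  if (!all(is.finite(values)))
    stop("source values must be finite", call. = FALSE)
  structure(as.numeric(stats::setNames(values, names(values))),
            names = names(values), class = "source_values")
}

#' Read source gene values (2-column TSV: gene_id, value; no header)
#' @param path path to the TSV file.
#' @return a [source_values()] vector.
#' @export
read_source_values <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "numeric"),
                          quote = "", comment.char = "")
  if (ncol(df) != 2L)
    stop("source value file must have exactly 2 columns (gene_id, value)",
         call. = FALSE)
  source_values(stats::setNames(df[[2L]], df[[1L]]))
}

#' Write source gene values
#' @param x a [source_values()] vector.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_source_values <- function(x, path) {
  stopifnot(inherits(x, "source_values"))
  write_atomic(path, function(tmp)
    utils::write.table(
      data.frame(gene = names(x), value = as.numeric(x)),
      tmp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE))
}
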