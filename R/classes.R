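# S3 containers used throughout the pipeline.

#' Construct a gene pool
#'
#' A gene pool is a curated, ordered set of disease-associated gene symbols,
#' optionally annotated with the number of independent supporting references
#' per gene. Symbols are compared case-insensitively and stored uppercased.
#'
#' @param symbols Character vector of gene symbols. Duplicates (after case
#'   normalisation) are collapsed, summing their reference counts; first-seen
#'   order is preserved.
#' @param ref_counts Optional integer vector of supporting-reference counts,
#'   one per element of `symbols` (each >= 1). If `NULL`, each occurrence of a
#'   symbol counts as one reference.
#' @return An object of class `gene_pool` with elements `symbols` and
#'   `ref_counts` (named integer vector).
#' @examples
#' gene_pool(c("GRIN2A", "DISC1", "grin2a"))
#' @export
gene_pool <- function(symbols, ref_counts = NULL) {
  if (length(symbols) == 0L) .stopf("empty gene pool")
  symbols <- .norm_symbols(symbols)
  if (any(!nzchar(symbols))) .stopf("blank gene symbol in pool")
  if (is.null(ref_counts)) ref_counts <- rep(1L, length(symbols))
  if (length(ref_counts) != length(symbols))
    .stopf("ref_counts length (%d) != symbols length (%d)",
           length(ref_counts), length(symbols))
  if (any(!is.finite(ref_counts)) || any(ref_counts < 1) ||
      any(ref_counts != floor(ref_counts)))
    .stopf("every ref_count must be a positive integer")
  counts <- vapply(split(as.integer(ref_counts), factor(symbols, levels = unique(symbols))),
                   sum, integer(1))
  structure(list(symbols = unique(symbols), ref_counts = counts),
            class = "gene_pool")
}

#' @export
print.gene_pool <- function(x, ...) {
  cat(sprintf("<gene_pool> %d symbols (%s%s)\n", length(x$symbols),
              paste(utils::head(x$symbols, 4), collapse = ", "),
              if (length(x$symbols) > 4) ", ..." else ""))
  invisible(x)
}

#' @export
length.gene_pool <- function(x) length(x$symbols)

#' Construct a case/control expression dataset
#'
#' A genes-by-samples matrix of (preprocessed, log-like scale) expression
#' values with binary case/control sample labels and cohort metadata. Gene
#' symbols are uppercased; rows containing any non-finite value are dropped
#' with a message, matching the no-imputation policy of the pipeline.
#'
#' @param values Numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids).
#' @param labels Named character vector mapping every sample id to `"case"`
#'   or `"control"`.
#' @param metadata List of cohort descriptors; `cohort_id`, `brain_region`
#'   and `ethnicity` are filled with `NA` if absent.
#' @return An object of class `expression_dataset` with elements `values`,
#'   `labels` (aligned to columns) and `metadata`.
#' @export
expression_dataset <- function(values, labels, metadata = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("values must carry gene symbols as rownames and sample ids as colnames")
  rownames(values) <- .norm_symbols(rownames(values))
  if (anyDuplicated(rownames(values)))
    .stopf("duplicate gene symbol after case normalisation: %s",
           rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    .stopf("duplicate sample id: %s", colnames(values)[duplicated(colnames(values))][1])
  bad <- !apply(is.finite(values), 1L, all)
  if (any(bad)) {
    .msgf("dropping %d gene row(s) with non-finite values", sum(bad))
    values <- values[!bad, , drop = FALSE]
  }
  if (nrow(values) == 0L) .stopf("no gene rows remain after dropping non-finite values")
  if (is.null(names(labels))) .stopf("labels must be named by sample id")
  missing_lab <- setdiff(colnames(values), names(labels))
  if (length(missing_lab))
    .stopf("sample(s) without a label: %s", paste(missing_lab, collapse = ", "))
  labels <- labels[colnames(values)]
  if (!all(labels %in% c("case", "control")))
    .stopf("labels must be 'case' or 'control'; got: %s",
           paste(unique(setdiff(labels, c("case", "control"))), collapse = ", "))
  for (f in c("cohort_id", "brain_region", "ethnicity"))
    if (is.null(metadata[[f]])) metadata[f] <- list(NA_character_)
  structure(list(values = values, labels = labels, metadata = metadata),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples (%d case / %d control)%s\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control"),
              if (!is.na(x$metadata$cohort_id))
                paste0(" [", x$metadata$cohort_id, "]") else ""))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Numeric class encoding of a dataset's labels
#'
#' Cases are encoded +1 and controls -1, the response convention used by the
#' sparse-regression ranking and by centroid tie-breaking.
#'
#' @param dataset An `expression_dataset`.
#' @return Named numeric vector of +1/-1, aligned to sample columns.
#' @export
label_vector <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  out <- ifelse(dataset$labels == "case", 1, -1)
  names(out) <- colnames(dataset$values)
  out
}

# Guard used by every classifier-training operation.
.check_two_per_class <- function(dataset) {
  n_case <- sum(dataset$labels == "case")
  n_ctrl <- sum(dataset$labels == "control")
  if (n_case < 2L || n_ctrl < 2L)
    .stopf("need at least 2 samples per class (have %d case, %d control)",
           n_case, n_ctrl)
  invisible(TRUE)
}

#' Construct a ranked gene list
#'
#' @param method `"SRVS"` or `"ANOVA"` (the two ranking schemes), or another
#'   short label for derived rankings.
#' @param table Data frame with at least columns `gene` and `score`;
#'   `anova_scores()` adds `p_value`. Must already be sorted into rank order.
#' @return Object of class `ranked_gene_list`: the table with a `rank`
#'   column and a `method` attribute.
#' @export
ranked_gene_list <- function(method, table) {
  stopifnot(is.data.frame(table), all(c("gene", "score") %in% names(table)))
  table$rank <- seq_len(nrow(table))
  rownames(table) <- NULL
  structure(table, method = method, class = c("ranked_gene_list", "data.frame"))
}

#' @export
print.ranked_gene_list <- function(x, ...) {
  cat(sprintf("<ranked_gene_list> method=%s, %d genes; top: %s\n",
              attr(x, "method"), nrow(x),
              paste(utils::head(x$gene, 5), collapse = ", ")))
  invisible(x)
}

#' Top-n genes of a ranking
#' @param ranking A `ranked_gene_list`.
#' @param n Number of leading genes to return.
#' @return Character vector of the `n` best-ranked gene symbols.
#' @export
top_genes <- function(ranking, n) {
  stopifnot(inherits(ranking, "ranked_gene_list"))
  if (n < 1L || n > nrow(ranking)) .stopf("n must be in [1, %d]", nrow(ranking))
  ranking$gene[seq_len(n)]
}
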