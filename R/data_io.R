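# Readers and writers for the pipeline's plain-text interchange formats:
# gene-pool lists, expression/label TSVs, and GEO Series Matrix text files.

#' Read a gene-pool list
#'
#' One gene symbol per line, with an optional tab-separated second column
#' giving the number of supporting references. Lines starting with `#` are
#' ignored. Duplicate symbols are collapsed and their counts summed; if the
#' count column is absent each line contributes one reference.
#'
#' @param path Path to the pool file.
#' @return A [gene_pool()].
#' @export
read_gene_pool <- function(path) {
  if (!file.exists(path)) .stopf("gene pool file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) .stopf("empty gene pool")
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  symbols <- vapply(parts, `[[`, "", 1L)
  counts <- rep(1L, length(parts))
  has_count <- lengths(parts) >= 2L
  if (any(has_count)) {
    raw <- vapply(parts[has_count], `[[`, "", 2L)
    val <- suppressWarnings(as.numeric(raw))
    bad <- !is.finite(val) | val < 1 | val != floor(val)
    if (any(bad))
      .stopf("malformed reference count '%s' at line %d", raw[bad][1],
             keep[has_count][bad][1])
    counts[has_count] <- as.integer(val)
  }
  gene_pool(symbols, counts)
}

#' Write a gene-pool list
#' @param pool A [gene_pool()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_pool <- function(pool, path) {
  stopifnot(inherits(pool, "gene_pool"))
  writeLines(paste(pool$symbols, pool$ref_counts, sep = "\t"), path)
  invisible(path)
}

# Labels TSV: columns sample_id, label in {case, control}.
.read_labels <- function(path) {
  if (!file.exists(path)) .stopf("labels file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (!all(c("sample_id", "label") %in% names(tab)))
    .stopf("labels file must have columns sample_id and label: %s", path)
  if (anyDuplicated(tab$sample_id))
    .stopf("duplicate sample id in labels file: %s",
           tab$sample_id[duplicated(tab$sample_id)][1])
  bad <- setdiff(unique(tab$label), c("case", "control"))
  if (length(bad)) .stopf("label value outside {case, control}: %s", bad[1])
  stats::setNames(tab$label, tab$sample_id)
}

#' Read an expression matrix with sample labels
#'
#' The matrix is a UTF-8 TSV whose header row holds sample ids and whose
#' first column (`gene_symbol`) holds gene symbols; the labels file is a TSV
#' with columns `sample_id` and `label` (`case`/`control`). Gene rows with
#' any non-finite value are dropped with a message; samples present in the
#' matrix but absent from the labels file are dropped with a warning.
#'
#' @param path Path to the expression TSV.
#' @param labels_path Path to the labels TSV.
#' @param metadata Optional list of cohort descriptors (`cohort_id`,
#'   `brain_region`, `ethnicity`).
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(path, labels_path, metadata = list()) {
  if (!file.exists(path)) .stopf("expression file not found: %s", path)
  labels <- .read_labels(labels_path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (ncol(tab) < 2L) .stopf("expression TSV needs a gene column plus samples: %s", path)
  genes <- .norm_symbols(as.character(tab[[1L]]))
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyDuplicated(colnames(mat)))
    .stopf("duplicate sample id: %s", colnames(mat)[duplicated(colnames(mat))][1])
  if (anyDuplicated(genes)) {
    .msgf("collapsing %d duplicate gene row(s) by mean", sum(duplicated(genes)))
    mat <- .collapse_rows(mat, genes, method = "mean")
  } else {
    rownames(mat) <- genes
  }
  unlabeled <- setdiff(colnames(mat), names(labels))
  if (length(unlabeled)) {
    warning(sprintf("dropping %d unlabeled sample(s): %s", length(unlabeled),
                    paste(unlabeled, collapse = ", ")), call. = FALSE)
    mat <- mat[, setdiff(colnames(mat), unlabeled), drop = FALSE]
  }
  if (ncol(mat) == 0L) .stopf("no labeled samples remain")
  expression_dataset(mat, labels, metadata)
}

#' Write an expression dataset and its labels as TSV
#'
#' Values are written with full double precision so that a write/read cycle
#' round-trips bit-exactly.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path for the expression TSV.
#' @param labels_path Optional output path for the labels TSV.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(dataset, path, labels_path = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = "\t"), "")
  writeLines(c(paste(c("gene_symbol", colnames(v)), collapse = "\t"), body), path)
  if (!is.null(labels_path))
    writeLines(c("sample_id\tlabel",
                 paste(colnames(v), dataset$labels, sep = "\t")), labels_path)
  invisible(path)
}

# Collapse duplicate row keys: arithmetic mean (default) or the single row of
# maximal variance per key.
.collapse_rows <- function(mat, keys, method = c("mean", "max_var")) {
  method <- match.arg(method)
  if (method == "mean") {
    out <- rowsum(mat, group = keys, reorder = FALSE) /
      as.vector(table(factor(keys, levels = unique(keys))))
  } else {
    pick <- vapply(split(seq_along(keys), factor(keys, levels = unique(keys))),
                   function(idx) {
                     if (length(idx) == 1L) return(idx)
                     idx[which.max(apply(mat[idx, , drop = FALSE], 1L, stats::var))]
                   }, integer(1))
    out <- mat[pick, , drop = FALSE]
    rownames(out) <- unique(keys)
  }
  out
}

#' Read a GEO Series Matrix text file
#'
#' Tolerant reader for the Series Matrix dialect: `!`-prefixed metadata
#' lines, then a sample-by-probe table between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers. Probe
#' rows are collapsed to gene-symbol level with the supplied probe-to-symbol
#' map. Labels must either be supplied directly (`labels`/`labels_path`) or
#' be derivable from a `!Sample_characteristics` metadata line via a
#' case-matching regular expression.
#'
#' @param path Path to the (uncompressed) series-matrix text file.
#' @param symbol_map Optional path to a two-column TSV (probe, symbol); probes
#'   without a mapping are dropped. If `NULL`, probe ids are used as symbols.
#' @param labels Optional named character vector of `case`/`control` labels.
#' @param labels_path Optional path to a labels TSV (see
#'   [read_expression_tsv()]).
#' @param case_pattern Optional regular expression; samples whose
#'   characteristics text matches are labeled `case`, the rest `control`.
#' @param characteristics_field Optional regular expression selecting which
#'   `!Sample_characteristics` line to scan (matched against the line's
#'   content); by default all such lines are combined per sample.
#' @param collapse `"mean"` (default) or `"max_var"`: how multiple probes per
#'   symbol are merged.
#' @param metadata Optional cohort descriptors.
#' @return An [expression_dataset()].
#' @export
read_series_matrix <- function(path, symbol_map = NULL, labels = NULL,
                               labels_path = NULL, case_pattern = NULL,
                               characteristics_field = NULL,
                               collapse = c("mean", "max_var"),
                               metadata = list()) {
  collapse <- match.arg(collapse)
  if (!file.exists(path)) .stopf("series-matrix file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    .stopf("not a series-matrix file (missing table markers): %s", path)
  tab <- utils::read.delim(text = paste(lines[(beg + 1L):(end - 1L)], collapse = "\n"),
                           header = TRUE, sep = "\t", quote = "\"",
                           check.names = FALSE)
  probes <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  colnames(mat) <- gsub("^\"|\"$", "", colnames(mat))

  if (!is.null(symbol_map)) {
    map <- utils::read.delim(symbol_map, header = FALSE, sep = "\t",
                             colClasses = "character")
    sym <- stats::setNames(.norm_symbols(map[[2L]]), map[[1L]])
    hit <- probes %in% names(sym)
    if (!any(hit)) .stopf("no probe in the expression table has a symbol mapping")
    mat <- mat[hit, , drop = FALSE]
    keys <- unname(sym[probes[hit]])
  } else {
    keys <- .norm_symbols(probes)
  }
  mat <- .collapse_rows(mat, keys, method = collapse)

  if (is.null(labels) && !is.null(labels_path)) labels <- .read_labels(labels_path)
  if (is.null(labels)) {
    if (is.null(case_pattern))
      .stopf("labels must be supplied (labels/labels_path) or parsed via case_pattern")
    ch <- grep("^!Sample_characteristics", lines, value = TRUE)
    if (!is.null(characteristics_field))
      ch <- ch[grepl(characteristics_field, ch, ignore.case = TRUE)]
    if (length(ch) == 0L) .stopf("no !Sample_characteristics line to parse labels from")
    fields <- lapply(strsplit(ch, "\t", fixed = TRUE), function(x)
      gsub("^\"|\"$", "", x[-1L]))
    if (any(lengths(fields) != ncol(mat)))
      .stopf("characteristics line has %d entries for %d samples",
             lengths(fields)[lengths(fields) != ncol(mat)][1], ncol(mat))
    txt <- do.call(paste, c(fields, sep = "; "))
    labels <- stats::setNames(ifelse(grepl(case_pattern, txt, ignore.case = TRUE),
                                     "case", "control"), colnames(mat))
  }
  expression_dataset(mat, labels, metadata)
}

#' Restrict a dataset to the genes of a curated pool
#'
#' Keeps the intersection of the dataset's genes with the pool, preserving
#' the dataset's gene order, and reports the intersection size. This is the
#' trimming step applied to every cohort before ranking: only curated
#' disease-associated genes enter the feature space.
#'
#' @param dataset An [expression_dataset()].
#' @param pool A [gene_pool()].
#' @return The trimmed `expression_dataset`.
#' @export
trim_to_pool <- function(dataset, pool) {
  stopifnot(inherits(dataset, "expression_dataset"), inherits(pool, "gene_pool"))
  keep <- rownames(dataset$values) %in% pool$symbols
  if (!any(keep)) .stopf("no pool genes measured")
  .msgf("trimmed to %d of %d measured genes present in the pool",
        sum(keep), nrow(dataset$values))
  out <- dataset
  out$values <- dataset$values[keep, , drop = FALSE]
  out
}
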