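# Euclidean nearest-centroid classification under leave-one-out
# cross-validation, and selection of the best top-n gene vector.

#' Classification ratio
#'
#' The accuracy of a classifier: correctly classified subjects over total
#' subjects.
#'
#' @param correct Non-negative integer count of correct classifications.
#' @param total Positive integer count of subjects.
#' @return `correct / total`.
#' @examples
#' classification_ratio(62, 69) # 0.8986
#' @export
classification_ratio <- function(correct, total) {
  if (!.is_count(total) || total <= 0) .stopf("total must be a positive integer")
  if (!.is_count(correct) || correct < 0) .stopf("correct must be a non-negative integer")
  if (correct > total) .stopf("correct (%d) exceeds total (%d)", correct, total)
  correct / total
}

# Precomputed per-gene, per-fold squared standardised distances to each class
# centroid. Because squared Euclidean distance is additive over genes, the
# LOO prediction for ANY gene subset reduces to column sums over the subset's
# rows of these two matrices; every downstream evaluation (CR curves,
# permutation runs, baselines) reuses one precomputation.
#
# For fold i (sample i left out), gene g: training mean/SD standardisation of
# both the test value and the class centroids makes the contribution
#   (x[g,i] - mean_class^{(-i)}[g])^2 / var^{(-i)}[g].
# Genes whose training fold has zero variance contribute 0 to both classes
# (their standardised column is defined as all-zero).
.loo_contrib <- function(dataset) {
  x <- dataset$values
  G <- nrow(x); N <- ncol(x)
  if (N < 3L) .stopf("need at least 3 samples for leave-one-out")
  .check_two_per_class(dataset)
  ic <- dataset$labels == "case"
  n_case <- sum(ic); n_ctrl <- N - n_case

  S <- rowSums(x)
  Q <- rowSums(x^2)
  M <- (S - x) / (N - 1)                      # training mean, G x N
  VAR <- ((Q - x^2) - (N - 1) * M^2) / (N - 2) # training variance, G x N
  icm <- matrix(ic, G, N, byrow = TRUE)
  s_case <- rowSums(x[, ic, drop = FALSE])
  s_ctrl <- S - s_case
  MC <- (s_case - x * icm) / matrix(n_case - ic, G, N, byrow = TRUE)
  MD <- (s_ctrl - x * (!icm)) / matrix(n_ctrl - !ic, G, N, byrow = TRUE)

  zero_var <- VAR <= 1e-12 * (Q / N + 1)      # constant (or near) training fold
  VAR[zero_var] <- 1
  d_case <- (x - MC)^2 / VAR
  d_ctrl <- (x - MD)^2 / VAR
  d_case[zero_var] <- 0
  d_ctrl[zero_var] <- 0

  list(d_case = d_case, d_ctrl = d_ctrl, is_case = ic,
       n_case = n_case, n_ctrl = n_ctrl, genes = rownames(x))
}

# Fold predictions from cumulative class distances DC/DD (folds in columns).
# Exact distance ties go to the class with more training samples, then to
# control.
.loo_decide <- function(DC, DD, contrib) {
  ic <- contrib$is_case
  N <- length(ic)
  if (is.null(dim(DC))) { DC <- matrix(DC, 1L, N); DD <- matrix(DD, 1L, N) }
  pred_case <- DC < DD
  tie <- abs(DC - DD) <= 1e-9 * pmax(1, abs(DC) + abs(DD))
  if (any(tie)) {
    tr_case <- matrix(contrib$n_case - ic, nrow(DC), N, byrow = TRUE)
    tr_ctrl <- matrix(contrib$n_ctrl - !ic, nrow(DC), N, byrow = TRUE)
    pred_case[tie] <- (tr_case > tr_ctrl)[tie]
  }
  correct <- sweep(pred_case, 2L, ic, `==`)
  rowMeans(correct)
}

# LOO CR of one gene subset given precomputed contributions.
.loo_cr_rows <- function(contrib, rows) {
  DC <- colSums(contrib$d_case[rows, , drop = FALSE])
  DD <- colSums(contrib$d_ctrl[rows, , drop = FALSE])
  .loo_decide(DC, DD, contrib)[1L]
}

#' Leave-one-out classification ratio of a gene subset
#'
#' Each sample in turn is held out; every gene is standardised with the
#' training fold's mean and SD, case and control centroids are the training
#' class means in the selected gene subspace, and the held-out sample is
#' assigned to the class with the smaller Euclidean distance (exact ties go
#' to the class with more training samples, then to control). Deterministic.
#'
#' @param dataset An [expression_dataset()].
#' @param genes Character vector of gene symbols to classify with.
#' @return The classification ratio in `[0, 1]`.
#' @export
loo_cr <- function(dataset, genes) {
  stopifnot(inherits(dataset, "expression_dataset"))
  genes <- .norm_symbols(genes)
  miss <- setdiff(genes, rownames(dataset$values))
  if (length(miss)) .stopf("gene(s) absent from dataset: %s", paste(miss, collapse = ", "))
  contrib <- .loo_contrib(dataset)
  .loo_cr_rows(contrib, match(genes, contrib$genes))
}

#' Classification-ratio curve over top-n gene vectors
#'
#' `cr_values[n]` is the LOO classification ratio of the top-`n` genes of the
#' ranking. The ranking is computed once on the full dataset before
#' cross-validation (the workflow's published ordering of steps); see the
#' package vignette for the selection-bias caveat and the nested alternative.
#'
#' @param dataset An [expression_dataset()].
#' @param ranking A [ranked_gene_list()] over genes of `dataset`.
#' @param n_max Largest subset size to evaluate (defaults to all ranked
#'   genes).
#' @return Object of class `cr_curve`: a data frame with columns `n`, `cr`.
#' @export
cr_curve <- function(dataset, ranking, n_max = nrow(ranking)) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(ranking, "ranked_gene_list"))
  if (!.is_count(n_max) || n_max < 1 || n_max > nrow(ranking))
    .stopf("n_max must be in [1, %d]", nrow(ranking))
  contrib <- .loo_contrib(dataset)
  rows <- match(ranking$gene[seq_len(n_max)], contrib$genes)
  if (anyNA(rows))
    .stopf("ranked gene absent from dataset: %s",
           ranking$gene[seq_len(n_max)][is.na(rows)][1])
  DC <- apply(contrib$d_case[rows, , drop = FALSE], 2L, cumsum)
  DD <- apply(contrib$d_ctrl[rows, , drop = FALSE], 2L, cumsum)
  cr <- .loo_decide(DC, DD, contrib)
  structure(data.frame(n = seq_len(n_max), cr = cr),
            method = attr(ranking, "method"),
            class = c("cr_curve", "data.frame"))
}

#' Select the best top-n classifier from a CR curve
#'
#' The best gene vector is the smallest `n` attaining the curve's maximum
#' classification ratio.
#'
#' @param curve A [cr_curve()].
#' @param ranking The [ranked_gene_list()] the curve was computed from.
#' @return A `classifier_result`: list with `method`, `gene_vector`,
#'   `best_n`, `max_cr`, `curve`, and (initially `NULL`) `permutation`.
#' @export
select_best <- function(curve, ranking) {
  stopifnot(inherits(curve, "cr_curve"), inherits(ranking, "ranked_gene_list"))
  if (nrow(curve) == 0L) .stopf("empty CR curve")
  best <- which.max(curve$cr)  # first maximum = smallest n
  classifier_result(method = attr(ranking, "method"),
                    gene_vector = top_genes(ranking, curve$n[best]),
                    best_n = curve$n[best], max_cr = curve$cr[best],
                    curve = curve)
}

#' Construct a classifier result
#' @param method Ranking method label (`"SRVS"`, `"ANOVA"`, `"POOL_ALL"`,
#'   `"RANDOM"`).
#' @param gene_vector Ordered gene symbols of the classifier.
#' @param best_n Number of genes (must equal `length(gene_vector)`).
#' @param max_cr The classifier's LOO classification ratio.
#' @param curve The full [cr_curve()] (may be a single point).
#' @param permutation Optional [permutation_pvalue()] result.
#' @return Object of class `classifier_result`.
#' @export
classifier_result <- function(method, gene_vector, best_n, max_cr, curve,
                              permutation = NULL) {
  if (best_n != length(gene_vector))
    .stopf("best_n (%d) != length(gene_vector) (%d)", best_n, length(gene_vector))
  if (max_cr < 0 || max_cr > 1) .stopf("max_cr must be in [0, 1]")
  structure(list(method = method, gene_vector = gene_vector,
                 best_n = as.integer(best_n), max_cr = max_cr, curve = curve,
                 permutation = permutation),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("<classifier_result> %s: best_n=%d, CR=%.4f%s\n",
              x$method, x$best_n, x$max_cr,
              if (!is.null(x$permutation))
                paste0(", permutation p ", x$permutation$reported) else ""))
  invisible(x)
}
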