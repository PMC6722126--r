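# Comparison of classifier gene sets across cohorts and methods: Jaccard
# similarity, factor ANOVA on similarity, and cross-study summary statistics.

#' Jaccard similarity of two gene sets
#'
#' Intersection size over union size, computed on case-normalised unique
#' symbols.
#'
#' @param set_a,set_b Character vectors of gene symbols (non-empty).
#' @return The Jaccard similarity in `[0, 1]`.
#' @export
jaccard_score <- function(set_a, set_b) {
  a <- unique(.norm_symbols(set_a))
  b <- unique(.norm_symbols(set_b))
  if (length(a) == 0L || length(b) == 0L) .stopf("empty gene set")
  length(intersect(a, b)) / length(union(a, b))
}

#' Jaccard similarity matrix over (cohort, method) classifier gene sets
#'
#' Builds the full square matrix of pairwise Jaccard similarities among the
#' supplied classifier gene sets. Following the display convention of the
#' workflow this mirrors, diagonal entries (a set against itself, trivially
#' 1) are set to 0 so off-diagonal structure is readable.
#'
#' @param gene_sets List of character vectors (classifier gene sets).
#' @param cohort Character vector of cohort ids, one per set.
#' @param method Character vector of method labels, one per set.
#' @return Object of class `similarity_matrix`: a square numeric matrix with
#'   `"cohort.method"` dimnames and attributes `cohort`, `method`.
#' @export
jaccard_matrix <- function(gene_sets, cohort, method) {
  if (length(gene_sets) < 2L) .stopf("need at least 2 gene sets")
  if (length(cohort) != length(gene_sets) || length(method) != length(gene_sets))
    .stopf("cohort and method must have one entry per gene set")
  labels <- paste(cohort, method, sep = ".")
  if (anyDuplicated(labels))
    .stopf("duplicate (cohort, method) label: %s", labels[duplicated(labels)][1])
  L <- length(gene_sets)
  m <- diag(0, L)
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    m[i, j] <- m[j, i] <- jaccard_score(gene_sets[[i]], gene_sets[[j]])
  }
  dimnames(m) <- list(labels, labels)
  structure(m, cohort = as.character(cohort), method = as.character(method),
            class = c("similarity_matrix", "matrix", "array"))
}

#' Write a similarity matrix as TSV
#' @param sim A [jaccard_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  utils::write.table(cbind(label = rownames(sim), as.data.frame(unclass(sim))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Main-effects N-way ANOVA with sequential sums of squares
#'
#' Fits a main-effects-only linear model of the response on the given
#' categorical factors and returns the sequential (Type I) ANOVA table in
#' the supplied factor order: per factor, sum of squares, degrees of
#' freedom, mean square, `F` against the error mean square, and the p-value
#' from the F distribution; plus `Error` and `Total` rows.
#'
#' @param response Numeric vector.
#' @param factors List of categorical vectors, each the length of
#'   `response`, each with at least 2 observed levels.
#' @param factor_names Names for the table's factor rows (defaults to
#'   `names(factors)` or `F1..Fk`).
#' @return Object of class `anova_table`: data frame with columns `source`,
#'   `sum_sq`, `df`, `mean_sq`, `f`, `p`.
#' @export
nway_anova <- function(response, factors, factor_names = names(factors)) {
  if (!is.list(factors) || length(factors) == 0L) .stopf("factors must be a non-empty list")
  if (is.null(factor_names)) factor_names <- paste0("F", seq_along(factors))
  if (any(lengths(factors) != length(response)))
    .stopf("every factor must have the length of the response (%d)", length(response))
  fl <- lapply(factors, function(f) factor(as.character(f)))
  if (any(vapply(fl, nlevels, 0L) < 2L))
    .stopf("each factor needs at least 2 observed levels")
  dat <- data.frame(.y = as.numeric(response), fl)
  names(dat) <- c(".y", paste0(".f", seq_along(fl)))
  fit <- stats::lm(stats::as.formula(
    paste(".y ~", paste(names(dat)[-1L], collapse = " + "))), data = dat)
  if (stats::df.residual(fit) == 0L) .stopf("saturated model")
  a <- stats::anova(fit)  # sequential Type I SS in model order
  k <- length(fl)
  tab <- data.frame(
    source = c(factor_names, "Error", "Total"),
    sum_sq = c(a$`Sum Sq`[seq_len(k)], a$`Sum Sq`[k + 1L], sum(a$`Sum Sq`)),
    df = c(a$Df[seq_len(k)], a$Df[k + 1L], sum(a$Df)),
    mean_sq = c(a$`Mean Sq`[seq_len(k)], a$`Mean Sq`[k + 1L], NA_real_),
    f = c(a$`F value`[seq_len(k)], NA_real_, NA_real_),
    p = c(a$`Pr(>F)`[seq_len(k)], NA_real_, NA_real_))
  structure(tab, class = c("anova_table", "data.frame"))
}

#' Factor ANOVA on a classifier-similarity matrix
#'
#' Regresses every cell of the similarity matrix (including the zeroed
#' diagonal) on cohort-level factors of the cell's ROW study, mirroring the
#' convention under which a 28 x 28 matrix yields total df = 783. The
#' statistically cleaner variant using only the upper off-diagonal triangle
#' is available via `cells = "offdiag-upper"`.
#'
#' @param sim A [jaccard_matrix()] result.
#' @param factors Named list of per-set factor vectors (one value per matrix
#'   row), e.g. brain region, ethnicity, ranking method.
#' @param cells `"all"` (default) or `"offdiag-upper"`.
#' @return An `anova_table` (see [nway_anova()]).
#' @export
similarity_anova <- function(sim, factors, cells = c("all", "offdiag-upper")) {
  cells <- match.arg(cells)
  stopifnot(inherits(sim, "similarity_matrix"))
  L <- nrow(sim)
  if (any(lengths(factors) != L))
    .stopf("each factor must have one value per matrix row (%d)", L)
  if (cells == "all") {
    keep <- matrix(TRUE, L, L)
  } else {
    keep <- upper.tri(matrix(0, L, L))
  }
  row_of_cell <- matrix(seq_len(L), L, L)[keep]  # column-major: row index
  nway_anova(unclass(sim)[keep],
             lapply(factors, function(f) f[row_of_cell]),
             factor_names = names(factors))
}

# Parse permutation p-values that may be censored as "<bound"; returns the
# numeric value (bound for censored entries) and a censoring flag.
.parse_p <- function(p) {
  p <- trimws(as.character(p))
  cens <- startsWith(p, "<")
  val <- suppressWarnings(as.numeric(sub("^<", "", p)))
  if (anyNA(val)) .stopf("unparseable permutation p-value: %s", p[is.na(val)][1])
  list(value = val, censored = cens)
}

#' Cross-study summary of per-cohort classifier results
#'
#' Aggregates per-cohort classification ratios and permutation p-values into
#' per-method summary statistics: mean and sample SD of CR on the percent
#' scale, and the mean permutation p-value, where censored entries of the
#' form `"<x"` contribute their upper bound `x`. Between-method CR
#' differences are assessed per method pair with the Welch two-sample t-test
#' (and, when cohorts align, the paired t-test).
#'
#' @param results Long-format data frame with columns `cohort`, `method`,
#'   `cr` (classification ratio, fraction or percent), `perm_p` (numeric or
#'   character, `"<x"` allowed). Build it from `classifier_result` objects
#'   with [results_table()], or read a published results table with
#'   [read_results_fixture()].
#' @return Object of class `cross_study_summary`: list with `per_method`
#'   (data frame: method, n, mean_cr, sd_cr, mean_perm_p) and `pairwise`
#'   (data frame: method_a, method_b, welch_p, paired_p).
#' @export
summarize_studies <- function(results) {
  req <- c("cohort", "method", "cr", "perm_p")
  if (!is.data.frame(results) || !all(req %in% names(results)))
    .stopf("results must be a data frame with columns %s", paste(req, collapse = ", "))
  if (length(unique(results$cohort)) < 2L) .stopf("need at least 2 cohorts")
  cr <- as.numeric(results$cr)
  if (max(cr, na.rm = TRUE) <= 1) {
    .msgf("classification ratios look fractional; converting to percent")
    cr <- cr * 100
  } else if (min(cr, na.rm = TRUE) < 1 && max(cr, na.rm = TRUE) > 1) {
    .msgf("mixed CR scales detected; normalising values <= 1 to percent")
    cr[cr <= 1] <- cr[cr <= 1] * 100
  }
  pp <- .parse_p(results$perm_p)
  methods <- unique(results$method)
  per_method <- do.call(rbind, lapply(methods, function(m) {
    i <- results$method == m
    data.frame(method = m, n = sum(i), mean_cr = mean(cr[i]),
               sd_cr = stats::sd(cr[i]), mean_perm_p = mean(pp$value[i]),
               perm_p_censored = any(pp$censored[i]))
  }))
  pairs <- if (length(methods) >= 2L) utils::combn(methods, 2L, simplify = FALSE) else list()
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    ia <- results$method == pr[1]; ib <- results$method == pr[2]
    paired_p <- NA_real_
    if (sum(ia) == sum(ib) &&
        identical(sort(results$cohort[ia]), sort(results$cohort[ib]))) {
      a <- cr[ia][order(results$cohort[ia])]
      b <- cr[ib][order(results$cohort[ib])]
      paired_p <- if (stats::sd(a - b) == 0) 1 else
        stats::t.test(a, b, paired = TRUE)$p.value
    }
    welch_p <- if (stats::sd(cr[ia]) == 0 && stats::sd(cr[ib]) == 0 &&
                   mean(cr[ia]) == mean(cr[ib])) 1 else
                     stats::t.test(cr[ia], cr[ib])$p.value
    data.frame(method_a = pr[1], method_b = pr[2], welch_p = welch_p,
               paired_p = paired_p)
  }))
  structure(list(per_method = per_method, pairwise = pairwise),
            class = "cross_study_summary")
}

#' @export
print.cross_study_summary <- function(x, ...) {
  cat("<cross_study_summary>\n")
  pm <- x$per_method
  for (i in seq_len(nrow(pm)))
    cat(sprintf("  %-8s CR = %.2f +/- %.2f%%, mean permutation p %s%.3g\n",
                pm$method[i], pm$mean_cr[i], pm$sd_cr[i],
                if (pm$perm_p_censored[i]) "<= " else "= ", pm$mean_perm_p[i]))
  if (!is.null(x$pairwise) && nrow(x$pairwise))
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %s vs %s: Welch p = %.3g\n", x$pairwise$method_a[i],
                  x$pairwise$method_b[i], x$pairwise$welch_p[i]))
  invisible(x)
}

#' Flatten per-cohort classifier results into a summary table
#'
#' @param cohort_results Named list (by cohort id) of lists of
#'   `classifier_result` objects (e.g. the output of [run_cohort()] per
#'   cohort).
#' @return Long-format data frame with columns `cohort`, `method`, `cr`
#'   (percent), `n_genes`, `perm_p` (character; censored entries keep their
#'   `"<x"` form).
#' @export
results_table <- function(cohort_results) {
  rows <- list()
  for (cid in names(cohort_results)) {
    for (res in cohort_results[[cid]]) {
      stopifnot(inherits(res, "classifier_result"))
      perm_p <- if (is.null(res$permutation)) NA_character_ else
        res$permutation$reported
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = cid, method = res$method, cr = 100 * res$max_cr,
        n_genes = res$best_n, perm_p = perm_p)
    }
  }
  do.call(rbind, rows)
}

#' Read a published per-cohort results table
#'
#' Reads the wide results-fixture layout: one row per cohort with columns
#' `cohort`, `cr_srvs`, `cr_anova`, `cr_pool` (percent), `n_srvs`,
#' `n_anova`, `n_pool`, `p_srvs`, `p_anova`, `p_pool` (permutation
#' p-values, `"<x"` allowed), and converts it to the long format expected by
#' [summarize_studies()]. The package ships such a fixture for the 14-cohort
#' schizophrenia brain-expression study its workflow mirrors; see
#' `system.file("extdata", "scz_cohort_summary.tsv", package = "coresig")`.
#'
#' @param path Path to the TSV.
#' @return Long-format data frame with columns `cohort`, `method`, `cr`,
#'   `n_genes`, `perm_p`.
#' @export
read_results_fixture <- function(path) {
  if (!file.exists(path)) .stopf("results fixture not found: %s", path)
  w <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         colClasses = "character")
  need <- c("cohort", "cr_srvs", "cr_anova", "cr_pool", "p_srvs", "p_anova", "p_pool")
  if (!all(need %in% names(w)))
    .stopf("results fixture must have columns %s", paste(need, collapse = ", "))
  long <- do.call(rbind, lapply(list(c("SRVS", "srvs"), c("ANOVA", "anova"),
                                     c("POOL_ALL", "pool")), function(m) {
    data.frame(cohort = w$cohort, method = m[1],
               cr = as.numeric(w[[paste0("cr_", m[2])]]),
               n_genes = if (paste0("n_", m[2]) %in% names(w))
                 as.integer(w[[paste0("n_", m[2])]]) else NA_integer_,
               perm_p = w[[paste0("p_", m[2])]])
  }))
  rownames(long) <- NULL
  long
}
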