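# Permutation significance of an observed classifier CR against random
# same-size gene sets, and random-gene CR baselines.

#' Permutation p-value of an observed classification ratio
#'
#' Tests whether randomly selected gene sets of the same size reach an equal
#' or higher LOO classification ratio. Each run draws `k` distinct genes
#' uniformly from the permutation universe (by default all genes measured in
#' `dataset`), evaluates the nearest-centroid LOO classifier, and the
#' p-value is the fraction of runs with CR at least the observed value.
#' When no run qualifies, the reported string is `"<1/runs"`, e.g.
#' `"<2.00e-04"` at 5000 runs.
#'
#' Each run uses an independent seeded RNG stream, so the result is
#' identical for any evaluation order or worker count given the same seed.
#'
#' @param dataset An [expression_dataset()] defining the permutation
#'   universe (pass the untrimmed dataset to draw from all measured genes,
#'   or the trimmed one to restrict the universe to pool genes).
#' @param k Size of each random gene set (the observed classifier's size).
#' @param observed_cr The observed classification ratio in `[0, 1]`.
#' @param runs Number of permutation runs (default 5000).
#' @param seed Integer seed.
#' @param estimator `"count"` (default): `p = count / runs`, the convention
#'   under which a zero count reports `"<1/runs"`; `"plus_one"`: the
#'   conventional `(count + 1) / (runs + 1)` estimator.
#' @return Object of class `permutation_result`: list with `runs`,
#'   `better_or_equal`, `p_value`, `reported`, `seed`, `estimator`.
#' @export
permutation_pvalue <- function(dataset, k, observed_cr, runs = 5000L, seed = 1L,
                               estimator = c("count", "plus_one")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!.is_count(runs) || runs < 1) .stopf("runs must be a positive integer")
  if (!is.numeric(observed_cr) || observed_cr < 0 || observed_cr > 1)
    .stopf("observed_cr must be in [0, 1]")
  contrib <- .loo_contrib(dataset)
  G <- nrow(dataset$values)
  if (!.is_count(k) || k < 1 || k > G)
    .stopf("k must be in [1, %d] (permutation universe size)", G)
  crs <- vapply(seq_len(runs), function(r) {
    rows <- .with_seed(.derive_seed(seed, r), sample.int(G, k))
    .loo_cr_rows(contrib, rows)
  }, numeric(1))
  count <- sum(crs >= observed_cr - 1e-12)
  p <- if (estimator == "count") count / runs else (count + 1) / (runs + 1)
  reported <- if (estimator == "count" && count == 0L)
    paste0("<", formatC(1 / runs, format = "e", digits = 2))
  else formatC(p, format = "e", digits = 2)
  structure(list(runs = as.integer(runs), better_or_equal = as.integer(count),
                 p_value = p, reported = reported, seed = as.integer(seed),
                 estimator = estimator),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> p %s (%d/%d runs with equal or better CR)\n",
              x$reported, x$better_or_equal, x$runs))
  invisible(x)
}

#' Random-gene classification-ratio baseline curve
#'
#' The chance-level reference for a top-n CR curve: for each `n`, the mean
#' LOO classification ratio of `reps` gene sets of size `n` drawn uniformly
#' from the genes measured in `dataset` (default 300 repetitions per point).
#' Deterministic given the seed, independent of evaluation order.
#'
#' @param dataset An [expression_dataset()].
#' @param n_values Integer vector of set sizes.
#' @param reps Repetitions per point (default 300).
#' @param seed Integer seed.
#' @return Object of class `baseline_curve`: data frame with columns `n`,
#'   `mean_cr`; attributes `reps` and `seed`.
#' @export
baseline_curve <- function(dataset, n_values, reps = 300L, seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!.is_count(reps) || reps < 1) .stopf("reps must be a positive integer")
  contrib <- .loo_contrib(dataset)
  G <- nrow(dataset$values)
  n_values <- as.integer(n_values)
  if (any(n_values < 1L) || max(n_values) > G)
    .stopf("n_values must lie in [1, %d]", G)
  mean_cr <- vapply(seq_along(n_values), function(j) {
    n <- n_values[j]
    mean(vapply(seq_len(reps), function(r) {
      rows <- .with_seed(.derive_seed(seed, as.double(j) * 100003 + r),
                         sample.int(G, n))
      .loo_cr_rows(contrib, rows)
    }, numeric(1)))
  }, numeric(1))
  structure(data.frame(n = n_values, mean_cr = mean_cr),
            reps = as.integer(reps), seed = as.integer(seed),
            class = c("baseline_curve", "data.frame"))
}

#' Write a baseline curve as TSV
#' @param baseline A [baseline_curve()].
#' @param path Output path (columns n, mean_cr).
#' @return `path`, invisibly.
#' @export
write_baseline_tsv <- function(baseline, path) {
  stopifnot(inherits(baseline, "baseline_curve"))
  utils::write.table(as.data.frame(baseline), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
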