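# Per-gene ranking of pool genes within one cohort: SRVS sparse weights and
# one-way ANOVA p-values.

#' SRVS configuration
#'
#' Tuning parameters for sparse representation-based variable selection.
#' Each iteration regresses the centred +/-1 class label on a random gene
#' subset with an l1 penalty; a gene's SRVS score is its mean absolute
#' coefficient over the iterations in which it was sampled.
#'
#' @param iterations Number of random-subset regressions (default 1000).
#' @param subset_size Genes drawn per iteration; default
#'   `min(n_samples - 2, ceiling(n_genes / 10))`, resolved when the dataset
#'   is seen.
#' @param l1_penalty Penalty weight lambda of the objective
#'   `||y - X b||^2 / (2n) + lambda * ||b||_1` on per-gene standardised
#'   expression. If `NULL`, chosen from an internal logarithmic grid of 10
#'   values by maximising the leave-one-out classification ratio of the
#'   top-10 ranked genes on a reduced-iteration pass (the choice is
#'   reported).
#' @param seed Integer seed; the whole ranking is deterministic given it.
#' @return Object of class `srvs_config`.
#' @export
srvs_config <- function(iterations = 1000L, subset_size = NULL,
                        l1_penalty = NULL, seed = 1L) {
  if (!.is_count(iterations) || iterations < 1) .stopf("iterations must be a positive integer")
  if (!is.null(subset_size) && (!.is_count(subset_size) || subset_size < 1))
    .stopf("subset_size must be a positive integer")
  if (!is.null(l1_penalty) && (!is.numeric(l1_penalty) || l1_penalty <= 0))
    .stopf("l1_penalty must be positive")
  structure(list(iterations = as.integer(iterations), subset_size = subset_size,
                 l1_penalty = l1_penalty, seed = as.integer(seed)),
            class = "srvs_config")
}

# Per-gene z-scoring across samples (rows of a genes x samples matrix).
# Zero-variance genes become all-zero rows, so they can never earn weight.
.standardize_rows <- function(v) {
  mu <- rowMeans(v)
  sd <- sqrt(rowSums((v - mu)^2) / max(ncol(v) - 1L, 1L))
  z <- (v - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

# Coordinate descent for min_b ||y - X b||^2 / (2n) + lambda ||b||_1.
# Covariance updates; converges for any fixed lambda since the objective is
# convex and separable per coordinate.
.lasso_cd <- function(X, y, lambda, tol = 1e-8, maxit = 100000L) {
  n <- nrow(X)
  p <- ncol(X)
  G <- crossprod(X) / n
  cvec <- drop(crossprod(X, y)) / n
  b <- numeric(p)
  d <- diag(G)
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (d[j] <= 0) next  # zero-variance column: coefficient stays 0
      r <- cvec[j] - sum(G[, j] * b) + d[j] * b[j]
      bj <- sign(r) * max(abs(r) - lambda, 0) / d[j]
      delta <- max(delta, abs(bj - b[j]))
      b[j] <- bj
    }
    if (delta < tol) break
  }
  b
}

# Internal: one full SRVS accumulation pass at a fixed lambda.
.srvs_pass <- function(z, y, iterations, subset_size, lambda, seed) {
  G <- nrow(z)
  acc <- numeric(G)
  cnt <- integer(G)
  .with_seed(seed, {
    for (t in seq_len(iterations)) {
      idx <- sample.int(G, subset_size)
      b <- .lasso_cd(t(z[idx, , drop = FALSE]), y, lambda)
      acc[idx] <- acc[idx] + abs(b)
      cnt[idx] <- cnt[idx] + 1L
    }
  })
  list(score = acc / pmax(cnt, 1L), count = cnt)
}

#' Rank genes by SRVS score
#'
#' Repeatedly draws random gene subsets, solves an l1-penalised least-squares
#' regression of the centred class label on the subset's standardised
#' expression, and accumulates each gene's absolute coefficient. The final
#' score (mean absolute coefficient over times sampled) ranks genes in
#' descending order; ties break lexicographically by symbol.
#'
#' @param dataset An [expression_dataset()], already trimmed to the pool.
#' @param config An [srvs_config()].
#' @return A [ranked_gene_list()] with columns `gene`, `score`, `n_sampled`,
#'   `rank`; attribute `l1_penalty` records the penalty used.
#' @export
srvs_scores <- function(dataset, config = srvs_config()) {
  stopifnot(inherits(dataset, "expression_dataset"), inherits(config, "srvs_config"))
  .check_two_per_class(dataset)
  G <- nrow(dataset$values)
  n <- ncol(dataset$values)
  m <- config$subset_size
  if (is.null(m)) m <- max(1L, min(n - 2L, ceiling(G / 10)))
  if (m > G) .stopf("subset_size (%d) exceeds number of genes (%d)", m, G)
  if (config$iterations * m < 5 * G)
    warning(sprintf(
      "iterations x subset_size = %d < 5 x genes = %d; some genes may never be sampled",
      config$iterations * m, 5L * G), call. = FALSE)

  z <- .standardize_rows(dataset$values)
  y <- label_vector(dataset)
  y <- y - mean(y)

  lambda <- config$l1_penalty
  if (is.null(lambda)) {
    lambda <- .select_lambda(dataset, z, y, config, m)
    .msgf("selected l1_penalty = %.6g by top-10 LOO classification ratio", lambda)
  }

  pass <- .srvs_pass(z, y, config$iterations, m, lambda, config$seed)
  if (any(pass$count == 0L))
    warning(sprintf("%d gene(s) never sampled; their SRVS score is 0",
                    sum(pass$count == 0L)), call. = FALSE)
  ord <- order(-pass$score, rownames(dataset$values))
  tab <- data.frame(gene = rownames(dataset$values)[ord],
                    score = pass$score[ord],
                    n_sampled = pass$count[ord])
  out <- ranked_gene_list("SRVS", tab)
  attr(out, "l1_penalty") <- lambda
  out
}

# Lambda grid: 10 log-spaced values below lambda_max = max |X'y| / n (above
# which every coefficient is zero). Scored by LOO CR of the top-10 genes from
# a reduced-iteration pass; ties prefer the larger (sparser) lambda.
.select_lambda <- function(dataset, z, y, config, m) {
  lambda_max <- max(abs(z %*% y)) / length(y)
  if (lambda_max <= 0) return(1e-3)
  grid <- lambda_max * 10^seq(log10(0.5), log10(0.005), length.out = 10)
  iters <- min(config$iterations, 100L)
  contrib <- .loo_contrib(dataset)
  best <- grid[1]
  best_cr <- -Inf
  for (lam in grid) {
    pass <- .srvs_pass(z, y, iters, m, lam, .derive_seed(config$seed, 7L))
    ord <- order(-pass$score, rownames(dataset$values))
    k <- min(10L, nrow(dataset$values))
    cr <- .loo_cr_rows(contrib, ord[seq_len(k)])
    if (cr > best_cr + 1e-12) {
      best_cr <- cr
      best <- lam
    }
  }
  best
}

#' Rank genes by one-way ANOVA p-value
#'
#' For every gene, a fixed-effects one-way ANOVA between the case and control
#' groups: `F` = between-group mean square over within-group mean square,
#' with `(1, N - 2)` degrees of freedom. Genes are ordered by ascending
#' p-value (ties break lexicographically); the stored `score` is
#' `-log10(p)`. Degenerate genes follow fixed conventions: zero within-group
#' variance with equal group means gives p = 1; zero within-group variance
#' with differing means gives the smallest representable positive p (a
#' message reports how many genes hit this).
#'
#' @param dataset An [expression_dataset()].
#' @return A [ranked_gene_list()] with columns `gene`, `p_value`, `f_stat`,
#'   `score`, `rank`.
#' @export
anova_scores <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  .check_two_per_class(dataset)
  v <- dataset$values
  is_case <- dataset$labels == "case"
  n1 <- sum(is_case); n2 <- sum(!is_case); n <- n1 + n2
  m1 <- rowMeans(v[, is_case, drop = FALSE])
  m2 <- rowMeans(v[, !is_case, drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ss_between <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ss_within <- rowSums((v[, is_case, drop = FALSE] - m1)^2) +
    rowSums((v[, !is_case, drop = FALSE] - m2)^2)
  f <- (ss_between / 1) / (ss_within / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)

  flat <- ss_within == 0 & ss_between == 0
  sep <- ss_within == 0 & ss_between > 0
  f[flat] <- 0; p[flat] <- 1
  if (any(sep)) {
    f[sep] <- Inf
    p[sep] <- .Machine$double.xmin
    .msgf("%d gene(s) with zero within-group variance and separated means; p set to %.3g",
          sum(sep), .Machine$double.xmin)
  }
  ord <- order(p, rownames(v))
  tab <- data.frame(gene = rownames(v)[ord], p_value = p[ord], f_stat = f[ord],
                    score = -log10(p[ord]))
  ranked_gene_list("ANOVA", tab)
}

#' Write a ranking as a score table
#' @param ranking A [ranked_gene_list()].
#' @param path Output TSV path (columns gene_symbol, method, score, rank).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranked_gene_list"))
  utils::write.table(
    data.frame(gene_symbol = ranking$gene, method = attr(ranking, "method"),
               score = ranking$score, rank = ranking$rank),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
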