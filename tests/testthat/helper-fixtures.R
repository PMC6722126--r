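# In-code fixtures and independent oracles shared across test files.

# Minimal dataset constructor: values by row (gene), labels in column order.
make_dataset <- function(values, labels, genes = NULL, samples = NULL,
                         metadata = list()) {
  if (!is.matrix(values))
    values <- matrix(values, ncol = length(labels), byrow = TRUE)
  if (is.null(genes)) genes <- sprintf("GENE%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_dataset(values, stats::setNames(labels, samples), metadata)
}

# Balanced two-class Gaussian dataset with optional perfectly-aligned gene.
noise_dataset <- function(n_genes = 10, n_per_class = 5, seed = 1,
                          perfect_gene = FALSE) {
  set.seed(seed)
  n <- 2 * n_per_class
  v <- matrix(rnorm(n_genes * n), n_genes, n)
  labels <- rep(c("case", "control"), each = n_per_class)
  if (perfect_gene) v[1, ] <- ifelse(labels == "case", 1, -1)
  make_dataset(v, labels)
}

# --- Oracle: l1-penalised least squares by sign-pattern enumeration -------
# Solves min_b ||y - X b||^2/(2n) + lambda ||b||_1 exactly for small p by
# enumerating all sign patterns and checking the KKT conditions.
lasso_oracle <- function(X, y, lambda, tol = 1e-9) {
  n <- nrow(X); p <- ncol(X)
  G <- crossprod(X) / n
  cv <- drop(crossprod(X, y)) / n
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (r in seq_len(nrow(signs))) {
    s <- signs[r, ]
    A <- which(s != 0)
    b <- numeric(p)
    if (length(A)) {
      sol <- try(solve(G[A, A, drop = FALSE], cv[A] - lambda * s[A]),
                 silent = TRUE)
      if (inherits(sol, "try-error")) next
      b[A] <- sol
      if (any(sign(b[A]) != s[A] & abs(b[A]) > tol)) next
      if (any(abs(b[A]) <= tol & s[A] != 0)) next
    }
    grad_inactive <- cv - drop(G %*% b)
    if (all(abs(grad_inactive[setdiff(seq_len(p), A)]) <= lambda + 1e-7))
      return(b)
  }
  stop("lasso oracle found no KKT-consistent sign pattern")
}

# --- Oracle: fold-by-fold nearest-centroid LOO ---------------------------
# Direct re-implementation with explicit loops: per fold, standardise by
# training mean/SD, compare distances to class centroids.
loo_oracle <- function(dataset, genes) {
  v <- dataset$values[genes, , drop = FALSE]
  labels <- dataset$labels
  n <- ncol(v)
  correct <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mu <- rowMeans(v[, tr, drop = FALSE])
    sd <- apply(v[, tr, drop = FALSE], 1, stats::sd)
    z <- (v - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    ic <- labels[tr] == "case"
    cen_case <- rowMeans(z[, tr[ic], drop = FALSE])
    cen_ctrl <- rowMeans(z[, tr[!ic], drop = FALSE])
    dc <- sum((z[, i] - cen_case)^2)
    dd <- sum((z[, i] - cen_ctrl)^2)
    pred <- if (abs(dc - dd) <= 1e-9 * max(1, dc + dd)) {
      if (sum(ic) > sum(!ic)) "case" else "control"
    } else if (dc < dd) "case" else "control"
    if (pred == labels[i]) correct <- correct + 1L
  }
  correct / n
}

# --- Oracle: sequential (Type I) sums of squares by explicit projection ---
# SS of factor k = increase in ||P y||^2 when factor k's dummy columns join
# the cumulative design matrix.
typeI_ss_oracle <- function(response, factors) {
  y <- as.numeric(response)
  Xcum <- matrix(1, length(y), 1)
  fit_ss <- function(X) {
    q <- qr(X)
    sum(qr.fitted(q, y)^2)
  }
  ss_prev <- fit_ss(Xcum)
  out <- numeric(length(factors))
  for (k in seq_along(factors)) {
    d <- stats::model.matrix(~f, data.frame(f = factor(factors[[k]])))[, -1, drop = FALSE]
    Xcum <- cbind(Xcum, d)
    ss_new <- fit_ss(Xcum)
    out[k] <- ss_new - ss_prev
    ss_prev <- ss_new
  }
  err <- sum(y^2) - ss_prev
  list(factor_ss = out, error_ss = err,
       total_ss = sum((y - mean(y))^2))
}

fixture_path <- function() {
  system.file("extdata", "scz_cohort_summary.tsv", package = "coresig")
}
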