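# SRVS and ANOVA gene ranking.

test_that("a perfect predictor dominates the SRVS ranking, deterministically", {
  ds <- noise_dataset(n_genes = 10, n_per_class = 5, seed = 3, perfect_gene = TRUE)
  cfg <- srvs_config(iterations = 500L, subset_size = 3L, l1_penalty = 0.05,
                     seed = 11L)
  rk <- srvs_scores(ds, cfg)
  expect_equal(rk$gene[1], "GENE01")
  expect_true(all(rk$score >= 0))
  # same seed, same config: identical score maps
  rk2 <- srvs_scores(ds, cfg)
  expect_identical(as.data.frame(rk), as.data.frame(rk2))
})

test_that("single-subset SRVS coefficients match the KKT enumeration oracle", {
  # fixed 6-sample x 3-gene instance, one subset covering all genes
  v <- matrix(c(1.2, 0.7, -0.3, -1.1, 0.4, -0.9,
                0.1, 1.5, -0.8, 0.9, -1.2, -0.5,
                2.0, 1.1, 0.2, -0.4, -1.3, -1.6),
              nrow = 3, byrow = TRUE)
  ds <- make_dataset(v, c("case", "case", "case", "control", "control", "control"))
  lambda <- 0.12
  rk <- suppressWarnings(  # one subset deliberately undersamples
    srvs_scores(ds, srvs_config(iterations = 1L, subset_size = 3L,
                                l1_penalty = lambda, seed = 2L)))
  # reconstruct the standardised design the ranking regressed on
  z <- t(apply(ds$values, 1, function(x) (x - mean(x)) / sd(x)))
  y <- unname(label_vector(ds)); y <- y - mean(y)
  b <- lasso_oracle(t(z), y, lambda)
  expected <- abs(b)[match(rownames(ds$values), rk$gene)]
  expect_equal(rk$score[match(rownames(ds$values), rk$gene)],
               abs(b), tolerance = 1e-6)
})

test_that("the coordinate-descent solver agrees with glmnet on random problems", {
  skip_if_not_installed("glmnet")
  set.seed(17)
  for (rep in 1:3) {
    n <- 30; p <- 8
    X <- scale(matrix(rnorm(n * p), n, p))
    X <- X / sqrt((n - 1) / n)  # glmnet standardises internally by 1/n; keep raw
    y <- rnorm(n); y <- y - mean(y)
    lambda <- 0.08
    b1 <- coresig:::.lasso_cd(X, y, lambda)
    b2 <- as.numeric(glmnet::glmnet(X, y, alpha = 1, lambda = lambda,
                                    standardize = FALSE, intercept = FALSE,
                                    thresh = 1e-14)$beta)
    expect_equal(b1, b2, tolerance = 1e-6)
  }
})

test_that("per-gene ANOVA matches the sum-of-squares oracle and equals pooled t^2", {
  ds <- make_dataset(c(1, 2, 3, 4, 5, 6,
                       2, 1, 4, 3, 6, 5),
                     c("case", "case", "case", "control", "control", "control"))
  rk <- anova_scores(ds)
  # direct sum-of-squares oracle for gene 1: cases (1,2,3), controls (4,5,6)
  ssb <- 3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2
  ssw <- sum((c(1, 2, 3) - 2)^2) + sum((c(4, 5, 6) - 5)^2)
  f_expected <- (ssb / 1) / (ssw / 4)
  i <- match("GENE01", rk$gene)
  expect_equal(rk$f_stat[i], f_expected, tolerance = 1e-12)
  expect_equal(rk$p_value[i], pf(f_expected, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # cross-check against the standard linear-model ANOVA
  lab <- factor(ds$labels)
  a <- anova(lm(ds$values["GENE01", ] ~ lab))
  expect_equal(rk$f_stat[i], a$`F value`[1], tolerance = 1e-10)

  # F equals the square of the pooled two-sample t statistic, every gene
  for (g in rownames(ds$values)) {
    tt <- t.test(ds$values[g, ds$labels == "case"],
                 ds$values[g, ds$labels == "control"], var.equal = TRUE)
    expect_equal(rk$f_stat[match(g, rk$gene)], unname(tt$statistic)^2,
                 tolerance = 1e-10)
  }
})

test_that("ANOVA handles degenerate genes by the stated conventions", {
  ds <- make_dataset(c(2, 2, 2, 2,   # flat everywhere: p = 1
                       1, 1, 5, 5,   # zero within-group variance, separated
                       1, 3, 1, 3),  # equal class means, nonzero within var
                     c("case", "case", "control", "control"))
  rk <- suppressMessages(anova_scores(ds))
  expect_equal(rk$p_value[match("GENE01", rk$gene)], 1)
  expect_equal(rk$p_value[match("GENE02", rk$gene)], .Machine$double.xmin)
  expect_equal(rk$f_stat[match("GENE03", rk$gene)], 0)
  expect_equal(rk$p_value[match("GENE03", rk$gene)], 1)
})

test_that("ANOVA ranking is invariant under affine transforms of a gene", {
  ds <- noise_dataset(n_genes = 6, n_per_class = 6, seed = 8)
  rk1 <- anova_scores(ds)
  ds2 <- ds
  ds2$values[3, ] <- -2.5 * ds2$values[3, ] + 7
  rk2 <- anova_scores(ds2)
  expect_equal(rk1$f_stat[order(rk1$gene)], rk2$f_stat[order(rk2$gene)],
               tolerance = 1e-10)
  expect_identical(rk1$gene, rk2$gene)
})

test_that("both rankings recover planted informative genes near the top", {
  # planted effect 2 SDs, 20 informative of 200 pool genes, 40+40 samples
  hits_srvs <- hits_anova <- integer(0)
  for (seed in 1:10) {
    g <- generate_dataset(cohort_spec(n_genome = 200L, n_pool = 200L,
                                      n_informative = 20L, effect_size = 2,
                                      seed = seed))
    ds <- g$dataset
    rk_a <- anova_scores(ds)
    rk_s <- srvs_scores(ds, srvs_config(iterations = 300L, subset_size = 20L,
                                        l1_penalty = 0.05, seed = seed))
    hits_anova <- c(hits_anova,
                    sum(g$truth$informative %in% rk_a$gene[1:40]))
    hits_srvs <- c(hits_srvs,
                   sum(g$truth$informative %in% rk_s$gene[1:40]))
  }
  expect_gte(mean(hits_anova) / 20, 0.9)
  expect_gte(mean(hits_srvs) / 20, 0.9)
})

test_that("subset_size guardrails fire", {
  ds <- noise_dataset(n_genes = 5, n_per_class = 4)
  expect_error(srvs_scores(ds, srvs_config(subset_size = 9L, l1_penalty = 0.1)),
               "subset_size")
  expect_warning(
    expect_warning(srvs_scores(ds, srvs_config(iterations = 2L, subset_size = 2L,
                                               l1_penalty = 0.1)),
                   "may never be sampled"),
    "score is 0")
})
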