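# Nearest-centroid LOO classification and best-classifier selection.

test_that("classification ratio is correct/total with guardrails", {
  expect_equal(classification_ratio(62, 69), 62 / 69)
  expect_equal(round(100 * classification_ratio(62, 69), 2), 89.86)
  expect_equal(classification_ratio(0, 10), 0)
  expect_equal(classification_ratio(10, 10), 1)
  expect_error(classification_ratio(5, 0), "positive")
  expect_error(classification_ratio(11, 10), "exceeds")
})

test_that("separable clusters classify perfectly and folds match the hand oracle", {
  # cases at (+5,+5), controls at (-5,-5), no noise beyond tiny jitter
  set.seed(1)
  v <- rbind(c(5, 5.1, 4.9, -5, -5.1, -4.9),
             c(5.2, 5, 4.8, -5.2, -5, -4.8))
  ds <- make_dataset(v, rep(c("case", "control"), each = 3))
  expect_equal(loo_cr(ds, c("GENE01", "GENE02")), 1)

  # 4-sample single-gene instance: cases (10, 8), controls (0, 2); every
  # fold trains on 3 samples whose centroids keep the held-out side correct
  ds2 <- make_dataset(c(10, 8, 0, 2), c("case", "case", "control", "control"))
  expect_equal(loo_cr(ds2, "GENE01"), 1)
  expect_equal(loo_cr(ds2, "GENE01"), loo_oracle(ds2, "GENE01"))
})

test_that("fast LOO equals the fold-by-fold oracle on random data and subsets", {
  for (seed in 1:5) {
    ds <- noise_dataset(n_genes = 12, n_per_class = 7, seed = seed)
    genes <- sample(rownames(ds$values), sample(2:8, 1))
    expect_equal(loo_cr(ds, genes), loo_oracle(ds, genes))
  }
  # unbalanced classes too
  ds <- make_dataset(matrix(rnorm(10 * 9), 10, 9),
                     c(rep("case", 3), rep("control", 6)))
  for (k in c(1, 4, 10)) {
    genes <- rownames(ds$values)[seq_len(k)]
    expect_equal(loo_cr(ds, genes), loo_oracle(ds, genes))
  }
})

test_that("LOO CR is invariant under per-gene affine rescaling", {
  ds <- noise_dataset(n_genes = 6, n_per_class = 6, seed = 2)
  cr1 <- loo_cr(ds, rownames(ds$values))
  ds2 <- ds
  ds2$values <- ds2$values * c(3, 0.1, 1, 10, 2, 5) + c(-4, 0, 7, 1, 0, 100)
  expect_equal(loo_cr(ds2, rownames(ds2$values)), cr1)
})

test_that("LOO CR on label-permuted pure noise is centred at chance", {
  # Monte-Carlo null: mean CR over replicates close to 0.5
  crs <- vapply(1:100, function(s) {
    ds <- noise_dataset(n_genes = 5, n_per_class = 20, seed = 1000 + s)
    loo_cr(ds, rownames(ds$values))
  }, numeric(1))
  expect_lt(abs(mean(crs) - 0.5), 0.06)
})

test_that("CR times sample count is an integer and missing genes error", {
  ds <- noise_dataset(n_genes = 4, n_per_class = 5, seed = 4)
  cr <- loo_cr(ds, c("GENE01", "GENE03"))
  expect_equal(cr * 10, round(cr * 10))
  expect_error(loo_cr(ds, "GENE99"), "GENE99")
})

test_that("distance ties go to the larger training class, then control", {
  # one flat gene: all contributions zero, every fold is an exact tie
  ds <- make_dataset(c(1, 1, 1, 1, 1), c("case", "case", "control", "control",
                                         "control"))
  # training class sizes: leaving out a case -> 1 case vs 3 controls -> control
  # leaving out a control -> 2 case vs 2 controls -> control (final tie-break)
  expect_equal(loo_cr(ds, "GENE01"), 3 / 5)
})

test_that("the CR curve evaluates top-n prefixes and selection picks smallest best n", {
  ds <- noise_dataset(n_genes = 10, n_per_class = 6, seed = 5, perfect_gene = TRUE)
  rk <- anova_scores(ds)
  curve <- cr_curve(ds, rk, n_max = 10)
  expect_equal(nrow(curve), 10L)
  expect_equal(curve$cr[1], 1)  # perfectly separating top gene
  # each curve point equals a direct LOO call on that prefix
  for (n in c(1, 3, 10))
    expect_equal(curve$cr[n], loo_cr(ds, rk$gene[seq_len(n)]))

  best <- select_best(curve, rk)
  expect_equal(best$best_n, 1L)
  expect_equal(best$max_cr, 1)
  expect_equal(best$gene_vector, rk$gene[1])
})

test_that("select_best breaks CR ties at the smallest n", {
  fake_curve <- structure(data.frame(n = 1:3, cr = c(0.6, 0.9, 0.9)),
                          method = "ANOVA", class = c("cr_curve", "data.frame"))
  rk <- ranked_gene_list("ANOVA", data.frame(gene = c("A", "B", "C"),
                                             score = c(3, 2, 1)))
  best <- select_best(fake_curve, rk)
  expect_equal(best$best_n, 2L)
  expect_equal(best$max_cr, 0.9)
  expect_equal(best$gene_vector, c("A", "B"))

  one <- structure(data.frame(n = 1, cr = 0.7), method = "ANOVA",
                   class = c("cr_curve", "data.frame"))
  expect_equal(select_best(one, rk)$best_n, 1L)
})

test_that("with planted signal the curve's argmax stays small", {
  small_argmax <- vapply(1:10, function(seed) {
    g <- generate_dataset(cohort_spec(n_genome = 100L, n_pool = 100L,
                                      n_informative = 5L, effect_size = 2,
                                      n_cases = 25L, n_controls = 25L,
                                      seed = 100 + seed))
    rk <- anova_scores(g$dataset)
    curve <- cr_curve(g$dataset, rk)
    which.max(curve$cr) <= 30
  }, logical(1))
  expect_gte(sum(small_argmax), 8)
})
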