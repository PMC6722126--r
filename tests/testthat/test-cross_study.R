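# Jaccard comparison of classifier gene sets, factor ANOVA on similarity,
# and cross-study summary statistics.

test_that("Jaccard score covers the analytic cases and is symmetric", {
  expect_equal(jaccard_score(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard_score(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard_score(c("A", "B"), c("B", "C")), 1 / 3)
  expect_equal(jaccard_score(c("a", "b"), c("B", "C")),
               jaccard_score(c("B", "C"), c("a", "b")))
  # equals 1 iff the sets are equal
  expect_lt(jaccard_score(c("A", "B", "C"), c("A", "B")), 1)
  expect_error(jaccard_score(character(0), "A"), "empty gene set")
})

test_that("the Jaccard matrix is symmetric, zero-diagonal and label-checked", {
  sets <- list(c("A", "B"), c("B", "C"), c("X", "Y"),
               sprintf("G%02d", 1:10), c(sprintf("G%02d", 1:5), sprintf("H%d", 1:5)))
  m <- jaccard_matrix(sets, cohort = c("c1", "c2", "c3", "c4", "c5"),
                      method = rep("SRVS", 5))
  expect_true(isSymmetric(unclass(m)))
  expect_equal(unname(diag(m)), rep(0, 5))
  expect_true(all(m >= 0 & m <= 1))
  # two sets sharing 5 of 10 genes: 5 / 15
  expect_equal(m["c4.SRVS", "c5.SRVS"], 5 / 15)
  # pairwise-disjoint sets give all-zero off-diagonals
  m0 <- jaccard_matrix(list("A", "B", "C"), cohort = c("x", "y", "z"),
                       method = rep("SRVS", 3))
  expect_equal(max(m0), 0)
  expect_error(jaccard_matrix(sets[1:2], cohort = c("c1", "c1"),
                              method = c("SRVS", "SRVS")),
               "duplicate")
})

test_that("sequential N-way ANOVA matches the explicit projection oracle", {
  # balanced 2x2 two-factor design with fixed response
  y <- c(3.1, 2.9, 4.0, 4.2, 5.1, 4.9, 6.2, 6.0)
  f1 <- rep(c("a", "b"), each = 4)
  f2 <- rep(c("u", "u", "v", "v"), 2)
  tab <- nway_anova(y, list(f1, f2), c("first", "second"))
  orc <- typeI_ss_oracle(y, list(f1, f2))
  expect_equal(tab$sum_sq[1:2], orc$factor_ss, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$source == "Error"], orc$error_ss, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$source == "Total"], orc$total_ss, tolerance = 1e-10)
  # mean squares are SS/df and the decomposition closes
  k <- tab$df > 0 & tab$source != "Total"
  expect_equal(tab$mean_sq[k], tab$sum_sq[k] / tab$df[k])
  expect_equal(sum(tab$sum_sq[tab$source != "Total"]),
               tab$sum_sq[tab$source == "Total"], tolerance = 1e-8)

  # unbalanced three-factor case against the same oracle
  set.seed(31)
  y2 <- rnorm(30)
  fs <- list(sample(letters[1:3], 30, TRUE), sample(c("p", "q"), 30, TRUE),
             sample(c("m", "n"), 30, TRUE))
  tab2 <- nway_anova(y2, fs)
  orc2 <- typeI_ss_oracle(y2, fs)
  expect_equal(tab2$sum_sq[1:3], orc2$factor_ss, tolerance = 1e-10)
})

test_that("single-factor N-way ANOVA reproduces the per-gene one-way F", {
  ds <- noise_dataset(n_genes = 4, n_per_class = 6, seed = 12)
  rk <- anova_scores(ds)
  for (g in rownames(ds$values)) {
    tab <- nway_anova(ds$values[g, ], list(group = ds$labels))
    expect_equal(tab$f[1], rk$f_stat[match(g, rk$gene)], tolerance = 1e-10)
    expect_equal(tab$p[1], rk$p_value[match(g, rk$gene)], tolerance = 1e-10)
  }
  # balanced equal-mean groups: F = 0, p = 1
  flat <- nway_anova(rep(c(1, 2), 4), list(rep(c("g1", "g2"), each = 4)))
  expect_equal(flat$f[1], 0)
  expect_equal(flat$p[1], 1)
})

test_that("Type I decomposition closes for any factor ordering", {
  set.seed(13)
  y <- rnorm(24)
  f1 <- sample(c("a", "b"), 24, TRUE)
  f2 <- sample(c("u", "v", "w"), 24, TRUE)
  t12 <- nway_anova(y, list(f1, f2))
  t21 <- nway_anova(y, list(f2, f1))
  tot <- sum((y - mean(y))^2)
  expect_equal(sum(t12$sum_sq[1:3]), tot, tolerance = 1e-8)
  expect_equal(sum(t21$sum_sq[1:3]), tot, tolerance = 1e-8)
  expect_error(nway_anova(c(1, 2), list(c("a", "b"))), "saturated")
})

test_that("similarity ANOVA labels all cells by their row study", {
  sets <- list(c("A", "B"), c("B", "C"), c("C", "D"), c("A", "D"))
  sim <- jaccard_matrix(sets, cohort = c("c1", "c1", "c2", "c2"),
                        method = c("SRVS", "ANOVA", "SRVS", "ANOVA"))
  factors <- list(region = c("pfc", "pfc", "ba10", "ba10"),
                  method = c("SRVS", "ANOVA", "SRVS", "ANOVA"))
  tab <- similarity_anova(sim, factors)
  # all 16 cells used: total df = 15
  expect_equal(tab$df[tab$source == "Total"], 15)
  tab2 <- similarity_anova(sim, factors, cells = "offdiag-upper")
  expect_equal(tab2$df[tab2$source == "Total"], 5)
})

test_that("cross-study summary reproduces published-scale statistics", {
  long <- read_results_fixture(fixture_path())
  s <- summarize_studies(long)
  pm <- s$per_method
  expect_equal(round(pm$mean_cr[pm$method == "SRVS"], 2), 83.16)
  expect_equal(round(pm$sd_cr[pm$method == "SRVS"], 2), 12.79)
  expect_equal(round(pm$mean_cr[pm$method == "ANOVA"], 2), 82.36)
  expect_equal(round(pm$mean_cr[pm$method == "POOL_ALL"], 2), 63.19)
  expect_equal(round(pm$mean_perm_p[pm$method == "POOL_ALL"], 2), 0.41)
  # censored entries contribute their bounds
  expect_lte(pm$mean_perm_p[pm$method == "SRVS"], 6.30e-3)
  expect_lte(pm$mean_perm_p[pm$method == "ANOVA"], 5.00e-4)
  w <- s$pairwise
  expect_equal(round(w$welch_p[w$method_a == "SRVS" & w$method_b == "ANOVA"], 2),
               0.85)
})

test_that("summary scaling, degenerate SD and cohort-order invariance", {
  df <- data.frame(cohort = rep(c("c1", "c2", "c3"), 2),
                   method = rep(c("SRVS", "ANOVA"), each = 3),
                   cr = rep(0.8, 6), perm_p = rep("0.5", 6))
  expect_message(s <- summarize_studies(df), "percent")
  expect_equal(s$per_method$mean_cr, c(80, 80))
  expect_equal(s$per_method$sd_cr, c(0, 0))
  expect_equal(s$pairwise$welch_p, 1)

  long <- read_results_fixture(fixture_path())
  s1 <- summarize_studies(long)
  s2 <- summarize_studies(long[sample(nrow(long)), ])
  expect_equal(s1$per_method[order(s1$per_method$method), ],
               s2$per_method[order(s2$per_method$method), ],
               ignore_attr = TRUE)
})
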