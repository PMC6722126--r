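# End-to-end orchestration: read -> trim -> rank -> CR curve -> select ->
# permutation -> baseline, per cohort and across cohorts.

#' Serialize a classifier result to JSON
#'
#' @param result A [classifier_result()].
#' @param path Output path.
#' @param config Optional list of effective run parameters; embedded
#'   together with its md5 hash so identical configurations provably give
#'   identical artifacts.
#' @return `path`, invisibly.
#' @export
write_classifier_json <- function(result, path, config = NULL) {
  stopifnot(inherits(result, "classifier_result"))
  obj <- list(method = result$method, best_n = result$best_n,
              max_cr = result$max_cr, gene_vector = result$gene_vector,
              curve = list(n = result$curve$n, cr = result$curve$cr))
  if (!is.null(result$permutation))
    obj$permutation <- result$permutation[c("runs", "better_or_equal",
                                            "p_value", "reported", "seed",
                                            "estimator")]
  if (!is.null(config)) {
    obj$config <- config
    obj$config_hash <- .config_hash(config)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# md5 of the canonical JSON form of a config (base R has file-level md5 only).
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the signature-selection workflow on one cohort
#'
#' Executes the per-cohort stages: trim the expression matrix to the curated
#' pool, rank pool genes (SRVS and/or ANOVA), trace the top-n CR curve,
#' select the best gene vector, assess it by permutation over random
#' same-size gene sets, and (optionally) compute the random-gene baseline
#' curve. The `pool_all` method evaluates the whole trimmed pool as a single
#' classifier, the pan-signature reference.
#'
#' @param dataset An [expression_dataset()] (untrimmed: all measured genes;
#'   the permutation universe). Alternatively supply `expression_path` +
#'   `labels_path`.
#' @param pool A [gene_pool()], or `pool_path` to read one.
#' @param expression_path,labels_path,pool_path Optional file inputs used
#'   when `dataset`/`pool` are not given.
#' @param methods Subset of `c("srvs", "anova", "pool_all")`.
#' @param srvs SRVS tuning, an [srvs_config()].
#' @param perm_runs Permutation runs per classifier (default 5000).
#' @param baseline_reps Repetitions per baseline point; 0 (default) skips
#'   the baseline stage.
#' @param n_max Largest top-n evaluated (default: all trimmed genes).
#' @param universe `"dataset"` (default): permutations draw from all
#'   measured genes; `"pool"`: restrict draws to trimmed pool genes.
#' @param seed Integer seed for the permutation and baseline stages.
#' @param out_dir Optional directory; when given, per-method JSON artifacts,
#'   score tables and baselines are written there.
#' @return Named list of `classifier_result`s (`SRVS`, `ANOVA`,
#'   `POOL_ALL`), with the baseline curve attached as attribute
#'   `"baseline"` when computed.
#' @export
run_cohort <- function(dataset = NULL, pool = NULL, expression_path = NULL,
                       labels_path = NULL, pool_path = NULL,
                       methods = c("srvs", "anova", "pool_all"),
                       srvs = srvs_config(), perm_runs = 5000L,
                       baseline_reps = 0L, n_max = NULL,
                       universe = c("dataset", "pool"), seed = 1L,
                       out_dir = NULL) {
  universe <- match.arg(universe)
  methods <- match.arg(methods, c("srvs", "anova", "pool_all"), several.ok = TRUE)
  for (p in c(expression_path, labels_path, pool_path))
    if (!is.null(p) && !file.exists(p)) .stopf("input file not found: %s", p)
  if (is.null(dataset)) {
    if (is.null(expression_path) || is.null(labels_path))
      .stopf("supply dataset or expression_path + labels_path")
    dataset <- read_expression_tsv(expression_path, labels_path)
  }
  if (is.null(pool)) {
    if (is.null(pool_path)) .stopf("supply pool or pool_path")
    pool <- read_gene_pool(pool_path)
  }
  trimmed <- .stage("trim", trim_to_pool(dataset, pool))
  perm_data <- if (universe == "dataset") dataset else trimmed
  if (is.null(n_max)) n_max <- nrow(trimmed$values)

  config <- list(cohort_id = trimmed$metadata$cohort_id, methods = methods,
                 srvs_iterations = srvs$iterations,
                 srvs_subset_size = srvs$subset_size,
                 srvs_l1_penalty = srvs$l1_penalty, srvs_seed = srvs$seed,
                 perm_runs = perm_runs, baseline_reps = baseline_reps,
                 n_max = n_max, universe = universe, seed = seed)

  results <- list()
  if ("srvs" %in% methods) {
    rk <- .stage("srvs ranking", srvs_scores(trimmed, srvs))
    results$SRVS <- .finish_method(trimmed, perm_data, rk, n_max, perm_runs, seed)
  }
  if ("anova" %in% methods) {
    rk <- .stage("anova ranking", anova_scores(trimmed))
    results$ANOVA <- .finish_method(trimmed, perm_data, rk, n_max, perm_runs, seed)
  }
  if ("pool_all" %in% methods) {
    genes <- rownames(trimmed$values)
    cr <- .stage("pool_all classification", loo_cr(trimmed, genes))
    curve <- structure(data.frame(n = length(genes), cr = cr),
                       method = "POOL_ALL", class = c("cr_curve", "data.frame"))
    perm <- .stage("permutation", permutation_pvalue(
      perm_data, k = length(genes), observed_cr = cr, runs = perm_runs,
      seed = .derive_seed(seed, 11L)))
    results$POOL_ALL <- classifier_result("POOL_ALL", genes, length(genes),
                                          cr, curve, perm)
  }
  if (baseline_reps > 0L) {
    bl <- .stage("baseline", baseline_curve(
      perm_data, n_values = unique(round(seq(1, n_max, length.out = min(n_max, 25L)))),
      reps = baseline_reps, seed = .derive_seed(seed, 13L)))
    attr(results, "baseline") <- bl
  }
  if (!is.null(out_dir)) .write_cohort_artifacts(results, out_dir, config)
  results
}

# Wrap a stage so failures name the stage they came from.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

.finish_method <- function(trimmed, perm_data, ranking, n_max, perm_runs, seed) {
  curve <- .stage("cr curve", cr_curve(trimmed, ranking, n_max = n_max))
  best <- .stage("selection", select_best(curve, ranking))
  best$permutation <- .stage("permutation", permutation_pvalue(
    perm_data, k = best$best_n, observed_cr = best$max_cr, runs = perm_runs,
    seed = .derive_seed(seed, 11L)))
  best
}

.write_cohort_artifacts <- function(results, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cid <- if (is.null(config$cohort_id) || is.na(config$cohort_id)) "cohort"
  else config$cohort_id
  for (m in names(results))
    write_classifier_json(results[[m]],
                          file.path(out_dir, sprintf("%s_%s.json", cid, tolower(m))),
                          config = config)
  bl <- attr(results, "baseline")
  if (!is.null(bl))
    write_baseline_tsv(bl, file.path(out_dir, sprintf("%s_baseline.tsv", cid)))
  invisible(out_dir)
}

#' Run the workflow across a collection of cohorts
#'
#' Runs [run_cohort()] on every dataset, then compares the selected
#' classifier gene sets across cohorts: Jaccard similarity matrix over
#' (cohort, method) pairs, main-effects factor ANOVA of similarity on brain
#' region, ethnicity and ranking method, and the cross-study summary
#' statistics.
#'
#' @param datasets List of [expression_dataset()]s (>= 2), each with
#'   `cohort_id`, `brain_region`, `ethnicity` metadata.
#' @param pool A [gene_pool()] shared by all cohorts.
#' @param methods,srvs,perm_runs,n_max,universe,seed,out_dir As in
#'   [run_cohort()]; per-cohort seeds are derived from `seed`.
#' @param similarity_methods Methods whose gene sets enter the similarity
#'   matrix (default the selection-based ones, `c("SRVS", "ANOVA")`).
#' @return List with `cohort_results` (per-cohort lists of
#'   `classifier_result`s), `similarity` (a [jaccard_matrix()]), `anova`
#'   (an `anova_table`, `NULL` when a factor is constant), and `summary`
#'   (a [summarize_studies()] result).
#' @export
run_collection <- function(datasets, pool,
                           methods = c("srvs", "anova", "pool_all"),
                           srvs = srvs_config(), perm_runs = 5000L,
                           n_max = NULL, universe = c("dataset", "pool"),
                           seed = 1L, out_dir = NULL,
                           similarity_methods = c("SRVS", "ANOVA")) {
  if (length(datasets) < 2L) .stopf("need at least 2 cohorts")
  universe <- match.arg(universe)
  cohort_results <- list()
  meta <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    cid <- d$metadata$cohort_id
    if (is.null(cid) || is.na(cid)) cid <- sprintf("cohort%02d", i)
    srvs_i <- srvs
    srvs_i$seed <- .derive_seed(seed, 500L + i)
    cohort_results[[cid]] <- run_cohort(
      dataset = d, pool = pool, methods = methods, srvs = srvs_i,
      perm_runs = perm_runs, n_max = n_max, universe = universe,
      seed = .derive_seed(seed, 900L + i), out_dir = out_dir)
    meta[[cid]] <- d$metadata
  }
  sets <- list(); cohort <- character(); method <- character()
  region <- character(); ethnicity <- character()
  for (cid in names(cohort_results)) for (m in similarity_methods) {
    res <- cohort_results[[cid]][[m]]
    if (is.null(res)) next
    sets[[length(sets) + 1L]] <- res$gene_vector
    cohort <- c(cohort, cid); method <- c(method, m)
    region <- c(region, as.character(meta[[cid]]$brain_region))
    ethnicity <- c(ethnicity, as.character(meta[[cid]]$ethnicity))
  }
  sim <- jaccard_matrix(sets, cohort, method)
  factors <- list(brain_region = region, ethnicity = ethnicity, method = method)
  usable <- vapply(factors, function(f) length(unique(f)) >= 2L, logical(1))
  anova_tab <- if (any(usable)) similarity_anova(sim, factors[usable]) else NULL
  summary <- summarize_studies(results_table(cohort_results))
  out <- list(cohort_results = cohort_results, similarity = sim,
              anova = anova_tab, summary = summary)
  if (!is.null(out_dir)) {
    write_similarity_tsv(sim, file.path(out_dir, "similarity_matrix.tsv"))
    if (!is.null(anova_tab))
      utils::write.table(as.data.frame(anova_tab),
                         file.path(out_dir, "similarity_anova.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(per_method = summary$per_method,
                              pairwise = summary$pairwise),
                         file.path(out_dir, "cross_study_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
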