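# Synthetic cohorts with known ground truth, emulating the case/control
# brain-expression studies the pipeline targets: two-class cohorts of
# 25-200 samples, several hundred to ~1,500 measured pool genes, Gaussian
# log-scale expression with a planted subset of informative genes shifted
# between classes, and cohort metadata factors for the cross-study stage.

#' Specification of a synthetic case/control cohort
#'
#' Defaults emulate a mid-sized brain-expression cohort: balanced 40 + 40
#' samples, 1,000 measured genes of which 200 belong to the curated pool,
#' 20 informative pool genes shifted by 1.5 within-class SDs, baseline
#' means/SDs on a log2-like scale.
#'
#' @param n_cases,n_controls Positive sample counts per class.
#' @param n_genome Total measured genes.
#' @param n_pool Pool genes among them (`<= n_genome`).
#' @param n_informative Informative genes among the pool (`<= n_pool`).
#' @param effect_size Class mean shift delta, in units of the gene's
#'   within-class SD (>= 0).
#' @param base_mean_range Range of per-gene baseline means (log-like scale).
#' @param base_sd_range Range of per-gene within-class SDs (positive).
#' @param correlation_block Optional `list(size =, rho =)`: equicorrelated
#'   noise (`0 <= rho < 1`) within consecutive gene blocks of the given size.
#' @param brain_region,ethnicity Cohort metadata labels.
#' @param cohort_id Cohort identifier.
#' @param seed Integer seed; generation is deterministic given it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 40L, n_controls = 40L, n_genome = 1000L,
                        n_pool = 200L, n_informative = 20L, effect_size = 1.5,
                        base_mean_range = c(6, 10), base_sd_range = c(0.5, 1.5),
                        correlation_block = NULL,
                        brain_region = "prefrontal cortex", ethnicity = "USA",
                        cohort_id = "SYN1", seed = 1L) {
  if (!.is_count(n_cases) || n_cases < 1 || !.is_count(n_controls) || n_controls < 1)
    .stopf("sample counts must be positive integers")
  if (n_informative > n_pool || n_pool > n_genome)
    .stopf("need n_informative <= n_pool <= n_genome")
  if (effect_size < 0) .stopf("effect_size must be >= 0")
  if (any(base_sd_range <= 0)) .stopf("base_sd_range must be positive")
  if (!is.null(correlation_block)) {
    if (is.null(correlation_block$size) || is.null(correlation_block$rho) ||
        correlation_block$rho < 0 || correlation_block$rho >= 1)
      .stopf("correlation_block needs size and rho in [0, 1)")
  }
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 n_genome = as.integer(n_genome), n_pool = as.integer(n_pool),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, base_mean_range = base_mean_range,
                 base_sd_range = base_sd_range,
                 correlation_block = correlation_block,
                 brain_region = brain_region, ethnicity = ethnicity,
                 cohort_id = cohort_id, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic gene pool within a synthetic genome
#'
#' @param n_pool Pool size.
#' @param n_genome Genome size (`>= n_pool`).
#' @param seed Integer seed.
#' @return List with `pool` (a [gene_pool()], a uniform random subset of the
#'   genome, in genome order) and `genome` (all synthetic symbols,
#'   `"G000001"` upward).
#' @export
generate_pool <- function(n_pool, n_genome, seed = 1L) {
  if (!.is_count(n_pool) || !.is_count(n_genome) || n_pool < 1)
    .stopf("n_pool and n_genome must be positive integers")
  if (n_pool > n_genome) .stopf("n_pool (%d) exceeds n_genome (%d)", n_pool, n_genome)
  genome <- sprintf("G%06d", seq_len(n_genome))
  idx <- .with_seed(seed, sort(sample.int(n_genome, n_pool)))
  list(pool = gene_pool(genome[idx]), genome = genome)
}

#' Generate a synthetic case/control cohort
#'
#' Per gene, a baseline mean and within-class SD are drawn uniformly from
#' the spec's ranges; sample values are Gaussian around the baseline, and
#' each informative gene's case mean is shifted by `effect_size` SDs.
#' Optional equicorrelated noise is shared within consecutive gene blocks.
#'
#' @param spec A [cohort_spec()].
#' @param informative Optional character vector forcing the informative gene
#'   set (must be pool symbols); used by [generate_study_collection()] to
#'   plant partially overlapping signals.
#' @param pool_seed Optional seed for the genome/pool draw, so several
#'   cohorts can share one pool; defaults to a stream derived from
#'   `spec$seed`.
#' @return List with `dataset` (an [expression_dataset()] over the full
#'   genome), `truth` (list: `informative`, `effect` named per-gene shift in
#'   SD units, `pool` a [gene_pool()], `metadata`).
#' @export
generate_dataset <- function(spec, informative = NULL, pool_seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(pool_seed)) pool_seed <- .derive_seed(spec$seed, 1L)
  gp <- generate_pool(spec$n_pool, spec$n_genome, seed = pool_seed)
  n <- spec$n_cases + spec$n_controls
  out <- .with_seed(.derive_seed(spec$seed, 2L), {
    if (is.null(informative)) {
      informative <- sample(gp$pool$symbols, spec$n_informative)
    } else {
      informative <- .norm_symbols(informative)
      if (!all(informative %in% gp$pool$symbols))
        .stopf("informative genes must belong to the pool")
    }
    G <- spec$n_genome
    mu <- stats::runif(G, spec$base_mean_range[1], spec$base_mean_range[2])
    sd <- stats::runif(G, spec$base_sd_range[1], spec$base_sd_range[2])
    eps <- matrix(stats::rnorm(G * n), G, n)
    if (!is.null(spec$correlation_block)) {
      bs <- spec$correlation_block$size
      rho <- spec$correlation_block$rho
      block <- rep(seq_len(ceiling(G / bs)), each = bs)[seq_len(G)]
      z <- matrix(stats::rnorm(max(block) * n), max(block), n)
      eps <- sqrt(1 - rho) * eps + sqrt(rho) * z[block, , drop = FALSE]
    }
    x <- mu + sd * eps
    is_case <- c(rep(TRUE, spec$n_cases), rep(FALSE, spec$n_controls))
    ginf <- match(informative, gp$genome)
    x[ginf, is_case] <- x[ginf, is_case] + spec$effect_size * sd[ginf]
    dimnames(x) <- list(gp$genome,
                        sprintf("%s_S%03d", spec$cohort_id, seq_len(n)))
    labels <- stats::setNames(ifelse(is_case, "case", "control"), colnames(x))
    list(x = x, labels = labels, informative = informative)
  })
  metadata <- list(cohort_id = spec$cohort_id, brain_region = spec$brain_region,
                   ethnicity = spec$ethnicity)
  effect <- stats::setNames(rep(spec$effect_size, length(out$informative)),
                            out$informative)
  list(dataset = expression_dataset(out$x, out$labels, metadata),
       truth = list(informative = out$informative, effect = effect,
                    pool = gp$pool, metadata = metadata))
}

#' Generate a multi-cohort study collection with overlapping signals
#'
#' All cohorts share the genome and pool of the first spec. A common core of
#' `round(overlap * n_informative)` informative genes is shared by every
#' cohort; the remainder of each cohort's informative set is drawn from the
#' rest of the pool, without reuse across cohorts while genes remain.
#'
#' @param specs List of [cohort_spec()]s (>= 2).
#' @param overlap Fraction in `[0, 1]` of each informative set drawn from
#'   the shared core.
#' @param seed Integer seed governing the core/specific assignment.
#' @return List of per-cohort results as returned by [generate_dataset()].
#' @export
generate_study_collection <- function(specs, overlap = 0.5, seed = 1L) {
  if (length(specs) < 2L) .stopf("need at least 2 cohort specs")
  if (overlap < 0 || overlap > 1) .stopf("overlap must be in [0, 1]")
  base <- specs[[1L]]
  gp <- generate_pool(base$n_pool, base$n_genome, seed = .derive_seed(base$seed, 1L))
  n_core <- round(overlap * base$n_informative)
  .with_seed(.derive_seed(seed, 3L), {
    core <- sample(gp$pool$symbols, n_core)
    rest <- setdiff(gp$pool$symbols, core)
    lapply(seq_along(specs), function(i) {
      sp <- specs[[i]]
      # share genome/pool across cohorts so gene sets are comparable
      sp$n_genome <- base$n_genome; sp$n_pool <- base$n_pool
      sp$seed <- .derive_seed(seed, 100L + i)
      n_specific <- sp$n_informative - n_core
      if (n_specific < 0) .stopf("overlap core larger than cohort %d informative set", i)
      specific <- if (n_specific > 0) {
        take <- sample(rest, min(n_specific, length(rest)))
        rest <<- setdiff(rest, take)
        if (length(take) < n_specific)  # pool exhausted: reuse uniformly
          take <- c(take, sample(setdiff(gp$pool$symbols, c(core, take)), n_specific - length(take)))
        take
      } else character(0)
      generate_dataset(sp, informative = c(core, specific),
                       pool_seed = .derive_seed(base$seed, 1L))
    })
  })
}
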