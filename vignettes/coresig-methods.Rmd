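---
title: "Cohort-specific gene signatures from a curated disease gene pool: methods and design"
author: "coresig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coresig methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coresig)
```

## The problem

Schizophrenia genetics suffers from a replication paradox: hundreds of genes
have each been associated with the disorder in at least one study, yet the
differentially expressed gene sets reported by independent case/control
cohorts barely overlap. One response is to curate the union of all reported
disease genes into a single "pan-disease" pool and then, within each cohort,
select the small subset of pool genes that best separates that cohort's
cases from its controls. The working hypothesis is that the pool as a whole
is too heterogeneous to classify any particular cohort well, while
cohort-specific subsets of it can — and that the subsets selected in
different cohorts, although largely non-overlapping as gene lists, all draw
on the same underlying disease biology.

`coresig` implements this workflow end to end for preprocessed (log-like
scale) expression matrices: pool trimming, two gene-ranking schemes, top-n
classifier selection under leave-one-out (LOO) cross-validation, permutation
significance, and cross-cohort comparison of the selected signatures.

## The per-cohort procedure

Within one cohort the stages are:

1. **Trim** the expression matrix to the genes of the curated pool
   (`trim_to_pool()`). Gene symbols are compared case-insensitively; probes
   are collapsed to symbols by arithmetic mean beforehand if the input is a
   GEO Series Matrix file.
2. **Rank** the trimmed genes by one of two schemes (below).
3. **Classify**: for each n, the top-n gene vector is evaluated by Euclidean
   nearest-centroid classification under LOO (`cr_curve()`), scoring the
   classification ratio CR = correct/total.
4. **Select** the smallest n attaining the maximal CR (`select_best()`).
5. **Test**: the best classifier's CR is referred to the distribution of CRs
   of random same-size gene sets (`permutation_pvalue()`), and a random-gene
   baseline curve (`baseline_curve()`) provides the chance-level reference
   for the whole top-n curve.

### SRVS ranking

Sparse representation-based variable selection regresses the class label on
random gene subsets with a sparsity-inducing penalty and accumulates each
gene's absolute coefficient. Concretely, with labels encoded $y_i = +1$
(case) / $-1$ (control) and centred, each of $T$ iterations draws $m$ genes
uniformly without replacement, forms the per-gene z-scored expression matrix
$X$ of that subset (samples in rows), and solves the lasso problem

$$\hat\beta = \arg\min_\beta \frac{1}{2n}\lVert y - X\beta\rVert_2^2
  + \lambda \lVert\beta\rVert_1$$

by coordinate descent (tolerance $10^{-8}$). A gene's SRVS score is its
mean $|\hat\beta_j|$ over the iterations in which it was sampled; genes are
ranked by descending score, ties broken lexicographically so the ordering
is fully reproducible.

Tunables (`srvs_config()`):

* `iterations` (default 1000): more iterations reduce the Monte-Carlo noise
  of the scores; the default satisfies the coverage heuristic
  $T \cdot m \ge 5G$ for the cohort sizes the package targets, and a warning
  fires when it does not.
* `subset_size` $m$ (default $\min(N-2, \lceil G/10\rceil)$): keeps each
  regression overdetermined enough to be stable while letting informative
  genes compete against changing random backgrounds.
* `l1_penalty` $\lambda$: if unset, chosen from a 10-point logarithmic grid
  below $\lambda_{\max} = \max_j |X^\top y|/n$ (the smallest penalty that
  zeroes every coefficient) by maximising the LOO CR of the top-10 genes of
  a reduced-iteration pass; the selected value is reported and recorded in
  the result. A fixed $\lambda$ makes runs cheaper and is recommended for
  simulation studies.

The subset-regression scheme is deliberately specified in full here —
uniform subsets, per-column z-scoring, centred $\pm 1$ response, count-
normalised mean absolute coefficient — because published descriptions of
this family of algorithms leave these internals open; the choices above
were made once for reproducibility, not tuned per dataset.

### ANOVA ranking

`anova_scores()` computes, per gene, the classic one-way fixed-effects
ANOVA between the two class groups: $F$ = between-group mean square over
within-group mean square with $(1, N-2)$ degrees of freedom, which for two
groups equals the squared pooled t statistic. Genes are ranked by ascending
p-value and the stored score is $-\log_{10} p$. The p-values are used only
as ranking scores, so no multiple-testing correction is applied. Degenerate
genes follow fixed conventions: zero within-group variance with equal means
gives $p = 1$; zero within-group variance with separated means gives the
smallest representable positive p (reported via a message).

### The classifier and its standardisation

"Euclidean multivariate classification" is implemented as nearest class
centroid: the held-out sample goes to the class whose training-mean vector
is closer in the selected gene subspace. Every gene is z-scored with the
*training fold's* mean and SD before distances are computed; this prevents
single high-variance genes from dominating the distance and makes the CR
invariant under per-gene affine rescaling of the input. Genes whose
training fold is constant contribute zero to both distances. Exact distance
ties are resolved to the class with more training samples, then to control
— an arbitrary but fixed convention that only matters on degenerate inputs.
A ranking computed once on the full dataset, as this workflow prescribes,
leaks selection information into the LOO estimate; the package follows that
prescription because it is the procedure being reproduced, and the
permutation test (which applies the same LOO machinery to random gene sets
of the same size) is the guard against over-interpreting the inflated CR.

Because squared Euclidean distance is additive over genes, the package
precomputes per-gene, per-fold distance contributions once per dataset;
every curve point, permutation run and baseline repetition is then a column
sum over the relevant gene rows. This is what makes 5,000-run permutations
routine.

### Permutation significance

The permutation p-value is defined as the fraction of runs whose random
same-size gene set reaches a CR at least as high as the observed one,
`count/runs`, with `"<1/runs"` reported when the count is zero — exactly
the convention of the workflow this package mirrors (the conventional
`(count+1)/(runs+1)` estimator is available via `estimator = "plus_one"`).
The permutation universe defaults to *all* genes measured in the dataset,
not only pool genes, extending the stated design of the random baselines to
the test; `universe = "pool"` restricts it. Each run draws from an
independent seeded stream, so results are identical for any evaluation
order or worker count.

Two calibration properties, verified in the test suite, are worth knowing:

* On cohorts of around 160 samples the p-value of a *fixed* random gene set
  under a no-signal simulation is approximately uniform (empirical
  rejection at $\alpha = 0.1$ inside its binomial 95% interval over 200
  replicates).
* On small cohorts (tens of samples) the tie-inclusive `count/runs`
  definition is visibly conservative: CR takes only $N+1$ values, the atom
  of probability at the observed CR is counted in full, and we measured a
  median p of about 0.62 and $P(p \le 0.1) \approx 0.04$ at 20+20 samples.
  This is an inherent property of the printed-p convention, not a defect of
  the implementation; users comparing small cohorts should read the
  p-values as upper bounds.

## Cross-study comparison

Selected gene vectors from all (cohort, method) combinations are compared
by Jaccard similarity $|A \cap B| / |A \cup B|$ (`jaccard_matrix()`), with
the diagonal forced to zero following the display convention of the matrix
this reproduces. `similarity_anova()` then asks whether cohort-level
factors (brain region, ethnicity, ranking method) explain the similarity
structure, via a main-effects-only sequential (Type I) ANOVA. By default
*every* cell of the matrix, including the zeroed diagonal, enters the
model, labelled with its row study's factors — the convention under which a
28×28 matrix yields total df = 783, matching the published analysis this
mirrors; `cells = "offdiag-upper"` gives the statistically cleaner variant
that drops the structural zeros and duplicate cells. Factor vectors are
explicit inputs rather than parsed from metadata, because factor codings
(e.g. how ethnicity is levelled) materially change the table and cannot be
recovered from a published summary.

`summarize_studies()` aggregates per-cohort results into per-method mean ±
sample-SD CR on the percent scale and the mean permutation p-value, with
censored entries `"<x"` contributing their upper bound x (so the reported
mean is itself an upper bound). Between-method CR differences use the Welch
two-sample t-test; the paired t-test is also reported when cohorts align,
since cohort-paired CRs are arguably the more natural comparison.

## The synthetic-data generator

`generate_dataset()` emulates the study conditions the pipeline targets:
balanced-to-moderately-unbalanced two-class cohorts of 25–200 samples,
several hundred to ~1,500 measured pool genes, Gaussian per-gene expression
on a log-like scale with a planted subset of informative pool genes whose
case mean is shifted by `effect_size` within-class SDs, and cohort
metadata (brain region, ethnicity) for the cross-study stage.
`generate_study_collection()` plants partially overlapping informative sets
across cohorts (fraction `overlap` shared) over a common genome and pool.

Defaults — 40+40 samples, 1,000 measured genes, 200 pool genes, 20
informative at effect 1.5 SD, baseline means Uniform(6, 10) and SDs
Uniform(0.5, 1.5) on a log2-like scale — represent a mid-sized microarray
brain cohort with a moderately strong planted signal. The generator is
Gaussian by construction (its inputs are preprocessed array intensities,
not counts) and does not simulate probe-level structure or batch effects;
passing tests on it therefore demonstrate the pipeline's statistical
machinery, not robustness to normalisation artefacts or platform
heterogeneity in real GEO series. One consequence worth noting: at these
default conditions the planted signal is strong enough that even the
all-pool classifier approaches ceiling CR (we observe ~99.6% versus 100%
for the selected subsets over ten simulated cohorts), so the in-silico gap
between cohort-specific subsets and the whole pool is real but much
narrower than the published 83% vs 63% on real cohorts, where most pool
genes carry no signal for any given cohort.

## Numerical and design choices

* Gene symbols are uppercased before any comparison (mixed-case symbols
  across array platforms); duplicate rows collapse by arithmetic mean
  (`max_var` keeps the most variable probe instead).
* Rows containing any non-finite value are dropped, never imputed.
* Labels encode case = +1, control = −1 throughout.
* All stochastic stages (SRVS subsets, permutation runs, baselines,
  generators) draw from per-stream derived seeds; reruns with equal
  configurations produce byte-identical JSON artifacts, and artifacts embed
  the md5 hash of their effective configuration.
* Problem sizes in the test suite and acceptance script are scaled to
  desk-class hardware: e.g. 10 simulated cohorts for parameter recovery,
  200 calibration replicates at 200 permutation runs, 120-gene cohorts for
  the 14-cohort similarity structure. These sizes were chosen once as
  adequate for the Monte-Carlo precision each check needs.

## Known limitations

* Per-cohort CRs published for specific GEO series are not reproduced here:
  they depend on the original preprocessing of 14 external downloads. The
  package instead verifies the summary statistics computed *from* those
  published per-cohort values (shipped as a plain-text fixture) and the
  full pipeline's behaviour on synthetic cohorts with known truth.
* The ranking-before-LOO design overstates absolute CR (selection bias); a
  nested re-rank-per-fold mode is a natural extension but is deliberately
  not the default, since the point is fidelity to the published procedure.
* The permutation test conditions on the selected classifier's size; it
  does not account for the selection of n itself.
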