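---
title: "Methods: optimal-cutoff survival analysis of hallmark gene signatures"
author: "hallmarksurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal-cutoff survival analysis of hallmark gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hallmarksurv)
```

# The analysis

`hallmarksurv` implements a pancancer prognostic pipeline for cancer
hallmark genes measured by bulk RNA-seq. Per tumor cohort it

1. normalizes raw HTSeq-style counts in two stages (median-of-ratios size
   factors, then per-sample mean rescaling to 1000),
2. scores each hallmark gene set as the mean expression of its member
   genes per sample,
3. finds, for every gene, signature and the tumor mutation burden, the
   *strongest survival cutoff*: every candidate dichotomization threshold
   between the feature's quartiles is tested with a two-group Cox model,
   the scan is corrected with Benjamini–Hochberg, and the cutoff with the
   lowest p-value is selected (accepted only at FDR < 10%),
4. checks independence from clinical covariates with multivariate Cox
   models, and
5. aggregates across tumor types: the hallmark-by-tumor percentage of
   significant genes, its hierarchical clustering, recurrently prognostic
   genes, and cutoff-keyed gene set enrichment analysis.

A synthetic-data module generates cohorts with the statistical structure
the analysis assumes, with survival effects planted at known expression
quantiles, so every stage is testable against ground truth without
controlled-access patient data.

# Normalization

**Size factors.** For sample $j$,
$s_j = \operatorname{median}_{g \in G^+} \; c_{gj} \big/ \big(\prod_{j'} c_{gj'}\big)^{1/m}$,
where $G^+$ is the set of genes with strictly positive counts in *every*
sample (the classic median-of-ratios reference convention) and $m$ the
number of samples. The median of an even number of ratios is the midpoint
of the two central values; this must be fixed because the factors depend
on it. When no gene is positive everywhere the estimator fails with a
diagnostic count rather than silently switching reference sets.

**Mean rescaling.** Each sample column is then multiplied by
$1000 / \text{mean}(x_{\cdot j})$, the mean taken over *all* genes in the
matrix including zeros, so every sample's mean expression is exactly 1000
(to floating tolerance; the operation is idempotent). The target of 1000
is the conventional choice for this rescaling and is configurable
(`target_mean`).

Two consequences worth knowing: scaling one sample's raw column by $c$
scales its size factor by $c$, but it also shifts the geometric-mean
pseudo-reference by $c^{1/m}$, so the *whole* size-factor-normalized
matrix moves by that constant — the mean-rescaling stage removes it. No
log transform is applied anywhere; all downstream stages consume the
linear mean-rescaled matrix.

# Signature scores

The surrogate activity of a hallmark in a sample is the unweighted
arithmetic mean of its member genes' normalized expression
(`signature_scores()`). This is taken literally: no z-scoring, no
weighting, linear scale. Because the member set is pre-selected, relative
changes among members drive the score even when individual members
correlate negatively. Sets with fewer than `min_genes = 2` members found
in the matrix are dropped with a warning naming the missing symbols — a
single gene should not silently stand in for a hallmark. Scores are
computed on the mean-rescaled matrix (the final normalization stage);
gene membership may overlap between hallmarks and each membership
contributes independently.

# The cutoff scan

**Candidates.** For a feature vector $x$, candidates are every *distinct
observed value* $v$ with $Q_1 \le v \le Q_3$, quartiles by linear
interpolation (R type-7 quantiles), such that both $\{x \le v\}$ and
$\{x > v\}$ are non-empty (minimum group size configurable, default 1).
Observed values are scanned rather than a fixed grid so the lowest
achievable p-value is never missed on small cohorts. At least 8
non-missing values are required.

**Per-cutoff test.** Low is $x \le v$, high is $x > v$; a Cox
proportional hazards model is fitted on the high indicator with Efron tie
handling, and the reported p-value is the *score test* of that fit — the
log-rank test, identical to the classic hypergeometric form in the
absence of ties. The HR is $e^{\hat\beta}$ (high vs low) with a 95%
normal-approximation CI on the log scale. When one group has no events
the likelihood is monotone: the fit is flagged degenerate, the HR is a
one-sided extreme and the CI is suppressed; degenerate cutoffs stay in
the scan but are never selected as best while a non-degenerate
alternative exists.

**Correction and selection.** Benjamini–Hochberg is applied *across the
cutoffs of one feature* (the scan is the family being corrected); the
best cutoff is the argmin of p, ties resolved toward the smaller cutoff
for determinism, and the feature is significant iff the q-value at the
best cutoff is below `fdr_threshold = 0.10`. An optional second-stage BH
across features (`across_features_fdr`) is available because the
correction family is genuinely ambiguous in this design; within-scan is
the default as it matches the per-feature acceptance rule.

The best-cutoff procedure is anti-conservative by construction — it
selects the minimum over correlated tests. The within-scan BH correction
mitigates but does not nominally bound the per-feature type-I rate; the
test suite measures both the corrected and the naive min-p null rates on
500 simulated null genes and asserts the corrected rate is strictly lower
and below 0.25. Interpret per-feature significance accordingly.

**Multivariate models.** The feature enters as its best-cutoff dichotomy
(matching how single HRs per signature are reported); age is continuous
(years), stage ordinal 0–4, sex and grade binary factors (reference F /
low), race one-hot against its largest category. Complete cases only,
with at least 10 events required; constant, all-missing or collinear
terms are dropped and reported with reasons rather than silently
vanishing.

# Tumor mutation burden

TMB is the raw per-sample count of qualifying variants from the MAF
table; the default qualifying set is the non-silent classes (missense,
nonsense, nonstop, frameshift and in-frame indels, splice site,
translation start). No per-megabase normalization is applied by default
because a count is what the upstream table supports without an assumed
territory size; `per_mb` converts to mutations/Mb when a size is known.
TMB feeds the same cutoff scan as any continuous feature; integer ties
simply collapse the candidate set to the distinct observed values.

# Aggregation

The significance matrix holds, per hallmark and tumor type,
$100 \cdot (\text{significant member genes}) / (\text{member genes
evaluable and scanned})$; numerators and denominators are retained, and a
hallmark with no scanned gene in a tumor gets a missing cell, never a
zero. For clustering only, missing cells impute to 0 (with a warning) so
the dendrogram stays total; the stored matrix keeps the NA. Default
clustering is Euclidean distance with average linkage on the percentage
matrix — the choice is stated explicitly and configurable
(`distance = "correlation"`, `linkage = "complete"/"single"`) because the
original visualization tooling for such matrices does not pin these
parameters down. Dendrograms export to Newick. Recurrent features are
those significant in at least `min_tumors = 10` tumor types, ordered by
count then best p.

# GSEA

Phenotype labels reuse the survival scan's best cutoff (high iff
expression strictly exceeds it — the same tie convention as the scan).
Genes are ranked by signal-to-noise,
$(\bar x_{hi} - \bar x_{lo}) / (s_{hi} + s_{lo})$, each class sd floored
at $\max(0.2\,|\bar x|, 10^{-8})$ in the classic manner; ties in the
metric break by gene id. The enrichment score is the signed extremum of
the weighted Kolmogorov–Smirnov running sum with weight exponent
$p = 1$: hits add $|r|^p$ normalized by the summed hit weights, misses
subtract $1/(N - N_h)$. Significance is by phenotype permutation with the
add-one estimator among same-sign permutation scores,
$p = (1 + \#\{|ES^\pi| \ge |ES|,\ \text{same sign}\}) / (1 + \#\{\text{same sign}\})$,
which can never return zero.

Phenotype permutation preserves gene–gene correlation — that is its
point. A consequence demonstrated in the test suite: a perfectly
coherent module (every member tracking the phenotype, hence mutually
correlated) can reach $|ES| = 1$ under the permutation null as well, so
even an extreme observed score is not guaranteed the smallest attainable
p-value. The permutation p answers "is this set more concentrated than
its internal correlation explains", not "is the ES large".

# The synthetic cohort generator

`simulate_cohort()` emulates the inputs the pipeline expects:

- **Counts**: negative-binomial with mean = size factor × base
  expression and dispersion `nb_dispersion` (variance
  $\mu + \phi\mu^2$; 0 gives the Poisson limit). Size factors are
  log-uniform over `size_factor_range` (default 0.5–2, a typical
  sequencing-depth spread), base expressions log-uniform over
  `base_expr_range` (default 5–5000) so quartile-based cutoff scans are
  well-populated across the dynamic range. Default dispersion 0.2 is in
  the range typical of bulk tumor RNA-seq.
- **Survival**: exponential event times — the simplest model satisfying
  proportional hazards, which is exactly the assumption the Cox analyses
  make. Each planted effect multiplies the hazard by its `hazard_ratio`
  for samples whose expression of the planted gene exceeds the configured
  quantile. Baseline hazard 0.02 events/month puts the mean event time
  near 50 months, comparable to observed cohort medians. Censoring is an
  independent exponential whose rate is solved numerically so the
  expected censored fraction hits the target (default 0.3); censoring is
  therefore non-informative by construction.
- **Covariates**: sex/race/stage/grade drawn from configurable
  categorical distributions and age from a truncated normal,
  *independent of survival* — adequate for exercising model plumbing and
  collinearity handling, but deliberately unable to generate real
  confounding.
- **Mutations**: each (sample, gene) pair mutates independently with a
  per-gene probability; variant classes are drawn from a configurable mix
  that includes silent classes so class filtering is exercised.

One master seed drives all generators through deterministically derived
sub-streams, so an entire cohort is reproducible from a single integer,
and all downstream outputs are byte-identical across reruns.

What the generator does *not* emulate: between-gene correlation, batch
effects, copy-number-driven expression, informative censoring, or
covariate–survival confounding. Passing tests on synthetic data therefore
demonstrate that the statistical machinery is correct under its stated
assumptions — not that those assumptions hold in any real cohort.

# Numerical choices and degenerate inputs

- Quantiles everywhere are linear-interpolation (type 7); candidate
  cutoff sets depend on this.
- Efron tie handling throughout (the survival ecosystem's default); the
  reported p is the score test of the binary fit.
- Ties at the minimum scan p-value resolve to the smaller cutoff.
- Features that cannot be scanned (fewer than 8 values, constant values,
  no events, only degenerate fits) return `evaluable = FALSE` results,
  never exceptions, so cohort-wide scans don't fall over on edge genes.
- KM median survival is the smallest time with $S(t) \le 0.5$, `NA` when
  the curve never reaches 0.5.
- Missing-value tokens on ingest: empty string, `NA`, `NaN`
  (case-insensitive). Stage labels accept Roman or Arabic forms;
  sub-stages (IIa) truncate to the major stage. Survival times are taken
  as months as-is.
- Cohorts are included only when strictly larger than `min_cohort_size`
  (default 100 samples).

# Problem sizes in the test suite

The suite verifies the Cox core against a brute-force Newton
maximization of the Efron partial likelihood and a hand-rolled log-rank
test on 200 random small instances (n ≤ 20, tie-free times, finite MLE);
BH against the literal step-up definition for vector lengths up to 12;
cutoff/effect recovery on 50 seeded cohorts of n = 400 with 30%
censoring and a planted HR of 3 at the 0.6 quantile; the null-rate
comparison on one 500-gene cohort of n = 200; GSEA against a literal
running-sum re-implementation on 100 random instances plus a 500-replicate
permutation-null uniformity check; and end-to-end determinism on a
two-tumor demo of 300 samples × 500 genes. These sizes were chosen to
make each property measurable with comfortable statistical margins while
keeping the default suite quick to run.

# Known limitations

- Minimum-p cutoff selection inflates effect sizes at the selected
  cutoff (winner's curse); reported HRs at the best cutoff are biased
  away from 1 even with FDR control.
- The FDR family is per-feature by default; pancancer screens of many
  features should enable `across_features_fdr`.
- The multivariate model assumes proportional hazards for all terms; no
  diagnostics are run.
- GSEA nominal p-values are per-set; the BH column in `run_gsea()` is a
  convenience, not the full multi-set normalized-ES procedure.
- TMB as a raw count is not comparable across assays with different
  captured territory; use `per_mb` for cross-assay work.
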