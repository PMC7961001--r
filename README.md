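# hallmarksurv

Pancancer survival analysis of cancer hallmark gene signatures from bulk
RNA-seq, built around the *strongest-cutoff* statistic: instead of
dichotomizing a biomarker at a preset threshold such as the median, every
candidate cutoff between the lower and upper quartiles of its expression
is tested with a two-group Cox proportional hazards model, the scan is
corrected with Benjamini–Hochberg, and the best-performing cutoff with
the lowest p-value is used in the final analysis — accepted as
prognostic only at FDR < 10%.

The package is for computational biologists and biostatisticians who
want this optimal-dichotomization screen as tested, composable R
functions rather than a web tool: raw counts in, tidy result tables out,
with every statistical core verified against independent brute-force
oracles and a synthetic-cohort generator that plants effects at known
cutoffs.

## What it computes

For a cohort (gene-by-sample counts, clinical table, optional MAF):

- **Normalization** — median-of-ratios size factors
  $s_j = \mathrm{median}_{g}\, c_{gj} / (\prod_{j'} c_{gj'})^{1/m}$ over
  genes positive in all samples, then per-sample rescaling so each
  sample's mean expression is 1000.
- **Signatures** — each hallmark's surrogate activity is the mean
  expression of its member genes per sample (GMT input).
- **Cutoff scan** — per feature: candidates are all distinct observed
  values in $[Q_1, Q_3]$; at each, a Cox fit (Efron ties) of high
  ($x > v$) vs low ($x \le v$) with the score (log-rank) test p-value;
  BH over the scan; best cutoff = argmin p; significant iff q < 0.10.
  Reported: HR with 95% CI, group and event counts, cutoff quantile,
  degenerate-fit flags.
- **Multivariate Cox** — the dichotomized feature plus sex, race
  (one-hot vs largest category), stage (ordinal), grade, age, on
  complete cases, with constant/collinear terms dropped and reported.
- **TMB** — per-sample count of non-silent MAF variants, scanned like
  any continuous feature.
- **Aggregation** — hallmark × tumor percentage-of-significant-genes
  matrix, hierarchical clustering (euclidean/average by default, Newick
  export), and genes recurrently prognostic in ≥ 10 tumor types.
- **GSEA** — phenotype labels from the scan's best cutoff,
  signal-to-noise ranking, weighted Kolmogorov–Smirnov enrichment score,
  phenotype-permutation p-values.

## Worked example

Simulate a 250-sample cohort with an HR = 3 effect planted at the 0.6
expression quantile of one gene, then run the screen:

```r
library(hallmarksurv)

sets <- synthetic_hallmark_sets(n_genes = 200, genes_per_set = 10,
                                overlap = 2, seed = 42)
cfg <- simulation_config(
  n_samples = 250, n_genes = 200, censoring_fraction = 0.3,
  size_factor_range = c(1, 1),   # unit depth: the planted dichotomy
                                 # carries through normalization unchanged
  planted_effects = tibble::tibble(gene_id = sets$gene_symbol[1],  # "G0021"
                                   cutoff_quantile = 0.6, hazard_ratio = 3),
  seed = 42)
cohort <- simulate_cohort(cfg)

expr  <- normalize_counts(cohort$counts)       # per-sample mean = 1000
scans <- scan_expression(expr, cohort$clinical, endpoint = "os")
dplyr::arrange(scans, p)[1, c("feature", "cutoff_quantile", "hr",
                              "ci_low", "ci_high", "p", "q")]
#> # A tibble: 1 × 7
#>   feature cutoff_quantile    hr ci_low ci_high        p            q
#>   <chr>             <dbl> <dbl>  <dbl>   <dbl>    <dbl>        <dbl>
#> 1 G0021             0.648  2.76   1.99    3.83 2.42e-10 0.0000000300
```

The planted gene comes out on top: the recovered cutoff quantile (0.648)
sits next to the planted 0.6, and the HR of 2.76 [1.99, 3.83] estimates
the planted 3 (minimum-p selection biases it slightly). Twelve of 200
genes pass FDR < 10% — the planted signal plus a small winner's-curse
background, which is why the q-value, not the raw p, gates significance.

The dichotomy survives adjustment for clinical covariates, and the
groups separate on the Kaplan–Meier scale:

```r
best <- dplyr::arrange(scans, p)[1, ]
grp <- tibble::tibble(
  sample_id = cohort$clinical$sample_id,
  group = ifelse(as.numeric(as.matrix(
    expr[expr$gene_id == best$feature, -1])) > best$best_cutoff,
    "high", "low"))

glance(multivariate_cox(cohort$clinical, grp))
#>       n n_events n_terms n_dropped feature_hr feature_p
#>     250      183       7         0       3.10  6.11e-11

km_curve(dplyr::inner_join(cohort$clinical, grp, by = "sample_id"),
         group = group, time = os_time, event = os_event)$median
#>   group     n n_events median
#> 1 high     88       71   11.4
#> 2 low     162      112   26.9
```

High expressors live a median 11.4 months against 26.9 for low
expressors. GSEA keyed to the same cutoff ranks the planted gene's own
hallmark first:

```r
run_gsea(expr, best$feature, best$best_cutoff, sets,
         n_permutations = 200, seed = 1)[1, ]
#>   set_name                           n_present    es nominal_p      q
#> 1 sustaining_proliferative_signaling        10 0.720    0.0108 0.0860
```

`signature_scores()` + `scan_expression()` run the same screen on the
hallmark signatures, `tmb_scan()` on mutation burden, and
`run_pancancer()` orchestrates multiple cohorts into the significance
matrix, dendrograms and recurrent-gene table. Result objects have
`tidy()`, `glance()` and `autoplot()` methods.

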