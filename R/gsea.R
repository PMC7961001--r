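# Two-phenotype gene set enrichment analysis keyed to the survival scan:
# samples are labeled high/low at the same cutoff used in the survival
# analysis, genes are ranked by signal-to-noise between the two phenotype
# classes, and a weighted Kolmogorov-Smirnov running statistic measures
# each set's concentration at the extremes of the ranking. Significance is
# by phenotype permutation.

#' Phenotype labels from an expression cutoff
#'
#' A sample is `"high"` iff its expression of the gene exceeds the cutoff
#' (same convention as the survival scan: ties go low).
#'
#' @param expr wide expression tibble.
#' @param gene gene symbol present in `expr`.
#' @param cutoff numeric cutoff, normally the scan's best cutoff.
#' @return tibble with columns `sample_id`, `label` (`"high"`/`"low"`).
#' @export
phenotype_labels <- function(expr, gene, cutoff) {
  m <- wide_to_matrix(expr)
  if (!gene %in% rownames(m)) abort(sprintf("gene not in matrix: %s", gene))
  x <- m[gene, ]
  tibble(sample_id = colnames(m),
         label = unname(ifelse(x > cutoff, "high", "low")))
}

# signal-to-noise metric for a genes x samples matrix and a logical
# high-class indicator; each class sd is floored at max(0.2 |class mean|,
# a tiny constant) in the classic GSEA manner.
s2n_metric <- function(m, is_high, floor_frac = 0.2, tiny = 1e-8) {
  row_stats <- function(sub) {
    mu <- rowMeans(sub)
    sd_ <- sqrt(rowSums((sub - mu)^2) / (ncol(sub) - 1))
    sd_ <- pmax(sd_, floor_frac * abs(mu), tiny)
    list(mu = mu, sd = sd_)
  }
  hi <- row_stats(m[, is_high, drop = FALSE])
  lo <- row_stats(m[, !is_high, drop = FALSE])
  (hi$mu - lo$mu) / (hi$sd + lo$sd)
}

#' Rank genes by signal-to-noise between phenotype classes
#'
#' Metric = (mean_high - mean_low) / (sd_high + sd_low), with each class
#' sd floored at max(0.2 x |class mean|, a tiny positive constant).
#' Genes are ordered by descending metric, ties broken by gene id.
#'
#' @param expr wide expression tibble.
#' @param labels tibble from [phenotype_labels()] (`sample_id`, `label`).
#' @return tibble with columns `gene_id`, `metric`, in ranking order.
#' @export
rank_genes <- function(expr, labels) {
  m <- wide_to_matrix(expr)
  labels <- as_tibble(labels)
  common <- intersect(colnames(m), labels$sample_id)
  lab <- labels$label[match(common, labels$sample_id)]
  is_high <- lab == "high"
  if (sum(is_high) < 3 || sum(!is_high) < 3) {
    abort("each phenotype class needs >= 3 samples")
  }
  metric <- s2n_metric(m[, common, drop = FALSE], is_high)
  ord <- order(-metric, rownames(m))
  tibble(gene_id = rownames(m)[ord], metric = unname(metric[ord]))
}

# Core running-sum statistic on an already-ordered metric vector.
running_sum <- function(metric, hit, weight_p = 1) {
  n <- length(metric)
  nh <- sum(hit)
  w <- abs(metric)^weight_p * hit
  denom <- sum(w)
  if (denom == 0) w[hit] <- 1 / nh else w <- w / denom
  miss <- (!hit) / (n - nh)
  cumsum(w - miss)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walking down the ranked list, hits increment the running sum by
#' |metric|^p normalized by the total hit weight and misses decrement it
#' by 1/(N - Nh); the enrichment score is the signed extremum.
#'
#' @param ranked ranked gene tibble from [rank_genes()].
#' @param gene_set character vector of member gene symbols.
#' @param weight_p exponent on the metric weights, default 1.
#' @return an object of class `enrichment_score`: `$es` plus `$running`
#'   (tibble `rank`, `gene_id`, `metric`, `hit`, `running`). Has an
#'   [autoplot()] method.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  hit <- ranked$gene_id %in% gene_set
  if (!any(hit)) abort("no gene-set member present in the ranked list")
  if (all(hit)) abort("gene set covers the whole ranked list; statistic undefined")
  rs <- running_sum(ranked$metric, hit, weight_p)
  es <- rs[which.max(abs(rs))]
  structure(list(
    es = es,
    running = tibble(rank = seq_along(rs), gene_id = ranked$gene_id,
                     metric = ranked$metric, hit = hit, running = rs)
  ), class = "enrichment_score")
}

#' @export
print.enrichment_score <- function(x, ...) {
  cat(sprintf("<enrichment_score> ES = %.4f (%d/%d hits)\n",
              x$es, sum(x$running$hit), nrow(x$running)))
  invisible(x)
}

#' Plot the GSEA running sum
#'
#' @param object an `enrichment_score` object.
#' @param ... unused.
#' @return a ggplot of the running statistic with hit positions marked.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_score <- function(object, ...) {
  df <- object$running
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = filter(df, .data$hit), sides = "b") +
    ggplot2::labs(x = "Rank", y = "Running enrichment score") +
    ggplot2::theme_minimal()
}

#' Phenotype-permutation p-value for a gene set
#'
#' Recomputes the signal-to-noise ranking and enrichment score under
#' random permutations of the phenotype labels (class sizes preserved) and
#' reports the add-one nominal p-value among same-sign permutation scores:
#' p = (1 + #{|ES_perm| >= |ES_obs|, same sign}) / (1 + #{same sign}).
#'
#' @param expr wide expression tibble.
#' @param labels tibble from [phenotype_labels()].
#' @param gene_set character vector of member gene symbols.
#' @param n_permutations number of label permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param weight_p exponent on the metric weights.
#' @return one-row tibble: `es`, `nominal_p`, `n_permutations`, `seed`.
#' @export
permutation_pvalue <- function(expr, labels, gene_set, n_permutations = 1000,
                               seed = 1, weight_p = 1) {
  if (n_permutations < 100) abort("n_permutations must be >= 100")
  m <- wide_to_matrix(expr)
  labels <- as_tibble(labels)
  common <- intersect(colnames(m), labels$sample_id)
  m <- m[, common, drop = FALSE]
  is_high <- labels$label[match(common, labels$sample_id)] == "high"
  if (sum(is_high) < 3 || sum(!is_high) < 3) {
    abort("each phenotype class needs >= 3 samples")
  }
  hit_of <- function(metric) {
    ord <- order(-metric, rownames(m))
    list(metric = metric[ord], hit = rownames(m)[ord] %in% gene_set)
  }
  es_of <- function(is_high_perm) {
    r <- hit_of(s2n_metric(m, is_high_perm))
    rs <- running_sum(r$metric, r$hit, weight_p)
    rs[which.max(abs(rs))]
  }
  obs <- es_of(is_high)
  perm <- withr::with_seed(derive_seed(seed, 5), {
    purrr::map_dbl(seq_len(n_permutations), function(i) {
      es_of(sample(is_high))
    })
  })
  same_sign <- sign(perm) == sign(obs)
  p <- (1 + sum(same_sign & abs(perm) >= abs(obs))) / (1 + sum(same_sign))
  tibble(es = obs, nominal_p = p, n_permutations = n_permutations,
         seed = seed)
}

#' GSEA over a gene-set collection with a cutoff-keyed phenotype
#'
#' Labels samples at the given cutoff of the given gene (the survival
#' scan's best cutoff in the intended workflow), then computes the
#' enrichment score and permutation p-value for every set in the
#' collection, with a BH q-value across sets.
#'
#' @param expr wide expression tibble.
#' @param gene phenotype-defining gene symbol.
#' @param cutoff expression cutoff for the high/low split.
#' @param sets long gene-set tibble from [read_gmt()].
#' @param n_permutations,seed,weight_p passed to [permutation_pvalue()].
#' @param min_genes minimum member genes present to test a set.
#' @return tibble, one row per set: `set_name`, `n_present`, `es`,
#'   `nominal_p`, `q`.
#' @export
run_gsea <- function(expr, gene, cutoff, sets, n_permutations = 1000,
                     seed = 1, weight_p = 1, min_genes = 2) {
  labels <- phenotype_labels(expr, gene, cutoff)
  genes_in <- expr[[1]]
  res <- sets |>
    distinct(.data$set_name, .data$gene_symbol) |>
    group_by(.data$set_name) |>
    summarise(members = list(.data$gene_symbol), .groups = "drop") |>
    mutate(n_present = purrr::map_int(.data$members,
                                      ~ sum(.x %in% genes_in))) |>
    filter(.data$n_present >= min_genes, .data$n_present < length(genes_in))
  if (nrow(res) == 0) abort("no testable gene set")
  stats <- purrr::map2(res$members, seq_len(nrow(res)), function(mem, i) {
    permutation_pvalue(expr, labels, mem, n_permutations = n_permutations,
                       seed = derive_seed(seed, 100 + i), weight_p = weight_p)
  }) |> list_rbind()
  out <- bind_cols(select(res, "set_name", "n_present"),
                   select(stats, "es", "nominal_p"))
  out$q <- p.adjust(out$nominal_p, method = "BH")
  arrange(out, .data$nominal_p)
}
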