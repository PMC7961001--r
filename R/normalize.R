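# Two-stage normalization: median-of-ratios size factors (the classic
# negative-binomial count normalization), then per-sample rescaling so the
# mean expression of all genes in each sample equals a fixed target
# (default 1000). No log transform is applied anywhere; downstream survival
# and GSEA stages consume the mean-rescaled linear-scale matrix.

#' Median-of-ratios size factors
#'
#' For each sample j the factor is the median over reference genes g of
#' counts[g, j] / geometric_mean_over_samples(counts[g, ]). The reference
#' set is the genes with strictly positive counts in every sample. The
#' median of an even number of ratios is the midpoint of the two central
#' values.
#'
#' @param counts wide count tibble (`gene_id` + sample columns).
#' @return tibble with columns `sample_id`, `size_factor`.
#' @export
compute_size_factors <- function(counts) {
  m <- wide_to_matrix(counts)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    abort(sprintf(
      "no gene is positive in every sample (%d of %d genes contain a zero); cannot estimate size factors",
      sum(!ref), nrow(m)))
  }
  mr <- m[ref, , drop = FALSE]
  geomean <- exp(rowMeans(log(mr)))
  sf <- apply(mr / geomean, 2, median)
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Divide counts by their per-sample size factors
#'
#' @param counts wide count tibble.
#' @param size_factors tibble from [compute_size_factors()] covering every
#'   sample of `counts`.
#' @return wide expression tibble tagged with stage
#'   `"size_factor_normalized"` (see [expr_stage()]).
#' @export
apply_size_factors <- function(counts, size_factors) {
  m <- wide_to_matrix(counts)
  missing <- setdiff(colnames(m), size_factors$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("no size factor for sample(s): %s", paste(head(missing, 5), collapse = ", ")))
  }
  sf <- setNames(size_factors$size_factor, size_factors$sample_id)[colnames(m)]
  if (any(!is.finite(sf) | sf <= 0)) abort("size factors must be finite and > 0")
  out <- matrix_to_wide(sweep(m, 2, sf, "/"), "gene_id")
  set_stage(out, "size_factor_normalized")
}

#' Rescale every sample's mean expression to a fixed target
#'
#' Multiplies each sample column by target / mean(column), the mean taken
#' over all genes present in the matrix (zeros included), so each sample's
#' mean expression equals the target exactly (to floating tolerance).
#' Idempotent.
#'
#' @param expr wide expression tibble.
#' @param target positive target mean, default 1000.
#' @return wide expression tibble tagged with stage `"mean_rescaled"`.
#' @export
rescale_sample_means <- function(expr, target = 1000) {
  if (target <= 0) abort("target must be > 0")
  m <- wide_to_matrix(expr)
  mu <- colMeans(m)
  zero <- mu <= 0
  if (any(zero)) {
    abort(sprintf("sample(s) with zero mean expression: %s",
                  paste(head(colnames(m)[zero], 5), collapse = ", ")))
  }
  out <- matrix_to_wide(sweep(m, 2, target / mu, "*"), "gene_id")
  set_stage(out, "mean_rescaled")
}

#' Full two-stage normalization
#'
#' [compute_size_factors()] then [apply_size_factors()] then
#' [rescale_sample_means()].
#'
#' @param counts wide count tibble.
#' @param target_mean per-sample target mean after rescaling.
#' @return wide expression tibble, stage `"mean_rescaled"`, with the size
#'   factors attached as attribute `"size_factors"`.
#' @export
normalize_counts <- function(counts, target_mean = 1000) {
  sf <- compute_size_factors(counts)
  out <- counts |>
    apply_size_factors(sf) |>
    rescale_sample_means(target = target_mean)
  attr(out, "size_factors") <- sf
  out
}
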