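# Hallmark signature scoring: the surrogate signature of a hallmark in a
# sample is the unweighted arithmetic mean of its member genes' normalized
# expression, on the linear scale (no z-scoring, no log). This follows the
# "mean expression as surrogate activity" convention for multigene
# signatures; because the mean is taken over a pre-selected hallmark gene
# set, relative changes of the members drive the score.

#' Score gene-set signatures as mean member expression
#'
#' For each set and sample, the score is the mean expression of the set's
#' member genes present in the matrix. Sets with fewer than `min_genes`
#' members present are dropped with a warning listing the missing symbols.
#'
#' @param expr wide expression tibble, normally the mean-rescaled matrix
#'   from [normalize_counts()].
#' @param sets long gene-set tibble from [read_gmt()] (columns `set_name`,
#'   `gene_symbol`).
#' @param min_genes minimum member genes that must be present to score a
#'   set (default 2, so a single gene cannot silently stand in for a
#'   hallmark).
#' @return wide signature tibble (`set_name` + one column per sample) with
#'   attribute `"set_info"`: a tibble of `set_name`, `n_members`,
#'   `n_present`, `missing_genes`.
#' @export
signature_scores <- function(expr, sets, min_genes = 2) {
  if (nrow(sets) == 0) abort("empty gene-set collection")
  m <- wide_to_matrix(expr)
  info <- sets |>
    group_by(.data$set_name) |>
    summarise(
      n_members = dplyr::n_distinct(.data$gene_symbol),
      n_present = sum(unique(.data$gene_symbol) %in% rownames(m)),
      missing_genes = paste(setdiff(unique(.data$gene_symbol), rownames(m)),
                            collapse = ","),
      .groups = "drop"
    ) |>
    arrange(match(.data$set_name, unique(sets$set_name)))
  drop <- info$set_name[info$n_present < min_genes]
  if (length(drop) > 0) {
    bad <- filter(info, .data$set_name %in% drop)
    warn(sprintf(
      "dropping %d set(s) with fewer than %d member genes present: %s",
      length(drop), min_genes,
      paste(sprintf("%s (missing: %s)", bad$set_name,
                    ifelse(nzchar(bad$missing_genes), bad$missing_genes, "none")),
            collapse = "; ")))
  }
  keep <- setdiff(info$set_name, drop)
  if (length(keep) == 0) {
    abort(sprintf("no gene set has >= %d member genes present in the matrix", min_genes))
  }
  scores <- purrr::map(keep, function(s) {
    genes <- intersect(unique(sets$gene_symbol[sets$set_name == s]), rownames(m))
    colMeans(m[genes, , drop = FALSE])
  })
  sm <- do.call(rbind, scores)
  rownames(sm) <- keep
  out <- matrix_to_wide(sm, "set_name")
  attr(out, "set_info") <- filter(info, .data$set_name %in% keep)
  attr(out, "hs_stage") <- expr_stage(expr)
  out
}
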