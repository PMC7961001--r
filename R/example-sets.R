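# Synthetic hallmark gene-set collections for demos and tests. The eight
# set names mirror the eight classical cancer hallmark categories; the
# member symbols are synthetic (matching simulate_counts() gene ids), not
# the published hallmark gene catalog.

hallmark_names <- function() {
  c("sustaining_proliferative_signaling", "resisting_cell_death",
    "inducing_angiogenesis", "genome_instability",
    "evading_growth_suppressors", "enabling_replicative_immortality",
    "deregulation_cellular_energetics", "activation_invasion_metastasis")
}

#' Synthetic hallmark gene sets over simulated gene ids
#'
#' Builds eight gene sets named after the classical cancer hallmarks,
#' drawing members from the gene ids of a simulated matrix
#' (`G0001`, `G0002`, ...). Consecutive sets share a configurable number
#' of genes, mirroring the real catalog's property that a gene may belong
#' to several hallmarks. Deterministic for a given seed.
#'
#' @param n_genes number of genes in the simulated matrix.
#' @param genes_per_set members per set.
#' @param overlap members shared between consecutive sets.
#' @param seed integer seed.
#' @return long gene-set tibble (`set_name`, `description`,
#'   `gene_symbol`).
#' @export
synthetic_hallmark_sets <- function(n_genes = 500, genes_per_set = 20,
                                    overlap = 3, seed = 1) {
  nm <- hallmark_names()
  need <- length(nm) * (genes_per_set - overlap) + overlap
  if (n_genes < need) {
    abort(sprintf("need at least %d genes for %d sets of %d with overlap %d",
                  need, length(nm), genes_per_set, overlap))
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  withr::with_seed(derive_seed(seed, 6), {
    pool <- sample(genes, need)
    step <- genes_per_set - overlap
    purrr::imap(nm, function(s, i) {
      idx <- ((i - 1) * step + 1):((i - 1) * step + genes_per_set)
      tibble(set_name = s, description = "synthetic hallmark set",
             gene_symbol = pool[idx])
    }) |> list_rbind()
  })
}
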