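# End-to-end orchestration: per-tumor normalize -> signatures -> gene
# scans -> signature scans -> TMB scan -> multivariate models, then
# cross-tumor aggregation (significance matrix, dendrograms, recurrent
# features, forest-plot data). All outputs are deterministic TSV/JSON;
# rerunning with the same configuration and seed reproduces them byte for
# byte.

#' Pipeline configuration
#'
#' @param endpoint survival endpoint, `"os"` or `"rfs"`.
#' @param fdr_threshold scan FDR acceptance level, default 0.10.
#' @param min_cohort_size cohorts with `n_samples <= min_cohort_size` are
#'   skipped (default 100, i.e. more than 100 specimens required).
#' @param min_group minimum group size at a candidate cutoff.
#' @param across_features_fdr also BH-adjust best p-values across features.
#' @param per_mb optional megabase size for rate-scale TMB.
#' @param target_mean per-sample mean after rescaling, default 1000.
#' @param min_set_genes minimum member genes present to score a signature.
#' @param forest_p_threshold p-value threshold for the signature forest
#'   table (default 0.05).
#' @param min_tumors minimum tumor types for a recurrent feature, default
#'   10.
#' @param seed integer seed recorded in the manifest.
#' @param output_dir optional directory; when set, every stage writes its
#'   result tables there.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(endpoint = "os", fdr_threshold = 0.10,
                            min_cohort_size = 100, min_group = 1,
                            across_features_fdr = FALSE, per_mb = NULL,
                            target_mean = 1000, min_set_genes = 2,
                            forest_p_threshold = 0.05, min_tumors = 10,
                            seed = 1L, output_dir = NULL) {
  stopifnot(endpoint %in% c("os", "rfs"),
            fdr_threshold > 0, fdr_threshold < 1,
            min_cohort_size >= 0, target_mean > 0)
  structure(list(
    endpoint = endpoint, fdr_threshold = fdr_threshold,
    min_cohort_size = min_cohort_size, min_group = min_group,
    across_features_fdr = across_features_fdr, per_mb = per_mb,
    target_mean = target_mean, min_set_genes = min_set_genes,
    forest_p_threshold = forest_p_threshold, min_tumors = min_tumors,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields mirror the arguments of [pipeline_config()]; absent fields keep
#' their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config` object.
#' @export
pipeline_config_from_file <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) abort("yaml package not installed")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, vals[intersect(names(vals), names(formals(pipeline_config)))])
}

write_stage_tsv <- function(x, dir, name) {
  if (!is.null(dir)) {
    readr::write_tsv(x, file.path(dir, name), progress = FALSE)
  }
  invisible(x)
}

#' Run the full analysis for one tumor cohort
#'
#' Normalizes the counts, scores the hallmark signatures, scans every
#' hallmark gene and every signature (and TMB when mutations are given)
#' for its strongest survival cutoff, and fits a multivariate Cox model
#' per signature at its best cutoff. Cohorts at or below the minimum size
#' are skipped with a logged reason rather than an error.
#'
#' @param cohort list with `counts` (wide count tibble), `clinical`
#'   (clinical tibble) and optionally `maf` (mutation tibble), as produced
#'   by [simulate_cohort()] or the readers.
#' @param sets long gene-set tibble from [read_gmt()].
#' @param config a [pipeline_config()].
#' @param tumor_type cohort label used in outputs.
#' @return an object of class `tumor_result`: skipped flag, scan tibbles
#'   (`gene_scans`, `signature_scans`, `tmb_scan`), `multivariate`
#'   per-signature term table, `km` step tables for significant
#'   signatures, plus the normalized `expr` and `signatures` matrices.
#' @export
run_tumor <- function(cohort, sets, config = pipeline_config(),
                      tumor_type = "tumor") {
  stopifnot(inherits(config, "pipeline_config"))
  n_samples <- length(sample_ids_of(cohort$counts))
  if (n_samples <= config$min_cohort_size) {
    msg <- sprintf("cohort %s skipped: %d samples <= minimum %d",
                   tumor_type, n_samples, config$min_cohort_size)
    message(msg)
    return(structure(list(tumor_type = tumor_type, skipped = TRUE,
                          reason = msg, n_samples = n_samples),
                     class = "tumor_result"))
  }
  dir <- NULL
  if (!is.null(config$output_dir)) {
    dir <- file.path(config$output_dir, tumor_type)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  expr <- normalize_counts(cohort$counts, target_mean = config$target_mean)
  write_stage_tsv(attr(expr, "size_factors"), dir, "size_factors.tsv")
  sig <- signature_scores(expr, sets, min_genes = config$min_set_genes)
  hallmark_genes <- intersect(unique(sets$gene_symbol), expr$gene_id)
  gene_scans <- scan_expression(
    expr, cohort$clinical, endpoint = config$endpoint,
    features = hallmark_genes, fdr_threshold = config$fdr_threshold,
    min_group = config$min_group,
    across_features_fdr = config$across_features_fdr
  )
  write_stage_tsv(gene_scans, dir, "gene_scans.tsv")
  signature_scans <- scan_expression(
    sig, cohort$clinical, endpoint = config$endpoint,
    fdr_threshold = config$fdr_threshold, min_group = config$min_group
  )
  write_stage_tsv(signature_scans, dir, "signature_scans.tsv")
  tmb_row <- NULL
  if (!is.null(cohort$maf)) {
    tmb <- compute_tmb(cohort$maf, samples = sample_ids_of(cohort$counts),
                       per_mb = config$per_mb)
    tmb_row <- glance(tmb_scan(tmb, cohort$clinical,
                               endpoint = config$endpoint,
                               fdr_threshold = config$fdr_threshold,
                               min_group = config$min_group))
    write_stage_tsv(tmb_row, dir, "tmb_scan.tsv")
  }
  cols <- endpoint_cols(config$endpoint)
  sig_m <- wide_to_matrix(sig, "set_name")
  mv <- purrr::map(signature_scans$feature[signature_scans$evaluable],
                   function(s) {
    row <- filter(signature_scans, .data$feature == s)
    grp <- tibble(sample_id = colnames(sig_m),
                  group = ifelse(sig_m[s, ] > row$best_cutoff, "high", "low"))
    fit <- tryCatch(
      multivariate_cox(cohort$clinical, grp, endpoint = config$endpoint),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    mutate(tidy(fit), signature = s, .before = 1)
  })
  multivariate <- list_rbind(purrr::compact(mv))
  write_stage_tsv(multivariate, dir, "multivariate.tsv")
  km <- list()
  sig_hits <- signature_scans$feature[signature_scans$significant]
  for (s in sig_hits) {
    row <- filter(signature_scans, .data$feature == s)
    d <- tibble(
      group = ifelse(sig_m[s, ] > row$best_cutoff, "high", "low"),
      time = cohort$clinical[[cols["time"]]][match(colnames(sig_m), cohort$clinical$sample_id)],
      event = cohort$clinical[[cols["event"]]][match(colnames(sig_m), cohort$clinical$sample_id)]
    )
    km[[s]] <- km_curve(d)
    write_stage_tsv(km[[s]]$steps, dir, sprintf("km_%s.tsv", gsub("[^A-Za-z0-9_-]", "_", s)))
  }
  structure(list(
    tumor_type = tumor_type, skipped = FALSE, n_samples = n_samples,
    gene_scans = gene_scans, signature_scans = signature_scans,
    tmb_scan = tmb_row, multivariate = multivariate, km = km,
    expr = expr, signatures = sig
  ), class = "tumor_result")
}

#' @export
print.tumor_result <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat(sprintf("<tumor_result> %s: skipped (%s)\n", x$tumor_type, x$reason))
    return(invisible(x))
  }
  cat(sprintf("<tumor_result> %s: n = %d; %d/%d genes and %d/%d signatures significant\n",
              x$tumor_type, x$n_samples,
              sum(x$gene_scans$significant), nrow(x$gene_scans),
              sum(x$signature_scans$significant), nrow(x$signature_scans)))
  invisible(x)
}

#' Run the pancancer analysis across tumor cohorts
#'
#' Runs [run_tumor()] per cohort, then aggregates: the hallmark-by-tumor
#' significance matrix, hierarchical dendrograms on both axes, the
#' recurrent-feature table, and the forest-plot data for significant
#' signature scans (best-cutoff p below the forest threshold).
#'
#' @param cohorts named list of cohort lists (names are tumor types).
#' @param sets long gene-set tibble from [read_gmt()].
#' @param config a [pipeline_config()].
#' @return an object of class `pancancer_result`: `$tumors` (per-tumor
#'   results), `$gene_scans` (combined), `$significance`
#'   (significance_matrix), `$dendro_hallmarks`, `$dendro_tumors`,
#'   `$recurrent`, `$forest`.
#' @export
run_pancancer <- function(cohorts, sets, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    abort("cohorts must be a named list")
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  tumors <- purrr::imap(cohorts, function(co, tt) run_tumor(co, sets, config, tt))
  done <- purrr::keep(tumors, ~ !isTRUE(.x$skipped))
  if (length(done) < 2) abort("fewer than 2 tumor cohorts passed the size filter")
  gene_scans <- purrr::imap(done, function(res, tt) {
    mutate(res$gene_scans, tumor_type = tt, .before = 1)
  }) |> list_rbind()
  signature_scans <- purrr::imap(done, function(res, tt) {
    mutate(res$signature_scans, tumor_type = tt, .before = 1)
  }) |> list_rbind()
  sig_mat <- significance_matrix(gene_scans, sets)
  dendro_h <- if (nrow(sig_mat$percent) >= 2) {
    hierarchical_cluster(sig_mat, axis = "hallmarks")
  }
  dendro_t <- if (length(done) >= 2) hierarchical_cluster(sig_mat, axis = "tumors")
  recurrent <- recurrent_features(gene_scans,
                                  min_tumors = min(config$min_tumors, length(done)))
  forest <- signature_scans |>
    filter(.data$evaluable, !is.na(.data$p),
           .data$p < config$forest_p_threshold) |>
    select("tumor_type", "feature", "hr", "ci_low", "ci_high", "p", "q",
           "significant") |>
    arrange(.data$tumor_type, .data$p)
  if (!is.null(config$output_dir)) {
    d <- config$output_dir
    readr::write_tsv(sig_mat$percent, file.path(d, "significance_percent.tsv"), progress = FALSE)
    readr::write_tsv(sig_mat$numerator, file.path(d, "significance_numerator.tsv"), progress = FALSE)
    readr::write_tsv(sig_mat$denominator, file.path(d, "significance_denominator.tsv"), progress = FALSE)
    if (!is.null(dendro_h)) write_newick(dendro_h, file.path(d, "dendrogram_hallmarks.nwk"))
    if (!is.null(dendro_t)) write_newick(dendro_t, file.path(d, "dendrogram_tumors.nwk"))
    readr::write_tsv(recurrent, file.path(d, "recurrent_features.tsv"), progress = FALSE)
    readr::write_tsv(forest, file.path(d, "forest_signatures.tsv"), progress = FALSE)
    manifest <- list(
      package = "hallmarksurv",
      version = as.character(utils::packageVersion("hallmarksurv")),
      seed = config$seed,
      endpoint = config$endpoint,
      fdr_threshold = config$fdr_threshold,
      min_cohort_size = config$min_cohort_size,
      tumors_run = names(done),
      tumors_skipped = names(purrr::keep(tumors, ~ isTRUE(.x$skipped)))
    )
    jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(
    tumors = tumors, gene_scans = gene_scans,
    signature_scans = signature_scans, significance = sig_mat,
    dendro_hallmarks = dendro_h, dendro_tumors = dendro_t,
    recurrent = recurrent, forest = forest
  ), class = "pancancer_result")
}

#' @export
print.pancancer_result <- function(x, ...) {
  done <- purrr::keep(x$tumors, ~ !isTRUE(.x$skipped))
  cat(sprintf("<pancancer_result> %d tumor types analyzed, %d recurrent feature(s)\n",
              length(done), nrow(x$recurrent)))
  invisible(x)
}
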