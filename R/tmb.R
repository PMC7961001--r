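# Tumor mutation burden: per-sample count of qualifying somatic variants
# from a MAF-derived mutation table, fed to the cutoff scan as a
# continuous prognostic feature. TMB is a raw variant count by default; a
# per-megabase rate is available when a target size is supplied.

#' Per-sample tumor mutation burden
#'
#' Counts each sample's mutation records whose variant class is in
#' `qualifying_classes` (default: the non-silent set, so Silent and other
#' non-coding classes never contribute). Samples without records get 0.
#' Multiple records for the same sample-gene pair all count.
#'
#' @param mutations mutation tibble from [read_maf()].
#' @param samples character vector of cohort sample ids.
#' @param qualifying_classes variant classes that count, default
#'   [maf_nonsilent_classes()].
#' @param per_mb optional target territory size in megabases; when given,
#'   counts are divided by it (mutations/Mb).
#' @return tibble with columns `sample_id`, `tmb`.
#' @export
compute_tmb <- function(mutations, samples,
                        qualifying_classes = maf_nonsilent_classes(),
                        per_mb = NULL) {
  unknown <- setdiff(qualifying_classes, maf_all_classes())
  if (length(unknown) > 0) {
    abort(sprintf("unknown variant class(es) in qualifying_classes: %s",
                  paste(unknown, collapse = ", ")))
  }
  counts <- mutations |>
    filter(.data$variant_classification %in% qualifying_classes,
           .data$sample_id %in% samples) |>
    dplyr::count(.data$sample_id, name = "tmb")
  out <- tibble(sample_id = samples) |>
    left_join(counts, by = "sample_id") |>
    mutate(tmb = dplyr::coalesce(.data$tmb, 0L))
  if (!is.null(per_mb)) {
    if (per_mb <= 0) abort("per_mb must be > 0")
    out$tmb <- out$tmb / per_mb
  }
  out
}

#' Cutoff scan of tumor mutation burden against survival
#'
#' Delegates to [cutoff_scan()] on the per-sample TMB values joined to the
#' clinical table; the procedure is identical to the gene-expression scan
#' (candidate cutoffs between the TMB quartiles, BH over the scan).
#'
#' @param tmb tibble from [compute_tmb()].
#' @param clinical clinical tibble.
#' @param endpoint `"os"` or `"rfs"`.
#' @param ... passed to [cutoff_scan()] (`fdr_threshold`, `min_group`).
#' @return a `cutoff_scan` object with `feature_id = "TMB"`.
#' @export
tmb_scan <- function(tmb, clinical, endpoint = "os", ...) {
  cols <- endpoint_cols(endpoint)
  d <- inner_join(tmb, clinical, by = "sample_id")
  d <- tibble(value = d$tmb, time = d[[cols["time"]]], event = d[[cols["event"]]])
  cutoff_scan(d, feature_id = "TMB", ...)
}
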