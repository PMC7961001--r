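# Internal helpers shared across modules.

# A "wide" expression/count tibble has one id column (gene_id or set_name)
# followed by one numeric column per sample.

#' Convert a wide gene-by-sample tibble to a numeric matrix
#'
#' @param x wide tibble whose first column holds feature identifiers.
#' @param id_col name of the identifier column.
#' @return numeric matrix with feature rownames and sample colnames.
#' @keywords internal
#' @noRd
wide_to_matrix <- function(x, id_col = NULL) {
  id_col <- id_col %||% names(x)[1]
  ids <- as.character(x[[id_col]])
  m <- as.matrix(x[setdiff(names(x), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_wide <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}

sample_ids_of <- function(x, id_col = NULL) {
  id_col <- id_col %||% names(x)[1]
  setdiff(names(x), id_col)
}

#' Stage tag of an expression tibble
#'
#' Normalization functions tag their output so downstream stages can assert
#' they receive the matrix they expect (`"raw"`, `"size_factor_normalized"`,
#' `"mean_rescaled"`).
#'
#' @param x a wide expression tibble.
#' @return a character scalar, or `"raw"` when untagged.
#' @export
expr_stage <- function(x) attr(x, "hs_stage") %||% "raw"

set_stage <- function(x, stage) {
  attr(x, "hs_stage") <- stage
  x
}

assert_count_matrix <- function(x, what = "count matrix") {
  if (!is.data.frame(x) || ncol(x) < 3) {
    abort(sprintf("%s must be a wide tibble with an id column and >= 2 sample columns", what))
  }
  ids <- as.character(x[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene identifier(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  samples <- sample_ids_of(x)
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0) {
    abort(sprintf("duplicate sample identifier(s): %s", paste(head(dup_s, 5), collapse = ", ")))
  }
  m <- wide_to_matrix(x)
  if (anyNA(m)) abort(sprintf("%s contains missing values", what))
  if (any(m < 0)) abort(sprintf("%s contains negative values", what))
  if (any(m != round(m))) abort(sprintf("%s contains non-integer values", what))
  invisible(x)
}

# Quartiles throughout use linear interpolation (stats::quantile type 7).
quartiles <- function(x) quantile(x, c(0.25, 0.75), names = FALSE, type = 7)

# Deterministic derived seeds for independent sub-streams: a Lehmer step keeps
# the value inside 32-bit integer range whatever small seed the user supplies.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 7919 + 1) %% 2147483647)
}
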