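# Readers and writers for the tabular formats the pipeline touches:
# counts (TSV / MatrixMarket), clinical tables, MAF mutation tables, GMT
# gene sets. All readers validate on ingest; all writers emit UTF-8
# tab-separated text with '.' decimals and deterministic row order.

MISSING_TOKENS <- c("", "na", "nan")

#' Controlled Variant_Classification vocabulary of the MAF standard
#'
#' @return character vector of recognized variant classes.
#' @export
maf_all_classes <- function() {
  c(
    "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation", "Silent",
    "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del",
    "Splice_Site", "Splice_Region", "Translation_Start_Site",
    "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "RNA", "IGR",
    "Targeted_Region", "De_novo_Start_InFrame", "De_novo_Start_OutOfFrame"
  )
}

#' Default non-silent variant classes used for mutation-derived features
#'
#' The conventional protein-altering set: missense, nonsense, nonstop,
#' frameshift and in-frame indels, splice site, and translation start.
#'
#' @return character vector, a subset of [maf_all_classes()].
#' @export
maf_nonsilent_classes <- function() {
  c(
    "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del",
    "Splice_Site", "Translation_Start_Site"
  )
}

#' Read a raw gene-by-sample count matrix
#'
#' Accepts either a TSV with gene identifiers in the first column and sample
#' identifiers in the header, or a MatrixMarket triplet file with sidecar
#' row-name and column-name files (one identifier per line). Counts must be
#' nonnegative integers with unique gene and sample identifiers.
#'
#' @param path file path of the TSV or MTX file.
#' @param format `"tsv"` (default) or `"mtx"`.
#' @param row_names,col_names sidecar paths for `format = "mtx"`; default
#'   `<path>.rownames` / `<path>.colnames`.
#' @param id_map optional two-column data frame (or TSV path) mapping input
#'   gene identifiers to preferred symbols, applied at load; unmapped
#'   identifiers are kept as-is.
#' @return a wide tibble: `gene_id` column followed by one integer column per
#'   sample.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        row_names = NULL, col_names = NULL, id_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "tsv") {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
    if (ncol(x) < 3) abort("counts TSV needs a gene id column and >= 2 sample columns")
    names(x)[1] <- "gene_id"
    x$gene_id <- as.character(x$gene_id)
    for (j in seq(2, ncol(x))) {
      if (!is.numeric(x[[j]])) {
        abort(sprintf("non-numeric counts in column '%s'", names(x)[j]))
      }
    }
  } else {
    row_names <- row_names %||% paste0(path, ".rownames")
    col_names <- col_names %||% paste0(path, ".colnames")
    if (!file.exists(row_names) || !file.exists(col_names)) {
      abort("MTX input needs row-name and column-name sidecar files")
    }
    m <- as.matrix(Matrix::readMM(path))
    rn <- readr::read_lines(row_names)
    cn <- readr::read_lines(col_names)
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      abort("sidecar name files do not match MTX dimensions")
    }
    dimnames(m) <- list(rn, cn)
    x <- matrix_to_wide(m, "gene_id")
  }
  if (!is.null(id_map)) {
    if (is.character(id_map)) {
      id_map <- readr::read_tsv(id_map, show_col_types = FALSE, progress = FALSE)
    }
    lut <- setNames(as.character(id_map[[2]]), as.character(id_map[[1]]))
    hit <- x$gene_id %in% names(lut)
    x$gene_id[hit] <- unname(lut[x$gene_id[hit]])
  }
  x <- as_tibble(x)
  assert_count_matrix(x)
  x
}

#' Write a count matrix to TSV
#'
#' @param counts wide count tibble as returned by [read_counts()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

is_missing_token <- function(x) {
  is.na(x) | tolower(trimws(as.character(x))) %in% MISSING_TOKENS
}

parse_numeric_col <- function(x, what) {
  miss <- is_missing_token(x)
  out <- suppressWarnings(as.numeric(as.character(x)))
  bad <- !miss & is.na(out)
  if (any(bad)) abort(sprintf("unparseable %s value(s): %s", what,
                              paste(head(unique(x[bad]), 3), collapse = ", ")))
  out[miss] <- NA_real_
  out
}

#' Parse tumor stage labels to ordinal 0-4
#'
#' Accepts arabic digits (`0`-`4`), roman numerals (`0`, `I`-`IV`), and the
#' `"Stage IIa"` convention; sub-stage letters truncate to the major stage.
#'
#' @param x character or numeric vector of stage labels.
#' @return integer vector in 0..4 with `NA` for missing.
#' @export
parse_stage <- function(x) {
  raw <- as.character(x)
  miss <- is_missing_token(raw)
  s <- toupper(trimws(raw))
  s <- stringr::str_remove(s, "^STAGE\\s*")
  s <- stringr::str_remove(s, "[A-C][12]?$")  # sub-stage suffix, e.g. IIA
  roman <- c("0" = 0L, "I" = 1L, "II" = 2L, "III" = 3L, "IV" = 4L)
  out <- rep(NA_integer_, length(s))
  is_rom <- s %in% names(roman)
  out[is_rom] <- roman[s[is_rom]]
  is_num <- !is_rom & grepl("^[0-4]$", s)
  out[is_num] <- as.integer(s[is_num])
  bad <- !miss & !is_rom & !is_num
  if (any(bad)) {
    abort(sprintf("unparseable stage value(s): %s",
                  paste(head(unique(raw[bad]), 3), collapse = ", ")))
  }
  out[miss] <- NA_integer_
  out
}

#' Read a per-sample clinical table
#'
#' Expects a TSV with a `sample_id` column and at least one survival endpoint
#' pair (`os_time`/`os_event` or `rfs_time`/`rfs_event`); optional covariate
#' columns `sex`, `race`, `stage`, `grade`, `age`. Column order is
#' irrelevant. Empty strings, `NA` and `NaN` (any case) are missing. Times
#' are in months. A time observed without its event indicator is a
#' validation error.
#'
#' @param path TSV file path.
#' @return tibble with one row per sample: `sample_id`, `os_time`,
#'   `os_event`, `rfs_time`, `rfs_event`, `sex`, `race`, `stage`, `grade`,
#'   `age` (absent optional columns are filled with `NA`).
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (!"sample_id" %in% names(x)) abort("clinical table must have a sample_id column")
  has_os <- all(c("os_time", "os_event") %in% names(x))
  has_rfs <- all(c("rfs_time", "rfs_event") %in% names(x))
  if (!has_os && !has_rfs) {
    abort("clinical table needs at least one (time, event) column pair")
  }
  out <- tibble(sample_id = as.character(x$sample_id))
  dup <- unique(out$sample_id[duplicated(out$sample_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample id(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  grab_num <- function(col) {
    if (col %in% names(x)) parse_numeric_col(x[[col]], col) else rep(NA_real_, nrow(x))
  }
  grab_chr <- function(col) {
    if (!col %in% names(x)) return(rep(NA_character_, nrow(x)))
    v <- as.character(x[[col]])
    v[is_missing_token(v)] <- NA_character_
    v
  }
  out$os_time <- grab_num("os_time")
  out$os_event <- grab_num("os_event")
  out$rfs_time <- grab_num("rfs_time")
  out$rfs_event <- grab_num("rfs_event")
  for (ep in c("os", "rfs")) {
    tm <- out[[paste0(ep, "_time")]]
    ev <- out[[paste0(ep, "_event")]]
    orphan <- !is.na(tm) & is.na(ev)
    if (any(orphan)) {
      abort(sprintf("%s_time present without %s_event for sample(s): %s", ep, ep,
                    paste(head(out$sample_id[orphan], 5), collapse = ", ")))
    }
    if (any(!is.na(ev) & !ev %in% c(0, 1))) {
      abort(sprintf("%s_event values must be 0 or 1", ep))
    }
    if (any(!is.na(tm) & (tm < 0 | !is.finite(tm)))) {
      abort(sprintf("%s_time values must be finite and >= 0", ep))
    }
  }
  out$sex <- grab_chr("sex")
  out$race <- grab_chr("race")
  out$stage <- if ("stage" %in% names(x)) parse_stage(x$stage) else rep(NA_integer_, nrow(x))
  out$grade <- grab_chr("grade")
  out$age <- grab_num("age")
  if (any(!is.na(out$age) & out$age <= 0)) abort("age values must be > 0")
  out
}

#' Write a clinical table to TSV
#'
#' @param clinical tibble as returned by [read_clinical()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path, progress = FALSE)
  invisible(path)
}

#' Read a MAF somatic mutation table
#'
#' Header-driven: requires `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification` columns in any order; lines starting with `#`
#' are comments. Classification values must belong to the MAF controlled
#' vocabulary.
#'
#' @param path MAF file path.
#' @return tibble with columns `sample_id`, `gene_symbol`,
#'   `variant_classification`, one row per variant record.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("MAF lacks mandatory column(s): %s", paste(miss, collapse = ", ")))
  }
  out <- tibble(
    sample_id = as.character(x$Tumor_Sample_Barcode),
    gene_symbol = as.character(x$Hugo_Symbol),
    variant_classification = as.character(x$Variant_Classification)
  )
  unknown <- setdiff(unique(out$variant_classification), maf_all_classes())
  if (length(unknown) > 0) {
    abort(sprintf("Variant_Classification value(s) outside the MAF vocabulary: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  out
}

#' Write a mutation table as a minimal MAF
#'
#' @param mutations tibble as returned by [read_maf()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(mutations, path) {
  out <- tibble(
    Hugo_Symbol = mutations$gene_symbol,
    Tumor_Sample_Barcode = mutations$sample_id,
    Variant_Classification = mutations$variant_classification
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-separated. Duplicate genes within a set are removed; a gene may
#' belong to several sets.
#'
#' @param path GMT file path.
#' @return long tibble with columns `set_name`, `description`,
#'   `gene_symbol`, one row per set membership.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- stringr::str_split(lines, "\t")
  short <- which(purrr::map_int(fields, length) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  sets <- purrr::map(fields, function(f) {
    tibble(set_name = f[1], description = f[2],
           gene_symbol = unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  }) |> list_rbind()
  nm <- purrr::map_chr(fields, 1)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene set name(s): %s", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(sets$gene_symbol))) abort("empty gene symbol in GMT")
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets long tibble as returned by [read_gmt()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- sets |>
    group_by(.data$set_name) |>
    summarise(line = paste(c(.data$set_name[1], .data$description[1], .data$gene_symbol),
                           collapse = "\t"), .groups = "drop") |>
    arrange(match(.data$set_name, unique(sets$set_name)))
  readr::write_lines(lines$line, path)
  invisible(path)
}
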