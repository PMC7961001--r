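# Cross-tumor aggregation: the hallmark-by-tumor significance matrix (the
# percentage of each hallmark's scanned genes that are prognostic in each
# tumor type), its hierarchical clustering, and the recurrent features
# that are prognostic in many tumor types.

#' Hallmark-by-tumor significance matrix
#'
#' Each cell is 100 x (significant member genes) / (member genes evaluable
#' and scanned) for one hallmark in one tumor type. A gene belonging to
#' several hallmarks counts in each. Hallmarks with no scanned gene in a
#' tumor get a missing cell (NA), not zero.
#'
#' @param scans tibble of per-feature scan summaries across tumors: the
#'   row-bound [scan_expression()] outputs with an added `tumor_type`
#'   column (columns used: `tumor_type`, `feature`, `significant`,
#'   `evaluable`, and `p` when `criterion = "p"`).
#' @param sets long gene-set tibble from [read_gmt()].
#' @param criterion `"q"` (default: the scan's FDR-based `significant`
#'   flag) or `"p"` (best p < `p_threshold`).
#' @param p_threshold p-value threshold when `criterion = "p"`.
#' @return an object of class `significance_matrix` with wide tibbles
#'   `$percent`, `$numerator`, `$denominator` (`set_name` + one column per
#'   tumor type). Has [tidy()] and [autoplot()] methods.
#' @export
significance_matrix <- function(scans, sets, criterion = c("q", "p"),
                                p_threshold = 0.05) {
  criterion <- match.arg(criterion)
  stopifnot(all(c("tumor_type", "feature", "significant", "evaluable") %in% names(scans)))
  hit <- if (criterion == "q") scans$significant
         else !is.na(scans$p) & scans$p < p_threshold
  scans <- mutate(scans, .hit = hit)
  cells <- sets |>
    distinct(.data$set_name, .data$gene_symbol) |>
    inner_join(scans, by = c(gene_symbol = "feature"),
               relationship = "many-to-many") |>
    filter(.data$evaluable) |>
    group_by(.data$set_name, .data$tumor_type) |>
    summarise(numerator = sum(.data$.hit), denominator = dplyr::n(),
              .groups = "drop") |>
    mutate(percent = 100 * .data$numerator / .data$denominator)
  set_names <- unique(sets$set_name)
  tumor_types <- unique(scans$tumor_type)
  widen <- function(col) {
    cells |>
      select("set_name", "tumor_type", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "tumor_type", values_from = dplyr::all_of(col)) |>
      dplyr::right_join(tibble(set_name = set_names), by = "set_name") |>
      arrange(match(.data$set_name, set_names))
  }
  out <- list(percent = widen("percent"), numerator = widen("numerator"),
              denominator = widen("denominator"), tumor_types = tumor_types)
  for (tt in setdiff(tumor_types, names(out$percent))) {
    out$percent[[tt]] <- NA_real_
    out$numerator[[tt]] <- NA_real_
    out$denominator[[tt]] <- NA_real_
  }
  structure(out, class = "significance_matrix")
}

#' @export
print.significance_matrix <- function(x, ...) {
  cat("<significance_matrix> % significant genes per hallmark per tumor\n")
  print(x$percent)
  invisible(x)
}

#' Tidy a significance matrix: one row per hallmark-tumor cell
#'
#' @param x a `significance_matrix` object.
#' @param ... unused.
#' @return long tibble with `set_name`, `tumor_type`, `percent`,
#'   `numerator`, `denominator`.
#' @export
#' @exportS3Method generics::tidy
tidy.significance_matrix <- function(x, ...) {
  lng <- function(w, nm) {
    tidyr::pivot_longer(w, -"set_name", names_to = "tumor_type", values_to = nm)
  }
  lng(x$percent, "percent") |>
    left_join(lng(x$numerator, "numerator"), by = c("set_name", "tumor_type")) |>
    left_join(lng(x$denominator, "denominator"), by = c("set_name", "tumor_type"))
}

#' Heatmap of a significance matrix
#'
#' @param object a `significance_matrix` object.
#' @param cluster reorder rows/columns by hierarchical clustering.
#' @param ... unused.
#' @return a ggplot tile heatmap of the percentages.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.significance_matrix <- function(object, cluster = TRUE, ...) {
  df <- tidy(object)
  if (cluster && nrow(object$percent) >= 2 &&
      length(object$tumor_types) >= 2) {
    ord_h <- hierarchical_cluster(object, axis = "hallmarks")
    ord_t <- hierarchical_cluster(object, axis = "tumors")
    df$set_name <- factor(df$set_name, levels = ord_h$labels[ord_h$order])
    df$tumor_type <- factor(df$tumor_type, levels = ord_t$labels[ord_t$order])
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tumor_type, y = .data$set_name,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "% significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

sig_axis_matrix <- function(x, axis) {
  m <- wide_to_matrix(x$percent, "set_name")
  if (anyNA(m)) {
    warn("missing cells imputed as 0 for clustering only")
    m[is.na(m)] <- 0
  }
  if (axis == "tumors") m <- t(m)
  m
}

#' Hierarchically cluster the significance matrix
#'
#' Agglomerative clustering of hallmarks (rows) or tumor types (columns)
#' using the percentage-of-significant-genes profiles as coordinates.
#' Missing cells are imputed as 0 for the distance computation only.
#'
#' @param x a `significance_matrix`, or a wide tibble / numeric matrix.
#' @param axis `"hallmarks"` (rows) or `"tumors"` (columns).
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an object of class `hs_dendrogram` wrapping the `hclust` result
#'   (`$merge`, `$height`, `$order`, `$labels` and the parameters used).
#' @export
hierarchical_cluster <- function(x, axis = c("hallmarks", "tumors"),
                                 distance = c("euclidean", "correlation"),
                                 linkage = c("average", "complete", "single")) {
  axis <- match.arg(axis); distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- if (inherits(x, "significance_matrix")) sig_axis_matrix(x, axis)
       else if (is.matrix(x)) { if (axis == "tumors") t(x) else x }
       else { mm <- wide_to_matrix(x); if (axis == "tumors") t(mm) else mm }
  if (nrow(m) < 2) abort("need at least 2 rows on the chosen axis")
  d <- if (distance == "euclidean") dist(m)
       else stats::as.dist(1 - cor(t(m)))
  hc <- hclust(d, method = linkage)
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc, axis = axis,
                 distance = distance, linkage = linkage),
            class = "hs_dendrogram")
}

#' @export
print.hs_dendrogram <- function(x, ...) {
  cat(sprintf("<hs_dendrogram> %s, %s distance, %s linkage, %d leaves\n",
              x$axis, x$distance, x$linkage, length(x$labels)))
  cat("leaf order:", paste(x$labels[x$order], collapse = ", "), "\n")
  invisible(x)
}

#' Write a dendrogram in Newick format
#'
#' @param dendro an `hs_dendrogram` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendro, path) {
  phy <- ape::as.phylo(dendro$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Features prognostic in many tumor types
#'
#' Returns the features whose scan is significant in at least `min_tumors`
#' tumor types, sorted by the number of significant tumors (descending)
#' and then by the best p-value across tumors (ascending).
#'
#' @param scans cross-tumor scan summary tibble (as for
#'   [significance_matrix()]; columns `tumor_type`, `feature`,
#'   `significant`, `p`).
#' @param min_tumors minimum number of tumor types, default 10.
#' @return tibble with `feature`, `n_significant`, `n_tumors_scanned`,
#'   `best_p`.
#' @export
recurrent_features <- function(scans, min_tumors = 10) {
  n_types <- dplyr::n_distinct(scans$tumor_type)
  if (n_types < min_tumors) {
    abort(sprintf("only %d tumor types present (min_tumors = %d)", n_types, min_tumors))
  }
  scans |>
    group_by(.data$feature) |>
    summarise(n_significant = sum(.data$significant, na.rm = TRUE),
              n_tumors_scanned = sum(.data$evaluable, na.rm = TRUE),
              best_p = suppressWarnings(min(.data$p, na.rm = TRUE)),
              .groups = "drop") |>
    filter(.data$n_significant >= min_tumors) |>
    arrange(dplyr::desc(.data$n_significant), .data$best_p, .data$feature)
}
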