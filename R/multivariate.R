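# Multivariate Cox models: the dichotomized feature plus clinical
# covariates (sex, race, stage, grade, age), to assess whether a feature's
# prognostic association is independent of known epidemiological and
# clinical variables. Also the helper that turns a mutation table into a
# binary mutant/wild-type grouping for such models.

#' Mutant/wild-type grouping from a mutation table
#'
#' A sample is mutant iff it carries at least one record for the gene whose
#' variant class is in `qualifying_classes` (default: the non-silent set).
#' A gene absent from the table gives all wild-type.
#'
#' @param mutations mutation tibble from [read_maf()].
#' @param gene gene symbol.
#' @param samples character vector of cohort sample ids (so unmutated
#'   samples are representable).
#' @param qualifying_classes variant classes that count, default
#'   [maf_nonsilent_classes()].
#' @return tibble with columns `sample_id` and `group`
#'   (`"mutant"`/`"wild-type"`).
#' @export
binary_group_from_mutations <- function(mutations, gene, samples,
                                        qualifying_classes = maf_nonsilent_classes()) {
  unknown <- setdiff(qualifying_classes, maf_all_classes())
  if (length(unknown) > 0) {
    abort(sprintf("unknown variant class(es): %s", paste(unknown, collapse = ", ")))
  }
  mut <- mutations |>
    filter(.data$gene_symbol == gene,
           .data$variant_classification %in% qualifying_classes) |>
    pull(.data$sample_id) |>
    unique()
  tibble(sample_id = samples,
         group = ifelse(samples %in% mut, "mutant", "wild-type"))
}

covariate_design <- function(cl, covariates) {
  # Returns list(cols = named list of numeric columns, dropped = tibble)
  cols <- list(); dropped <- list()
  drop_it <- function(term, reason) {
    dropped[[length(dropped) + 1]] <<- tibble(term = term, reason = reason)
  }
  for (cv in covariates) {
    v <- cl[[cv]]
    if (all(is.na(v))) { drop_it(cv, "all-missing"); next }
    if (cv %in% c("age", "stage")) {
      x <- as.numeric(v)
      if (length(unique(x)) < 2) drop_it(cv, "constant") else cols[[cv]] <- x
    } else if (cv %in% c("sex", "grade")) {
      f <- factor(v)
      if (nlevels(f) < 2) { drop_it(cv, "constant"); next }
      ref <- if (cv == "sex" && "F" %in% levels(f)) "F"
             else if (cv == "grade" && "low" %in% levels(f)) "low"
             else levels(f)[1]
      f <- stats::relevel(f, ref = ref)
      for (lv in levels(f)[-1]) cols[[paste0(cv, lv)]] <- as.numeric(f == lv)
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) { drop_it(cv, "constant"); next }
      largest <- names(sort(table(f), decreasing = TRUE))[1]
      f <- stats::relevel(f, ref = largest)
      for (lv in levels(f)[-1]) cols[[paste0(cv, lv)]] <- as.numeric(f == lv)
    }
  }
  list(cols = cols, dropped = if (length(dropped)) list_rbind(dropped)
                              else tibble(term = character(), reason = character()))
}

#' Multivariate Cox model: feature group plus clinical covariates
#'
#' Fits a Cox proportional hazards model (Efron ties) on the feature's
#' binary group indicator together with the requested clinical covariates,
#' on the complete-case subset. Age enters continuously, stage as an
#' ordinal number, sex and grade as binary factors, race one-hot against
#' its largest category. Constant, all-missing or collinear terms are
#' dropped and reported.
#'
#' @param clinical clinical tibble with `sample_id`, endpoint columns and
#'   covariates.
#' @param group data frame with columns `sample_id` and `group` holding a
#'   two-level label. `"high"` (vs `"low"`) and `"mutant"` (vs
#'   `"wild-type"`) are recognized as the risk level whose HR is reported;
#'   any other pair uses the second factor level. A best-cutoff
#'   dichotomization from [cutoff_scan()] fits directly.
#' @param endpoint `"os"` or `"rfs"`.
#' @param covariates covariate names among sex, race, stage, grade, age.
#' @param min_events minimum events in the complete-case subset (default
#'   10).
#' @return an object of class `mv_cox` with [tidy()] (per-term HR, CI, p)
#'   and [glance()] methods.
#' @export
multivariate_cox <- function(clinical, group, endpoint = "os",
                             covariates = c("sex", "race", "stage", "grade", "age"),
                             min_events = 10) {
  cols <- endpoint_cols(endpoint)
  bad <- setdiff(covariates, c("sex", "race", "stage", "grade", "age"))
  if (length(bad) > 0) abort(sprintf("unknown covariate(s): %s", paste(bad, collapse = ", ")))
  cl <- inner_join(clinical, as_tibble(group), by = "sample_id")
  g <- factor(cl$group)
  if (nlevels(g) != 2) abort("group must have exactly 2 levels")
  lv <- levels(g)
  # risk level: the group whose HR is reported (vs the other as reference)
  risk_level <- if (setequal(lv, c("low", "high"))) "high"
                else if (setequal(lv, c("wild-type", "mutant"))) "mutant"
                else lv[2]
  keep <- !is.na(cl[[cols["time"]]]) & !is.na(cl[[cols["event"]]]) & !is.na(cl$group)
  for (cv in covariates) {
    if (!all(is.na(cl[[cv]]))) keep <- keep & !is.na(cl[[cv]])
  }
  cl <- cl[keep, ]
  n_events <- sum(cl[[cols["event"]]])
  if (n_events < min_events) {
    abort(sprintf("only %d events in the complete-case subset (need >= %d)",
                  n_events, min_events))
  }
  des <- covariate_design(cl, covariates)
  feature_term <- paste0("group", risk_level)
  X <- cbind(as.numeric(factor(cl$group) == risk_level),
             if (length(des$cols)) do.call(cbind, des$cols))
  colnames(X) <- c(feature_term, names(des$cols))
  dropped <- des$dropped
  # rank check: drop aliased columns (keep the feature term first)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep_idx <- sort(setdiff(qrX$pivot[seq_len(qrX$rank)], 1) - 1)
    aliased <- setdiff(seq_len(ncol(X)), keep_idx)
    dropped <- bind_rows(dropped,
                         tibble(term = colnames(X)[aliased], reason = "collinear"))
    X <- X[, keep_idx, drop = FALSE]
  }
  y <- survival::Surv(cl[[cols["time"]]], cl[[cols["event"]]])
  fit <- suppressWarnings(survival::coxph.fit(
    X, y, strata = NULL, offset = NULL, init = rep(0, ncol(X)),
    control = survival::coxph.control(), weights = rep(1, nrow(X)),
    method = "efron", rownames = NULL
  ))
  beta <- fit$coefficients
  se <- sqrt(diag(fit$var))
  z <- beta / se
  terms <- tibble(
    term = colnames(X), hr = exp(unname(beta)),
    ci_low = exp(unname(beta - 1.96 * se)),
    ci_high = exp(unname(beta + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(unname(z)))
  )
  structure(list(terms = terms, dropped = dropped, n = nrow(cl),
                 n_events = n_events, risk_level = risk_level,
                 feature_term = feature_term, endpoint = endpoint),
            class = "mv_cox")
}

#' @export
print.mv_cox <- function(x, ...) {
  cat(sprintf("<mv_cox> %s endpoint, n = %d, events = %d\n",
              toupper(x$endpoint), x$n, x$n_events))
  print(x$terms)
  if (nrow(x$dropped) > 0) {
    cat("dropped terms:\n"); print(x$dropped)
  }
  invisible(x)
}

#' Tidy a multivariate Cox fit: one row per model term
#'
#' @param x an `mv_cox` object.
#' @param ... unused.
#' @return tibble with `term`, `hr`, `ci_low`, `ci_high`, `p`.
#' @export
#' @exportS3Method generics::tidy
tidy.mv_cox <- function(x, ...) x$terms

#' One-row summary of a multivariate Cox fit
#'
#' @param x an `mv_cox` object.
#' @param ... unused.
#' @return one-row tibble with model n, events, and the feature term's HR
#'   and p.
#' @export
#' @exportS3Method generics::glance
glance.mv_cox <- function(x, ...) {
  ft <- filter(x$terms, .data$term == x$feature_term)
  tibble(n = x$n, n_events = x$n_events, n_terms = nrow(x$terms),
         n_dropped = nrow(x$dropped),
         feature_hr = if (nrow(ft)) ft$hr else NA_real_,
         feature_p = if (nrow(ft)) ft$p else NA_real_)
}
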