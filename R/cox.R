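# The core statistic: dichotomize a continuous feature at every candidate
# cutoff between its lower and upper quartiles, fit a two-group Cox
# proportional hazards model at each cutoff (Efron ties; the score test is
# the reported log-rank p-value), correct the scan with Benjamini-Hochberg,
# and select the best-performing cutoff with the lowest p-value. A result
# is accepted as significant only at FDR < 10% (by default).

#' Candidate cutoffs between the expression quartiles
#'
#' Every distinct observed value v with Q1 <= v <= Q3 (quartiles by linear
#' interpolation) such that both groups x <= v and x > v are non-empty and
#' at least `min_group` large.
#'
#' @param x numeric vector of per-sample feature values (NAs ignored).
#' @param min_group minimum size of either group at a candidate cutoff.
#' @return ascending numeric vector of cutoffs (possibly empty).
#' @export
candidate_cutoffs <- function(x, min_group = 1) {
  x <- x[!is.na(x)]
  if (length(x) < 8) {
    abort(sprintf("need >= 8 non-missing values to scan cutoffs (got %d)", length(x)))
  }
  q <- quartiles(x)
  v <- sort(unique(x))
  v <- v[v >= q[1] & v <= q[2]]
  keep <- purrr::map_lgl(v, function(cut) {
    sum(x <= cut) >= min_group && sum(x > cut) >= min_group
  })
  v[keep]
}

as_low_high <- function(group) {
  g <- as.character(group)
  bad <- setdiff(unique(g[!is.na(g)]), c("low", "high"))
  if (length(bad) > 0) {
    abort(sprintf("group values must be 'low'/'high' (got: %s)", paste(bad, collapse = ", ")))
  }
  g
}

# Single-covariate Cox fit on a high-group indicator via survival's fitting
# engine. Returns the row consumed by cutoff_scan.
cox_binary_row <- function(time, event, high) {
  n_low <- sum(!high); n_high <- sum(high)
  ev_low <- sum(event[!high]); ev_high <- sum(event[high])
  if (n_low == 0 || n_high == 0) abort("both groups must be non-empty")
  if (ev_low + ev_high == 0) abort("no events: cannot fit a survival model")
  y <- survival::Surv(time, event)
  f <- suppressWarnings(survival::coxph.fit(
    matrix(as.numeric(high), ncol = 1), y, strata = NULL, offset = NULL,
    init = 0, control = survival::coxph.control(),
    weights = rep(1, length(time)), method = "efron", rownames = NULL
  ))
  beta <- unname(f$coefficients)
  se <- sqrt(f$var[1, 1])
  p <- pchisq(f$score, df = 1, lower.tail = FALSE)
  degenerate <- (ev_low == 0 || ev_high == 0)
  tibble(
    n_low = n_low, n_high = n_high,
    events_low = ev_low, events_high = ev_high,
    hr = exp(beta),
    ci_low = if (degenerate) NA_real_ else exp(beta - 1.96 * se),
    ci_high = if (degenerate) NA_real_ else exp(beta + 1.96 * se),
    p = p, degenerate = degenerate
  )
}

#' Two-group Cox proportional hazards fit
#'
#' Fits a Cox model on the high-group indicator with Efron tie handling.
#' The p-value is the score test of that fit (the log-rank test); the
#' hazard ratio is exp(coefficient) for high vs low, with a 95% CI from
#' the normal approximation on the log scale. When one group has no
#' events the fit is flagged degenerate: the HR is a one-sided extreme
#' and the CI is suppressed.
#'
#' @param data data frame with one row per sample.
#' @param group,time,event columns of `data` (tidy-eval): group labels
#'   `"low"`/`"high"`, follow-up time in months, event indicator 0/1.
#' @return one-row tibble: `n_low`, `n_high`, `events_low`, `events_high`,
#'   `hr`, `ci_low`, `ci_high`, `p`, `degenerate`.
#' @export
fit_cox_binary <- function(data, group = group, time = time, event = event) {
  g <- as_low_high(dplyr::pull(data, {{ group }}))
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  ok <- !is.na(g) & !is.na(t) & !is.na(e)
  cox_binary_row(t[ok], e[ok], g[ok] == "high")
}

#' Scan all candidate cutoffs of a continuous feature against survival
#'
#' Dichotomizes the feature at each candidate cutoff (low: x <= cutoff,
#' high: x > cutoff), fits a two-group Cox model at each, adjusts the
#' scan's p-values with Benjamini-Hochberg, and selects the best cutoff
#' with the lowest p-value (ties broken toward the smaller cutoff).
#' Degenerate fits are kept in the scan but never selected as best while a
#' non-degenerate alternative exists. The feature is significant when the
#' BH q-value at the best cutoff is below `fdr_threshold`.
#'
#' Inputs that cannot be scanned (fewer than 8 values, a constant feature,
#' no events, no non-degenerate fit) yield an `evaluable = FALSE` result
#' rather than an error.
#'
#' @param data data frame with one row per sample.
#' @param value,time,event columns of `data` (tidy-eval): the continuous
#'   feature, follow-up time in months, event indicator 0/1. Rows with a
#'   missing value in any of the three are dropped pairwise.
#' @param fdr_threshold FDR acceptance level, default 0.10.
#' @param min_group minimum group size at a candidate cutoff, default 1.
#' @param feature_id optional label stored in the result.
#' @return an object of class `cutoff_scan`; see [tidy.cutoff_scan()] and
#'   [glance.cutoff_scan()].
#' @export
cutoff_scan <- function(data, value = value, time = time, event = event,
                        fdr_threshold = 0.10, min_group = 1,
                        feature_id = NULL) {
  x <- dplyr::pull(data, {{ value }})
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  ok <- !is.na(x) & !is.na(t) & !is.na(e)
  x <- x[ok]; t <- t[ok]; e <- e[ok]
  not_evaluable <- function() {
    structure(list(
      feature_id = feature_id, n = length(x), n_events = sum(e),
      scan = tibble(cutoff = numeric(), n_low = integer(), n_high = integer(),
                    events_low = numeric(), events_high = numeric(),
                    hr = numeric(), ci_low = numeric(), ci_high = numeric(),
                    p = numeric(), q = numeric(), degenerate = logical()),
      best_cutoff = NA_real_, best_quantile = NA_real_, best = NULL,
      significant = FALSE, evaluable = FALSE, fdr_threshold = fdr_threshold
    ), class = "cutoff_scan")
  }
  if (length(x) < 8 || sum(e) == 0) return(not_evaluable())
  cuts <- candidate_cutoffs(x, min_group = min_group)
  if (length(cuts) == 0) return(not_evaluable())
  rows <- purrr::map(cuts, function(cut) cox_binary_row(t, e, x > cut))
  scan <- bind_cols(tibble(cutoff = cuts), list_rbind(rows))
  scan$q <- p.adjust(scan$p, method = "BH")
  if (all(scan$degenerate)) {
    out <- not_evaluable()
    out$scan <- scan
    return(out)
  }
  elig <- which(!scan$degenerate)
  best_i <- elig[order(scan$p[elig], scan$cutoff[elig])][1]
  best <- scan[best_i, ]
  structure(list(
    feature_id = feature_id, n = length(x), n_events = sum(e),
    scan = scan,
    best_cutoff = best$cutoff,
    best_quantile = mean(x <= best$cutoff),
    best = best,
    significant = best$q < fdr_threshold,
    evaluable = TRUE, fdr_threshold = fdr_threshold
  ), class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat("<cutoff_scan>", if (!is.null(x$feature_id)) x$feature_id else "", "\n")
  cat(sprintf("  n = %d, events = %d, cutoffs scanned = %d\n",
              x$n, x$n_events, nrow(x$scan)))
  if (x$evaluable) {
    cat(sprintf("  best cutoff %.4g (quantile %.2f): HR = %.3g [%.3g, %.3g], p = %.3g, q = %.3g\n",
                x$best_cutoff, x$best_quantile, x$best$hr, x$best$ci_low,
                x$best$ci_high, x$best$p, x$best$q))
    cat(sprintf("  significant at FDR < %.2g: %s\n", x$fdr_threshold, x$significant))
  } else {
    cat("  not evaluable\n")
  }
  invisible(x)
}

#' Tidy a cutoff scan: one row per candidate cutoff
#'
#' @param x a `cutoff_scan` object.
#' @param ... unused.
#' @return tibble with per-cutoff fit statistics and BH q-values.
#' @export
#' @exportS3Method generics::tidy
tidy.cutoff_scan <- function(x, ...) {
  bind_cols(tibble(feature = x$feature_id %||% NA_character_), x$scan)
}

#' One-row summary of a cutoff scan
#'
#' @param x a `cutoff_scan` object.
#' @param ... unused.
#' @return one-row tibble: feature, sample/event counts, best cutoff and
#'   its quantile, HR with CI, p, q, significance and evaluability flags.
#' @export
#' @exportS3Method generics::glance
glance.cutoff_scan <- function(x, ...) {
  if (!x$evaluable) {
    return(tibble(
      feature = x$feature_id %||% NA_character_, n = x$n, n_events = x$n_events,
      n_cutoffs = nrow(x$scan), best_cutoff = NA_real_, cutoff_quantile = NA_real_,
      n_low = NA_integer_, n_high = NA_integer_, events_low = NA_real_,
      events_high = NA_real_, hr = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p = NA_real_, q = NA_real_,
      significant = FALSE, degenerate = NA, evaluable = FALSE
    ))
  }
  b <- x$best
  tibble(
    feature = x$feature_id %||% NA_character_, n = x$n, n_events = x$n_events,
    n_cutoffs = nrow(x$scan), best_cutoff = x$best_cutoff,
    cutoff_quantile = x$best_quantile,
    n_low = b$n_low, n_high = b$n_high, events_low = b$events_low,
    events_high = b$events_high, hr = b$hr, ci_low = b$ci_low,
    ci_high = b$ci_high, p = b$p, q = b$q,
    significant = x$significant, degenerate = b$degenerate, evaluable = TRUE
  )
}

endpoint_cols <- function(endpoint = c("os", "rfs")) {
  endpoint <- match.arg(endpoint)
  c(time = paste0(endpoint, "_time"), event = paste0(endpoint, "_event"))
}

#' Scan every feature of an expression (or signature) matrix
#'
#' Runs [cutoff_scan()] for each row feature of a wide matrix against a
#' survival endpoint of the clinical table, and returns the per-feature
#' summaries as one tibble. Optionally applies a second-stage BH
#' correction across features (columns `q_across`,
#' `significant_across`).
#'
#' @param expr wide feature tibble (`gene_id` or `set_name` + sample
#'   columns).
#' @param clinical clinical tibble with `sample_id` and endpoint columns.
#' @param endpoint `"os"` or `"rfs"`.
#' @param features optional subset of feature ids to scan.
#' @param fdr_threshold,min_group passed to [cutoff_scan()].
#' @param across_features_fdr also BH-adjust the best p-values across
#'   features.
#' @return tibble, one row per scanned feature (see
#'   [glance.cutoff_scan()]).
#' @export
scan_expression <- function(expr, clinical, endpoint = "os", features = NULL,
                            fdr_threshold = 0.10, min_group = 1,
                            across_features_fdr = FALSE) {
  cols <- endpoint_cols(endpoint)
  m <- wide_to_matrix(expr)
  common <- intersect(colnames(m), clinical$sample_id)
  if (length(common) < 8) abort("fewer than 8 samples shared between matrix and clinical table")
  cl <- clinical[match(common, clinical$sample_id), ]
  feats <- features %||% rownames(m)
  missing <- setdiff(feats, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("feature(s) not in matrix: %s", paste(head(missing, 5), collapse = ", ")))
  }
  res <- purrr::map(feats, function(f) {
    d <- tibble(value = m[f, common], time = cl[[cols["time"]]],
                event = cl[[cols["event"]]])
    glance(cutoff_scan(d, fdr_threshold = fdr_threshold,
                       min_group = min_group, feature_id = f))
  }) |> list_rbind()
  if (across_features_fdr) {
    res$q_across <- NA_real_
    ok <- res$evaluable
    res$q_across[ok] <- p.adjust(res$p[ok], method = "BH")
    res$significant_across <- !is.na(res$q_across) & res$q_across < fdr_threshold
  }
  res
}
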