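# Kaplan-Meier product-limit curves and median survival, for visualizing
# the survival difference between the two cutoff-defined groups.

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator per group, with the median survival defined as
#' the smallest time at which S(t) <= 0.5 (undefined — NA — when S never
#' reaches 0.5).
#'
#' @param data data frame with one row per sample.
#' @param group,time,event columns of `data` (tidy-eval): group label,
#'   follow-up time in months, event indicator 0/1.
#' @return an object of class `km_curve`: `$steps` (tibble `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`), `$median` (tibble `group`,
#'   `n`, `n_events`, `median`). Has [tidy()] and [autoplot()] methods.
#' @export
km_curve <- function(data, group = group, time = time, event = event) {
  g <- as.character(dplyr::pull(data, {{ group }}))
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  ok <- !is.na(g) & !is.na(t) & !is.na(e)
  g <- g[ok]; t <- t[ok]; e <- e[ok]
  if (length(g) == 0) abort("no usable samples")
  steps <- purrr::map(sort(unique(g)), function(lev) {
    sel <- g == lev
    sf <- survival::survfit(survival::Surv(t[sel], e[sel]) ~ 1)
    tibble(group = lev, time = sf$time, n_risk = sf$n.risk,
           n_event = sf$n.event, n_censor = sf$n.censor, surv = sf$surv)
  }) |> list_rbind()
  med <- steps |>
    group_by(.data$group) |>
    summarise(median = {
      i <- which(.data$surv <= 0.5)
      if (length(i) == 0) NA_real_ else min(.data$time[i])
    }, .groups = "drop")
  counts <- tibble(group = g, event = e) |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), n_events = sum(.data$event), .groups = "drop")
  med <- left_join(counts, med, by = "group")
  structure(list(steps = steps, median = med), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve>\n")
  print(x$median)
  invisible(x)
}

#' Tidy a Kaplan-Meier curve: one row per step time per group
#'
#' @param x a `km_curve` object.
#' @param ... unused.
#' @return the `$steps` tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.km_curve <- function(x, ...) x$steps

#' Plot Kaplan-Meier curves
#'
#' @param object a `km_curve` object.
#' @param ... unused.
#' @return a ggplot of the survival step functions, censor marks included.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  start <- object$steps |>
    distinct(.data$group) |>
    mutate(time = 0, surv = 1)
  df <- bind_rows(start,
                  select(object$steps, "group", "time", "surv")) |>
    arrange(.data$group, .data$time)
  cens <- filter(object$steps, .data$n_censor > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3, show.legend = FALSE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  color = NULL) +
    ggplot2::theme_minimal()
}
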