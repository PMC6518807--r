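#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator with Greenwood-variance log-log 95% confidence
#' intervals, optionally stratified by a grouping column. The median is
#' the smallest time at which the estimated survival drops to 0.5 or
#' below; when the curve never reaches 0.5 the median is not reached
#' (reported as `NA`).
#'
#' @param data data frame of survival records.
#' @param time,event,group column names (strings) for follow-up time in
#'   months, the event indicator (1/TRUE = death, 0/FALSE = censored) and
#'   an optional group label.
#' @return A `km_fit` wrapping the [survival::survfit] object; use
#'   [tidy()] for the stepwise curve and [glance()] for per-group
#'   medians with confidence bounds.
#' @examples
#' d <- tibble::tibble(os_months = c(1, 2, 3), event = 1)
#' glance(km_estimate(d))
#' @export
km_estimate <- function(data, time = "os_months", event = "event",
                        group = NULL) {
  check_cols(data, c(time, event), "`data`")
  if (nrow(data) == 0) abort("empty survival data")
  tt <- data[[time]]
  ev <- as.integer(data[[event]])
  if (any(is.na(tt)) || any(tt < 0)) abort("survival times must be >= 0")
  if (!all(ev %in% c(0L, 1L))) abort("event indicator must be 0/1")
  if (!is.null(group)) {
    check_cols(data, group, "`data`")
    g <- factor(data[[group]])
    fit <- survival::survfit(survival::Surv(tt, ev) ~ g,
                             conf.type = "log-log")
  } else {
    g <- NULL
    fit <- survival::survfit(survival::Surv(tt, ev) ~ 1,
                             conf.type = "log-log")
  }
  structure(list(fit = fit, group = group, n = nrow(data)),
            class = "km_fit")
}

#' @rdname km_estimate
#' @param x a `km_fit`.
#' @param ... unused.
#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  grp <- if (!is.null(s$strata)) {
    sub("^g=", "", as.character(s$strata))
  } else {
    rep("all", length(s$time))
  }
  tibble(
    group = grp,
    time = s$time,
    n_risk = s$n.risk,
    n_event = s$n.event,
    n_censor = s$n.censor,
    estimate = s$surv,
    conf_low = s$lower,
    conf_high = s$upper
  )
}

#' @rdname km_estimate
#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  curve <- tidy(x)
  curve |>
    group_by(.data$group) |>
    summarise(
      n = max(.data$n_risk),
      events = sum(.data$n_event),
      median = km_median_from_curve(.data$time, .data$estimate),
      # median CI: times where the pointwise CI for S(t) still contains 0.5
      conf_low = km_median_from_curve(.data$time, .data$conf_low),
      conf_high = km_median_from_curve(.data$time, .data$conf_high),
      .groups = "drop"
    )
}

# smallest time with S(t) <= 0.5; NA when the curve never reaches 0.5
km_median_from_curve <- function(time, surv) {
  hit <- which(!is.na(surv) & surv <= 0.5)
  if (length(hit) == 0) NA_real_ else min(time[hit])
}

#' Median overall survival
#'
#' @param x a `km_fit`.
#' @return named numeric vector of per-group medians (months; `NA` =
#'   not reached).
#' @export
km_median <- function(x) {
  g <- glance(x)
  setNames(g$median, g$group)
}

#' Log-rank (Mantel-Haenszel) test between survival groups
#'
#' Chi-square statistic on k-1 degrees of freedom comparing observed and
#' expected event counts across groups, with the standard hypergeometric
#' variance under ties; two-sided p-value.
#'
#' @inheritParams km_estimate
#' @param group grouping column name (required; >= 2 non-empty groups).
#' @return one-row tibble: `statistic`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(data, time = "os_months", event = "event",
                         group = "group") {
  check_cols(data, c(time, event, group), "`data`")
  g <- factor(data[[group]])
  g <- droplevels(g)
  if (nlevels(g) < 2) abort("log-rank test needs >= 2 non-empty groups")
  tt <- data[[time]]
  ev <- as.integer(data[[event]])
  sd_fit <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  df <- nlevels(g) - 1
  tibble(
    statistic = sd_fit$chisq,
    df = df,
    p_value = pchisq(sd_fit$chisq, df, lower.tail = FALSE),
    n_groups = nlevels(g)
  )
}

#' Kaplan-Meier survival curve plot
#'
#' @param object a `km_fit`.
#' @param ... unused.
#' @return a ggplot object (stepwise survival with censoring marks).
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  curve <- tidy(object)
  start <- curve |>
    group_by(.data$group) |>
    summarise(n_risk = max(.data$n_risk), .groups = "drop") |>
    mutate(time = 0, n_event = 0L, n_censor = 0L, estimate = 1,
           conf_low = 1, conf_high = 1)
  curve <- bind_rows(start, curve) |> arrange(.data$group, .data$time)
  ggplot2::ggplot(curve, ggplot2::aes(.data$time, .data$estimate,
                                      color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = filter(curve, .data$n_censor > 0),
      shape = 3, show.legend = FALSE
    ) +
    ggplot2::labs(x = "Months", y = "Overall survival", color = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
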