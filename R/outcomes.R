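# Exploratory outcome stratification: quantile split of immune-response
# scores, Kaplan-Meier estimation and the two-group log-rank test.
# The product-limit and log-rank machinery is provided by the survival
# package; this module fixes the conventions (median definition, quantile
# type, tie handling) and the reporting surface.

#' Stratify subjects by a score quantile
#'
#' Splits subjects at the `q`-th percentile of their scores (linear
#' interpolation, the default type-7 sample quantile). Scores less than or
#' equal to the threshold go to `"low"`; ties at the threshold therefore
#' fall low.
#'
#' @param scores Named numeric vector, subject -> score.
#' @param q Quantile in (0, 1); default 0.25 (lowest-quartile split).
#' @return Named character vector of `"low"` / `"high"` labels.
#' @export
stratify_by_quantile <- function(scores, q = 0.25) {
  stopifnot(length(scores) >= 2, q > 0, q < 1)
  if (length(unique(scores)) == 1) {
    warning("degenerate stratification: all scores identical; all subjects 'high'")
    return(setNames(rep("high", length(scores)), names(scores)))
  }
  thr <- as.numeric(quantile(scores, probs = q, type = 7))
  setNames(ifelse(scores <= thr, "low", "high"), names(scores))
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function; the median is the
#' earliest event time at which the estimate drops to 0.5 or below,
#' reported as `NA` ("not reached") when it never does.
#'
#' @param time Positive event/censoring times (months).
#' @param event Logical or 0/1: event observed.
#' @return Object of class `km_fit`: data.frame `curve` (`time`, `n_risk`,
#'   `n_event`, `surv`), `median`, `n`, `n_events`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  drops <- curve$time[curve$n_event > 0 & curve$surv <= 0.5 + 1e-12]
  med <- if (length(drops)) min(drops) else NA_real_
  structure(list(curve = curve, median = med, n = length(time),
                 n_events = sum(as.integer(event))),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: n = %d, events = %d, median = %s\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
plot.km_fit <- function(x, xlab = "Time (months)", ylab = "Survival probability",
                        ...) {
  tt <- c(0, x$curve$time)
  ss <- c(1, x$curve$surv)
  graphics::plot(tt, ss, type = "s", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param time,event Survival times and event indicators.
#' @param group Two-level grouping vector.
#' @return List: `statistic` (chi-square, 1 df), `df`, `p_value`, `n` per
#'   group.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("log-rank test requires exactly two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  stat <- as.numeric(sd$chisq)
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       n = as.integer(table(group)))
}

#' Quantile stratification with KM and log-rank in one call
#'
#' @param scores Named vector subject -> immune-response score.
#' @param time,event Named (by subject) or aligned survival data.
#' @param q Split quantile (default 0.25).
#' @return List: `groups`, per-group `km` fits and medians, `logrank`.
#' @export
stratified_survival <- function(scores, time, event, q = 0.25) {
  groups <- stratify_by_quantile(scores, q)
  if (!is.null(names(time))) {
    time <- time[names(groups)]
    event <- event[names(groups)]
  }
  km <- lapply(split(seq_along(groups), groups), function(i)
    km_estimate(time[i], event[i]))
  lr <- if (length(unique(groups)) == 2) logrank_test(time, event, groups) else NULL
  list(groups = groups,
       km = km,
       medians = vapply(km, function(f) f$median, numeric(1)),
       logrank = lr)
}
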