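# ELISPOT immunogenicity cascade and the pre-specified responder rule.
#
# Input is a long-format table of spot-forming units (SFU per million
# cells): subject_id, week, stimulation, replicate, sfu. Replicates are
# averaged; the antigen response at each timepoint is normalized to the
# irrelevant control peptide, folded over baseline, and the maximum fold
# change within the evaluation window is the subject's T-cell response.
# A pre-to-post change greater than 2.77 cross-patient baseline SDs is a
# significant change at two-sided alpha = 0.05 (2.77 = z(0.975) * sqrt(2),
# the critical value for a difference of two equally variable
# measurements).

ELISPOT_STIMS <- c("unstimulated", "control_peptide", MKRAS_ANTIGENS)

#' Responder threshold multiplier
#'
#' The critical multiplier for a pre/post difference of two equally
#' variable measurements at two-sided level `alpha`:
#' `qnorm(1 - alpha/2) * sqrt(2)`; 2.77 (2 dp) at `alpha = 0.05`.
#'
#' @param alpha Two-sided significance level (default 0.05).
#' @param digits Rounding (default 2, the conventional printed value).
#' @return Numeric scalar.
#' @export
responder_threshold_k <- function(alpha = 0.05, digits = 2) {
  round(qnorm(1 - alpha / 2) * sqrt(2), digits)
}

#' Fold change of antigen SFU over control-peptide SFU
#'
#' `(sfu_antigen + pseudocount) / (sfu_control + pseudocount)`. The
#' pseudocount (default 1 SFU) keeps the ratio defined when the control
#' well is empty.
#'
#' @param sfu_antigen,sfu_control Replicate-mean SFU values (vectors,
#'   recycled).
#' @param pseudocount Added to numerator and denominator (default 1).
#' @return Numeric vector of fold changes.
#' @export
fold_vs_control <- function(sfu_antigen, sfu_control, pseudocount = 1) {
  stopifnot(all(sfu_antigen >= 0), all(sfu_control >= 0), pseudocount >= 0)
  if (pseudocount == 0 && any(sfu_control == 0 & sfu_antigen == 0))
    stop("fold change undefined: antigen and control SFU both zero with pseudocount 0")
  (sfu_antigen + pseudocount) / (sfu_control + pseudocount)
}

mean_sfu_table <- function(sfu) {
  need <- c("subject_id", "week", "stimulation", "sfu")
  stopifnot(all(need %in% names(sfu)))
  aggregate(sfu ~ subject_id + week + stimulation, data = sfu, FUN = mean)
}

#' Per-antigen normalized responses over time
#'
#' Averages replicates, computes the fold change of each mutant-KRAS
#' antigen over the control peptide at each timepoint, and normalizes to
#' the baseline (week 0) fold change, so `fold_vs_baseline` is exactly 1
#' at week 0.
#'
#' @param sfu Long-format data.frame: `subject_id`, `week`, `stimulation`,
#'   `replicate`, `sfu`.
#' @param pseudocount See [fold_vs_control()].
#' @return Data.frame `subject_id`, `antigen`, `week`, `sfu_antigen`
#'   (replicate mean), `fold_vs_control`, `fold_vs_baseline`.
#' @export
antigen_responses <- function(sfu, pseudocount = 1) {
  m <- mean_sfu_table(sfu)
  ctrl <- m[m$stimulation == "control_peptide", c("subject_id", "week", "sfu")]
  names(ctrl)[3] <- "sfu_control"
  ag <- m[m$stimulation %in% MKRAS_ANTIGENS, , drop = FALSE]
  names(ag)[names(ag) == "stimulation"] <- "antigen"
  names(ag)[names(ag) == "sfu"] <- "sfu_antigen"
  x <- merge(ag, ctrl, by = c("subject_id", "week"))
  x$fold_vs_control <- fold_vs_control(x$sfu_antigen, x$sfu_control, pseudocount)
  base <- x[x$week == 0, c("subject_id", "antigen", "fold_vs_control")]
  names(base)[3] <- "fold_base"
  x <- merge(x, base, by = c("subject_id", "antigen"))
  x$fold_vs_baseline <- x$fold_vs_control / x$fold_base
  x <- x[order(x$subject_id, x$antigen, x$week, method = "radix"),
         c("subject_id", "antigen", "week", "sfu_antigen", "fold_vs_control",
           "fold_vs_baseline")]
  rownames(x) <- NULL
  x
}

#' Maximum fold change within an evaluation window
#'
#' The T-cell response endpoint: the maximum of `fold_vs_baseline` over
#' post-vaccine timepoints with `0 < week <= window_weeks` (inclusive
#' boundary). `window_weeks = Inf` gives the any-time secondary-endpoint
#' variant.
#'
#' @param week,fold Numeric vectors: timepoints (week 0 = baseline) and
#'   the corresponding fold-vs-baseline values.
#' @param window_weeks Window end in weeks (default 17).
#' @return Numeric scalar.
#' @export
max_fold_change <- function(week, fold, window_weeks = 17) {
  stopifnot(length(week) == length(fold))
  if (!any(week == 0)) stop("baseline (week 0) measurement missing")
  in_window <- week > 0 & week <= window_weeks
  if (!any(in_window))
    stop("no post-vaccine timepoint within ", window_weeks,
         " weeks; available weeks: ", paste(sort(unique(week)), collapse = ", "))
  max(fold[in_window])
}

#' Pooled average response across antigens
#'
#' Arithmetic mean of per-antigen maximal fold changes. Missing antigens
#' (e.g. vaccine-lot exclusions) are omitted with a warning, never
#' imputed.
#'
#' @param folds Named or unnamed numeric vector of per-antigen values;
#'   `NA` marks an excluded antigen.
#' @return Numeric scalar.
#' @export
pooled_average <- function(folds) {
  if (length(folds) == 0 || all(is.na(folds)))
    stop("pooled average undefined: no antigen values")
  if (anyNA(folds)) {
    excl <- if (!is.null(names(folds))) paste(names(folds)[is.na(folds)],
                                              collapse = ", ")
            else paste(sum(is.na(folds)), "antigen(s)")
    warning("excluded from pooled average: ", excl)
  }
  mean(folds, na.rm = TRUE)
}

#' Responder call from a pre-to-post change
#'
#' A subject is a responder when the pre-to-post change exceeds `k` times
#' the cross-patient standard deviation of the baseline values (strict
#' `>`). `significant_change` additionally reports the two-sided event
#' `|delta| > k * sd`, the exceedance the multiplier `k = z(0.975)*sqrt(2)`
#' is calibrated for.
#'
#' @param delta Pre-to-post change (vectorized over subjects).
#' @param baseline_sd Standard deviation of baseline values across
#'   patients (scalar > 0, computed on the same scale as `delta`'s
#'   endpoints).
#' @param k Threshold multiplier (default 2.77).
#' @param subject_id Optional subject labels.
#' @param mode Label recorded in the output (`"pooled_average"` or
#'   `"tumor_matched"`).
#' @return Data.frame `subject_id`, `mode`, `delta`, `threshold`,
#'   `responder`, `significant_change`.
#' @export
responder_call <- function(delta, baseline_sd, k = 2.77,
                           subject_id = NULL,
                           mode = c("pooled_average", "tumor_matched")) {
  mode <- match.arg(mode)
  if (!is.finite(baseline_sd) || baseline_sd <= 0)
    stop("degenerate threshold: baseline SD must be > 0 (computed across >= 2 subjects)")
  thr <- k * baseline_sd
  data.frame(subject_id = if (is.null(subject_id)) seq_along(delta) else subject_id,
             mode = mode, delta = delta, threshold = thr,
             responder = delta > thr,
             significant_change = abs(delta) > thr,
             stringsAsFactors = FALSE)
}

# per-subject response value series on the chosen scale
subject_value_series <- function(sfu, antigens, scale, pseudocount) {
  if (scale == "sfu") {
    m <- mean_sfu_table(sfu)
    m <- m[m$stimulation %in% antigens, , drop = FALSE]
    v <- aggregate(sfu ~ subject_id + week, data = m, FUN = mean)
    names(v)[3] <- "value"
  } else {
    r <- antigen_responses(sfu, pseudocount)
    r <- r[r$antigen %in% antigens, , drop = FALSE]
    v <- aggregate(fold_vs_control ~ subject_id + week, data = r, FUN = mean)
    names(v)[3] <- "value"
  }
  v
}

#' Cohort responder calls from an SFU table
#'
#' Computes, per subject, the pooled response value (mean over antigens of
#' replicate-mean SFU, or of control-normalized folds when `scale =
#' "fold"`), takes the post-vaccine timepoint with the maximal value
#' within the window, forms `delta` = post − baseline, and applies the
#' `k`-SD rule with the baseline SD computed across patients on the same
#' scale. `mode = "tumor_matched"` restricts to each subject's tumor
#' mutation antigen.
#'
#' @param sfu Long-format SFU table (see [antigen_responses()]).
#' @param mode `"pooled_average"` (default) or `"tumor_matched"`.
#' @param tumor_mutation Named character vector subject -> antigen
#'   (required for tumor-matched mode).
#' @param k Threshold multiplier (default 2.77).
#' @param window_weeks Evaluation window (default 17).
#' @param scale `"sfu"` (default; raw SFU differences per the pre-specified
#'   rule) or `"fold"` (control-normalized).
#' @param pseudocount See [fold_vs_control()].
#' @return Data.frame from [responder_call()] plus `baseline_value`,
#'   `peak_week`, `max_fold`. Subjects lacking a baseline are excluded and
#'   listed in attribute `"excluded"`.
#' @export
elispot_responders <- function(sfu, mode = c("pooled_average", "tumor_matched"),
                               tumor_mutation = NULL, k = 2.77,
                               window_weeks = 17,
                               scale = c("sfu", "fold"), pseudocount = 1) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  subjects <- sort(unique(sfu$subject_id), method = "radix")
  excluded <- character(0)
  rows <- list()
  for (s in subjects) {
    x <- sfu[sfu$subject_id == s, , drop = FALSE]
    if (!any(x$week == 0)) {
      excluded <- c(excluded, s)
      next
    }
    antigens <- if (mode == "tumor_matched") {
      if (is.null(tumor_mutation) || is.na(tumor_mutation[s]))
        stop("tumor-matched mode requires tumor_mutation for subject ", s)
      tumor_mutation[[s]]
    } else MKRAS_ANTIGENS
    v <- subject_value_series(x, antigens, scale, pseudocount)
    base <- v$value[v$week == 0]
    post <- v[v$week > 0 & v$week <= window_weeks, , drop = FALSE]
    if (nrow(post) == 0) {
      excluded <- c(excluded, s)
      next
    }
    peak <- post[which.max(post$value), ]
    rows[[s]] <- data.frame(subject_id = s, baseline_value = base,
                            peak_week = peak$week,
                            delta = peak$value - base,
                            max_fold = if (base > 0) peak$value / base else NA_real_,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no evaluable subjects (baseline + in-window post required)")
  tab <- do.call(rbind, rows)
  baseline_sd <- sd(tab$baseline_value)
  calls <- responder_call(tab$delta, baseline_sd, k = k,
                          subject_id = tab$subject_id, mode = mode)
  out <- cbind(calls, tab[, c("baseline_value", "peak_week", "max_fold")])
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "baseline_sd") <- baseline_sd
  out
}

#' Number of antigens with a significant response per subject
#'
#' Applies the `k`-SD rule antigen by antigen (each antigen's baseline SD
#' computed across patients) and counts, per subject, the antigens whose
#' pre-to-post change exceeds its threshold.
#'
#' @inheritParams elispot_responders
#' @return Data.frame `subject_id`, `n_positive_antigens` (0-6).
#' @export
antigen_positivity_count <- function(sfu, k = 2.77, window_weeks = 17,
                                     scale = c("sfu", "fold"),
                                     pseudocount = 1) {
  scale <- match.arg(scale)
  subjects <- sort(unique(sfu$subject_id), method = "radix")
  deltas <- base_vals <- matrix(NA_real_, length(subjects), length(MKRAS_ANTIGENS),
                                dimnames = list(subjects, MKRAS_ANTIGENS))
  for (s in subjects) {
    x <- sfu[sfu$subject_id == s, , drop = FALSE]
    if (!any(x$week == 0)) next
    for (a in MKRAS_ANTIGENS) {
      if (!a %in% x$stimulation) next
      v <- subject_value_series(x, a, scale, pseudocount)
      base <- v$value[v$week == 0]
      post <- v$value[v$week > 0 & v$week <= window_weeks]
      if (length(base) != 1 || length(post) == 0) next
      base_vals[s, a] <- base
      deltas[s, a] <- max(post) - base
    }
  }
  sds <- apply(base_vals, 2, sd, na.rm = TRUE)
  pos <- sweep(deltas, 2, k * sds, FUN = ">")
  data.frame(subject_id = subjects,
             n_positive_antigens = as.integer(rowSums(pos, na.rm = TRUE)),
             stringsAsFactors = FALSE)
}

#' Clamp out-of-range multiplex (Luminex) readings
#'
#' Replaces the sentinel strings `"OOR<"` / `"OOR>"` with the lower /
#' upper limit of the assay's standard curve; in-range values are returned
#' unchanged.
#'
#' @param x Character or numeric vector of measured concentrations,
#'   possibly containing OOR sentinels.
#' @param lower,upper Standard-curve limits (`lower < upper`).
#' @return Numeric vector.
#' @export
clamp_oor <- function(x, lower, upper) {
  stopifnot(lower < upper)
  if (is.numeric(x)) return(pmin(pmax(x, lower), upper))
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  out[x == "OOR<"] <- lower
  out[x == "OOR>"] <- upper
  if (anyNA(out))
    stop("unparseable concentration value: '", x[which(is.na(out))[1]], "'")
  pmin(pmax(out, lower), upper)
}
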