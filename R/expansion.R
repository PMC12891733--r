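# Antigen-stimulated clonotype expansion calling.
#
# For each clonotype observed in a peptide expansion culture, its read
# count is compared against a reference culture (vehicle-only or
# irrelevant control peptide) with a one-sided Fisher exact test
# (enrichment direction), Benjamini-Yekutieli FDR control across all
# clonotypes tested in that culture, a read-count ratio ("odds ratio" in
# the trial's usage: count_cond / count_ref, not a contingency-table OR)
# and a frequency cutoff. Clonotypes already present in the unstimulated
# pre-vaccine baseline are then filtered out of the antigen-specific set.

#' Repertoire clonality (one minus Shannon evenness)
#'
#' Computes `1 - H / ln(n)` where `H = -sum(p_i ln p_i)` is the
#' natural-log Shannon entropy of clonotype frequencies and `n` the number
#' of unique clonotypes. The value is 0 for a perfectly even repertoire
#' and approaches 1 at maximal clonality.
#'
#' Note on naming: this is the trial literature's "Shannon equitability";
#' conventionally that term denotes evenness `H / ln(n)` itself — the
#' statistic implemented here is its complement, a clonality index.
#'
#' @param x A `tcr_repertoire` or a vector of positive clonotype counts.
#' @return Numeric scalar in `[0, 1]`.
#' @export
shannon_equitability <- function(x) {
  counts <- if (inherits(x, "tcr_repertoire")) x$clonotypes$count else x
  counts <- as.numeric(counts)
  stopifnot(all(counts > 0))
  n <- length(counts)
  if (n < 2)
    stop("equitability undefined for fewer than 2 clonotypes (ln(1) = 0)")
  # perfectly even counts give H = ln(n) exactly; return 0 directly so the
  # endpoint is not blurred by floating-point summation
  if (all(counts == counts[1])) return(0)
  p <- counts / sum(counts)
  h <- -sum(p * log(p))
  1 - h / log(n)
}

#' Read-count ratio between expansion and reference condition
#'
#' The trial's "odds ratio": the absolute read count of a clonotype in the
#' expansion condition divided by its count in the reference condition.
#' `+Inf` when the clonotype is absent from the reference.
#'
#' @param count_cond,count_ref Non-negative integer vectors (recycled).
#' @return Numeric vector (possibly `Inf`).
#' @export
odds_ratio <- function(count_cond, count_ref) {
  if (any(count_cond == 0 & count_ref == 0))
    stop("odds ratio undefined: clonotype absent from both samples")
  ifelse(count_ref == 0, Inf, count_cond / count_ref)
}

#' One-sided Fisher exact test for clonotype enrichment
#'
#' Exact hypergeometric upper-tail probability for the 2x2 table
#' `[[count_cond, depth_cond - count_cond], [count_ref, depth_ref -
#' count_ref]]`, in the enrichment direction (frequency higher in the
#' expansion condition). Vectorized over all four arguments.
#'
#' @param count_cond,depth_cond Clonotype count and total reads in the
#'   expansion condition.
#' @param count_ref,depth_ref Clonotype count and total reads in the
#'   reference condition.
#' @return Numeric vector of one-sided p-values.
#' @export
fisher_one_sided <- function(count_cond, depth_cond, count_ref, depth_ref) {
  n <- max(length(count_cond), length(depth_cond),
           length(count_ref), length(depth_ref))
  count_cond <- rep_len(count_cond, n); depth_cond <- rep_len(depth_cond, n)
  count_ref <- rep_len(count_ref, n);   depth_ref <- rep_len(depth_ref, n)
  if (any(count_cond < 0 | count_ref < 0 | count_cond > depth_cond |
          count_ref > depth_ref))
    stop("invalid 2x2 table: counts must lie within their depths")
  # P(X >= count_cond), X ~ Hypergeom(depth_cond, depth_ref, count_cond + count_ref)
  phyper(count_cond - 1, depth_cond, depth_ref, count_cond + count_ref,
         lower.tail = FALSE)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjusted q-values `q_(i) = min_{j >= i} min(1, m c(m) p_(j) / j)`
#' with `c(m) = sum_{k=1}^m 1/k`, valid under arbitrary dependence,
#' restored to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @export
by_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BY")
}

#' Expansion-calling configuration
#'
#' @param or_min Minimum read-count ratio (inclusive); default 5.
#' @param freq_min Minimum clonotype frequency in the expansion culture
#'   (inclusive); default 0.001 (0.1%).
#' @param q_max Maximum BY-adjusted q-value (inclusive); default 0.05.
#' @param apply_freq_cutoff Apply the frequency cutoff (default `TRUE`);
#'   set `FALSE` for the mapping mode that keeps all OR-passing TCRs.
#' @param reference_condition Reference culture: `"vehicle_only"` (default)
#'   or `"control_peptide"`.
#' @return A list of class `expansion_config`.
#' @export
expansion_config <- function(or_min = 5, freq_min = 0.001, q_max = 0.05,
                             apply_freq_cutoff = TRUE,
                             reference_condition = c("vehicle_only",
                                                     "control_peptide")) {
  reference_condition <- match.arg(reference_condition)
  stopifnot(or_min > 0, q_max > 0, q_max <= 1, freq_min >= 0, freq_min < 1)
  structure(list(or_min = or_min, freq_min = freq_min, q_max = q_max,
                 apply_freq_cutoff = isTRUE(apply_freq_cutoff),
                 reference_condition = reference_condition),
            class = "expansion_config")
}

#' Per-clonotype expansion statistics for one culture
#'
#' Tests every clonotype observed in the expansion-condition repertoire
#' (clonotypes seen only in the reference cannot be "expanded") against
#' the reference repertoire: counts, depths, read-count ratio, frequency,
#' one-sided Fisher p and BY q adjusted across this culture's whole
#' family of tests.
#'
#' @param cond_rep Expansion-condition `tcr_repertoire`.
#' @param ref_rep Reference `tcr_repertoire` (same subject).
#' @return Data.frame with one row per condition clonotype: `subject_id`,
#'   `condition`, `v_gene`, `cdr3_aa`, `count_cond`, `depth_cond`,
#'   `count_ref`, `depth_ref`, `odds_ratio`, `freq_cond`, `p_one_sided`,
#'   `q_by`.
#' @export
expansion_tests <- function(cond_rep, ref_rep) {
  stopifnot(inherits(cond_rep, "tcr_repertoire"),
            inherits(ref_rep, "tcr_repertoire"))
  if (!is.na(cond_rep$subject_id) && !is.na(ref_rep$subject_id) &&
      cond_rep$subject_id != ref_rep$subject_id)
    stop("condition and reference repertoires belong to different subjects")
  cl <- cond_rep$clonotypes
  key <- clonotype_key(cl$v_gene, cl$cdr3_aa)
  ref_key <- clonotype_key(ref_rep$clonotypes$v_gene,
                           ref_rep$clonotypes$cdr3_aa)
  idx <- match(key, ref_key)
  count_ref <- ifelse(is.na(idx), 0L, ref_rep$clonotypes$count[idx])
  out <- data.frame(subject_id = cond_rep$subject_id,
                    condition = cond_rep$condition,
                    v_gene = cl$v_gene, cdr3_aa = cl$cdr3_aa,
                    count_cond = cl$count,
                    depth_cond = cond_rep$total_reads,
                    count_ref = as.integer(count_ref),
                    depth_ref = ref_rep$total_reads,
                    stringsAsFactors = FALSE)
  out$odds_ratio <- odds_ratio(out$count_cond, out$count_ref)
  out$freq_cond <- out$count_cond / out$depth_cond
  out$p_one_sided <- fisher_one_sided(out$count_cond, out$depth_cond,
                                      out$count_ref, out$depth_ref)
  out$q_by <- by_adjust(out$p_one_sided)
  out
}

#' Apply expansion thresholds
#'
#' A clonotype is called expanded when `q_by <= q_max` AND
#' `odds_ratio >= or_min` AND (`freq_cond >= freq_min` when the frequency
#' cutoff is applied). All thresholds are inclusive.
#'
#' @param tests Data.frame from [expansion_tests()].
#' @param config An [expansion_config()].
#' @return `tests` with a logical `expanded` column appended.
#' @export
call_expanded <- function(tests, config = expansion_config()) {
  stopifnot(inherits(config, "expansion_config"))
  ok <- tests$q_by <= config$q_max & tests$odds_ratio >= config$or_min
  if (config$apply_freq_cutoff) ok <- ok & tests$freq_cond >= config$freq_min
  tests$expanded <- ok
  tests
}

#' Filter expanded clonotypes present at the unstimulated baseline
#'
#' TCRs already detectable in the pre-vaccine unstimulated sample are
#' unlikely to be vaccine-induced antigen-specific cells, so any call
#' whose clonotype appears in the subject's baseline repertoire (count >=
#' 1) is flagged and removed from the antigen-specific set.
#'
#' @param calls Data.frame of expansion calls (rows with `expanded ==
#'   TRUE` are the candidates; other rows pass through with
#'   `filtered_by_baseline = FALSE`).
#' @param baseline_rep Baseline `tcr_repertoire` of the same subject.
#' @return `calls` with a logical `filtered_by_baseline` column; the
#'   number of removed calls is attached as attribute `"n_filtered"`.
#' @export
filter_baseline <- function(calls, baseline_rep) {
  stopifnot(inherits(baseline_rep, "tcr_repertoire"))
  subj <- unique(calls$subject_id)
  if (length(subj) > 1)
    stop("calls span multiple subjects; filter one subject at a time")
  if (length(subj) == 1 && !is.na(subj) && !is.na(baseline_rep$subject_id) &&
      subj != baseline_rep$subject_id)
    stop("baseline repertoire subject (", baseline_rep$subject_id,
         ") does not match calls (", subj, ")")
  base_key <- clonotype_key(baseline_rep$clonotypes$v_gene,
                            baseline_rep$clonotypes$cdr3_aa)
  key <- clonotype_key(calls$v_gene, calls$cdr3_aa)
  calls$filtered_by_baseline <- key %in% base_key
  attr(calls, "n_filtered") <- sum(calls$filtered_by_baseline &
                                     isTRUE_vec(calls$expanded))
  calls
}

isTRUE_vec <- function(x) if (is.null(x)) TRUE else x

#' Collapse calls to per-clonotype antigen sets and cross-reactivity
#'
#' Groups expanded, baseline-retained calls by subject and clonotype,
#' unions the antigen (condition) labels, and flags clonotypes meeting
#' expansion criteria for two or more mutant-KRAS peptides as
#' cross-reactive.
#'
#' @param calls Data.frame of calls (after [call_expanded()] and,
#'   typically, [filter_baseline()]). Only rows with `expanded == TRUE`
#'   and `filtered_by_baseline != TRUE` contribute.
#' @return Data.frame with one row per (subject, clonotype): `subject_id`,
#'   `v_gene`, `cdr3_aa`, `antigens` (comma-joined sorted labels),
#'   `n_antigens`, `cross_reactive`.
#' @export
classify_cross_reactive <- function(calls) {
  keep <- calls$expanded
  if (!is.null(calls$filtered_by_baseline)) keep <- keep & !calls$filtered_by_baseline
  x <- calls[keep, , drop = FALSE]
  if (nrow(x) == 0)
    return(data.frame(subject_id = character(), v_gene = character(),
                      cdr3_aa = character(), antigens = character(),
                      n_antigens = integer(), cross_reactive = logical(),
                      stringsAsFactors = FALSE))
  grp <- paste(x$subject_id, clonotype_key(x$v_gene, x$cdr3_aa), sep = "\r")
  ag <- tapply(x$condition, grp, function(a) paste(sort(unique(a)), collapse = ","))
  first <- !duplicated(grp)
  out <- data.frame(subject_id = x$subject_id[first],
                    v_gene = x$v_gene[first], cdr3_aa = x$cdr3_aa[first],
                    stringsAsFactors = FALSE)
  out$antigens <- as.character(ag[grp[first]])
  out$n_antigens <- lengths(strsplit(out$antigens, ","))
  out$cross_reactive <- out$n_antigens >= 2
  ord <- order(out$subject_id, out$cdr3_aa, out$v_gene, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Antigen-set distribution for cross-reactivity summaries
#'
#' Tabulates how many clonotypes expanded to each single antigen and to
#' each multi-antigen combination (the upset-plot summary).
#'
#' @param specific Data.frame from [classify_cross_reactive()].
#' @return Data.frame `antigens`, `n_clonotypes`, sorted by decreasing
#'   count then label.
#' @export
antigen_set_distribution <- function(specific) {
  tb <- table(specific$antigens)
  out <- data.frame(antigens = names(tb), n_clonotypes = as.integer(tb),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_clonotypes, out$antigens, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Public clonotypes across subjects
#'
#' A clonotype (exact TRBV + CDR3aa identity) expanded in two or more
#' subjects is public. Same-CDR3/different-TRBV pairs are not public by
#' the identity rule; see [hs_public_pairs()] for the near-identical
#' high-similarity variant.
#'
#' @param specific Per-subject specific catalogue
#'   ([classify_cross_reactive()] output) covering two or more subjects.
#' @return Data.frame with one row per public clonotype: `v_gene`,
#'   `cdr3_aa`, `n_subjects`, `subjects` (comma-joined), `shared_antigens`
#'   (intersection across subjects, comma-joined, may be empty),
#'   `antigens_intersect` (logical).
#' @export
find_public <- function(specific) {
  if (length(unique(specific$subject_id)) < 2)
    stop("public-clonotype detection requires calls from >= 2 subjects")
  key <- clonotype_key(specific$v_gene, specific$cdr3_aa)
  counts <- table(key)
  pub_keys <- names(counts)[counts >= 2]
  rows <- lapply(pub_keys, function(k) {
    x <- specific[key == k, , drop = FALSE]
    sets <- strsplit(x$antigens, ",")
    shared <- Reduce(intersect, sets)
    data.frame(v_gene = x$v_gene[1], cdr3_aa = x$cdr3_aa[1],
               n_subjects = nrow(x),
               subjects = paste(sort(x$subject_id), collapse = ","),
               shared_antigens = paste(sort(shared), collapse = ","),
               antigens_intersect = length(shared) > 0,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(v_gene = character(), cdr3_aa = character(),
                         n_subjects = integer(), subjects = character(),
                         shared_antigens = character(),
                         antigens_intersect = logical(),
                         stringsAsFactors = FALSE)
  out <- out[order(out$cdr3_aa, out$v_gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of the antigen-specific set with a tumor repertoire
#'
#' @param specific Data.frame of specific clonotypes (needs `v_gene`,
#'   `cdr3_aa`; an `antigens` column enables the per-antigen breakdown).
#' @param tumor_rep `tcr_repertoire` with condition `"tumor_tissue"`.
#' @return List: `n_overlap`, `fraction` (of the specific set found in the
#'   tumor), `overlap` (the overlapping rows), `per_antigen` (data.frame
#'   `antigen`, `n_overlap` or `NULL` when antigens are unavailable).
#' @export
tumor_overlap <- function(specific, tumor_rep) {
  stopifnot(inherits(tumor_rep, "tcr_repertoire"))
  if (!is.na(tumor_rep$condition) && tumor_rep$condition != "tumor_tissue")
    stop("tumor repertoire must have condition 'tumor_tissue'")
  if (nrow(specific) == 0)
    stop("tumor overlap undefined for an empty specific set")
  tum_key <- clonotype_key(tumor_rep$clonotypes$v_gene,
                           tumor_rep$clonotypes$cdr3_aa)
  key <- clonotype_key(specific$v_gene, specific$cdr3_aa)
  hit <- key %in% tum_key
  per_antigen <- NULL
  if (!is.null(specific$antigens) && any(hit)) {
    ags <- unlist(strsplit(specific$antigens[hit], ","))
    tb <- table(ags)
    per_antigen <- data.frame(antigen = names(tb), n_overlap = as.integer(tb),
                              stringsAsFactors = FALSE)
  }
  list(n_overlap = sum(hit), fraction = sum(hit) / nrow(specific),
       overlap = specific[hit, , drop = FALSE], per_antigen = per_antigen)
}

#' Full expansion analysis for one subject
#'
#' Runs [expansion_tests()] + [call_expanded()] for every mutant-KRAS
#' peptide condition against the configured reference, applies the
#' baseline filter, and classifies cross-reactivity.
#'
#' @param reps Named list of `tcr_repertoire` objects for one subject;
#'   names are condition labels. Must include the reference condition;
#'   `baseline` enables the baseline filter.
#' @param config An [expansion_config()].
#' @param antigens Conditions to test (default the six mutant-KRAS
#'   peptides present in `reps`).
#' @return List: `tests` (row-bound per-condition test tables with
#'   `expanded` and `filtered_by_baseline`), `specific` (per-clonotype
#'   catalogue from [classify_cross_reactive()]), `equitability`
#'   (data.frame condition/equitability), `n_baseline_filtered`.
#' @export
subject_expansion <- function(reps, config = expansion_config(),
                              antigens = intersect(MKRAS_ANTIGENS, names(reps))) {
  ref_name <- config$reference_condition
  if (!ref_name %in% names(reps))
    stop("reference condition '", ref_name, "' missing for subject")
  ref <- reps[[ref_name]]
  tests <- do.call(rbind, lapply(antigens, function(a)
    call_expanded(expansion_tests(reps[[a]], ref), config)))
  n_filt <- 0L
  if ("baseline" %in% names(reps)) {
    tests <- filter_baseline(tests, reps[["baseline"]])
    n_filt <- sum(tests$filtered_by_baseline & tests$expanded)
  } else {
    tests$filtered_by_baseline <- FALSE
  }
  eq <- vapply(names(reps), function(cn) {
    if (nrow(reps[[cn]]$clonotypes) >= 2) shannon_equitability(reps[[cn]]) else NA_real_
  }, numeric(1))
  list(tests = tests,
       specific = classify_cross_reactive(tests),
       equitability = data.frame(condition = names(reps), equitability = eq,
                                 row.names = NULL, stringsAsFactors = FALSE),
       n_baseline_filtered = n_filt)
}
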