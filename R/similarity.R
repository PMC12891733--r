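# High-similarity (HS-TCR) CDR3 matching.
#
# Matching against external tumor CDR3 lists is done on the CDR3 alone
# (external calls often lack reliable V annotation); near-identical public
# pairs additionally require identical TRBV. Two deliberately different
# rules.

#' Edit distance between CDR3 amino-acid sequences
#'
#' Default metric is optimal string alignment (OSA): Levenshtein distance
#' extended with adjacent transpositions, each counted once. Plain
#' Levenshtein is available via `method = "levenshtein"`. Inputs are
#' normalized to uppercase; vectorized over pairs (recycled).
#'
#' @param a,b Character vectors of non-empty amino-acid sequences.
#' @param method `"osa"` (default) or `"levenshtein"`.
#' @return Integer vector of distances.
#' @export
cdr3_distance <- function(a, b, method = c("osa", "levenshtein")) {
  method <- match.arg(method)
  n <- max(length(a), length(b))
  a <- toupper(rep_len(as.character(a), n))
  b <- toupper(rep_len(as.character(b), n))
  if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b))
    stop("CDR3 sequences must be non-empty")
  pair_distance_cpp(a, b, if (method == "osa") 1L else 2L)
}

#' Find high-similarity CDR3 matches against external samples
#'
#' Reports every (query clonotype, target CDR3) pair within `max_dist`
#' amino-acid differences. A length-difference pre-filter (`||a|-|b|| >
#' max_dist` implies distance `> max_dist`) is used for speed and cannot
#' change the result.
#'
#' @param queries Character vector of query CDR3 sequences, or a
#'   data.frame with a `cdr3_aa` column (e.g. a specific-TCR catalogue).
#' @param targets Data.frame with columns `sample_id`, `cdr3_aa` (see
#'   [read_cdr3_targets()]), or a named list of character vectors.
#' @param max_dist Maximum distance (default 2).
#' @param method Distance metric, see [cdr3_distance()].
#' @param length_filter Apply the length pre-filter (default `TRUE`;
#'   exposed for equivalence testing).
#' @return Data.frame of matches: `query_cdr3`, `target_cdr3`, `distance`,
#'   `target_sample`.
#' @export
hs_matches <- function(queries, targets, max_dist = 2,
                       method = c("osa", "levenshtein"),
                       length_filter = TRUE) {
  method <- match.arg(method)
  stopifnot(max_dist >= 0)
  if (is.data.frame(queries)) queries <- queries$cdr3_aa
  queries <- unique(toupper(queries))
  if (is.list(targets) && !is.data.frame(targets)) {
    targets <- data.frame(
      sample_id = rep(names(targets), lengths(targets)),
      cdr3_aa = unlist(targets, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_id", "cdr3_aa") %in% names(targets)))
  tcdr3 <- toupper(targets$cdr3_aa)
  empty <- data.frame(query_cdr3 = character(), target_cdr3 = character(),
                      distance = integer(), target_sample = character(),
                      stringsAsFactors = FALSE)
  if (length(queries) == 0 || nrow(targets) == 0) return(empty)
  m <- cross_matches_cpp(queries, tcdr3, as.integer(max_dist),
                         if (method == "osa") 1L else 2L,
                         isTRUE(length_filter))
  if (length(m$query_idx) == 0) return(empty)
  out <- data.frame(query_cdr3 = queries[m$query_idx],
                    target_cdr3 = tcdr3[m$target_idx],
                    distance = m$distance,
                    target_sample = targets$sample_id[m$target_idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$target_sample, out$query_cdr3, out$target_cdr3,
                   method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count distinct HS-TCR clonotypes per external sample
#'
#' @param matches Data.frame from [hs_matches()].
#' @return Data.frame `sample_id`, `n_hs_clonotypes` (distinct target
#'   CDR3s matched), sorted by decreasing count then sample.
#' @export
summarize_per_sample <- function(matches) {
  if (nrow(matches) == 0)
    return(data.frame(sample_id = character(), n_hs_clonotypes = integer(),
                      stringsAsFactors = FALSE))
  n <- tapply(matches$target_cdr3, matches$target_sample,
              function(x) length(unique(x)))
  out <- data.frame(sample_id = names(n), n_hs_clonotypes = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_hs_clonotypes, out$sample_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Samples with at least k HS-TCR clonotypes
#'
#' @param summary Data.frame from [summarize_per_sample()].
#' @param k Threshold.
#' @return Character vector of sample ids.
#' @export
samples_with_at_least <- function(summary, k) {
  summary$sample_id[summary$n_hs_clonotypes >= k]
}

#' Near-identical public clonotype pairs
#'
#' Finds pairs of expanded clonotypes from different subjects that use the
#' same TRBV allele and whose CDR3s differ by at most `max_dist` amino
#' acids (default 1) — high-similarity counterparts of exactly-public
#' clonotypes.
#'
#' @param specific Per-subject specific catalogue
#'   ([classify_cross_reactive()] output; needs `subject_id`, `v_gene`,
#'   `cdr3_aa` and optionally `antigens`).
#' @param max_dist Maximum CDR3 distance (default 1).
#' @param method Distance metric, see [cdr3_distance()].
#' @return Data.frame, one row per unordered pair: `v_gene`, `cdr3_aa_1`,
#'   `subject_1`, `cdr3_aa_2`, `subject_2`, `distance`, `shared_antigens`.
#' @export
hs_public_pairs <- function(specific, max_dist = 1,
                            method = c("osa", "levenshtein")) {
  method <- match.arg(method)
  empty <- data.frame(v_gene = character(), cdr3_aa_1 = character(),
                      subject_1 = character(), cdr3_aa_2 = character(),
                      subject_2 = character(), distance = integer(),
                      shared_antigens = character(), stringsAsFactors = FALSE)
  if (nrow(specific) < 2) return(empty)
  rows <- list()
  for (v in unique(specific$v_gene)) {
    x <- specific[specific$v_gene == v, , drop = FALSE]
    if (nrow(x) < 2) next
    for (i in seq_len(nrow(x) - 1)) for (j in (i + 1):nrow(x)) {
      if (x$subject_id[i] == x$subject_id[j]) next
      d <- cdr3_distance(x$cdr3_aa[i], x$cdr3_aa[j], method = method)
      if (d > max_dist) next
      shared <- if (is.null(x$antigens)) character(0) else
        intersect(strsplit(x$antigens[i], ",")[[1]],
                  strsplit(x$antigens[j], ",")[[1]])
      rows[[length(rows) + 1]] <- data.frame(
        v_gene = v, cdr3_aa_1 = x$cdr3_aa[i], subject_1 = x$subject_id[i],
        cdr3_aa_2 = x$cdr3_aa[j], subject_2 = x$subject_id[j],
        distance = as.integer(d),
        shared_antigens = paste(sort(shared), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$v_gene, out$cdr3_aa_1, out$cdr3_aa_2,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an external CDR3 target list
#'
#' Two-column tab-separated file with header `sample_id`, `cdr3_aa`.
#'
#' @param path File path.
#' @return Data.frame `sample_id`, `cdr3_aa`.
#' @export
read_cdr3_targets <- function(path) {
  x <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                  stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cdr3_aa") %in% names(x)))
    stop("target list must have columns sample_id, cdr3_aa")
  x$cdr3_aa <- toupper(x$cdr3_aa)
  x
}
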