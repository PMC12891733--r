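# Independent reference implementations used as test oracles. These are
# deliberately written along different routes than the package code
# (explicit enumeration / full DP matrices / direct formulas).

# exhaustive one-sided hypergeometric tail: sum the probabilities of all
# tables at the observed margins at least as enriched as the observed one
fisher_enum_oracle <- function(count_cond, depth_cond, count_ref, depth_ref) {
  k <- count_cond + count_ref
  xs <- seq(max(0, k - depth_ref), min(depth_cond, k))
  xs <- xs[xs >= count_cond]
  sum(exp(lchoose(depth_cond, xs) + lchoose(depth_ref, k - xs) -
            lchoose(depth_cond + depth_ref, k)))
}

# direct Benjamini-Yekutieli step-up formula
by_direct_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q <- pmin(1, m * cm * p[o] / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# full-matrix optimal-string-alignment dynamic program
osa_ref_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    cost <- if (a[i] == b[j]) 0L else 1L
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
    if (i > 1 && j > 1 && a[i] == b[j - 1] && a[i - 1] == b[j])
      d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
  }
  d[n + 1, m + 1]
}

# two-group log-rank chi-square from the observed-minus-expected table
logrank_ref_oracle <- function(time, event, group) {
  group <- as.character(group)
  g1 <- unique(group)[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

random_cdr3_pool <- function(n, min_len = 8, max_len = 20) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(sample(min_len:max_len, n, replace = TRUE), function(l)
    paste(sample(aa, l, replace = TRUE), collapse = ""), character(1))
}

# small repertoire builder for unit tests
make_rep <- function(counts, subject = "S1", condition = NA_character_,
                     v_gene = NULL, cdr3 = NULL) {
  n <- length(counts)
  if (is.null(v_gene)) v_gene <- sprintf("TCRBV%02d.01.01", seq_len(n))
  if (is.null(cdr3)) cdr3 <- sprintf("CASS%sF", strrep("A", seq_len(n)))
  tcr_repertoire(data.frame(v_gene = v_gene, cdr3_aa = cdr3, count = counts,
                            stringsAsFactors = FALSE),
                 sample_id = paste0(subject, "_x"), subject_id = subject,
                 condition = condition)
}

airr_fixture_lines <- c(
  "v_call\tjunction_aa\tduplicate_count\tproductive",
  "TCRBV28.01.01\tCASRLGNTGELFF\t10\tT",
  "TCRBV05.01.01\tCASSLAPGATNEKLFF\t5\tT",
  "TCRBV12.01.01\tCASSFGREF\t1\tT")

write_airr_fixture <- function(lines = airr_fixture_lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
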