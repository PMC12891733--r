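# Reading, validating and aggregating TCR-beta rearrangement tables.
# The clonotype identity used throughout is (TRBV label, CDR3 amino-acid
# sequence); two rearrangements with the same CDR3 but different TRBV are
# distinct clonotypes.

#' Normalize a TRBV gene/allele label
#'
#' Uppercases the label and strips whitespace. Allele-level resolution is
#' preserved verbatim (e.g. `"TCRBV28.01.01"` stays allele-level); alleles
#' are never collapsed to the gene level because clonotype identity is
#' defined on the label as reported.
#'
#' @param v Character vector of V gene labels.
#' @return Character vector of normalized labels.
#' @export
normalize_v_gene <- function(v) {
  toupper(gsub("\\s+", "", as.character(v)))
}

#' Clonotype key
#'
#' Canonical string identity of a clonotype: `"<v_gene>_<cdr3_aa>"`.
#'
#' @param v_gene,cdr3_aa Character vectors (recycled together).
#' @return Character vector of keys.
#' @export
clonotype_key <- function(v_gene, cdr3_aa) {
  paste(normalize_v_gene(v_gene), toupper(cdr3_aa), sep = "_")
}

valid_cdr3 <- function(x) {
  grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

parse_logical_flag <- function(x) {
  lx <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[lx %in% c("t", "true", "1", "yes")] <- TRUE
  out[lx %in% c("f", "false", "0", "no")] <- FALSE
  out
}

#' Read an AIRR-C Rearrangement TSV
#'
#' Reads a tab-separated rearrangement table following the AIRR-C
#' Rearrangement schema. Mandatory columns are `v_call`, a CDR3
#' amino-acid column (`junction_aa`, or `cdr3_aa` as a fallback) and the
#' named count column. The `productive` column is parsed when present and
#' defaults to `TRUE` otherwise.
#'
#' @param path Path to the TSV file.
#' @param count_field Name of the count column; default `"duplicate_count"`
#'   (AIRR also allows `consensus_count` — the vendor pipelines behind
#'   these data report template/read counts without standardizing a name).
#' @return A data.frame of rearrangement records with columns `v_gene`,
#'   `cdr3_aa`, `read_count`, `productive`, plus any extra input columns
#'   passed through untouched.
#' @export
read_airr_tsv <- function(path, count_field = "duplicate_count") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  cdr3_col <- if ("junction_aa" %in% names(raw)) "junction_aa"
              else if ("cdr3_aa" %in% names(raw)) "cdr3_aa" else NA_character_
  for (col in c("v_call", count_field)) {
    if (!col %in% names(raw))
      stop("AIRR format error: missing mandatory column '", col, "' in ", path)
  }
  if (is.na(cdr3_col))
    stop("AIRR format error: missing mandatory column 'junction_aa' (or 'cdr3_aa') in ", path)
  counts_chr <- raw[[count_field]]
  if (any(is.na(counts_chr) | counts_chr == ""))
    stop("AIRR format error: missing count in column '", count_field, "', row ",
         which(is.na(counts_chr) | counts_chr == "")[1])
  counts <- suppressWarnings(as.numeric(counts_chr))
  bad <- is.na(counts) | counts != floor(counts) | counts < 0
  if (any(bad))
    stop("AIRR parse error: non-integer count '", counts_chr[which(bad)[1]],
         "' at row ", which(bad)[1])
  productive <- if ("productive" %in% names(raw)) {
    p <- parse_logical_flag(raw$productive)
    p[is.na(p)] <- TRUE
    p
  } else rep(TRUE, nrow(raw))
  out <- data.frame(v_gene = normalize_v_gene(raw$v_call),
                    cdr3_aa = toupper(raw[[cdr3_col]]),
                    read_count = as.integer(counts),
                    productive = productive,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(raw), c("v_call", cdr3_col, count_field, "productive"))
  if (length(extra)) out <- cbind(out, raw[extra])
  out
}

# default column synonyms for the Adaptive immunoSEQ export dialect
adaptive_default_map <- function() {
  list(
    v_gene  = c("vMaxResolved", "v_resolved", "vGeneName", "v_gene"),
    cdr3_aa = c("aminoAcid", "amino_acid", "cdr3_amino_acid", "aminoacid"),
    count   = c("count (templates/reads)", "templates", "count", "reads"),
    frame   = c("sequenceStatus", "frame_type", "frameType")
  )
}

#' Read an Adaptive-style immunoSEQ TSV export
#'
#' Maps the vendor export dialect onto the common rearrangement record
#' model. Frame type `"In"` maps to `productive = TRUE`; anything else
#' (`"Out"`, `"Stop"`) maps to `FALSE`. The column map is configurable and
#' a default synonym table ships with the package
#' (`system.file("extdata", "adaptive_column_map.yaml", package = "vaxtcr")`).
#'
#' @param path Path to the TSV file.
#' @param column_map Optional named list with entries `v_gene`, `cdr3_aa`,
#'   `count`, `frame`, each a character vector of acceptable column names
#'   in priority order. Defaults to the shipped map.
#' @return A data.frame of rearrangement records (see [read_airr_tsv()]).
#' @export
read_adaptive_tsv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(column_map)) column_map <- adaptive_default_map()
  raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  pick <- function(slot) {
    hit <- intersect(column_map[[slot]], names(raw))
    if (length(hit) == 0) NA_character_ else hit[1]
  }
  cols <- vapply(c("v_gene", "cdr3_aa", "count"), pick, character(1))
  if (any(is.na(cols)))
    stop("unrecognized Adaptive dialect: could not find ",
         paste(names(cols)[is.na(cols)], collapse = ", "),
         " among columns: ", paste(names(raw), collapse = ", "))
  frame_col <- pick("frame")
  counts <- suppressWarnings(as.numeric(raw[[cols["count"]]]))
  bad <- is.na(counts) | counts != floor(counts) | counts < 0
  if (any(bad))
    stop("Adaptive parse error: non-integer count at row ", which(bad)[1])
  productive <- if (!is.na(frame_col)) tolower(raw[[frame_col]]) == "in"
                else rep(TRUE, nrow(raw))
  out <- data.frame(v_gene = normalize_v_gene(raw[[cols["v_gene"]]]),
                    cdr3_aa = toupper(raw[[cols["cdr3_aa"]]]),
                    read_count = as.integer(counts),
                    productive = productive,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(raw), c(cols, frame_col))
  if (length(extra)) out <- cbind(out, raw[extra])
  out
}

#' Aggregate rearrangement records into a repertoire
#'
#' Sums read counts over identical (TRBV, CDR3aa) clonotypes. Records
#' failing the productive filter, carrying zero counts, or whose CDR3
#' contains characters outside the 20-letter amino-acid alphabet (stop
#' `*`, frameshift `X`, etc.) are excluded before aggregation.
#'
#' @param records Data.frame of rearrangement records with columns
#'   `v_gene`, `cdr3_aa`, `read_count`, `productive`.
#' @param productive_only Drop non-productive records first (default
#'   `TRUE`; the analyses downstream concern productive TCRs).
#' @param sample_id,subject_id Sample and subject labels.
#' @param condition One of [CONDITIONS].
#' @return A `tcr_repertoire` object: list with `clonotypes` (data.frame
#'   `v_gene`, `cdr3_aa`, `count`, sorted by descending count with a
#'   stable (cdr3_aa, v_gene) tie-break), `total_reads`, `sample_id`,
#'   `subject_id`, `condition`.
#' @export
aggregate_clonotypes <- function(records, productive_only = TRUE,
                                 sample_id = NA_character_,
                                 subject_id = NA_character_,
                                 condition = NA_character_) {
  stopifnot(is.data.frame(records))
  keep <- records$read_count > 0 & valid_cdr3(records$cdr3_aa)
  if (productive_only) keep <- keep & records$productive
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0)
    stop("empty repertoire: no records survive filtering (productive_only = ",
         productive_only, ")")
  key <- clonotype_key(rec$v_gene, rec$cdr3_aa)
  counts <- tapply(rec$read_count, key, sum)
  first <- !duplicated(key)
  cl <- data.frame(v_gene = rec$v_gene[first], cdr3_aa = rec$cdr3_aa[first],
                   stringsAsFactors = FALSE)
  cl$count <- as.integer(counts[clonotype_key(cl$v_gene, cl$cdr3_aa)])
  tcr_repertoire(cl, sample_id = sample_id, subject_id = subject_id,
                 condition = condition)
}

#' Construct a TCR repertoire object
#'
#' @param clonotypes Data.frame with columns `v_gene`, `cdr3_aa`, `count`
#'   (positive integers; duplicates not allowed).
#' @param sample_id,subject_id,condition Metadata labels; `condition` must
#'   be `NA` or one of [CONDITIONS].
#' @return An object of class `tcr_repertoire`.
#' @export
tcr_repertoire <- function(clonotypes, sample_id = NA_character_,
                           subject_id = NA_character_,
                           condition = NA_character_) {
  stopifnot(is.data.frame(clonotypes),
            all(c("v_gene", "cdr3_aa", "count") %in% names(clonotypes)))
  if (!is.na(condition) && !condition %in% CONDITIONS)
    stop("unknown condition '", condition, "'")
  if (any(clonotypes$count < 1)) stop("all clonotype counts must be >= 1")
  if (anyDuplicated(clonotype_key(clonotypes$v_gene, clonotypes$cdr3_aa)))
    stop("duplicate clonotypes; aggregate first")
  ord <- order(-clonotypes$count, clonotypes$cdr3_aa, clonotypes$v_gene,
               method = "radix")
  clonotypes <- clonotypes[ord, c("v_gene", "cdr3_aa", "count"), drop = FALSE]
  rownames(clonotypes) <- NULL
  clonotypes$count <- as.integer(clonotypes$count)
  structure(list(clonotypes = clonotypes,
                 total_reads = sum(as.numeric(clonotypes$count)),
                 sample_id = sample_id, subject_id = subject_id,
                 condition = condition),
            class = "tcr_repertoire")
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat("TCR-beta repertoire:", x$sample_id,
      sprintf("(subject %s, condition %s)\n", x$subject_id, x$condition))
  cat(sprintf("  %d clonotypes, %s reads\n",
              nrow(x$clonotypes), format(x$total_reads, big.mark = ",")))
  print(head(x$clonotypes, 5))
  if (nrow(x$clonotypes) > 5) cat("  ...\n")
  invisible(x)
}

#' Clonotype frequency in a repertoire
#'
#' @param repertoire A `tcr_repertoire`.
#' @param v_gene,cdr3_aa Clonotype identity (vectors, recycled).
#' @return Numeric vector of frequencies in `[0, 1]`; 0 for clonotypes
#'   absent from the repertoire.
#' @export
clonotype_frequency <- function(repertoire, v_gene, cdr3_aa) {
  stopifnot(inherits(repertoire, "tcr_repertoire"))
  key <- clonotype_key(v_gene, cdr3_aa)
  rep_key <- clonotype_key(repertoire$clonotypes$v_gene,
                           repertoire$clonotypes$cdr3_aa)
  idx <- match(key, rep_key)
  cnt <- ifelse(is.na(idx), 0L, repertoire$clonotypes$count[idx])
  cnt / repertoire$total_reads
}

#' Write a repertoire (or record table) as AIRR TSV
#'
#' Emits columns `v_call`, `junction_aa`, `duplicate_count`, `productive`,
#' sorted by descending count with a stable (cdr3_aa, v_gene) tie-break so
#' outputs are bit-exact reproducible.
#'
#' @param x A `tcr_repertoire` or a rearrangement record data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr_tsv <- function(x, path) {
  if (inherits(x, "tcr_repertoire")) {
    df <- data.frame(v_call = x$clonotypes$v_gene,
                     junction_aa = x$clonotypes$cdr3_aa,
                     duplicate_count = x$clonotypes$count,
                     productive = "T", stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(x))
    df <- data.frame(v_call = x$v_gene, junction_aa = x$cdr3_aa,
                     duplicate_count = x$read_count,
                     productive = ifelse(x$productive, "T", "F"),
                     stringsAsFactors = FALSE)
  }
  df <- df[order(-df$duplicate_count, df$junction_aa, df$v_call,
                 method = "radix"), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
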