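# End-to-end study runs over an on-disk study directory, with fixed
# 12-significant-digit numeric serialization and a deterministic run
# manifest so identical configs produce byte-identical reports.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"),
                formatC(x, digits = 12, format = "g")))
}

write_report_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmt_num(out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a study directory
#'
#' Reads the layout written by [simulate_study_dir()]: AIRR repertoires
#' named `<subject>_<condition>.airr.tsv` under `repertoires/`, an
#' `elispot.csv`, and a `subjects.csv` with `subject_id`,
#' `tumor_mutation`, `dfs_months`, `dfs_event`.
#'
#' @param dir Study directory.
#' @param count_field AIRR count column (default `"duplicate_count"`).
#' @return List: `repertoires` (subject -> condition -> `tcr_repertoire`),
#'   `elispot` (data.frame or `NULL`), `subjects` (data.frame or `NULL`).
#' @export
read_study <- function(dir, count_field = "duplicate_count") {
  rep_dir <- file.path(dir, "repertoires")
  if (!dir.exists(rep_dir)) stop("no repertoires/ directory under ", dir)
  files <- sort(list.files(rep_dir, pattern = "\\.airr\\.tsv$"),
                method = "radix")
  reps <- list()
  for (f in files) {
    stem <- sub("\\.airr\\.tsv$", "", f)
    cond <- CONDITIONS[endsWith(stem, paste0("_", CONDITIONS))]
    if (length(cond) != 1)
      stop("cannot parse condition from repertoire file name: ", f)
    sid <- sub(paste0("_", cond, "$"), "", stem)
    recs <- read_airr_tsv(file.path(rep_dir, f), count_field = count_field)
    reps[[sid]][[cond]] <- aggregate_clonotypes(
      recs, sample_id = stem, subject_id = sid, condition = cond)
  }
  # fixed, locale-independent ordering of subjects and conditions
  reps <- reps[sort(names(reps), method = "radix")]
  reps <- lapply(reps, function(r) r[intersect(CONDITIONS, names(r))])
  elispot <- NULL
  if (file.exists(file.path(dir, "elispot.csv")))
    elispot <- utils::read.csv(file.path(dir, "elispot.csv"),
                               stringsAsFactors = FALSE)
  subjects <- NULL
  if (file.exists(file.path(dir, "subjects.csv")))
    subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                                stringsAsFactors = FALSE)
  list(repertoires = reps, elispot = elispot, subjects = subjects)
}

config_fingerprint <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(x), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(outdir, config, outputs, warnings = character(0)) {
  manifest <- list(
    package = "vaxtcr",
    version = as.character(utils::packageVersion("vaxtcr")),
    config = config,
    config_md5 = config_fingerprint(config),
    outputs = as.list(tools::md5sum(file.path(outdir, outputs))),
    warnings = warnings)
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the TCR expansion pipeline over a study
#'
#' Per subject: repertoire equitability, per-condition expansion tests and
#' calls, the baseline-filtered antigen-specific catalogue, cross-reactive
#' classification, then cohort-level public clonotypes and per-subject
#' tumor overlap. Subjects missing the reference condition are skipped
#' with a logged warning, not an error.
#'
#' @param study A study list from [read_study()] (or the in-memory
#'   equivalent with a `repertoires` element).
#' @param outdir Output directory for the report bundle.
#' @param config An [expansion_config()].
#' @return Invisibly, a list with `specific`, `public`, `equitability`,
#'   `tumor_overlap`, `summary`, and the paths written.
#' @export
run_expansion_pipeline <- function(study, outdir,
                                   config = expansion_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  reps <- study$repertoires
  warnings <- character(0)
  if (length(reps) == 0) {
    warnings <- "empty subject list"
    warning(warnings)
  }
  tests_all <- list(); specific_all <- list(); eq_all <- list()
  tumor_rows <- list()
  for (sid in names(reps)) {
    sub <- reps[[sid]]
    if (!config$reference_condition %in% names(sub)) {
      warnings <- c(warnings, paste0("subject ", sid, ": missing reference '",
                                     config$reference_condition, "', skipped"))
      next
    }
    res <- subject_expansion(sub, config)
    tests_all[[sid]] <- res$tests
    specific_all[[sid]] <- res$specific
    eq <- res$equitability
    eq$subject_id <- sid
    eq_all[[sid]] <- eq[, c("subject_id", "condition", "equitability")]
    if ("tumor_tissue" %in% names(sub) && nrow(res$specific) > 0) {
      ov <- tumor_overlap(res$specific, sub$tumor_tissue)
      tumor_rows[[sid]] <- data.frame(subject_id = sid,
                                      n_specific = nrow(res$specific),
                                      n_overlap = ov$n_overlap,
                                      fraction = ov$fraction,
                                      stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(tests_all)) do.call(rbind, tests_all) else NULL
  specific <- if (length(specific_all)) do.call(rbind, specific_all)
              else data.frame()
  rownames(specific) <- NULL
  equitability <- if (length(eq_all)) do.call(rbind, eq_all) else data.frame()
  rownames(equitability) <- NULL
  tumor <- if (length(tumor_rows)) do.call(rbind, tumor_rows) else data.frame()
  rownames(tumor) <- NULL
  public <- if (length(unique(specific$subject_id)) >= 2) find_public(specific)
            else data.frame()

  outputs <- character(0)
  if (!is.null(tests)) {
    write_report_tsv(tests, file.path(outdir, "expansion_tests.tsv"))
    outputs <- c(outputs, "expansion_tests.tsv")
  }
  write_report_tsv(specific, file.path(outdir, "specific_catalogue.tsv"))
  write_report_tsv(equitability, file.path(outdir, "equitability.tsv"))
  write_report_tsv(public, file.path(outdir, "public_clonotypes.tsv"))
  outputs <- c(outputs, "specific_catalogue.tsv", "equitability.tsv",
               "public_clonotypes.tsv")
  if (nrow(tumor)) {
    write_report_tsv(tumor, file.path(outdir, "tumor_overlap.tsv"))
    outputs <- c(outputs, "tumor_overlap.tsv")
  }
  summary <- list(
    n_subjects = length(tests_all),
    n_specific = nrow(specific),
    n_cross_reactive = sum(specific$cross_reactive),
    n_public = nrow(public),
    per_antigen = if (nrow(specific)) {
      tb <- table(unlist(strsplit(specific$antigens, ",")))
      as.list(setNames(as.integer(tb), names(tb)))
    } else list(),
    reference_condition = config$reference_condition)
  jsonlite::write_json(summary, file.path(outdir, "expansion_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- c(outputs, "expansion_summary.json")
  write_manifest(outdir, unclass(config), outputs, warnings)
  invisible(list(tests = tests, specific = specific, public = public,
                 equitability = equitability, tumor_overlap = tumor,
                 summary = summary, outputs = file.path(outdir, outputs)))
}

#' Run the ELISPOT responder pipeline over a study
#'
#' Produces pooled-average and (when tumor mutations are available)
#' tumor-matched responder calls, per-antigen positivity counts, and —
#' when survival columns are present — the lowest-quartile stratification
#' with Kaplan-Meier medians and the log-rank test.
#'
#' @param study Study list from [read_study()] (needs `elispot`;
#'   `subjects` enables tumor-matched calls and survival).
#' @param outdir Output directory.
#' @param k Threshold multiplier (default 2.77).
#' @param window_weeks Evaluation window (default 17).
#' @param scale Response scale, see [elispot_responders()].
#' @param q Stratification quantile (default 0.25).
#' @return Invisibly, a list with `responders`, `positivity`, `survival`,
#'   `summary`.
#' @export
run_elispot_pipeline <- function(study, outdir, k = 2.77, window_weeks = 17,
                                 scale = "sfu", q = 0.25) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(study$elispot)) stop("study has no ELISPOT table")
  sfu <- study$elispot
  warnings <- character(0)
  calls <- elispot_responders(sfu, mode = "pooled_average", k = k,
                              window_weeks = window_weeks, scale = scale)
  if (length(attr(calls, "excluded")))
    warnings <- c(warnings, paste0("excluded (no baseline or in-window post): ",
                                   paste(attr(calls, "excluded"), collapse = ", ")))
  tm_calls <- NULL
  if (!is.null(study$subjects) && "tumor_mutation" %in% names(study$subjects)) {
    tmut <- setNames(study$subjects$tumor_mutation, study$subjects$subject_id)
    tm_calls <- elispot_responders(sfu, mode = "tumor_matched",
                                   tumor_mutation = tmut, k = k,
                                   window_weeks = window_weeks, scale = scale)
  }
  responders <- rbind(calls, tm_calls)
  pos <- antigen_positivity_count(sfu, k = k, window_weeks = window_weeks,
                                  scale = scale)
  outputs <- c("responder_calls.tsv", "antigen_positivity.tsv")
  write_report_tsv(responders, file.path(outdir, "responder_calls.tsv"))
  write_report_tsv(pos, file.path(outdir, "antigen_positivity.tsv"))

  surv <- NULL
  if (!is.null(study$subjects) &&
      all(c("dfs_months", "dfs_event") %in% names(study$subjects))) {
    scores <- setNames(calls$max_fold, calls$subject_id)
    meta <- study$subjects[match(names(scores), study$subjects$subject_id), ]
    ok <- !is.na(scores) & !is.na(meta$dfs_months)
    if (sum(ok) >= 4) {
      surv <- stratified_survival(scores[ok], setNames(meta$dfs_months[ok],
                                                       meta$subject_id[ok]),
                                  setNames(meta$dfs_event[ok],
                                           meta$subject_id[ok]), q = q)
      surv_report <- data.frame(
        group = names(surv$medians),
        n = vapply(surv$km, function(f) f$n, numeric(1)),
        events = vapply(surv$km, function(f) f$n_events, numeric(1)),
        median_months = surv$medians, stringsAsFactors = FALSE)
      write_report_tsv(surv_report, file.path(outdir, "survival_strata.tsv"))
      outputs <- c(outputs, "survival_strata.tsv")
    }
  }
  summary <- list(
    n_evaluable = nrow(calls),
    n_responders_pooled = sum(calls$responder),
    n_responders_tumor_matched = if (!is.null(tm_calls))
      sum(tm_calls$responder) else NA,
    positivity_histogram = as.list(setNames(
      as.integer(table(factor(pos$n_positive_antigens, levels = 0:6))),
      as.character(0:6))),
    logrank_p = if (!is.null(surv) && !is.null(surv$logrank))
      surv$logrank$p_value else NA,
    k = k, window_weeks = window_weeks, scale = scale)
  jsonlite::write_json(summary, file.path(outdir, "elispot_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- c(outputs, "elispot_summary.json")
  write_manifest(outdir, list(k = k, window_weeks = window_weeks,
                              scale = scale, q = q), outputs, warnings)
  invisible(list(responders = responders, positivity = pos, survival = surv,
                 summary = summary, outputs = file.path(outdir, outputs)))
}
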