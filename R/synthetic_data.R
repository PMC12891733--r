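# Seeded synthetic-data generator with ground truth.
#
# Emulates the study's inputs: per-subject bulk TCR-beta repertoires for
# an unstimulated baseline, vehicle-only and irrelevant-peptide control
# cultures, six mutant-KRAS peptide expansion cultures and (optionally)
# tumor tissue; an ELISPOT SFU panel over time with known responders; and
# exponential survival data. Background clone frequencies are
# heavy-tailed (Dirichlet with small concentration); reads are multinomial
# at the stated depth; truly expanded clones are spiked by a known fold.
# Everything is a pure function of (config, seed).

#' Synthetic-cohort configuration
#'
#' Defaults are the study conditions the generator emulates: 12 subjects,
#' 2e4 clonotypes per repertoire at sequencing depth 1e5; 10 spiked
#' (truly antigen-reactive) clones per mutant-KRAS antigen at fold 20 with
#' post-spike frequency at or above 0.2%; 20% of spiked clones
#' cross-reactive (biased toward G12C/G12A/G12V); 2 public clones shared
#' by subject pairs; 10% of spiked clones also present at baseline (and
#' therefore filtered by design); negative-binomial ELISPOT baselines of
#' mean 50 SFU (size 10) and a responder effect of 6 baseline SDs.
#'
#' @param n_subjects,n_clonotypes,depth Cohort and repertoire sizes.
#' @param clone_freq_shape Gamma/Dirichlet concentration of the background
#'   clone-frequency distribution (smaller = heavier tail).
#' @param n_spiked_per_antigen,spike_fold,spike_freq_floor Spiked-clone
#'   design: clones per antigen, expansion fold, and minimum post-spike
#'   frequency.
#' @param cross_reactive_fraction Fraction of spiked clones assigned a
#'   second antigen.
#' @param public_clone_count Clonotypes planted in two subjects each with
#'   a shared antigen.
#' @param baseline_overlap_fraction Fraction of spiked clones also planted
#'   in the baseline repertoire.
#' @param tumor_overlap_count Specific clones planted in each subject's
#'   tumor repertoire.
#' @param elispot_baseline_mean,elispot_dispersion Negative-binomial mean
#'   and size of baseline SFU per well.
#' @param responder_effect_sd_units Post-vaccine shift for responders, in
#'   units of the cross-patient baseline SD of the pooled response.
#' @param seed Integer seed; fully determines every output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12, n_clonotypes = 20000, depth = 1e5,
                       clone_freq_shape = 0.1, n_spiked_per_antigen = 10,
                       spike_fold = 20, spike_freq_floor = 0.002,
                       cross_reactive_fraction = 0.2, public_clone_count = 2,
                       baseline_overlap_fraction = 0.1,
                       tumor_overlap_count = 5,
                       elispot_baseline_mean = 50, elispot_dispersion = 10,
                       responder_effect_sd_units = 6, seed = 1) {
  stopifnot(depth >= 1000, n_subjects >= 1, n_clonotypes >= 100,
            spike_fold > 0, spike_freq_floor > 0, spike_freq_floor < 1,
            cross_reactive_fraction >= 0, cross_reactive_fraction <= 1,
            baseline_overlap_fraction >= 0, baseline_overlap_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

random_cdr3 <- function(n, len_range = c(10, 18)) {
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(len, function(l)
    paste0("CASS", paste(sample(AA_ALPHABET, l - 5, replace = TRUE),
                         collapse = ""), "F"),
    character(1))
}

random_v_gene <- function(n) {
  sprintf("TCRBV%02d.01.01", sample(1:30, n, replace = TRUE))
}

# n unique clonotype labels, avoiding the keys in `exclude`
random_clonotypes <- function(n, exclude = character(0)) {
  v <- character(0); c3 <- character(0)
  while (length(v) < n) {
    k <- n - length(v)
    nv <- random_v_gene(k + ceiling(k * 0.05) + 10)
    nc <- random_cdr3(length(nv))
    key <- clonotype_key(nv, nc)
    ok <- !duplicated(key) & !key %in% exclude &
      !key %in% clonotype_key(v, c3)
    v <- c(v, nv[ok]); c3 <- c(c3, nc[ok])
  }
  data.frame(v_gene = v[seq_len(n)], cdr3_aa = c3[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Sample one repertoire from clone frequencies
#'
#' Multinomial read sampling at `depth` from a background frequency
#' vector, with designated spiked clones' frequencies multiplied by
#' `spike_fold` (the whole vector is renormalized afterwards so it remains
#' a proper distribution). Clones listed in `force_present` are guaranteed
#' a count of at least 1 so emitted truth sets are always consistent with
#' the data.
#'
#' @param labels Data.frame `v_gene`, `cdr3_aa` (one row per clone).
#' @param base_freq Background frequency vector (sums to 1).
#' @param depth Total reads to sample.
#' @param spike_idx Indices of spiked clones (empty for null conditions).
#' @param spike_fold Multiplicative spike (1 = null).
#' @param force_present Indices guaranteed a nonzero count.
#' @param sample_id,subject_id,condition Repertoire metadata.
#' @return A `tcr_repertoire`.
#' @export
simulate_repertoire <- function(labels, base_freq, depth,
                                spike_idx = integer(0), spike_fold = 1,
                                force_present = integer(0),
                                sample_id = "sim", subject_id = "S1",
                                condition = NA_character_) {
  stopifnot(nrow(labels) == length(base_freq), all(base_freq >= 0))
  p <- base_freq / sum(base_freq)
  if (length(spike_idx)) {
    spike_mass <- sum(p[spike_idx]) * spike_fold
    if (spike_mass >= 1)
      stop("config error: spike mass ", round(spike_mass, 3),
           " >= 1 after scaling")
    p[spike_idx] <- p[spike_idx] * spike_fold
    p <- p / sum(p)
  }
  counts <- as.integer(rmultinom(1, size = depth, prob = p))
  if (length(force_present)) counts[force_present] <- pmax(counts[force_present], 1L)
  keep <- counts > 0
  tcr_repertoire(data.frame(v_gene = labels$v_gene[keep],
                            cdr3_aa = labels$cdr3_aa[keep],
                            count = counts[keep], stringsAsFactors = FALSE),
                 sample_id = sample_id, subject_id = subject_id,
                 condition = condition)
}

# antigen weights used when assigning the extra antigen of a
# cross-reactive clone: the most common observed cross-reactivity is
# between G12C, G12A and G12V, with G12R to a lesser extent
CROSS_REACTIVE_WEIGHTS <- c(G12V = 3, G12A = 3, G12R = 1, G12C = 3,
                            G12D = 0.5, G13D = 0.5)

#' Simulate a full cohort of repertoires with ground truth
#'
#' Per subject: a heavy-tailed background repertoire observed under
#' baseline, vehicle-only, control-peptide, six antigen-expansion
#' conditions and a tumor-tissue sample. Spiked clones carry a reference
#' frequency of at least `spike_freq_floor / spike_fold` so their
#' post-spike frequency clears the floor; they are absent from baseline
#' except the designated overlap fraction. Public clones are planted in
#' two subjects with a shared antigen; a fraction of spiked clones gets a
#' second antigen (cross-reactive truth); `tumor_overlap_count` specific
#' clones are planted in the tumor sample.
#'
#' @param config A [sim_config()].
#' @param include_tumor Emit tumor-tissue repertoires (default `TRUE`).
#' @return List with `repertoires` (nested list subject -> condition ->
#'   `tcr_repertoire`) and `truth`: `spiked` (data.frame `subject_id`,
#'   `v_gene`, `cdr3_aa`, `antigens`, `baseline_present`, `tumor_planted`,
#'   `public`), `specific` (the spiked rows not planted at baseline),
#'   `public` (data.frame `v_gene`, `cdr3_aa`, `subjects`,
#'   `shared_antigen`).
#' @export
simulate_cohort <- function(config = sim_config(), include_tumor = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_sub <- config$n_subjects
  subjects <- sprintf("S%02d", seq_len(n_sub))

  # public clonotypes, each shared by a pair of subjects
  n_pub <- config$public_clone_count
  pub <- random_clonotypes(n_pub)
  pub_truth <- NULL
  pub_assign <- vector("list", n_sub)
  if (n_pub > 0) {
    if (n_sub < 2) stop("public clones require >= 2 subjects")
    pairs <- lapply(seq_len(n_pub), function(i) {
      s <- 2 * ((i - 1) %% (n_sub %/% 2)) + c(1, 2)
      if (s[2] > n_sub) s <- c(1, 2)
      s
    })
    pub_antigen <- sample(MKRAS_ANTIGENS, n_pub, replace = TRUE)
    pub_truth <- data.frame(v_gene = pub$v_gene, cdr3_aa = pub$cdr3_aa,
                            subjects = vapply(pairs, function(s)
                              paste(subjects[s], collapse = ","), character(1)),
                            shared_antigen = pub_antigen,
                            stringsAsFactors = FALSE)
    for (i in seq_len(n_pub)) for (s in pairs[[i]])
      pub_assign[[s]] <- rbind(pub_assign[[s]],
                               data.frame(v_gene = pub$v_gene[i],
                                          cdr3_aa = pub$cdr3_aa[i],
                                          antigen = pub_antigen[i],
                                          stringsAsFactors = FALSE))
  }

  reps <- list()
  spiked_truth <- list()
  for (s in seq_len(n_sub)) {
    sid <- subjects[s]
    pub_s <- pub_assign[[s]]
    n_pub_s <- if (is.null(pub_s)) 0L else nrow(pub_s)
    labels <- random_clonotypes(config$n_clonotypes,
                                exclude = clonotype_key(pub$v_gene, pub$cdr3_aa))
    if (n_pub_s > 0) {
      labels$v_gene[seq_len(n_pub_s)] <- pub_s$v_gene
      labels$cdr3_aa[seq_len(n_pub_s)] <- pub_s$cdr3_aa
    }

    # spiked-clone design: one antigen each, public clones keep their
    # shared antigen, then a fraction gains a second antigen
    n_spike <- 6L * config$n_spiked_per_antigen
    spike_idx <- seq_len(n_spike)  # includes the public slots
    antigen_of <- rep(MKRAS_ANTIGENS, each = config$n_spiked_per_antigen)
    if (n_pub_s > 0) antigen_of[seq_len(n_pub_s)] <- pub_s$antigen
    antigens <- as.list(antigen_of)
    is_public <- seq_len(n_spike) <= n_pub_s
    n_cross <- floor(config$cross_reactive_fraction * n_spike)
    cross_pool <- which(!is_public)
    if (n_cross > 0 && length(cross_pool) > 0) {
      cross_idx <- sample(cross_pool, min(n_cross, length(cross_pool)))
      for (i in cross_idx) {
        w <- CROSS_REACTIVE_WEIGHTS[setdiff(MKRAS_ANTIGENS, antigens[[i]])]
        antigens[[i]] <- sort(c(antigens[[i]],
                                sample(names(w), 1, prob = w)))
      }
    }
    n_base <- floor(config$baseline_overlap_fraction * n_spike)
    baseline_present <- rep(FALSE, n_spike)
    if (n_base > 0 && length(cross_pool) > 0)
      baseline_present[sample(cross_pool, min(n_base, length(cross_pool)))] <- TRUE

    # frequencies: heavy-tailed background, spiked clones pinned to a
    # reference frequency whose spiked value clears the frequency floor
    f0 <- config$spike_freq_floor / config$spike_fold * runif(n_spike, 1.5, 5)
    g <- rgamma(config$n_clonotypes, shape = config$clone_freq_shape)
    p <- g / sum(g)
    p[spike_idx] <- 0
    p <- p / sum(p) * (1 - sum(f0))
    p[spike_idx] <- f0

    cond_spikes <- lapply(MKRAS_ANTIGENS, function(a)
      spike_idx[vapply(antigens, function(x) a %in% x, logical(1))])
    names(cond_spikes) <- MKRAS_ANTIGENS

    p_base <- p
    p_base[spike_idx[!baseline_present]] <- 0
    p_base <- p_base / sum(p_base)

    sub_reps <- list(
      baseline = simulate_repertoire(labels, p_base, config$depth,
                                     force_present = spike_idx[baseline_present],
                                     sample_id = paste0(sid, "_baseline"),
                                     subject_id = sid, condition = "baseline"),
      vehicle_only = simulate_repertoire(labels, p, config$depth,
                                         sample_id = paste0(sid, "_vehicle"),
                                         subject_id = sid,
                                         condition = "vehicle_only"),
      control_peptide = simulate_repertoire(labels, p, config$depth,
                                            sample_id = paste0(sid, "_ctrl"),
                                            subject_id = sid,
                                            condition = "control_peptide"))
    for (a in MKRAS_ANTIGENS) {
      sub_reps[[a]] <- simulate_repertoire(labels, p, config$depth,
                                           spike_idx = cond_spikes[[a]],
                                           spike_fold = config$spike_fold,
                                           force_present = cond_spikes[[a]],
                                           sample_id = paste0(sid, "_", a),
                                           subject_id = sid, condition = a)
    }

    tumor_planted <- rep(FALSE, n_spike)
    if (include_tumor) {
      plantable <- which(!baseline_present)
      k <- min(config$tumor_overlap_count, length(plantable))
      planted <- if (k > 0) sample(plantable, k) else integer(0)
      tumor_planted[planted] <- TRUE
      spec_keys <- clonotype_key(labels$v_gene[spike_idx],
                                 labels$cdr3_aa[spike_idx])
      n_tum <- max(1000L, config$n_clonotypes %/% 4L)
      tum_labels <- rbind(labels[spike_idx[planted], , drop = FALSE],
                          random_clonotypes(n_tum - k, exclude = spec_keys))
      tg <- rgamma(nrow(tum_labels), shape = config$clone_freq_shape)
      tp <- tg / sum(tg)
      if (k > 0) {
        tp[seq_len(k)] <- 0
        tp <- tp / sum(tp) * (1 - 0.001 * k)
        tp[seq_len(k)] <- 0.001
      }
      sub_reps$tumor_tissue <- simulate_repertoire(
        tum_labels, tp, config$depth,
        force_present = seq_len(k),
        sample_id = paste0(sid, "_tumor"), subject_id = sid,
        condition = "tumor_tissue")
    }

    spiked_truth[[sid]] <- data.frame(
      subject_id = sid,
      v_gene = labels$v_gene[spike_idx], cdr3_aa = labels$cdr3_aa[spike_idx],
      antigens = vapply(antigens, paste, character(1), collapse = ","),
      baseline_present = baseline_present, tumor_planted = tumor_planted,
      public = is_public, stringsAsFactors = FALSE)
    reps[[sid]] <- sub_reps
  }
  spiked <- do.call(rbind, spiked_truth)
  rownames(spiked) <- NULL
  list(repertoires = reps,
       truth = list(spiked = spiked,
                    specific = spiked[!spiked$baseline_present, , drop = FALSE],
                    public = pub_truth))
}

#' Simulate an ELISPOT SFU panel with known responders
#'
#' Per subject x week x stimulation (unstimulated, control peptide, six
#' antigens) x 3 replicates, SFU are negative binomial around
#' `baseline_mean`. Responders receive an additive post-vaccine shift of
#' `effect_sd_units` times the theoretical cross-patient baseline SD of
#' the pooled response (mean over 6 antigens x 3 replicates), with a
#' ramp at week 4, a plateau over weeks 8-16 (the boosting period) and
#' exponential decay afterwards.
#'
#' @param n_subjects Number of subjects.
#' @param weeks Measurement weeks; must include 0 (baseline).
#' @param responder_ids Indices of true responders; default all but the
#'   last subject (an 11-of-12-like cohort at the default size). Use
#'   `integer(0)` for an all-null cohort.
#' @param baseline_mean,dispersion Negative-binomial mean and size per
#'   well.
#' @param effect_sd_units Responder effect size in baseline-SD units.
#' @param seed Integer seed.
#' @return List: `sfu` (long-format data.frame `subject_id`, `week`,
#'   `stimulation`, `replicate`, `sfu`), `truth` (data.frame `subject_id`,
#'   `responder`, `effect_sd_units`).
#' @export
simulate_elispot <- function(n_subjects = 12, weeks = c(0, 4, 8, 12, 16),
                             responder_ids = seq_len(max(n_subjects - 1, 0)),
                             baseline_mean = 50, dispersion = 10,
                             effect_sd_units = 6, seed = 1) {
  stopifnot(0 %in% weeks, n_subjects >= 1)
  set.seed(seed)
  subjects <- sprintf("E%04d", seq_len(n_subjects))
  sigma_pool <- sqrt((baseline_mean + baseline_mean^2 / dispersion) / 18)
  shape <- function(w) ifelse(w <= 0, 0,
                       ifelse(w < 8, 0.5,
                       ifelse(w <= 16, 1, exp(-(w - 16) / 12))))
  grid <- expand.grid(replicate = 1:3, stimulation = ELISPOT_STIMS,
                      week = sort(weeks), subject_id = subjects,
                      stringsAsFactors = FALSE)[, 4:1]
  is_resp <- match(grid$subject_id, subjects) %in% responder_ids
  is_antigen <- grid$stimulation %in% MKRAS_ANTIGENS
  mu <- rep(baseline_mean, nrow(grid)) +
    ifelse(is_resp & is_antigen,
           effect_sd_units * sigma_pool * shape(grid$week), 0)
  grid$sfu <- rnbinom(nrow(grid), mu = mu, size = dispersion)
  truth <- data.frame(subject_id = subjects,
                      responder = seq_len(n_subjects) %in% responder_ids,
                      effect_sd_units = ifelse(seq_len(n_subjects) %in%
                                                 responder_ids,
                                               effect_sd_units, 0),
                      stringsAsFactors = FALSE)
  list(sfu = grid, truth = truth)
}

#' Simulate two-group exponential survival data
#'
#' Exponential event times at the given hazards with independent
#' exponential censoring.
#'
#' @param n_per_group Subjects per group.
#' @param hazard_low,hazard_high Event hazards (per month) of the two
#'   groups.
#' @param censor_rate Censoring hazard; 0 disables censoring.
#' @param seed Integer seed.
#' @return Data.frame `subject_id`, `group` (`"low_hazard"` /
#'   `"high_hazard"`), `time`, `event`.
#' @export
simulate_survival <- function(n_per_group, hazard_low, hazard_high,
                              censor_rate = 0, seed = 1) {
  stopifnot(hazard_low > 0, hazard_high > 0, censor_rate >= 0)
  set.seed(seed)
  n <- n_per_group
  ev_time <- c(rexp(n, hazard_low), rexp(n, hazard_high))
  cens <- if (censor_rate > 0) rexp(2 * n, censor_rate) else rep(Inf, 2 * n)
  data.frame(subject_id = sprintf("P%04d", seq_len(2 * n)),
             group = rep(c("low_hazard", "high_hazard"), each = n),
             time = pmin(ev_time, cens), event = ev_time <= cens,
             stringsAsFactors = FALSE)
}

#' Write a complete toy study directory
#'
#' Emits the on-disk study layout the pipeline reads: AIRR TSV repertoires
#' under `repertoires/`, a long-format `elispot.csv`, a `subjects.csv`
#' with tumor mutation and disease-free-survival columns, a `truth.json`,
#' and a `config.yaml` describing the run.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param include_tumor Emit tumor repertoires.
#' @return `dir`, invisibly.
#' @export
simulate_study_dir <- function(config = sim_config(), dir,
                               include_tumor = TRUE) {
  dir.create(file.path(dir, "repertoires"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- simulate_cohort(config, include_tumor = include_tumor)
  for (sid in names(cohort$repertoires)) {
    for (cn in names(cohort$repertoires[[sid]])) {
      write_airr_tsv(cohort$repertoires[[sid]][[cn]],
                     file.path(dir, "repertoires",
                               paste0(sid, "_", cn, ".airr.tsv")))
    }
  }
  es <- simulate_elispot(n_subjects = config$n_subjects,
                         baseline_mean = config$elispot_baseline_mean,
                         dispersion = config$elispot_dispersion,
                         effect_sd_units = config$responder_effect_sd_units,
                         seed = config$seed + 1)
  es$sfu$subject_id <- names(cohort$repertoires)[match(
    es$sfu$subject_id, sprintf("E%04d", seq_len(config$n_subjects)))]
  es$truth$subject_id <- names(cohort$repertoires)
  write.csv(es$sfu, file.path(dir, "elispot.csv"), row.names = FALSE,
            quote = FALSE)
  set.seed(config$seed + 2)
  subjects <- names(cohort$repertoires)
  meta <- data.frame(
    subject_id = subjects,
    tumor_mutation = sample(MKRAS_ANTIGENS, length(subjects), replace = TRUE),
    dfs_months = round(rexp(length(subjects),
                            rate = ifelse(es$truth$responder, 1 / 18, 1 / 4)), 2),
    dfs_event = sample(c(1L, 1L, 0L), length(subjects), replace = TRUE),
    stringsAsFactors = FALSE)
  meta$dfs_months <- pmax(meta$dfs_months, 0.5)
  write.csv(meta, file.path(dir, "subjects.csv"), row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(list(spiked = cohort$truth$spiked,
                            public = cohort$truth$public,
                            elispot = es$truth),
                       file.path(dir, "truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  invisible(dir)
}
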