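# small config used across generator tests
toy_cfg <- function(seed = 1, ...) {
  sim_config(n_subjects = 2, n_clonotypes = 500, depth = 10000,
             n_spiked_per_antigen = 3, public_clone_count = 1,
             tumor_overlap_count = 2, seed = seed, ...)
}

test_that("the generator is a pure function of its seed", {
  a <- simulate_cohort(toy_cfg(seed = 33))
  b <- simulate_cohort(toy_cfg(seed = 33))
  expect_identical(a, b)
  c <- simulate_cohort(toy_cfg(seed = 34))
  expect_false(identical(a$repertoires$S01$G12V$clonotypes,
                         c$repertoires$S01$G12V$clonotypes))
  e1 <- simulate_elispot(n_subjects = 3, seed = 5)
  e2 <- simulate_elispot(n_subjects = 3, seed = 5)
  expect_identical(e1, e2)
})

test_that("truth sets are consistent with the emitted repertoires", {
  co <- simulate_cohort(toy_cfg(seed = 2))
  for (sid in names(co$repertoires)) {
    tr <- co$truth$spiked[co$truth$spiked$subject_id == sid, ]
    reps <- co$repertoires[[sid]]
    base_key <- clonotype_key(reps$baseline$clonotypes$v_gene,
                              reps$baseline$clonotypes$cdr3_aa)
    for (i in seq_len(nrow(tr))) {
      k <- clonotype_key(tr$v_gene[i], tr$cdr3_aa[i])
      for (a in strsplit(tr$antigens[i], ",")[[1]]) {
        ck <- clonotype_key(reps[[a]]$clonotypes$v_gene,
                            reps[[a]]$clonotypes$cdr3_aa)
        expect_true(k %in% ck)
      }
      expect_equal(k %in% base_key, tr$baseline_present[i])
    }
    tum_key <- clonotype_key(reps$tumor_tissue$clonotypes$v_gene,
                             reps$tumor_tissue$clonotypes$cdr3_aa)
    planted <- clonotype_key(tr$v_gene[tr$tumor_planted],
                             tr$cdr3_aa[tr$tumor_planted])
    expect_true(all(planted %in% tum_key))
    # non-planted specific clones stay out of the tumor sample
    not_planted <- clonotype_key(tr$v_gene[!tr$tumor_planted],
                                 tr$cdr3_aa[!tr$tumor_planted])
    expect_false(any(not_planted %in% tum_key))
  }
})

test_that("public and cross-reactive truth follow the config", {
  co <- simulate_cohort(toy_cfg(seed = 3))
  expect_equal(nrow(co$truth$public), 1)
  subs <- strsplit(co$truth$public$subjects, ",")[[1]]
  expect_equal(length(subs), 2)
  nocross <- simulate_cohort(toy_cfg(seed = 3, cross_reactive_fraction = 0))
  n_ag <- lengths(strsplit(nocross$truth$spiked$antigens, ","))
  expect_true(all(n_ag == 1))
})

test_that("spike mass above one is rejected", {
  lab <- data.frame(v_gene = "TCRBV01.01.01",
                    cdr3_aa = sprintf("CASS%sF", strrep("A", 1:10)),
                    stringsAsFactors = FALSE)
  p <- rep(0.1, 10)
  expect_error(simulate_repertoire(lab, p, 5000, spike_idx = 1:5,
                                   spike_fold = 5), "spike mass")
})

test_that("planted spikes produce the expected read-count ratio", {
  set.seed(13)
  lab <- data.frame(v_gene = sprintf("TCRBV%02d.01.01", rep(1:30, length.out = 2000)),
                    cdr3_aa = sprintf("CASSA%dF", 1:2000), stringsAsFactors = FALSE)
  g <- rgamma(2000, 0.5)
  p <- g / sum(g)
  p[1] <- 1e-4
  p <- p / sum(p)
  ors <- replicate(20, {
    r_cond <- simulate_repertoire(lab, p, 1e5, spike_idx = 1, spike_fold = 50,
                                  force_present = 1, condition = "G12V")
    r_ref <- simulate_repertoire(lab, p, 1e5, condition = "vehicle_only",
                                 force_present = 1)
    cc <- r_cond$clonotypes$count[r_cond$clonotypes$cdr3_aa == "CASSA1F"]
    cr <- r_ref$clonotypes$count[r_ref$clonotypes$cdr3_aa == "CASSA1F"]
    cc / cr
  })
  expect_gt(mean(ors), 25)
  expect_lt(mean(ors), 100)
})

test_that("null spikes give exchangeable condition and reference repertoires", {
  set.seed(14)
  lab <- data.frame(v_gene = "TCRBV01.01.01",
                    cdr3_aa = sprintf("CASSB%dF", 1:3000), stringsAsFactors = FALSE)
  g <- rgamma(3000, 0.1)
  p <- g / sum(g)
  r1 <- simulate_repertoire(lab, p, 5e4, spike_idx = 1:5, spike_fold = 1,
                            condition = "G12V")
  r2 <- simulate_repertoire(lab, p, 5e4, condition = "vehicle_only")
  called <- call_expanded(expansion_tests(r1, r2))
  expect_lte(sum(called$expanded), 1)
})

test_that("ELISPOT generator marks responders and nulls as configured", {
  es <- simulate_elispot(n_subjects = 12, seed = 21)
  expect_equal(sum(es$truth$responder), 11)  # 11-of-12 default cohort
  expect_equal(nrow(es$sfu), 12 * 5 * 8 * 3)
  expect_true(all(es$sfu$sfu >= 0))
  nul <- simulate_elispot(n_subjects = 5, responder_ids = integer(0), seed = 22)
  expect_false(any(nul$truth$responder))
})

test_that("survival generator honours censoring and hazard settings", {
  d <- simulate_survival(100, hazard_low = 0.05, hazard_high = 0.25,
                         censor_rate = 0, seed = 7)
  expect_true(all(d$event))
  expect_equal(nrow(d), 200)
  # exponential medians scale as the inverse hazard ratio
  m_low <- median(d$time[d$group == "low_hazard"])
  m_high <- median(d$time[d$group == "high_hazard"])
  expect_gt(m_low / m_high, 2.5)
})

test_that("a written study directory reads back into the same repertoires", {
  dir <- tempfile("study")
  cfg <- toy_cfg(seed = 40)
  simulate_study_dir(cfg, dir)
  study <- read_study(dir)
  co <- simulate_cohort(cfg)
  expect_setequal(names(study$repertoires), names(co$repertoires))
  r_disk <- study$repertoires$S01$G12V
  r_mem <- co$repertoires$S01$G12V
  expect_identical(r_disk$clonotypes, r_mem$clonotypes)
  expect_true(file.exists(file.path(dir, "elispot.csv")))
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
})
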