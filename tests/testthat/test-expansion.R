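test_that("clonality index hits its analytic endpoints", {
  expect_equal(shannon_equitability(rep(7, 100)), 0)
  # counts {2,1,1}: H = 1.5 ln2 approx 1.03972, ln 3 = 1.09861
  expect_equal(shannon_equitability(c(2, 1, 1)),
               1 - (1.5 * log(2)) / log(3), tolerance = 1e-12)
  expect_equal(round(shannon_equitability(c(2, 1, 1)), 4), 0.0536)
  v <- shannon_equitability(c(999999, 1))
  expect_gt(v, 0.9999)
  expect_lt(v, 1)
  expect_error(shannon_equitability(c(5)), "fewer than 2")
})

test_that("clonality index stays in [0,1] on random repertoires", {
  set.seed(1)
  for (i in 1:200) {
    counts <- sample(1:1000, sample(2:300, 1), replace = TRUE)
    v <- shannon_equitability(counts)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("read-count ratio follows the printed definition", {
  expect_equal(odds_ratio(50, 10), 5)
  expect_equal(odds_ratio(7, 7), 1)
  expect_equal(odds_ratio(12, 0), Inf)
  expect_error(odds_ratio(0, 0), "undefined")
})

test_that("one-sided Fisher p matches exhaustive tail enumeration", {
  # no enrichment: equal tables give p well above 0.5
  expect_gte(fisher_one_sided(5, 100, 5, 100), 0.5)
  # hand-checkable table [[3,7],[0,10]]
  expect_equal(fisher_one_sided(3, 10, 0, 10),
               choose(10, 3) / choose(20, 3), tolerance = 1e-12)
  # zero condition count: p = 1 in the enrichment direction
  expect_equal(fisher_one_sided(0, 50, 5, 50), 1)
  # enumeration oracle on a grid of small tables
  set.seed(2)
  for (i in 1:400) {
    d1 <- sample(1:25, 1); d2 <- sample(1:25, 1)
    c1 <- sample(0:d1, 1); c2 <- sample(0:d2, 1)
    expect_equal(fisher_one_sided(c1, d1, c2, d2),
                 fisher_enum_oracle(c1, d1, c2, d2), tolerance = 1e-12)
  }
  expect_error(fisher_one_sided(5, 3, 0, 10), "invalid")
})

test_that("Fisher p is monotone decreasing in the condition count at fixed margins", {
  for (d1 in c(10, 30, 50)) for (d2 in c(10, 40)) for (k in c(3, 8)) {
    cs <- 0:min(d1, k)
    ps <- fisher_one_sided(cs, d1, k - cs, d2)
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("BY adjustment matches the direct step-up formula", {
  expect_equal(by_adjust(0.02), 0.02)
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3), tolerance = 1e-12)
  expect_equal(by_adjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    q <- by_adjust(p)
    expect_equal(q, by_direct_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("expansion thresholds are inclusive and monotone in the config", {
  tests <- data.frame(
    subject_id = "S1", condition = "G12V",
    v_gene = "TCRBV01.01.01", cdr3_aa = c("CASSAF", "CASSBF", "CASSCF"),
    count_cond = c(100L, 49L, 10L), depth_cond = 100000L,
    count_ref = c(20L, 10L, 0L), depth_ref = 100000L,
    odds_ratio = c(5, 4.9, Inf), freq_cond = c(0.001, 0.01, 1e-04),
    p_one_sided = c(1e-6, 1e-6, 1e-3), q_by = c(0.01, 0.001, 0.01),
    stringsAsFactors = FALSE)
  called <- call_expanded(tests, expansion_config())
  expect_true(called$expanded[1])    # OR = 5, freq = 0.001, q = 0.01: inclusive
  expect_false(called$expanded[2])   # OR below 5
  expect_false(called$expanded[3])   # below frequency floor
  no_freq <- call_expanded(tests, expansion_config(apply_freq_cutoff = FALSE))
  expect_true(no_freq$expanded[3])   # OR-only mapping mode keeps it

  # loosening any threshold never drops a called clonotype
  base <- call_expanded(tests, expansion_config())$expanded
  for (cfg in list(expansion_config(or_min = 2),
                   expansion_config(freq_min = 1e-5),
                   expansion_config(q_max = 0.2))) {
    loose <- call_expanded(tests, cfg)$expanded
    expect_true(all(loose[base]))
  }
})

test_that("expansion tests compare every condition clonotype against the reference", {
  cond <- make_rep(c(500, 50, 5), condition = "G12V")
  ref <- make_rep(c(10, 50, 5), condition = "vehicle_only")
  tt <- expansion_tests(cond, ref)
  expect_equal(nrow(tt), 3)
  expect_equal(tt$freq_cond, tt$count_cond / tt$depth_cond)
  expect_true(all(tt$q_by >= tt$p_one_sided - 1e-15))
  i <- which(tt$cdr3_aa == "CASSAF")
  expect_equal(tt$odds_ratio[i], 50)
  # clonotype absent from reference gets OR = Inf
  cond2 <- make_rep(c(100, 1), cdr3 = c("CASSAF", "CASSNEWF"),
                    v_gene = c("TCRBV01.01.01", "TCRBV02.01.01"),
                    condition = "G12A")
  tt2 <- expansion_tests(cond2, ref)
  expect_equal(tt2$odds_ratio[tt2$cdr3_aa == "CASSNEWF"], Inf)
})

test_that("baseline filtering removes pre-existing clonotypes only", {
  calls <- data.frame(subject_id = "S1", condition = "G12V",
                      v_gene = c("TCRBV01.01.01", "TCRBV02.01.01"),
                      cdr3_aa = c("CASSAF", "CASSBF"),
                      expanded = TRUE, stringsAsFactors = FALSE)
  baseline <- make_rep(c(2, 9), cdr3 = c("CASSAF", "CASSOTHERF"),
                       v_gene = c("TCRBV01.01.01", "TCRBV09.01.01"),
                       condition = "baseline")
  out <- filter_baseline(calls, baseline)
  expect_true(out$filtered_by_baseline[1])   # present at baseline, count 2
  expect_false(out$filtered_by_baseline[2])  # absent at baseline: retained
  spec <- classify_cross_reactive(out)
  expect_equal(spec$cdr3_aa, "CASSBF")

  other <- make_rep(c(1), subject = "S2", condition = "baseline")
  expect_error(filter_baseline(calls, other), "does not match")
})

test_that("cross-reactive classification unions antigen sets", {
  calls <- data.frame(
    subject_id = "S1",
    condition = c("G12V", "G12A", "G12D", "G12V", "G12A", "G12C"),
    v_gene = "TCRBV01.01.01",
    cdr3_aa = c("CASSAF", "CASSAF", "CASSBF", "CASSCF", "CASSCF", "CASSCF"),
    expanded = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    filtered_by_baseline = FALSE, stringsAsFactors = FALSE)
  spec <- classify_cross_reactive(calls)
  a <- spec[spec$cdr3_aa == "CASSAF", ]
  expect_true(a$cross_reactive)
  expect_equal(a$antigens, "G12A,G12V")
  expect_false(spec$cross_reactive[spec$cdr3_aa == "CASSBF"])
  expect_equal(spec$n_antigens[spec$cdr3_aa == "CASSCF"], 3L)
  dist <- antigen_set_distribution(spec)
  expect_equal(sum(dist$n_clonotypes), 3L)
})

test_that("public clonotypes require exact identity in two or more subjects", {
  spec <- data.frame(
    subject_id = c("S1", "S2", "S1", "S2", "S3"),
    v_gene = c("TCRBV28.01.01", "TCRBV28.01.01", "TCRBV05.01.01",
               "TCRBV06.01.01", "TCRBV07.01.01"),
    cdr3_aa = c("CASRLGNTGELFF", "CASRLGNTGELFF", "CASSXF", "CASSXF", "CASSYF"),
    antigens = c("G13D", "G13D", "G12V", "G12V", "G12A"),
    stringsAsFactors = FALSE)
  pub <- find_public(spec)
  # exact V+CDR3 match in two subjects, shared antigen G13D
  expect_equal(nrow(pub), 1)
  expect_equal(pub$cdr3_aa, "CASRLGNTGELFF")
  expect_equal(pub$shared_antigens, "G13D")
  expect_true(pub$antigens_intersect)
  # same CDR3 under different TRBV is not public
  expect_false("CASSXF" %in% pub$cdr3_aa)
  expect_error(find_public(spec[spec$subject_id == "S1", ]), ">= 2 subjects")
})

test_that("tumor overlap reports counts and fractions", {
  spec <- data.frame(v_gene = sprintf("TCRBV%02d.01.01", 1:10),
                     cdr3_aa = sprintf("CASS%sF", strrep("A", 1:10)),
                     antigens = "G12V", stringsAsFactors = FALSE)
  tum <- make_rep(c(5, 5), v_gene = spec$v_gene[1:2], cdr3 = spec$cdr3_aa[1:2],
                  condition = "tumor_tissue")
  ov <- tumor_overlap(spec, tum)
  expect_equal(ov$n_overlap, 2)
  expect_equal(ov$fraction, 0.2)
  expect_equal(ov$per_antigen$n_overlap, 2L)
  disjoint <- make_rep(c(3), cdr3 = "CASSZZZF", v_gene = "TCRBV30.01.01",
                       condition = "tumor_tissue")
  ov0 <- tumor_overlap(spec, disjoint)
  expect_equal(ov0$n_overlap, 0)
  expect_equal(ov0$fraction, 0)
  expect_error(tumor_overlap(spec[0, ], tum), "empty")
})
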