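test_that("AIRR reader preserves counts, flags and extra columns", {
  path <- write_airr_fixture()
  rec <- read_airr_tsv(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$read_count, c(10L, 5L, 1L))
  expect_true(all(rec$productive))

  # non-productive flag passthrough, stop codon in junction
  path2 <- write_airr_fixture(c(airr_fixture_lines,
                                "TCRBV09.01.01\tCASSL*GELFF\t3\tF"))
  rec2 <- read_airr_tsv(path2)
  expect_false(rec2$productive[4])
  expect_equal(rec2$cdr3_aa[4], "CASSL*GELFF")
})

test_that("AIRR reader errors name the offending column or row", {
  bad <- write_airr_fixture(c("v_call\tjunction_aa", "TCRBV01.01.01\tCASSF"))
  expect_error(read_airr_tsv(bad), "duplicate_count")
  bad2 <- write_airr_fixture(c("v_call\tjunction_aa\tduplicate_count",
                               "TCRBV01.01.01\tCASSF\tten"))
  expect_error(read_airr_tsv(bad2), "row 1")
  bad3 <- write_airr_fixture(c("junction_aa\tduplicate_count", "CASSF\t3"))
  expect_error(read_airr_tsv(bad3), "v_call")
})

test_that("write -> read round-trips records exactly", {
  path <- write_airr_fixture(c(airr_fixture_lines,
                               "TCRBV09.01.01\tCASSLYGELFF\t5\tF"))
  rec <- read_airr_tsv(path)
  out <- tempfile(fileext = ".tsv")
  write_airr_tsv(rec, out)
  rec2 <- read_airr_tsv(out)
  cols <- c("v_gene", "cdr3_aa", "read_count", "productive")
  key <- function(d) d[order(d$v_gene, d$cdr3_aa), cols]
  expect_equal(key(rec2), key(rec), ignore_attr = TRUE)
})

test_that("Adaptive dialect maps onto the common model and matches AIRR", {
  lines <- c("aminoAcid\tvMaxResolved\ttemplates\tsequenceStatus",
             "CASRLGNTGELFF\tTCRBV28.01.01\t10\tIn",
             "CASSLAPGATNEKLFF\tTCRBV05.01.01\t5\tIn",
             "CASSFGREF\tTCRBV12.01.01\t1\tIn",
             "CASSLWGELFF\tTCRBV09.01.01\t42\tOut")
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  rec <- read_adaptive_tsv(path)
  expect_equal(rec$read_count[4], 42L)
  expect_false(rec$productive[4])
  expect_true(all(rec$productive[1:3]))

  # same content through both dialects yields the identical repertoire
  airr <- read_airr_tsv(write_airr_fixture())
  rep_airr <- aggregate_clonotypes(airr, sample_id = "a", subject_id = "s",
                                   condition = "G12V")
  rep_adap <- aggregate_clonotypes(rec, sample_id = "a", subject_id = "s",
                                   condition = "G12V")
  expect_identical(rep_airr$clonotypes, rep_adap$clonotypes)
  expect_identical(rep_airr$total_reads, rep_adap$total_reads)

  expect_error(read_adaptive_tsv(write_airr_fixture(
    c("foo\tbar", "1\t2"))), "unrecognized")
})

test_that("aggregation sums identical clonotypes and respects TRBV identity", {
  rec <- data.frame(
    v_gene = c("TCRBV28.01.01", "TCRBV28.01.01", "TCRBV05.01.01"),
    cdr3_aa = c("CASRLGNTGELFF", "CASRLGNTGELFF", "CASRLGNTGELFF"),
    read_count = c(3L, 7L, 4L), productive = TRUE, stringsAsFactors = FALSE)
  rep <- aggregate_clonotypes(rec)
  # same V+CDR3 collapses; same CDR3 with different TRBV stays distinct
  expect_equal(nrow(rep$clonotypes), 2)
  expect_equal(rep$clonotypes$count[rep$clonotypes$v_gene == "TCRBV28.01.01"], 10L)
  expect_equal(rep$total_reads, 14)

  # productive filter removes the out-of-frame row and its reads
  rec2 <- rbind(rec, data.frame(v_gene = "TCRBV09.01.01", cdr3_aa = "CASSF",
                                read_count = 5L, productive = FALSE))
  expect_equal(aggregate_clonotypes(rec2, productive_only = TRUE)$total_reads, 14)
  expect_equal(aggregate_clonotypes(rec2, productive_only = FALSE)$total_reads, 19)
  expect_error(aggregate_clonotypes(rec2[rec2$productive == FALSE, ]),
               "empty repertoire")
})

test_that("aggregation is order-independent and totals are consistent", {
  set.seed(5)
  rec <- data.frame(
    v_gene = sample(sprintf("TCRBV%02d.01.01", 1:6), 60, replace = TRUE),
    cdr3_aa = sample(c("CASSAF", "CASSGF", "CASSCF", "CASSDF"), 60, TRUE),
    read_count = sample(1:20, 60, TRUE), productive = TRUE,
    stringsAsFactors = FALSE)
  r1 <- aggregate_clonotypes(rec)
  r2 <- aggregate_clonotypes(rec[sample(nrow(rec)), ])
  expect_identical(r1$clonotypes, r2$clonotypes)
  expect_equal(r1$total_reads, sum(rec$read_count))
  expect_equal(r1$total_reads, sum(r1$clonotypes$count))
})

test_that("clonotype frequencies behave as relative abundances", {
  rep <- make_rep(c(10, 990))
  expect_equal(clonotype_frequency(rep, "TCRBV01.01.01", "CASSAF"), 0.01)
  expect_equal(clonotype_frequency(rep, "TCRBV09.01.01", "CASSZZF"), 0)
  freqs <- rep$clonotypes$count / rep$total_reads
  expect_equal(sum(freqs), 1, tolerance = 1e-12)
})

test_that("V gene labels normalize case and whitespace but keep alleles", {
  expect_equal(normalize_v_gene(" tcrbv28.01.01 "), "TCRBV28.01.01")
  expect_equal(normalize_v_gene("TCRBV28.01.01"), "TCRBV28.01.01")
  # alleles stay distinct
  expect_false(normalize_v_gene("TCRBV28.01.01") == normalize_v_gene("TCRBV28.01.02"))
})
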