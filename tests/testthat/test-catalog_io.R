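test_that("per-consequence duplicate rows collapse to one call with the most severe consequence", {
  path <- withr::local_tempfile(fileext = ".tsv")
  # 6 rows, 2 donors, 3 distinct mutations; d1's 7:100 mutation is annotated
  # twice (missense + stop_gained rows)
  write_ssm_fixture(path, list(
    c("d1", "BRCA-US", "7", "100", "A", "T", "missense_variant", "TP53"),
    c("d1", "BRCA-US", "7", "100", "A", "T", "stop_gained", "TP53"),
    c("d1", "BRCA-US", "7", "200", "C", "G", "synonymous_variant", "KRAS"),
    c("d2", "BRCA-US", "7", "100", "A", "T", "missense_variant", "TP53"),
    c("d2", "BRCA-US", "8", "300", "G", "A", "missense_variant", "EGFR"),
    c("d2", "BRCA-US", "8", "300", "G", "A", "intron_variant", "EGFR")))
  cat1 <- read_icgc_ssm(path)
  expect_equal(nrow(cat1$calls), 4L)
  expect_equal(nrow(cat1$roster), 2L)
  collapsed <- cat1$calls[chromosome == "7" & start == 100L & donor_id == "d1"]
  expect_equal(collapsed$consequence, "stop_gained")
  expect_equal(
    cat1$calls[chromosome == "8" & start == 300L]$consequence, "missense_variant")
})

test_that("an empty SSM file with a valid header yields an empty catalog", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ssm_fixture(path, list())
  cat1 <- read_icgc_ssm(path)
  expect_equal(nrow(cat1$calls), 0L)
  expect_equal(nrow(cat1$roster), 0L)
})

test_that("chromosome label normalization unifies chr7 and 7 into one mutation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ssm_fixture(path, list(
    c("d1", "SKCM", "chr7", "100", "A", "T", "missense_variant", "BRAF"),
    c("d2", "SKCM", "7", "100", "A", "T", "missense_variant", "BRAF")))
  cat1 <- read_icgc_ssm(path)
  rec <- recurrence_counts(cat1, "PanCancer")
  expect_equal(nrow(rec$counts), 1L)
  expect_equal(rec$counts$recurrence, 2L)
})

test_that("missing mandatory columns and bad records are reported usefully", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("icgc_donor_id\tproject_code\tchromosome",
               "d1\tBRCA-US\t7"), path)
  expect_error(read_icgc_ssm(path), "chromosome_start")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_ssm_fixture(path2, list(
    c("d1", "BRCA-US", "7", "100", "A", "T", "missense_variant", "TP53"),
    c("d2", "BRCA-US", "7", "oops", "A", "T", "missense_variant", "TP53")))
  expect_error(read_icgc_ssm(path2), "line\\(s\\) 3")
  expect_warning(cat2 <- read_icgc_ssm(path2, on_bad_record = "skip"),
                 "skipped")
  expect_equal(nrow(cat2$calls), 1L)
})

test_that("manifest rosters extend beyond mutation-bearing donors and reject conflicts", {
  mpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("icgc_donor_id\tproject_code",
               paste0("d", 1:5, "\tBRCA-US"),
               "d3\tBRCA-US"), mpath)  # duplicate same-project row: deduplicated
  roster <- read_donor_manifest(mpath)
  expect_equal(nrow(roster), 5L)

  spath <- withr::local_tempfile(fileext = ".tsv")
  write_ssm_fixture(spath, list(
    c("d1", "BRCA-US", "1", "10", "A", "T", "missense_variant", "X1"),
    c("d2", "BRCA-US", "1", "20", "A", "T", "missense_variant", "X1"),
    c("d3", "BRCA-US", "1", "30", "A", "T", "missense_variant", "X1")))
  cat1 <- read_icgc_ssm(spath, manifest = roster)
  expect_equal(nrow(cat1$roster), 5L)
  expect_equal(uniqueN(cat1$calls$donor_id), 3L)

  # no manifest: roster defaults to observed donors
  cat2 <- read_icgc_ssm(spath)
  expect_setequal(cat2$roster$donor_id, c("d1", "d2", "d3"))

  cpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("icgc_donor_id\tproject_code", "d1\tBRCA-US", "d1\tOV-AU"),
             cpath)
  expect_error(read_donor_manifest(cpath), "conflicting")
})

test_that("merge_projects pools national projects, preserves donor-mutation pairs, and is idempotent", {
  calls <- data.frame(
    donor_id = c("a1", "a2", "a3", "b1", "b2", "s1"),
    cancer_type = c("BRCA-US", "BRCA-US", "BRCA-US", "BRCA-UK", "BRCA-UK", "SKCM"),
    chromosome = "1", start = c(1L, 2L, 3L, 4L, 5L, 6L),
    ref = "A", alt = "T", consequence = "missense_variant", gene = "G1")
  cat1 <- merge_projects(new_catalog(calls))
  expect_setequal(unique(cat1$roster$cancer_type), c("BRCA", "SKCM"))
  expect_equal(nrow(cat1$roster[cancer_type == "BRCA"]), 5L)
  expect_equal(cat1$calls[donor_id == "s1"]$cancer_type, "SKCM")

  # same donor and mutation listed under both national projects: one call
  dup <- rbind(calls,
               data.frame(donor_id = "a1", cancer_type = "BRCA-UK",
                          chromosome = "1", start = 1L, ref = "A", alt = "T",
                          consequence = "missense_variant", gene = "G1"))
  merged <- merge_projects(new_catalog(dup))
  expect_equal(nrow(merged$calls[donor_id == "a1" & start == 1L]), 1L)
  n_pairs <- nrow(unique(merged$calls[, .(donor_id, chromosome, start, ref, alt)]))
  expect_equal(nrow(merged$calls), n_pairs)

  expect_identical(merge_projects(merged)$calls, merged$calls)
})

test_that("consequence filtering keeps the roster and is idempotent", {
  calls <- data.frame(
    donor_id = c("d1", "d1", "d1", "d2", "d2"),
    cancer_type = "T1", chromosome = "1", start = 1:5,
    ref = "A", alt = "T",
    consequence = c("missense_variant", "missense_variant", "missense_variant",
                    "intron_variant", "intron_variant"),
    gene = "G1")
  cat1 <- new_catalog(calls)
  flt <- filter_consequences(cat1)
  expect_equal(nrow(flt$calls), 3L)
  # d2 had only intron calls but stays enrolled with zero burden
  expect_true("d2" %in% flt$roster$donor_id)
  expect_equal(donor_burden(flt)[donor_id == "d2"]$n_mutations, 0L)
  expect_identical(filter_consequences(flt)$calls, flt$calls)
  # include-list of all observed terms is the identity
  all_terms <- unique(cat1$calls$consequence)
  expect_equal(nrow(filter_consequences(cat1, all_terms)$calls), nrow(cat1$calls))
  expect_warning(filter_consequences(cat1, c("missense_variant", "made_up_term")),
                 "made_up_term")
  expect_error(filter_consequences(cat1, character(0)), "non-empty")
})

test_that("cancer types failing mutation or donor thresholds are removed entirely", {
  calls <- data.frame(
    donor_id = c(sprintf("a%d", 1:3), sprintf("b%d", 1:2)),
    cancer_type = c(rep("BIG", 3), rep("TINY", 2)),
    chromosome = "1", start = c(1L, 2L, 3L, 4L, 5L),
    ref = "A", alt = "T", consequence = "missense_variant", gene = "G1")
  cat1 <- new_catalog(calls)
  expect_message(flt <- filter_cancer_types(cat1, min_mutations = 3L),
                 "TINY")
  expect_setequal(unique(flt$roster$cancer_type), "BIG")
  expect_equal(nrow(flt$calls[cancer_type == "TINY"]), 0L)
  # identity when thresholds are 0
  same <- filter_cancer_types(cat1, 0L, 0L)
  expect_equal(nrow(same$calls), nrow(cat1$calls))
  # 49 donors fail a 50-donor floor
  many <- new_catalog(data.frame(
    donor_id = sprintf("d%03d", 1:49), cancer_type = "ALMOST",
    chromosome = "1", start = 1:49, ref = "A", alt = "T",
    consequence = "missense_variant", gene = "G1"))
  expect_message(out <- filter_cancer_types(many, min_donors = 50L), "ALMOST")
  expect_equal(nrow(out$roster), 0L)
})

test_that("tidy TSV round-trip reproduces calls and roster exactly", {
  # indel alleles written as "-" survive the round trip
  calls <- data.frame(
    donor_id = c("d1", "d2"), cancer_type = "T1", chromosome = c("1", "X"),
    start = c(10L, 20L), ref = c("-", "AT"), alt = c("G", "-"),
    consequence = "frameshift_variant", gene = c("", "G2"))
  roster <- data.frame(donor_id = c("d1", "d2", "d3"), cancer_type = "T1")
  cat1 <- new_catalog(calls, roster)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat1, path)
  back <- read_catalog(path)
  expect_identical(as.data.frame(back$calls), as.data.frame(cat1$calls))
  expect_identical(as.data.frame(back$roster), as.data.frame(cat1$roster))

  # empty catalog round-trips to a header-only file
  empty <- new_catalog(calls[0, ], roster[0, ])
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(empty, path2)
  expect_equal(length(readLines(path2)), 1L)
  expect_equal(nrow(read_catalog(path2)$calls), 0L)
})

test_that("round-trip identity holds across randomized catalogs", {
  for (seed in 1:50) {
    cat1 <- random_catalog(seed, donors = 12L, types = 2L)
    path <- tempfile(fileext = ".tsv")
    write_catalog(cat1, path)
    back <- read_catalog(path)
    expect_identical(as.data.frame(back$calls), as.data.frame(cat1$calls))
    expect_identical(as.data.frame(back$roster), as.data.frame(cat1$roster))
    file.remove(path, default_roster_path(path))
  }
})

test_that("catalog invariants are enforced", {
  base <- data.frame(donor_id = "d1", cancer_type = "T1", chromosome = "1",
                     start = 1L, ref = "A", alt = "T",
                     consequence = "missense_variant", gene = "G1")
  expect_error(new_catalog(transform(base, start = 0L)), "start")
  expect_error(new_catalog(transform(base, alt = "A")), "differ")
  expect_error(new_catalog(transform(base, chromosome = "weird")), "chromosome")
  expect_error(new_catalog(base, roster = data.frame(donor_id = "other",
                                                     cancer_type = "T1")),
               "missing from roster")
  # duplicate (donor, mutation) rows are collapsed by the constructor
  expect_equal(nrow(new_catalog(rbind(base, base))$calls), 1L)
})
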