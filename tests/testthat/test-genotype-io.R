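write_tmp <- function(lines) {
  p <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("delimited matrix parsing normalizes calls and counts missing", {
  p <- write_tmp(c("id,m1,m2", "s1,AA,AG", "s2,aa,NA"))
  g <- read_geno_matrix(p)
  expect_equal(g$sample_ids, c("s1", "s2"))
  expect_equal(g$marker_ids, c("m1", "m2"))
  expect_equal(unname(g$calls[2, 1]), "AA")     # lowercase normalized
  expect_true(is.na(g$calls[2, 2]))
  expect_equal(g$missing_counts, c(0, 1))
})

test_that("heterozygote spellings collapse to one canonical class", {
  p <- write_tmp(c("id\tm1", "s1\tGA", "s2\tAG"))
  g <- read_geno_matrix(p)
  expect_equal(unname(g$calls[, 1]), c("AG", "AG"))
  expect_equal(normalize_calls(c("GA", "AG", "1|0", "0/1", "0/.", "--")),
               c("AG", "AG", "0/1", "0/1", NA, NA))
})

test_that("duplicate IDs and ragged rows are hard errors with context", {
  p <- write_tmp(c("id,m1,m2", "s1,AA,AG", "s1,GG,AA"))
  expect_error(read_geno_matrix(p), "duplicate sample ID.*s1")
  p2 <- write_tmp(c("id,m1,m2", "s1,AA,AG", "s2,GG,AA,CC"))
  expect_error(read_geno_matrix(p2), "ragged row 3")
  p3 <- write_tmp(c("id,m1,m1", "s1,AA,AG"))
  expect_error(read_geno_matrix(p3), "duplicate marker ID.*m1")
})

test_that("matrix write/read round-trips ids and calls for both delimiters", {
  g0 <- rand_geno(8, 10, miss = 0.25, seed = 42)
  for (d in c("\t", ",")) {
    p <- withr::local_tempfile(fileext = ".txt")
    write_geno_matrix(g0, p, delim = d)
    g1 <- read_geno_matrix(p)
    expect_identical(g1$sample_ids, g0$sample_ids)
    expect_identical(g1$marker_ids, g0$marker_ids)
    expect_identical(g1$calls, g0$calls)
    expect_identical(g1$missing_counts, g0$missing_counts)
  }
})

vcf_lines <- function(records, samples = c("S1", "S2", "S3", "S4")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

test_that("VCF GT parsing collapses phasing and maps half-calls to missing", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(
    paste(c("1", "100", "m1", "A", "G", ".", ".", ".", "GT",
            "0/0", "0/1", "1|0", "./."), collapse = "\t"),
    paste(c("1", "200", "m2", "A", "G,T", ".", ".", ".", "GT",
            "1/2", "0/2", "0/0", "0/."), collapse = "\t"))), p)
  g <- read_geno_vcf(p)
  expect_equal(g$sample_ids, c("S1", "S2", "S3", "S4"))
  expect_equal(g$marker_ids, c("m1", "m2"))
  expect_equal(unname(g$calls[, "m1"]), c("0/0", "0/1", "0/1", NA))
  expect_equal(unname(g$calls[, "m2"]), c("1/2", "0/2", "0/0", NA))
  # hom-ref 1, het 2, missing 1 at m1; triallelic site has distinct classes
  tab <- table(g$calls[, "m1"])
  expect_equal(as.integer(tab[c("0/0", "0/1")]), c(1L, 2L))
  expect_equal(sum(is.na(g$calls[, "m1"])), 1L)
})

test_that("permuting allele order within unphased GTs leaves the matrix unchanged", {
  rec1 <- paste(c("1", "100", "m1", "A", "G", ".", ".", ".", "GT",
                  "0/1", "1/0", "0|1", "1|0"), collapse = "\t")
  rec2 <- paste(c("1", "100", "m1", "A", "G", ".", ".", ".", "GT",
                  "1/0", "0/1", "1|0", "0|1"), collapse = "\t")
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(rec1), p1)
  writeLines(vcf_lines(rec2), p2)
  g1 <- read_geno_vcf(p1)
  g2 <- read_geno_vcf(p2)
  expect_identical(g1$calls, g2$calls)
})

test_that("single-sample single-site VCF and degenerate VCFs behave", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(
    paste(c("1", "5", ".", "A", "G", ".", ".", ".", "GT", "0/0"),
          collapse = "\t"), samples = "only"), p)
  g <- read_geno_vcf(p)
  expect_equal(dim(g), c(1L, 1L))
  expect_equal(g$missing_counts, 0)
  expect_equal(g$marker_ids, "1:5")          # blank ID falls back to CHROM:POS
  # record without GT is a hard error
  p2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(
    paste(c("1", "5", "m1", "A", "G", ".", ".", ".", "DP", "10"),
          collapse = "\t"), samples = "only"), p2)
  expect_error(read_geno_vcf(p2), "GT")
})

test_that("VCF export round-trips the genotype-class structure", {
  sim <- simulate_geno(n_founders = 4, dups_per_founder = 2, n_markers = 15,
                       missing_rate = 0.1, seed = 5)
  p <- withr::local_tempfile(fileext = ".vcf")
  write_geno_vcf(sim$geno, p)
  g2 <- read_geno_vcf(p)
  expect_identical(g2$sample_ids, sim$geno$sample_ids)
  expect_identical(g2$marker_ids, sim$geno$marker_ids)
  expect_identical(is.na(g2$calls), is.na(sim$geno$calls))
  # same sample partition per marker even though codes changed alphabet
  for (i in seq_len(15)) {
    a <- sim$geno$calls[, i]
    b <- g2$calls[, i]
    ok <- !is.na(a)
    expect_equal(as.integer(factor(a[ok], levels = unique(a[ok]))),
                 as.integer(factor(b[ok], levels = unique(b[ok]))))
  }
})

test_that("core list and trace files round-trip and keep CV non-decreasing", {
  sim <- simulate_geno(n_founders = 3, dups_per_founder = 4, n_markers = 30,
                       missing_rate = 0, seed = 3)
  res <- select_core(sim$geno, target_cv = 100, delta = 0)
  pc <- withr::local_tempfile(fileext = ".txt")
  pt <- withr::local_tempfile(fileext = ".csv")
  write_core_list(res, pc)
  write_trace(res, pt)
  expect_identical(read_core_list(pc), res$core_ids)
  tr <- utils::read.csv(pt)
  expect_identical(names(tr),
                   c("step", "sample_id", "coverage_score", "diversity_score",
                     "cumulative_cv_percent", "n_removed_duplicates"))
  expect_true(all(diff(tr$cumulative_cv_percent) >= 0))
})
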