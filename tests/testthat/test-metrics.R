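test_that("coverage CV matches hand-derived cases", {
  # every marker has two classes; a fully-called single sample covers half
  calls <- cbind(c("AA", "AG", "AA"), c("CC", "CT", "CC"), c("GG", "GT", "GG"))
  g <- genotype_matrix(calls, c("a", "b", "c"), paste0("m", 1:3))
  T <- class_table(g)
  expect_equal(cv_coverage("a", g, T), 50)
  expect_equal(cv_coverage(g$sample_ids, g, T), 100)
  expect_equal(cv_coverage(character(0), g, T), 0)
})

test_that("CV is monotone under subset growth and matches the naive count", {
  for (r in 1:8) {
    g <- rand_geno(sample(4:10, 1), sample(4:12, 1), miss = 0.2,
                   seed = 5000 + r)
    T <- class_table(g)
    n <- nrow(g$calls)
    ord <- sample(n)
    prev <- 0
    for (k in seq_len(n)) {
      cv <- cv_coverage(ord[seq_len(k)], g, T)
      expect_equal(cv, naive_CV(g, ord[seq_len(k)]), tolerance = 1e-12)
      expect_gte(cv, prev - 1e-12)
      prev <- cv
    }
  }
})

test_that("Shannon index follows -sum p ln p over reference-allele frequencies", {
  # monomorphic collection: p_i = 1 everywhere -> SH = 0
  g0 <- genotype_matrix(matrix("AA", 3, 5), paste0("s", 1:3), paste0("m", 1:5))
  expect_equal(shannon_index(g0$sample_ids, allele_freq_table(g0)), 0)
  # two markers with p = 0.5 -> SH = 2 * (-0.5 * log 0.5) = log 2
  g1 <- genotype_matrix(rbind(c("AA", "CC"), c("GG", "TT")), c("a", "b"),
                        c("m1", "m2"))
  expect_equal(shannon_index(c("a", "b"), allele_freq_table(g1)), log(2),
               tolerance = 1e-12)
  # invariant to sample ordering, matches the naive loop
  g <- rand_geno(8, 10, miss = 0.15, seed = 61)
  A <- allele_freq_table(g)
  sub <- c("s003", "s001", "s007")
  expect_equal(shannon_index(sub, A), shannon_index(rev(sub), A))
  expect_equal(shannon_index(sub, A), naive_SH(g, sub), tolerance = 1e-12)
})

test_that("modified Rogers distance matches closed-form cases", {
  g <- genotype_matrix(rbind(c("AA", "CC"), c("GG", "TT"), c("AG", "CC")),
                       c("x", "y", "z"), c("m1", "m2"))
  A <- allele_freq_table(g)
  expect_equal(modified_rogers("x", "x", A), 0)
  expect_equal(modified_rogers("x", "y", A), 1)   # opposite homozygotes
  g2 <- genotype_matrix(rbind("AA", "AG"), c("x", "y"), "m1")
  expect_equal(modified_rogers("x", "y", allele_freq_table(g2)), 0.5)
})

test_that("MR is symmetric, bounded, zero on the diagonal, and naive-equal", {
  g <- rand_geno(10, 12, miss = 0.2, seed = 71)
  A <- allele_freq_table(g)
  M <- mr_matrix(g$sample_ids, A)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_true(all(M[!is.na(M)] >= 0 & M[!is.na(M)] <= 1 + 1e-12))
  for (r in 1:15) {
    xy <- sample(10, 2)
    expect_equal(M[xy[1], xy[2]], naive_MR(g, xy[1], xy[2]),
                 tolerance = 1e-12)
    expect_equal(modified_rogers(xy[1], xy[2], A), M[xy[1], xy[2]],
                 tolerance = 1e-12)
  }
})

test_that("MR is undefined (with a warning) when no marker is shared", {
  g <- genotype_matrix(rbind(c("AA", NA), c(NA, "CC")), c("x", "y"),
                       c("m1", "m2"))
  A <- allele_freq_table(g)
  expect_warning(v <- modified_rogers("x", "y", A), "no non-missing marker")
  expect_true(is.na(v))
})

test_that("evaluate_core assembles the standard report", {
  g <- genotype_matrix(rbind(c("AA", "AG"), c("AA", "AG"), c("GG", "GG")),
                       c("a", "b", "c"), c("m1", "m2"))
  met2 <- evaluate_core(c("a", "b"), g)
  expect_equal(met2$mr_mean, 0)
  expect_equal(met2$mr_min, 0)
  met3 <- evaluate_core(c("a", "b", "c"), g)
  pair_mrs <- c(naive_MR(g, 1, 2), naive_MR(g, 1, 3), naive_MR(g, 2, 3))
  expect_equal(met3$mr_min, min(pair_mrs), tolerance = 1e-12)
  expect_equal(met3$mr_mean, mean(pair_mrs), tolerance = 1e-12)
  expect_equal(met3$cv_percent, 100)
  met1 <- evaluate_core("a", g)
  expect_true(is.na(met1$mr_mean) && is.na(met1$mr_min))
  df <- as.data.frame(met3)
  expect_identical(names(df), c("n_samples", "MR", "Min.MR", "SH", "CV"))
})

test_that("selection trace CV agrees with the metrics-module CV", {
  sim <- simulate_geno(n_founders = 8, dups_per_founder = 3, n_markers = 120,
                       missing_rate = 0.05, seed = 13)
  T <- class_table(sim$geno)
  res <- select_core(sim$geno, target_cv = 100, delta = 0, table = T)
  expect_equal(cv_coverage(res$core_ids, sim$geno, T), res$final_cv,
               tolerance = 1e-9)
  for (k in seq_along(res$core_ids))
    expect_equal(cv_coverage(res$core_ids[seq_len(k)], sim$geno, T),
                 res$trace$cumulative_cv_percent[k], tolerance = 1e-9)
})

test_that("allele-frequency spectra compare subsets as expected", {
  g <- rand_geno(12, 40, miss = 0.1, seed = 91)
  A <- allele_freq_table(g)
  expect_equal(spectrum_max_diff(g$sample_ids, g$sample_ids, A, 0.05), 0)
  g1 <- genotype_matrix(matrix("AA", 4, 6), paste0("s", 1:4), paste0("m", 1:6))
  sp <- allele_spectrum(paste0("s", 1:4), allele_freq_table(g1), 0.1)
  expect_equal(sum(sp$counts > 0), 1L)     # all mass in the p = 1 bin
  expect_equal(sum(sp$proportion), 1)
  expect_error(allele_spectrum(paste0("s", 1:4), allele_freq_table(g1), 0),
               "bin_width")
})
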