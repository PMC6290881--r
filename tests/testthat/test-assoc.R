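uc_s361l_tab <- table2x2(10, 5894, 5, 14143)

test_that("chi-square statistics follow the closed forms, with and without continuity correction", {
  expect_equal(varcascade:::chi2_statistic(uc_s361l_tab, yates = TRUE), 8.299, tolerance = 1e-3)
  p_yates <- allelic_association_test(uc_s361l_tab, "chi2_yates")
  expect_equal(p_yates, 0.0040, tolerance = 0.01)
  p_plain <- allelic_association_test(uc_s361l_tab, "chi2")
  expect_lt(p_plain, p_yates)
  # no association on a balanced table
  expect_equal(allelic_association_test(c(5, 95, 5, 95), "chi2"), 1)
  expect_equal(allelic_association_test(c(5, 95, 5, 95), "fisher_exact"), 1)
  expect_error(allelic_association_test(c(0, 0, 3, 4), "chi2"), "degenerate")
})

test_that("continuity correction never increases the statistic; swaps leave it unchanged", {
  set.seed(5)
  for (i in 1:25) {
    tab <- rpois(4, 20) + 1
    plain <- varcascade:::chi2_statistic(tab)
    yates <- varcascade:::chi2_statistic(tab, yates = TRUE)
    expect_lte(yates, plain)
    swapped <- tab[c(3, 4, 1, 2)]  # swap rows
    expect_equal(varcascade:::chi2_statistic(swapped), plain)
    cols <- tab[c(2, 1, 4, 3)]     # swap columns
    expect_equal(varcascade:::chi2_statistic(cols), plain)
  }
})

test_that("odds ratios reproduce the published cross-products", {
  expect_equal(odds_ratio_2x2(uc_s361l_tab), 4.7991, tolerance = 1e-4)
  expect_equal(fmt_or(odds_ratio_2x2(c(13, 11589, 5, 14143))), "3.17")
  expect_equal(odds_ratio_2x2(c(5, 100, 5, 100)), 1)
  # group-swap reciprocity
  set.seed(11)
  for (i in 1:20) {
    tab <- rpois(4, 15) + 1
    expect_equal(odds_ratio_2x2(tab) * odds_ratio_2x2(tab[c(3, 4, 1, 2)]), 1)
  }
})

test_that("zero cells trigger the Haldane-Anscombe correction or an explicit error", {
  expect_equal(odds_ratio_2x2(c(0, 10, 5, 10)),
               (0.5 * 10.5) / (10.5 * 5.5))
  expect_error(odds_ratio_2x2(c(5, 0, 5, 10), zero_correction = FALSE), "undefined")
  expect_error(woolf_confidence_interval(c(0, 10, 5, 10), zero_correction = FALSE),
               "zero cell")
})

test_that("the Woolf interval matches the log-scale formula and brackets the odds ratio", {
  ci <- woolf_confidence_interval(uc_s361l_tab)
  expect_equal(unname(ci["low"]), 1.64, tolerance = 0.005)
  expect_equal(unname(ci["high"]), 14.05, tolerance = 0.005)
  expect_lt(ci["low"], odds_ratio_2x2(uc_s361l_tab))
  expect_gt(ci["high"], odds_ratio_2x2(uc_s361l_tab))
  # symmetric table brackets 1 symmetrically on the log scale
  ci_sym <- woolf_confidence_interval(c(20, 80, 20, 80))
  expect_equal(log(ci_sym[["low"]]) + log(ci_sym[["high"]]), 0, tolerance = 1e-10)
  # wider level strictly contains narrower
  ci99 <- woolf_confidence_interval(uc_s361l_tab, level = 0.99)
  expect_lt(ci99[["low"]], ci[["low"]])
  expect_gt(ci99[["high"]], ci[["high"]])
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni_correct(0.0039, 6), 0.0234)
  expect_equal(bonferroni_correct(0.018, 3), 0.054)
  expect_equal(bonferroni_correct(0.5, 6), 1)
})

test_that("allele counts and minor allele frequencies derive from genotype counts", {
  expect_equal(genotype_to_allele_counts(c(2942, 10, 0)),
               c(n_minor = 10, n_total = 5904))
  expect_equal(genotype_to_allele_counts(c(1, 1, 1)), c(n_minor = 3, n_total = 6))
  expect_equal(genotype_to_allele_counts(c(0, 0, 0)), c(n_minor = 0, n_total = 0))
  expect_equal(fmt_pct(minor_allele_frequency(c(7069, 5, 0)), 3), "0.035")
  expect_equal(fmt_pct(minor_allele_frequency(c(5749, 3, 0)), 3), "0.026")
  expect_equal(minor_allele_frequency(c(0, 10, 0)), 0.5)
  expect_error(minor_allele_frequency(c(0, 0, 0)), "n = 0")
})

test_that("the exact HWE test matches hand-checked cases", {
  # 5 minor alleles in 7074 diploids: the all-het configuration is modal
  expect_equal(hwe_exact_test(7069, 5, 0), 1)
  # strong disequilibrium: intermediate allele frequency but no heterozygotes
  expect_lt(hwe_exact_test(5, 0, 5), 0.05)
  # monomorphic site
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_error(hwe_exact_test(-1, 0, 5), "non-negative")
})

test_that("single-variant association reproduces the published UC and CD rows", {
  counts <- table1_counts()
  uc <- single_variant_association(c(2942, 10, 0), c(7069, 5, 0),
                                   phenotype = "UC", variant = "p.S361L")
  expect_equal(fmt_or(uc$or), "4.79")
  expect_lt(uc$p_corrected, 0.05)
  expect_equal(uc$p_corrected, 6 * uc$p)
  cd <- single_variant_association(c(2846, 3, 0), c(7069, 5, 0))
  expect_equal(fmt_or(cd$or), "1.49")
  # identical case/control counts: no association
  null <- single_variant_association(c(100, 5, 0), c(100, 5, 0),
                                     method = "fisher_exact")
  expect_equal(null$or, 1)
  expect_equal(null$p, 1)
})

test_that("the combined carrier analysis reproduces the published pooled rows", {
  counts <- table1_counts()
  panel <- function(cohort) t(vapply(c("p.S361L", "p.R801H"),
                                     function(v) varcascade:::counts_for(counts, cohort, v),
                                     numeric(3)))
  ibd <- combined_carrier_analysis(panel("IBD"), panel("control"), phenotype = "IBD")
  expect_equal(fmt_or(ibd$or), "2.77")
  expect_equal(fmt_pct(ibd$freq_case, 2), "0.28")
  expect_equal(fmt_pct(ibd$freq_control, 2), "0.10")
  expect_equal(ibd$n_case, 5752)
  uc <- combined_carrier_analysis(panel("UC"), panel("control"), phenotype = "UC")
  expect_equal(fmt_or(uc$or), "3.73")
  cd <- combined_carrier_analysis(panel("CD"), panel("control"), phenotype = "CD")
  expect_equal(fmt_or(cd$or), "1.77")
  # allele and carrier bases agree closely when no homozygotes exist
  ibd_carrier <- combined_carrier_analysis(panel("IBD"), panel("control"),
                                           basis = "carrier", phenotype = "IBD")
  expect_lt(abs(ibd$or - ibd_carrier$or) / ibd$or, 0.005)
})

test_that("a single-variant panel collapses to the single-variant carrier test", {
  case <- c(2942, 10, 0)
  ctrl <- c(7069, 5, 0)
  combined <- combined_carrier_analysis(matrix(case, nrow = 1), matrix(ctrl, nrow = 1),
                                        basis = "carrier", m_tests = 6)
  single <- single_variant_association(case, ctrl, basis = "carrier", m_tests = 6)
  expect_equal(combined$or, single$or)
  expect_equal(combined$p, single$p)
})

test_that("mismatched panels are rejected", {
  expect_error(combined_carrier_analysis(matrix(1:6, 2), matrix(1:3, 1)),
               "mismatched")
})

test_that("samples missing the whole panel are dropped; partial missingness is kept", {
  gm <- make_gm(c("a", "b", "c"), list(
    v1 = c(NA, 1L, 0L),
    v2 = c(NA, NA, 0L)
  ))
  res <- drop_fully_missing_samples(gm, cohort = c(a = "CD", b = "CD", c = "control"))
  expect_equal(rownames(res$genotypes), c("b", "c"))
  expect_equal(res$removed[["CD"]], 1L)
  # no missingness: identity
  full <- make_gm(c("a", "b"), list(v1 = c(0L, 1L), v2 = c(1L, 0L)))
  expect_equal(drop_fully_missing_samples(full)$genotypes, full)
  expect_error(drop_fully_missing_samples(full[, 0, drop = FALSE]), "at least one")
})

test_that("call rate counts non-missing calls", {
  gm <- make_gm(sprintf("s%d", 1:100),
                list(v = c(rep(1L, 50), rep(0L, 49), NA)))
  expect_equal(variant_call_rate(gm, "v"), 0.99)
  gm2 <- make_gm(c("a", "b"), list(v = c(0L, 1L)))
  expect_equal(variant_call_rate(gm2, "v"), 1)
})

test_that("genotype count tables read and validate", {
  counts <- table1_counts()
  expect_equal(nrow(counts), 8)
  expect_equal(varcascade:::counts_for(counts, "UC", "p.S361L"), c(2942, 10, 0))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cohort\tvariant\tn_hom_ref\tn_het\tn_hom_alt",
               "CD\tv1\t10\t-2\t0"), bad)
  expect_error(read_genotype_counts(bad), "row 1.*n_het")
})
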