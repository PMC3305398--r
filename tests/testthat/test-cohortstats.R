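test_that("Hardy-Weinberg expectations: closed forms and normalization", {
  expect_equal(unname(hwe_genotype_freqs(1)), c(0, 0, 1))
  expect_equal(unname(hwe_genotype_freqs(0)), c(1, 0, 0))
  f <- hwe_genotype_freqs(0.52)
  expect_equal(unname(f["hom_alt"]), 0.2704)
  f13 <- hwe_genotype_freqs(0.13)
  expect_equal(unname(f13["het"]), 0.2262)
  expect_equal(unname(f13["hom_alt"]), 0.0169)
  for (q in seq(0, 1, by = 0.05))
    expect_equal(sum(hwe_genotype_freqs(q)), 1, tolerance = 1e-12)
})

test_that("probability of zero homozygotes: bounds and monotonicity", {
  expect_equal(prob_no_homozygotes(0, 50)$p, 1)
  expect_equal(prob_no_homozygotes(1, 1)$p, 0)
  res <- prob_no_homozygotes(0.13, 824)
  expect_equal(res$p, (1 - 0.13^2)^824, tolerance = 1e-12)
  expect_equal(res$expected, 824 * 0.0169, tolerance = 1e-12)
  p_q <- vapply(seq(0.01, 0.5, by = 0.05), function(q)
    prob_no_homozygotes(q, 100)$p, numeric(1L))
  expect_true(all(diff(p_q) < 0))
  p_n <- vapply(c(10, 50, 200, 824), function(n)
    prob_no_homozygotes(0.13, n)$p, numeric(1L))
  expect_true(all(diff(p_n) < 0))
})

test_that("segregation tests: hand-computed chi-square, G and exact agreement", {
  counts <- c(26, 56, 23)
  pe <- segregation_test(counts, c(1, 2, 1), "pearson")
  # hand computation: (26-26.25)^2/26.25 + (56-52.5)^2/52.5 +
  # (23-26.25)^2/26.25 = 0.638095...
  expect_equal(pe$statistic, 0.25^2 / 26.25 + 3.5^2 / 52.5 + 3.25^2 / 26.25,
               tolerance = 1e-9)
  expect_equal(pe$df, 2)
  expect_equal(pe$p_value, stats::pchisq(pe$statistic, 2, lower.tail = FALSE))
  expect_equal(round(pe$p_value, 2), 0.73)
  g <- segregation_test(counts, c(1, 2, 1), "g_test")
  expect_equal(g$statistic,
               2 * sum(counts * log(counts / c(26.25, 52.5, 26.25))),
               tolerance = 1e-9)
  expect_equal(round(g$p_value, 2), 0.72)
  # frozen value from an independent full-enumeration oracle (all
  # compositions of 105 into three classes, probability ordering)
  ex <- segregation_test(counts, c(1, 2, 1), "exact_multinomial")
  expect_equal(ex$p_value, 0.7481806503, tolerance = 1e-8)
  expect_lt(abs(ex$p_value - pe$p_value), 0.025)
  # exact proportions give a null result
  perfect <- segregation_test(c(25, 50, 25), c(1, 2, 1), "pearson")
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)
  expect_error(segregation_test(c(5, 5), c(1, 0), "pearson"),
               "zero expected")
})

test_that("exact genotype-by-outcome test: 2x2 oracle and invariances", {
  # independence with identical row proportions
  even <- matrix(c(10, 30, 5, 15), 2, byrow = TRUE)
  expect_equal(genotype_outcome_exact_test(even)$p_value, 1)
  # 2x2 tables equal the classical two-sided Fisher exact test
  set.seed(21)
  for (r in 1:10) {
    tab <- matrix(rpois(4, 8) + 1L, 2)
    expect_equal(genotype_outcome_exact_test(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # 3x2 tables (N <= 40) equal fisher.test's network enumeration
  for (r in 1:10) {
    tab <- matrix(rpois(6, 4) + 1L, 3)
    expect_equal(genotype_outcome_exact_test(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  # row/column permutation symmetry, p in (0, 1]
  tab <- rbind(c(0, 26), c(1, 55), c(17, 6))
  p <- genotype_outcome_exact_test(tab)$p_value
  expect_gt(p, 0)
  expect_lte(p, 1)
  expect_equal(genotype_outcome_exact_test(tab[c(3, 1, 2), ])$p_value, p)
  expect_equal(genotype_outcome_exact_test(tab[, 2:1])$p_value, p)
  expect_error(genotype_outcome_exact_test(rbind(c(0, 0), c(1, 2))),
               "margins")
})

test_that("linkage disequilibrium: coupling, independence, correlation oracle", {
  perfect <- two_locus_ld(c(AB = 50, Ab = 0, aB = 0, ab = 50))
  expect_equal(perfect$D_prime, 1)
  expect_equal(perfect$r2, 1)
  indep <- two_locus_ld(c(AB = 25, Ab = 25, aB = 25, ab = 25))
  expect_equal(indep$D, 0)
  expect_equal(indep$r2, 0)
  near <- two_locus_ld(c(AB = 49, Ab = 1, aB = 0, ab = 50))
  expect_equal(near$D_prime, 1)
  # correlation oracle: r2 equals squared Pearson correlation of the
  # allele indicator variables over the 100 haplotypes
  x <- c(rep(1, 50), rep(0, 50))           # A allele indicator
  y <- c(rep(1, 49), 0, rep(0, 50))        # B allele indicator
  expect_equal(near$r2, stats::cor(x, y)^2, tolerance = 1e-12)
  expect_error(two_locus_ld(c(AB = 10, Ab = 10, aB = 0, ab = 0)),
               "monomorphic")
  # 0 <= r2 <= |D'| <= 1 across random haplotype tables
  set.seed(31)
  for (r in 1:25) {
    counts <- rmultinom(1, 60, prob = runif(4, 0.05, 1))[, 1]
    if (any(c(counts[1] + counts[2], counts[3] + counts[4],
              counts[1] + counts[3], counts[2] + counts[4]) == 0)) next
    ld <- two_locus_ld(counts)
    expect_gte(ld$r2, -1e-12)
    expect_lte(ld$r2, abs(ld$D_prime) + 1e-12)
    expect_lte(abs(ld$D_prime), 1 + 1e-12)
  }
})

test_that("expected affected offspring of carrier and homozygous sires", {
  expect_equal(expected_affected_offspring(0.13, "carrier"), 0.065)
  expect_equal(expected_affected_offspring(0, "carrier"), 0)
  expect_equal(expected_affected_offspring(0.13, "hom"), 0.13)
})

test_that("carrier frequency comparison matches the 2x2 exact oracle", {
  res <- carrier_freq_comparison(29, 86, 211, 829)
  expect_equal(res$freq1, 29 / 86)
  expect_equal(res$freq2, 211 / 829)
  expect_equal(round(res$freq1, 2), 0.34)
  expect_equal(round(res$freq2, 2), 0.25)
  oracle <- stats::fisher.test(matrix(c(29, 57, 211, 618), 2,
                                      byrow = TRUE))$p.value
  expect_equal(res$p_value, oracle, tolerance = 1e-9)
  expect_gt(res$p_value, 0.05)  # not significantly different
  expect_equal(carrier_freq_comparison(10, 40, 20, 80)$p_value, 1)
})

test_that("growth regression: deficit sign, identical-data zero difference", {
  # built-in deficit: affected slope lower inside the post-onset window
  cohort <- simulate_cohort(rmendelian_dosages(105, seed = 4),
                            outcome_model(), seed = 4)
  gr <- growth_group_regression(cohort, response = "weight",
                                window = c(180, 360))
  aff <- gr$groups$slope[gr$groups$group == "affected"]
  una <- gr$groups$slope[gr$groups$group == "unaffected"]
  expect_lt(aff, una)

  # duplicated measures labelled as two groups: slope difference exactly 0
  half <- as.data.frame(cohort[cohort$genotype == "AA", ])
  twin <- transform(half, calf = paste0(calf, "_t"), genotype = "GG")
  dup <- cohort_table(rbind(half, twin))
  gr0 <- growth_group_regression(dup, response = "weight",
                                 window = c(0, 360))
  expect_equal(diff(gr0$groups$slope), 0, tolerance = 1e-12)
  expect_error(
    growth_group_regression(cohort, grouping = list(a = "AA", b = "AG"),
                            response = "weight", window = c(359, 360)),
    "singular|at least 2")
})

test_that("growth regression null calibration: interaction p uniform", {
  # identical generating law for all genotypes: the age-by-group
  # interaction p-value should be Uniform(0, 1) across simulated cohorts
  model <- outcome_model(gg_mortality = 0, baseline_mortality = 0,
                         stature_deficit = 0)
  pvals <- vapply(1:200, function(s) {
    cohort <- simulate_cohort(rmendelian_dosages(60, seed = 5000 + s),
                              model, seed = 6000 + s)
    growth_group_regression(cohort, response = "weight",
                            window = c(180, 360))$interaction_p
  }, numeric(1L))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.001)
})
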