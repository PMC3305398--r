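#!/usr/bin/env Rscript
# Stage 3: population-genetic and cohort statistics, twice over: on the
# published worked numbers (printed genotype counts, allele frequencies and
# haplotype counts), and on the synthetic prospective cohort from stage 1.

suppressPackageStartupMessages(library(stuntscan))

out <- file.path("results", "cohort_stats")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
report <- list()

cat("== Published worked numbers ==\n")

# expected homozygote fraction at the case haplotype frequency
f52 <- hwe_genotype_freqs(0.52)
cat(sprintf("HWE at q=0.52: expected homozygotes %.1f%%\n",
            100 * f52[["hom_alt"]]))
report$hwe_hom_alt_52 <- f52[["hom_alt"]]

# no homozygotes among 824 genotyped healthy adults at q = 0.13
nh <- prob_no_homozygotes(0.13, 824)
cat(sprintf("P(no homozygote | q=0.13, N=824) = %.2e (%.1f expected)\n",
            nh$p, nh$expected))
report$p_no_homozygotes <- nh$p

# 1:2:1 segregation in the 105-calf cohort
counts <- c(AA = 26, AG = 56, GG = 23)
for (m in c("pearson", "g_test", "exact_multinomial")) {
  s <- segregation_test(counts, c(1, 2, 1), m)
  cat(sprintf("segregation %-18s p = %.3f\n", m, s$p_value))
  report[[paste0("segregation_", m)]] <- s$p_value
}

# mortality: 18 of 105 died or culled, 17 of them homozygous mutants
tab <- rbind(AA = c(0, 26), AG = c(1, 55), GG = c(17, 6))
ex <- genotype_outcome_exact_test(tab)
cat(sprintf("genotype x outcome exact p = %.3g (%d tables)\n",
            ex$p_value, ex$n_tables))
report$outcome_exact_p <- ex$p_value

# variant vs risk-haplotype linkage disequilibrium (near-perfect coupling)
ld <- two_locus_ld(c(AB = 49, Ab = 1, aB = 0, ab = 50))
cat(sprintf("example LD: D' = %.3f, r2 = %.3f\n", ld$D_prime, ld$r2))
report$ld <- ld[c("D", "D_prime", "r2")]

# expected affected offspring of carrier sires at q = 0.13
cat(sprintf("expected affected offspring (carrier sire, q=0.13): %.1f%%\n",
            100 * expected_affected_offspring(0.13, "carrier")))
report$expected_affected <- expected_affected_offspring(0.13, "carrier")

# carrier frequency in non-homozygous cases vs controls
cmp <- carrier_freq_comparison(29, 86, 211, 829)
cat(sprintf("carrier freq %.0f%% vs %.0f%%, exact p = %.2f\n",
            100 * cmp$freq1, 100 * cmp$freq2, cmp$p_value))
report$carrier_comparison <- cmp

cat("\n== Synthetic prospective cohort ==\n")
cohort <- read_cohort_table(file.path("results", "synthetic_study",
                                      "cohort.csv"))
calves <- cohort_calves(cohort)
cnt <- table(factor(calves$genotype, c("AA", "AG", "GG")))
cat(sprintf("genotypes at birth AA/AG/GG: %s\n", paste(cnt, collapse = "/")))
seg <- segregation_test(as.integer(cnt), c(1, 2, 1))
cat(sprintf("segregation vs 1:2:1: chi2 = %.2f, p = %.2f\n",
            seg$statistic, seg$p_value))
events <- calves$status != "alive"
otab <- cbind(tapply(events, calves$genotype, sum),
              tapply(!events, calves$genotype, sum))
oex <- genotype_outcome_exact_test(otab)
cat(sprintf("deaths/cullings: %d, genotype x outcome exact p = %.3g\n",
            sum(events), oex$p_value))
for (resp in c("weight", "height")) {
  gr <- growth_group_regression(cohort, response = resp,
                                window = c(180, 360))
  cat(sprintf("%s growth 180-360 d: slopes %.3f (GG) vs %.3f (AA/AG), interaction p = %.3g\n",
              resp, gr$groups$slope[gr$groups$group == "affected"],
              gr$groups$slope[gr$groups$group == "unaffected"],
              gr$interaction_p))
  report[[paste0("growth_", resp)]] <- list(groups = gr$groups,
                                            interaction_p = gr$interaction_p)
}
report$synthetic <- list(genotype_counts = as.integer(cnt),
                         segregation_p = seg$p_value,
                         outcome_exact_p = oex$p_value)

if (requireNamespace("jsonlite", quietly = TRUE))
  jsonlite::write_json(report, file.path(out, "cohort_stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
cat("\nReport written to", file.path(out, "cohort_stats.json"), "\n")
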