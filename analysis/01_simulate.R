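#!/usr/bin/env Rscript
# Stage 1: generate one synthetic study — a multi-generation AI-sire
# genealogy descending from a single heterozygous founder, SNP genotypes
# with the dropped ancestral haplotype, a prospective carrier x carrier
# cohort, and a qPCR plate — and write every table in its text dialect.
# Later stages re-read these files, exercising the full IO surface.

suppressPackageStartupMessages(library(stuntscan))

seed <- 1L
out <- file.path("results", "synthetic_study")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

config <- sim_config(seed = seed)
model <- outcome_model()
study <- simulate_study(config, model, seed = seed)

write_pedigree(study$pedigree, file.path(out, "pedigree.csv"), "csv")
write_pedigree(study$pedigree, file.path(out, "pedigree.ped"), "linkage")
write_genotype_matrix(study$genotypes, file.path(out, "genotypes.csv"),
                      "csv_matrix")
write_cohort_table(study$cohort, file.path(out, "cohort.csv"))
write_qpcr_table(study$qpcr, file.path(out, "qpcr.csv"))
write.csv(study$truth, file.path(out, "truth.csv"), row.names = FALSE)
writeLines(c(sprintf("seed: %d", seed),
             sprintf("mutation_pos: %d", study$mutation_pos),
             sprintf("tau_true: %g", config$tau_true),
             sprintf("q0: %g", config$q0),
             sprintf("f_skip_true: %g", study$splice_truth[["f_skip"]]),
             sprintf("d_nmrd_true: %g", study$splice_truth[["d_nmrd"]])),
           file.path(out, "truth_params.txt"))

cat("Synthetic study written to", out, "\n")
cat(sprintf("  pedigree: %d individuals (%d founders, %d generations)\n",
            nrow(study$pedigree), n_founders(study$pedigree),
            max(study$pedigree$generation)))
cat(sprintf("  genotypes: %d samples x %d markers\n",
            nrow(study$genotypes$geno), ncol(study$genotypes$geno)))
cat(sprintf("  true carriers: %d; homozygous for the lineage haplotype: %d\n",
            sum(study$truth$carrier), sum(study$truth$lineage_dosage == 2)))
cat(sprintf("  cohort: %d calves; qPCR: %d rows\n",
            length(unique(study$cohort$calf)), nrow(study$qpcr)))
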