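#!/usr/bin/env Rscript
# Stage 5: selective-sweep test by gene dropping. Re-reads the synthetic
# genealogy, takes the realized carrier count among descendant males as
# the observation, computes the Mendelian-null tail probability at three
# outside-lineage allele frequencies, and scans the transmission rate for
# the value most compatible with the observation.

suppressPackageStartupMessages(library(stuntscan))

out <- file.path("results", "genedrop")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ped <- read_pedigree(file.path("results", "synthetic_study", "pedigree.csv"),
                     "csv")
truth <- read.csv(file.path("results", "synthetic_study", "truth.csv"))
founder <- "M1"
target <- ped$id[ped$sex == "M" & !ped$founder]
k_obs <- sum(truth$carrier[truth$id %in% target])
cat(sprintf("Observed carriers among %d descendant males: %d (%.0f%%)\n",
            length(target), k_obs, 100 * k_obs / length(target)))

cat("\nMendelian-null upper-tail probabilities (10,000 simulations):\n")
tails <- data.frame()
for (q0 in c(0, 0.01, 0.05)) {
  d <- gene_drop(ped, founder, target, tau = 0.5, q0 = q0,
                 n_sims = 10000, seed = 1)
  tp <- tail_probability(d, k_obs)
  cat(sprintf("  q0 = %.2f: P(count >= %d) = %.4f (se %.4f)\n",
              q0, k_obs, tp$p, tp$se))
  tails <- rbind(tails, data.frame(q0 = q0, k_obs = k_obs, p = tp$p,
                                   se = tp$se))
  write.csv(data.frame(count = as.integer(names(d$counts)),
                       n_sims = as.integer(d$counts)),
            file.path(out, sprintf("null_histogram_q0_%g.csv", q0)),
            row.names = FALSE)
}
write.csv(tails, file.path(out, "tail_probabilities.csv"),
          row.names = FALSE)

cat("\nTransmission-rate compatibility scan (2,000 sims/point, step 0.02):\n")
scan <- scan_transmission(ped, founder, target, k_obs,
                          tau_grid = seq(0, 1, by = 0.02), q0 = 0.01,
                          n_sims = 2000, seed = 1)
write.csv(scan$profile, file.path(out, "tau_scan.csv"), row.names = FALSE)
cat(sprintf("  most compatible transmission rate tau* = %.2f (true value used by the generator: 0.60)\n",
            scan$tau_star))
cat(sprintf("  exact-hit count at tau*: %d of %d simulations\n",
            max(scan$profile$n_exact), scan$n_sims))
cat("Profiles written to", out, "\n")
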