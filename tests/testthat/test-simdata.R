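small_cfg <- function(...) {
  sim_config(n_generations = 3, n_founder_males = 2, n_founder_females = 6,
             max_matings = 6, chrom_length = 2e6, marker_density = 10,
             ...)
}

test_that("pedigree simulation: trio, determinism, structure", {
  trio_cfg <- sim_config(n_generations = 1, n_founder_males = 1,
                         n_founder_females = 1, sibship_lambda = 1e-9,
                         max_matings = 1, seed = 2)
  trio <- simulate_pedigree(trio_cfg)
  expect_equal(nrow(trio), 3L)  # zero-truncated sibship => exactly 1 calf
  expect_equal(n_founders(trio), 2L)

  cfg <- small_cfg(seed = 11)
  ped1 <- simulate_pedigree(cfg)
  ped2 <- simulate_pedigree(cfg)
  expect_identical(ped1, ped2)
  # offspring of generation g have parents of earlier generations
  gen <- ped1$generation[match(ped1$id, ped1$id)]
  for (i in which(!ped1$founder)) {
    expect_lt(ped1$generation[match(ped1$sire[i], ped1$id)],
              ped1$generation[i])
    expect_lt(ped1$generation[match(ped1$dam[i], ped1$id)],
              ped1$generation[i])
  }
})

test_that("pedigree simulation reports extinction with a remedy", {
  cfg <- sim_config(n_generations = 4, n_founder_males = 1,
                    n_founder_females = 1, sibship_lambda = 1e-9,
                    max_matings = 1, seed = 3)
  # a 1-calf-per-generation line dies out as soon as the calf's sex
  # mismatches the required role
  expect_error(simulate_pedigree(cfg), "sibship_lambda|extinct")
})

test_that("haplotype dropping: no recombination makes lineage homozygotes fully homozygous", {
  cfg <- small_cfg(recomb_rate = 0, q0 = 0, tau_true = 0.6, seed = 21)
  ped <- simulate_pedigree(cfg)
  dr <- drop_haplotypes(ped, cfg)
  gg <- dr$truth$id[dr$truth$lineage_dosage == 2L]
  expect_gt(length(gg), 0)
  for (id in gg)
    expect_true(all(dr$genotypes$geno[id, ] %in% c(0L, 2L)))
})

test_that("haplotype dropping: tau 0 with q0 0 confines the allele to the founder", {
  cfg <- small_cfg(tau_true = 0, q0 = 0, seed = 22)
  ped <- simulate_pedigree(cfg)
  dr <- drop_haplotypes(ped, cfg)
  carriers <- dr$truth$id[dr$truth$carrier]
  expect_equal(carriers, cfg$mutation_founder)
})

test_that("haplotype dropping transmits at the configured rate (binomial oracle)", {
  n_off <- 10000
  ped <- pedigree(c("M1", "F0", paste0("C", seq_len(n_off))),
                  c(NA, NA, rep("M1", n_off)),
                  c(NA, NA, rep("F0", n_off)),
                  c("M", "F", rep("F", n_off)))
  cfg <- sim_config(tau_true = 0.5, q0 = 0, chrom_length = 2e6,
                    marker_density = 5, seed = 5)
  dr <- drop_haplotypes(ped, cfg)
  frac <- mean(dr$truth$carrier[dr$truth$id != "M1" & dr$truth$id != "F0"])
  se <- sqrt(0.25 / n_off)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("carrier probabilities match exact enumeration under Mendelian dropping", {
  # Monte-Carlo carrier frequency from the haplotype dropper vs the exact
  # per-individual probability from the gene-dropping enumerator
  ped <- fixture_f1()
  cfg <- sim_config(tau_true = 0.5, q0 = 0, chrom_length = 1e6,
                    marker_density = 5, seed = 31)
  n_rep <- 400
  hits <- setNames(numeric(length(f1_target)), f1_target)
  for (r in seq_len(n_rep)) {
    dr <- drop_haplotypes(ped, cfg, seed = 1000 + r)
    hits <- hits + dr$truth$carrier[match(f1_target, dr$truth$id)]
  }
  for (id in f1_target) {
    p_exact <- marginal_carrier_prob(ped, "M1", id, tau = 0.5, q0 = 0)
    se <- sqrt(p_exact * (1 - p_exact) / n_rep)
    expect_lt(abs(hits[[id]] / n_rep - p_exact), 4 * se + 1e-9)
  }
})

test_that("cohort simulation: boundary mortality settings behave exactly", {
  dos <- rmendelian_dosages(120, seed = 41)
  all_die <- simulate_cohort(dos, outcome_model(gg_mortality = 1,
                                                baseline_mortality = 0),
                             seed = 42)
  calves <- cohort_calves(all_die)
  gg <- calves[calves$genotype == "GG", ]
  expect_true(all(gg$status != "alive"))
  expect_true(all(gg$event_age <= 210))
  expect_true(all(calves$status[calves$genotype != "GG"] == "alive"))

  none <- simulate_cohort(dos, outcome_model(gg_mortality = 0,
                                             baseline_mortality = 0,
                                             stature_deficit = 0),
                          seed = 43)
  expect_true(all(cohort_calves(none)$status == "alive"))
})

test_that("cohort simulation reproduces the configured homozygote mortality", {
  # Monte-Carlo oracle: mean GG death fraction over 200 cohorts of 105
  model <- outcome_model(baseline_mortality = 0)
  set.seed(3)
  dead <- 0L; total <- 0L
  for (r in 1:200) {
    calves <- cohort_calves(simulate_cohort(rmendelian_dosages(105), model))
    gg <- calves$genotype == "GG"
    dead <- dead + sum(gg & calves$status != "alive")
    total <- total + sum(gg)
  }
  p_hat <- dead / total
  se <- sqrt((1 / 3) * (2 / 3) / total)
  expect_lt(abs(p_hat - 1 / 3), 2 * se)
})

test_that("qPCR simulation matches the closed-form Cq difference", {
  q <- simulate_qpcr(0.8, 0.5, noise_sd = 0, seed = 51)
  cq <- function(s, g) mean(q$cq[q$sample == s & q$target == g &
                                   is.na(q$dilution)])
  # truth (f_skip .8, f_cryptic .2, d .5): surviving exon-2 level 0.1
  expect_equal(cq("MUT", "exon2") - cq("WT", "exon2"), log2(10),
               tolerance = 1e-12)
  expect_equal(cq("MUT", "exon3") - cq("WT", "exon3"), -log2(0.9),
               tolerance = 1e-12)
  expect_equal(cq("MUT", "ACTB"), cq("WT", "ACTB"))
})

test_that("qPCR simulation flags unamplifiable targets and is reproducible", {
  q <- simulate_qpcr(1, 0.3, noise_sd = 0.1, seed = 52)
  expect_true(all(is.na(q$cq[q$sample == "MUT" & q$target == "exon2"])))
  expect_identical(simulate_qpcr(0.7, 0.4, noise_sd = 0.2, seed = 53),
                   simulate_qpcr(0.7, 0.4, noise_sd = 0.2, seed = 53))
  expect_error(simulate_qpcr(0.8, 0.5, efficiencies = c(exon2 = 0, exon3 = 2,
                                                        ACTB = 2, YWHAZ = 2)),
               "exceed 1")
})

test_that("splice pipeline recovers the truth from simulated qPCR data", {
  # exact recovery with noise-free data across a truth grid
  for (f in c(0.2, 0.5, 0.8)) for (d in c(0.1, 0.55, 0.9)) {
    sp <- splice_pipeline(simulate_qpcr(f, d, noise_sd = 0, seed = 61))
    expect_equal(sp$estimate$f_skip, f, tolerance = 1e-9)
    expect_equal(sp$estimate$d_nmrd, d, tolerance = 1e-9)
  }
  # parameter recovery within +-0.05 at Cq noise sd 0.1, 3 replicates,
  # at truth points where both parameters are identified (f_cryptic not
  # small; a small exon-2-retaining fraction leaves d_nmrd weakly
  # identified because it divides by f_cryptic)
  for (tr in list(c(0.44, 0.95), c(0.2, 0.5))) {
    err_f <- err_d <- numeric(25)
    for (r in 1:25) {
      sp <- suppressWarnings(
        splice_pipeline(simulate_qpcr(tr[1], tr[2], noise_sd = 0.1,
                                      seed = 700 + r)))
      err_f[r] <- sp$estimate$f_skip - tr[1]
      err_d[r] <- sp$estimate$d_nmrd - tr[2]
    }
    expect_lt(mean(abs(err_f)), 0.05)
    expect_lt(mean(abs(err_d)), 0.05)
  }
  # at a spleen-like truth (f_skip 0.8) the skip fraction itself is still
  # recovered to +-0.05
  err_f <- numeric(25)
  for (r in 1:25) {
    sp <- suppressWarnings(
      splice_pipeline(simulate_qpcr(0.8, 0.55, noise_sd = 0.1,
                                    seed = 800 + r)))
    err_f[r] <- sp$estimate$f_skip - 0.8
  }
  expect_lt(mean(abs(err_f)), 0.05)
})
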