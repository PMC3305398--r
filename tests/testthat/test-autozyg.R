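test_that("an all-homozygous chromosome yields one spanning segment", {
  g <- rep(c(0L, 2L), 50)
  gm <- toy_genotype_matrix(S1 = g)
  seg <- detect_roh(gm, "S1", min_markers = 20, max_het = 0,
                    max_missing = 0)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, gm$map$pos[1L])
  expect_equal(seg$end, gm$map$pos[100L])
  expect_equal(seg$n_markers, 100L)
})

test_that("alternating het/hom calls yield no segment when het is disallowed", {
  g <- rep(c(0L, 1L), 50)
  gm <- toy_genotype_matrix(S1 = g)
  seg <- detect_roh(gm, "S1", min_markers = 2, max_het = 0,
                    max_missing = 0)
  expect_equal(nrow(seg), 0L)
})

test_that("ROH detection equals the brute-force window oracle", {
  for (seed in c(5, 6, 7)) {
    set.seed(seed)
    n <- 500
    g <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                prob = c(0.45, 0.08, 0.45, 0.02))
    pos <- sort(sample.int(5e6, n))
    gm <- toy_genotype_matrix(S1 = g, pos = pos)
    for (params in list(list(mm = 20, mh = 1, ms = 2, gap = 1e6),
                        list(mm = 10, mh = 0, ms = 1, gap = 2e5))) {
      seg <- detect_roh(gm, "S1", min_markers = params$mm,
                        max_het = params$mh, max_missing = params$ms,
                        max_gap_bp = params$gap)
      oracle <- oracle_roh(g, pos, params$mm, params$mh, params$ms,
                           params$gap)
      if (is.null(oracle)) {
        expect_equal(nrow(seg), 0L)
      } else {
        expect_equal(seg$start, oracle$start)
        expect_equal(seg$end, oracle$end)
        expect_equal(seg$n_markers, oracle$n_markers)
      }
    }
  }
})

test_that("ROH detection is idempotent and marker-name invariant", {
  set.seed(8)
  g <- sample(c(0L, 1L, 2L), 300, replace = TRUE, prob = c(0.46, 0.08, 0.46))
  gm <- toy_genotype_matrix(S1 = g)
  seg1 <- detect_roh(gm, "S1")
  seg2 <- detect_roh(gm, "S1")
  expect_identical(seg1, seg2)
  gm2 <- gm
  gm2$map$marker <- paste0("renamed_", seq_along(gm2$map$marker))
  colnames(gm2$geno) <- gm2$map$marker
  seg3 <- detect_roh(gm2, "S1")
  expect_equal(seg3$start, seg1$start)
  expect_equal(seg3$end, seg1$end)
})

test_that("unsorted markers are rejected", {
  gm <- toy_genotype_matrix(S1 = rep(0L, 10))
  gm$map$pos[3] <- gm$map$pos[5]  # break sortedness behind the constructor
  expect_error(detect_roh(gm, "S1"), "unsorted")
})

test_that("the shared interval reproduces the printed-boundary arithmetic", {
  # two cases homozygous over [100727788, 104017608] with flanking
  # heterozygous markers delimiting the shared segment
  core <- c(100727788L, 101500000L, 102500000L, 103200000L, 104017608L)
  pos <- c(100000000L, 100500000L, core, 104500000L, 105000000L)
  n <- length(pos)
  mk_case <- function(het_left, het_right) {
    g <- rep(0L, n)
    g[pos < 100727788] <- het_left
    g[pos > 104017608] <- het_right
    g
  }
  gm <- toy_genotype_matrix(case1 = mk_case(1L, 1L), case2 = mk_case(1L, 1L),
                            pos = pos)
  iv <- shared_autozygous_interval(gm, c("case1", "case2"), min_markers = 5,
                                   max_het = 0, max_missing = 0,
                                   max_gap_bp = 5e6)
  expect_equal(iv$start, 100727788)
  expect_equal(iv$end, 104017608)
  expect_equal(iv$support, 2L)
  expect_equal(iv$length_bp, 3289820)
  expect_equal(signif(iv$length_bp / 1e6, 2), 3.3)
})

test_that("shared interval: degenerate overlap collapses to one marker", {
  # case ROHs overlap at exactly one marker position
  g1 <- c(rep(0L, 20), rep(1L, 19))
  g2 <- c(rep(1L, 19), rep(0L, 20))
  gm <- toy_genotype_matrix(case1 = g1, case2 = g2)
  iv <- shared_autozygous_interval(gm, c("case1", "case2"), min_markers = 5,
                                   max_het = 0, max_missing = 0)
  expect_equal(iv$support, 2L)
  expect_equal(iv$start, iv$end)
  expect_equal(iv$start, gm$map$pos[20L])
})

test_that("every shared interval is contained in each supporting case ROH", {
  cfg <- sim_config(seed = 17)
  ped <- simulate_pedigree(cfg)
  dr <- drop_haplotypes(ped, cfg)
  cases <- dr$truth$id[dr$truth$lineage_dosage == 2L]
  expect_gte(length(cases), 2L)
  cases <- utils::head(cases, 8L)
  iv <- shared_autozygous_interval(dr$genotypes, cases)
  n_contain <- 0L
  for (s in cases) {
    roh <- detect_roh(dr$genotypes, s)
    n_contain <- n_contain +
      any(roh$chrom == iv$chrom & roh$start <= iv$start & roh$end >= iv$end)
  }
  expect_equal(n_contain, iv$support)
})

test_that("without recombination the shared interval approaches the dropped haplotype", {
  cfg <- sim_config(n_generations = 3, n_founder_males = 2,
                    n_founder_females = 8, max_matings = 8,
                    recomb_rate = 0, q0 = 0, seed = 19)
  ped <- simulate_pedigree(cfg)
  dr <- drop_haplotypes(ped, cfg)
  cases <- dr$truth$id[dr$truth$lineage_dosage == 2L]
  expect_gte(length(cases), 2L)
  iv <- shared_autozygous_interval(dr$genotypes, cases)
  # homozygosity spans the full marker range of the founder haplotype
  expect_equal(iv$start, dr$genotypes$map$pos[1L])
  expect_equal(iv$end, utils::tail(dr$genotypes$map$pos, 1L))
  expect_equal(iv$support, length(cases))
})

test_that("state frequency contrast matches direct counting", {
  # all haplotypes in one state
  states <- matrix("s1", nrow = 4, ncol = 2)
  out <- state_frequency_contrast(states, rep(c("case", "control"), 2))
  expect_equal(out$freq_case, 1)
  expect_equal(out$freq_control, 1)

  # constructed contrast: state X on 52% of case and 12% of control
  # haplotypes (50 cases, 50 controls)
  case_h <- c(rep("X", 52), rep("Y", 48))
  ctrl_h <- c(rep("X", 12), rep("Y", 88))
  states <- rbind(matrix(case_h, ncol = 2), matrix(ctrl_h, ncol = 2))
  group <- c(rep("case", 50), rep("control", 50))
  out <- state_frequency_contrast(states, group)
  expect_equal(out$freq_case[out$state == "X"], 0.52)
  expect_equal(out$freq_control[out$state == "X"], 0.12)
  expect_equal(sum(out$freq_case), 1)
  expect_equal(sum(out$freq_control), 1)

  # random assignment vs direct counting
  set.seed(2)
  states <- matrix(sample(paste0("s", 1:20), 400, replace = TRUE), ncol = 2)
  group <- sample(c("case", "control"), 200, replace = TRUE)
  out <- state_frequency_contrast(states, group)
  for (k in sample(out$state, 5)) {
    h_case <- as.vector(states[group == "case", ])
    expect_equal(out$freq_case[out$state == k], mean(h_case == k))
  }
  expect_true(all(diff(out$diff) <= 0))
  expect_error(state_frequency_contrast(states, rep(NA, 200)), "label")
})

test_that("BED conversion is 0-based half-open", {
  iv <- data.frame(chrom = "chr3", start = 100727788, end = 104017608,
                   support = 14L)
  bed <- interval_to_bed(iv)
  expect_equal(bed$start, 100727787)
  expect_equal(bed$end, 104017608)
  expect_equal(bed$end - bed$start, iv$end - iv$start + 1)
  path <- withr::local_tempfile()
  interval_to_bed(iv, path)
  line <- strsplit(readLines(path), "\t")[[1L]]
  expect_equal(line, c("chr3", "100727787", "104017608", "14"))
})
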