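#' Simulation configuration
#'
#' Bundles the parameters of the synthetic study generator, which emulates a
#' closed AI-heavy cattle population in which a single founder sire carries
#' one copy of a recessive mutation on a tagged chromosome. Defaults are
#' chosen to resemble the mapped population: a handful of AI sires serving
#' most matings, a 50K-array-like marker density (20 markers/Mb), ~1 cM/Mb
#' recombination, and a transmission rate of the mutant allele from
#' heterozygous parents (`tau_true`) of 0.6, the distortion magnitude the
#' selective-sweep analysis estimates.
#'
#' @param n_generations number of discrete offspring generations.
#' @param n_founder_males,n_founder_females founder counts; the first male
#'   founder (`M1`) is the mutation founder, heterozygous by construction.
#' @param sibship_lambda mean of the zero-truncated Poisson sibship size per
#'   mating.
#' @param ai_top_frac fraction of available sires designated AI sires in each
#'   generation (the mutation founder is always one in generation 1).
#' @param ai_mating_frac fraction of matings served by the AI-sire subset.
#' @param max_matings cap on matings per generation (limits population
#'   growth; dams in excess are left unmated).
#' @param mutation_founder id of the founder carrying the tagged haplotype.
#' @param chrom_length simulated chromosome length in bp.
#' @param carrier_hap_length length (bp) of the tagged ancestral haplotype
#'   region centred on the mutation; defaults to the whole chromosome.
#' @param marker_density markers per Mb.
#' @param afs_min,afs_max bounds of the uniform background allele-frequency
#'   spectrum for marker alternate alleles.
#' @param recomb_rate recombination rate in cM/Mb (Haldane model,
#'   no-interference Poisson crossovers).
#' @param tau_true transmission probability of the mutant allele from a
#'   heterozygous parent (0.5 = Mendelian).
#' @param q0 mutant-allele frequency per haplotype among founders other than
#'   the mutation founder.
#' @param missing_rate genotype missing-call rate.
#' @param seed integer seed recorded in the config (used when a simulation
#'   function is called without an explicit seed).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_generations = 6,
                       n_founder_males = 5,
                       n_founder_females = 60,
                       sibship_lambda = 2,
                       ai_top_frac = 0.25,
                       ai_mating_frac = 0.75,
                       max_matings = 60,
                       mutation_founder = "M1",
                       chrom_length = 2e7,
                       carrier_hap_length = chrom_length,
                       marker_density = 20,
                       afs_min = 0.05, afs_max = 0.5,
                       recomb_rate = 1,
                       tau_true = 0.6,
                       q0 = 0.01,
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(tau_true >= 0, tau_true <= 1, q0 >= 0, q0 <= 1,
            chrom_length > 0, marker_density > 0, carrier_hap_length > 0,
            recomb_rate >= 0, sibship_lambda > 0, n_generations >= 1,
            n_founder_males >= 1, n_founder_females >= 1,
            missing_rate >= 0, missing_rate < 1,
            afs_min > 0, afs_max < 1, afs_min <= afs_max)
  structure(as.list(environment()), class = "sim_config")
}

#' Outcome model for the prospective cohort
#'
#' Parameters of the synthetic calf-outcome generator: homozygous mutants
#' (`GG`) die or are culled with probability `gg_mortality` by age
#' `mortality_age` days and, if surviving, diverge from the shared linear
#' growth law after `onset_age` days with a proportional reduction of the
#' post-onset growth increment (`stature_deficit`). Defaults mirror the
#' mapped syndrome: roughly one third of homozygotes lost prematurely,
#' stunting appearing around 5-6 months, and a ~15% stature deficit.
#'
#' @param gg_mortality probability a `GG` calf dies/is culled by
#'   `mortality_age`.
#' @param mortality_age age (days) by which excess `GG` mortality is
#'   realized.
#' @param baseline_mortality genotype-independent event probability in the
#'   first year (accidents, fractures).
#' @param onset_age age (days) at which the `GG` growth deficit starts.
#' @param stature_deficit proportional reduction of post-onset growth for
#'   `GG` survivors.
#' @param birth_weight_mean,birth_weight_sd birth weight (kg).
#' @param weight_gain daily weight gain (kg/day).
#' @param birth_height_mean,birth_height_sd birth height (cm).
#' @param height_gain daily height gain (cm/day).
#' @param weight_noise_sd,height_noise_sd measurement noise (kg, cm).
#' @param measure_interval days between repeated measures (first at birth,
#'   up to 360 days).
#' @return a list of class `outcome_model`.
#' @export
outcome_model <- function(gg_mortality = 1 / 3,
                          mortality_age = 210,
                          baseline_mortality = 0.01,
                          onset_age = 180,
                          stature_deficit = 0.15,
                          birth_weight_mean = 45, birth_weight_sd = 5,
                          weight_gain = 1.1,
                          birth_height_mean = 85, birth_height_sd = 4,
                          height_gain = 0.10,
                          weight_noise_sd = 3, height_noise_sd = 2,
                          measure_interval = 30) {
  stopifnot(gg_mortality >= 0, gg_mortality <= 1,
            baseline_mortality >= 0, baseline_mortality <= 1,
            onset_age >= 0, stature_deficit >= 0, stature_deficit <= 1,
            mortality_age > 0, measure_interval > 0)
  structure(as.list(environment()), class = "outcome_model")
}

# zero-truncated Poisson draws by inversion
rztpois <- function(n, lambda) {
  p0 <- stats::dpois(0, lambda)
  stats::qpois(stats::runif(n, p0, 1), lambda)
}

#' Simulate a multi-generation AI-sire pedigree
#'
#' Discrete generations; every mating pairs a dam of the previous generation
#' with a sire drawn from the previous generation's males, where a small
#' designated AI-sire subset serves most matings (the mutation founder is
#' always an AI sire for the first generation). Sibship sizes are
#' zero-truncated Poisson.
#'
#' @param config a [sim_config()].
#' @param seed optional integer; defaults to `config$seed`.
#' @return a [pedigree()] with an extra `generation` column (0 = founder).
#' @export
simulate_pedigree <- function(config = sim_config(), seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  males <- paste0("M", seq_len(config$n_founder_males))
  females <- paste0("F", seq_len(config$n_founder_females))
  if (!config$mutation_founder %in% c(males, females))
    stop("mutation founder '", config$mutation_founder,
         "' is not among the founders")
  id <- c(males, females)
  sire <- rep(NA_character_, length(id))
  dam <- rep(NA_character_, length(id))
  sex <- c(rep("M", length(males)), rep("F", length(females)))
  generation <- rep(0L, length(id))

  cur_males <- males
  cur_females <- females
  counter <- 0L
  for (g in seq_len(config$n_generations)) {
    if (!length(cur_males) || !length(cur_females))
      stop("population extinct at generation ", g,
           "; increase sibship_lambda or founder counts")
    n_mate <- min(length(cur_females), config$max_matings)
    dams <- sample(cur_females, n_mate)
    n_ai <- max(1L, ceiling(config$ai_top_frac * length(cur_males)))
    ai_pool <- if (g == 1L && config$mutation_founder %in% cur_males) {
      unique(c(config$mutation_founder,
               sample(cur_males, min(n_ai, length(cur_males)))))[seq_len(n_ai)]
    } else {
      sample(cur_males, n_ai)
    }
    use_ai <- stats::runif(n_mate) < config$ai_mating_frac
    sires <- character(n_mate)
    sires[use_ai] <- sample(ai_pool, sum(use_ai), replace = TRUE)
    sires[!use_ai] <- sample(cur_males, sum(!use_ai), replace = TRUE)
    sizes <- rztpois(n_mate, config$sibship_lambda)
    n_off <- sum(sizes)
    if (n_off == 0L)
      stop("no offspring drawn at generation ", g,
           "; increase sibship_lambda")
    off_id <- paste0("G", g, "I", seq_len(n_off) + counter)
    counter <- counter + n_off
    off_sire <- rep(sires, sizes)
    off_dam <- rep(dams, sizes)
    off_sex <- ifelse(stats::runif(n_off) < 0.5, "M", "F")
    id <- c(id, off_id)
    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    sex <- c(sex, off_sex)
    generation <- c(generation, rep(g, n_off))
    cur_males <- off_id[off_sex == "M"]
    cur_females <- off_id[off_sex == "F"]
  }
  ped <- pedigree(id, sire, dam, sex)
  ped$generation <- generation[match(ped$id, id)]
  ped
}

# one gamete from parental haplotypes under the Haldane model; the source
# haplotype at the mutation site is fixed first (with probability tau of
# being the mutant-bearing one when the parent is heterozygous), then the
# crossover mosaic is anchored to it. Mutation codes: 0 = wild type,
# 1 = mutant on the tagged founder lineage haplotype, 2 = mutant from a q0
# founder haplotype; the code travels with the transmitted allele.
make_gamete <- function(h1, h2, m1, m2, pos, mut_pos, chrom_length,
                        morgans, tau) {
  n_x <- stats::rpois(1L, morgans)
  xpos <- sort(stats::runif(n_x, 0, chrom_length))
  seg <- findInterval(pos, xpos)          # crossover segment per marker
  seg_mut <- findInterval(mut_pos, xpos)
  if (xor(m1 > 0L, m2 > 0L)) {
    mut_hap <- if (m1 > 0L) 0L else 1L
    target <- if (stats::runif(1L) < tau) mut_hap else 1L - mut_hap
  } else {
    target <- if (stats::runif(1L) < 0.5) 0L else 1L
  }
  start <- (target - seg_mut) %% 2L
  src <- (start + seg) %% 2L
  list(alleles = ifelse(src == 0L, h1, h2),
       mut = if (((start + seg_mut) %% 2L) == 0L) m1 else m2)
}

#' Drop haplotypes through a pedigree
#'
#' Assigns founder haplotypes (the mutation founder heterozygous for a
#' tagged mutant haplotype; every other founder haplotype mutant with
#' probability `q0`) and transmits recombined gametes down the pedigree.
#' Each meiosis places Poisson crossovers (Haldane, no interference); a
#' heterozygous parent transmits the mutant allele with probability
#' `tau_true`. Genotypes are alternate-allele dosages at markers drawn from
#' the background frequency spectrum; the mutation itself sits at the
#' chromosome midpoint and is reported in the truth table, not as a marker.
#'
#' @param ped a [pedigree()], e.g. from [simulate_pedigree()].
#' @param config a [sim_config()].
#' @param seed optional integer; defaults to `config$seed + 1`.
#' @return list with elements `genotypes` (a [genotype_matrix()]), `truth`
#'   (data frame `id`, `dosage` of the mutant allele, `lineage_dosage` =
#'   copies inherited identical-by-descent from the tagged founder
#'   haplotype, `carrier`), and `mutation_pos` (bp). Individuals with
#'   `lineage_dosage == 2` are autozygous around the mutation — the case
#'   definition used for interval mapping; a `dosage == 2` individual can
#'   carry a `q0`-derived copy and then shows no shared run of
#'   homozygosity.
#' @export
drop_haplotypes <- function(ped, config = sim_config(),
                            seed = config$seed + 1L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(ped, "pedigree"))
  L <- config$chrom_length
  n_mark <- round(config$marker_density * L / 1e6)
  if (n_mark < 1L) stop("marker map empty; increase marker_density")
  pos <- sort(sample.int(L, n_mark))
  freqs <- stats::runif(n_mark, config$afs_min, config$afs_max)
  mut_pos <- round(L / 2)
  morgans <- config$recomb_rate * L / 1e8
  founder_hap <- function() stats::rbinom(n_mark, 1L, freqs)

  n <- nrow(ped)
  H1 <- matrix(0L, n, n_mark)
  H2 <- matrix(0L, n, n_mark)
  m1 <- integer(n)
  m2 <- integer(n)
  row_of <- seq_len(n)
  names(row_of) <- ped$id
  for (i in seq_len(n)) {
    for (side in 1:2) {
      par <- if (side == 1L) ped$sire[i] else ped$dam[i]
      if (is.na(par)) {
        hap <- founder_hap()
        mut <- if (ped$id[i] == config$mutation_founder && side == 1L)
          1L else if (stats::runif(1L) < config$q0) 2L else 0L
        if (ped$id[i] == config$mutation_founder && side == 2L) mut <- 0L
      } else {
        j <- row_of[[par]]
        gam <- make_gamete(H1[j, ], H2[j, ], m1[j], m2[j], pos, mut_pos, L,
                           morgans, config$tau_true)
        hap <- gam$alleles
        mut <- gam$mut
      }
      if (side == 1L) { H1[i, ] <- hap; m1[i] <- mut }
      else { H2[i, ] <- hap; m2[i] <- mut }
    }
  }
  geno <- H1 + H2
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(geno)) < config$missing_rate,
                   nrow(geno))
    geno[drop] <- NA_integer_
  }
  rownames(geno) <- ped$id
  map <- data.frame(marker = paste0("snp", seq_len(n_mark)),
                    chrom = "chr1", pos = pos)
  truth <- data.frame(id = ped$id,
                      dosage = as.integer(m1 > 0L) + as.integer(m2 > 0L),
                      lineage_dosage = as.integer(m1 == 1L) +
                        as.integer(m2 == 1L))
  truth$carrier <- truth$dosage >= 1L
  list(genotypes = genotype_matrix(geno, map), truth = truth,
       mutation_pos = mut_pos)
}

#' Simulate a prospective calf cohort
#'
#' Given true mutant-allele dosages, draws survival outcomes and repeated
#' weight/height measures under an [outcome_model()]: `GG` calves suffer the
#' configured excess mortality by the stated age and, if surviving, a
#' proportional growth deficit after the onset age; `AA` and `AG` calves
#' follow the same baseline growth law.
#'
#' @param dosages integer vector in `{0, 1, 2}` (one calf per entry); names
#'   are used as calf ids when present.
#' @param model an [outcome_model()].
#' @param seed optional integer seed.
#' @param birth_start first birth date (`Date` or string); births are spread
#'   uniformly over the following 120 days.
#' @return a [cohort_table()].
#' @export
simulate_cohort <- function(dosages, model = outcome_model(), seed = NULL,
                            birth_start = "2009-01-01") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(dosages %in% 0:2))
  n <- length(dosages)
  ids <- if (!is.null(names(dosages))) names(dosages)
         else sprintf("calf%03d", seq_len(n))
  genotype <- c("AA", "AG", "GG")[dosages + 1L]
  birth <- as.Date(birth_start) + floor(stats::runif(n, 0, 120))

  event <- stats::runif(n) < model$baseline_mortality
  event_age <- ifelse(event, floor(stats::runif(n, 1, 360)), NA_real_)
  gg_event <- genotype == "GG" & stats::runif(n) < model$gg_mortality
  gg_age <- floor(stats::runif(n, 30, model$mortality_age))
  take <- gg_event & (!event | gg_age < event_age)
  event_age[take] <- gg_age[take]
  event[take] <- TRUE
  status <- ifelse(!event, "alive",
                   ifelse(stats::runif(n) < 0.55, "dead", "culled"))

  ages <- seq(0, 360, by = model$measure_interval)
  bw <- stats::rnorm(n, model$birth_weight_mean, model$birth_weight_sd)
  bh <- stats::rnorm(n, model$birth_height_mean, model$birth_height_sd)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- ages[is.na(event_age[i]) | ages <= event_age[i]]
    deficit <- if (genotype[i] == "GG") model$stature_deficit else 0
    grow <- function(base, gain) {
      pre <- pmin(a, model$onset_age)
      post <- pmax(a - model$onset_age, 0)
      base + gain * pre + (1 - deficit) * gain * post
    }
    rows[[i]] <- data.frame(
      calf = ids[i], genotype = genotype[i],
      birth_date = as.character(birth[i]),
      status = status[i], event_age = event_age[i],
      age = a,
      weight = grow(bw[i], model$weight_gain) +
        stats::rnorm(length(a), 0, model$weight_noise_sd),
      height = grow(bh[i], model$height_gain) +
        stats::rnorm(length(a), 0, model$height_noise_sd))
  }
  cohort_table(do.call(rbind, rows))
}

#' Draw Mendelian dosages for carrier x carrier matings
#'
#' Offspring mutant-allele dosages for matings between two heterozygous
#' carriers (the design of the prospective cohort), optionally with
#' transmission distortion.
#'
#' @param n number of calves.
#' @param tau transmission probability of the mutant allele from each
#'   heterozygous parent (0.5 = Mendelian 1:2:1).
#' @param seed optional integer seed.
#' @return integer vector of dosages in `{0, 1, 2}`.
#' @export
rmendelian_dosages <- function(n, tau = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, 1L, tau) + stats::rbinom(n, 1L, tau)
}

#' Simulate a qPCR experiment for the two-isoform decay model
#'
#' Forward model: in the mutant, a fraction `f_skip` of pre-mRNAs skip the
#' affected exon and `f_cryptic = 1 - f_skip` use the in-exon cryptic splice
#' site; a fraction `d_nmrd` of the cryptic (exon-retaining) transcripts is
#' degraded by nonsense-mediated decay. Relative to the wild-type calibrator,
#' surviving transcript levels are `rel_exon3 = f_skip + s` and
#' `rel_exon2 = s` with `s = f_cryptic * (1 - d_nmrd)`. Quantification
#' cycles follow `Cq = intercept - log(Q * dilution) / log(E)` plus Gaussian
#' noise; a two-fold five-point standard-dilution series on wild-type
#' material is emitted per assay for efficiency estimation. A zero quantity
#' yields `NA` Cq (no amplification).
#'
#' @param f_skip fraction of mutant pre-mRNAs skipping the exon.
#' @param d_nmrd fraction of exon-retaining transcripts degraded.
#' @param efficiencies named amplification efficiencies per assay; must
#'   include `exon2`, `exon3` and every reference gene.
#' @param ref_genes reference-gene assay names.
#' @param intercept Cq at unit relative quantity.
#' @param dilutions standard-curve relative input amounts.
#' @param replicates technical replicates per sample x assay.
#' @param noise_sd Gaussian Cq noise standard deviation.
#' @param seed optional integer seed.
#' @return a [qpcr_table()] with samples `WT`, `MUT` and standard-curve rows
#'   (sample `STD`, `dilution` set).
#' @export
simulate_qpcr <- function(f_skip, d_nmrd,
                          efficiencies = c(exon2 = 2, exon3 = 2,
                                           ACTB = 2, YWHAZ = 2),
                          ref_genes = c("ACTB", "YWHAZ"),
                          intercept = 24,
                          dilutions = c(1, 2, 4, 8, 16),
                          replicates = 3, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(f_skip >= 0, f_skip <= 1, d_nmrd >= 0, d_nmrd <= 1)
  if (any(efficiencies <= 1))
    stop("amplification efficiencies must exceed 1")
  targets <- c("exon2", "exon3")
  genes <- union(targets, ref_genes)
  if (!all(genes %in% names(efficiencies)))
    stop("missing efficiency for: ",
         paste(setdiff(genes, names(efficiencies)), collapse = ", "))
  s <- (1 - f_skip) * (1 - d_nmrd)
  q_mut <- c(exon2 = s, exon3 = f_skip + s)
  cq_of <- function(gene, q, dil = 1) {
    if (q <= 0) return(NA_real_)
    intercept - log(q * dil) / log(efficiencies[[gene]])
  }
  rows <- list()
  add <- function(sample, gene, q, dil = NA_real_) {
    base <- cq_of(gene, q, if (is.na(dil)) 1 else dil)
    cq <- if (is.na(base)) rep(NA_real_, replicates)
          else base + stats::rnorm(replicates, 0, noise_sd)
    rows[[length(rows) + 1L]] <<- data.frame(
      sample = sample, target = gene, replicate = seq_len(replicates),
      cq = cq, dilution = dil)
  }
  for (g in genes) {
    for (d in dilutions) add("STD", g, 1, d)
    add("WT", g, 1)
    add("MUT", g, if (g %in% targets) q_mut[[g]] else 1)
  }
  qpcr_table(do.call(rbind, rows))
}

#' Generate one full synthetic study
#'
#' Convenience wrapper running [simulate_pedigree()], [drop_haplotypes()],
#' [simulate_cohort()] (on a fresh carrier x carrier cohort of `n_cohort`
#' calves) and [simulate_qpcr()] from a single seed, so that every
#' downstream stage has coherent inputs.
#'
#' @param config a [sim_config()].
#' @param model an [outcome_model()].
#' @param n_cohort prospective-cohort size.
#' @param f_skip,d_nmrd splice-model truth for the qPCR stage.
#' @param qpcr_noise_sd Cq noise.
#' @param seed integer master seed (per-stage seeds are fixed offsets).
#' @return list with `pedigree`, `genotypes`, `truth`, `mutation_pos`,
#'   `cohort`, `qpcr`, `config`, `model` and the splice truth.
#' @export
simulate_study <- function(config = sim_config(), model = outcome_model(),
                           n_cohort = 105, f_skip = 0.8, d_nmrd = 0.55,
                           qpcr_noise_sd = 0.1, seed = config$seed) {
  ped <- simulate_pedigree(config, seed = seed)
  drop <- drop_haplotypes(ped, config, seed = seed + 1L)
  cohort <- simulate_cohort(rmendelian_dosages(n_cohort, seed = seed + 2L),
                            model, seed = seed + 3L)
  qpcr <- simulate_qpcr(f_skip, d_nmrd, noise_sd = qpcr_noise_sd,
                        seed = seed + 4L)
  list(pedigree = ped, genotypes = drop$genotypes, truth = drop$truth,
       mutation_pos = drop$mutation_pos, cohort = cohort, qpcr = qpcr,
       config = config, model = model,
       splice_truth = c(f_skip = f_skip, d_nmrd = d_nmrd), seed = seed)
}
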