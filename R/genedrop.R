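#' Monte-Carlo gene dropping through a pedigree
#'
#' Drops a mutant allele from a designated heterozygous founder through the
#' pedigree: in every simulation each founder haplotype other than the
#' mutation founder's is mutant with probability `q0`; each meiosis
#' transmits the mutant allele with probability `tau` from a heterozygous
#' parent, 1 from a homozygous mutant and 0 from a homozygous wild type;
#' an unrecorded parent behaves as a `q0` founder haplotype. The result is
#' the distribution of the number of carriers (dosage >= 1) in a target set
#' of individuals, the null distribution used to judge whether an observed
#' carrier count among descendants is compatible with a transmission rate.
#'
#' @param ped a [pedigree()].
#' @param founder id of the mutation founder (made heterozygous).
#' @param target character vector of individual ids to count carriers in.
#' @param tau transmission probability of the mutant allele from a
#'   heterozygous parent (0.5 = Mendelian).
#' @param q0 mutant-allele frequency per non-lineage founder haplotype.
#' @param n_sims number of simulations.
#' @param seed integer seed (results are bit-reproducible under a fixed
#'   seed).
#' @return object of class `carrier_count_distribution`: list with `counts`
#'   (named histogram over `0:length(target)`), `n_sims`, `tau`, `q0`,
#'   `seed`, `target_size`, `type = "monte_carlo"`.
#' @export
gene_drop <- function(ped, founder, target, tau = 0.5, q0 = 0,
                      n_sims = 10000, seed = 1L) {
  stopifnot(inherits(ped, "pedigree"), tau >= 0, tau <= 1,
            q0 >= 0, q0 <= 1, n_sims >= 1)
  missing_t <- setdiff(target, ped$id)
  if (length(missing_t))
    stop("target id(s) not in pedigree: ", paste(missing_t, collapse = ", "))
  if (!founder %in% ped$id) stop("founder not in pedigree: ", founder)
  if (!ped$founder[ped$id == founder])
    stop("'", founder, "' is not a founder of the pedigree")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  row_of <- seq_len(n)
  names(row_of) <- ped$id
  D <- matrix(0L, n_sims, n)  # sims x individuals, column-contiguous
  for (i in seq_len(n)) {
    if (ped$id[i] == founder) {
      D[, i] <- 1L  # heterozygous by construction
      next
    }
    alle <- function(par) {
      u <- stats::runif(n_sims)
      if (is.na(par)) return(u < q0)
      d <- D[, row_of[[par]]]
      d == 2L | (d == 1L & u < tau)
    }
    D[, i] <- alle(ped$sire[i]) + alle(ped$dam[i])
  }
  carriers <- rowSums(D[, row_of[target], drop = FALSE] >= 1L)
  counts <- tabulate(carriers + 1L, nbins = length(target) + 1L)
  names(counts) <- 0:length(target)
  structure(list(counts = counts, n_sims = n_sims, tau = tau, q0 = q0,
                 seed = seed, target_size = length(target),
                 type = "monte_carlo"),
            class = "carrier_count_distribution")
}

#' @export
print.carrier_count_distribution <- function(x, ...) {
  cat("Carrier-count distribution (", x$type, "): tau = ", x$tau,
      ", q0 = ", x$q0, ", target size ", x$target_size, "\n", sep = "")
  if (x$type == "monte_carlo")
    cat("  n_sims =", x$n_sims, " seed =", x$seed, "\n")
  nz <- x$counts[x$counts > 0]
  print(utils::head(nz, 20L))
  invisible(x)
}

#' Upper-tail probability of a carrier count
#'
#' Probability that the number of carriers in the target set is at least
#' `k_obs` under the dropped-allele null; the quantity used to test whether
#' an observed carrier excess among descendants is compatible with neutral
#' (or distorted) transmission.
#'
#' @param dist a `carrier_count_distribution`.
#' @param k_obs observed carrier count (`0 <= k_obs <=` target size).
#' @return list with `p` (upper-tail mass `P(count >= k_obs)`) and, for
#'   Monte-Carlo distributions, `se` (binomial standard error).
#' @export
tail_probability <- function(dist, k_obs) {
  stopifnot(inherits(dist, "carrier_count_distribution"),
            k_obs >= 0)
  k <- 0:dist$target_size
  if (dist$type == "monte_carlo") {
    p <- sum(dist$counts[k >= k_obs]) / dist$n_sims
    list(p = p, se = sqrt(p * (1 - p) / dist$n_sims))
  } else {
    list(p = sum(dist$probs[k >= k_obs]), se = NA_real_)
  }
}

#' Exact carrier-count distribution by enumeration
#'
#' Exact counterpart of [gene_drop()]: sums the probability of every
#' transmission and founder-haplotype outcome by depth-first recursion over
#' genotype configurations in pedigree order. Intended as the oracle for
#' the Monte-Carlo engine on small pedigrees: the number of meioses plus
#' stochastic founder haplotypes may not exceed 22.
#'
#' @inheritParams gene_drop
#' @return object of class `carrier_count_distribution` with `probs`
#'   (probabilities over `0:length(target)` summing to 1) and
#'   `type = "exact"`.
#' @export
enumerate_exact <- function(ped, founder, target, tau = 0.5, q0 = 0) {
  stopifnot(inherits(ped, "pedigree"), tau >= 0, tau <= 1, q0 >= 0, q0 <= 1)
  missing_t <- setdiff(target, ped$id)
  if (length(missing_t))
    stop("target id(s) not in pedigree: ", paste(missing_t, collapse = ", "))
  if (!founder %in% ped$id) stop("founder not in pedigree: ", founder)
  n <- nrow(ped)
  n_meioses <- sum(!is.na(ped$sire)) + sum(!is.na(ped$dam))
  n_stochastic <- if (q0 > 0)
    2L * sum(ped$founder & ped$id != founder) +
      sum(is.na(ped$sire) & !ped$founder) +
      sum(is.na(ped$dam) & !ped$founder)
  else 0L
  if (n_meioses + n_stochastic > 22L)
    stop("pedigree too large for exact enumeration: ", n_meioses,
         " meioses + ", n_stochastic, " stochastic founder haplotypes > 22")
  in_target <- ped$id %in% target
  probs <- numeric(length(target) + 1L)
  row_of <- seq_len(n)
  names(row_of) <- ped$id
  sire_row <- row_of[ped$sire]
  dam_row <- row_of[ped$dam]
  founder_row <- row_of[[founder]]

  # per-haplotype transmission probability given source dosage
  trans <- c(0, tau, 1)
  recurse <- function(i, dos, k, prob) {
    if (i > n) {
      probs[k + 1L] <<- probs[k + 1L] + prob
      return(invisible())
    }
    if (i == founder_row) {
      recurse(i + 1L, { dos[i] <- 1L; dos },
              k + (in_target[i]), prob)
      return(invisible())
    }
    ps <- if (is.na(sire_row[i])) q0 else trans[dos[sire_row[i]] + 1L]
    pd <- if (is.na(dam_row[i])) q0 else trans[dos[dam_row[i]] + 1L]
    pr <- c((1 - ps) * (1 - pd), ps * (1 - pd) + (1 - ps) * pd, ps * pd)
    for (d in 0:2) {
      if (pr[d + 1L] == 0) next
      recurse(i + 1L, { dos[i] <- d; dos },
              k + (in_target[i] && d >= 1L), prob * pr[d + 1L])
    }
    invisible()
  }
  recurse(1L, integer(n), 0L, 1)
  names(probs) <- 0:length(target)
  structure(list(probs = probs, tau = tau, q0 = q0,
                 target_size = length(target), type = "exact"),
            class = "carrier_count_distribution")
}

#' Exact marginal carrier probability for one individual
#'
#' Probability that a single individual carries the mutant allele, computed
#' by exact enumeration restricted to the individual's ancestor closure.
#' Used as an independent check that the mean of the carrier-count
#' distribution equals the sum of per-individual carrier probabilities.
#'
#' @inheritParams gene_drop
#' @param id individual of interest.
#' @return numeric probability.
#' @export
marginal_carrier_prob <- function(ped, founder, id, tau = 0.5, q0 = 0) {
  keep <- id
  repeat {
    parents <- unique(stats::na.omit(c(ped$sire[ped$id %in% keep],
                                       ped$dam[ped$id %in% keep])))
    new <- setdiff(parents, keep)
    if (!length(new)) break
    keep <- c(keep, new)
  }
  sub <- ped[ped$id %in% keep, , drop = FALSE]
  class(sub) <- c("pedigree", "data.frame")
  if (!founder %in% sub$id) {
    # no lineage path: the mutation founder joins as an unrelated extra so
    # only q0 founder haplotypes can make `id` a carrier
    sub <- pedigree(c(sub$id, founder), c(sub$sire, NA), c(sub$dam, NA),
                    c(sub$sex, NA))
  }
  d <- enumerate_exact(sub, founder, target = id, tau = tau, q0 = q0)
  unname(d$probs["1"])
}

#' Transmission-rate compatibility scan
#'
#' For each transmission rate on a grid, runs a gene-dropping experiment and
#' counts the simulations in which exactly `k_obs` carriers arise in the
#' target set — the profile whose maximum locates the transmission rate most
#' compatible with the observed carrier count. Grid point `i` uses seed
#' `seed + i` so profiles are reproducible and refinable.
#'
#' @inheritParams gene_drop
#' @param k_obs observed carrier count to match exactly.
#' @param tau_grid transmission-rate grid in `[0, 1]`.
#' @return list of class `tau_scan`: `profile` (data frame `tau`,
#'   `n_exact`, `tail_p`), `tau_star` (grid value maximizing the exact-hit
#'   count; ties broken by the smallest rate), `k_obs`, `n_sims`, `seed`.
#' @export
scan_transmission <- function(ped, founder, target, k_obs,
                              tau_grid = seq(0, 1, by = 0.01),
                              q0 = 0, n_sims = 10000, seed = 1L) {
  if (!length(tau_grid)) stop("empty transmission-rate grid")
  stopifnot(all(tau_grid >= 0), all(tau_grid <= 1),
            k_obs >= 0, k_obs <= length(target))
  n_exact <- numeric(length(tau_grid))
  tail_p <- numeric(length(tau_grid))
  for (i in seq_along(tau_grid)) {
    d <- gene_drop(ped, founder, target, tau = tau_grid[i], q0 = q0,
                   n_sims = n_sims, seed = seed + i)
    n_exact[i] <- d$counts[as.character(k_obs)]
    tail_p[i] <- tail_probability(d, k_obs)$p
  }
  best <- which(n_exact == max(n_exact))
  tau_star <- tau_grid[best[which.min(tau_grid[best])]]
  structure(list(profile = data.frame(tau = tau_grid, n_exact = n_exact,
                                      tail_p = tail_p),
                 tau_star = tau_star, k_obs = k_obs, n_sims = n_sims,
                 q0 = q0, seed = seed),
            class = "tau_scan")
}

#' @export
print.tau_scan <- function(x, ...) {
  cat("Transmission-rate scan: k_obs =", x$k_obs, " n_sims =", x$n_sims,
      " q0 =", x$q0, "\n  tau* =", x$tau_star, "(",
      max(x$profile$n_exact), "exact hits )\n")
  invisible(x)
}

#' Mean of a carrier-count distribution
#' @param dist a `carrier_count_distribution`.
#' @return expected carrier count.
#' @export
carrier_count_mean <- function(dist) {
  k <- 0:dist$target_size
  if (dist$type == "monte_carlo") sum(k * dist$counts) / dist$n_sims
  else sum(k * dist$probs)
}
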