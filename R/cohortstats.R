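#' Hardy-Weinberg genotype frequencies
#'
#' Expected genotype frequencies at a biallelic locus with alternate-allele
#' frequency `q` under random mating: `(1-q)^2`, `2q(1-q)`, `q^2`.
#'
#' @param q alternate-allele frequency in `[0, 1]`.
#' @return named numeric vector `hom_ref`, `het`, `hom_alt` summing to 1.
#' @export
hwe_genotype_freqs <- function(q) {
  stopifnot(q >= 0, q <= 1)
  c(hom_ref = (1 - q)^2, het = 2 * q * (1 - q), hom_alt = q^2)
}

#' Probability of observing no homozygotes under Hardy-Weinberg
#'
#' With allele frequency `q`, each of `N` individuals is homozygous
#' alternate with probability `q^2`; the probability that none is equals
#' `(1 - q^2)^N`. Used to judge whether the absence of homozygous mutants
#' among genotyped healthy adults is compatible with the allele frequency.
#'
#' @param q alternate-allele frequency.
#' @param N number of genotyped individuals.
#' @return list with `p` (`(1 - q^2)^N`) and `expected` (`N * q^2`
#'   homozygotes expected).
#' @export
prob_no_homozygotes <- function(q, N) {
  stopifnot(q >= 0, q <= 1, N >= 1)
  list(p = (1 - q^2)^N, expected = N * q^2)
}

#' Segregation test against an expected genotype ratio
#'
#' Tests observed genotype counts against an expected ratio (e.g. 1:2:1 for
#' the offspring of two carriers). Methods: Pearson chi-square (default),
#' the likelihood-ratio G-test, or an exact multinomial test enumerating all
#' outcomes (probability-ordering two-sided, `N <= 200`).
#'
#' @param counts non-negative integer vector of observed genotype counts.
#' @param ratio expected ratio, same length (e.g. `c(1, 2, 1)`).
#' @param method `"pearson"`, `"g_test"` or `"exact_multinomial"`.
#' @return list: `statistic`, `df`, `p_value`, `method`, `expected`.
#' @export
segregation_test <- function(counts, ratio = c(1, 2, 1),
                             method = c("pearson", "g_test",
                                        "exact_multinomial")) {
  method <- match.arg(method)
  stopifnot(length(counts) == length(ratio), all(ratio >= 0),
            sum(ratio) > 0, all(counts >= 0))
  N <- sum(counts)
  p_exp <- ratio / sum(ratio)
  expected <- N * p_exp
  if (method %in% c("pearson", "g_test") &&
      any(expected == 0 & counts > 0))
    stop("zero expected class with nonzero observed count")
  if (method == "pearson") {
    ct <- suppressWarnings(stats::chisq.test(counts, p = p_exp))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, method = method, expected = expected)
  } else if (method == "g_test") {
    nz <- counts > 0
    g <- 2 * sum(counts[nz] * log(counts[nz] / expected[nz]))
    df <- length(counts) - 1L
    list(statistic = g, df = df,
         p_value = stats::pchisq(g, df, lower.tail = FALSE),
         method = method, expected = expected)
  } else {
    if (N > 200) stop("exact multinomial limited to N <= 200")
    p_obs <- stats::dmultinom(counts, prob = p_exp)
    acc <- 0
    k <- length(counts)
    rec <- function(filled, left) {
      if (length(filled) == k - 1L) {
        pr <- stats::dmultinom(c(filled, left), prob = p_exp)
        if (pr <= p_obs * (1 + 1e-7)) acc <<- acc + pr
        return(invisible())
      }
      for (x in 0:left) rec(c(filled, x), left - x)
      invisible()
    }
    rec(integer(0), N)
    list(statistic = p_obs, df = NA_integer_, p_value = min(acc, 1),
         method = method, expected = expected)
  }
}

#' Exact genotype-by-outcome test
#'
#' Two-sided Fisher-type exact test for an `r x 2` contingency table
#' (genotype classes by event/no-event), using the probability-ordering
#' convention: the p-value sums the multivariate hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. For a 2 x 2 table this
#' reduces to the classical two-sided Fisher exact test.
#'
#' @param tab integer matrix with >= 2 rows and exactly 2 columns.
#' @return list: `p_value`, `p_obs` (probability of the observed table),
#'   `n_tables` (tables enumerated), `method`.
#' @export
genotype_outcome_exact_test <- function(tab) {
  tab <- as.matrix(tab)
  if (ncol(tab) != 2L || nrow(tab) < 2L)
    stop("need an r x 2 table with r >= 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("all row and column margins must be positive")
  N <- sum(tab)
  k1 <- cs[1L]
  # log multivariate hypergeometric probability of events-per-row vector a
  log_denom <- lchoose(N, k1)
  lp <- function(a) sum(lchoose(rs, a)) - log_denom
  p_obs <- exp(lp(tab[, 1L]))
  acc <- 0
  n_tables <- 0L
  r <- length(rs)
  rec <- function(i, a, left) {
    if (i == r) {
      if (left > rs[r]) return(invisible())
      pr <- exp(lp(c(a, left)))
      n_tables <<- n_tables + 1L
      if (pr <= p_obs * (1 + 1e-7)) acc <<- acc + pr
      return(invisible())
    }
    for (x in 0:min(rs[i], left)) rec(i + 1L, c(a, x), left - x)
    invisible()
  }
  rec(1L, integer(0), k1)
  list(p_value = min(acc, 1), p_obs = p_obs, n_tables = n_tables,
       method = "exact probability-ordering")
}

#' Two-locus linkage disequilibrium
#'
#' Computes `D = p_AB - p_A p_B`, the normalized `D' = D / Dmax` (with the
#' sign-appropriate Dmax) and the squared allelic correlation
#' `r2 = D^2 / (p_A p_a p_B p_b)` from counts of the four haplotypes.
#'
#' @param counts numeric vector of haplotype counts, in order
#'   `AB, Ab, aB, ab` (names, when present, are honoured).
#' @return list: `D`, `D_prime`, `r2`, allele frequencies `p_A`, `p_B`.
#' @export
two_locus_ld <- function(counts) {
  if (!is.null(names(counts)) &&
      all(c("AB", "Ab", "aB", "ab") %in% names(counts)))
    counts <- counts[c("AB", "Ab", "aB", "ab")]
  stopifnot(length(counts) == 4L, all(counts >= 0), sum(counts) > 0)
  n <- sum(counts)
  pAB <- counts[[1L]] / n
  pA <- (counts[[1L]] + counts[[2L]]) / n
  pB <- (counts[[1L]] + counts[[3L]]) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("linkage disequilibrium undefined: a locus is monomorphic")
  D <- pAB - pA * pB
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
           else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, D_prime = if (D == 0) 0 else D / d_max,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       p_A = pA, p_B = pB)
}

#' Expected affected offspring of a carrier or homozygous sire
#'
#' Under random mating at population allele frequency `q`, an offspring of
#' a heterozygous carrier sire is an affected homozygote with probability
#' `0.5 * q` (sire transmits the mutant with probability 1/2; the dam
#' allele is mutant with probability `q`); a homozygous mutant sire gives
#' `q`.
#'
#' @param q population mutant-allele frequency.
#' @param sire_genotype `"carrier"` or `"hom"`.
#' @return probability that an offspring is an affected homozygote.
#' @export
expected_affected_offspring <- function(q,
                                        sire_genotype = c("carrier", "hom")) {
  sire_genotype <- match.arg(sire_genotype)
  stopifnot(q >= 0, q <= 1)
  if (sire_genotype == "carrier") 0.5 * q else q
}

#' Compare two carrier frequencies
#'
#' Exact two-proportion comparison (2 x 2 probability-ordering exact test,
#' equivalent to the two-sided Fisher exact test) of `k1/n1` versus
#' `k2/n2`.
#'
#' @param k1,n1 carriers and total in group 1.
#' @param k2,n2 carriers and total in group 2.
#' @return list: `freq1`, `freq2`, `p_value`.
#' @export
carrier_freq_comparison <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L, byrow = TRUE)
  res <- genotype_outcome_exact_test(tab)
  list(freq1 = k1 / n1, freq2 = k2 / n2, p_value = res$p_value)
}

#' Per-group growth regression with a slope-difference test
#'
#' Fits an ordinary least-squares line of the response on age separately
#' for each genotype group within an age window (the descriptive lines one
#' would draw through the scatter), and tests for a slope difference via
#' the age-by-group interaction in a joint model that includes a fixed
#' effect per calf. The calf effects absorb animal-level intercept
#' variation (e.g. birth-weight differences), without which the repeated
#' measures per animal would leave the interaction test anti-conservative.
#'
#' @param cohort a [cohort_table()].
#' @param grouping named list mapping group labels to genotype codes, e.g.
#'   `list(affected = "GG", unaffected = c("AA", "AG"))`.
#' @param response `"weight"` or `"height"`.
#' @param window numeric `c(min_age, max_age)` in days (closed).
#' @return list of class `growth_regression`: `groups` (data frame `group`,
#'   `intercept`, `slope`, `n`), `interaction_p`, `response`, `window`.
#' @export
growth_group_regression <- function(cohort,
                                    grouping = list(affected = "GG",
                                                    unaffected = c("AA", "AG")),
                                    response = c("weight", "height"),
                                    window = c(180, 360)) {
  response <- match.arg(response)
  tab <- as.data.frame(cohort)
  tab$group <- NA_character_
  for (g in names(grouping))
    tab$group[tab$genotype %in% grouping[[g]]] <- g
  tab <- tab[!is.na(tab$group) & !is.na(tab[[response]]) &
               tab$age >= window[1L] & tab$age <= window[2L], , drop = FALSE]
  tab$group <- factor(tab$group, levels = names(grouping))
  n_per <- table(tab$group)
  if (any(n_per < 2L))
    stop("need at least 2 measures per group inside the window")
  groups <- do.call(rbind, lapply(levels(tab$group), function(g) {
    d <- tab[tab$group == g, ]
    fit <- stats::lm(stats::reformulate("age", response), data = d)
    data.frame(group = g, intercept = unname(stats::coef(fit)[1L]),
               slope = unname(stats::coef(fit)[2L]), n = nrow(d))
  }))
  # per-group slopes via age:group (no marginal age term, so the two slope
  # columns are not aliased), calf fixed effects for the repeated measures
  full <- stats::lm(stats::reformulate(c("calf", "age:group"), response),
                    data = tab)
  cf <- stats::coef(full)
  if (any(is.na(cf[grep("age:", names(cf))])))
    stop("singular design in joint model")
  reduced <- stats::lm(stats::reformulate(c("calf", "age"), response),
                       data = tab)
  interaction_p <- stats::anova(reduced, full)[2L, "Pr(>F)"]
  structure(list(groups = groups, interaction_p = unname(interaction_p),
                 response = response, window = window),
            class = "growth_regression")
}

#' @export
print.growth_regression <- function(x, ...) {
  cat("Growth regression on", x$response, "in window [",
      x$window[1L], ",", x$window[2L], "] days\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("  age-by-group interaction p = %.4g\n", x$interaction_p))
  invisible(x)
}
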