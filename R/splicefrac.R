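#' Amplification efficiency from a standard curve
#'
#' Least-squares fit of Cq on log10(relative input) over a dilution series;
#' the amplification efficiency is `E = 10^(-1/slope)` (fold amplification
#' per cycle; a perfect doubling assay gives slope -3.3219 on the log10
#' scale and `E = 2`). Efficiencies above 2.1 are capped with a warning.
#'
#' @param dilution relative input amounts (e.g. `c(1, 2, 4, 8, 16)` for a
#'   five-point two-fold series).
#' @param cq quantification cycles, same length.
#' @param assay optional assay name carried into the result.
#' @return list of class `efficiency_fit`: `assay`, `slope`, `efficiency`,
#'   `r_squared`, `n_points`.
#' @export
amplification_efficiency <- function(dilution, cq, assay = NA_character_) {
  ok <- !is.na(dilution) & !is.na(cq)
  dilution <- dilution[ok]; cq <- cq[ok]
  if (length(unique(dilution)) < 3L)
    stop("need at least 3 distinct dilution points")
  if (stats::sd(cq) == 0)
    stop("degenerate standard curve: constant Cq across dilutions")
  fit <- stats::lm(cq ~ log10(dilution))
  slope <- unname(stats::coef(fit)[2L])
  if (is.na(slope) || slope >= 0)
    stop("standard-curve slope must be negative (more input, lower Cq)")
  eff <- 10^(-1 / slope)
  if (eff > 2.1) {
    warning(sprintf("efficiency %.3f above 2.1, capped", eff))
    eff <- 2.1
  }
  structure(list(assay = assay, slope = slope, efficiency = eff,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_points = length(cq)),
            class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("Efficiency fit%s: slope %.4f, E = %.3f, R2 = %.4f (%d points)\n",
              if (is.na(x$assay)) "" else paste0(" [", x$assay, "]"),
              x$slope, x$efficiency, x$r_squared, x$n_points))
  invisible(x)
}

#' Reference-gene stability (geNorm M)
#'
#' For each candidate reference gene, the stability measure M is the mean,
#' over all other genes, of the standard deviation across samples of the
#' pairwise log2 expression ratio. Perfectly co-regulated genes have M = 0;
#' lower is more stable.
#'
#' @param quantities numeric matrix of relative quantities, genes in rows,
#'   samples in columns; all values must be positive.
#' @return data frame `gene`, `M`, sorted by increasing M (most stable
#'   first).
#' @export
reference_stability <- function(quantities) {
  q <- as.matrix(quantities)
  if (nrow(q) < 2L || ncol(q) < 2L)
    stop("need at least 2 genes and 2 samples")
  if (any(q <= 0)) stop("relative quantities must be positive")
  genes <- rownames(q)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(q)))
  M <- vapply(seq_len(nrow(q)), function(g) {
    others <- setdiff(seq_len(nrow(q)), g)
    mean(vapply(others, function(h)
      stats::sd(log2(q[g, ] / q[h, ])), numeric(1L)))
  }, numeric(1L))
  out <- data.frame(gene = genes, M = M)
  out[order(out$M), , drop = FALSE]
}

#' Normalized relative quantities from a qPCR table
#'
#' Replicate Cq values are averaged per sample x assay (standard-curve rows,
#' identified by a non-missing dilution, are excluded). For each assay the
#' relative quantity is `RQ = E^(Cq_calibrator - Cq_sample)`; the
#' normalized relative quantity divides the target RQ by the geometric mean
#' of the reference-gene RQs, so the calibrator sample has NRQ = 1 by
#' construction and rescaling every reference leaves the NRQ unchanged.
#'
#' @param cq a [qpcr_table()].
#' @param efficiencies named numeric vector of assay efficiencies, or a
#'   named list of `efficiency_fit` objects.
#' @param refs reference-gene assay names (non-empty).
#' @param calibrator calibrator sample id (NRQ = 1).
#' @param targets target assay names; defaults to all non-reference assays.
#' @return data frame of class `relative_expression`: `sample`, `target`,
#'   `nrq`, `fold_reduction` (`1/nrq`), `cq_sd` (replicate sd of the target
#'   assay).
#' @export
normalized_relative_quantity <- function(cq, efficiencies, refs, calibrator,
                                         targets = NULL) {
  stopifnot(length(refs) >= 1L)
  if (is.list(efficiencies))
    efficiencies <- vapply(efficiencies, function(e) e$efficiency,
                           numeric(1L))
  tab <- as.data.frame(cq)
  tab <- tab[is.na(tab$dilution), , drop = FALSE]
  if (!nrow(tab)) stop("no sample rows (all rows are standard-curve rows)")
  if (!calibrator %in% tab$sample)
    stop("calibrator sample not present: ", calibrator)
  if (is.null(targets)) targets <- setdiff(unique(tab$target), refs)
  assays <- union(targets, refs)
  miss_e <- setdiff(assays, names(efficiencies))
  if (length(miss_e))
    stop("no efficiency for assay(s): ", paste(miss_e, collapse = ", "))
  agg <- stats::aggregate(cq ~ sample + target, tab, mean, na.action = NULL)
  sds <- stats::aggregate(cq ~ sample + target, tab, stats::sd,
                          na.action = NULL)
  samples <- setdiff(unique(tab$sample), NULL)
  mean_cq <- function(s, g) {
    v <- agg$cq[agg$sample == s & agg$target == g]
    if (!length(v)) stop("no Cq for sample '", s, "', assay '", g, "'")
    v
  }
  rq <- function(s, g)
    efficiencies[[g]]^(mean_cq(calibrator, g) - mean_cq(s, g))
  out <- list()
  for (s in samples) {
    ref_rq <- vapply(refs, function(g) rq(s, g), numeric(1L))
    norm <- exp(mean(log(ref_rq)))
    for (g in targets) {
      nrq <- rq(s, g) / norm
      out[[length(out) + 1L]] <- data.frame(
        sample = s, target = g, nrq = nrq, fold_reduction = 1 / nrq,
        cq_sd = sds$cq[sds$sample == s & sds$target == g])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("relative_expression", "data.frame")
  res
}

#' Solve the two-isoform decay model for splice fractions
#'
#' In the homozygous mutant, pre-mRNAs either skip the affected exon
#' (fraction `f_skip`; transcript escapes nonsense-mediated decay) or use
#' the in-exon cryptic splice site (fraction `f_cryptic = 1 - f_skip`;
#' transcript retains the exon and is degraded with probability `d_nmrd`).
#' Exon-3 assays see both surviving isoforms, exon-2 assays only the
#' surviving cryptic isoform, so with `s = f_cryptic * (1 - d_nmrd)`:
#' `rel_exon3 = f_skip + s` and `rel_exon2 = s`. Inversion gives
#' `f_skip = rel_exon3 - rel_exon2` and `d_nmrd = 1 - rel_exon2 /
#' (1 - f_skip)`. Noisy inputs slightly above the calibrator are projected
#' back to the model boundary (with a warning), which keeps all solved
#' fractions inside `[0, 1]`.
#'
#' @param rel_exon2 mutant exon-2-containing transcript level relative to
#'   wild type (NRQ).
#' @param rel_exon3 mutant exon-3-containing transcript level relative to
#'   wild type.
#' @param tolerance slack allowed above 1 for noisy NRQs before the input
#'   is treated as a model violation; values in `(1, 1 + tolerance]` are
#'   projected back to 1.
#' @return list of class `splice_estimate`: `f_skip`, `f_cryptic`,
#'   `d_nmrd`, `s`, plus the inputs.
#' @export
estimate_splice_fractions <- function(rel_exon2, rel_exon3,
                                      tolerance = 0.2) {
  if (!is.finite(rel_exon2) || !is.finite(rel_exon3) || rel_exon2 <= 0)
    stop("relative levels must be positive and finite")
  if (rel_exon2 > rel_exon3 * (1 + 1e-12))
    stop("model violation: exon-2-containing transcripts (", rel_exon2,
         ") exceed exon-3-containing transcripts (", rel_exon3, ")")
  if (rel_exon3 > 1 + tolerance)
    stop("rel_exon3 = ", rel_exon3, " above 1 + tolerance")
  # noisy NRQs slightly above 1 are unphysical under the model (the mutant
  # cannot exceed the wild-type calibrator); project onto the feasible space
  # before inversion so f_cryptic stays bounded away from 0 and the solved
  # fractions land in [0, 1] by construction
  if (rel_exon3 > 1) {
    warning(sprintf("rel_exon3 = %.4f projected to 1 (noise above the %s",
                    rel_exon3, "calibrator)"))
    rel_exon3 <- 1
    rel_exon2 <- min(rel_exon2, rel_exon3)
  }
  s <- rel_exon2
  f_skip <- rel_exon3 - rel_exon2
  f_cryptic <- 1 - f_skip
  d_nmrd <- min(max(1 - s / f_cryptic, 0), 1)
  structure(list(f_skip = f_skip, f_cryptic = f_cryptic, d_nmrd = d_nmrd,
                 s = s, rel_exon2 = rel_exon2, rel_exon3 = rel_exon3),
            class = "splice_estimate")
}

#' @export
print.splice_estimate <- function(x, ...) {
  cat(sprintf(paste0("Splice estimate: f_skip = %.3f, f_cryptic = %.3f, ",
                     "d_nmrd = %.3f\n  (rel_exon2 = %.4f, rel_exon3 = %.4f)\n"),
              x$f_skip, x$f_cryptic, x$d_nmrd, x$rel_exon2, x$rel_exon3))
  invisible(x)
}

#' Full splice-quantification pipeline
#'
#' From a raw qPCR table (with standard-curve rows): fits amplification
#' efficiencies per assay, ranks candidate references by geNorm M, computes
#' normalized relative quantities of the mutant sample against the
#' wild-type calibrator and solves the two-isoform decay model. Uncertainty
#' is available by nonparametric bootstrap over technical replicates.
#'
#' @param cq a [qpcr_table()] with samples including `calibrator` and
#'   `mutant`, targets `exon2`/`exon3`, reference assays and standard-curve
#'   rows.
#' @param refs reference-gene assay names.
#' @param calibrator wild-type calibrator sample id.
#' @param mutant mutant sample id.
#' @param n_boot bootstrap resamples (0 = none).
#' @param seed seed for the bootstrap.
#' @return list of class `splice_pipeline`: `efficiency` (per-assay fits),
#'   `stability` (geNorm ranking of the reference assays), `nrq`, `estimate`
#'   and, when `n_boot > 0`, `boot_ci` (2.5/97.5 percentiles for `f_skip`
#'   and `d_nmrd`).
#' @export
splice_pipeline <- function(cq, refs = c("ACTB", "YWHAZ"),
                            calibrator = "WT", mutant = "MUT",
                            n_boot = 0, seed = 1L) {
  tab <- as.data.frame(cq)
  std <- tab[!is.na(tab$dilution), , drop = FALSE]
  assays <- union(c("exon2", "exon3"), refs)
  eff <- lapply(assays, function(g) {
    rows <- std[std$target == g, , drop = FALSE]
    if (!nrow(rows)) stop("no standard-curve rows for assay ", g)
    amplification_efficiency(rows$dilution, rows$cq, assay = g)
  })
  names(eff) <- assays

  run_once <- function(tbl) {
    nrq <- normalized_relative_quantity(tbl, eff, refs, calibrator,
                                        targets = c("exon2", "exon3"))
    m <- nrq[nrq$sample == mutant, ]
    estimate_splice_fractions(m$nrq[m$target == "exon2"],
                              m$nrq[m$target == "exon3"])
  }
  samp <- tab[is.na(tab$dilution), , drop = FALSE]
  nrq <- normalized_relative_quantity(qpcr_table(samp), eff, refs,
                                      calibrator,
                                      targets = c("exon2", "exon3"))
  est <- run_once(qpcr_table(samp))

  # geNorm stability on the reference candidates (relative quantities per
  # sample, each ref's own efficiency)
  samples <- unique(samp$sample)
  qmat <- sapply(samples, function(s)
    vapply(refs, function(g) {
      v <- samp$cq[samp$sample == s & samp$target == g]
      eff[[g]]$efficiency^(-mean(v))
    }, numeric(1L)))
  stability <- if (length(refs) >= 2L)
    reference_stability(matrix(qmat, nrow = length(refs),
                               dimnames = list(refs, samples)))
  else data.frame(gene = refs, M = NA_real_)

  boot_ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    draws <- matrix(NA_real_, n_boot, 2L,
                    dimnames = list(NULL, c("f_skip", "d_nmrd")))
    for (b in seq_len(n_boot)) {
      res <- do.call(rbind, lapply(split(samp, samp[c("sample", "target")]),
        function(gr) {
          gr$cq <- sample(gr$cq, nrow(gr), replace = TRUE)
          gr
        }))
      e <- tryCatch(suppressWarnings(run_once(qpcr_table(res))),
                    error = function(err) NULL)
      if (!is.null(e)) draws[b, ] <- c(e$f_skip, e$d_nmrd)
    }
    boot_ci <- apply(draws, 2L, stats::quantile,
                     probs = c(0.025, 0.975), na.rm = TRUE)
  }
  structure(list(efficiency = eff, stability = stability, nrq = nrq,
                 estimate = est, boot_ci = boot_ci, n_boot = n_boot),
            class = "splice_pipeline")
}
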