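#' Detect runs of homozygosity for one sample
#'
#' Scans each chromosome for maximal marker windows in which the number of
#' heterozygous calls is at most `max_het`, the number of missing calls at
#' most `max_missing`, no adjacent inter-marker gap exceeds `max_gap_bp`,
#' and the window holds at least `min_markers` markers. Windows are trimmed
#' to homozygous non-missing end markers, and overlapping candidates are
#' resolved greedily (most markers, then longest in bp, then leftmost), so
#' the returned segments are non-overlapping. Defaults are deliberately
#' permissive single-error tolerances suitable for 50K-array densities; no
#' published criterion is being reproduced, so all four are configurable.
#'
#' @param gm a [genotype_matrix()].
#' @param sample sample id (row of `gm`).
#' @param min_markers minimum markers per segment.
#' @param max_het maximum heterozygous calls tolerated inside a segment.
#' @param max_missing maximum missing calls tolerated inside a segment.
#' @param max_gap_bp maximum adjacent inter-marker gap bridged.
#' @return data frame of class `roh_segments`: `sample`, `chrom`, `start`,
#'   `end` (1-based closed, bp), `n_markers`, `n_het`, `n_missing`.
#' @export
detect_roh <- function(gm, sample, min_markers = 20, max_het = 1,
                       max_missing = 2, max_gap_bp = 1e6) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!sample %in% rownames(gm$geno)) stop("unknown sample: ", sample)
  g_all <- gm$geno[sample, ]
  out <- list()
  for (ch in unique(gm$map$chrom)) {
    sel <- gm$map$chrom == ch
    pos <- gm$map$pos[sel]
    if (any(diff(pos) <= 0)) stop("markers unsorted on chromosome ", ch)
    g <- g_all[sel]
    # chromosome chunks not interrupted by an unbridgeable gap
    breaks <- which(diff(pos) > max_gap_bp)
    chunk_start <- c(1L, breaks + 1L)
    chunk_end <- c(breaks, length(pos))
    for (k in seq_along(chunk_start)) {
      idx <- chunk_start[k]:chunk_end[k]
      cand <- roh_windows(g[idx], max_het, max_missing)
      for (w in cand) {
        tw <- roh_trim(g[idx], w[1L], w[2L])
        if (is.null(tw)) next
        span <- idx[tw[1L]:tw[2L]]
        out[[length(out) + 1L]] <- data.frame(
          sample = sample, chrom = ch,
          start = pos[span[1L]], end = pos[span[length(span)]],
          n_markers = length(span),
          n_het = sum(g[span] == 1L, na.rm = TRUE),
          n_missing = sum(is.na(g[span])))
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_markers = integer(), n_het = integer(),
                      n_missing = integer())
  } else {
    res <- do.call(rbind, out)
    res <- res[res$n_markers >= min_markers, , drop = FALSE]
    res <- roh_select(res)
  }
  rownames(res) <- NULL
  class(res) <- c("roh_segments", "data.frame")
  res
}

# maximal windows with het <= max_het and missing <= max_missing; validity
# is hereditary, so a two-pointer sweep finds them.
roh_windows <- function(g, max_het, max_missing) {
  n <- length(g)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  res <- list()
  j <- 0L; n_het <- 0L; n_mis <- 0L; last_j <- 0L
  for (i in seq_len(n)) {
    if (j < i - 1L) { j <- i - 1L; n_het <- 0L; n_mis <- 0L }
    while (j < n &&
           n_het + het[j + 1L] <= max_het &&
           n_mis + mis[j + 1L] <= max_missing) {
      j <- j + 1L
      n_het <- n_het + het[j]
      n_mis <- n_mis + mis[j]
    }
    if (j >= i && j > last_j) {
      res[[length(res) + 1L]] <- c(i, j)
      last_j <- j
    }
    if (j >= i) { n_het <- n_het - het[i]; n_mis <- n_mis - mis[i] }
  }
  res
}

# trim a window to homozygous non-missing end markers
roh_trim <- function(g, i, j) {
  hom <- function(k) !is.na(g[k]) && g[k] != 1L
  while (i <= j && !hom(i)) i <- i + 1L
  while (j >= i && !hom(j)) j <- j - 1L
  if (i > j) NULL else c(i, j)
}

# greedy non-overlap selection: most markers, then longest, then leftmost
roh_select <- function(res) {
  if (nrow(res) < 2L) return(res)
  res <- res[!duplicated(res[c("chrom", "start", "end")]), , drop = FALSE]
  ord <- order(-res$n_markers, -(res$end - res$start), res$start)
  res <- res[ord, , drop = FALSE]
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    prior <- res[keep & res$chrom == res$chrom[i], , drop = FALSE]
    keep[i] <- !any(res$start[i] <= prior$end & res$end[i] >= prior$start)
  }
  res <- res[keep, , drop = FALSE]
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Shared autozygous interval across cases
#'
#' Detects runs of homozygosity in every case and intersects them on the bp
#' scale (closed intervals, so differing missingness cannot shift marker
#' boundaries): the result is the maximal interval covered by one ROH in
#' every case or, when no interval is covered by all, the interval with the
#' greatest supporting case count (ties broken by bp length, then leftmost
#' start).
#'
#' @param gm a [genotype_matrix()] containing (at least) the cases.
#' @param cases character vector of >= 2 case sample ids.
#' @param ... ROH parameters passed to [detect_roh()].
#' @return data frame of class `shared_interval` with one row:
#'   `chrom`, `start`, `end`, `support` (cases whose ROH covers it),
#'   `n_cases` and `length_bp = end - start`.
#' @export
shared_autozygous_interval <- function(gm, cases, ...) {
  if (length(cases) < 2L) stop("need at least 2 cases")
  roh <- do.call(rbind, lapply(cases, function(s)
    as.data.frame(detect_roh(gm, s, ...))))
  if (is.null(roh) || !nrow(roh))
    stop("no runs of homozygosity detected in the cases")
  best <- NULL
  for (ch in unique(roh$chrom)) {
    r <- roh[roh$chrom == ch, , drop = FALSE]
    # sweep over breakpoints of the closed intervals
    bp <- sort(unique(c(r$start, r$end + 1)))
    if (length(bp) < 2L) next
    lo <- bp[-length(bp)]
    hi <- bp[-1L] - 1
    support <- vapply(seq_along(lo), function(k)
      length(unique(r$sample[r$start <= lo[k] & r$end >= hi[k]])),
      integer(1L))
    # merge adjacent regions with equal support
    run <- cumsum(c(TRUE, support[-1L] != support[-length(support)] |
                      lo[-1L] != hi[-length(hi)] + 1))
    for (u in unique(run)) {
      s <- support[run == u][1L]
      if (s == 0L) next
      cand <- data.frame(chrom = ch, start = min(lo[run == u]),
                         end = max(hi[run == u]), support = s)
      if (is.null(best) ||
          cand$support > best$support ||
          (cand$support == best$support &&
           (cand$end - cand$start) > (best$end - best$start)) ||
          (cand$support == best$support &&
           (cand$end - cand$start) == (best$end - best$start) &&
           cand$start < best$start)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) stop("no supported interval found")
  best$n_cases <- length(cases)
  best$length_bp <- best$end - best$start
  rownames(best) <- NULL
  class(best) <- c("shared_interval", "data.frame")
  best
}

#' Case/control haplotype-state frequency contrast
#'
#' Given a categorical state assignment for each of the two haplotypes per
#' individual and a case/control label per individual, tabulates per-state
#' haplotype frequencies within each group (each summing to 1) and sorts by
#' the case-minus-control difference, the descriptive contrast used to
#' single out the case-enriched ancestral haplotype.
#'
#' @param states matrix or data frame, individuals x 2 haplotype states.
#' @param group per-individual labels, values `"case"` / `"control"`.
#' @return data frame: `state`, `freq_case`, `freq_control`, `diff`,
#'   sorted by decreasing `diff`.
#' @export
state_frequency_contrast <- function(states, group) {
  states <- as.matrix(states)
  if (ncol(states) != 2L) stop("need two haplotype states per individual")
  if (length(group) != nrow(states))
    stop("one case/control label per individual required")
  if (anyNA(group) || !all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control', none missing")
  lv <- sort(unique(as.vector(states)))
  tab <- function(g) {
    h <- as.vector(states[group == g, , drop = FALSE])
    as.numeric(table(factor(h, levels = lv)) / length(h))
  }
  out <- data.frame(state = lv, freq_case = tab("case"),
                    freq_control = tab("control"))
  out$diff <- out$freq_case - out$freq_control
  out <- out[order(-out$diff), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert 1-based closed intervals to BED
#'
#' Internal intervals are 1-based closed `[start, end]`; BED is 0-based
#' half-open `[start, end)`. The conversion is `start - 1`, `end`.
#'
#' @param intervals data frame with `chrom`, `start`, `end` and optionally
#'   `support` (e.g. a `shared_interval` or `roh_segments`).
#' @param path optional path; when given, a tab-separated BED-like file is
#'   written.
#' @return data frame with BED coordinates (invisibly when `path` given).
#' @export
interval_to_bed <- function(intervals, path = NULL) {
  bed <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1,
                    end = intervals$end)
  extra <- intersect(c("support", "sample", "n_markers"), names(intervals))
  bed <- cbind(bed, intervals[extra])
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}
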