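# Shared fixtures and independent oracles, built in code at test time.

# F1: 4-generation, 12-individual pedigree; 4 founders (M1 is the mutation
# founder), 8 non-founders -> 16 meioses + 6 stochastic founder haplotypes,
# exactly at the exact-enumeration size bound when q0 > 0.
fixture_f1 <- function() {
  (pedigree(
    id   = c("M1", "F1", "M2", "F2", "S1", "D1", "S2", "D2",
             "S3", "D3", "S4", "D4"),
    sire = c(NA, NA, NA, NA, "M1", "M1", "M2", "M2", "S1", "S2", "S3", "S3"),
    dam  = c(NA, NA, NA, NA, "F1", "F2", "F1", "F2", "D1", "D2", "D3", "D3"),
    sex  = c("M", "F", "M", "F", "M", "F", "M", "F", "M", "F", "M", "F")))
}

f1_target <- c("S1", "D1", "S2", "D2", "S3", "D3", "S4", "D4")

# independent minimal pedigree parser (founder counting oracle): reads a
# whitespace file of id/sire/dam, treats "0" as unknown, and counts as
# founders all ids (listed or referenced) that never appear with a parent.
oracle_count_founders <- function(path) {
  rows <- strsplit(trimws(readLines(path)), "\\s+")
  ids <- vapply(rows, `[`, "", 1L)
  sires <- vapply(rows, `[`, "", 2L)
  dams <- vapply(rows, `[`, "", 3L)
  everyone <- union(ids, setdiff(c(sires, dams), "0"))
  with_parent <- ids[sires != "0" | dams != "0"]
  length(setdiff(everyone, with_parent))
}

# brute-force ROH oracle: O(n^2) scan of all windows of one chromosome's
# genotype vector, mirroring the documented segment definition.
oracle_roh <- function(g, pos, min_markers, max_het, max_missing,
                       max_gap_bp) {
  n <- length(g)
  valid <- function(i, j) {
    idx <- i:j
    sum(g[idx] == 1L, na.rm = TRUE) <= max_het &&
      sum(is.na(g[idx])) <= max_missing &&
      (j == i || all(diff(pos[idx]) <= max_gap_bp))
  }
  hom <- function(k) !is.na(g[k]) && g[k] != 1L
  wins <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (!valid(i, j)) break
    wins[[length(wins) + 1L]] <- c(i, j)
  }
  if (!length(wins)) return(NULL)
  w <- do.call(rbind, wins)
  # keep maximal windows only
  maximal <- vapply(seq_len(nrow(w)), function(k)
    !any(w[, 1L] <= w[k, 1L] & w[, 2L] >= w[k, 2L] &
           (w[, 1L] < w[k, 1L] | w[, 2L] > w[k, 2L])), logical(1L))
  w <- w[maximal, , drop = FALSE]
  # trim to homozygous ends
  out <- list()
  for (k in seq_len(nrow(w))) {
    i <- w[k, 1L]; j <- w[k, 2L]
    while (i <= j && !hom(i)) i <- i + 1L
    while (j >= i && !hom(j)) j <- j - 1L
    if (i <= j && (j - i + 1L) >= min_markers)
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(NULL)
  seg <- unique(do.call(rbind, out))
  # greedy non-overlap: most markers, then longest bp, then leftmost
  nm <- seg[, 2L] - seg[, 1L] + 1L
  len <- pos[seg[, 2L]] - pos[seg[, 1L]]
  ord <- order(-nm, -len, seg[, 1L])
  seg <- seg[ord, , drop = FALSE]
  keep <- logical(nrow(seg))
  for (k in seq_len(nrow(seg))) {
    prior <- seg[keep, , drop = FALSE]
    keep[k] <- !any(seg[k, 1L] <= prior[, 2L] & seg[k, 2L] >= prior[, 1L])
  }
  seg <- seg[keep, , drop = FALSE]
  seg <- seg[order(seg[, 1L]), , drop = FALSE]
  data.frame(start = pos[seg[, 1L]], end = pos[seg[, 2L]],
             n_markers = seg[, 2L] - seg[, 1L] + 1L)
}

# random genotype matrix for IO round trips
random_genotype_matrix <- function(n_samples, n_markers, missing = 0.05) {
  g <- matrix(sample(c(0:2, NA), n_samples * n_markers, replace = TRUE,
                     prob = c((1 - missing) / 3, (1 - missing) / 3,
                              (1 - missing) / 3, missing)),
              n_samples, n_markers,
              dimnames = list(paste0("S", seq_len(n_samples)), NULL))
  map <- data.frame(marker = paste0("m", seq_len(n_markers)),
                    chrom = "chr1",
                    pos = sort(sample.int(1e6, n_markers)))
  genotype_matrix(g, map)
}

# genotype matrix from an explicit single-chromosome code vector per sample
toy_genotype_matrix <- function(..., pos = NULL) {
  rows <- list(...)
  g <- do.call(rbind, rows)
  if (is.null(pos)) pos <- seq_len(ncol(g)) * 1000L
  map <- data.frame(marker = paste0("m", seq_len(ncol(g))),
                    chrom = "chr1", pos = pos)
  genotype_matrix(g, map)
}
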