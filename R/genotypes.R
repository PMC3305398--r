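#' SNP genotype matrices
#'
#' Biallelic genotypes are stored as an integer matrix (samples x markers)
#' with codes 0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate, `NA` = missing, together with a marker map (`marker`, `chrom`,
#' `pos`; positions are 1-based bp). Within each chromosome, marker
#' positions must be strictly increasing.
#'
#' @param geno integer matrix, samples in rows, markers in columns; values
#'   in `{0, 1, 2, NA}`. Row names are sample ids, column names marker ids.
#' @param map data frame with columns `marker`, `chrom`, `pos` in column
#'   order matching `geno`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno` and `map`.
#' @export
genotype_matrix <- function(geno, map) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (!all(geno %in% c(0L, 1L, 2L) | is.na(geno)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (!all(c("marker", "chrom", "pos") %in% names(map)))
    stop("map needs columns marker, chrom, pos")
  map <- data.frame(marker = as.character(map$marker),
                    chrom = as.character(map$chrom),
                    pos = as.numeric(map$pos))
  if (nrow(map) != ncol(geno))
    stop("map has ", nrow(map), " markers but genotype matrix has ",
         ncol(geno), " columns")
  if (anyNA(map$pos)) stop("non-numeric marker position")
  # sort markers by chromosome block then position, keep chrom blocks intact
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions not strictly increasing on chromosome ", ch)
  }
  if (is.null(rownames(geno))) rownames(geno) <- paste0("S", seq_len(nrow(geno)))
  colnames(geno) <- map$marker
  rownames(map) <- NULL
  structure(list(geno = geno, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$geno), "samples x", ncol(x$geno),
      "markers;", length(unique(x$map$chrom)), "chromosome(s);",
      sprintf("missing rate %.3f", missing_rate(x)), "\n")
  invisible(x)
}

#' Fraction of missing genotype calls
#' @param gm a `genotype_matrix`.
#' @return numeric in `[0, 1]`.
#' @export
missing_rate <- function(gm) mean(is.na(gm$geno))

#' Read a genotype matrix
#'
#' `"csv_matrix"` is a CSV with a `sample` column then one column per
#' marker holding codes 0/1/2 (empty or NA = missing); the marker map comes
#' from a companion `<path>.map` CSV (`marker,chrom,pos`) or is passed via
#' `map`. `"plink_ped_map"` reads the whitespace text PLINK pair
#' `<prefix>.ped` / `<prefix>.map`: alleles may be letters or 1/2, `0`
#' denotes a missing allele, and the first allele seen at a marker is taken
#' as the reference when counting the alternate dosage.
#'
#' @param path CSV path (csv_matrix) or file prefix (plink_ped_map).
#' @param dialect `"csv_matrix"` or `"plink_ped_map"`.
#' @param map optional marker map data frame for the csv dialect.
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, dialect = c("csv_matrix", "plink_ped_map"),
                                 map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "csv_matrix") {
    tab <- utils::read.csv(path, check.names = FALSE)
    if (names(tab)[1L] != "sample") stop("first column must be 'sample'")
    geno <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(geno) <- tab$sample
    if (is.null(map)) {
      map_path <- paste0(path, ".map")
      if (!file.exists(map_path))
        stop("no marker map: supply 'map' or provide ", map_path)
      map <- utils::read.csv(map_path)
    }
    genotype_matrix(geno, map)
  } else {
    ped_path <- paste0(path, ".ped")
    map_path <- paste0(path, ".map")
    map_tab <- utils::read.table(map_path, header = FALSE,
                                 colClasses = "character")
    # PLINK .map: chrom, marker, [cM,] bp
    pos_col <- ncol(map_tab)
    pos <- suppressWarnings(as.numeric(map_tab[[pos_col]]))
    if (anyNA(pos))
      stop("non-numeric position in ", map_path, " at row ",
           which(is.na(pos))[1L])
    map <- data.frame(marker = map_tab[[2L]], chrom = map_tab[[1L]],
                      pos = pos)
    lines <- utils::read.table(ped_path, header = FALSE,
                               colClasses = "character")
    n_mark <- nrow(map)
    if (ncol(lines) != 6L + 2L * n_mark)
      stop(".ped row has ", ncol(lines) - 6L, " allele columns for ",
           n_mark, " mapped markers")
    samples <- lines[[2L]]
    a1 <- as.matrix(lines[, 6L + 2L * seq_len(n_mark) - 1L, drop = FALSE])
    a2 <- as.matrix(lines[, 6L + 2L * seq_len(n_mark), drop = FALSE])
    geno <- matrix(NA_integer_, nrow(lines), n_mark,
                   dimnames = list(samples, map$marker))
    for (j in seq_len(n_mark)) {
      al1 <- a1[, j]; al2 <- a2[, j]
      obs <- as.vector(rbind(al1, al2))  # sample order, allele 1 then 2
      seen <- unique(obs[obs != "0"])
      if (!length(seen)) next            # all-missing marker
      # numeric 1/2 coding: allele "1" is the reference by convention;
      # letter coding: first-seen allele is the reference
      ref <- if (all(seen %in% c("1", "2"))) "1" else seen[1L]
      ok <- al1 != "0" & al2 != "0"
      geno[ok, j] <- (al1[ok] != ref) + (al2[ok] != ref)
    }
    genotype_matrix(geno, map)
  }
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotype_matrix()]. The csv dialect writes `<path>` plus
#' the marker map at `<path>.map`; the plink dialect writes `<prefix>.ped` /
#' `<prefix>.map` using numeric alleles 1 (reference) and 2 (alternate),
#' `0 0` for missing, so that a write/read round trip is exact.
#'
#' @param gm a `genotype_matrix`.
#' @param path CSV path or PLINK prefix.
#' @param dialect `"csv_matrix"` or `"plink_ped_map"`.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(gm, path,
                                  dialect = c("csv_matrix", "plink_ped_map")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (dialect == "csv_matrix") {
    out <- data.frame(sample = rownames(gm$geno), gm$geno,
                      check.names = FALSE)
    utils::write.csv(out, path, row.names = FALSE, na = "")
    utils::write.csv(gm$map, paste0(path, ".map"), row.names = FALSE)
  } else {
    map_out <- data.frame(gm$map$chrom, gm$map$marker, 0,
                          format(gm$map$pos, scientific = FALSE, trim = TRUE))
    utils::write.table(map_out, paste0(path, ".map"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    g <- gm$geno
    allele1 <- ifelse(is.na(g), "0", ifelse(g == 2L, "2", "1"))
    allele2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, "2", "1"))
    n <- nrow(g)
    inter <- matrix("", n, 2L * ncol(g))
    inter[, seq(1L, 2L * ncol(g), by = 2L)] <- allele1
    inter[, seq(2L, 2L * ncol(g), by = 2L)] <- allele2
    ped_out <- cbind("FAM", rownames(g), "0", "0", "0", "-9", inter)
    utils::write.table(ped_out, paste0(path, ".ped"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
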