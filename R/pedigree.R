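#' Pedigree objects
#'
#' A pedigree is stored as a data frame with one row per individual and
#' columns `id`, `sire`, `dam` (character; `NA` = unknown parent) and `sex`
#' (`"M"`, `"F"` or `NA`). Founders are individuals with both parents
#' unknown. The parent graph must be acyclic, and when sex codes are present
#' no individual may appear both as a sire and as a dam.
#'
#' @param id character vector of unique individual identifiers.
#' @param sire,dam character vectors of parent identifiers; `NA`, `""` or
#'   `"0"` denote an unknown parent. Parents that are referenced but not
#'   listed in `id` are appended as founders of the appropriate sex (with a
#'   warning), mirroring the incomplete sire-biased genealogies typical of
#'   AI-heavy cattle populations.
#' @param sex optional character vector (`"M"`/`"F"`/`NA`).
#' @return An object of class `pedigree`: a data frame with columns `id`,
#'   `sire`, `dam`, `sex` and logical `founder`, ordered so that every parent
#'   precedes its offspring (topological order).
#' @examples
#' ped <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"),
#'                 sex = c("M", "F", "M"))
#' n_founders(ped)
#' @export
pedigree <- function(id, sire = NULL, dam = NULL, sex = NULL) {
  id <- as.character(id)
  n <- length(id)
  norm_parent <- function(p) {
    if (is.null(p)) return(rep(NA_character_, n))
    p <- as.character(p)
    p[is.na(p) | p == "" | p == "0"] <- NA_character_
    p
  }
  sire <- norm_parent(sire)
  dam <- norm_parent(dam)
  if (length(sire) != n || length(dam) != n)
    stop("'sire' and 'dam' must have one entry per individual")
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (is.null(sex)) sex <- rep(NA_character_, n)
  sex <- toupper(as.character(sex))
  sex[!sex %in% c("M", "F")] <- NA_character_

  # auto-create referenced-but-unlisted parents as founders
  miss_sire <- setdiff(stats::na.omit(sire), id)
  miss_dam <- setdiff(stats::na.omit(dam), id)
  extra <- unique(c(miss_sire, miss_dam))
  if (length(extra)) {
    warning("parent(s) not listed as individuals, added as founder(s): ",
            paste(extra, collapse = ", "))
    id <- c(id, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
    sex <- c(sex, ifelse(extra %in% miss_sire, "M",
                         ifelse(extra %in% miss_dam, "F", NA_character_)))
  }

  ped <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                    stringsAsFactors = FALSE)
  ped$founder <- is.na(ped$sire) & is.na(ped$dam)
  ped <- ped[ped_topological_order(ped), , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

# Kahn topological sort; names one individual on a cycle on failure.
ped_topological_order <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  parents <- cbind(idx[ped$sire], idx[ped$dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in parents[i, ]) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    on_cycle <- ped$id[which(indeg > 0L)[1L]]
    stop("pedigree contains a cycle involving individual '", on_cycle, "'")
  }
  order
}

#' Validate a pedigree
#'
#' Checks acyclicity, parent existence and sire/dam sex-role consistency.
#' Called by [pedigree()]; exposed for re-validating externally built or
#' modified objects.
#'
#' @param ped a `pedigree`.
#' @return `ped`, invisibly, if valid; otherwise an error.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped_topological_order(ped)  # errors on cycles
  bad_sire <- setdiff(stats::na.omit(ped$sire), ped$id)
  bad_dam <- setdiff(stats::na.omit(ped$dam), ped$id)
  if (length(bad_sire) || length(bad_dam))
    stop("unknown parent id(s): ",
         paste(unique(c(bad_sire, bad_dam)), collapse = ", "))
  both <- intersect(stats::na.omit(ped$sire), stats::na.omit(ped$dam))
  if (length(both))
    stop("individual(s) recorded both as sire and as dam: ",
         paste(both, collapse = ", "))
  sire_sex <- ped$sex[match(stats::na.omit(ped$sire), ped$id)]
  dam_sex <- ped$sex[match(stats::na.omit(ped$dam), ped$id)]
  if (any(sire_sex == "F", na.rm = TRUE) || any(dam_sex == "M", na.rm = TRUE))
    stop("sex codes conflict with sire/dam roles")
  invisible(ped)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals,", sum(x$founder), "founders\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Number of founders in a pedigree
#' @param ped a `pedigree`.
#' @return integer count of individuals with both parents unknown.
#' @export
n_founders <- function(ped) sum(ped$founder)

#' Read a pedigree file
#'
#' Two text dialects are supported. `"linkage"` is whitespace-delimited with
#' columns id, sire, dam and optionally sex (1 = male, 2 = female,
#' 0/other = unknown), no header, and `"0"` for an unknown parent.
#' `"csv"` has a header with columns `id,sire,dam[,sex]`, empty field = an
#' unknown parent, sex coded `M`/`F`.
#'
#' @param path file path.
#' @param dialect `"linkage"` or `"csv"`.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path, dialect = c("linkage", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "linkage") {
    tab <- utils::read.table(path, header = FALSE, colClasses = "character")
    if (ncol(tab) < 3L) stop("linkage pedigree needs >= 3 columns")
    sex <- if (ncol(tab) >= 4L) c("1" = "M", "2" = "F")[tab[[4L]]] else NULL
    pedigree(tab[[1L]], tab[[2L]], tab[[3L]], sex)
  } else {
    tab <- utils::read.csv(path, colClasses = "character")
    need <- c("id", "sire", "dam")
    if (!all(need %in% names(tab)))
      stop("csv pedigree needs columns: ", paste(need, collapse = ", "))
    pedigree(tab$id, tab$sire, tab$dam, if ("sex" %in% names(tab)) tab$sex)
  }
}

#' Write a pedigree file
#'
#' Inverse of [read_pedigree()] for both dialects.
#'
#' @param ped a `pedigree`.
#' @param path output file path.
#' @param dialect `"linkage"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, dialect = c("linkage", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ped, "pedigree"))
  if (dialect == "linkage") {
    out <- data.frame(
      id = ped$id,
      sire = ifelse(is.na(ped$sire), "0", ped$sire),
      dam = ifelse(is.na(ped$dam), "0", ped$dam),
      sex = c(M = "1", F = "2")[ped$sex]
    )
    out$sex[is.na(out$sex)] <- "0"
    utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  } else {
    out <- data.frame(id = ped$id, sire = ped$sire, dam = ped$dam,
                      sex = ped$sex)
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
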