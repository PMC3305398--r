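#' Read a qPCR quantification-cycle table
#'
#' CSV with header `sample,target,replicate,cq[,dilution]`. Each
#' sample/target combination typically carries replicate triplets; standard
#' curve rows carry a positive `dilution` factor (relative input amount).
#'
#' @param path CSV file path.
#' @return a `qpcr_table`: a data frame with columns `sample`, `target`,
#'   `replicate` (integer), `cq` (numeric, `NA` = no amplification) and
#'   `dilution` (numeric or `NA`).
#' @export
read_qpcr_table <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("sample", "target", "replicate", "cq")
  if (!all(need %in% names(tab)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  if (!"dilution" %in% names(tab)) tab$dilution <- NA_real_
  qpcr_table(tab[c("sample", "target", "replicate", "cq", "dilution")])
}

#' Construct/validate a qPCR table
#' @param tab data frame with columns `sample`, `target`, `replicate`,
#'   `cq`, optional `dilution`.
#' @return the validated `qpcr_table`.
#' @export
qpcr_table <- function(tab) {
  tab <- as.data.frame(tab)
  if (!"dilution" %in% names(tab)) tab$dilution <- NA_real_
  tab$sample <- as.character(tab$sample)
  tab$target <- as.character(tab$target)
  tab$replicate <- as.integer(tab$replicate)
  tab$cq <- as.numeric(tab$cq)
  tab$dilution <- as.numeric(tab$dilution)
  bad <- which(!is.na(tab$cq) & tab$cq < 0)
  if (length(bad))
    stop("negative Cq in row(s): ", paste(bad, collapse = ", "))
  bad_d <- which(!is.na(tab$dilution) & tab$dilution <= 0)
  if (length(bad_d))
    stop("non-positive dilution in row(s): ", paste(bad_d, collapse = ", "))
  class(tab) <- c("qpcr_table", "data.frame")
  tab
}

#' Write a qPCR table
#' @param tab a `qpcr_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_qpcr_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a prospective-cohort table
#'
#' Long-format CSV, one row per measurement:
#' `calf,genotype,birth_date,status,event_age,age,weight,height`.
#' `genotype` is `AA`/`AG`/`GG`; `status` is `alive`, `dead` or `culled`
#' with `event_age` (days) the age at death/culling (`NA` while alive);
#' `age` (days), `weight` (kg) and `height` (cm) are the repeated measures.
#' Measures are sorted by age within calf on read.
#'
#' @param path CSV file path.
#' @return a `cohort_table` data frame.
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("calf", "genotype", "birth_date", "status", "event_age",
            "age", "weight", "height")
  if (!all(need %in% names(tab)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  cohort_table(tab[need])
}

#' Construct/validate a cohort table
#' @param tab data frame in the layout of [read_cohort_table()].
#' @return the validated `cohort_table`, measures sorted by age within calf.
#' @export
cohort_table <- function(tab) {
  tab <- as.data.frame(tab)
  tab$calf <- as.character(tab$calf)
  tab$genotype <- as.character(tab$genotype)
  if (any(is.na(tab$genotype) | !tab$genotype %in% c("AA", "AG", "GG")))
    stop("every calf needs a genotype in {AA, AG, GG}")
  if (!all(tab$status %in% c("alive", "dead", "culled")))
    stop("status must be alive, dead or culled")
  bad <- which(!is.na(tab$event_age) & tab$event_age < 0)
  if (length(bad))
    stop("negative event age in row(s): ", paste(bad, collapse = ", "))
  bad_a <- which(!is.na(tab$age) & tab$age < 0)
  if (length(bad_a))
    stop("negative measurement age in row(s): ", paste(bad_a, collapse = ", "))
  tab <- tab[order(match(tab$calf, unique(tab$calf)), tab$age), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Write a cohort table
#' @param tab a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-calf summary of a cohort table
#'
#' Collapses the long measurement table to one row per calf with genotype,
#' status and event age.
#'
#' @param tab a `cohort_table`.
#' @return data frame with one row per calf: `calf`, `genotype`, `status`,
#'   `event_age`.
#' @export
cohort_calves <- function(tab) {
  first <- !duplicated(tab$calf)
  out <- data.frame(calf = tab$calf[first], genotype = tab$genotype[first],
                    status = tab$status[first], event_age = tab$event_age[first])
  rownames(out) <- NULL
  out
}
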