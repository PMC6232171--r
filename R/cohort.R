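# Cohort sample sheets and bundled reference tables.

#' Read a cohort sample sheet
#'
#' Expected columns: sample_id plus any of genotype, entity, cgr_chroms
#' (comma-separated chromosome list; empty for none), mycn_gain, myc_gain,
#' biallelic_repair_hit. Logical columns are parsed from TRUE/FALSE; an
#' empty/NA `biallelic_repair_hit` is kept as unknown. `cgr_status` is
#' derived from `cgr_chroms` being non-empty (and checked for consistency
#' when present in the file).
#'
#' @param path path to the TSV.
#' @return cohort data.frame.
#' @export
read_cohort_tsv <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
  stopifnot("sample_id" %in% names(d))
  if (!"cgr_chroms" %in% names(d)) d$cgr_chroms <- NA_character_
  d$cgr_chroms[is.na(d$cgr_chroms)] <- ""
  derived <- nzchar(d$cgr_chroms)
  if ("cgr_status" %in% names(d)) {
    cs <- as.logical(d$cgr_status)
    if (any(cs != derived, na.rm = TRUE)) {
      stop("cgr_status inconsistent with cgr_chroms")
    }
  }
  d$cgr_status <- derived
  for (col in c("mycn_gain", "myc_gain", "biallelic_repair_hit")) {
    if (col %in% names(d)) d[[col]] <- as.logical(d[[col]])
  }
  d
}

#' The murine medulloblastoma reference cohort table
#'
#' The eleven cNHEJ-deficient (XRCC4/p53) mouse medulloblastomas with their
#' per-chromosome catastrophic-event calls and Myc/Mycn gain status, as
#' bundled with the package. Seven of the eleven carry a complex genome
#' rearrangement (64%) and ten of eleven a gain of Myc or Mycn.
#'
#' @return cohort data.frame (one row per tumor) with `cgr_status` and an
#'   additional `myc_or_mycn_gain` convenience column.
#' @export
mouse_mb_cohort <- function() {
  path <- system.file("extdata", "table1.tsv", package = "chromocata")
  d <- read_cohort_tsv(path)
  d$myc_or_mycn_gain <- d$mycn_gain | d$myc_gain
  d
}

#' The biallelic-inactivation contingency table for human brain tumors
#'
#' The published 2x2 table of complex-genome-rearrangement status against
#' biallelic inactivation of DNA-repair factors in 49 human MB/HGG patients
#' with pathogenic germline repair-gene mutations: 13 of 17 tumors with
#' catastrophic events had both alleles affected versus 7 of 32 tumors
#' without.
#'
#' @return 2x2 integer matrix (rows CGR+/CGR-, columns biallelic yes/no).
#' @export
biallelic_contingency <- function() {
  matrix(c(13L, 4L, 7L, 25L), nrow = 2, byrow = TRUE,
         dimnames = list(cgr = c("TRUE", "FALSE"),
                         biallelic = c("TRUE", "FALSE")))
}
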