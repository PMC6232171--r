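# Readers/writers for the interchange formats, record-level hard filters,
# and telomere repeat counting.
#
# Coordinate conventions: in memory every breakend position is 1-based;
# BEDPE on disk is 0-based half-open, so a single-base breakend at
# reference position p is stored as (start = p - 1, end = p).

SV_COLUMNS <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
                "svtype", "homology_len", "inserted_seq", "mapq", "support")

#' Construct an empty structural-variant table
#'
#' @return a zero-row data.frame with the canonical SV columns.
#' @export
empty_sv_records <- function() {
  data.frame(
    chrom1 = character(0), pos1 = integer(0), strand1 = character(0),
    chrom2 = character(0), pos2 = integer(0), strand2 = character(0),
    svtype = character(0), homology_len = integer(0),
    inserted_seq = character(0), mapq = integer(0), support = integer(0),
    stringsAsFactors = FALSE
  )
}

#' Validate a structural-variant table
#'
#' Checks the record invariants: positions >= 1, strands in {+,-}, svtype
#' consistent with intra/interchromosomal placement (TRA iff the two
#' breakends sit on different chromosomes), and mutual exclusivity of a
#' known microhomology length and a non-empty inserted sequence.
#'
#' @param svs data.frame of SV records.
#' @return the input, invisibly, or an error.
#' @export
validate_sv_records <- function(svs) {
  stopifnot(is.data.frame(svs))
  missing <- setdiff(SV_COLUMNS, names(svs))
  if (length(missing) > 0) {
    stop("SV table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(svs) == 0) return(invisible(svs))
  if (any(svs$pos1 < 1) || any(svs$pos2 < 1)) {
    stop("breakend positions must be >= 1 (1-based)")
  }
  if (!all(svs$strand1 %in% c("+", "-")) || !all(svs$strand2 %in% c("+", "-"))) {
    stop("strands must be '+' or '-'")
  }
  inter <- svs$chrom1 != svs$chrom2
  if (any(inter != (svs$svtype == "TRA"))) {
    stop("svtype TRA must coincide exactly with interchromosomal records")
  }
  has_ins <- !is.na(svs$inserted_seq) & nzchar(svs$inserted_seq)
  if (any(has_ins & !is.na(svs$homology_len) & svs$homology_len > 0)) {
    stop("a junction cannot carry both microhomology and an inserted sequence")
  }
  if (any(has_ins & !grepl("^[ACGTN]*$", svs$inserted_seq))) {
    stop("inserted_seq must match [ACGTN]*")
  }
  if (any(!is.na(svs$homology_len) & svs$homology_len < 0)) {
    stop("homology_len must be >= 0")
  }
  invisible(svs)
}

.parse_bedpe_extras <- function(field) {
  out <- list(SVTYPE = NA_character_, HOMLEN = NA_integer_,
              INSSEQ = "", MAPQ = NA_integer_, SUPPORT = NA_integer_)
  if (is.na(field) || field == "" || field == ".") return(out)
  for (kv in strsplit(field, ";", fixed = TRUE)[[1]]) {
    if (!nzchar(kv)) next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- substr(kv, 1, eq - 1)
    val <- substr(kv, eq + 1, nchar(kv))
    if (key %in% c("HOMLEN", "MAPQ", "SUPPORT")) {
      out[[key]] <- as.integer(val)
    } else if (key %in% c("SVTYPE", "INSSEQ")) {
      out[[key]] <- val
    }
  }
  out
}

#' Read structural variants from a BEDPE file
#'
#' Expects the standard ten BEDPE columns (chrom1, start1, end1, chrom2,
#' start2, end2, name, score, strand1, strand2) plus an optional 11th
#' key=value field carrying SVTYPE, HOMLEN, INSSEQ, MAPQ and SUPPORT.
#' On-disk 0-based half-open intervals are converted to 1-based breakend
#' positions (`pos = end`). Records are returned sorted by (chrom1, pos1);
#' a round trip through [write_sv_bedpe()] is the identity on all fields.
#'
#' @param path path to a tab-separated BEDPE file; lines starting with `#`
#'   are treated as comments/header.
#' @return data.frame of SV records (see [empty_sv_records()] for columns).
#' @export
read_sv_bedpe <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) return(empty_sv_records())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10) {
      stop("malformed BEDPE line ", lineno[i], ": expected >= 10 fields, got ",
           length(f))
    }
    s1 <- f[9]; s2 <- f[10]
    if (!s1 %in% c("+", "-") || !s2 %in% c("+", "-")) {
      stop("unknown strand symbol on BEDPE line ", lineno[i])
    }
    start1 <- suppressWarnings(as.numeric(f[2])); end1 <- suppressWarnings(as.numeric(f[3]))
    start2 <- suppressWarnings(as.numeric(f[5])); end2 <- suppressWarnings(as.numeric(f[6]))
    if (anyNA(c(start1, end1, start2, end2))) {
      stop("malformed BEDPE line ", lineno[i], ": non-numeric coordinates")
    }
    ex <- .parse_bedpe_extras(if (length(f) >= 11) f[11] else NA_character_)
    svtype <- ex$SVTYPE
    if (is.na(svtype)) svtype <- if (f[1] != f[4]) "TRA" else "BND"
    recs[[i]] <- data.frame(
      chrom1 = f[1], pos1 = as.integer(end1), strand1 = s1,
      chrom2 = f[4], pos2 = as.integer(end2), strand2 = s2,
      svtype = svtype, homology_len = ex$HOMLEN,
      inserted_seq = ex$INSSEQ,
      mapq = ex$MAPQ, support = ex$SUPPORT,
      stringsAsFactors = FALSE
    )
  }
  svs <- do.call(rbind, recs)
  svs <- svs[order(svs$chrom1, svs$pos1), , drop = FALSE]
  rownames(svs) <- NULL
  validate_sv_records(svs)
  svs
}

#' Write structural variants to a BEDPE file
#'
#' Inverse of [read_sv_bedpe()]: emits 0-based half-open single-base
#' intervals for each breakend and always carries SVTYPE/MAPQ/SUPPORT (plus
#' HOMLEN or INSSEQ when present) in the 11th column, since standard BEDPE
#' reserves no columns for them.
#'
#' @param svs data.frame of SV records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_bedpe <- function(svs, path) {
  validate_sv_records(svs)
  svs <- svs[order(svs$chrom1, svs$pos1), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\t",
                    "name\tscore\tstrand1\tstrand2\tinfo"), con)
  if (nrow(svs) == 0) return(invisible(path))
  info <- character(nrow(svs))
  for (i in seq_len(nrow(svs))) {
    kv <- c(paste0("SVTYPE=", svs$svtype[i]))
    if (!is.na(svs$homology_len[i])) {
      kv <- c(kv, paste0("HOMLEN=", svs$homology_len[i]))
    }
    if (!is.na(svs$inserted_seq[i]) && nzchar(svs$inserted_seq[i])) {
      kv <- c(kv, paste0("INSSEQ=", svs$inserted_seq[i]))
    }
    kv <- c(kv, paste0("MAPQ=", svs$mapq[i]), paste0("SUPPORT=", svs$support[i]))
    info[i] <- paste(kv, collapse = ";")
  }
  lines <- paste(svs$chrom1, svs$pos1 - 1L, svs$pos1,
                 svs$chrom2, svs$pos2 - 1L, svs$pos2,
                 ".", ".", svs$strand1, svs$strand2, info, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Hard-filter structural-variant records
#'
#' Keeps records with mapping quality and read support at or above the
#' thresholds. The defaults (mapq >= 30, support >= 2) are the hard filter
#' applied to assembly-based SV calls before scoring.
#'
#' @param svs data.frame of SV records.
#' @param min_mapq minimum mapping quality (default 30).
#' @param min_support minimum supporting read count (default 2).
#' @return the surviving records, input order preserved.
#' @export
filter_sv_records <- function(svs, min_mapq = 30, min_support = 2) {
  stopifnot(min_mapq >= 0, min_support >= 0)
  if (nrow(svs) == 0) return(svs)
  keep <- !is.na(svs$mapq) & svs$mapq >= min_mapq &
    !is.na(svs$support) & svs$support >= min_support
  out <- svs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

TELOMERE_REPEATS <- c("TTAGGG", "TCAGGG", "TGAGGG", "TTGGGG")

#' Count telomeric reads
#'
#' A read is telomeric if the total number of non-overlapping occurrences of
#' any of the four canonical telomere repeat units (TTAGGG, TCAGGG, TGAGGG,
#' TTGGGG) or their reverse complements reaches `min_repeats`. Reads with
#' characters outside A/C/G/T/N are skipped with a warning but still counted
#' in the denominator.
#'
#' @param reads character vector of read sequences.
#' @param min_repeats minimum repeat count for a read to qualify (default 6,
#'   appropriate for ~100 bp reads; exposed because no canonical value is
#'   universal).
#' @return a list of class `telomere_content` with `n_reads_total`,
#'   `n_telomeric` and `content_per_million`.
#' @export
count_telomeric_reads <- function(reads, min_repeats = 6) {
  stopifnot(min_repeats >= 1)
  reads <- toupper(reads)
  motifs <- c(TELOMERE_REPEATS, revcomp(TELOMERE_REPEATS))
  n_total <- length(reads)
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    warning(sum(bad), " read(s) with non-ACGTN characters skipped")
  }
  n_telo <- 0L
  for (r in reads[!bad]) {
    hits <- 0L
    for (m in motifs) {
      g <- gregexpr(m, r, fixed = TRUE)[[1]]
      if (g[1] != -1) hits <- hits + length(g)
    }
    if (hits >= min_repeats) n_telo <- n_telo + 1L
  }
  structure(list(
    n_reads_total = n_total,
    n_telomeric = n_telo,
    content_per_million = if (n_total > 0) 1e6 * n_telo / n_total else NA_real_
  ), class = "telomere_content")
}

#' Read copy-number segments from a SEG-like TSV
#'
#' Columns: sample, chrom, start (1-based), end (inclusive), log2. An
#' optional `state` column with precomputed integer copy states is carried
#' through.
#'
#' @param path path to the TSV; `#`-prefixed lines are comments.
#' @return data.frame with columns sample, chrom, start, end, log2_ratio and
#'   (possibly NA) state.
#' @export
read_cn_seg <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  if ("log2" %in% names(d) && !"log2_ratio" %in% names(d)) {
    names(d)[names(d) == "log2"] <- "log2_ratio"
  }
  need <- c("sample", "chrom", "start", "end", "log2_ratio")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("SEG file missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"state" %in% names(d)) d$state <- NA_integer_
  d$chrom <- as.character(d$chrom)
  d[c(need, "state")]
}

#' Write copy-number segments as a SEG-like TSV
#'
#' @param segments data.frame with sample, chrom, start, end, log2_ratio
#'   (and optionally state).
#' @param path output path.
#' @param params optional named list recorded in the commented header.
#' @return `path`, invisibly.
#' @export
write_cn_seg <- function(segments, path, params = NULL) {
  if (!"sample" %in% names(segments)) segments$sample <- "sample"
  cols <- c("sample", "chrom", "start", "end", "log2_ratio")
  if ("state" %in% names(segments)) cols <- c(cols, "state")
  write_tsv_commented(segments[cols], path, params)
}

#' Read a simple SNV table
#'
#' Columns: chrom, pos (1-based), ref, alt.
#'
#' @param path path to the TSV.
#' @return data.frame with columns chrom, pos, ref, alt.
#' @export
read_snv_tsv <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("SNV file missing columns: ", paste(missing, collapse = ", "))
  }
  d$chrom <- as.character(d$chrom)
  d[need]
}

#' Read structural variants from a minimal VCF breakend (BND) dialect
#'
#' Supports single-sample VCFs whose ALT fields use the bracket breakend
#' notation (e.g. `N[chr2:321682[`). Only the fields the downstream scoring
#' needs are imported: mate position/orientation, HOMLEN, SVINSSEQ/INSSEQ,
#' MAPQ and read support (SUPPORT or SR+PE). Each breakend pair is reported
#' once, keyed on the lexicographically first breakend.
#'
#' @param path path to an uncompressed VCF.
#' @return data.frame of SV records.
#' @export
read_sv_vcf_bnd <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_sv_records())
  recs <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed VCF line: ", ln)
    alt <- f[5]
    m <- regmatches(alt, regexec("([\\[\\]])([^:]+):([0-9]+)([\\[\\]])", alt,
                                 perl = TRUE))[[1]]
    if (length(m) == 0) next  # not a breakend record
    chrom1 <- f[1]; pos1 <- as.integer(f[2])
    chrom2 <- m[3]; pos2 <- as.integer(m[4])
    bracket <- m[2]
    seq_first <- regexpr("[\\[\\]]", alt, perl = TRUE) > 1
    # strand1: '+' when the reference segment left of pos1 is retained
    # (sequence precedes the bracket); strand2 from bracket direction:
    # ']' joins to the left of the mate (mate '+'), '[' to the right ('-').
    strand1 <- if (seq_first) "+" else "-"
    strand2 <- if (bracket == "]") "+" else "-"
    info <- .parse_vcf_info(f[8])
    key <- paste(chrom1, pos1, chrom2, pos2)
    mate_key <- paste(chrom2, pos2, chrom1, pos1)
    if (!is.null(recs[[mate_key]])) next  # mate of an already-seen breakend
    svtype <- if (chrom1 != chrom2) "TRA" else "BND"
    recs[[key]] <- data.frame(
      chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
      chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
      svtype = svtype,
      homology_len = info$homlen, inserted_seq = info$insseq,
      mapq = info$mapq, support = info$support,
      stringsAsFactors = FALSE
    )
  }
  if (length(recs) == 0) return(empty_sv_records())
  svs <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  svs <- svs[order(svs$chrom1, svs$pos1), , drop = FALSE]
  rownames(svs) <- NULL
  svs
}

.parse_vcf_info <- function(info) {
  out <- list(homlen = NA_integer_, insseq = "", mapq = NA_integer_,
              support = NA_integer_)
  kvs <- strsplit(info, ";", fixed = TRUE)[[1]]
  sr <- 0L; pe <- 0L; have_srpe <- FALSE
  for (kv in kvs) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- substr(kv, 1, eq - 1); val <- substr(kv, eq + 1, nchar(kv))
    switch(key,
      HOMLEN = { out$homlen <- as.integer(val) },
      INSSEQ = ,
      SVINSSEQ = { out$insseq <- val },
      MAPQ = { out$mapq <- as.integer(val) },
      SUPPORT = { out$support <- as.integer(val) },
      SR = { sr <- as.integer(val); have_srpe <- TRUE },
      PE = { pe <- as.integer(val); have_srpe <- TRUE }
    )
  }
  if (is.na(out$support) && have_srpe) out$support <- sr + pe
  out
}

# Shared TSV writer: commented header line naming tool version + parameters.
write_tsv_commented <- function(d, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  pstr <- if (is.null(params) || length(params) == 0) "" else
    paste0("; ", paste(names(params), unlist(lapply(params, format)),
                       sep = "=", collapse = " "))
  writeLines(paste0("# chromocata ",
                    as.character(utils::packageVersion("chromocata")), pstr), con)
  suppressWarnings(write.table(d, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
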