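# Junction microhomology: sequence-level extraction, binning into length
# categories, restriction to CGR regions, and group comparison by beta
# regression.

MH_BINS <- c("0-1", "2-3", "4-5", "6-7", "8-9")

# load a reference as a named list of character sequences
.as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (inherits(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
    names(seqs) <- sub("\\s.*$", "", names(reference))
    return(seqs)
  }
  if (is.character(reference) && !is.null(names(reference))) return(toupper(reference))
  stop("reference must be a FASTA path, DNAStringSet, or named character vector")
}

.lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  neq <- which(av != bv)
  if (length(neq) == 0) n else neq[1] - 1L
}

# safe substring with contig-end truncation tracking
.substr_clip <- function(seq, from, to) {
  n <- nchar(seq)
  f <- max(1, from); t <- min(n, to)
  if (f > t) return(list(s = "", clipped = TRUE))
  list(s = substr(seq, f, t), clipped = (from < 1 || to > n))
}

#' Compute junction microhomology from the reference sequence
#'
#' Reconstructs the two sequences religated at the junction and scans
#' outward (up to `max_scan` bp each way) for the longest exact match that
#' could be assigned to either side of the junction. Strand handling is
#' orientation-aware: a breakend retained on its right side enters the
#' junction reverse-complemented, so inversion-type joins are compared in
#' the correct reading frame. The reported length is the total ambiguity of
#' the junction placement (backward plus forward extension); blunt joins
#' give `(0, "")`. A junction whose record already carries an inserted
#' sequence is returned as such with zero homology.
#'
#' @param reference FASTA path, `DNAStringSet`, or named character vector.
#' @param sv a single SV record (one-row data.frame).
#' @param max_scan maximum scan length in bp (default 25).
#' @return list with `homology_len` and `inserted_seq`.
#' @export
compute_junction_homology <- function(reference, sv, max_scan = 25) {
  ref <- .as_reference(reference)
  stopifnot(nrow(sv) == 1)
  if (!is.na(sv$inserted_seq) && nzchar(sv$inserted_seq)) {
    return(list(homology_len = 0L, inserted_seq = sv$inserted_seq))
  }
  if (!sv$chrom1 %in% names(ref) || !sv$chrom2 %in% names(ref)) {
    stop("breakend contig absent from the reference")
  }
  r1 <- ref[[sv$chrom1]]; r2 <- ref[[sv$chrom2]]
  clipped <- FALSE
  # side A enters the junction reading left-to-right; A_in ends at the
  # junction, A_out is the reference continuation past it
  if (sv$strand1 == "+") {
    a_in <- .substr_clip(r1, sv$pos1 - max_scan + 1, sv$pos1)
    a_out <- .substr_clip(r1, sv$pos1 + 1, sv$pos1 + max_scan)
    A_in <- a_in$s; A_out <- a_out$s
  } else {
    a_in <- .substr_clip(r1, sv$pos1, sv$pos1 + max_scan - 1)
    a_out <- .substr_clip(r1, sv$pos1 - max_scan, sv$pos1 - 1)
    A_in <- revcomp(a_in$s); A_out <- revcomp(a_out$s)
  }
  # side B leaves the junction; B_in starts at the junction, B_pre is the
  # reference sequence immediately preceding it
  if (sv$strand2 == "-") {
    b_in <- .substr_clip(r2, sv$pos2, sv$pos2 + max_scan - 1)
    b_pre <- .substr_clip(r2, sv$pos2 - max_scan, sv$pos2 - 1)
    B_in <- b_in$s; B_pre <- b_pre$s
  } else {
    b_in <- .substr_clip(r2, sv$pos2 - max_scan + 1, sv$pos2)
    b_pre <- .substr_clip(r2, sv$pos2 + 1, sv$pos2 + max_scan)
    B_in <- revcomp(b_in$s); B_pre <- revcomp(b_pre$s)
  }
  clipped <- a_in$clipped || a_out$clipped || b_in$clipped || b_pre$clipped
  if (clipped) {
    warning("breakend within ", max_scan,
            " bp of a contig end; homology computed on available bases")
  }
  # forward: bases after the junction match what would have followed side A
  fwd <- .lcp(B_in, A_out)
  # backward: bases before the junction match what precedes side B
  rev_a <- paste(rev(strsplit(A_in, "")[[1]]), collapse = "")
  rev_b <- paste(rev(strsplit(B_pre, "")[[1]]), collapse = "")
  bwd <- .lcp(rev_a, rev_b)
  list(homology_len = as.integer(fwd + bwd), inserted_seq = "")
}

#' Bin junction microhomology lengths into the five length categories
#'
#' Junctions carrying an insertion, or homology longer than 9 bp, are
#' excluded before binning (the analysis is restricted to blunt ends and
#' microhomologies of 1-9 bp); the remainder are counted into the bins
#' 0-1, 2-3, 4-5, 6-7 and 8-9 bp.
#'
#' @param lengths integer homology lengths (NA allowed; excluded).
#' @param insertions logical vector, TRUE for junctions with an inserted
#'   sequence.
#' @return list of class `mh_distribution` with `counts` (named 5-vector),
#'   `n_junctions` (binned) and `n_excluded`.
#' @export
bin_homologies <- function(lengths, insertions = rep(FALSE, length(lengths))) {
  stopifnot(length(lengths) == length(insertions))
  if (any(!is.na(lengths) & lengths < 0)) stop("negative homology length")
  drop <- insertions | is.na(lengths) | lengths > 9
  kept <- lengths[!drop]
  counts <- setNames(integer(5), MH_BINS)
  if (length(kept) > 0) {
    idx <- kept %/% 2 + 1
    tab <- table(factor(idx, levels = 1:5))
    counts <- setNames(as.integer(tab), MH_BINS)
  }
  structure(list(counts = counts, n_junctions = length(kept),
                 n_excluded = sum(drop)),
            class = "mh_distribution")
}

# TRUE when either breakend of the record falls inside any region
.sv_in_regions <- function(svs, regions) {
  if (nrow(svs) == 0) return(logical(0))
  inside <- function(chrom, pos) {
    hit <- rep(FALSE, length(pos))
    for (r in seq_len(nrow(regions))) {
      hit <- hit | (chrom == regions$chrom[r] &
                      pos >= regions$start[r] & pos <= regions$end[r])
    }
    hit
  }
  inside(svs$chrom1, svs$pos1) | inside(svs$chrom2, svs$pos2)
}

#' Per-sample microhomology distributions inside and outside CGR regions
#'
#' A junction belongs to a region when either breakend falls inside it.
#' Homology lengths are computed from the reference sequence when one is
#' supplied (sequence-derived values take precedence over caller-reported
#' HOMLEN; disagreements are reported via a message), otherwise the
#' caller-reported lengths are used. A region class with fewer than
#' `min_breakpoints` junctions is dropped (NULL) for that sample.
#'
#' @param svs SV records of one sample.
#' @param regions data.frame of CGR regions (chrom, start, end), e.g. the
#'   passed calls of [call_cgr()].
#' @param reference optional reference for sequence-derived homology.
#' @param min_breakpoints minimum junction count per class (default 5).
#' @return list with elements `cgr` and `non_cgr`, each an
#'   `mh_distribution` or NULL.
#' @export
region_mh_distribution <- function(svs, regions, reference = NULL,
                                   min_breakpoints = 5) {
  validate_sv_records(svs)
  lengths <- svs$homology_len
  if (!is.null(reference) && nrow(svs) > 0) {
    seq_len_mh <- integer(nrow(svs))
    for (i in seq_len(nrow(svs))) {
      h <- compute_junction_homology(reference, svs[i, , drop = FALSE])
      seq_len_mh[i] <- h$homology_len
    }
    disagree <- !is.na(lengths) & lengths != seq_len_mh &
      !nzchar(svs$inserted_seq)
    if (any(disagree)) {
      message(sum(disagree),
              " junction(s) where sequence-derived homology disagrees with",
              " the caller-reported length; sequence-derived values used")
    }
    lengths <- ifelse(nzchar(svs$inserted_seq), NA_integer_, seq_len_mh)
  }
  ins <- !is.na(svs$inserted_seq) & nzchar(svs$inserted_seq)
  in_cgr <- .sv_in_regions(svs, regions)
  mk <- function(sel) {
    if (sum(sel) < min_breakpoints) return(NULL)
    bin_homologies(lengths[sel], ins[sel])
  }
  list(cgr = mk(in_cgr), non_cgr = mk(!in_cgr))
}

#' Share of junctions in one microhomology bin
#'
#' @param dist an `mh_distribution`.
#' @param bin bin label (default "2-3", the alt-EJ hallmark).
#' @return proportion in `[0, 1]`, or NA when the distribution is empty.
#' @export
mh_proportion <- function(dist, bin = "2-3") {
  stopifnot(inherits(dist, "mh_distribution"), bin %in% MH_BINS)
  if (dist$n_junctions == 0) return(NA_real_)
  unname(dist$counts[bin] / dist$n_junctions)
}
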