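# 96-channel substitution catalog conventions (pyrimidine strand,
# lexicographic within each of the six substitution classes).

.BASES <- c("A", "C", "G", "T")
.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Reverse-complement DNA strings
#'
#' Vectorized reverse complement for plain character DNA (IUPAC A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' The 96 substitution channels in canonical order
#'
#' Channels are ordered by substitution class (C>A, C>G, C>T, T>A, T>C, T>G)
#' and, within a class, lexicographically by 5' and then 3' flanking base,
#' e.g. `A[C>A]A`, `A[C>A]C`, ... This fixed order is written into every
#' catalog and signature file the package emits.
#'
#' @return character vector of length 96.
#' @export
sbs_channels <- function() {
  out <- character(0)
  for (s in .SUBS) {
    for (f in .BASES) {
      for (t in .BASES) {
        out <- c(out, paste0(f, "[", s, "]", t))
      }
    }
  }
  out
}

#' The 32 pyrimidine-centered trinucleotide contexts
#'
#' Context order matches the channel order: C-centered contexts first, then
#' T-centered, lexicographic by flanks. Each genomic trinucleotide and its
#' reverse complement are pooled into the pyrimidine-centered representative.
#'
#' @return character vector of length 32 (e.g. "ACA", "ACC", ..., "TTT").
#' @export
trinuc_contexts <- function() {
  out <- character(0)
  for (r in c("C", "T")) {
    for (f in .BASES) {
      for (t in .BASES) {
        out <- c(out, paste0(f, r, t))
      }
    }
  }
  out
}

# context (trinucleotide) of each of the 96 channels, aligned with
# sbs_channels()
channel_contexts <- function() {
  ch <- sbs_channels()
  paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7))
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
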