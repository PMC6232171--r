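# Supervised mutational-signature decomposition: 96-channel catalogs from
# SNV tables, cross-genome trinucleotide renormalization, non-negative
# least-squares exposure fitting, and the cosine-similarity fit criterion.

#' Construct a signature set
#'
#' @param matrix 96 x K matrix, columns non-negative and summing to 1
#'   (within 1e-8); rows in [sbs_channels()] order. Row/column names are
#'   added when absent.
#' @param source_trinuc_freq strictly positive 32-vector of
#'   pyrimidine-strand trinucleotide frequencies of the genome the
#'   signatures were derived on (normalized internally); defaults to
#'   uniform.
#' @return list of class `signature_set` with `matrix`, `names`,
#'   `source_trinuc_freq`.
#' @export
signature_set <- function(matrix, source_trinuc_freq = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 96, all(matrix >= 0))
  csum <- colSums(matrix)
  if (any(abs(csum - 1) > 1e-8)) {
    stop("signature columns must sum to 1 within 1e-8")
  }
  if (is.null(rownames(matrix))) rownames(matrix) <- sbs_channels()
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("Signature.", seq_len(ncol(matrix)))
  }
  if (is.null(source_trinuc_freq)) {
    source_trinuc_freq <- setNames(rep(1 / 32, 32), trinuc_contexts())
  }
  stopifnot(length(source_trinuc_freq) == 32, all(source_trinuc_freq > 0))
  if (is.null(names(source_trinuc_freq))) {
    names(source_trinuc_freq) <- trinuc_contexts()
  }
  source_trinuc_freq <- source_trinuc_freq / sum(source_trinuc_freq)
  structure(list(matrix = matrix, names = colnames(matrix),
                 source_trinuc_freq = source_trinuc_freq),
            class = "signature_set")
}

#' Build a 96-channel catalog from an SNV table
#'
#' Each SNV contributes to exactly one channel: the reference trinucleotide
#' is read from the genome, purine-reference mutations are
#' reverse-complemented (mutation and context) onto the pyrimidine strand,
#' and the count at the corresponding channel is incremented. Records whose
#' stated reference allele does not match the genome are rejected and
#' counted in the `n_rejected` attribute.
#'
#' @param snvs data.frame with chrom, pos (1-based), ref, alt.
#' @param reference FASTA path, DNAStringSet, or named character vector.
#' @return named integer vector of length 96 (channel order of
#'   [sbs_channels()]) with attribute `n_rejected`.
#' @export
catalog_from_snvs <- function(snvs, reference) {
  ref <- .as_reference(reference)
  channels <- sbs_channels()
  counts <- setNames(integer(96), channels)
  rejected <- 0L
  for (i in seq_len(nrow(snvs))) {
    chrom <- snvs$chrom[i]; pos <- snvs$pos[i]
    if (!chrom %in% names(ref) || pos < 2 || pos > nchar(ref[[chrom]]) - 1) {
      rejected <- rejected + 1L
      next
    }
    tri <- substr(ref[[chrom]], pos - 1, pos + 1)
    rb <- substr(tri, 2, 2)
    if (rb != toupper(snvs$ref[i])) {
      rejected <- rejected + 1L
      next
    }
    alt <- toupper(snvs$alt[i])
    if (rb %in% c("A", "G")) {
      tri <- revcomp(tri)
      rb <- substr(tri, 2, 2)
      alt <- revcomp(alt)
    }
    ch <- paste0(substr(tri, 1, 1), "[", rb, ">", alt, "]", substr(tri, 3, 3))
    if (!ch %in% channels) { rejected <- rejected + 1L; next }
    counts[ch] <- counts[ch] + 1L
  }
  attr(counts, "n_rejected") <- rejected
  counts
}

#' Pyrimidine-strand trinucleotide frequencies of a genome
#'
#' Counts all overlapping trinucleotides, pools each with its reverse
#' complement into the pyrimidine-centered representative, and normalizes.
#' An optional BED-like mask (chrom, start 0-based, end) restricts counting
#' to target regions (exome mode).
#'
#' @param reference FASTA path, DNAStringSet, or named character vector.
#' @param mask optional data.frame with chrom, start, end.
#' @return named 32-vector summing to 1, in [trinuc_contexts()] order.
#' @export
trinuc_frequencies <- function(reference, mask = NULL) {
  ref <- .as_reference(reference)
  if (!is.null(mask)) {
    pieces <- character(0)
    for (i in seq_len(nrow(mask))) {
      chrom <- mask$chrom[i]
      if (!chrom %in% names(ref)) next
      pieces <- c(pieces, substr(ref[[chrom]], mask$start[i] + 1, mask$end[i]))
    }
    ref <- pieces
  }
  dss <- Biostrings::DNAStringSet(ref)
  tf <- colSums(Biostrings::trinucleotideFrequency(dss))
  out <- setNames(numeric(32), trinuc_contexts())
  for (tri in names(tf)) {
    if (grepl("N", tri)) next
    key <- if (substr(tri, 2, 2) %in% c("C", "T")) tri else revcomp(tri)
    out[key] <- out[key] + tf[[tri]]
  }
  if (sum(out) == 0) stop("no countable trinucleotides in the reference")
  out / sum(out)
}

#' Renormalize signatures to a different trinucleotide background
#'
#' Divides every channel weight by the frequency of its context in the
#' source genome and multiplies by the frequency in the target genome, then
#' rescales each column to sum to 1. Applying the inverse renormalization
#' recovers the original set. Used to carry signatures derived on one
#' genome (or exome target space) onto another.
#'
#' @param signatures a [signature_set()].
#' @param target_trinuc_freq strictly positive 32-vector (named by context
#'   or in [trinuc_contexts()] order).
#' @return a new `signature_set` whose `source_trinuc_freq` is the target.
#' @export
renormalize_signatures <- function(signatures, target_trinuc_freq) {
  stopifnot(inherits(signatures, "signature_set"),
            length(target_trinuc_freq) == 32)
  if (is.null(names(target_trinuc_freq))) {
    names(target_trinuc_freq) <- trinuc_contexts()
  }
  if (any(target_trinuc_freq <= 0)) {
    bad <- names(target_trinuc_freq)[target_trinuc_freq <= 0]
    stop("zero target frequency for context(s): ", paste(bad, collapse = ", "))
  }
  src <- signatures$source_trinuc_freq
  if (any(src <= 0)) {
    stop("zero source frequency for context(s): ",
         paste(names(src)[src <= 0], collapse = ", "))
  }
  target <- target_trinuc_freq / sum(target_trinuc_freq)
  ctx <- channel_contexts()
  scale <- as.numeric(target[ctx] / src[ctx])
  m <- signatures$matrix * scale
  m <- sweep(m, 2, colSums(m), "/")
  signature_set(m, source_trinuc_freq = target)
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `min ||A x - b||^2` subject to `x >= 0`. The active-set iteration
#' never increases the residual, and at the solution the KKT conditions
#' hold: `x >= 0`, the gradient `w = t(A) (b - A x)` is `<= tol` on zero
#' coordinates and `~ 0` on positive ones.
#'
#' @param A numeric matrix (m x k).
#' @param b numeric vector (length m).
#' @param tol tolerance for the optimality test.
#' @return list with `x`, `residual_norm2`, `kkt_gradient` (the final
#'   gradient `w`), and `iterations`.
#' @export
nnls_fit <- function(A, b, tol = 1e-10) {
  k <- ncol(A)
  x <- numeric(k)
  passive <- logical(k)
  w <- as.numeric(crossprod(A, b - A %*% x))
  iter <- 0
  max_iter <- 30 * k
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(k)
      z[P] <- qr.solve(A[, P, drop = FALSE], b)
      if (all(z[P] > tol)) break
      # step back to the boundary along x -> z
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  r <- b - A %*% x
  list(x = x, residual_norm2 = sum(r^2), kkt_gradient = w,
       iterations = iter)
}

#' Fit signature exposures to a catalog
#'
#' Normalizes the catalog to channel proportions `m`, solves
#' `min ||S e - m||^2` over `e >= 0` by non-negative least squares,
#' renormalizes the exposures to sum to 1 (the cosine criterion is
#' scale-invariant), and evaluates the fit by the cosine similarity between
#' the reconstructed 96-channel composition and the input. Samples whose
#' cosine falls below `qc_threshold` are flagged as not kept.
#'
#' @param catalog 96-vector of channel counts (total > 0).
#' @param signatures a [signature_set()].
#' @param qc_threshold minimum cosine similarity (default 0.8).
#' @return list of class `exposure_fit`: `exposures` (named, sums to 1),
#'   `reconstruction`, `cosine`, `kept`.
#' @export
fit_exposures <- function(catalog, signatures, qc_threshold = 0.8) {
  stopifnot(inherits(signatures, "signature_set"), length(catalog) == 96)
  total <- sum(catalog)
  if (total <= 0) stop("all-zero catalog")
  m <- as.numeric(catalog) / total
  S <- signatures$matrix
  fit <- nnls_fit(S, m)
  e <- fit$x
  if (sum(e) > 0) {
    e <- e / sum(e)
    recon <- as.numeric(S %*% e)
    cosine <- cosine_similarity(m, recon)
  } else {
    # catalog has no non-negative projection onto the signatures at all
    recon <- numeric(96)
    cosine <- 0
  }
  structure(list(
    exposures = setNames(e, signatures$names),
    reconstruction = recon,
    cosine = cosine,
    kept = cosine >= qc_threshold
  ), class = "exposure_fit")
}

#' Write / read a signature matrix TSV (96 rows x K signature columns)
#'
#' @param signatures a [signature_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(signatures, path) {
  d <- data.frame(channel = rownames(signatures$matrix),
                  signatures$matrix, check.names = FALSE)
  write_tsv_commented(d, path,
                      params = list(channel_order = "pyrimidine-lexicographic"))
}

#' @rdname write_signature_tsv
#' @param source_trinuc_freq optional 32-vector attached to the loaded set.
#' @export
read_signature_tsv <- function(path, source_trinuc_freq = NULL) {
  d <- read.delim(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m <- m[sbs_channels(), , drop = FALSE]
  signature_set(m, source_trinuc_freq)
}

#' Write a 96-channel catalog TSV
#'
#' @param catalog named 96-vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  d <- data.frame(channel = names(catalog), count = as.integer(catalog))
  write_tsv_commented(d, path,
                      params = list(channel_order = "pyrimidine-lexicographic"))
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- setNames(as.integer(d$count), d$channel)
  out[sbs_channels()]
}
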