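# Shared in-code fixtures: random signature sets, tiny references, random
# CN profiles and SV tables. Everything is generated at test time.

# K random column-stochastic signatures, moderately spiky so mixtures are
# identifiable
random_signature_set <- function(k = 5, seed = 1, concentration = 0.3) {
  set.seed(seed)
  m <- matrix(rgamma(96 * k, shape = concentration), nrow = 96)
  m <- sweep(m, 2, colSums(m), "/")
  signature_set(m)
}

# random DNA string of length n as a named reference
random_reference <- function(n = 500, seed = 1, name = "chr1") {
  set.seed(seed)
  setNames(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = ""), name)
}

# random per-chromosome CN segment profile with n_seg segments
random_profile <- function(n_seg, states = 1:4, seg_len_range = c(1e5, 2e7)) {
  lens <- floor(runif(n_seg, seg_len_range[1], seg_len_range[2]))
  ends <- cumsum(lens)
  starts <- c(1, head(ends, -1) + 1)
  data.frame(chrom = "chr1", start = starts, end = ends,
             log2_ratio = 0, state = sample(states, n_seg, replace = TRUE),
             stringsAsFactors = FALSE)
}

# one random well-formed intrachromosomal SV record
random_sv_record <- function(chrom_len = 1e8) {
  p1 <- sample.int(chrom_len - 1e6, 1)
  p2 <- p1 + sample.int(5e6, 1)
  s <- sample(c("+", "-"), 2, replace = TRUE)
  svtype <- if (s[1] == s[2]) "BND" else if (s[1] == "+") "DEL" else "DUP"
  has_ins <- runif(1) < 0.15
  data.frame(
    chrom1 = "chr1", pos1 = p1, strand1 = s[1],
    chrom2 = "chr1", pos2 = p2, strand2 = s[2],
    svtype = svtype,
    homology_len = if (has_ins) NA_integer_ else sample(0:9, 1),
    inserted_seq = if (has_ins) paste(sample(c("A", "C", "G", "T"),
                                             sample(2:8, 1), replace = TRUE),
                                      collapse = "") else "",
    mapq = sample(10:60, 1), support = sample(1:20, 1),
    stringsAsFactors = FALSE
  )
}

random_sv_table <- function(n, chrom_len = 1e8) {
  if (n == 0) return(empty_sv_records())
  out <- do.call(rbind, replicate(n, random_sv_record(chrom_len),
                                  simplify = FALSE))
  out <- out[order(out$chrom1, out$pos1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force oracle: switches inside every window anchored at a switch
brute_max_switches <- function(segments, window = 50e6, min_seg_len = 1e4) {
  m <- chromocata:::merge_short_segments(segments, min_seg_len)
  if (nrow(m) <= 1) return(0L)
  pos <- m$end[which(m$state[-1] != m$state[-nrow(m)])]
  if (length(pos) == 0) return(0L)
  best <- 0L
  for (s in pos) {
    cnt <- sum(pos >= s & pos <= s + window)
    if (cnt > best) best <- cnt
  }
  best
}
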