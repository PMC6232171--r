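test_that("channel order is the canonical 96 and contexts align", {
  ch <- sbs_channels()
  expect_equal(length(ch), 96)
  expect_equal(ch[1], "A[C>A]A")
  expect_equal(ch[96], "T[T>G]T")
  expect_equal(anyDuplicated(ch), 0)
  ctx <- chromocata:::channel_contexts()
  expect_equal(ctx[1], "ACA")
  expect_true(all(ctx %in% trinuc_contexts()))
})

test_that("SNV catalogs collapse purine references onto the pyrimidine strand", {
  # reference: ...A C A... at 10:12 and ...T G T... at 30:32
  v <- rep("G", 60)
  v[10:12] <- c("A", "C", "A")
  v[30:32] <- c("T", "G", "T")
  ref <- setNames(paste(v, collapse = ""), "chr1")
  snvs <- data.frame(chrom = "chr1", pos = c(11L, 31L),
                     ref = c("C", "G"), alt = c("A", "T"),
                     stringsAsFactors = FALSE)
  cat96 <- catalog_from_snvs(snvs, ref)
  # both land in A[C>A]A: the G>T with T flanks is its reverse complement
  expect_equal(unname(cat96["A[C>A]A"]), 2L)
  expect_equal(sum(cat96), 2L)
  expect_equal(attr(cat96, "n_rejected"), 0L)
})

test_that("catalog totals are conserved and ref mismatches rejected", {
  set.seed(15)
  ref <- random_reference(3000, seed = 15)
  pos <- sample(2:2999, 300)
  refbase <- substring(ref[[1]], pos, pos)
  alt <- vapply(refbase, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  snvs <- data.frame(chrom = "chr1", pos = pos, ref = refbase, alt = alt,
                     stringsAsFactors = FALSE)
  # corrupt 20 records
  bad <- sample(300, 20)
  snvs$ref[bad] <- vapply(snvs$ref[bad],
                          function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  cat96 <- catalog_from_snvs(snvs, ref)
  expect_equal(sum(cat96) + attr(cat96, "n_rejected"), 300L)
  expect_equal(attr(cat96, "n_rejected"), 20L)
})

test_that("renormalization is the identity for equal backgrounds", {
  ss <- random_signature_set(k = 4, seed = 21)
  out <- renormalize_signatures(ss, ss$source_trinuc_freq)
  expect_lt(max(abs(out$matrix - ss$matrix)), 1e-12)
})

test_that("doubling one context doubles its channels before column rescale", {
  ss <- random_signature_set(k = 3, seed = 22)
  target <- ss$source_trinuc_freq
  target["ACA"] <- 2 * target["ACA"]
  out <- renormalize_signatures(ss, target)
  ctx <- chromocata:::channel_contexts()
  # hand computation: unnormalized weights scale by target/source per context
  tgt_n <- target / sum(target)
  scale <- as.numeric(tgt_n[ctx] / ss$source_trinuc_freq[ctx])
  hand <- ss$matrix * scale
  hand <- sweep(hand, 2, colSums(hand), "/")
  expect_lt(max(abs(out$matrix - hand)), 1e-12)
  # the three ACA channels gain relative weight in every column
  aca <- ctx == "ACA"
  expect_true(all(colSums(out$matrix[aca, , drop = FALSE]) >
                    colSums(ss$matrix[aca, , drop = FALSE])))
})

test_that("mouse->human->mouse renormalization round trip is exact to 1e-10", {
  ss <- random_signature_set(k = 5, seed = 23)
  set.seed(24)
  mouse <- rgamma(32, 5); mouse <- setNames(mouse / sum(mouse), trinuc_contexts())
  human <- rgamma(32, 5); human <- setNames(human / sum(human), trinuc_contexts())
  ss_m <- signature_set(ss$matrix, source_trinuc_freq = mouse)
  there <- renormalize_signatures(ss_m, human)
  back <- renormalize_signatures(there, mouse)
  expect_lt(max(abs(back$matrix - ss_m$matrix)), 1e-10)
})

test_that("zero frequencies are rejected with the context named", {
  ss <- random_signature_set(k = 2, seed = 25)
  bad <- ss$source_trinuc_freq
  bad["TCT"] <- 0
  expect_error(renormalize_signatures(ss, bad), "TCT")
})

test_that("genomic trinucleotide frequencies pool reverse complements", {
  # a sequence and its reverse complement must give identical spectra
  ref1 <- random_reference(4000, seed = 26)
  ref2 <- setNames(revcomp(ref1), "chr1")
  f1 <- trinuc_frequencies(ref1)
  f2 <- trinuc_frequencies(ref2)
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_equal(sum(f1), 1)
})

test_that("NNLS matches the reference solver and satisfies KKT", {
  set.seed(27)
  for (i in 1:20) {
    A <- matrix(rexp(40 * 8), 40, 8)
    b <- as.numeric(A %*% runif(8) + rnorm(40, 0, 0.1))
    fit <- nnls_fit(A, b)
    oracle <- pracma::lsqnonneg(A, b)
    expect_lt(max(abs(fit$x - oracle$x)), 1e-6)
    # KKT: gradient ~ 0 on the support, <= 0 off it
    w <- fit$kkt_gradient
    expect_lt(max(abs(w[fit$x > 1e-10])), 1e-8)
    expect_lt(max(c(w[fit$x <= 1e-10], -Inf)), 1e-8)
  }
})

test_that("exposure fitting recovers pure and noiseless mixed catalogs", {
  ss <- random_signature_set(k = 5, seed = 28)
  # pure signature
  pure <- round(ss$matrix[, 3] * 1e6)
  f <- fit_exposures(pure, ss)
  expect_gt(f$exposures[3], 0.999)
  expect_gt(f$cosine, 0.999)
  expect_true(f$kept)
  # noiseless 0.6 / 0.4 mixture, checked against an exhaustive grid oracle
  m <- as.numeric(ss$matrix %*% c(0.6, 0.4, 0, 0, 0))
  f2 <- fit_exposures(m * 1e6, ss)
  expect_lt(max(abs(f2$exposures - c(0.6, 0.4, 0, 0, 0))), 1e-6)
  grid <- seq(0, 1, by = 1e-3)
  rss <- vapply(grid, function(e1) {
    sum((as.numeric(ss$matrix[, 1:2] %*% c(e1, 1 - e1)) - m)^2)
  }, 0)
  expect_equal(grid[which.min(rss)], 0.6, tolerance = 1e-3)
})

test_that("catalogs outside the signature span fail the cosine QC", {
  set.seed(29)
  m <- matrix(0, 96, 3)
  m[1:30, 1] <- rexp(30); m[21:50, 2] <- rexp(30); m[41:70, 3] <- rexp(30)
  m <- sweep(m, 2, colSums(m), "/")
  ss <- signature_set(m)
  orthogonal <- setNames(integer(96), sbs_channels())
  orthogonal[90:96] <- 100L
  f <- fit_exposures(orthogonal, ss)
  expect_lt(f$cosine, 0.8)
  expect_false(f$kept)
  expect_error(fit_exposures(integer(96), ss), "all-zero")
})

test_that("signature and catalog TSVs round trip", {
  ss <- random_signature_set(k = 3, seed = 30)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signature_tsv(ss, f)
  back <- read_signature_tsv(f)
  expect_lt(max(abs(back$matrix - ss$matrix)), 1e-6)
  cat96 <- simulate_catalog(ss, c(0.5, 0.3, 0.2), 1000, seed = 31)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_catalog_tsv(cat96, f2)
  expect_equal(read_catalog_tsv(f2), cat96, ignore_attr = TRUE)
})

test_that("renormalized fitting removes cross-genome exposure bias", {
  # catalogs generated under a target background, fitted with signatures
  # stated on the source background: renormalizing first improves recovery
  ss <- random_signature_set(k = 4, seed = 32)
  set.seed(33)
  src <- rgamma(32, 5); src <- setNames(src / sum(src), trinuc_contexts())
  tgt <- src * c(rep(2, 8), rep(0.5, 8), rep(1, 16))
  tgt <- tgt / sum(tgt)
  ss_src <- signature_set(ss$matrix, source_trinuc_freq = src)
  ss_tgt <- renormalize_signatures(ss_src, tgt)
  truth <- c(0.5, 0.3, 0.2, 0)
  m_target <- as.numeric(ss_tgt$matrix %*% truth)
  cat96 <- round(m_target * 1e6)
  err_renorm <- max(abs(fit_exposures(cat96, ss_tgt)$exposures - truth))
  err_raw <- max(abs(fit_exposures(cat96, ss_src)$exposures - truth))
  expect_lt(err_renorm, 1e-4)
  expect_gt(err_raw, err_renorm)
})
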