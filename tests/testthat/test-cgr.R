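test_that("integer states follow round-half-away-from-zero on ploidy-scaled ratios", {
  seg <- data.frame(chrom = "chr1", start = 1, end = 10,
                    log2_ratio = c(0, -1, 0.585, log2(1.05), log2(1.25)),
                    state = NA_integer_)
  s <- infer_integer_states(seg)$state
  expect_equal(s, c(2L, 1L, 3L, 2L, 3L))  # 2*1.25 = 2.5 rounds up
})

test_that("switch counting merges short segments first", {
  one <- data.frame(chrom = "chr1", start = 1, end = 1e6, log2_ratio = 0,
                    state = 2L)
  expect_equal(count_cn_switches(one), 0L)

  seg <- data.frame(chrom = "chr1", start = c(1, 11, 21, 31, 41) * 1e6 - c(0, 1, 1, 1, 1) * 1e6 + c(0, 1, 1, 1, 1),
                    end = c(10, 20, 30, 40, 50) * 1e6,
                    log2_ratio = 0, state = c(2L, 1L, 2L, 1L, 2L))
  seg$start <- c(1, seg$end[-5] + 1)
  expect_equal(count_cn_switches(seg), 4L)

  # a 1 kb sliver between two equal-state segments disappears
  seg2 <- data.frame(chrom = "chr1", start = c(1, 1e6 + 1, 1e6 + 1001),
                     end = c(1e6, 1e6 + 1000, 3e6),
                     log2_ratio = 0, state = c(2L, 1L, 2L))
  expect_equal(count_cn_switches(seg2), 0L)
})

test_that("windowed switch maximum matches the anchored-window definition", {
  alt_states <- function(n, len) {
    ends <- cumsum(rep(len, n))
    data.frame(chrom = "chr1", start = c(1, head(ends, -1) + 1), end = ends,
               log2_ratio = 0, state = rep(c(2L, 1L), length.out = n))
  }
  expect_equal(max_switches_in_window(alt_states(12, 4e6)), 11L)
  expect_equal(max_switches_in_window(alt_states(11, 10e6)), 6L)
})

test_that("switch counters agree with brute force on random profiles", {
  set.seed(31)
  for (i in 1:200) {
    prof <- random_profile(sample(2:40, 1))
    expect_equal(max_switches_in_window(prof), brute_max_switches(prof))
    m <- chromocata:::merge_short_segments(prof, 1e4)
    expect_equal(count_cn_switches(prof),
                 sum(m$state[-1] != m$state[-nrow(m)]))
  }
})

test_that("oscillation profile counts states and two-back matches", {
  mk <- function(states) {
    n <- length(states)
    data.frame(chrom = "chr1", start = seq(1, by = 1e6, length.out = n),
               end = seq(1e6, by = 1e6, length.out = n),
               log2_ratio = 0, state = states)
  }
  expect_equal(oscillation_profile(mk(c(2, 3, 2, 3, 2, 3))),
               list(n_osc_states = 2L, osc_fraction = 1))
  expect_equal(oscillation_profile(mk(c(2, 3, 4, 2))),
               list(n_osc_states = 3L, osc_fraction = 0))
  expect_equal(oscillation_profile(mk(c(2, 1, 2, 1, 3, 1, 3))),
               list(n_osc_states = 3L, osc_fraction = 0.8))
  expect_error(oscillation_profile(mk(c(2, 3))), "fewer than 3")
})

test_that("the clustering test is calibrated, detects clusters and regularity", {
  # extreme clustering: 50 breakpoints in 5 Mb of a 100 Mb chromosome
  set.seed(41)
  p <- breakpoint_clustering_pvalue(sort(runif(50, 40e6, 45e6)), 100e6)
  expect_lt(p, 1e-6)
  # equally spaced positions also depart from exponential spacings
  p_reg <- breakpoint_clustering_pvalue(seq(1e6, 99e6, length.out = 50), 100e6)
  expect_lt(p_reg, 0.01)
  # not evaluable below the minimum breakpoint count
  expect_true(is.na(breakpoint_clustering_pvalue(c(1e6, 2e6, 3e6), 100e6)))
  # null calibration at alpha = 0.05 (uniform breakpoints)
  rej <- mean(replicate(400, {
    breakpoint_clustering_pvalue(sort(runif(50, 1, 1e8)), 1e8) < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("dominance classifies gain-, loss- and balanced profiles", {
  mk <- function(states, lens) {
    ends <- cumsum(lens)
    data.frame(chrom = "chr1", start = c(1, head(ends, -1) + 1), end = ends,
               log2_ratio = 0, state = states)
  }
  expect_equal(dominance(mk(c(2, 3, 2, 4, 2), c(5, 1, 5, 1, 5) * 1e6)), "gain")
  expect_equal(dominance(mk(c(2, 1, 2, 1, 2), c(5, 1, 5, 1, 5) * 1e6)), "loss")
  expect_equal(dominance(mk(c(2, 1, 2, 3, 2), c(5, 1, 5, 1, 5) * 1e6)), "mixed")
  # chromothripsis is loss-dominated by construction
  ev <- simulate_chromothripsis(simulation_config(seed = 2, n_breaks = 40,
                                                  loss_prob = 0.4))
  expect_equal(dominance(ev$segments), "loss")
})

test_that("CGR calling recovers a simulated event and rejects scattered SVs", {
  ev <- simulate_chromothripsis(simulation_config(seed = 1, n_breaks = 40,
                                                  loss_prob = 0.4))
  calls <- call_cgr(ev$svs, ev$segments)
  expect_equal(nrow(calls), 1)
  expect_true(calls$passed)
  expect_equal(calls$dominance, "loss")
  expect_true(calls$max_switches_50mb <= calls$n_switches)
  expect_true(calls$region_start <= calls$region_end)

  # three scattered deletions on a flat chromosome fail the switch rule
  cfg <- simulation_config(seed = 12)
  svs <- chromocata:::.scattered_svs(cfg, 3)
  seg <- data.frame(chrom = "chr1", start = 1, end = cfg$chrom_len,
                    log2_ratio = 0, state = 2L)
  calls0 <- call_cgr(svs, seg)
  expect_false(any(calls0$passed))
})

test_that("the 10-switches-in-50-Mb curation threshold is sharp", {
  # a background segment followed by alternating 2-Mb segments (first
  # boundary switches 2 -> 1, then n_switch - 1 internal switches; the
  # trailing flank repeats the last event state, adding none)
  mk_event <- function(n_switch) {
    v <- rep(c(1L, 2L), length.out = n_switch)
    ends <- 10e6 + cumsum(rep(2e6, n_switch))
    seg <- data.frame(chrom = "chr1",
                      start = c(10e6 + 1, head(ends, -1) + 1), end = ends,
                      log2_ratio = 0, state = v)
    seg <- rbind(
      data.frame(chrom = "chr1", start = 1, end = 10e6, log2_ratio = 0,
                 state = 2L),
      seg,
      data.frame(chrom = "chr1", start = max(ends) + 1, end = 150e6,
                 log2_ratio = 0, state = v[n_switch]))
    # fewer than 6 breakends: clustering not evaluable, switch rule decides
    svs <- data.frame(chrom1 = "chr1", pos1 = 11e6, strand1 = "+",
                      chrom2 = "chr1", pos2 = 13e6, strand2 = "-",
                      svtype = "DEL", homology_len = 2L, inserted_seq = "",
                      mapq = 60L, support = 5L, stringsAsFactors = FALSE)
    call_cgr(svs, seg)
  }
  expect_false(mk_event(9)$passed)
  expect_true(mk_event(10)$passed)
})

test_that("CGR calls are invariant under input record order", {
  ev <- simulate_chromothripsis(simulation_config(seed = 6, n_breaks = 35,
                                                  loss_prob = 0.4))
  set.seed(60)
  perm_svs <- ev$svs[sample(nrow(ev$svs)), ]
  perm_seg <- ev$segments[sample(nrow(ev$segments)), ]
  expect_equal(call_cgr(perm_svs, perm_seg), call_cgr(ev$svs, ev$segments))
})

test_that("disjoint chromosome name spaces raise a naming error", {
  ev <- simulate_chromothripsis(simulation_config(seed = 3, n_breaks = 10))
  seg <- ev$segments
  seg$chrom <- "1"  # stripped prefix
  expect_error(call_cgr(ev$svs, seg), "disjoint")
})

test_that("binned-count segmentation finds high-SNR boundaries exactly", {
  prof <- data.frame(chrom = "chr1", start = c(1, 2e6 + 1),
                     end = c(2e6, 4e6), log2_ratio = c(0, 1),
                     state = c(2L, 4L))
  bins <- simulate_bin_counts(prof, seed = 9)
  seg <- segment_bin_counts(bins)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$end[1], 2e6)
  expect_lt(abs(seg$log2_ratio[2] - seg$log2_ratio[1] - 1), 0.05)
})

test_that("flat Poisson bins rarely split", {
  set.seed(19)
  n_one <- sum(replicate(100, {
    prof <- data.frame(chrom = "chr1", start = 1, end = 4e6,
                       log2_ratio = 0, state = 2L)
    nrow(segment_bin_counts(simulate_bin_counts(prof))) == 1
  }))
  expect_gte(n_one, 95)
})
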