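test_that("a single forced internal loss gives one oscillation and one DEL junction", {
  cfg <- simulation_config(seed = 5, n_breaks = 2, loss_prob = 0)
  ev <- simulate_chromothripsis(cfg, shuffle = FALSE,
                                random_orientation = FALSE, force_loss = 1)
  expect_equal(ev$segments$state, c(2L, 1L, 2L))
  expect_equal(count_cn_switches(ev$segments, min_seg_len = 0), 2L)
  expect_equal(nrow(ev$svs), 1)
  expect_equal(ev$svs$svtype, "DEL")
  expect_equal(ev$svs$strand1, "+")
  expect_equal(ev$svs$strand2, "-")
})

test_that("the null event (no loss, identity order, all +) has no junctions", {
  cfg <- simulation_config(seed = 5, n_breaks = 10, loss_prob = 0)
  ev <- simulate_chromothripsis(cfg, shuffle = FALSE,
                                random_orientation = FALSE)
  expect_equal(nrow(ev$svs), 0)
  expect_equal(nrow(ev$segments), 1)
  expect_equal(unique(ev$segments$state), 2L)
  calls <- call_cgr(ev$svs, ev$segments)
  expect_true(nrow(calls) == 0 || !any(calls$passed))
})

test_that("a brute-force replay of the seeded decision trace reproduces the counts", {
  cfg <- simulation_config(seed = 1, n_breaks = 40, loss_prob = 0.4)
  ev <- simulate_chromothripsis(cfg)

  # independent replay of the documented decision order
  set.seed(1)
  win <- cfg$cluster_window
  lo <- floor(runif(1, 1, cfg$chrom_len - win))
  hi <- lo + win - 1
  repeat {
    breaks <- sort(unique(floor(runif(cfg$n_breaks, lo, hi + 1))))
    if (length(breaks) == cfg$n_breaks) break
  }
  n_frag <- cfg$n_breaks + 1
  internal <- 2:(n_frag - 1)
  lost_internal <- runif(length(internal)) < cfg$loss_prob
  kept <- internal[!lost_internal]
  ord <- sample(kept)
  orient_all <- rep("+", n_frag)
  orient_all[ord] <- sample(c("+", "-"), length(ord), replace = TRUE)

  # expected CN segment / switch counts from the loss pattern
  states <- rep(2L, n_frag)
  states[internal[lost_internal]] <- 1L
  runs <- rle(states)$values
  expect_equal(nrow(ev$segments), length(runs))
  expect_equal(sum(ev$segments$state[-1] != ev$segments$state[-nrow(ev$segments)]),
               sum(runs[-1] != runs[-length(runs)]))
  expect_equal(ev$derivative$source_breakpoints, breaks)

  # expected junction count: consecutive derivative pairs that are not
  # reference-adjacent in + orientation
  deriv <- c(1L, ord, n_frag)
  n_junc <- 0L
  for (k in seq_len(length(deriv) - 1)) {
    i <- deriv[k]; j <- deriv[k + 1]
    if (!(j == i + 1 && orient_all[i] == "+" && orient_all[j] == "+")) {
      n_junc <- n_junc + 1L
    }
  }
  expect_equal(nrow(ev$svs), n_junc)
})

test_that("identical seeds give identical simulations", {
  cfg <- simulation_config(seed = 99, n_breaks = 25, loss_prob = 0.35)
  expect_identical(simulate_chromothripsis(cfg), simulate_chromothripsis(cfg))
})

test_that("chromothripsis copy states stay within {background, background-1}", {
  for (seed in 1:10) {
    cfg <- simulation_config(seed = seed, n_breaks = sample(5:50, 1),
                             loss_prob = runif(1))
    ev <- simulate_chromothripsis(cfg)
    expect_true(all(ev$segments$state %in% c(2L, 1L)))
    validate_sv_records(ev$svs)
  }
})

test_that("chromoanasynthesis is gain-dominated with heterozygosity retained", {
  cfg <- simulation_config(seed = 7, n_breaks = 20,
                           gain_model = "template_switch", gain_prob = 0.5)
  ev <- simulate_chromoanasynthesis(cfg)
  expect_equal(dominance(ev$segments), "gain")
  # independent dominance oracle: summed segment lengths by side
  len <- ev$segments$end - ev$segments$start + 1
  gained <- sum(len[ev$segments$state > 2])
  lost <- sum(len[ev$segments$state < 2])
  expect_true(gained >= 2 * lost)
  expect_true(all(ev$segments$retained_het[ev$segments$state > 2]))
  expect_true(all(ev$segments$state >= 2))
})

test_that("chromoanasynthesis with gain_prob 0 reduces to the quiet limit", {
  cfg <- simulation_config(seed = 3, n_breaks = 15,
                           gain_model = "template_switch", gain_prob = 0)
  ev <- simulate_chromoanasynthesis(cfg)
  expect_equal(nrow(ev$svs), 0)
  expect_equal(nrow(ev$segments), 1)
  expect_equal(ev$segments$state, 2L)
  cfg2 <- simulation_config(seed = 3, n_breaks = 15, loss_prob = 0)
  ev2 <- simulate_chromothripsis(cfg2, shuffle = FALSE,
                                 random_orientation = FALSE)
  expect_equal(ev$segments$state, ev2$segments$state)
  expect_equal(nrow(ev2$svs), 0)
})

test_that("junction homology draws match the configured pathway distributions", {
  set.seed(123)
  alt <- draw_junction_homology("altEJ", n = 10000)
  expect_true(abs(mean(alt$homology_len %in% 2:3) - 0.625) < 0.03)
  nhej <- draw_junction_homology("cNHEJ", n = 10000)
  expect_true(abs(mean(nhej$homology_len %in% 0:1) - 0.5) < 0.03)
  expect_true(all(alt$homology_len <= 9))
  expect_true(all(nhej$homology_len >= 0))
  # insertions replace homology and P(mh >= 2) stays >= 0.8 for the
  # template-switching event class (insert_prob 0.05)
  mix <- draw_junction_homology("altEJ", n = 20000, insert_prob = 0.05)
  p_ge2 <- mean(!mix$inserted & !is.na(mix$homology_len) & mix$homology_len >= 2)
  expect_gt(p_ge2, 0.8)
  expect_true(all(is.na(mix$homology_len[mix$inserted])))
})

test_that("catalog simulation is multinomial over the mixed signature", {
  ss <- random_signature_set(k = 3, seed = 11)
  expect_equal(sum(simulate_catalog(ss, c(1, 0, 0), 0, seed = 1)), 0)
  expect_error(simulate_catalog(ss, c(0.5, 0.2, 0.2), 100), "sum to 1")
  expect_error(simulate_catalog(ss, c(0.5, 0.5), 100), "length")
  # pure-signature limit: catalog proportions approach the column
  cat96 <- simulate_catalog(ss, c(1, 0, 0), 2e5, seed = 2)
  cos <- sum((cat96 / sum(cat96)) * ss$matrix[, 1]) /
    sqrt(sum((cat96 / sum(cat96))^2) * sum(ss$matrix[, 1]^2))
  expect_gt(cos, 0.999)
  expect_equal(sum(simulate_catalog(ss, c(0.2, 0.3, 0.5), 5000, seed = 3)), 5000)
})

test_that("bin counts follow the purity/subclone copy-number mixture model", {
  prof <- data.frame(chrom = "chr1", start = c(1, 10e6 + 1),
                     end = c(10e6, 20e6), log2_ratio = c(0, log2(1.5)),
                     state = c(2L, 3L))
  bins <- simulate_bin_counts(prof, purity = 1, clone_fraction = 0.1,
                              seed = 4)
  half <- length(bins$counts) / 2
  shift <- log2(mean(bins$counts[(half + 1):(2 * half)]) /
                  mean(bins$counts[1:half]))
  # expected log2 shift for a 10% subclonal single-copy gain
  expect_true(abs(shift - log2(1.05)) < 0.01)
  # clone_fraction 0: the profile is invisible, bins exchangeable
  bins0 <- simulate_bin_counts(prof, purity = 1, clone_fraction = 0, seed = 5)
  ks <- suppressWarnings(stats::ks.test(bins0$counts[1:half],
                                        bins0$counts[(half + 1):(2 * half)]))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort simulation is deterministic and labels match the bundles", {
  cc <- list(genotypes = data.frame(genotype = c("cNHEJ/p53", "HR/p53"),
                                    n = c(4, 3), cgr_prev = c(0.75, 0.6),
                                    pathway = c("altEJ", "cNHEJ")),
             sim = simulation_config(seed = NULL, n_breaks = 30))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim1 <- simulate_cohort(cc, seed = 8, out_dir = d1)
  sim2 <- simulate_cohort(cc, seed = 8, out_dir = d2)
  expect_identical(sim1$cohort, sim2$cohort)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_equal(nrow(sim1$cohort), 7)
  for (sid in sim1$cohort$sample_id) {
    truth <- sim1$bundles[[sid]]$truth$cgr
    expect_equal(sim1$cohort$cgr_status[sim1$cohort$sample_id == sid], truth)
  }
  # empty cohort
  empty <- simulate_cohort(list(genotypes = data.frame(
    genotype = character(0), n = integer(0), cgr_prev = numeric(0))), seed = 1)
  expect_equal(length(empty$bundles), 0)
  expect_equal(nrow(empty$cohort), 0)
})

test_that("the Fisher pipeline recovers a configured CGR-biallelic odds ratio", {
  cc <- list(genotypes = data.frame(genotype = "g", n = 100, cgr_prev = 0.5),
             biallelic_base_prob = 0.2, biallelic_or = 10,
             sim = simulation_config(seed = NULL, n_breaks = 30))
  sim <- simulate_cohort(cc, seed = 17)
  tab <- cohort_contingency(sim$cohort)
  ft <- fisher_exact_2x2(tab)
  expect_true(ft$odds_ratio >= 5 && ft$odds_ratio <= 20)
  expect_lt(ft$p_value, 0.01)
})
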