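# Synthetic-data generator: shattered-and-religated chromosomes
# (chromothripsis), gain-dominated template-switching events
# (chromoanasynthesis), pathway-conditioned junction microhomology,
# signature-mixture catalogs, and binned read counts.

#' Simulation configuration
#'
#' Collects the generative knobs shared by the rearrangement simulators.
#' Breakpoints are placed uniformly *within* a cluster window (catastrophic
#' events are regional); set `cluster_window = NULL` for uniform placement
#' over the whole chromosome.
#'
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param chrom_len chromosome length in bp.
#' @param n_breaks number of double-strand breaks (>= 1).
#' @param loss_prob per-fragment loss probability (chromothripsis).
#' @param gain_model "none" (shatter/religate) or "template_switch".
#' @param gain_prob per-fragment probability of a copy gain
#'   (chromoanasynthesis).
#' @param pathway junction repair pathway, "cNHEJ" or "altEJ".
#' @param purity tumor purity in `[0, 1]`.
#' @param clone_fraction fraction of tumor cells carrying the event.
#' @param cluster_window width of the breakpoint cluster region in bp
#'   (default 50 Mb, matching the curation window), or NULL.
#' @param insert_prob probability that a junction carries a templated
#'   insertion instead of microhomology.
#' @param background_cn background (modal) integer copy number.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, chrom_len = 150e6, n_breaks = 40L,
                              loss_prob = 0.4, gain_model = c("none", "template_switch"),
                              gain_prob = 0.5, pathway = c("cNHEJ", "altEJ"),
                              purity = 1, clone_fraction = 1,
                              cluster_window = 50e6, insert_prob = 0.05,
                              background_cn = 2L) {
  gain_model <- match.arg(gain_model)
  pathway <- match.arg(pathway)
  stopifnot(n_breaks >= 1, n_breaks < chrom_len,
            loss_prob >= 0, loss_prob <= 1,
            gain_prob >= 0, gain_prob <= 1,
            purity >= 0, purity <= 1,
            clone_fraction >= 0, clone_fraction <= 1,
            insert_prob >= 0, insert_prob <= 1)
  if (!is.null(cluster_window)) {
    stopifnot(cluster_window > 0, cluster_window <= chrom_len)
  }
  structure(list(seed = seed, chrom_len = chrom_len, n_breaks = as.integer(n_breaks),
                 loss_prob = loss_prob, gain_model = gain_model,
                 gain_prob = gain_prob, pathway = pathway, purity = purity,
                 clone_fraction = clone_fraction, cluster_window = cluster_window,
                 insert_prob = insert_prob,
                 background_cn = as.integer(background_cn)),
            class = "simulation_config")
}

# draw n_breaks distinct integer break positions, clustered or genome-wide
.draw_breakpoints <- function(config) {
  len <- config$chrom_len
  win <- config$cluster_window
  if (is.null(win) || win >= len) {
    lo <- 1; hi <- len - 1
  } else {
    lo <- floor(runif(1, 1, len - win))
    hi <- lo + win - 1
  }
  repeat {
    breaks <- sort(unique(floor(runif(config$n_breaks, lo, hi + 1))))
    if (length(breaks) == config$n_breaks) return(breaks)
  }
}

# partition [1, chrom_len] at the break positions; fragment i spans
# (breaks[i-1]+1) .. breaks[i]
.fragments_from_breaks <- function(breaks, chrom_len) {
  starts <- c(1, breaks + 1)
  ends <- c(breaks, chrom_len)
  data.frame(start = starts, end = ends)
}

# collapse a per-fragment state vector into merged CN segments
.segments_from_states <- function(frags, states, ploidy = 2L,
                                  chrom = "chr1") {
  r <- rle(states)
  idx_end <- cumsum(r$lengths)
  idx_start <- c(1, head(idx_end, -1) + 1)
  data.frame(
    chrom = chrom,
    start = frags$start[idx_start],
    end = frags$end[idx_end],
    log2_ratio = log2(pmax(r$values, 0.5) / ploidy),
    state = r$values,
    stringsAsFactors = FALSE
  )
}

# junction between the right side of placed fragment X and the left side of
# placed fragment Y (orientations as placed on the derivative)
.make_junction <- function(fx, ox, fy, oy, chrom, hl, ins_seq, rng_support = TRUE) {
  p1 <- if (ox == "+") fx$end else fx$start
  s1 <- if (ox == "+") "+" else "-"
  p2 <- if (oy == "+") fy$start else fy$end
  s2 <- if (oy == "+") "-" else "+"
  # canonical order: lower breakend first
  if (p2 < p1) {
    tmp <- p1; p1 <- p2; p2 <- tmp
    tmp <- s1; s1 <- s2; s2 <- tmp
  }
  svtype <- if (s1 == s2) "BND" else if (s1 == "+") "DEL" else "DUP"
  data.frame(
    chrom1 = chrom, pos1 = as.integer(p1), strand1 = s1,
    chrom2 = chrom, pos2 = as.integer(p2), strand2 = s2,
    svtype = svtype,
    homology_len = hl, inserted_seq = ins_seq,
    mapq = 60L, support = 2L + rpois(1, 6),
    stringsAsFactors = FALSE
  )
}

#' Simulate a chromothripsis event
#'
#' Shatters one chromosome at `n_breaks` positions, loses each internal
#' fragment independently with probability `loss_prob`, shuffles and
#' randomly orients the survivors, and religates them into a linear
#' derivative chromosome (terminal fragments are kept in place so the
#' derivative stays linear). The emitted copy-number profile takes exactly
#' the states {background, background - 1}; the emitted junctions are typed
#' from their breakend orientations (+/- deletion-like, -/+ duplication-like,
#' same-orientation joins reported as BND) and carry microhomology lengths
#' drawn from the configured repair pathway.
#'
#' @param config a [simulation_config()] with `gain_model = "none"`.
#' @param shuffle shuffle retained internal fragments (default TRUE).
#' @param random_orientation randomly flip retained fragments (default TRUE).
#' @param force_loss optional integer indices (in 1..n_breaks-1, counting
#'   internal fragments) forced to be lost, overriding the Bernoulli draw;
#'   used to construct deterministic events.
#' @return a list with `derivative` (fragments + source breakpoints),
#'   `segments` (merged CN segments) and `svs` (junction records).
#' @export
simulate_chromothripsis <- function(config, shuffle = TRUE,
                                    random_orientation = TRUE,
                                    force_loss = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$gain_model != "none") {
    stop("simulate_chromothripsis requires gain_model = 'none'")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  breaks <- .draw_breakpoints(config)
  frags <- .fragments_from_breaks(breaks, config$chrom_len)
  n_frag <- nrow(frags)
  internal <- if (n_frag > 2) 2:(n_frag - 1) else integer(0)
  lost <- logical(n_frag)
  if (!is.null(force_loss)) {
    stopifnot(all(force_loss >= 1), all(force_loss <= length(internal)))
    lost[internal[force_loss]] <- TRUE
  } else if (length(internal) > 0) {
    lost[internal] <- runif(length(internal)) < config$loss_prob
  }
  kept_internal <- internal[!lost[internal]]
  order_internal <- if (shuffle && length(kept_internal) > 1) {
    sample(kept_internal)
  } else kept_internal
  orient <- rep("+", n_frag)
  if (random_orientation && length(order_internal) > 0) {
    orient[order_internal] <- sample(c("+", "-"), length(order_internal),
                                     replace = TRUE)
  }
  deriv_idx <- c(1L, order_internal, n_frag)
  deriv_idx <- unique(deriv_idx)  # n_frag == 1 guard

  # junctions between consecutive derivative fragments that are not
  # reference-adjacent in the same (+) orientation
  svs <- empty_sv_records()
  if (length(deriv_idx) > 1) {
    for (k in seq_len(length(deriv_idx) - 1)) {
      i <- deriv_idx[k]; j <- deriv_idx[k + 1]
      adjacent <- (j == i + 1) && orient[i] == "+" && orient[j] == "+" &&
        !lost[i] && !lost[j]
      if (adjacent) next
      d <- draw_junction_homology(config$pathway, n = 1,
                                  insert_prob = config$insert_prob)
      ins <- if (d$inserted) .random_dna(sample(2:10, 1)) else ""
      hl <- if (d$inserted) NA_integer_ else d$homology_len
      svs <- rbind(svs, .make_junction(frags[i, ], orient[i], frags[j, ],
                                       orient[j], "chr1", hl, ins))
    }
  }
  states <- ifelse(lost, config$background_cn - 1L, config$background_cn)
  segments <- .segments_from_states(frags, states, ploidy = 2L)
  segments$sample <- NULL
  derivative <- list(
    fragments = data.frame(start = frags$start[deriv_idx],
                           end = frags$end[deriv_idx],
                           orientation = orient[deriv_idx],
                           copy_index = 1L),
    source_breakpoints = breaks
  )
  if (nrow(svs) > 0) {
    svs <- svs[order(svs$chrom1, svs$pos1), , drop = FALSE]
    rownames(svs) <- NULL
  }
  list(derivative = derivative, segments = segments, svs = svs)
}

#' Simulate a chromoanasynthesis-like event
#'
#' A template-switching walk re-copies fragments of the shattered region:
#' each internal fragment is duplicated or triplicated with probability
#' `gain_prob`, producing a gain-dominated copy-number profile (all gains,
#' no losses, heterozygosity retained on every gained segment). Junctions
#' carry microhomology drawn from the alternative end-joining distribution
#' (so most have >= 2 bp) and templated insertions with probability
#' `insert_prob`.
#'
#' @param config a [simulation_config()] with `gain_model = "template_switch"`.
#' @return as [simulate_chromothripsis()]; segments gain a `retained_het`
#'   column, TRUE for every gained segment.
#' @export
simulate_chromoanasynthesis <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$gain_model != "template_switch") {
    stop("simulate_chromoanasynthesis requires gain_model = 'template_switch'")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  breaks <- .draw_breakpoints(config)
  frags <- .fragments_from_breaks(breaks, config$chrom_len)
  n_frag <- nrow(frags)
  internal <- if (n_frag > 2) 2:(n_frag - 1) else integer(0)
  copies <- rep(1L, n_frag)
  if (length(internal) > 0) {
    gained <- runif(length(internal)) < config$gain_prob
    extra <- integer(length(internal))
    extra[gained] <- sample(1:2, sum(gained), replace = TRUE,
                            prob = c(0.7, 0.3))
    copies[internal] <- 1L + extra
  }
  svs <- empty_sv_records()
  deriv <- list()
  for (i in seq_len(n_frag)) {
    for (ci in seq_len(copies[i])) {
      deriv[[length(deriv) + 1]] <- data.frame(
        start = frags$start[i], end = frags$end[i],
        orientation = "+", copy_index = ci)
      if (ci > 1) {
        # one tandem-style junction per extra copy
        d <- draw_junction_homology("altEJ", n = 1,
                                    insert_prob = config$insert_prob)
        ins <- if (d$inserted) .random_dna(sample(2:10, 1)) else ""
        hl <- if (d$inserted) NA_integer_ else d$homology_len
        svs <- rbind(svs, .make_junction(frags[i, ], "-", frags[i, ], "-",
                                         "chr1", hl, ins))
      }
    }
  }
  states <- config$background_cn + (copies - 1L)
  segments <- .segments_from_states(frags, states, ploidy = 2L)
  segments$retained_het <- segments$state > config$background_cn
  if (nrow(svs) > 0) {
    svs <- svs[order(svs$chrom1, svs$pos1), , drop = FALSE]
    rownames(svs) <- NULL
  }
  list(derivative = list(fragments = do.call(rbind, deriv),
                         source_breakpoints = breaks),
       segments = segments, svs = svs)
}

# default microhomology-length distributions on support 0..9 bp
.MH_PMF <- list(
  # canonical NHEJ: ~50% blunt or 0-1 bp
  cNHEJ = c(0.30, 0.20, 0.12, 0.10, 0.08, 0.06, 0.05, 0.04, 0.03, 0.02),
  # alternative end joining: 2-3 bp for 62.5% of junctions (mid of 50-75%)
  altEJ = c(0.05, 0.075, 0.35, 0.275, 0.09, 0.05, 0.04, 0.03, 0.025, 0.015)
)

#' Draw junction microhomology lengths for a repair pathway
#'
#' Canonical NHEJ favors blunt joins and very short homology
#' (P(0-1 bp) = 0.5 by default); alternative end joining favors 2-3 bp
#' (P = 0.625 by default, the midpoint of the reported 50-75% range).
#' Support is bounded at 9 bp. With probability `insert_prob` a junction
#' instead carries a templated insertion (no microhomology).
#'
#' @param pathway "cNHEJ" or "altEJ".
#' @param n number of draws.
#' @param probs optional length-10 probability vector over 0..9 bp,
#'   overriding the pathway default.
#' @param insert_prob per-junction insertion probability (default 0).
#' @return data.frame with columns `homology_len` (NA when inserted) and
#'   `inserted` (logical).
#' @export
draw_junction_homology <- function(pathway = c("cNHEJ", "altEJ"), n = 1,
                                   probs = NULL, insert_prob = 0) {
  pathway <- match.arg(pathway)
  if (is.null(probs)) probs <- .MH_PMF[[pathway]]
  stopifnot(length(probs) == 10, all(probs >= 0),
            abs(sum(probs) - 1) < 1e-8)
  len <- sample(0:9, n, replace = TRUE, prob = probs)
  inserted <- runif(n) < insert_prob
  len[inserted] <- NA_integer_
  data.frame(homology_len = as.integer(len), inserted = inserted)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a 96-channel mutation catalog from signature mixtures
#'
#' Draws `n_mut` mutations from the multinomial law with channel
#' probabilities `S %*% exposures`.
#'
#' @param signatures a [signature_set()].
#' @param exposures non-negative mixture weights summing to 1 (length K).
#' @param n_mut number of mutations.
#' @param seed optional seed.
#' @return named integer vector of length 96 summing to `n_mut`.
#' @export
simulate_catalog <- function(signatures, exposures, n_mut, seed = NULL) {
  stopifnot(inherits(signatures, "signature_set"))
  S <- signatures$matrix
  if (length(exposures) != ncol(S)) {
    stop("exposures must have length ", ncol(S))
  }
  if (any(exposures < 0) || abs(sum(exposures) - 1) > 1e-8) {
    stop("exposures must be non-negative and sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- as.vector(S %*% exposures)
  counts <- if (n_mut > 0) as.integer(rmultinom(1, n_mut, p)) else
    integer(96)
  setNames(counts, rownames(S))
}

#' Simulate binned read counts over a copy-number profile
#'
#' Per-bin counts are Poisson with mean
#' `base_rate * effective_cn / 2`, where
#' `effective_cn = 2 (1 - purity * f) + cn * purity * f` for a subclone at
#' fraction `f` in a tumor of the given purity, and
#' `base_rate = coverage * bin_size / read_span`. The defaults (30x, 4 kb
#' bins) are the analytic-sensitivity regime in which a 10% subclonal
#' single-copy gain shifts the expected log2 ratio by log2(1.05) ~ 0.07.
#'
#' @param cn_profile data.frame of CN segments (chrom, start, end, state).
#' @param coverage sequencing depth (fold).
#' @param bin_size bin width in bp.
#' @param purity tumor purity.
#' @param clone_fraction fraction of tumor cells carrying the CN profile.
#' @param read_span read length in bp (default 150).
#' @param seed optional seed.
#' @return list of class `bin_counts`: chrom, start positions, bin_size,
#'   integer counts.
#' @export
simulate_bin_counts <- function(cn_profile, coverage = 30, bin_size = 4000,
                                purity = 1, clone_fraction = 1,
                                read_span = 150, seed = NULL) {
  stopifnot(coverage > 0, bin_size > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cn_profile$state) || anyNA(cn_profile$state)) {
    cn_profile <- infer_integer_states(cn_profile)
  }
  lo <- min(cn_profile$start)
  hi <- max(cn_profile$end)
  starts <- seq(lo, hi - bin_size + 1, by = bin_size)
  mids <- starts + bin_size / 2
  seg_idx <- findInterval(mids, cn_profile$start)
  cn <- cn_profile$state[seg_idx]
  eff <- 2 * (1 - purity * clone_fraction) + cn * purity * clone_fraction
  base_rate <- coverage * bin_size / read_span
  counts <- rpois(length(starts), base_rate * eff / 2)
  structure(list(chrom = cn_profile$chrom[1], start = starts,
                 bin_size = bin_size, counts = counts),
            class = "bin_counts")
}

#' Simulate a tumor cohort with ground truth
#'
#' Generates per-sample rearrangement data (a catastrophic event or a quiet
#' genome with a few scattered rearrangements), a biallelic-repair-hit flag
#' whose odds depend on CGR status, oncogene-gain flags, and a
#' signature-mixture mutation catalog. Within one genotype the event
#' prevalence and junction repair pathway are fixed by the config.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{genotypes}{data.frame with columns genotype, entity, n,
#'       cgr_prev, pathway.}
#'     \item{biallelic_base_prob}{P(biallelic hit) for CGR-negative samples
#'       (default 0.2).}
#'     \item{biallelic_or}{odds ratio of a biallelic hit for CGR-positive
#'       samples (default 10).}
#'     \item{gain_prob_cgr, gain_prob_null}{P(Myc-or-Mycn gain) given CGR
#'       status (defaults 0.9, 0.5).}
#'     \item{signatures}{a [signature_set()] (optional; catalogs skipped
#'       when absent).}
#'     \item{exposures}{mixture weights for the catalogs.}
#'     \item{n_mut}{mutations per catalog (default 3000).}
#'     \item{sim}{a [simulation_config()] template for the events.}
#'   }
#' @param seed integer seed.
#' @param out_dir optional directory; per-sample BEDPE/SEG/catalog files and
#'   the sample sheet are written there in the package formats.
#' @return list with `cohort` (sample sheet incl. ground-truth columns) and
#'   `bundles` (per-sample list of svs, segments, catalog, truth).
#' @export
simulate_cohort <- function(config, seed = 1L, out_dir = NULL) {
  set.seed(seed)
  g <- config$genotypes
  stopifnot(is.data.frame(g), all(c("genotype", "n", "cgr_prev") %in% names(g)))
  if (is.null(g$pathway)) g$pathway <- rep("altEJ", nrow(g))
  if (is.null(g$entity)) g$entity <- rep("MB", nrow(g))
  base_p <- config$biallelic_base_prob %||% 0.2
  or <- config$biallelic_or %||% 10
  p_cgr_biall <- plogis(qlogis(base_p) + log(or))
  gain_p_cgr <- config$gain_prob_cgr %||% 0.9
  gain_p_null <- config$gain_prob_null %||% 0.5
  n_mut <- config$n_mut %||% 3000
  sim_template <- config$sim %||% simulation_config(seed = NULL)

  rows <- list(); bundles <- list()
  sample_i <- 0
  for (gi in seq_len(nrow(g))) {
    for (k in seq_len(g$n[gi])) {
      sample_i <- sample_i + 1
      sid <- sprintf("S%03d", sample_i)
      has_cgr <- runif(1) < g$cgr_prev[gi]
      cfg <- sim_template
      cfg$seed <- NULL
      cfg$pathway <- g$pathway[gi]
      if (has_cgr) {
        ev <- simulate_chromothripsis(cfg)
        svs <- ev$svs
        segments <- ev$segments
        cgr_chroms <- "chr1"
      } else {
        svs <- .scattered_svs(cfg, n = sample(0:3, 1))
        segments <- data.frame(chrom = "chr1", start = 1,
                               end = cfg$chrom_len, log2_ratio = 0,
                               state = cfg$background_cn,
                               stringsAsFactors = FALSE)
        cgr_chroms <- ""
      }
      biallelic <- runif(1) < (if (has_cgr) p_cgr_biall else base_p)
      gain <- runif(1) < (if (has_cgr) gain_p_cgr else gain_p_null)
      which_gene <- sample(c("mycn", "myc"), 1)
      catalog <- if (!is.null(config$signatures)) {
        simulate_catalog(config$signatures, config$exposures, n_mut)
      } else NULL
      rows[[sample_i]] <- data.frame(
        sample_id = sid, genotype = g$genotype[gi], entity = g$entity[gi],
        cgr_chroms = cgr_chroms, cgr_status = has_cgr,
        mycn_gain = gain && which_gene == "mycn",
        myc_gain = gain && which_gene == "myc",
        biallelic_repair_hit = biallelic,
        pathway = g$pathway[gi],
        stringsAsFactors = FALSE
      )
      bundles[[sid]] <- list(svs = svs, segments = segments,
                             catalog = catalog,
                             truth = list(cgr = has_cgr,
                                          pathway = g$pathway[gi]))
    }
  }
  cohort <- if (length(rows) == 0) {
    data.frame(sample_id = character(0), genotype = character(0),
               entity = character(0), cgr_chroms = character(0),
               cgr_status = logical(0), mycn_gain = logical(0),
               myc_gain = logical(0), biallelic_repair_hit = logical(0),
               pathway = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  rownames(cohort) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(bundles)) {
      b <- bundles[[sid]]
      write_sv_bedpe(b$svs, file.path(out_dir, paste0(sid, ".bedpe")))
      seg <- b$segments
      seg$sample <- sid
      write_cn_seg(seg, file.path(out_dir, paste0(sid, ".seg")),
                   params = list(seed = seed))
      if (!is.null(b$catalog)) {
        write_catalog_tsv(b$catalog, file.path(out_dir, paste0(sid, "_catalog.tsv")))
      }
    }
    write_tsv_commented(cohort, file.path(out_dir, "cohort.tsv"),
                        params = list(seed = seed))
  }
  list(cohort = cohort, bundles = bundles)
}

# a handful of isolated rearrangements on an otherwise quiet chromosome
.scattered_svs <- function(config, n = 3) {
  if (n == 0) return(empty_sv_records())
  out <- empty_sv_records()
  for (i in seq_len(n)) {
    p1 <- floor(runif(1, 1, config$chrom_len * 0.9))
    p2 <- p1 + floor(runif(1, 1e4, 5e6))
    d <- draw_junction_homology(config$pathway, n = 1)
    out <- rbind(out, data.frame(
      chrom1 = "chr1", pos1 = as.integer(p1), strand1 = "+",
      chrom2 = "chr1", pos2 = as.integer(p2), strand2 = "-",
      svtype = "DEL", homology_len = d$homology_len, inserted_seq = "",
      mapq = 60L, support = 2L + rpois(1, 6), stringsAsFactors = FALSE))
  }
  out <- out[order(out$pos1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
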