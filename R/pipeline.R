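# End-to-end pipeline: simulate (optional) -> CGR scoring -> microhomology
# -> signatures -> cohort association, with per-stage TSV outputs and a
# machine-readable run manifest.

#' Default pipeline configuration
#'
#' Every stage parameter defaults to the scoring thresholds used throughout
#' the package: 10 switches within 50 Mb, clustering alpha 0.05 with at
#' least 6 breakpoints, 5 junctions per microhomology region class,
#' 1-9 bp homology bins, cosine QC 0.8, and the mapq >= 30 / support >= 2
#' SV hard filter.
#'
#' @param seed integer seed for all stochastic stages.
#' @return nested list of per-stage parameter blocks.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = seed,
    io = list(min_mapq = 30, min_support = 2),
    cgr = cgr_params(),
    mh = list(min_breakpoints = 5, bin = "2-3"),
    signatures = list(qc_threshold = 0.8),
    association = list(fdr_q = 0.05),
    simulate = NULL,
    inputs = NULL
  )
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) the cohort simulator, then per-sample CGR scoring,
#' microhomology distributions inside/outside the called regions,
#' signature-exposure fits, and cohort-level association tests. Each stage
#' writes a TSV under `out_dir`; a JSON manifest records the package
#' version, the full parameter set, the seed and checksums of any file
#' inputs, and `summary.txt` gives a human-readable overview.
#'
#' @param config list as from [pipeline_config()], or a path to a YAML file
#'   with the same structure. Provide either a `simulate` block (passed to
#'   [simulate_cohort()]) or an `inputs` block with `cohort` (sample-sheet
#'   TSV) and per-sample `sv`/`seg` file templates containing `{sample}`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the cohort table, per-sample CGR calls,
#'   microhomology table, exposure fits and association results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  base <- pipeline_config()
  for (nm in names(base)) {
    if (is.null(config[[nm]])) config[[nm]] <- base[[nm]]
    else if (is.list(base[[nm]])) {
      for (k in names(base[[nm]])) {
        if (is.null(config[[nm]][[k]])) config[[nm]][[k]] <- base[[nm]][[k]]
      }
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  input_files <- character(0)

  if (!is.null(config$simulate)) {
    sim <- simulate_cohort(config$simulate, seed = config$seed)
    cohort <- sim$cohort
    bundles <- sim$bundles
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (is.null(inp$cohort)) stop("inputs block must name a cohort sample sheet")
    cohort <- read_cohort_tsv(inp$cohort)
    input_files <- inp$cohort
    bundles <- list()
    for (sid in cohort$sample_id) {
      svp <- gsub("{sample}", sid, inp$sv, fixed = TRUE)
      segp <- gsub("{sample}", sid, inp$seg, fixed = TRUE)
      if (!file.exists(svp) || !file.exists(segp)) {
        stop("stage io failed for sample ", sid, ": missing ", svp, " or ", segp)
      }
      input_files <- c(input_files, svp, segp)
      seg <- read_cn_seg(segp)
      bundles[[sid]] <- list(svs = read_sv_bedpe(svp),
                             segments = seg[setdiff(names(seg), "sample")],
                             catalog = NULL)
    }
  } else {
    stop("config must provide either a simulate block or an inputs block")
  }

  # stage: CGR scoring
  calls <- list(); regions <- list()
  for (sid in names(bundles)) {
    b <- bundles[[sid]]
    svs <- filter_sv_records(b$svs, config$io$min_mapq, config$io$min_support)
    cc <- tryCatch(call_cgr(svs, b$segments, config$cgr),
                   error = function(e) stop("stage score-cgr failed for sample ",
                                            sid, ": ", conditionMessage(e)))
    if (nrow(cc) > 0) cc <- cbind(sample_id = sid, cc)
    calls[[sid]] <- cc
    passed <- cc[!is.na(cc$passed) & cc$passed, , drop = FALSE]
    regions[[sid]] <- if (nrow(passed) > 0) {
      data.frame(chrom = passed$chrom, start = passed$region_start,
                 end = passed$region_end, stringsAsFactors = FALSE)
    } else NULL
    bundles[[sid]]$svs_filtered <- svs
  }
  calls_df <- do.call(rbind, calls[vapply(calls, nrow, 0L) > 0])
  if (is.null(calls_df)) calls_df <- cbind(sample_id = character(0), call_cgr(
    empty_sv_records(), data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0), log2_ratio = numeric(0),
                                   state = integer(0))))
  rownames(calls_df) <- NULL
  write_tsv_commented(calls_df, file.path(out_dir, "cgr_calls.tsv"),
                      params = config$cgr)

  # stage: microhomology
  mh_rows <- list()
  for (sid in names(bundles)) {
    reg <- regions[[sid]]
    if (is.null(reg)) next
    md <- region_mh_distribution(bundles[[sid]]$svs_filtered, reg,
                                 min_breakpoints = config$mh$min_breakpoints)
    for (cls in c("cgr", "non_cgr")) {
      if (is.null(md[[cls]])) next
      counts <- md[[cls]]$counts
      mh_rows[[length(mh_rows) + 1]] <- data.frame(
        sample_id = sid, region_label = cls, n_junctions = md[[cls]]$n_junctions,
        t(counts), proportion_2_3 = mh_proportion(md[[cls]], config$mh$bin),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  mh_df <- if (length(mh_rows) > 0) do.call(rbind, mh_rows) else
    data.frame(sample_id = character(0))
  write_tsv_commented(mh_df, file.path(out_dir, "microhomology.tsv"),
                      params = config$mh)

  # stage: signatures
  sig_df <- data.frame(sample_id = character(0))
  if (!is.null(config$simulate$signatures)) {
    sig_rows <- list()
    for (sid in names(bundles)) {
      cat96 <- bundles[[sid]]$catalog
      if (is.null(cat96) || sum(cat96) == 0) next
      f <- fit_exposures(cat96, config$simulate$signatures,
                         config$signatures$qc_threshold)
      sig_rows[[length(sig_rows) + 1]] <- data.frame(
        sample_id = sid, t(f$exposures), cosine = f$cosine, kept = f$kept,
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    if (length(sig_rows) > 0) sig_df <- do.call(rbind, sig_rows)
  }
  write_tsv_commented(sig_df, file.path(out_dir, "signature_fits.tsv"),
                      params = config$signatures)

  # stage: association
  cohort$cgr_status_called <- vapply(cohort$sample_id, function(sid) {
    !is.null(regions[[sid]])
  }, TRUE)
  assoc <- NULL
  if ("biallelic_repair_hit" %in% names(cohort)) {
    tab <- cohort_contingency(cohort, "biallelic_repair_hit")
    ft <- fisher_exact_2x2(tab)
    assoc <- data.frame(test = "cgr_vs_biallelic",
                        odds_ratio = ft$odds_ratio, p = ft$p_value,
                        n_excluded = attr(tab, "n_excluded"))
    write_tsv_commented(assoc, file.path(out_dir, "association.tsv"),
                        params = config$association)
  }
  prev <- prevalence(cohort, "genotype", "cgr_status_called")
  write_tsv_commented(prev, file.path(out_dir, "prevalence.tsv"),
                      params = list(feature = "cgr_status_called"))
  write_tsv_commented(cohort, file.path(out_dir, "cohort_annotated.tsv"),
                      params = list(seed = config$seed))

  manifest <- list(
    package = "chromocata",
    version = as.character(utils::packageVersion("chromocata")),
    seed = config$seed,
    parameters = config[c("io", "cgr", "mh", "signatures", "association")],
    input_checksums = if (length(input_files) > 0)
      as.list(tools::md5sum(input_files)) else list(),
    n_samples = nrow(cohort)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  summary_lines <- c(
    sprintf("chromocata run (seed %d): %d samples", config$seed, nrow(cohort)),
    sprintf("CGR-positive (called): %d/%d (%.0f%%)",
            sum(cohort$cgr_status_called), nrow(cohort),
            100 * mean(cohort$cgr_status_called)),
    if (!is.null(assoc)) sprintf("CGR x biallelic Fisher p = %.3g (OR %.2f)",
                                 assoc$p, assoc$odds_ratio)
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(cohort = cohort, calls = calls_df, microhomology = mh_df,
                 signature_fits = sig_df, association = assoc,
                 prevalence = prev))
}
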