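# Cohort-level statistics: exact 2x2 tests, prevalence tables, and a
# genome-wide amplified-locus screen with FDR control.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability method: the two-sided p is the sum of hypergeometric
#' point probabilities not exceeding that of the observed table (with a
#' 1e-7 relative tolerance for ties), computed in log space so tables with
#' totals up to ~1e6 remain exact. The odds ratio is the sample `ad / bc`
#' (reported as NA when a margin is zero; the p-value is still computed).
#'
#' @param a,b,c,d cell counts; rows are CGR+/CGR-, columns feature+/feature-
#'   by the package's convention. A 2x2 matrix may be given as `a`.
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers")
  }
  n <- a + b + c + d
  if (n < 1) stop("empty table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  logp_obs <- logp[k == a]
  p <- sum(exp(logp[logp <= logp_obs + log1p(1e-7)]))
  p <- min(p, 1)
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else a * d / (b * c)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) or <- NA_real_
  list(odds_ratio = or, p_value = p)
}

#' Build the CGR x feature contingency table from a cohort
#'
#' Rows are CGR status (TRUE first), columns the feature (TRUE first).
#' Samples with unknown (NA) feature values are excluded listwise; the
#' number excluded is attached as the `n_excluded` attribute.
#'
#' @param cohort cohort data.frame with a logical `cgr_status` column.
#' @param feature name of a logical cohort column (default
#'   "biallelic_repair_hit").
#' @return 2x2 integer matrix.
#' @export
cohort_contingency <- function(cohort, feature = "biallelic_repair_hit") {
  stopifnot(feature %in% names(cohort))
  f <- cohort[[feature]]
  keep <- !is.na(f) & !is.na(cohort$cgr_status)
  excluded <- sum(!keep)
  cg <- cohort$cgr_status[keep]; f <- f[keep]
  m <- matrix(c(sum(cg & f), sum(cg & !f),
                sum(!cg & f), sum(!cg & !f)),
              nrow = 2, byrow = TRUE,
              dimnames = list(cgr = c("TRUE", "FALSE"),
                              feature = c("TRUE", "FALSE")))
  attr(m, "n_excluded") <- excluded
  m
}

#' Prevalence of a feature per cohort group
#'
#' @param cohort cohort data.frame.
#' @param group_by name of the grouping column (e.g. "genotype").
#' @param feature logical column counted (default "cgr_status").
#' @return data.frame with group, k (feature-positive), n and fraction;
#'   empty groups are omitted with a warning.
#' @export
prevalence <- function(cohort, group_by = "genotype", feature = "cgr_status") {
  stopifnot(group_by %in% names(cohort), feature %in% names(cohort))
  if (nrow(cohort) == 0) {
    return(data.frame(group = character(0), k = integer(0), n = integer(0),
                      fraction = numeric(0)))
  }
  groups <- unique(cohort[[group_by]])
  rows <- list()
  for (g in groups) {
    sel <- cohort[[group_by]] == g
    f <- cohort[[feature]][sel]
    f <- f[!is.na(f)]
    if (length(f) == 0) {
      warning("group '", g, "' has no usable rows; omitted")
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      group = g, k = sum(f), n = length(f), fraction = mean(f),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genome-wide amplified-locus vs CGR association screen
#'
#' Per locus, a Fisher exact test of amplification status against CGR
#' status, with Benjamini-Hochberg control of the false discovery rate.
#' Constant locus columns (amplified in all or none) carry no information
#' and are assigned p = 1 with a flag.
#'
#' @param amp samples x loci logical matrix of amplification calls.
#' @param cgr logical vector of per-sample CGR status (length = nrow(amp)).
#' @param fdr_q FDR threshold (default 0.05).
#' @return data.frame with one row per locus: odds_ratio, p, q (BH),
#'   significant, constant.
#' @export
locus_cgr_association <- function(amp, cgr, fdr_q = 0.05) {
  amp <- as.matrix(amp)
  stopifnot(nrow(amp) == length(cgr))
  loci <- colnames(amp) %||% paste0("locus", seq_len(ncol(amp)))
  p <- numeric(ncol(amp)); or <- numeric(ncol(amp))
  constant <- logical(ncol(amp))
  for (j in seq_len(ncol(amp))) {
    x <- amp[, j]
    if (all(x) || all(!x)) {
      constant[j] <- TRUE
      p[j] <- 1
      or[j] <- NA_real_
      next
    }
    ft <- fisher_exact_2x2(sum(cgr & x), sum(cgr & !x),
                           sum(!cgr & x), sum(!cgr & !x))
    p[j] <- ft$p_value
    or[j] <- ft$odds_ratio
  }
  q <- p.adjust(p, method = "BH")
  data.frame(locus = loci, odds_ratio = or, p = p, q = q,
             significant = q <= fdr_q, constant = constant,
             stringsAsFactors = FALSE)
}
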