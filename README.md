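# chromocata

Scoring, simulation and cohort analysis of catastrophic genomic
rearrangements (chromothripsis and chromoanasynthesis) in
DNA-repair-deficient tumors.

## What it is for

Tumors lacking double-strand-break repair — homologous recombination (HR;
e.g. BRCA2) or canonical non-homologous end joining (cNHEJ; e.g. XRCC4,
LIG4) on a p53-deficient background — frequently carry complex genome
rearrangements (CGR): one-off events that shatter a chromosome region into
tens to hundreds of fragments which are religated in scrambled order, with
copy-number profiles oscillating between two or three integer states
(chromothripsis) or dominated by template-switching gains
(chromoanasynthesis). The package is for analysts who want to

* **call CGRs** per chromosome from copy-number segments and SV junctions,
* **infer the repair pathway** that religated the fragments from junction
  microhomology lengths (cNHEJ: blunt/0–1 bp; alt-EJ: 2–3 bp),
* **decompose mutation catalogs** into known signatures across genomes
  with different trinucleotide backgrounds, and
* **test cohort-level associations** (CGR vs biallelic repair-gene
  inactivation, CGR vs amplified oncogene loci) exactly,

with a seeded simulator providing ground truth for every stage.

## The statistics at the core

* **CGR call**: a chromosome passes when (i) the number of copy-number
  switches (boundaries between different integer states, after merging
  segments < 10 kb) within some 50-Mb window is ≥ 10, and (ii) the
  breakpoint positions depart from complete spatial randomness — a
  one-sample Kolmogorov–Smirnov test of inter-breakpoint spacings against
  Exp(rate = (n−1)/L), calibrated against a Monte-Carlo null — at
  α = 0.05 (or too few breakpoints to test). Oscillation statistics and
  gain/loss dominance are reported for audit.
* **Microhomology**: junction homology = total placement ambiguity of the
  junction in the reference (orientation-aware, reverse-complementing
  inverted breakends), binned into 0–1/2–3/4–5/6–7/8–9 bp; per-sample
  shares of the 2–3 bp bin compared between groups by beta regression
  (logit mean link, common precision, ML + Wald test).
* **Signatures**: exposures solve min ‖S·e − m‖², e ≥ 0 (Lawson–Hanson
  NNLS), with cross-genome renormalization of S by context-frequency
  ratios and a cosine ≥ 0.8 reconstruction criterion.
* **Association**: two-sided Fisher exact tests by the point-probability
  method in log space; Benjamini–Hochberg FDR over genome-wide locus
  screens.

## Worked example

Simulate a chromothripsis event and score it:

```r
library(chromocata)
cfg <- simulation_config(seed = 1, n_breaks = 40, loss_prob = 0.4)
ev  <- simulate_chromothripsis(cfg)
call_cgr(ev$svs, ev$segments)
#>   chrom region_start region_end n_breakpoints n_switches max_switches_50mb
#> 1  chr1     35861747   73286128            54         18                18
#>   n_osc_states osc_fraction    cluster_p dominance passed
#> 1            2            1 2.841759e-07      loss   TRUE
```

The 40 breaks fall in a 50-Mb cluster window; 18 switches between states
2 and 1 (a perfect two-state oscillation, `osc_fraction = 1`) land in one
window, the 54 junction breakends are far more clustered than chance
(`cluster_p ≈ 3e-7`), and the loss-dominated event is called
(`passed = TRUE`).

Cohort statistics on the bundled murine medulloblastoma reference table:

```r
prevalence(mouse_mb_cohort(), "genotype")
#>       group k  n  fraction
#> 1 XRCC4/p53 7 11 0.6363636
fisher_exact_2x2(biallelic_contingency())
#> $odds_ratio
#> [1] 11.60714
#> $p_value
#> [1] 0.0005228921
```

Seven of the eleven cNHEJ-deficient medulloblastomas (64%) carry a CGR,
and in the human biallelic-inactivation contingency (13/17 CGR-positive
tumors with both repair-gene alleles hit vs 7/32 without) the exact test
gives p = 0.0005, OR ≈ 11.6.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on a simulated
26-sample cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + per-sample BEDPE/SEG/catalogs
Rscript analysis/02_score_cgr.R         # CGR calls vs ground truth
Rscript analysis/03_microhomology.R     # 2-3 bp share, beta regression by genotype
Rscript analysis/04_signatures.R        # NNLS exposure fits, cosine QC
Rscript analysis/05_association.R       # reference tables, Fisher, locus screen
```

On the default seed this reproduces, end to end: 16/26 samples called
CGR-positive (100% agreement with the simulated truth), a 2–3 bp
microhomology share of 0.64 in the alt-EJ arm vs 0.19 in the cNHEJ arm
(beta regression p ≈ 5e-10), mean fitted exposures within 0.01 of the
simulated mixture, and the planted MYC-like locus ranked first in the
genome-wide screen (q ≈ 0.002).

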