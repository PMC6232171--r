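---
title: "Scoring catastrophic genomic rearrangements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring catastrophic genomic rearrangements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromocata)
```

## The problem

Chromothripsis and chromoanasynthesis are one-off catastrophic events that
rearrange one or a few chromosomes. In chromothripsis, tens to hundreds of
clustered double-strand breaks shatter a chromosome; error-prone end
joining religates the fragments in scrambled order and orientation, and
some fragments are lost. The resulting copy-number profile oscillates
between two (occasionally three) integer states, and the rearrangement
junctions cluster in one region. Chromoanasynthesis instead arises from
microhomology-mediated template switching during replication: fragments
are re-copied rather than lost, so the profile is dominated by gains and
heterozygosity is retained. In DNA-repair-deficient tumors (loss of HR
factors such as BRCA2, or of cNHEJ factors such as XRCC4 or LIG4, on a
p53-null background) these events are frequent, tightly associated with
*Myc*/*Mycn* amplification, and the repair chemistry that religated the
fragments leaves a measurable fingerprint: the distribution of junction
microhomology lengths.

`chromocata` implements the full analysis chain: CGR scoring from
copy-number segments and SV junctions, junction-microhomology inference of
the active repair pathway, supervised mutational-signature decomposition,
and cohort-level association tests — together with a seeded simulator that
generates ground truth with the statistical structure each stage assumes.

## CGR scoring

A chromosome is scored from two inputs: copy-number segments (log2 ratios,
converted to integer states as `round(ploidy * 2^log2)`, halves away from
zero) and SV breakends. The call combines two criteria:

* **Switch density.** A copy-number switch is a boundary between adjacent
  segments with different integer states. Segments shorter than 10 kb
  (`min_seg_len`) are merged into their longer neighbor first, so
  segmentation chatter does not inflate the count. The curation rule
  requires at least `min_switches = 10` switches within *some* 50-Mb
  window; we read "within 50 Mb" literally as a window slid over switch
  positions (anchored at each switch), not as a whole-chromosome count.
* **Breakpoint clustering.** Under complete spatial randomness, n
  breakpoints scattered on a chromosome of length L have inter-breakpoint
  spacings close to Exponential with rate (n−1)/L. The test statistic is
  the one-sample Kolmogorov–Smirnov distance of the observed spacings from
  that law. Because the rate is scaled from the data, the plug-in KS
  p-value is far from uniform under the null, so the p-value is taken from
  a Monte-Carlo null of uniformly placed breakpoints (1999 draws, cached
  per n, fixed internal seed, caller RNG state untouched). When the
  observed statistic exceeds every null draw, the asymptotic KS tail bound
  is reported instead, so extreme clustering yields p-values far below the
  Monte-Carlo resolution. Note that *regularly spaced* breakpoints also
  depart from exponential spacings and also give small p-values; this is
  documented behavior of the spacing statistic. Chromosomes with fewer
  than 6 breakpoints return NA and the call falls back to the switch
  criterion alone.

A chromosome passes when the windowed switch count reaches the threshold
AND the clustering p-value is below 0.05 (or not evaluable). Oscillation
statistics — the number of distinct states and the fraction of segments
whose state matches the state two segments back — and the gain/loss
dominance label (gain when at least twice as much length lies above the
length-weighted modal state as below, loss for the converse, else mixed)
are reported for audit but do not gate the call, since many real events do
not display simple two-state oscillations.

## The simulator

The generator is first-class, tested code; its defaults define the study
conditions of every recovery experiment.

* **Chromothripsis** (`simulate_chromothripsis`): `n_breaks` (default 40)
  distinct positions are drawn uniformly *within* a cluster window
  (default 50 Mb, placed uniformly on a 150-Mb chromosome). Catastrophic
  events are regional, so clustered placement is the default; passing
  `cluster_window = NULL` scatters breaks over the whole chromosome, which
  is useful for null calibration. Each internal fragment is lost
  independently with `loss_prob` (default 0.4); terminal fragments are
  always retained so the derivative chromosome stays linear (the simplest
  valid topology). Survivors are shuffled, randomly oriented and
  religated. Copy states are exactly {background, background−1}. Junctions
  between religated non-adjacent fragments are typed from their breakend
  orientations: +/− deletion-like, −/+ duplication-like; same-orientation
  intrachromosomal joins are emitted as BND, since their connection to
  copy-number changes is not resolvable inside complex events.
* **Chromoanasynthesis** (`simulate_chromoanasynthesis`): a
  template-switching walk duplicates (70%) or triplicates (30%) each
  internal fragment with probability `gain_prob`. All changes are gains,
  every gained segment keeps both alleles (`retained_het`), and each extra
  copy emits one tandem-style junction.
* **Junction microhomology** (`draw_junction_homology`): lengths are drawn
  on 0–9 bp. The cNHEJ distribution puts P(0–1 bp) = 0.5 (blunt or
  near-blunt joins); the alt-EJ distribution puts P(2–3 bp) = 0.625, the
  midpoint of the reported 50–75% range. Both are configurable. A junction
  carries a templated insertion instead of microhomology with probability
  `insert_prob`; the chromoanasynthesis default is 0.05, which keeps
  P(microhomology ≥ 2 bp) = 0.95 × 0.875 ≈ 0.83 among its junctions while
  still producing the occasional templated insert. Insertion and homology
  are mutually exclusive on a junction record.
* **Binned read counts** (`simulate_bin_counts`): per-bin counts are
  Poisson with mean `base_rate * effective_cn / 2`, where `effective_cn =
  2(1 − p·f) + cn·p·f` for a subclone at fraction f in a tumor of purity
  p, and `base_rate = coverage * bin_size / read_span`. Defaults are 30×
  coverage, 4-kb bins and 150-bp reads (the read length of the platform
  the data model emulates), i.e. 800 expected reads per bin. A 10%
  subclonal single-copy gain at purity 1 shifts the expected log2 ratio by
  log2(1.05) ≈ 0.070. (A frequently quoted round figure for this regime
  is 0.1; the exact arithmetic gives 0.07, and the simulation targets the
  derived value.)
* **Cohorts** (`simulate_cohort`): per-genotype sample counts, CGR
  prevalences and repair pathways; a biallelic-repair-hit flag whose odds
  scale with CGR status by a configurable odds ratio (default 10 against a
  base rate of 0.2); oncogene-gain flags (default P = 0.9 given CGR, 0.5
  otherwise); and signature-mixture catalogs. One seed fixes the whole
  bundle byte-for-byte.

What the simulator does *not* emulate: read-level data (no FASTQ/BAM),
aneuploid backgrounds, allele-specific copy number, breakage–fusion–bridge
cycles, and caller-specific artifacts. Recovery results on simulated data
therefore demonstrate the internal consistency of the scoring chain under
its own model — clustered breaks, Poisson depth, exact integer states —
not performance on real sequencing data.

## Change-point segmentation of binned counts

`segment_bin_counts` works on log2(count/median). Recursive binary
splitting proposes, per segment, the boundary maximizing the two-sample
t statistic (equivalently minimizing the two-mean residual sum of
squares), accepts it when the Bayesian information criterion improves
(two extra parameters per split: one mean, one boundary), and recurses.
Because a greedy first split can be displaced when two true change points
interact, accepted boundaries are then re-optimized locally: each boundary
is re-fit as the single best split of the stretch between its neighboring
boundaries, iterated to stability. Minimum segment length is 3 bins.

The BIC penalty controls the null false-split rate (flat profiles stay
single-segment in well over 95% of replicates); localization accuracy at
low signal-to-noise is limited by the data themselves — at 800 reads/bin a
0.07 log2 shift gives a per-bin standardized effect of ≈ 1.4, and the
maximum-likelihood change-point estimator then has an irreducible error
tail of a few bins. The detection experiments in the test suite use a 1-Mb
gain inside 10 Mb of bins (2,500 bins), 200 replicates.

## Junction microhomology and pathway inference

For precisely mapped junctions, `compute_junction_homology` reconstructs
the two religated sequences from the reference and measures the total
placement ambiguity of the junction: the longest run of bases that could
be assigned to either side, scanning up to 25 bp outward in both
directions. A breakend retained on its right side enters the junction
reverse-complemented, so inversion-type joins are compared in the correct
reading frame. Sequence-derived lengths take precedence over
caller-reported HOMLEN when a reference is available; disagreements are
messaged.

Lengths are binned into five categories — 0–1, 2–3, 4–5, 6–7, 8–9 bp —
after excluding junctions with templated insertions or homology longer
than 9 bp (the analysis is defined on blunt ends and 1–9 bp
microhomologies; the five bins complete the stated category pattern over
that range). Junctions belong to a CGR region when either breakend falls
inside it (end handling is not otherwise specified; either-end membership
is the inclusive choice), and samples with fewer than 5 junctions in a
region class are excluded from that class.

The per-sample summary statistic is the share of junctions in the 2–3 bp
bin — the alt-EJ hallmark — modeled between groups by beta regression:
y ~ Beta(μφ, (1−μ)φ) with logit(μ) linear in the group indicator and a
common precision φ. The fit is maximum likelihood (BFGS with analytic
gradients from logistic-moment starting values, followed by Newton
polishing until the gradient norm is below 1e−6); inference on the group
coefficient is a Wald z test. Proportions exactly at 0 or 1 are shrunk by
the standard boundary transform y' = (y(n−1) + 0.5)/n before fitting.

## Mutational signatures

Catalogs live on the 96 strand-collapsed trinucleotide channels in the
canonical order (six substitution classes × 16 flank contexts,
lexicographic); the order is written into every file header to prevent
silent misalignment. Purine-reference SNVs are reverse-complemented onto
the pyrimidine strand; records whose stated reference allele does not
match the genome are rejected and counted.

Signatures derived on one trinucleotide background are carried onto
another by dividing each channel weight by its context frequency in the
source genome and multiplying by the target frequency, then rescaling each
column to sum to one. The operation is exactly invertible. Context
frequencies are counted on the pyrimidine strand (each trinucleotide
pooled with its reverse complement); an optional BED mask restricts
counting to enrichment-kit target regions for exome-mode normalization.

Exposures solve min ‖S e − m‖² over e ≥ 0 by a Lawson–Hanson active-set
non-negative least squares written for this package (the active-set
iteration never increases the residual and terminates at the
Karush–Kuhn–Tucker conditions). The unit-sum constraint is handled by
post-normalizing the NNLS solution rather than by a constrained QP with an
equality row: the subsequent cosine quality criterion is scale-invariant,
so the two formulations select the same kept/dropped verdicts at desk
scale. A sample is dropped when the cosine similarity between the
reconstructed 96-channel composition and the input falls below 0.8. No
regularization is applied: none is specified for the supervised setting,
and adding one would trade recovery bias for variance invisibly.

## Cohort statistics

`fisher_exact_2x2` implements the two-sided exact test by the
point-probability method — the sum of hypergeometric point probabilities
not exceeding that of the observed table, with a 1e−7 relative tolerance
for ties — in log space, so totals up to ~1e6 stay exact. Table
orientation is fixed (rows = CGR status, columns = feature) so odds ratios
are comparable across analyses; samples with unknown feature status are
excluded listwise and the exclusion count is reported. The genome-wide
amplified-locus screen applies the exact test per locus with
Benjamini–Hochberg FDR control; constant locus columns are assigned p = 1
and flagged. The locus definition itself (window size, amplification
threshold) is deliberately an interface: the screen takes a boolean
samples × loci matrix supplied by the caller.

## Numerical and design choices

* Integer states round half away from zero, so a 2.5-copy estimate maps to
  state 3 rather than the banker's-rounding 2.
* The clustering null is Monte-Carlo with a fixed internal seed and cached
  per breakpoint count; the caller's RNG stream is saved and restored, so
  simulation reproducibility never depends on how often the test runs.
* `loss_prob = 1` cannot produce a degenerate (empty) derivative in the
  implemented topology because terminal fragments are always retained;
  out-of-range probabilities are rejected at configuration time instead.
* The telomere-content counter classifies a read as telomeric when the
  non-overlapping occurrences of the four canonical repeat units (TTAGGG,
  TCAGGG, TGAGGG, TTGGGG) or their reverse complements total at least 6 —
  a conventional threshold for ~100-bp reads, exposed as a parameter since
  no universal value exists.
* All problem sizes in the test suite (1000 scorer replicates, 500
  beta-regression null replicates, 200 segmentation replicates, 100
  signature-recovery replicates) were chosen as the package's own
  standard experiment sizes; they run on one CPU in about a minute.

## Known limitations

* The dominance label is a description of the copy-number profile, not a
  mechanistic classification: no statistical framework distinguishes
  chromothripsis from chromoanasynthesis, and none is attempted beyond
  gain/loss dominance.
* Allele-specific copy number and loss of heterozygosity are out of scope
  (inbred-model data typically cannot support BAF analysis), as are ploidy
  estimation and read alignment/SV-calling internals.
* The beta-regression Wald test relies on asymptotic normality; at very
  small arm sizes (n ≲ 10) a permutation test would be preferable.
* The spacing-based clustering test flags any departure from complete
  spatial randomness, including regularity — interpret small p-values
  together with the switch statistics, as `call_cgr` does.
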