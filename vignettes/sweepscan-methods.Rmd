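---
title: "Methods and design of the sweepscan selective-sweep pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the sweepscan selective-sweep pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# The scientific problem

A selective sweep — an allele driven rapidly toward fixation — leaves two
local footprints in a population: elevated differentiation from populations
that did not experience the selection, and depressed nucleotide diversity.
`sweepscan` detects both footprints jointly in a two-group (case/control)
resequencing design, where the "selected" population is a cohort of animals
sharing a heritable phenotype (the motivating design: sheep with mandibular
prognathism versus phenotypically normal flockmates) and selection is the
breeding history that concentrated the causal haplotype in the cases.

The pipeline assumes biallelic SNPs with diploid genotypes, a VCF carrying
GATK-style site annotations and per-genotype GQ/DP/AD fields, and a GFF3
gene annotation on the same assembly. It does not model linkage explicitly:
the window size is the device that integrates signal across linked sites.

# Filtering

Site-level hard filters follow the usual GATK short-variant practice: a SNP
fails if any of QD < 3.0, FS > 30.0, SOR > 4.0, MQ < 30.0,
MQRankSum < −10.0, QUAL < 50.0, ReadPosRankSum < −5.0 holds (OR semantics;
InDels use QD < 3.0, FS > 100.0, ReadPosRankSum < −10.0 behind a
variant-type switch, though the scan itself consumes SNPs only). All
inequalities are strict exactly as written, so boundary values (QD = 3.0,
GQ = 20, DP = 3× mean, AD ratio = 0.2) pass. Annotations that GATK emits
only conditionally (the rank-sum statistics need heterozygotes) may be
missing; a missing annotation skips that rule for that site rather than
failing it, and the skip is logged. This is a deliberate policy choice —
failing sites on absent annotations would discard every invariant-context
site.

Genotype-level masking sets calls to missing when GQ < 20, when DP falls
below 1/3× or above 3× the *individual's own* mean depth (supplied as a
table or estimated from the cohort VCF in a first pass), or when a
heterozygote's allele-depth balance min(AD)/sum(AD) is below 0.2. The AD
rule applies to heterozygotes only; a heterozygote with zero total AD reads
carries no balance evidence and is left to the other rules. After masking,
the biallelic rule recomputes the alternate-allele count and frequency over
non-missing calls and keeps a site iff 0 < AF < 1; sites with no calls left
are dropped as `all-missing`. The order — site filters, then masking, then
the biallelic rule — is fixed, and the surviving-site count is invariant
under sample reordering.

# Scan statistics

## Weir–Cockerham variance components

For two populations with $n_i$ called diploids, alternate-allele frequency
$p_i$ and observed heterozygote proportion $h_i$, the per-site components
are (with $r = 2$, $\bar n = \sum n_i / r$,
$n_c = (r\bar n - \sum n_i^2 / (r\bar n))/(r-1)$,
$\bar p = \sum n_i p_i / (r\bar n)$,
$s^2 = \sum n_i (p_i - \bar p)^2 / ((r-1)\bar n)$,
$\bar h = \sum n_i h_i / (r\bar n)$):

$$a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right]$$
$$b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right],
\qquad c = \frac{\bar h}{2}.$$

$a$ captures between-population variance, $b$ between-individual variance
within populations, $c$ within-individual variance. A window's FST is the
ratio of sums $\sum a / \sum(a+b+c)$ over its SNPs — not the mean of
per-site $\theta = a/(a+b+c)$ — which is the standard windowed form and is
stable at low-information sites. Negative per-site components are retained
in the sums; truncating them at zero would bias the estimator upward. Sites
with fewer than 2 called diploids in either group are uninformative and
skipped. The per-site $\theta$ can be negative; the ratio of sums is always
$\le 1$ and equals 1 exactly under a complete fixed difference with no
heterozygotes.

## Nucleotide diversity and the π-ratio

Per site and population, with $m = 2 n_{\text{called}}$ allele copies and
alternate frequency $p$, the unbiased diversity is
$\pi = \frac{m}{m-1}\, 2p(1-p)$ — identical to the mean pairwise difference
over all $\binom{m}{2}$ haplotype pairs, which is how the test suite checks
it. Window π is the sum of per-site π divided by the *window span in bp*
(partial trailing windows use their actual span). Dividing by span rather
than by SNP count is the dominant windowed-π convention; the choice matters
only for cross-window comparability and is stated here because either
reading is defensible.

The π-ratio is reported as $\pi_{\text{control}} / \pi_{\text{case}}$ by
default, so that *large* values flag diversity loss in the case population —
the direction in which a sweep among cases pushes the statistic, and the
direction used for upper-tail ranking. `invert_pi_ratio = TRUE` gives the
opposite convention; both produce identical outlier windows when the
appropriate tail is ranked, and the package's default simply makes "top 1%"
mean the same tail for both statistics.

## Windows

Windows are half-open `[start, end)` intervals in bp tiling each chromosome
from 0 with a 100 kb size and 50 kb stride (both configurable). Every SNP
contributes to each window overlapping it — two, for the default 50%
overlap; this double-counting is inherent to overlapping-window scans. A
final partial window is emitted only when it covers territory beyond the
last full window, and is flagged. Genomic sites and gene intervals are
1-based inclusive (VCF/GFF native); the 0-based half-open convention exists
only inside the window arithmetic.

# Outlier calling and annotation

The outlier threshold per statistic is the empirical 99th percentile of the
non-NA window values, computed by linear interpolation of the empirical CDF
(`quantile` type 7), with selection rule `statistic >= threshold` — ties at
the cutoff are all kept, which is the conservative direction for candidate
discovery. NA windows (no informative SNPs, or zero case π) are excluded
from both the quantile and the selection. Windows outlying in *both*
statistics are the putative selection signals; the per-statistic window
lists, the realized thresholds, and the SNPs inside outlier windows are all
reported, so downstream users can count "loci" either as windows or as
SNPs.

Candidate genes are genes within ±50 kb of a selected SNP: distance 0 when
the SNP lies inside the gene interval, otherwise the distance to the nearer
gene boundary, inclusive at exactly 50,000 bp. Gene midpoints are not used,
and strand is ignored (the rule is symmetric). An optional chromosome
allow-list restricts the scan (e.g. autosomes only). The FST-derived and
π-derived candidate sets are intersected, with the three-part Venn
breakdown (FST-only, π-only, shared) reported alongside.

# Robustness procedures

Two procedures address case/control imbalance:

**Down-sampling.** Cases are repeatedly drawn without replacement down to
the control count (default 30, 100 iterations), the windowed scan is
recomputed on the same grid, and concordance with the full-data scan is
summarized per statistic as Spearman's ρ over windows non-NA in both runs,
plus top-1% outlier overlap as both Jaccard index and recall of the
full-data outlier set (the two readings of "overlap"). Constant rankings
make ρ undefined; it is reported NA with a warning. The whole procedure is
deterministic given its seed.

**Block-jackknife.** The genome is partitioned into contiguous 200 kb
blocks per chromosome and delete-one-block estimates
$\hat\theta_{(-j)}$ give
$SE^2 = \frac{B-1}{B}\sum_j(\hat\theta_{(-j)} - \hat\theta_{(\cdot)})^2$
with CI $\hat\theta \pm 1.96\,SE$. Because one block exceeds one window, a
per-window jackknife would delete the window's own data; the jackknife
therefore targets *genome-wide* summaries — the ratio-of-sums FST, the
genome-wide π-ratio, or any user-supplied statistic of the site components.
This reading of "window statistics" is a documented design choice, not the
only possible one.

# Phenotype comparison

Group summaries use the sample SD ($n-1$). The default test is Welch's
unequal-variance two-sample t-test with Welch–Satterthwaite df — the
defensible default for a 145-vs-30 imbalance — with a pooled-variance mode
behind a flag. `test_from_summary()` computes the identical test from
(mean, SD, n) triples alone, enabling reproduction of published tables
without raw data; `published_trait_summaries()` ships the motivating study's printed
craniofacial summaries. Recomputing from those summaries reproduces the
printed mean differences (−7.80 mm, −14.03 mm, −0.23°) exactly, but *not*
the printed p-values (Welch and pooled both give p ≈ 0.10 for the maxilla,
against a printed 0.036); the published tests may have used a different
subset or sidedness, so the package asserts the mean differences only.
Degenerate inputs follow fixed conventions: both groups constant and equal
gives t = 0, p = 1; constant with a nonzero difference is an error.

# Over-representation analysis

For each term, the upper-tail hypergeometric $P(X \ge k)$ with $k$ of $n$
candidates carrying the term against $K$ of $N$ universe genes, BH-adjusted
across tested terms, significant at adjusted p < 0.05. Terms with zero
candidate overlap are excluded from the tested family — the convention of
the widely used over-representation tools; it changes the BH family size
and is therefore stated. The universe defaults to all genes of the supplied
map, and candidates must be a subset of it. Database access (GO/KEGG
hierarchies) is out of scope by design: the statistic operates on any
two-column gene-to-term map.

# The synthetic cohort generator

The generator exists so that every downstream stage is testable against a
known truth. Its model:

- Sites are Poisson along each chromosome (default 3 chromosomes × 2 Mb at
  10⁻³ SNPs/bp — small enough for fast tests, sized like real data only in
  density; the real autosome count is a config choice, not a constant).
- Each site draws an ancestral frequency $p \sim U(0.05, 0.95)$, then
  population frequencies from the Balding–Nichols Beta
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ independently per population,
  with $F$ the background differentiation (default 0.02) outside sweeps and
  the region's `sweep_fst` inside. This Beta has mean $p$ and variance
  $F p(1-p)$, so $F$ *is* the expected Weir–Cockerham FST — an analytically
  known truth enabling parameter-recovery tests.
- Inside a sweep, the drawn case frequency is additionally shrunk toward
  the nearest fixation boundary so that the expected case heterozygosity
  equals `case_diversity_factor` × the *neutral-region* case expectation.
  The shrink factor solves $s^2 q - s + d(1-q) = 0$ in closed form per site
  (effective $d_\mathrm{eff} = \min\{1,\ d(1-F_\mathrm{bg})/(1-F_\mathrm{sweep})\}$,
  capped because shrinking cannot *add* diversity when `sweep_fst` alone
  already depresses it below the target). Pairing the frequency shift with
  the diversity shrink makes both scan statistics fire on the same region —
  the intersection logic the pipeline is built around. The default planted
  effect (`sweep_fst = 0.5`, factor 0.3 against background 0.02) is chosen
  for detectability in small test genomes, not biological fidelity: no
  effect size is known for the real signal.
- Genotypes are Hardy–Weinberg binomial draws; DP ~ Poisson(10) (the
  motivating cohort's mean coverage), AD split binomially for
  heterozygotes, GQ high except for a 2% corrupted fraction (GQ < 20), and
  site annotations passing except for a 2% corrupted fraction that violates
  one random hard-filter rule — so the filters have real work to do.
  Monomorphic draws are retained in the VCF deliberately; the biallelic
  rule must remove them.
- Phenotypes are Normal draws per group from configurable (mean, SD), with
  the printed craniofacial summaries as defaults.

Everything is a pure function of (config, seed); the same seed yields
byte-identical VCFs.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: linkage disequilibrium and recombination (sites
are exchangeable within a region; real sweeps have haplotype structure),
allele-frequency spectra from demography, sequencing-error correlation,
multi-allelic sites, and reference bias. The fixture bundle's gene layout
plants genes inside, within 50 kb of, and at least 300 kb from each sweep,
and drops background genes within 250 kb of one, so that the ±50 kb
annotation outcome is unambiguous by construction; the planted
`TERM_SWEEP` annotation makes the enrichment stage's expected answer exact.

# Numerical choices and degenerate inputs

- Empirical quantiles: type 7 (linear CDF interpolation); selection is
  `>= threshold`, keeping ties.
- All filter inequalities strict, as printed in their source convention;
  boundaries pass.
- Undefined statistics are NA, never 0: window FST with
  $\sum(a+b+c) \le 0$ or no SNPs, π-ratio with zero case π, Spearman ρ on
  constant rankings. NA windows are excluded from ranking and concordance.
- Site annotations are serialized at 2 decimals and window statistics at 10
  significant digits, both of which round-trip exactly through the text
  formats.
- The jackknife CI multiplier is the normal quantile rounded to 1.96.
- Genotype missingness is encoded as absent, never as reference; every
  estimator uses only non-missing calls at each site.

# Validation problem sizes

The shipped tests and the acceptance script validate at deliberately modest
scales: oracle equivalence on 1,000 random genotype configurations
(components against an independent scalar transcription; π against
brute-force pairwise differences at ≤ 12 haplotypes), parameter recovery on
a single 11 Mb chromosome at 5 × 10⁻³ SNPs/bp (~55,000 sites), sweep
detection and candidate-gene recovery over 20 seeded replicates of the
default 3 × 2 Mb cohort, jackknife coverage over 20 replicates, and
down-sampling concordance at 100 iterations. These sizes make the whole
suite run in minutes while leaving the Monte-Carlo error well below the
asserted tolerances.

# Known limitations

- Exchangeable-site simulation: detection-rate results on synthetic data
  will be optimistic relative to LD-structured real genomes at equal SNP
  counts.
- The windowed scan reports no significance beyond the empirical top-1%
  rule; no composite-likelihood or haplotype statistics (iHS, XP-EHH) are
  implemented.
- The block-jackknife quantifies uncertainty for genome-wide summaries
  only, per the design reading above.
- Multi-allelic normalization, BCF/tabix, phasing and VQSR are out of
  scope; inputs are assumed pre-normalized biallelic SNP VCFs.
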