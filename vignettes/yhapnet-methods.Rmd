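---
title: "Discovering Y-chromosome haplogroups from SNP genotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering Y-chromosome haplogroups from SNP genotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yhapnet)
```

## The problem

In most salmonids the X and Y chromosomes are morphologically
undifferentiated: the main sequence difference is an insertion carrying the
sex-determining gene *sdY*. Because male recombination is restricted to the
telomeres (heterochiasmy), the X and Y copies of the sex chromosome rarely
exchange material over most of their length. Any allele that becomes fixed on
a Y lineage therefore stays associated with every other allele on that
lineage, producing *megabase-scale linkage disequilibrium (LD)* visible even
in unphased diploid genotypes. A set of such non-recombining Y lineages —
**haplogroups** — can segregate within and among populations, and, because
each lineage can capture different variants, can be associated with
male life-history traits such as size and age at maturity.

`yhapnet` implements the full discovery-to-association workflow for this
setting:

1. **SNP QC** — missingness, minor allele frequency (MAF), and
   collapsed-paralog filtering from heterozygote allele read ratios;
2. **LD network analysis** — all-pairs composite r² on the sex chromosome,
   thresholded into a graph whose long-range connected components are
   candidate haplotype blocks;
3. **Phasing** — partition–ligation EM over the union of block SNPs;
4. **Haplogroup discovery** — Ward clustering of phased haplotypes,
   X/Y classification from carrier sex, naming, and diagnostic-SNP
   extraction;
5. **Assignment** — expected-genotype matching against a diagnostic panel
   (or joint clustering with the reference);
6. **Association** — two-factor ANOVA of length/age on haplogroup with
   population as covariate, Tukey post hoc tests and compact letter
   displays.

A seeded synthetic-data generator with a full truth table
(`simulate_ychap()`) makes every stage testable end to end.

## Statistical components

### Composite LD from unphased genotypes

For a SNP pair, haplotype frequencies are estimated from the 3×3 table of
minor-allele dosages by EM: every cell except the double heterozygote
determines its two haplotypes; the double-heterozygote mass is split between
the *cis* and *trans* configurations in each E-step. With estimated
frequencies $p_{AB}$ and allele frequencies $p_A, p_B$,

$$ D = p_{AB} - p_A p_B, \qquad
   r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}. $$

The EM starts from independence ($p_{AB} = p_A p_B$), runs to a parameter
tolerance of 1e-10 or 100 iterations, and preserves the sample allele
frequencies exactly. Monomorphic pairs are skipped. The all-pairs matrix is
computed by indicator cross-products with the EM update vectorised over all
pairs; the scalar `pairwise_r2()` shares that code path so the LD graph and
individual queries can never disagree. A genotype-dosage correlation fallback
(`method = "dosage"`) is provided for quick screening.

Edges with $r^2 \ge$ `r2_min` (default 0.3, inclusive) form the LD graph.
Blocks are plain connected components filtered to at least `min_snps = 5`
SNPs spanning at least `min_span` = 1 Mb; no community detection is applied
because the target structure is a small number of disjoint high-LD SNP sets.
LD is pooled across all samples by default — appropriate when all
populations carry the same haplogroups; per-population analysis can be run by
subsetting samples first.

### Partition–ligation EM phasing

A hidden-Markov phaser is unnecessary here: the phasing target is a small set
of long, conserved haplotypes (one X pool plus a handful of Y lineages) over
a few dozen SNPs. `em_phase()` therefore uses partition–ligation EM:

* windows of at most `window = 6` SNPs are phased by EM over all $2^w$
  haplotypes (each individual's likelihood sums over compatible ordered
  haplotype pairs; missing sites are marginalised);
* adjacent segments are ligated: candidate joint haplotypes are the
  cross-products of the retained pools, truncated to the `top_k = 50` largest
  initial frequencies, then refined by EM;
* after truncation, any individual left without a compatible pair gets a
  forced-compatible pair added to the pool at low frequency, so the
  genotype-consistency invariant — the two output haplotypes sum to the
  observed genotype at every non-missing SNP — holds unconditionally;
* each individual is assigned its most probable compatible pair, with
  deterministic lexicographic tie-breaking; the EM initialisation adds a
  seeded 1e-3 jitter to break symmetry.

`top_k = 50` bounds the pool; haplotypes rarer than roughly $1/(2N)$ can be
lost, which is acceptable for lineage-scale structure. Missing sites are
*not* imputed in the output — they stay unknown and are mean-imputed only
inside the clustering distance.

### Ward clustering and X/Y classification

Haplotypes (0 = major, 1 = minor) are clustered with Ward's
minimum-variance criterion. `cluster_haplotypes()` feeds *squared* Euclidean
distances to the Ward linkage so that merge heights equal within-cluster
sum-of-squares increases — the criterion's textbook definition, verified in
the tests against a naive agglomeration that recomputes SS increases from
scratch. With `k = "auto"` the cut maximising mean silhouette width over
k = 2..10 is used; k can also be fixed, since the number of visually distinct
clusters in real data is a judgement call (published analyses of this kind
have described the same dendrogram as five or six groups depending on
whether X substructure is counted).

A cluster is called **Y-type** when at least `male_frac_min = 80%` of its
sexed carriers are male. The threshold sits deliberately below the 85–95%
male composition observed for real Y clusters because phenotypic (visual)
sexing has non-trivial error; `sex_from = "genetic_sex"` can be used when a
genetic sex assay is available. Y clusters are named
`<chrom>-MH1, -MH2, ...` in decreasing carrier count, ties broken by the
leftmost minor-consensus position.

**Diagnostic SNPs** are those with an absolute minor-allele frequency
difference of at least `fixed_threshold = 0.95` between a Y haplogroup and
the pooled X haplotypes ("fixed or nearly fixed"). Shared diagnostics —
SNPs diagnostic for several haplogroups, a signature of common lineage
ancestry — are emitted once per haplogroup.

### Assignment

`expected_genotypes()` assumes fixation on both chromosomes: a male of
haplogroup *h* is expected to be heterozygous X-allele/Y-allele at *h*'s
diagnostic SNPs and homozygous for the X allele elsewhere on the panel. A
sample is assigned when exactly one haplogroup has fewer than
`max_mismatch = 2` mismatches (strict: 0 or 1) over its non-missing panel
SNPs and satisfies all discriminator rules; ties and sparse genotypes
(fewer than `min_informative = 5` informative SNPs) stay unassigned.
Discriminator rules are auto-generated for every haplogroup pair separated by
at most two panel SNPs: each such haplogroup must positively show its own
allele at those SNPs. A rule is only treated as violated when the genotype is
observed and lacks the allele — a missing genotype neither confirms nor
vetoes, which avoids penalising low-coverage samples twice. Using the
X-major allele as "the" X allele even where X is polymorphic follows the
fixation assumption and is a known, tolerated source of occasional
mismatches.

The alternative route, `assign_by_clustering()`, re-runs phasing jointly
with the reference samples and transfers cluster labels; it assigns more
samples (no mismatch cap) but degrades when a haplogroup retains few panel
SNPs, which is why the genotype-matching route is the default.

### Association tests

`anova_factor()` fits `response ~ haplogroup + population` and reports
**Type II sums of squares** — each term tested after the other — because the
designs are invariably unbalanced; the SS are computed from nested
least-squares fits and cross-checked in the tests against an independent
implementation. Perfect confounding of haplogroup with population raises an
error rather than a silently dropped term. When the response is constant the
F statistics are reported as 0 (no variation to apportion), a convention the
table documents rather than returning 0/0. Ages in European notation
(`"f.o"`) are parsed by `parse_age_euro()`; total age = freshwater + ocean +
1 incubation year, and total age (not ocean age) is the default response.
Females carry no haplogroup and are excluded from association tests.

Post hoc comparisons use Tukey's HSD (Tukey–Kramer under imbalance) on the
covariate-adjusted fit, summarised by a compact letter display built with an
insert-and-absorb algorithm whose letters provably share a letter exactly
when the pair is not significant at `alpha = 0.05`.

## The synthetic-data generator

`simulate_ychap()` emulates the data regime the method targets, with every
latent quantity recorded in a truth table:

* **Design**: 4 populations × 250 samples, 50% male, 500 SNPs on a 25 Mb
  sex chromosome with 10% off-target SNPs (exercising the chromosome
  filter).
* **Haplogroup structure**: 4 Y haplogroups whose diagnostic SNPs fall in 3
  megabase-scale blocks (4.5, 9.5 and 6 Mb): MH1 and MH4 have private
  blocks; MH2 and MH3 share one block containing 5 + 7 + 5 SNPs
  (MH2-private, shared, MH3-private). The shared set mirrors the partially
  shared ancestry seen in real Y lineages and makes the MH2/MH3 SNPs one LD
  component, so 4 haplogroups yield exactly 3 blocks. Cross-block r² was
  derived analytically from the default frequencies (expected < 0.15,
  within-block edges > 0.4) so block recovery is a property of the design,
  not luck.
* **Frequencies**: per-population haplogroup frequencies follow four
  Alaska-like profiles spanning the observed range (one dominated by two
  co-frequent lineages, one MH1-heavy, one MH3-heavy, one MH4-heavy). One
  profile's printed source values summed to 1.01 and was adjusted by 0.01 on
  its third entry to satisfy the simplex constraint.
* **X pool**: linkage equilibrium (independent per-SNP draws from a
  Beta(0.8, 3) MAF distribution), fixed major at diagnostic SNPs. This is a
  deliberate simplification justified by female whole-chromosome
  recombination; it means the generator cannot produce X-side substructure
  or LD decay, so passing tests say nothing about those regimes.
* **Noise**: 0.5% genotype error (uniform miscall), 2% missingness, 5%
  visual-sexing label flips (a free parameter, not an estimate — real
  visual-sexing error is unreported), Poisson(24) read depth with
  Binomial(0.5) heterozygote splits.
* **Paralogs**: 10% of background SNPs are collapsed duplicates — reads of
  the target locus plus a second, fixed-heterozygous locus — giving the
  elevated heterozygosity and skewed (about 3:1) read ratios that the
  HDplot-style `H`/`D` statistics flag. The H and D cutoffs (0.55 and 7) are
  tunable because published analyses do not report the values they used.
* **Phenotypes**: male length = population mean + haplogroup effect
  (defaults −40 to +50 mm around ~800 mm, SD 60 mm); female length from a
  separate mean with no haplogroup effect; ocean-age classes drawn per
  haplogroup (one lineage 3:1 in favour of age 1.3, another balanced
  1.3/1.4).

Same seed, same output, bit for bit; all randomness flows from the single
`seed` entry.

## Numerical and design choices

* **Strict-inequality filters**: "more than 10% missing" and "MAF < 0.01"
  remove; the boundary cases (exactly 10% missing, MAF exactly 0.01) are
  retained. The r² ≥ 0.3 edge rule is inclusive.
* **Multiple SNPs per locus** are treated as independent SNPs.
* **Alignment-quality filtering is out of scope**: chromosome labels and
  positions are trusted inputs.
* **Determinism**: clustering ties are broken by index order, assignment
  ties by lexicographic haplotype order, and reruns of `run_pipeline()` with
  one seed are byte-identical.
* **Problem sizes**: the test suite validates oracle equivalences on tiny
  instances (2–3 SNP phasing against exhaustive EM, ≤ 50-sample LD tables
  against a 1e-4 grid search), parameter recovery at the generator's default
  scale (1,000 samples × 500 SNPs), and ANOVA calibration with 1,000 null
  replicates — sizes chosen so the full suite runs in well under a minute of
  compute per component.

## Limitations

* The phaser is not a general chromosome-scale tool: it assumes a small pool
  of long conserved haplotypes and will truncate very rare recombinants.
* The generator plants non-recombining Y lineages; occasional X–Y
  recombination, block erosion, or X substructure are not simulated, so the
  pipeline's behaviour under those conditions is untested here.
* Silhouette-based `k` selection can fold a small Y haplogroup into the X
  pool when its frequency is very low; fixing `k` from inspection of the
  dendrogram is the recommended fallback, which is why `k` is exposed.
* The fixation threshold (0.95) interacts with cluster size: with fewer than
  ~30 carriers per haplogroup, a couple of miscalled haplotypes can push a
  truly fixed SNP below threshold. Study-scale sample sizes (hundreds of
  carriers) make this a non-issue.
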