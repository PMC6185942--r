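---
title: "Exhaustive SNP-SNP interaction scanning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive SNP-SNP interaction scanning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibit)
```

## The problem

Single-SNP association tests leave much of the heritability of common
diseases unexplained.  Some variants show little marginal association but a
strong joint association with a second variant — epistasis.  Testing every
unordered pair of SNPs in a genome-wide case-control panel is
computationally brutal (hundreds of billions of pairs) and statistically
brutal (each 3×3 joint-genotype table admits 2^9 = 512 ways of splitting
genotypes into high- and low-risk groups).  `epibit` implements an
exhaustive pairwise scan that attacks both problems at once: a mechanistic
argument reduces the 512 possible genotype groupings to eight, and a
bit-packed lookup table makes the counting of each pair's contingency table
a handful of memory lookups.

## Genotype encoding

Genotypes are encoded per SNP as 0 = missing, 1 = homozygous major,
2 = heterozygous, 3 = homozygous minor, with the major allele the more
frequent allele over non-missing calls.  An exact 50/50 allele tie is
broken toward the lexicographically smaller allele label, so the encoding
never depends on sample order.  Samples with unknown phenotype are dropped
at read time: the scan is strictly case/control.  Monomorphic SNPs are kept
at read time; `epi_scan(min_maf =, min_callrate =)` filters them when asked
(quality control proper is assumed done upstream, e.g. in PLINK).

## The eight interaction patterns

The mechanistic model: each of the two loci sits in a functional site whose
product depends on the allele present, so site 1 yields bio-molecule
subtypes from the major (`p_A`) and minor (`p_a`) allele and site 2
likewise (`p_B`, `p_b`).  Subtypes dock into at most four complexes.  A
complex can be disease-associated in two ways:

* **presence** — the complex promotes or inhibits disease whenever it can
  form.  For complex (α, β) every joint genotype carrying at least one copy
  of α at locus 1 *and* at least one copy of β at locus 2 is "black"
  (risk-grouped): a 2×2 block of the 3×3 table, 4 cells.
* **solo** — the complex matters only when it is the sole complex formed,
  which requires both loci homozygous: exactly 1 black cell.

Four complexes × two conditions give eight distinct masks
(`enumerate_patterns()`), ordered presence 1–4 then solo 5–8 with
complexes in the fixed order (maj,maj), (maj,min), (min,maj), (min,min).
This ordering is a convention of the package, chosen so result files are
comparable across runs.  The set is closed under transposition (swapping
the two SNPs maps pattern(α, β) to pattern(β, α)), which is what makes
scanning only unordered pairs `i < j` under all eight patterns equivalent
to scanning ordered pairs — a property the test suite verifies against an
ordered-pair oracle.  Missing genotypes belong to neither the black nor the
white group.

## Contingency tables and the lookup table

Under a pattern, a pair's 3×3 case/control table collapses to 2×2: cases
in black cells (`n_db`), controls in black (`n_hb`), cases in white
(`n_dw`), controls in white (`n_hw`).  A sample missing either genotype is
excluded from that pair's table — the conservation law
`n_db + n_dw + n_hb + n_hw + #missing-at-pair = n` is tested.

Counting is the hot loop of an exhaustive scan, so two engines are
provided with a bit-identical output contract:

* **naive** — per-sample accumulation of the 4×4 joint code table, then
  mask sums.  This is the reference semantics.
* **lookup** — each genotype code is 2 bits; `p = 4` codes pack into one
  byte-valued word, and each SNP column is split into a case word vector
  and a control word vector (zero-padded, and padding is the missing code
  so it never counts).  For all 256×256 ordered word pairs and all 8
  patterns, the number of black positions and of mutually non-missing
  positions is pre-computed once (`build_lookup_table()`, ~2 MiB, built
  and cached per session).  A pair's table is then the sum of table
  entries along the word vectors.  `p = 4` keeps the table byte-indexed
  and cache-resident, which is what makes its load time effectively
  constant regardless of dataset size.  Internally the compiled engine
  fuses the eight per-pattern counts of a word pair into byte lanes of a
  single 64-bit word, so the inner loop performs one load and one add per
  word pair (lanes are unpacked every 63 words, before they can overflow).

The equivalence of the two engines is asserted both per-pair (200
randomized 50-sample pairs × 8 patterns against an independently written
counting oracle) and on full scans (identical reports on a 100-SNP
dataset).

## Statistics

Each 2×2 table is scored by the uncorrected 1-d.f. Pearson chi-square
`n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`.  No Yates correction is applied —
the uncorrected statistic is the convention in exhaustive epistasis scans,
and the continuity correction would only add conservatism at genome-wide
thresholds.  A table with a zero margin carries no information and is
reported as chi-square 0, p = 1 with a `degenerate` flag (never NaN, so
ranking never sees missing keys).  The odds ratio is the cross-product
ratio, with explicit infinite/undefined flags for zero cells.

The **improvement metric** of a pair is
`min(p1 / p_pair, p2 / p_pair)` — how much more significant the pair is
than its better component SNP.  Genome-scale pairwise p-values can
underflow double precision, so all p-values are carried with their base-10
logarithms and the metric is computed on the log scale; a pairwise p of
1e-320 is handled exactly like any other.

Single-SNP p-values (cached once per SNP before the pair loop) default to
the **best-dichotomy** method: the smaller p over the dominant
({hom-major} vs {het, hom-minor}) and recessive ({hom-major, het} vs
{hom-minor}) collapses.  These two collapses are exactly the marginal
projections of the eight patterns, so the improvement metric compares like
with like.  An **allelic** 1-d.f. test (2×2 allele-count table) is offered
as the alternative, since a "1-d.f. single-SNP chi-square" in the GWAS
literature can mean either; the choice only affects the improvement
metric, never the pairwise scan itself.

## The scan

`epi_scan()` enumerates all `m(m−1)/2` unordered pairs (counted in exact
double arithmetic — `count_pairs(352945)` = 62,284,910,040 and
`count_pairs(790527)` = 312,466,073,601, eight tests each).  The default
significance threshold is the Bonferroni bound `0.05 / (8·C(m,2))` over
every test performed; fixed thresholds such as 1e-13 or 1e-14 can be set
explicitly.  By default one row per significant pair is kept (its
minimum-p pattern; `dedupe = "all-patterns"` keeps all eight), and two
rankings are returned: by pairwise p-value and by improvement metric, with
ties broken by the other key, then SNP indices, then pattern id.  The scan
is deterministic given data and configuration; the engine choice does not
change a single bit of the output.  The threshold is applied on the
chi-square scale inside the compiled loop (with a hair of slack) and
re-checked on the exact p-value in R, so float rounding cannot drop a hit.

## The simulator

`simulate_gwas()` emulates a case-control panel with one planted pair:

* **Null SNPs** — per-SNP MAF drawn uniformly from `maf_range` (default
  0.05–0.5), genotypes drawn under Hardy–Weinberg equilibrium,
  independent of phenotype and of each other (no LD model: the planted
  signal is a genuine joint effect, not a haplotype).
* **Planted pair** — a two-level penetrance model over the pattern's
  black/white groups.  With `p` the population frequency of black joint
  genotypes (HWE, linkage equilibrium), prevalence `K` and broad-sense
  heritability `h²` of the 0/1 trait determine the penetrances through
  `K = p·f_B + (1−p)·f_W` and `h² = p(1−p)(f_B − f_W)² / (K(1−K))`.
  Broad-sense heritability on the observed scale is the natural definition
  for a two-level penetrance model; the calibration errors out explicitly
  when the demanded `h²` is infeasible for the pattern's `p` and `K`.
  Individuals are drawn from population genotype frequencies, assigned
  disease by their group's penetrance, and accumulated by rejection until
  the case and control quotas are exactly met (retrospective
  ascertainment).
* **Defaults** — 1000 SNPs, 1000 cases + 1000 controls, planted pattern 1
  between two MAF-0.5 variants at `h² = 0.1`, prevalence `K = 0.2`, no
  missing data, everything determined by one seed.  Prevalence 0.2 rather
  than a rarer-disease value is forced by the calibration algebra: for the
  presence patterns the black-group frequency is at least 0.5625 at any
  MAF ≤ 0.5, and `h² = 0.1` with `K = 0.1` would demand a negative
  `f_white`.  Common variants (MAF 0.5) are used for the planted pair for
  the same reason: they minimise the black-group frequency of a presence
  pattern and so maximise the feasible heritability range.

What the generator deliberately does **not** emulate: linkage
disequilibrium and haplotype structure, population stratification,
genotyping batch effects, and covariates.  Passing the recovery tests
therefore demonstrates that the scan finds a pattern-faithful planted
signal against independent noise — not that it is robust to the
confounders of real panels, which the upstream QC and the user's judgement
must handle.

## Validation design and problem sizes

The package's validation suite runs at sizes chosen to exercise every code
path in seconds: engine-equivalence scans at 100 SNPs, recovery of the
planted pair on twenty 1000-SNP replicates at `h² = 0.1` (the planted pair
must be the minimum-p pair of all ~5×10⁵ pairs in at least 18 of 20
seeds), a 200-replicate null (`h² = 0`) check that the planted pair's
fixed-pattern p-value is Kolmogorov–Smirnov-consistent with Uniform(0,1),
and a type-I-error check at α = 0.05 over 2500 *disjoint* null pairs.
Two design choices there deserve a note:

* disjoint pairs, because pairs sharing a SNP are correlated and would
  invalidate the binomial error bar;
* null MAFs at or above 0.2 for the calibration check, because a presence
  pattern at MAF 0.05 leaves an expected white-cell count of a few
  samples, where the chi-square approximation is visibly conservative.
  This is the classic expected-cell-count validity condition, not a
  property of the counting engines; at MAF ≥ 0.2 the empirical size is
  0.045–0.054.

The speed comparison between engines is asserted only as "lookup strictly
faster than naive" on a 1000-SNP dataset, since the exact ratio is
hardware-dependent (3–4× on the development machine).

## Gene networks

For interpretation, each SNP of a top-ranked interaction is mapped to its
nearest gene: distance 0 inside a gene, otherwise the gap to the nearest
interval end on the same chromosome, ties broken toward the smaller gene
start then the lexicographically smaller identifier.  Gene annotations are
read from BED (0-based half-open) and converted once, at the boundary, to
the 1-based inclusive convention used internally — SNP positions follow
the 1-based MAP/VCF convention, and keeping the two dialects explicit
avoids the classic off-by-one.  An interaction between SNPs mapping to
genes G1 and G2 contributes one (unordered, deduplicated) edge with its
supporting SNP pairs; both SNPs mapping to one gene flags a self-loop,
excluded from exports and intersections by default.  Networks inferred
from independent datasets can be intersected to keep only replicated
edges.

## Known limitations

* Only second-order interactions; no third-order scans.
* No covariate adjustment, logistic interaction terms, or Fisher exact
  tests — the scan is a screen, and its hits deserve model-based
  follow-up.
* The nearest-gene rule is a convention; regulatory variants may act on a
  gene that is not the nearest.
* Genome-scale inputs (~10⁵–10⁶ SNPs) are supported by the arithmetic and
  the bookkeeping, but a full 3×10¹¹-pair scan is a cluster job, not a
  desk job; the package targets the desk-scale end plus the method's
  mechanics.

## A worked example

```{r example}
sim <- simulate_gwas(n_snps = 200, n_cases = 500, n_controls = 500,
                     seed = 42)
scan <- epi_scan(sim$genotypes)
scan
head(scan$top_p[, c("snp_i", "snp_j", "pattern", "chi2", "p",
                    "odds_ratio", "improvement")], 3)
```

The planted pair (SNPs 1 and 2, pattern 1) surfaces as the top hit, with a
pairwise p-value orders of magnitude below either single-SNP p-value —
exactly the signature the improvement metric is built to rank.
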