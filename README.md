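# epibit

Exhaustive second-order SNP-SNP interaction search for case-control
genome-wide association studies (GWAS).

Many disease variants show little association on their own but a strong
joint association with a second variant.  Finding such epistatic pairs
exhaustively means testing every unordered SNP pair — `m(m−1)/2` pairs,
hundreds of billions at genome scale — and deciding, for each pair, how to
group the nine joint genotypes into high- and low-risk sets out of the
2⁹ = 512 possibilities.  `epibit` is for statistical geneticists who want
that scan to be both tractable and mechanistically interpretable:

* **Eight biologically plausible genotype interaction patterns.**  A
  two-site bio-molecule complex model (each allele produces a product;
  products dock into complexes; a complex is disease-associated either
  whenever present or only in solo presence) reduces the 512 genotype
  groupings to exactly 8 black/white masks over the 3×3 joint-genotype
  table, closed under SNP swap.
* **2×2 contingency statistics.**  Under each pattern a pair's 3×3 table
  collapses to the 2×2 case/control table (N_D,B, N_H,B, N_D,W, N_H,W),
  scored by the uncorrected 1-d.f. Pearson chi-square
  `n(ad − bc)²/((a+b)(c+d)(a+c)(b+d))`, the odds ratio, and the
  *improvement metric*
  `min(p_SNP1/p_pair, p_SNP2/p_pair)`, which ranks pairs far more
  significant jointly than either SNP alone (computed in log space, so
  p-values below double-precision underflow are fine).
* **Bit-packed lookup-table counting.**  Genotypes are 2-bit codes; four
  pack into a byte word, and per-pattern black/non-missing counts for all
  256×256 word pairs are pre-computed once (~2 MiB).  Counting any pair's
  table then costs a few dozen memory lookups instead of a pass over all
  samples — 3–4× faster than direct counting in the compiled engines, with
  bit-identical output.
* **A penetrance-calibrated simulator** that plants one pattern-faithful
  interaction at a stated heritability and prevalence in an otherwise null
  HWE panel, for power and calibration studies.
* **Nearest-gene network inference** from top-ranked interactions, with
  network intersection across datasets and self-loop handling.

Genotype input: PLINK text (`.ped`/`.map`) or a coded TSV matrix; gene
annotations: BED.

## A worked example

```r
library(epibit)

# 200 SNPs, 500 cases + 500 controls, one planted pattern-1 interaction
# between SNPs 1 and 2 at heritability 0.1, prevalence 0.2
sim  <- simulate_gwas(n_snps = 200, n_cases = 500, n_controls = 500,
                      seed = 42)
scan <- epi_scan(sim$genotypes)
scan
#> Exhaustive SNP-SNP interaction scan (lookup engine)
#>   200 SNPs -> 19,900 pairs, 159,200 pattern tests
#>   significant at p <= 3.14e-07: 367
#>   best pair: snp00001 x snp00002 (pattern 1, p = 3.86e-34, OR = 6.091)
#>   runtime: 0.08 s

head(scan$top_p[, c("snp_i", "snp_j", "pattern", "chi2", "p",
                    "odds_ratio", "improvement")], 3)
#>      snp_i    snp_j pattern   chi2         p odds_ratio improvement
#> 1 snp00001 snp00002       1 148.41 3.862e-34      6.091   8.997e+14
#> 2 snp00001 snp00089       1  84.69 3.492e-20      5.471   9.951e+00
#> 3 snp00001 snp00037       1  83.55 6.224e-20      5.419   5.583e+00
```

Every unordered pair was tested under all 8 patterns (19,900 × 8 =
159,200 tests); the default threshold is the Bonferroni bound
0.05/159,200 ≈ 3.1e-7.  The planted pair tops the ranking under its true
pattern: its pairwise p (3.9e-34) is ~15 orders of magnitude below its
better single-SNP p, hence the improvement metric of 9.0e14, while the
runner-up pairs (each sharing the strong planted SNP 1) improve on their
marginals by less than a factor of ten — marginal signal leaking into
pairs, exactly what the metric is designed to demote.

The ranked hits feed straight into network inference:

```r
hits <- scan_loci(scan$top_improvement, sim$genotypes)
net  <- infer_gene_network(hits, read_gene_bed("genes.bed"))
export_network(net, "network.tsv")
```

A command-line wrapper with `scan`, `simulate` and `network` subcommands
is installed at `inst/cli/epibit` (run it with `Rscript`).

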