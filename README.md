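# modulescout

Discovery and scoring of paired-motif cis-regulatory modules in gene
upstream regions.

## The problem

In many fungi, genes of a co-regulated set (the classic example being
ribosome biogenesis genes) carry two short regulatory motifs in their
promoters — an A/T-rich element (RRPE) and the polymerase A/C box (PAC,
consensus `GATGAG`; its single-nucleotide variant `GATAAG` is called
PAC2).  What matters biologically is not just the presence of the motifs
but their *arrangement*: the pair tends to occur with a conserved spacing,
a preferred 5'→3' order relative to the translation start, a position
close to the start codon, and a preferred strand relationship.  Such an
arrangement of two motif instances is called a **module**.

`modulescout` is for researchers who have a set of upstream sequences
(one per gene, e.g. 800 bp ending at the ATG) and candidate motif
consensus strings, and who want to find, score and compare the module
arrangements those motifs form.

## The method

Motifs are IUPAC consensus strings scanned on both strands with an
allowed mismatch count (an `N` in the sequence never matches).  All
non-overlapping 5'→3' occurrence pairs with an edge-to-edge gap of at
most `max_gap` (default 200 bp) are module instances.  Each module order
(e.g. `RRPE-PAC` vs `PAC-RRPE`) is scored with five statistics:

* **Sig** — per component motif, the overrepresentation significance in
  bits: `Sig = -log2 P(X ≥ k)`, `X ~ Binomial(n, p0)` over the `n`
  scanned windows with background match probability `p0` (240 bits ≈
  p = 5.7×10⁻⁷³);
* **ABC** (area between curves) — spacing non-randomness:
  `(mean(null gaps) − mean(actual gaps)) / d_max`, the signed area
  between the empirical gap CDFs of the observed modules and of modules
  re-paired after shuffling the same numbers of instances uniformly into
  the same regions; +1 = maximally tighter than chance, −1 = maximally
  looser;
* **position** — Kolmogorov–Smirnov statistic of the module midpoint
  upstream distances against Uniform(0, L);
* **coverage** — fraction of genes in the set with ≥ 1 instance;
* **orientation** — strand-preference score `|2·f_same − 1|`, where
  `f_same` is the fraction of instances with both motifs on one strand.

The components are normalized to [0, 1] and combined as a user-weighted
mean into a **module score** in [0, 1].  Downstream analyses reproduce
the method's companion procedures: positional quartile fractions,
group-wise attribute aggregation, partitioning genes by exclusive module
orientation with exact hypergeometric term enrichment, and a greedy
search for extra genes that improve a motif's Sig value.

A synthetic-promoter generator plants modules with known spacing, order,
strand agreement, position bias and coverage, so every statistic is
testable without external data.

## Worked example

```r
library(modulescout)

motifs <- default_motifs(rrpe = "TGAAAAWTTT")   # synthetic RRPE stand-in
sp <- plant_spec(n_genes = 200, coverage = 0.46, seed = 42)
ds <- generate_dataset(sp)                      # 200 x 800 bp promoters

occ <- scan_regions(ds$regions, motifs)
nrow(occ)
#> [1] 368

round(quartile_fractions(occ[occ$motif == "PAC", ]), 3)
#>   0-200 200-400 400-600 600-800
#>   0.485   0.282   0.129   0.104

attrs <- score_module(ds$regions, occ, c("RRPE", "PAC"), motifs,
                      R = 1000, seed = 7)
t(round(attrs[, -1], 3))
#> n_genes                   200.000
#> n_occurrences             104.000
#> sig_first                 365.068
#> sig_second                 79.785
#> abc                         0.408
#> position_score              0.495
#> coverage                    0.460
#> orientation_f_same          0.846
#> median_gap                 12.000
#> median_upstream_position -149.000
#> module_score                0.537
```

Reading the output: the planted world (coverage 0.46, constant 12-bp gap,
proximal placement, 90% same-strand) is recovered — `median_gap` is
exactly 12, `coverage` 0.46, the positive `abc` (0.41) says observed
pairs are far tighter than the shuffling null, the KS `position_score`
(0.50) flags the proximal bias, and `orientation_f_same` (0.85) reflects
the planted strand preference diluted by a few accidental background
modules.  `median_upstream_position` is negative: module midpoints sit
~149 bp upstream of the ATG.

A subcommand CLI covers the same pipeline
(`inst/cli/modulescout scan|modules|score|quartiles|aggregate|partition|`
`enrich|extra-genes|simulate|run`); `run` executes
scan → modules → score → quartiles from a JSON config and writes a
manifest with parameters, seed and input checksums.

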