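---
title: "Scoring paired-motif regulatory modules: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring paired-motif regulatory modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modulescout)
```

## The model

A *module* is an arrangement of two motif occurrences in one upstream
region with conserved spacing and organization.  `modulescout` takes a
set of upstream sequences (5'→3' on the gene's strand, last base
adjacent to the translation start; 800 bp is the conventional length),
scans them for IUPAC consensus motifs on both strands, pairs occurrences
into modules, and scores each module *order* — the 5'→3' sequence of the
two motif names, e.g. `RRPE-PAC` versus `PAC-RRPE` — with five
statistics combined into a single normalized module score.

Coordinates are 0-based and end-exclusive on the upstream string; the
upstream distance of a feature is `L − end`, the number of bases between
its 3' edge and the ATG.  This makes "distance 0–200" the proximal
quarter of an 800-bp region, matching the usual quartile convention.

### The five components

**Sig (bits).**  For a motif with `k` occurrences over `n` scanned
windows (both strands of every offset), `Sig = −log₂ P(X ≥ k)` with
`X ~ Binomial(n, p0)`.  The tail is computed in log space
(`pbinom(..., log.p = TRUE)`), so Sig values of hundreds of bits are
representable; 240 bits corresponds to p ≈ 5.7×10⁻⁷³.  `p0` is the
probability that a single window matches the consensus within its
mismatch budget under an i.i.d. base model; per-position match
probabilities are convolved exactly over mismatch counts.  Base
frequencies come from a genome-background region set when one is given,
otherwise from the gene set itself, always symmetrized over strands
(A with T, C with G).  This is a deliberately transparent stand-in for
motif-finder-internal significance measures, which are defined relative
to a whole-genome scan we do not require.

**ABC (area between curves).**  The observed module gaps (edge-to-edge,
`second.start − first.end`) are compared with gaps from a shuffling
null: per gene and replicate, the same numbers of A and B instances are
repositioned uniformly over all non-overlapping arrangements (an exact
combinatorial construction: `k` distinct draws from `L − ΣW + k` slots,
sorted, then shifted by preceding widths — uniform over all
`C(L−ΣW+k, k)` arrangements), re-paired with the same pairing rule, and
all gaps pooled.  The statistic is
`(mean(null) − mean(actual)) / d_max`, clamped to [−1, 1].  The source
names this statistic and its range but not its formula; the mean
difference normalized by the maximum distance *is* the signed area
between the two empirical CDFs over `[0, d_max]` divided by `d_max`, so
it reproduces both the stated range and the stated sign semantics
(positive = tighter than chance).  `d_max` defaults to the pairing
`max_gap`.

**Position.**  The upstream distances of module midpoints are tested
against Uniform(0, L) with the one-sample Kolmogorov–Smirnov statistic.
KS was chosen because the underlying positional statistic is not
specified at the source: it is distribution-free, bounded in [0, 1], and
directly testable (point mass → 1; uniform quantiles → 1/(2n)).  Ties
are handled by evaluating the empirical CDF at sample points and their
left limits.

**Coverage.**  Fraction of genes in the starting set with at least one
instance of the module order; a gene with several instances counts once.

**Orientation.**  `|2·f_same − 1|` where `f_same` is the fraction of
instances with both motifs on the same strand.  The score is symmetric:
a systematic preference for *opposite* strands is as non-random as one
for the same strand, and both regimes occur in real data.

### The combined score

Each component is mapped to [0, 1]: `sig_norm = min(min(Sig_A, Sig_B) /
sig_ref, 1)` with `sig_ref = 240` bits by default (a typical strong
motif saturates the component), `abc_norm = (ABC + 1)/2`, and the other
three are already in range.  The module score is the weighted mean with
user-adjustable non-negative weights (equal by default — the original
weighting is not published), hence normalized to [0, 1] and invariant to
uniform weight rescaling, and monotone in every component.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_gap` | 200 bp | largest edge-to-edge gap that still counts as a module; generous relative to reported median spacings (12–106 bp) |
| `d_max` | `max_gap` | ABC normalization constant |
| `R` | 1000 | shuffling-null replicates; gives ±0.01-stable ABC at typical occurrence counts |
| `sig_ref` | 240 bits | Sig saturation for the normalized component |
| `alpha` | 10⁻³ | enrichment threshold on the raw hypergeometric p, matching the conventional cut; Benjamini–Hochberg adjustment is available but off by default (fidelity first, rigor on request) |
| weights | equal | component weights of the module score |

Module position uses the **midpoint** of the spanned interval (the
source does not say whether midpoint, 5' edge or proximal edge is used;
the midpoint is symmetric in the two motifs).  Positional quartiles use
the occurrence's **3' edge** distance with half-open bins, so boundary
occurrences are counted exactly once and "0–200" is proximal.  Signed
upstream positions are negative (e.g. −118 = 118 bp upstream); group
summaries additionally report the display transforms used for box-plot
pipelines that cannot take negatives (`abc + 1` in [0, 2], and
`|median upstream position|`).

## Downstream procedures

* `quartile_fractions` / `proximal_majority_flag`: fraction of motif
  occurrences per positional bin; the proximal flag requires a *strict*
  maximum in bin 1 (ties are not a majority).
* `aggregate_group_attributes`: arithmetic means of every attribute per
  (group × order) across gene sets, plus the display transforms.
* `partition_by_orientation`: genes whose modules are *all* in one
  order form a subset; genes with both orders, other orders, or no
  modules are excluded.  Enrichment of each subset is an exact
  hypergeometric upper tail per term.
* `extra_gene_search`: greedy — each step adds the candidate gene whose
  inclusion maximally increases the motif's Sig (recomputed on the
  enlarged set; the background `p0` is estimated once and held fixed),
  stopping when nothing improves or `max_added` is reached.  Whether the
  original feature is greedy or single-pass is unstated; greedy is this
  package's documented choice, and it guarantees Sig strictly increases
  along the additions.  Candidates without a single occurrence are never
  added.

## The synthetic world

`plant_spec()` / `generate_dataset()` emulate the regime reported for
budding-yeast-like gene sets: 200 genes × 800 bp, background GC 0.38,
module coverage 0.46, constant 12-bp gap, proximal placement
(distance fraction ~ Beta(1, 4), mean ≈ 160 bp upstream), 90%
same-strand, order `RRPE-PAC`.  The alternative regimes (wider 38/106-bp
spacings, opposite-strand preference) are reachable by changing the
spec.  PAC and PAC2 ship as `GATGAG`/`GATAAG`; RRPE has no published
fixed consensus, so the generator uses the clearly labelled synthetic
stand-in `TGAAAAWTTT` — A/T-rich and deliberately **non-palindromic**,
because a self-reverse-complementary consensus is reported on both
strands at every site, which erases strand-preference information.

What the generator does *not* emulate: phylogenetic correlation between
"species", promoter composition heterogeneity (background is i.i.d.),
and motif degeneracy beyond the consensus/mismatch model.  Accidental
background matches are **not** scrubbed — they are part of realistic
noise.  Consequently truth-based tests use set containment (every
planted site must be rediscovered; extras are legitimate), and
parameter-recovery checks distinguish two kinds of claims: aggregate
statistics (median gap, coverage) are measured on *all* discovered
modules, while the planted strand parameter is measured on the
truth-matched instances, since accidental modules carry no strand
signal by construction.  A green recovery test therefore establishes
that the pipeline recovers planted structure amid realistic background
noise, not that it would match any particular biological dataset.

One calibration note: the bound "uniform placement gives position_score
< 0.1" is checked at coverage 1.0.  At coverage 0.46 only ~100 module
instances exist and the KS statistic's own sampling noise has median
≈ 0.08, so the 0.1 bound would be a coin flip for a perfectly correct
implementation; with the full 200-instance sample the bound is met with
wide margin.  All other recovery claims are tested at the stated
coverage 0.46.

## Numerical choices and degenerate inputs

* Binomial and hypergeometric tails are exact (`pbinom`/`phyper`), and
  both are cross-checked in the test suite against independent
  summation/enumeration oracles (≤ 10⁻⁹ relative at small sizes).
* The placement null is sampled by an exact combinatorial scheme (no
  rejection), cross-checked against exhaustive enumeration of a tiny
  region (total variation < 2% at R = 5000).
* Equal-start occurrence pairs (possible only for distinct motifs with
  identical coordinates) are overlap-excluded from modules; the order
  label tie-break is lexicographic and logged.
* A motif wider than its region yields an empty scan, not an error; a
  region too short to host a shuffle replicate is skipped with a
  warning; a module order with zero instances warns and reports `NA`
  attributes with coverage 0.
* All randomness flows through explicit `seed` arguments, and seeded
  helpers restore the caller's RNG state.

## Known limitations

* Sig is a transparent binomial model, not a reimplementation of any
  motif finder's internal significance; concordance with such tools is
  not claimed.
* Only motif pairs are considered (no triplets or higher-order
  arrangements).
* The enrichment interface is generic: annotation catalogs must be
  supplied by the user as gene→term tables.
* Upstream regions are inputs; extracting them from a genome + GFF is
  out of scope.
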