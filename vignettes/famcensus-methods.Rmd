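---
title: "famcensus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famcensus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famcensus)
```

# Scope

`famcensus` packages the stages of a genome-wide gene-family survey of
the kind run for malectin / malectin-like domain (MD/MLD) receptor
kinase families in trees: domain-architecture census, distance-based
phylogeny with bootstrap clade calling, tandem-cluster and intron
statistics, multi-experiment expression with tissue-specificity
scoring, and guide-gene co-expression networks. Upstream steps that
belong to external tools — BLAST searches, multiple sequence
alignment, signal-peptide or localisation prediction, read QC and
pseudoalignment — are consumed as inputs, never recomputed.

# The census model

A domain model is a consensus sequence plus an identity threshold.
Scanning computes exact-position identity (matches / model length) at
every window offset and keeps windows at or above the threshold,
resolving overlaps greedily by descending identity (ties: smaller
start, then token). This is a deliberate stand-in for profile-HMM
scanning: on annotated (or synthetic) data the scanned token set, not
the scoring scheme, is what downstream stages consume, and a hit table
from `hmmscan` can be supplied directly to `census_architectures()`.

Two consecutive `MD` hits whose gap is at most `mld_gap` collapse into
one `MLD` token. The default `mld_gap = 120` residues reflects that
the two sub-domains of a malectin-like domain are adjacent in crystal
structures; no published gap rule exists for the annotation tools this
mimics, so the parameter is exposed. Superclade classification uses
presence and relative order of `LRR`, `MD`, `MLD`, `PK`, `Kin` only;
`SP`, `TMD`, `CC` are ignored, which makes the rules invariant to
signal peptides and membrane topology — a property tested by fuzzing.

Molecular weight uses average residue masses plus one water.  The
isoelectric point is the bisection root of a Henderson–Hasselbalch
net-charge model with the EMBOSS pKa set, tolerance 0.01 pH; the test
suite checks it against an exhaustive grid search.

# Phylogeny

Distances are per-site mismatch fractions with pairwise gap deletion;
the Poisson correction `d = -ln(1 - p)` (p capped at 0.99) is the
default for amino-acid data. Neighbor-joining follows the standard
Q-criterion with two determinism rules: ties in Q break to the
lexicographically smallest id pair, and negative branch lengths clamp
to zero with the deficit moved to the sibling. NJ is exact on additive
matrices — the suite verifies topology and branch lengths against 50
random generating trees, using `ape` as the independent oracle.

Bootstrap support resamples alignment columns, rebuilds the NJ tree,
and scores each internal bipartition of the full-data tree by the
percentage of replicates containing it (the display convention of
MEGA-style tools, not a consensus tree). Clade extraction takes the
smaller side of each supported bipartition as the candidate clade
(tie: the side not containing the alphabetically first taxon), then
keeps maximal mutually disjoint candidates with support at or above
`min_support` and at least `min_size` members; everything else is an
orphan. `min_support` defaults to 70 — published family surveys
report observed minima (e.g. "at least 87%") rather than chosen
thresholds, so this is a free parameter. At `min_size = 1`, orphans
are promoted to singleton clades, mirroring how surveys promote
orphans with cross-species orthologs; by default promotion is off
because that judgement cannot be automated.

Clade expansion between two species uses the 2×2 Pearson chi-square
(1 df, no continuity correction) on clade versus family counts. A
simulated null (2,000 replicates, n = 150 per species) keeps the
type-I error within [0.03, 0.07] at alpha = 0.05; zero expected cells
raise an error advising an exact test.

# Gene models and tandem clusters

Coordinates are 1-based inclusive GFF3 throughout; parsing is backed
by `rtracklayer` with the module's own error contracts (end < start,
exon outside parent) layered on top. Introns are exon count minus one.

Tandem clusters chain family genes along a seqid while *both* bounds
hold: at most `max_intervening` non-family gene models between
consecutive members and at most `max_gap` bp start-to-start. The
literature the rule descends from does not restate its definition, so
the defaults (8 intervening genes, 250 kb) are explicit surrogates and
both are configurable. Strand is ignored: tandem repeats occur in the
same or reverse orientation. Scaffold-resident genes participate in
clustering (clusters do occur on scaffolds); seqids are classified by
prefix (`Chr` vs anything else).

# Expression

Counts are normalised per experiment by median-of-ratios size factors
(fallback: total-count ratios when no gene is positive everywhere)
and stabilised as `log2(count/factor + 1)`. This VST surrogate keeps
the two properties the downstream statistics rely on — approximate
variance flattening across the NB mean range and rank preservation —
without reproducing any particular parametric implementation; the
flattening is asserted by simulation in the suite. Experiments are
merged by independent per-sample median centering and joined on the
gene-id union, with genes absent from an experiment kept missing, not
zero.

Tau is `sum_i (1 - x_i/max x) / (N - 1)` over per-tissue means.
Negative centered values are clipped to zero first (tau is defined on
non-negative profiles; whether the original workflow computed it on
centered or shifted values is unstated), tissues without data are
excluded from `N`, and an all-zero profile yields `NA`. One
consequence worth knowing: after median centering, genuinely flat
genes sit near zero in most tissues and small positive noise drives
their tau upward, so absolute tau values are inflated relative to tau
on raw stabilised means — but the *ranking* that separates specific
from ubiquitous genes is preserved (AUROC > 0.95 on planted truth in
the suite). Peak tissue is the argmax with ties to the declared
tissue order; heatmap ordering groups genes by peak tissue and orders
within groups by average-linkage clustering on `1 - r`.

# Co-expression

Mutual information uses a plug-in estimator over equal-frequency bins
(rank-based, ties broken by position for determinism). The default
bin count is 10, **capped at `floor(sqrt(n_positions))`**: with short
series, ten bins hold two to three points each and the plug-in
estimator's null tail becomes heavy enough that the CLR false-positive
rate at Z >= 5 exceeds 1e-3 — the cap (the same guard used by
standard MI-network estimators) restores calibration while leaving
long-series behaviour unchanged. CLR scores are
`sqrt(z_i(j)^2 + z_j(i)^2)` with row-wise standardisation excluding
the diagonal; rows with zero spread contribute zero. The edge
threshold applies to the clr score itself (the workflow this mirrors
reports "Z-score threshold 5.0" without further detail). Edge signs
come from Pearson correlation of the same stabilised profiles —
signed edges are displayed in such networks but the sign rule is not
published. Networks are guide-anchored at depth one (guides plus
first neighbours), and guides without any neighbour are reported
rather than dropped.

# The synthetic world

The generators state the world the tests live in; none of their
parameters are tuned to outcomes.

* **Proteome** — family proteins concatenate uniform-random linkers
  (15–40 aa) with mutated copies of their clade founder's domains;
  `MLD` emits two tandem MDs separated by 8 residues. Clade founders
  diverge from the shared consensi at rate `clade_divergence`
  (default 0.08) and genes from their founder at `substitution`
  (default 0.05) — jointly validated against the identity threshold
  so planted domains stay detectable. Background proteins are
  rejection-sampled to contain no window above any threshold.
* **Layout** — 19 chromosomes (the poplar karyotype), clusters
  planted with controlled intervening-gene counts and gaps; isolated
  family genes are separated from any family neighbour by more than
  both default bounds; `scaffold_fraction` defaults to 0.13,
  echoing the 19-of-146 scaffold share of the family this emulates.
* **Counts** — negative binomial with variance `mu + mu^2 phi`,
  `phi = 0.05` (typical biological-replicate dispersion), 3
  replicates per tissue (the floor in the emulated atlases), mild
  lognormal library-size jitter around per-experiment factors.
  Planted modules share a per-sample latent `z ~ N(0,1)`; member
  means are multiplied by `2^(sign * strength * z)`.
* **Profile series** — 50 ordered positions by default: the
  high-resolution cryosection series this emulates has ~25 sections
  per tree across four trees, so 50 is a conservative stand-in. The
  null-calibration test keeps the 25-position, 100-gene world its
  criterion states.

What a green test does **not** establish: real proteomes have domain
families with genuine sequence heterogeneity (the scanner's exact-
position identity is far cruder than profile HMMs), real alignments
have gaps and alignment error, real RNA-seq has batch structure beyond
a global size factor, and real co-expression has correlated background
modules. Headline counts of any real survey (146 genes, 14 clades,
87%) depend on the real proteome and annotation releases and are not
reproduced here; the package reproduces the *methods* and verifies
them on planted truth.

# Numerical choices

* NJ ties: lexicographic id pairs; negative branches clamped with the
  deficit moved to the sibling — bit-reproducible trees.
* Distances: p capped at 0.99 before the Poisson log; pairs with no
  comparable column are an error naming the pair.
* pI bisection: interval halving to < 0.01 pH on a monotone
  net-charge function.
* Tau: negatives clipped before the formula; `NA` for all-zero
  profiles; scale invariance holds to 1e-9 over 10,000 fuzzed
  profiles.
* MI bins: equal-frequency, rank ties by position; effective bins =
  `min(bins, floor(sqrt(n)))`, never below 2.
* Master seed: per-stage seeds are `seed + 1000 * stage_index`, so
  stages are independently reproducible; all generator randomness is
  wrapped so the caller's RNG state is untouched.

# Known limitations

* The scanner requires roughly length-conserved domain instances; it
  is not a remote-homology tool.
* `extract_clades` cannot call a clade holding more than half the
  taxa (smaller-side convention on an unrooted tree).
* The chi-square expansion test is asymptotic; small clades trip the
  zero-expected-cell guard and need an exact test outside this
  package.
* Merging experiments aligns medians, not distributions; strong
  composition differences between experiments survive centering.
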