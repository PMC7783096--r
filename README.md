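# famcensus

Genome-wide gene-family census, phylogeny and expression analysis for
protein families defined by domain content — modelled on the workflow
used to survey malectin / malectin-like domain (MD/MLD) receptor
kinases in woody plants, but reusable for any family whose members are
recognised by ordered domain architectures.

## Who this is for

Plant comparative genomicists running a family survey: given a
proteome, gene models and domain annotations (or the built-in
synthetic generator with planted truth), the package

1. **census** — locates domain instances by sliding-window consensus
   identity, builds ordered architecture strings over
   `SP, LRR, MD, MLD, TMD, PK, Kin, CC` (two tandem MD hits within a
   gap collapse into one MLD), classifies each protein into one of
   five superclades (`LRR-MD-PK`, `MLD-LRR-PK`, `MLD-PK`, `MLD-LRR`,
   `MD-Kin`), and computes molecular weight and isoelectric point;
2. **phylogeny** — p / Poisson distances (`d = -ln(1 - p)`) from an
   aligned FASTA, deterministic neighbor-joining, bootstrap support on
   the full-data tree's bipartitions, extraction of supported clades
   and orphans, and a Pearson chi-square (1 df, no continuity
   correction) test of clade expansion between two species;
3. **genome map** — GFF3 gene models, intron counts
   (`exons - 1`), tandem-duplication clusters (chained while
   intervening non-family genes <= `max_intervening` **and**
   start-to-start gap <= `max_gap`), chromosome-vs-scaffold
   localisation;
4. **expression** — median-of-ratios size factors, a
   `log2(normalised + 1)` variance-stabilising transform, per-sample
   median centering, cross-experiment merging, the tau specificity
   index `tau = sum_i (1 - x_i/max x) / (N - 1)` (0 = ubiquitous,
   1 = single tissue), peak-tissue assignment and peak-grouped heatmap
   ordering;
5. **co-expression** — plug-in mutual information on equal-frequency
   bins, CLR background correction
   `clr_ij = sqrt(z_i(j)^2 + z_j(i)^2)` with
   `z_i(j) = max(0, (MI_ij - mu_i)/sigma_i)`, guide-gene first
   neighbours at a Z threshold (default 5.0), Pearson-signed edges,
   GraphML export.

A synthetic-data module generates proteomes, chromosome layouts and
negative-binomial count matrices with planted truth, so every stage is
testable offline.

## Worked example

```r
library(famcensus)
rpt <- run_pipeline(pipeline_config(seed = 1), outdir = "famcensus_out")

rpt$family_size
#> [1] 42
head(rpt$clade_table[, c("clade", "n", "support")], 4)
#>     clade n support
#> I       I 3    96.0
#> II     II 3    99.5
#> III   III 3    95.5
#> IV     IV 3   100.0
unlist(rpt$superclade_table)
#>  LRR-MD-PK     MD-Kin    MLD-LRR MLD-LRR-PK     MLD-PK
#>         24          3          3          9          3
rpt$percent_chromosomal
#> [1] 88
rpt$cluster_table[, c("cluster_id", "seqid", "n")]
#>   cluster_id seqid n
#> 1       C1.1 Chr01 2
#> 2       C2.1 Chr02 3
#> 3       C5.1 Chr05 4
```

The default configuration simulates a 14-clade family, three genes per
clade. The census classifies all 42 proteins into the five superclades
(24 LRR-MD-PK, 9 MLD-LRR-PK, 3 each MLD-PK / MLD-LRR / MD-Kin —
matching the planted architectures); the NJ/bootstrap stage recovers
all 14 clades with supports of 84-100%; 88% of family genes map to
chromosomes (5 of 42 are planted on scaffolds); and the three planted
tandem clusters (2, 3 and 4 members on Chr01/Chr02/Chr05) are detected
exactly. Per-gene tau scores and peak tissues, the heatmap ordering,
the co-expression edge table and a GraphML network are written to
`famcensus_out/`, with everything summarised in `report.json`.

A command-line entry point with subcommands
(`simulate | census | phylo | map | express | coexpress | report | all`)
is installed at `inst/cli/famcensus.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/famcensus.R", package="famcensus"))')" \
    all --seed 1 --outdir famcensus_out
```

## Layout

- `R/` — modules: `domain_models`, `synth_proteome`, `synth_genome`,
  `synth_counts`, `census`, `phylogeny`, `genome_map`, `expression`,
  `coexpression`, `pipeline`
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/famcensus-methods.Rmd` — models, parameter choices,
  generator scope and limitations
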