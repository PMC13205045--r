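# mitoPanels

Cell-type marker panels and lineage tracing from single-cell
mitochondrial DNA SNPs.

## The problem

Mitochondrial DNA mutates 10–100× faster than the nuclear genome and is
present at 100–1000 copies per cell, so somatic mtDNA variants — each
observed as a per-cell heteroplasmy, the fraction of a cell's mtDNA
molecules carrying the variant — behave as endogenous, heritable lineage
barcodes readable by single-cell assays (MAESTER-style mitochondrial
transcript enrichment, mitochondria-optimized scATAC). A single mtDNA
SNP is almost never specific to one cell type: early-embryonic and
maternally inherited variants are shared across organs. The way out is
combinatorial. mitoPanels implements, for people analyzing
mgatk/maegatk-style per-cell allele counts:

* **Binary SNP calling** per cell: a variant is present when its allele
  frequency exceeds 1% of the reads at the site (strictly), its mean
  base quality exceeds 30 (strictly), with configurable depth guards;
  cells with fewer than 5 SNPs are dropped.
* **Unique three-SNP combinations**: exhaustive, target-driven
  enumeration of all SNP triples carried by at least one cell of a
  target cell type and by *no* other cell of the same individual, then
  greedy set cover to assemble a panel of triples collectively marking
  ≥ 90% of the target class, each covered cell anchored to one triple.
* **Clonal structure**: descending shared-SNP ordering and
  Jaccard/average-linkage hierarchical clustering of binary SNP
  profiles for heatmaps.
* **Lineage tracing**: matching a reference sample's panel against a
  second sample of the same individual (e.g. pre- vs post-hepatectomy
  liver), with cluster-distribution tables, reporter-tag concordance and
  a permutation test for cluster enrichment.
* **A ground-truth simulator**: neutral heteroplasmy drift
  (`Binomial(N, h)/N` per division) along a cell-division tree with
  Poisson mutation, two-timepoint clade-weighted sampling and a noisy
  sequencing readout — so the whole pipeline is testable without any
  sequencing data.

Inputs are sparse Matrix Market per-base count matrices (plus barcodes
and a reference FASTA) or a long-form TSV, with a cell-annotation TSV
carrying sample, cell-type, cluster and optional reporter-tag labels.

## A worked example

Simulate a small two-timepoint study (four clades fixed at generation 2;
cholangiocytes carry the reporter tag), genotype it, and discover the
cholangiocyte panel:

```r
library(mitoPanels)

cfg <- simConfig(seed = 7, n_generations = 10, clade_generation = 2,
                 clade_types = c("hepatocyte", "cholangiocyte",
                                 "B_cell", "T_cell"),
                 mutation_rate = 1, n_germline = 4,
                 sampling = list(
                     pre  = list(generation = 8,  n_cells = 60,
                                 expansion = NULL),
                     post = list(generation = 10, n_cells = 80,
                                 expansion = c(hepatocyte = 2))),
                 readout = list(mean_coverage = 100,
                                n_background_sites = 50))
sim  <- simulateDataset(cfg)
calls <- callVariants(sim$counts)            # thresholds: >1% VAF, >Q30
m    <- buildSNPMatrix(calls, sim$annotations)
m    <- filterCellsMinSNPs(m, 5)             # at least five SNPs per cell
panel <- discoverPanels(m, "cholangiocyte")
panel
#> SNPPanelSet for cell type 'cholangiocyte' (sample post+pre)
#>   13 three-SNP combination(s); 23/25 target cells anchored (coverage 0.920)
verifyUniqueness(panel, m)$ok
#> [1] TRUE
```

13 triples jointly mark 23 of the 25 cholangiocytes that passed the SNP
filter (92%), and no non-cholangiocyte cell of the individual carries
any complete triple — the uniqueness guarantee that makes a later match
interpretable. Tracing the panel into the post-timepoint cells of the
same simulation and scoring against the known lineage tree
(`tracePanels()`, `evaluateTracing()`) reports which matched cells truly
descend from the cholangiocyte clade.

The same pipeline is scriptable from a shell via the bundled entry point
(`inst/scripts/mitopanels`): `simulate`, `call`, `panels`, `cluster`,
`trace`, `evaluate`, each writing its resolved configuration and log
next to its outputs and fully reproducible from a single `--seed`.

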