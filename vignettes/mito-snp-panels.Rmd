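---
title: "Defining cell types and tracing lineages with mitochondrial SNP combinations"
author: "mitoPanels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining cell types and tracing lineages with mitochondrial SNP combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoPanels)
```

## The problem and the model

Mitochondrial DNA is a compact, high-copy genome that mutates one to two
orders of magnitude faster than nuclear DNA. Each cell carries hundreds of
mtDNA molecules, and the fraction of molecules carrying a given variant —
its *heteroplasmy* `h` — segregates stochastically at every cell
division. Somatic mtDNA variants therefore act as endogenous, heritable
lineage barcodes: cells of a common clone share the variants their
ancestor carried, and even heteroplasmies of a few percent persist across
divisions. Single-cell assays that enrich mitochondrial sequence
(3'-transcript enrichment on scRNA-seq libraries, or
mitochondria-optimized scATAC) yield per-cell, per-position, per-base read
counts from which such variants can be genotyped.

A single mtDNA SNP is rarely specific to one cell type: variants
inherited maternally or arising before germ-layer differentiation are
shared across organs, and sporadic detection errors corrupt any
single-marker rule. mitoPanels instead works with *combinations of three
SNPs* observed together in one cell. The defining property of a valid
triple for a target cell class is:

* at least `min_support` target cells carry all three SNPs, and
* **no** other cell of the same individual (the *comparison scope*)
  carries all three.

Because simultaneous errors at three positions in the same cell are
vanishingly rare, a triple is a robust cell-class marker even when its
member SNPs are individually common. A *panel* is a set of such triples
chosen so that together they mark the required fraction of the target
class (90% by default); each covered cell is *anchored* to the first
selected triple it carries. Panels discovered in one sample of an
individual can then be searched for in a second sample of the same
individual — for example, a resected liver lobe before partial
hepatectomy versus the regenerated liver — to identify putative
descendants of the original class.

## Binary SNP calling

Allele counts are reduced to binary presence/absence calls per cell. A
call for alternate base `a` at position `p` in cell `c` requires all of:

| parameter           | default | meaning                                        |
|---------------------|---------|------------------------------------------------|
| `min_vaf`           | 0.01    | alt reads / site coverage **strictly above** 1% |
| `min_quality`       | 30      | mean Phred base quality **strictly above** 30   |
| `min_site_coverage` | 10      | total reads at the site                         |
| `min_alt_reads`     | 2       | alt-supporting reads                            |

The two headline thresholds are deliberately strict inequalities —
boundary observations (VAF exactly 1%, quality exactly 30) are excluded.
The depth guards exist because a lone stray read at a shallow site would
otherwise pass the frequency rule; both are configurable and can be
disabled (`0`/`1`). Each alternate base is an independent variant
(`pos_ref>alt`), so a cell may legitimately carry two variants at one
position. When an input provides no quality summaries the quality filter
is inapplicable; calls then pass with `mean_quality = NA`, which keeps
counts-only genotyping output usable. Cells are finally filtered to a
minimum SNP count (default 5, inclusive), since cells with fewer SNPs
cannot support discriminative triples; absence of a call is treated as
absence of the variant, deliberately conflating dropout with true
absence (a coverage-aware mode is out of scope).

## Panel discovery

Enumeration is *target-driven*: every valid triple must be a 3-subset of
some target cell's SNP set, so candidates are generated per target cell
(`choose(k, 3)` subsets of its `k` SNPs, deduplicated in C++), never as
`choose(V, 3)` over the variant universe. Uniqueness is then checked
against an inverted index (variant → scope cells) with a three-way
sorted intersection, so scope cells sharing no variant with a triple cost
nothing. An independent exhaustive reference (`bruteForceTriples()`,
capped at 25 variants) exists purely to cross-check the fast path.

Panel assembly is greedy set cover: repeatedly take the triple covering
the most not-yet-anchored target cells until coverage reaches
`target_coverage` (default 0.90, stop rule `>=`) or no triple adds
coverage. Greedy reaches any coverage the union of valid triples can
achieve, because it stops only when the marginal gain is zero; if the
union itself falls short, the best achievable panel is returned with a
`shortfall` flag rather than an error. Ties are resolved
deterministically (higher mean target prevalence of the members, then
lexicographic variant ids), and serialization has a fixed key order, so
identical inputs give byte-identical panels.

Within a selected triple the *tertiary* SNP is the most target-specific
member, maximizing `s(v) = prev_target(v) / (prev_target(v) +
prev_scope(v))` (with `s = 1` when no scope cell carries `v`); ties go
to the lower target prevalence, then the higher position. The remaining
two members are ordered primary/secondary by descending target
prevalence. This realizes the design in which the primary and secondary
members are high-frequency population SNPs while the third contributes
the specificity; the exact formula is this package's choice, since only
the qualitative roles are fixed by the method.

Uniqueness is evaluated at the **triple** level, not per SNP — that is
the only reading under which organ-shared SNPs can serve as
primary/secondary members at all. The comparison scope defaults to every
non-target cell of the individual across all provided samples, and can be
narrowed to within-sample. `min_support` defaults to 1 because the
method itself imposes no support floor; raising it suppresses triples
that exist only through a single (possibly noisy) cell.

## Clonal ordering and clustering

For heatmaps, variants are ordered by descending carrier prevalence and
each cell's presence row is read as a binary word over that variant
order; cells are sorted by the word, descending, with barcode as the tie
break. This reproduces a multi-column descending spreadsheet sort and
places cells sharing the most prevalent SNPs top-left. Hierarchical
clustering uses the Jaccard distance on SNP sets
(`d = 1 - |x & y| / |x | y|`, with `d = 0` for two empty sets by
convention) under average (default) or complete linkage via
`stats::hclust()`; the distance and linkage are package choices, as the
method fixes neither. Leaves are traversed denser-subtree-first so
layouts are deterministic.

## Tracing and enrichment

A query cell matches a panel when it carries **all three** SNPs of at
least one triple; 2-of-3 matching is rejected because it would void the
uniqueness guarantee that makes a match interpretable. Matched cells are
tabulated against the query's cluster labels and against the boolean
`reporter_tag` annotation — the stand-in for an orthogonal lineage label
such as a recombinase-excision reporter; detecting that label from reads
is upstream of this package. Whether matched cells concentrate in
expected clusters is quantified by a label-shuffling permutation test
with the add-one estimator `p = (1 + #{null >= observed}) / (1 + n_perm)`,
which cannot return zero and is valid (if slightly conservative at small
match counts, where the discrete null creates ties).

## The simulator

The generator exists so that every claim above is testable against known
ground truth. It grows a binary division tree from one founder:

* the founder carries `n_germline` homoplasmic variants (`h = 1`);
* at each division each daughter redraws every variant's heteroplasmy as
  `Binomial(N, h)/N` — one neutral resampling of `N` segregating units
  per division, the simplest vegetative-segregation model; 0 and 1 are
  absorbing, the mean is conserved, and variance accumulates along
  lineages;
* each daughter gains `Poisson(mutation_rate)` new variants at uniformly
  chosen **unused** genome positions, starting from a single molecule
  (`h = 1/N`), so early-arising variants are the plausibly
  clade-defining ones;
* clades are the tree nodes at `clade_generation`; each carries a cell
  type, and designated types carry the reporter tag.

`copy_number` (default `N = 100`) is an *effective* number of
segregating units, not the raw genome count: mtDNA replicates and
segregates in nucleoid packages, so the drift-relevant unit count sits at
the low end of the 100–1000 genomes a cell carries. This matters
quantitatively: with one binomial resampling per division, the per-division
variance of `h` is `h(1-h)/N`, and at `N` of several hundred a
single-molecule variant essentially never reaches the 1% calling
threshold within the few dozen divisions a simulation can cover —
no mutation rate can then produce realistic per-cell SNP counts, because
new variants draw from a finite pool of 16,299 positions. At `N = 100`
and 24 generations the default preset yields roughly 6–25 detectable
SNPs per cell, inside the 5–60 range typical of enrichment-based
single-cell mtDNA assays.

Cells to be sampled at each timepoint are chosen first — a stratified
multinomial over clades weighted by `expansion` factors (so a
regenerating clade can be over-represented in the post sample), uniform
within a clade — and only lineages ancestral to a sampled cell are
materialized. Because each branch evolves independently given its
parent, the sampled cells' joint law is untouched; this is what makes
division depths of dozens of generations tractable.

The readout draws per-site coverage from a negative binomial, alt reads
from `Binomial(cov, h(1-e) + (1-h)e/3)`, independent `Binomial(cov, e/3)`
error reads for each other non-reference base, and zeroes a cell's alt
reads with probability `dropout` per variant. Mean base qualities are
clipped normals with one deliberate asymmetry: error-only read piles
draw from a lower-mean distribution (25 ± 4) than reference- and
true-variant piles (37 ± 3). Without that asymmetry a quality filter
would be inert in simulation; with it, the `> 30` rule removes most
error-driven calls, exactly as on real data. Only positions carrying a
variant in some sampled cell, plus `n_background_sites` invariant
positions, are materialized — unassayed invariant positions could
contribute nothing callable and would only inflate the matrices.

The default preset (two timepoints at generations 21 and 24, 250 + 500
cells, eight clades with liver/spleen-style labels, threefold hepatocyte
expansion post, coverage 150, error rate `1e-3`, dropout 0.1) is the
study design the acceptance pipeline runs. What the simulator does *not*
emulate: selection on variants, copy-number differences between cell
types, strand-specific error signatures, doublets, and mitophagy-driven
loss of ancestral variants. Passing tests therefore demonstrate the
machinery is correct under neutral drift with well-behaved noise, not
that any particular tissue meets those assumptions.

## Numerical and scale choices

* Positions are 1-based against the supplied reference (mouse chrM,
  16,299 bp, is the default length); Matrix Market files are 1-indexed,
  so the mapping is the identity.
* Strand-split inputs are summed on read; per-strand qualities combine
  as count-weighted means. No strand-concordance filter is applied — the
  thresholds refer to total per-cell frequency.
* All orderings (variants by position, barcodes lexicographic, greedy
  tie-breaks, JSON key order) are fixed, so every writer is
  byte-deterministic under a fixed seed; the lineage, readout and
  permutation stages derive their generators from one seed by fixed
  offsets.
* Test suites run at deliberately small scales: oracle equivalence on
  200 random instances of at most 30 cells and 12 variants; uniqueness
  on 100 simulated datasets of 40–80 cells across three mutation rates;
  the end-to-end check on the full default preset. These sizes exercise
  every code path while keeping the whole suite quick on one CPU.
* Degenerate inputs are contracts, not crashes: empty comparison scopes
  make uniqueness vacuous, a panel with no triples traces to an empty
  result with a warning, zero matched cells give `p = 1` and an `NA`
  precision, and a single-cell matrix is refused by the clustering
  entry point with a pointer to the sort.

## Known limitations

Binary matching ignores heteroplasmy magnitude, so a panel cannot
distinguish a descendant that diluted a variant below threshold from a
non-descendant; dropout and coverage loss depress recall
correspondingly. Panels are individual-specific by construction and
meaningless across individuals. The permutation test conditions on the
matched set and shuffles labels, so it tests label association, not the
matching process itself. Finally, the greedy panel is not guaranteed
minimal — minimum set cover is out of scope.
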