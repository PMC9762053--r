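---
title: "GWAS-driven pan-genome co-expression networks: models and methods"
author: "pancoex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GWAS-driven pan-genome co-expression networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancoex)
```

## The problem

In a species panel such as the maize NAM founders, every genome has its own
transcriptome, and a gene pair that is tightly co-expressed in one genome
need not be co-expressed in another. `pancoex` builds, for each genome, a
co-expression network restricted to genes that carry a GWAS trait
association, takes the union of those per-genome networks — the
*pan-network* — and classifies each edge by how many genomes support it.
The classification separates regulatory relationships that are conserved
across the panel (core), common (near-core), variable (dispensable), or
seen in a single genome (private). Trait-specific subnetworks, hub genes,
pleiotropy counts and GO over-representation are then computed on top of
the classified pan-network.

## The pipeline, stage by stage

### 1. GWAS hits to candidate genes

A SNP is assigned to a gene when its position falls inside the annotated
gene body `[start, end]` or, optionally, inside the *promoter window*: the
5000 bases immediately upstream of the gene start, strand-aware. All
coordinates are 1-based and inclusive on both ends, the GFF3 convention;
for a `+` strand gene the promoter is `[max(1, start - 5000), start - 1]`,
for a `-` strand gene `[end + 1, end + 5000]`. We use the closed interval
at the outer boundary; an open convention would differ by a single base
row. One SNP may hit one gene's body and a neighbour's promoter, and is
then assigned to both — the behaviour of interval-intersection tools such
as bedtools. Trait annotations are *nonredundant*: a gene hit by several
SNPs of the same trait carries the trait once.

```{r}
gene <- data.frame(pan_gene_id = "g1", genome_id = "B73", chrom = "chr1",
                   start = 10001L, end = 12000L, strand = "+")
promoter_interval(gene, window = 5000)
```

### 2. Expression filtering

Genes with median TPM below 5 across the samples of a genome are removed
before any correlation is computed; a median of exactly 5 is retained. The
median of an even number of samples is the mean of the two middle order
statistics, so a gene with ten zeros and ten tens sits exactly on the
boundary and is kept.

### 3. Per-genome networks

Edges are unordered gene pairs with sample Pearson correlation `r > 0.9`
and two-sided `p < 0.01`, where `p` comes from the exact null distribution
of `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. Two
remarks on these thresholds:

* With the study design of `n = 20` samples, `p(r = 0.9, n = 20)` is below
  `1e-7`, so the correlation cutoff dominates and the choice between the
  two candidate significance levels 0.01 and 0.001 (both are plausible
  readings of the method description) does not change a single edge. We
  default to `p_max = 0.01` and expose the threshold in
  `pipeline_config()`.
* The network is *unsigned* in the sense that edges carry no sign label,
  and the literal rule `r > 0.9` is applied to the signed correlation, so
  only positive co-expression forms edges by default. If strong negative
  correlation should also count, `absolute_r = TRUE` thresholds `|r|`.

Genes that are constant across samples after filtering have no defined
correlation; they are excluded from pairing and counted in the
`n_constant` attribute rather than propagating `NaN`. Correlations are
computed on TPM values as given, without a log transform.

### 4. The pan-network and its categories

`union_networks()` merges the per-genome edge lists into one edge per
distinct pair with its *occurrence* (number of supporting genomes).
`classify_edges()` then works on whole occurrence levels, ranked by
occurrence descending:

* **core** — the maximal prefix of levels whose cumulative edge fraction
  stays at or below `core_frac` (default 0.01);
* **near-core** — subsequent levels up to and including the level at which
  the cumulative fraction first reaches `nearcore_frac` (default 0.05);
* **private** — every edge observed in exactly one genome, always;
* **dispensable** — everything else.

Working level-granularly means all edges with the same occurrence share a
fate, so the realized core fraction under-shoots 1% while core+near-core
over-shoots 5% — the tie-break we consider the only defensible one, since
edges within a level are indistinguishable. The occurrence-1 rule is
absolute: in a tiny network where single-genome edges would fall inside
the top percentiles, they are still private. A `strict_core = TRUE` option
restores the classical all-genomes core definition.

`category_summary()` counts edges and genes per category; a gene incident
to edges of several categories is counted in each, which is why category
gene counts can exceed the pan total. `growth_curve()` traces pan and core
edge counts for random genome subsets of size `k = 1..G` (default 100
seeded replicates per size); the resampling scheme is our choice, as the
growth-curve idea fixes only the x-axis, not the subsampling protocol.

### 5. Trait subnetworks, hubs, pleiotropy

A trait's subnetwork keeps the pan-network edges whose **both** endpoints
carry the trait (after merging per-genome trait maps by pan-gene union).
The one-endpoint alternative would inflate node counts with genes that
have no association to the trait, which is at odds with reporting per-trait
node/edge statistics. Degree is the number of incident edges; hub genes are
the full argmax set (ties are reported, never broken). A gene is
pleiotropic when it carries at least two distinct traits;
`pleiotropic_genes()` also tabulates, for a focal trait, how many of its
pleiotropic genes are shared with each other trait.

Because the normalization of "trait representation per category" can be
read two ways, `trait_representation()` emits both: the proportion of a
category's genes that belong to the trait's subnetwork, and that
proportion rescaled to sum to one across traits within the category.

### 6. GO enrichment

One-sided hypergeometric over-representation per GO term present in the
study set, with Benjamini–Hochberg FDR control at `alpha = 0.05`. Genes
without any GO annotation are excluded from both study and background
counts, so the unit of analysis is the annotated universe. Annotations are
used flat, exactly as the InterPro-derived gene-to-GO map provides them —
no ontology-graph up-propagation, mirroring term-list enrichment as
practiced with flat annotation exports. The default background is the set
of all median-filtered annotated genes (the high-coverage universe); the
pan-network gene set can be substituted via
`pipeline_config(enrichment_background = "pan")`.

## The synthetic data generator

Real multi-genome panels with planted truth do not exist, so
`generate_dataset()` manufactures one. Its model, on the log scale, is a
one-factor model per module: for module genes in a genome belonging to the
module's genome subset,

    x_gs = b * z_s + e_gs,   z_s ~ N(0,1) shared within the module,
                             e_gs ~ N(0, sigma^2) independent,

exponentiated to positive TPM-like values and per-gene rescaled so
non-low genes have median TPM >= 5 (per-gene scaling is affine and leaves
Pearson correlations untouched). The population correlation of two module
genes on the latent scale is

```{r}
expected_module_correlation(loading = 1, noise_sd = 0.1)
```

i.e. `b^2 / (b^2 + sigma^2)`, the design dial for placing planted pairs
above or below the `r > 0.9` screen. Genome-private pairs get a factor of
their own in exactly one genome; background genes are independent
log-normal noise (log-sd 0.5, a realistic spread for expression data);
low-expression genes are a constant small value plus jitter, guaranteed
below the median-5 boundary. Genes sit on chromosomes 20 kb apart on
alternating strands, so genic and promoter windows never collide and each
simulated GWAS hit has exactly one intended target gene, recorded in the
ground truth together with every planted pair.

Default study conditions (chosen once, as what we consider a realistic
desk-scale panel): 10 genomes, 300 genes, 20 samples per genome, one
10-gene module shared by all genomes at latent correlation ~0.990
(`b = 1, sigma = 0.1`), 5 private pairs per genome, 10% low-expression
genes, three traits of 10 SNPs each (one targeting the module, one
targeting private pairs in whole pairs — both endpoints — one arbitrary),
half of the hits in promoters. Low-expression genes are drawn from the
background only, so the planted structure stays recoverable by design.

What the generator deliberately does **not** emulate: presence/absence
variation of genes across genomes (every pan-gene exists everywhere),
read-level sampling noise and library-size effects, isoforms, batch
effects, LD structure among SNPs, and heavy-tailed single-sample outliers
beyond log-normality. Passing recovery tests therefore demonstrates the
correctness of the pipeline's screens and bookkeeping, not robustness to
every artefact of real RNA-seq.

## Numerical and engineering choices

* Gene pairs are stored once, in canonical order (`gene_a < gene_b` under
  C collation), everywhere — edge lists, SIF exports, unions.
* The vectorized correlation screen (`cor` on the transposed matrix) is
  required to agree with a per-pair `cor.test` loop to `1e-12`; the
  hypergeometric tail is delegated to the stable `phyper` routine and
  checked against exhaustive enumeration for all universes up to 30 genes.
* `|r| = 1` maps to `p = 0` exactly; p-values are clamped to `[0, 1]`.
* Degenerate inputs are contracts, not crashes: empty GWAS tables, empty
  filtered matrices, single-gene networks, all-private pan-networks and
  empty trait subnetworks all return well-formed empty results, while
  invalid values (negative TPM, strand ".", malformed GO ids, `start >
  end`) raise informative errors.
* All artifacts are written with fixed number formatting, and every source
  of randomness (simulation, growth-curve subsampling) flows from one
  integer seed, so a rerun with the same configuration is byte-identical;
  runs are stamped with an MD5 configuration hash.

## Problem sizes used by the test suite

The automated checks run at desk scale, our choice for a suite that a
developer can run routinely: oracle equivalence on 100 genes x 20 samples;
planted-structure recovery on the default 10-genome x 300-gene
conditions (~36,000 null pairs per genome, >360,000 in total);
classification invariants on 1000 random occurrence histograms;
enrichment enumeration on all universes up to N = 30; a 1000-replicate
null simulation for FDR control; and two full end-to-end pipeline runs
for byte determinism. Headline counts from a full-size panel (millions of
pan edges) are not reproducible at this scale and are not asserted.

## Known limitations

* The pan-gene namespace is assumed consistent across genomes; no
  liftover or orthology inference is attempted.
* Enrichment ignores the GO DAG; a term is tested exactly as annotated.
* The growth curve resamples genomes uniformly; stratified or
  leave-one-out designs are not implemented.
* Correlation is Pearson on TPM as given; rank-based or log-scale
  alternatives are out of scope by design.
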