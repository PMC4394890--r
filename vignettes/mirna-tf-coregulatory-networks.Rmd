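---
title: "Building and testing miRNA-TF co-regulatory networks with fflnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and testing miRNA-TF co-regulatory networks with fflnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflnet)
```

## The model

Transcription factors (TFs) activate or repress transcription of genes and
of miRNA host loci; mature miRNAs post-transcriptionally repress mRNAs,
including those of TFs. fflnet works on a directed, typed, evidence-labelled
edge set over three node classes and enumerates the two recurrent motifs of
combinatorial miRNA-TF regulation:

* **Feed-forward loops (FFLs)**: a (TF, miRNA, gene) triple where the TF
  regulates the gene, the miRNA represses the gene, and the TF and miRNA
  cross-regulate. The triple is a **TF-FFL** when only TF&rarr;miRNA is
  present, a **miRNA-FFL** when only miRNA&#8867;TF is present, and a
  **composite-FFL** when both are.
* **Feedback loops (FBLs)**: a (TF, miRNA) pair with mutual regulation.

Each motif instance is emitted once per (TF, miRNA, gene, type), in
lexicographic order, and is flagged *verified* exactly when every
constituent edge carries experimentally validated evidence. Assembling the
union of motif participants and constituent edges yields the co-regulatory
network; a validated-only view of the edge set yields the verified network.

### Scope rule

Disease scoping is deliberately asymmetric (`restrict_to_scope()`): miRNA
regulation is kept only from the curated disease miRNAs — miRNA target
prediction is noisy, and curation is the main false-positive control — while
TF regulation is kept from **any** TF in the universe so that no upstream
transcriptional control of the disease genes is lost. A disease gene that
itself encodes a TF may occupy the gene role of one triple and the TF role
of another, but never two roles within one triple; in the assembled network
such a symbol is categorized TF (the regulator role dominates) and the
conflict is logged.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| TFBS Z-score cutoff | 2.33 | one-sided 1% normal quantile; binding-site records at or above it become predicted TF edges (inclusive, since a published "cutoff" conventionally retains the boundary) |
| DE p cutoff | 0.01 | strict `<` filter on differential-expression p-values (dimensionless) |
| hub fraction | 0.05 | per-category top share by total degree |
| permutation replicates | 10000 | null draws for the FFL-count test |
| enrichment alpha | 0.01 | raw hypergeometric cutoff; optional BH flag |

Hub counts use `ceiling(fraction * category size)` with full tie inclusion
at the cut: published hub lists are generally not reproducible from any
single rounding rule without knowing the tie structure, so fflnet fixes a
deterministic rule and logs the applied counts rather than mimicking any
particular published list.

## The permutation test

`permutation_test()` asks whether an observed gene set forms more FFLs with
fixed TF and miRNA sets than equally sized gene sets drawn uniformly
without replacement from a user-supplied gene universe (the universe is a
required input — protein-coding inventories differ between annotation
releases, so defaulting one silently would change p-values). The p-value is
the plain proportion of null counts at or above the observed count, which
can be exactly zero at finite replicates; `conservative = TRUE` switches to
the (b+1)/(R+1) estimator. Counting is done on a precomputed pair index
(shared targets of every cross-regulating TF-miRNA pair), so each replicate
costs one membership scan. Each replicate re-seeds from a substream derived
from the root seed, making results byte-identical for identical seeds and
independent of evaluation order. `exact_null()` enumerates all
`choose(n, k)` subsets (refusing above 1e5) and is the oracle the
Monte-Carlo path is tested against.

## Enrichment

The over-representation step is a plain one-sided hypergeometric upper tail
(`stats::phyper`) against an explicit background, with an optional
Benjamini-Hochberg flag and a raw 0.01 default cutoff. This is a deliberate
simplification of tool-specific scores such as DAVID/EASE, whose jackknifed
overlap penalty is not a portable statistic; enrichment results here are
meant to be read qualitatively.

## The synthetic generator and what passing tests mean

`synth_generate()` draws each potential edge independently with a
per-edge-type probability (TF&rarr;gene, TF&rarr;miRNA, miRNA&#8867;gene,
miRNA&#8867;TF), labels each edge validated with probability
`validated_fraction`, wires gene-targeting edges across the whole gene
universe, and samples the disease-gene catalog uniformly from that
universe. Independence gives closed-form motif expectations
(`expected_motif_counts()`), e.g.

$$E[\mathrm{TF\text{-}FFL}] = n_{tf}\, n_{mir}\, n_{gene}\;
p_{tg}\, p_{mg}\, p_{tm}\, (1 - p_{mt}),$$

which is the analytic surface the test suite calibrates the enumerator
against: over 500 seeded replicates the mean enumerated count of every
motif class must sit within four standard errors of its expectation.

```{r expectations}
p <- synth_params(n_tf = 6, n_mirna = 6, n_gene = 15, universe_size = 20,
                  p_tg = 0.25, p_tm = 0.2, p_mg = 0.25, p_mt = 0.2)
expected_motif_counts(p)
```

The `"paper-scale"` preset (169 TFs, 83 miRNAs, 153 disease genes in a
1000-gene universe, `p_tg = p_mg = 0.15`, `p_tm = p_mt = 0.025`) was chosen
from these formulas to land in the 2&ndash;3k-FFL regime typical of
disease co-regulatory studies — a realistic workload for demonstrations,
not a reproduction of any particular dataset.

What this generator does **not** emulate matters for interpreting green
tests: real regulatory networks have heavy-tailed degree distributions,
correlated targeting (co-regulated gene modules), arm/family structure in
miRNA naming, and database-specific biases in which edges are validated.
Passing the calibration and oracle tests shows the *counting machinery* is
exact and the pipeline is deterministic; it does not certify biological
conclusions drawn from any particular curated input.

## Numerical and design choices

* **Evidence merging**: edges are keyed by (regulator, target,
  regulator_type); a key seen as both predicted and validated becomes
  `both`. A motif counts once regardless of evidence mix ("merged"
  enumeration); the verified view re-enumerates on the validated edges.
* **Enumeration strategy**: iterate cross-regulating (TF, miRNA) pairs and
  intersect their target sets. The contract — tested on 200 random graphs —
  is equality with the exhaustive \(O(n^3)\) triple scan.
* **Determinism**: output tables are radix-sorted, so row order does not
  depend on the session locale; all generators and the permutation test are
  pure functions of their seed.
* **Degenerate inputs**: empty catalogs raise configuration errors before
  any stage runs; degree skewness (moment-based \(g_1\)) refuses fewer than
  3 nodes or a constant degree sequence; `exact_null()` refuses
  combinatorially infeasible enumerations with a size report.
* **Problem sizes in the suite**: oracle checks use graphs of at most 50
  nodes, calibration uses 500 replicates of a 6/6/15 world, and the
  Monte-Carlo-vs-exact check uses a 12-gene universe (220 subsets) — sizes
  at which the exhaustive oracles are themselves fast and exact.
* **miRNA naming**: symbols are matched exactly as given. The optional
  `normalize_mirna()` strips a species prefix and canonicalizes the "miR"
  casing, and nothing more: collapsing arms or precursor families is a
  curation decision, not something a normalizer should guess.

## Limitations

The package consumes already-curated catalogs and already-scored edge
tables; it does not fetch from target-prediction or interaction databases,
does not compute differential expression from raw data, and restricts
motif search to 3-node FFLs and 2-node FBLs (longer cycles through the
gene are out of scope). Betweenness and other centralities beyond degree
are left to igraph on the exported GraphML.
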