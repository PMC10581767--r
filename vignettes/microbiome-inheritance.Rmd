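---
title: "Quantifying vertical transmission of gut microbiomes across colony pedigrees"
author: "mbInherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vertical transmission of gut microbiomes across colony pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbInherit)
```

## The problem

Social insects such as fungus-farming termites found new colonies through
winged reproductives (alates) that leave the parental nest carrying a gut
inoculum. Which bacteria make it through this bottleneck — and whether
abundance alone explains who makes it — is a question about *vertical
transmission*. mbInherit works from three tables that any 16S amplicon
workflow produces: an ASV read-count matrix, a taxonomy table, and sample
metadata describing a pedigree design in which several maternal colonies are
crossed with a shared paternal colony, with samples from three tiers:
parental-colony workers, founding reproductives, and offspring-colony
workers. Each sample is a pool of several dissected guts treated as one
community observation.

## The inheritance rule

An ASV is called **transmitted to founders** in a pedigree–lineage when it is

1. present in at least one parental-colony sample of that lineage
   (worker samples by default, since workers house most of the colony
   microbiome; `parentalCastes` widens this), and
2. present in *every* founding-reproductive sample of that lineage and
   pedigree.

It is **vertically transmitted** when, additionally, it is present in at
least one offspring-colony sample of the pedigree. Presence means at least
one read (`minCount` is exposed for sensitivity analysis) after a
dataset-level filter that removes ASVs with fewer than 25 reads in the whole
dataset. Requiring *all* founder samples makes the call deliberately strict:
a single founder pool without the ASV vetoes it. Maternal and paternal calls
use the same rule and are merged into uniquely-maternal / uniquely-paternal
/ shared / none status per ASV (`attributeParentage()`).

Two readings of "present in the parental colony" are possible when lineages
are merged (per lineage, or in either colony); classifying per lineage and
merging afterwards reproduces both, and is what the package does. Offspring
presence is evaluated per sample, not per colony, because offspring worker
pools can span colonies within a pedigree.

Summary statistics mirror the standard presentation of such designs:
per-sample inherited fractions of relative abundance and of ASV richness
(`sampleInheritedSummary()`), the partition of inherited ASVs by the exact
pedigree combination they were inherited in (`pedigreeSharing()`), pairwise
inherited-genus overlap |G~i~ ∩ G~j~| / mean(|G~i~|, |G~j~|)
(`genusOverlap()`), and founder-to-offspring retention
(`founderRetention()`). ASVs with an unresolved genus are grouped as
`unclassified_<lowest resolved rank>` so genus-level partitions stay
exhaustive and disjoint.

## The abundance-driven null model

Does abundance alone explain inheritance? The null model draws, for each
pedigree, the same *number* of ASVs as were observed to be inherited, from
the ASVs detected in that pedigree's maternal workers, weighted by their
mean relative abundance there. Draws are sequential weighted sampling
without replacement (selection probability proportional to weight,
renormalized after each pick); inherited sets contain no duplicates, so
draws are sets. One hundred iterations is the default. Genus richness per
draw gives the null distribution for "how many genera would be inherited if
only abundance mattered" (`genusRichnessTest()`).

P-values follow the manual proportion convention: the fraction of null
iterations at or beyond the observed value on its side, with ties counted
toward the tail (conservative). With 100 iterations the smallest raw p is
0.01 and an observed value outside the whole null range gives exactly 0;
the add-one correction (count + 1)/(n + 1) is reported alongside and never
returns 0. Both are always in the output so the reader can choose.

## Within-genus abundance and transmission

To ask whether an ASV's standing *within its genus* predicts transmission,
abundances are centered by subtracting the genus mean
(`centerWithinGenus()`; per-genus zero sums are a built-in invariant). For
display, centered values pass through the odd, monotone signed-log transform
y(x) = sign(x)·ln(1 + |x|/10⁻⁵); the 10⁻⁵ constant sets where the transform
turns from linear to logarithmic and the natural log is used throughout.

The package tests the association with a stratified permutation test
(`transmissionAssociation()`): the statistic is the mean centered abundance
of transmitted minus non-transmitted ASVs, and the null shuffles
transmission labels *within* (pedigree, genus) strata, which preserves every
stratum's label counts and thereby controls for both grouping factors. A
mixed-effects model is the classical alternative for this question; the
permutation test targets the same hypothesis without distributional
assumptions, at the cost of estimating no variance components. Strata with
a single label class are uninformative and dropped with a warning. Whether
means are compared on raw centered or transformed values is a display
choice; the test can be run on either, and both are written by the
pipeline.

## Inheritance assortativity of co-occurrence networks

Signed ASV association networks (from any inference tool, supplied as an
edge list; ASVs with fewer than 200 reads are removed before network work)
are analysed for *categorical assortativity* of the inheritance label:
with e the edge mixing matrix over label classes and a, b its marginals,
r = (Σᵢeᵢᵢ − Σᵢaᵢbᵢ)/(1 − Σᵢaᵢbᵢ). r = 1 means edges only join same-class
nodes; negative r marks disassortative mixing; when all edges sit in one
class the denominator vanishes and r is reported as undefined rather than
forced. Edges are unweighted in the coefficient by default (a weighted
variant exists but is off), and the positive and negative subnetworks are
analysed separately on the same node set. The null for assortativity reuses
the abundance-driven draws: each null set labels the *fixed* topology, and
the observed r is compared by the same permutation convention (one-sided,
observed-high). Filtering to well-connected nodes (≥ 6 edges) is provided
for display only and never precedes the coefficient.

## What the synthetic generator emulates

`simulatePedigreeDataset()` plants a ground truth to validate the pipeline
end to end: 4 maternal pedigrees sharing one paternal colony; 2 parental
worker, 3 founder (per lineage) and 3 offspring samples per pedigree;
~60 genera with geometric (mean 5) ASVs per genus plus 200 environment-only
ASVs; a heritable subset (25% of each parental community) enriched 3× in
founders; non-heritable parental ASVs dropping out of each founder sample
with probability 0.8; 50 000 reads per sample drawn Dirichlet-multinomial
with concentration 50 × expected proportions. Base abundances are
log-normal (σ = 1.5) — a choice made for realistic steep rank-abundance
curves, not estimated from data — and each parental colony carries a random
70% subset of the ASV pool so pedigrees have partly distinct repertoires.
Pooled-gut samples are simulated as single community draws; pooling is
recorded in metadata only.

The planted presence pattern (heritable ASVs in parental workers, all
founder samples, and ≥ 1 offspring sample) is guaranteed structurally: when
multinomial sampling leaves a planted ASV at zero reads in a required
sample, one read is reallocated from that sample's most abundant ASV,
keeping the sample total exact. Recovery tests therefore measure the
classifier's logic plus the dataset-level read filter — rare planted ASVs
can still fall below 25 dataset-wide reads — not sequencing dropout, which
real data adds on top. The generator likewise does not emulate
contamination, compositional biases of PCR, chimeras, or genuinely shared
environmental pools between tiers; passing recovery tests says the
pipeline's logic is correct under its own model, not that real inference is
error-free.

`simulateSignedNetwork()` provides planted-partition signed graphs
(within-block positive-edge probability vs between-block, independent
negative edges, one edge per pair) for the assortativity stages.

## Numerical and design choices

- **Ties and boundaries.** Both read filters are strict ("fewer than");
  a 25-read ASV survives the 25-read filter. Permutation ties count toward
  the tail. Two-sided p doubles the smaller tail, capped at 1.
- **Degenerate inputs.** Zero-total samples are kept, flagged, and excluded
  from per-sample fractions (reported as NA) rather than dropped. Empty
  sample tiers abort classification with the tier named. Single-class
  networks yield flagged-undefined assortativity.
- **Determinism.** Every stochastic routine takes a seed and restores the
  caller's RNG state; pipeline outputs embed the seed and a config hash.
- **Problem sizes.** The shipped tests run the generator at full default
  size (about 46 samples × 500 ASVs, which simulates in about a second) and
  use reduced variants (2 pedigrees, 10–15 genera, 5–20 k reads) where many
  replicates are needed, e.g. 500-replicate calibration of the permutation
  p-value and 60-seed network null checks.

## Worked example

```{r example}
sim <- simulatePedigreeDataset(simParams(seed = 1))
pe <- filterMinTotalReads(sim$experiment)
calls <- classifyAllPedigrees(pe)
recoverPlantedTruth(calls, sim$truth)[c("precision", "recall")]

res <- genusRichnessTest(pe, subset(calls, pedigree == "red" &
                                        lineage == "maternal"),
                         "red", iterations = 100, seed = 1)
c(observed = res$observed_genera, p_raw = res$p_raw,
  p_add_one = res$p_add_one)
```

## Known limitations

Paternal inheritance is classified by the same rule as maternal; if
paternal colonies were sampled later than the cross (as in the motivating
design), paternal calls underestimate transmission — the package reports
this caveat in its documentation rather than modelling it. ASVs are treated
as strain proxies; amplicon resolution limits what "same strain" means.
Network inference itself is out of scope: assortativity is only as good as
the supplied edge list.
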