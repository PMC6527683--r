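---
title: "Scoring GWAS loci per cell type and testing risk-network connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring GWAS loci per cell type and testing risk-network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prenet)
library(data.table)
```

## The model

Association regions rarely identify the causal gene, and regulatory
variants act cell-specifically. `prenet` turns a regulatory-feature
catalogue — rows linking a SNP to a feature (promoter, enhancer, TFBS,
histone mark, DHS, ...) targeting a gene in a source cell type — into a
per-cell prioritization score and a network-level test of whether the
prioritized genes hang together in the interactome.

Heterogeneous source cell labels are collapsed into buckets (B cells,
T cells, monocytes, CNS, optionally T-helper subsets and a lung control);
cancer lines are excluded. Feature labels are collapsed into three classes:
activating (PEX, weight +1), repressive (R, weight −1) and inert (ZQI,
weight 0). Each feature contributes its supporting experiment count,
normalized by the bucket's total experiment count so that heavily assayed
cell types are not automatically favoured. Summing the signed, normalized
weights over a region's SNPs (leads plus LD proxies at a configurable
r² cutoff; 0.5 is the default, 0.1 and 0.8 are the sensitivity settings)
gives the predicted regulatory effect PRE(gene, region, bucket). Scores are
linear in the risk-allele dosage: population mode fixes every dosage at 1,
individual mode uses the subject's 0–2 counts, and the two coincide exactly
at all-ones dosage — a property the test suite asserts.

Three modelling consequences are worth spelling out. First, scaling every
experiment count in a bucket by a constant leaves its scores unchanged, so
only the *relative* weight of evidence within a bucket matters. Second,
swapping activating and repressive classes negates every score — the score
is a signed balance of evidence, not a magnitude of annotation. Third,
scores are additive over any partition of the catalogue rows once the
bucket totals are held fixed, which is what makes the per-subject
computation a single sparse matrix product (`cohort_pre()`).

## Choices where the design was open

* **Normalization denominator.** Bucket totals count inert (ZQI)
  experiments, because the denominator represents experiments *conducted*,
  not signed evidence; `bucket_totals(include_zqi = FALSE)` provides the
  alternative.
* **eQTL evidence** enters as single-experiment pseudo-features signed by
  the direction of the risk-allele effect, counted in the totals — the
  minimal embedding consistent with treating eQTLs as one more line of
  regulatory evidence. It is switched off by omitting the eQTL table.
* **Feature-class map.** The shipped `default_class_map()` assigns
  promoters, enhancers, TFBS/protein binding, open chromatin and activating
  histone marks to PEX, repressive marks and quiescent states to R, and
  everything unrecognized to ZQI (lenient mode) — i.e. unknown annotation
  carries zero weight rather than a guessed sign. Strict mode turns unknown
  labels into errors. Both maps are plain YAML/JSON and fully overridable.
* **Missing genotypes** impute to dosage 1 (the population value) with a
  logged count, so a sparsely genotyped subject is pulled toward the
  population score rather than silently deflated; a zero policy is
  selectable.
* **Percentiles** use linear interpolation (R type 7), and selection is
  strictly greater than both the cutoff and zero, so ties at the cutoff are
  excluded deterministically and a constant score vector selects nothing.
* **LCC tie-breaks**: equal-size components are ordered by edge count, then
  by lexicographically smallest member set, so reports are identical across
  platforms.
* **Null model**: node sets are drawn uniformly without replacement from
  the *cell-specific* interactome — size-matched, not degree-matched,
  matching the plain reading of "random networks of equal size". A
  degree-decile-matched sampler is available behind
  `degree_matched = TRUE` as a robustness check; for high-degree
  selections it yields denser nulls and therefore more conservative
  p-values. Sampling from the unfiltered interactome instead is a
  one-line change (pass the global graph).
* **Empirical p** uses the add-one estimator `(r + 1) / (R + 1)`: it never
  returns zero, and augmenting a null with the observed value itself can
  only make the result less significant.
* **Case–control test**: one-sided Mann–Whitney U (normal approximation,
  tie-corrected) of the directional hypothesis that cases' risk networks
  are more connected; connectivity distributions are skewed counts, so a
  rank test is preferred over a t-test.
* **Subject percentiles** use the `100 × #{≤ value} / n` convention: the
  top subject is the 100th percentile and ties share the higher rank.
* **Median-of-ratios size factors** are the arithmetic median of
  count/reference ratios, the reference being the genewise geometric mean
  over genes with all-positive counts. For an odd number of reference
  genes this coincides with the log-scale median used by DESeq2 (the test
  suite cross-checks against `DESeq2::estimateSizeFactorsForMatrix`); for
  even counts the two interpolation conventions differ slightly. Bucket
  expression is the mean of normalized counts over the bucket's samples;
  an optional `log2(x + 1)` transform is off by default.
* **Correlation significance** permutes the gene labels of the expression
  vector and is two-sided on |r|.

## What the synthetic generator emulates

`sim_config()` defines a complete, self-contained study: tiered effect
lists (GW/SR/NR) over 20 regions tiling 200 genes, five SNPs per region
with uniform-r² proxies, a feature catalogue with Poisson feature counts
and geometric experiment counts (heavy-tailed, like public catalogues), a
cell-bucket map including an excluded cancer line, an interactome, a
genotyped cohort and cell-sorted expression counts. Signal is planted four
ways, each parameterized:

* causal genes (15% of the universe) receive activating features at 10×
  the background rate, in one signal bucket and the GW tier only;
* 30 causal genes form a module at 5× the background edge density
  (p = 0.05) in the interactome;
* cases' risk-allele frequencies are shifted by +0.15 at causal-region
  SNPs (200 cases, 50 controls);
* negative-binomial expression means increase with the *same bucket's*
  population score (dispersion from `expression_noise_sd`, per-sample
  library factors), so matched score/expression pairs correlate and
  mismatched pairs do not.

By default the interactome's node set *is* the scored gene universe. This
is a deliberate calibration choice: selections are always subsets of scored
genes, so if the interactome also contained unscored proteins, a
score-based selection in a bucket *without* planted signal would still
over-represent the dense planted module relative to uniform draws from the
whole graph, and the no-signal buckets would appear spuriously enriched.
With the pools aligned, a no-signal selection is exchangeable with a
uniform draw and its empirical p is uniform. In real data the analogous
bias exists in principle but is negligible because the disease module is a
tiny fraction of a 15,000-node interactome; at simulation scale (hundreds
of nodes) it is not, which is why the default aligns the universes.
`ppi_nodes` above `n_genes` re-introduces anonymous proteins for users who
want to study exactly that distortion.

What the generator does **not** emulate: realistic LD block structure
(proxies are independent draws per lead), genomic coordinates, allele
frequency spectra, linkage between regions, population structure, or
expression covariance between genes. Passing tests therefore demonstrate
that the statistical machinery recovers planted signal of the assumed
form at realistic effect sizes — not that any particular biological claim
holds in real data.

## Numerical and scale choices

Subnetwork metrics use an indexed edge representation with membership
masking and union-find components, so a 10,000-draw null on a
few-hundred-node interactome takes about a second and the full
tier × r² × percentile sensitivity grid (27 combinations × buckets) runs in
seconds at simulation scale; the same path handles a 455,000-edge
interactome at tens of draws per second. The test suite runs the heavy
statistical checks at the defaults the generator defines: 100 generator
seeds for the planted-signal and correlation-recovery checks (1,000 null
draws each), 500 calibration trials at 500 draws, 2,000 draws for the
closed-form edge-count check, and a 250-subject cohort for the
case–control power check — about three and a half minutes in total.
Degenerate inputs are defined, not special-cased: empty selections give
zeroed, ineligible metrics; all-zero score vectors select nothing;
single-sample count matrices get size factor 1; a catalogue with no
all-positive gene is an error that names the pseudocount escape hatch.

## Known limitations

The scoring treats every LD proxy as carrying the full association signal
(no fine-mapping weights), treats feature experiment counts as independent
evidence, and sums signed evidence linearly — three simplifications
inherited from the score's definition. The uniform null ignores degree
structure; the degree-matched flag exists precisely because hub-heavy
selections can be significant under the uniform null for topological
reasons alone. Individual scores are linear in dosage, so dominance and
epistasis are out of scope, as are imputation of genotypes, ancestry
adjustment and polygenic-score construction.
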