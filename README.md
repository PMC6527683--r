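# prenet

Cell-specific regulatory scoring of GWAS loci and risk-network inference.

A genome-wide association study ends with a list of associated regions, but
not with the genes the risk variants act on, nor the cell types they act in.
`prenet` addresses that gap for any trait with dense regulatory annotation:
it scores every gene under every associated region in every cell type from
SNP-linked regulatory evidence, asks whether the high-scoring genes of a
cell type form an unexpectedly connected module in the protein interactome,
recomputes the same quantities per genotyped individual, and validates the
scores against cell-sorted expression. It is aimed at statistical
geneticists and systems biologists who have association summary lists, a
regulatory-feature catalogue (e.g. a RegulomeDB-style export), an
interactome, and optionally cohort genotypes and RNA-seq counts.

## The score

Each catalogue row links a SNP *s* to a regulatory feature *f* targeting
gene *g* in cell bucket *b*, with a class (PEX = promoter/enhancer/
transcription-activating, R = repressive, ZQI = inert) and an experiment
count *n(f)*. The feature's weighted weight is

    ww(f) = sign(class) * n(f) / N(b),      sign = +1 (PEX), -1 (R), 0 (ZQI)

where *N(b)* is the total experiment count of bucket *b* — the
normalization that removes bias against well-studied cell types. The
predicted regulatory effect of gene *g* in region *r* and bucket *b* is the
dosage-weighted sum over the region's SNPs (leads plus LD proxies at
r² ≥ 0.5 by default) and their features:

    PRE(g, r, b) = sum_{s in r} d(s) * sum_{f: s -> g, b} ww(f)

with *d(s) = 1* at population level and *d(s)* = the subject's risk-allele
count (0–2) in individual mode. A positive PRE means the associated region
is predicted to activate the gene's transcription in that cell type;
negative means repression.

Per cell type, genes with PRE above a percentile threshold (25th by
default) and above zero are projected onto an expression-filtered
interactome; the node, edge and largest-connected-component (LCC) counts of
their subnetwork are compared with those of 10,000 random node sets of the
same size, giving add-one empirical p-values (Phipson–Smyth). LCCs of 15
nodes or fewer are flagged ineligible.

## Worked example

The package ships a generator that emulates every input with planted
signal, so the whole pipeline runs without downloads:

```r
library(prenet)
library(data.table)

cfg <- sim_config(seed = 3)            # planted signal in bucket "T"
sim <- simulate_catalogue(cfg)
cat_cl <- classify_catalogue(sim$catalogue, sim$class_map, sim$bucket_map)
#> catalogue: dropped 5 row(s) from excluded cells

region_snps <- expand_ld(sim$effects$GW, sim$proxies$GW, r2_min = 0.5)
pre <- compute_pre(region_snps, cat_cl)
gene_pre <- aggregate_gene_pre(pre)
head(gene_pre, 3)
#>      gene bucket           pre
#> 1:   g001      B -0.0002389486
#> 2:   g001      M  0.0006599208
#> 3:   g001      T  0.0004047764

ppi <- simulate_ppi(cfg)
ci <- filter_interactome(ppi, igraph::V(ppi)$name, "T")
gb <- gene_pre[bucket == "T"]
sel <- select_high_pre(setNames(gb$pre, gb$gene), q = 25)
enrich_test(ci, sel, reps = 10000, seed = 3)
#> <network_metrics> bucket T: 93/93 selected genes in graph, 284 edges
#>   LCC: 93 nodes, 284 edges
#>   empirical p (reps = 10000): edges 0.0007, LCC nodes 0.598, LCC edges 0.0007
```

The 93 genes selected in the signal bucket carry 284 interactions — far
more than random 93-node sets of the same interactome ever reach
(p ≈ 7×10⁻⁴, the add-one floor region), because the generator planted a
dense module among the causal genes. The same selection in a bucket without
planted signal is indistinguishable from random draws. `run_score()`,
`run_enrich()`, `run_individual()`, `run_validate()` and `run_grid()` wrap
these steps with file input/output and run manifests, and

```sh
Rscript inst/scripts/prenet.R simulate --out demo_in --seed 3
Rscript inst/scripts/prenet.R enrich --in demo_in --out demo_out --seed 3
```

drives the same stages from a shell.

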