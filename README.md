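# gcnet — genetic correlation networks from metagenome gene abundances

Shotgun metagenomes give relative abundances of thousands of functional
genes across samples. Genes that act in the same pathway or respond to the
same drivers co-vary across sites, so the gene-by-gene correlation
structure carries a map of the community's functional organisation: modules
of co-varying genes, hub genes that anchor them, a hierarchy of modules,
and — through guilt by association — hypotheses for genes whose protein
domains have no known function (DUF genes). `gcnet` implements that
analysis as a tested R package for microbiome researchers who have a
gene × sample abundance table and want a defensible signed co-occurrence
network rather than an ad-hoc correlation cutoff.

## The method

Starting from a genes × samples table of non-negative abundances:

1. **Relative abundance and prevalence filter.** Each sample column is
   scaled to sum 1. A gene present (abundance > 0) in all *n* samples is a
   *core* gene; in at least `min_prevalence` (default 25 of 45) but not all,
   *non-core*; below that it is excluded — sparse genes bias rank
   correlations.
2. **Spearman matrix with FDR.** ρ is the Pearson correlation of average
   ranks; two-sided p-values come from *t* = ρ√((n−2)/(1−ρ²)) on n−2 df,
   and Benjamini–Hochberg adjustment runs over the g(g−1)/2 gene pairs.
3. **Network deconvolution** (α = 1, β = 0.99) inverts the transitive
   closure G_obs = G_dir + G_dir² + … via the eigenvalue map
   λ → γλ/(1+γλ), damping correlations that are explained by indirect
   paths; γ is chosen in closed form so the output spectral radius is β.
4. **Random-matrix-theory threshold.** Candidate cutoffs are scanned; for
   each, the nearest-neighbour spacing distribution (NNSD) of the unfolded
   eigenvalues of the retained matrix is tested by χ² against Poisson
   e^(−s) (uncorrelated levels: modular structure) and the Wigner surmise
   (πs/2)e^(−πs²/4) (GOE: noise-coupled matrix). The chosen threshold is
   the first grid point from which the NNSD is stably Poisson.
5. **Signed network.** Edge (i, j) iff |ρ_ij| > threshold and q_ij < 0.05;
   the sign is the correlation's sign; degree-0 genes are not nodes.
   Topology summaries include density, clustering coefficient, diameter of
   the giant component, the degree distribution's log–log R² power-law fit,
   and a same-size Erdős–Rényi G(n, m) null.
6. **Clusters, hierarchy, hubs, roles.** Multilevel (Louvain) modularity on
   the positive subgraph at resolutions R = 1…15 (larger R merges more;
   internally γ = 1/R). Clusters meeting the size rule are *dominant*; the
   hierarchy links each cluster to the next resolution's cluster holding the
   plurality of its nodes, recording merge events. Each dominant cluster's
   maximum-degree member is its *hub*; nodes with zero between-cluster
   degree are *intra-cluster*, the rest *inter-cluster*. Negative edges are
   summarised by endpoint class (n-n / n-e / e-e) and compared by Wilcoxon
   rank-sum tests.
7. **Function and environment.** Per-cluster category enrichment is a
   hypergeometric upper-tail test with BH control (DUF genes held out of the
   universe). A DUF gene wired firmly into one dominant cluster (kb = 0,
   kw ≥ 3) inherits that cluster's enriched categories as its predicted
   function. Environmental factors are linked to genes by Spearman + FDR
   and tested for concentration within clusters.

A synthetic-data generator (`synthetic_spec()`, `generate_abundance()`,
…) plants all of this structure — modular blocks with one high-loading hub
each, core/non-core prevalence, anti-correlated cluster pairs, nested
sibling clusters, coupled environmental factors, withheld DUF labels — with
exact sample-space geometry, so every stage is verifiable against a known
ground truth without any external data.

## Worked example

The `analysis/` scripts run the whole study on a simulated 500-gene ×
45-sample survey (20 planted clusters, one anti-correlated pair, three
environmental factors):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_network.R
Rscript analysis/03_clusters.R
Rscript analysis/04_functions.R
Rscript analysis/05_report.R
```

which prints, among other things:

```
Prevalence: 276 core, 184 non-core, 40 excluded by the 25-of-45 filter
RMT threshold: 0.61 (Poisson-stable from the NNSD scan)
Network: 309 nodes, 579 edges (565 positive, 14 negative)
Degree distribution: power-law R2 = 0.70 in log-log
Edge partition: 425 core-core, 21 noncore-noncore, 133 bridging
Clusters at R = 1: 48 (18 dominant with >= 10 members, 46 loose nodes)
Hubs: 18 (one per dominant cluster); 17 intra-cluster, 1 inter-cluster
Planted hub recovered in 14/18 dominant clusters
DUF candidates (kb = 0, kw >= 3): 30; top-1 category correct for 30 (100%)
```

Reading: the 40 genes seeded below the prevalence floor are dropped; the
NNSD scan finds the threshold (0.61) at which the matrix decomposes into
modular blocks; the resulting network keeps 309 of 460 filtered genes. The
planted clusters return as the 18 dominant clusters, their planted
high-loading hubs are the detected maximum-degree hubs in 14 of 18, and
every eligible DUF gene's withheld category is recovered from its cluster's
enrichment. The same objects are available programmatically:

```r
library(gcnet)
spec <- synthetic_spec(n_clusters = 6, genes_per_cluster = 20, seed = 1)
sim  <- generate_abundance(spec)
res  <- run_pipeline(pipeline_config(sim$table, min_eigen = 40L, seed = 1))
res$summary$threshold
res$hubs
```

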