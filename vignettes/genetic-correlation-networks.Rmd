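---
title: "Genetic correlation networks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic correlation networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcnet)
```

# The problem and the model

A shotgun metagenome survey yields, for each of *n* samples, the relative
abundance of thousands of annotated genes. Because functionally related
genes respond coherently to the same environmental drivers and community
shifts, their abundance profiles co-vary across samples. `gcnet` turns a
gene × sample table into a *signed genetic correlation network* and mines
that network for functional organisation: modules, hubs, a module
hierarchy, regulatory-looking negative links, and function predictions for
genes annotated only as a domain of unknown function (DUF).

The inference chain is deliberately conservative. Rank (Spearman)
correlation guards against the heavy-tailed, nonlinear abundance scale;
a prevalence filter removes sparse genes whose rank correlations are
dominated by shared absences; network deconvolution strips correlation
that is attributable to indirect paths; and the similarity cutoff is not a
user-chosen constant but is located by a random-matrix-theory criterion.
Only pairs that additionally pass false-discovery-rate control become
edges.

## Spearman correlation and FDR

For genes *x*, *y* over *n* samples, ρ is the Pearson correlation of
average ranks (ties receive average ranks). Two-sided p-values use
*t* = ρ√((n−2)/(1−ρ²)) with n−2 degrees of freedom — accurate at the
survey sizes this package targets (n ≈ 45); for very small n an exact
permutation p-value is available (`p_method = "exact"`). Each unordered
gene pair is one hypothesis: Benjamini–Hochberg runs over the upper
triangle (m = g(g−1)/2), never over the full symmetric matrix. Genes with
constant profiles carry no rank information and are assigned ρ = 0, p = 1.

Because every transform applied to abundances downstream of the generator
is strictly increasing (per-sample scaling, exp), rank correlations are
preserved exactly — this invariance is asserted by tests.

## Prevalence classes

Presence is abundance strictly above `min_abundance` (default 0: any
detection counts; no read-count floor is imposed, and the parameter is
exposed for users whose pipelines need one). With defaults, a gene seen in
all *n* samples is *core*; in `min_prevalence` (25) up to n−1 samples,
*non-core*; below that it is excluded from all network stages. The
thresholds are parameters because the 25-of-45 rule is specific to a
45-sample design.

## Network deconvolution

Observed correlation mixes direct dependence with paths through third
genes: G_obs = G_dir + G_dir² + ⋯ = G_dir(I − G_dir)⁻¹. On the
eigenvalues of the (zero-diagonal, symmetrised) matrix this closure is
λ → λ/(1−λ), so its inverse is applied spectrally:
λ' = γλ/(1+γλ), with γ chosen in closed form,

γ = min(1, β/((1−β)·λ⁺max), β/((1+β)·|λ⁻min|)),

which makes the output spectral radius exactly β (default 0.99) on the
binding side. `alpha` (default 1) optionally keeps only the top fraction
of input entries by magnitude before the transform. Two numerical points:

* The raw eigenvalue map shrinks entry magnitudes far below the
  correlation scale (on a typical 500-gene matrix the largest deconvolved
  entry is ≈ 0.2). The default therefore rescales the output by a single
  positive scalar so its largest off-diagonal magnitude matches the
  input's. A scalar multiple preserves signs and the ranking of
  magnitudes, and puts thresholds back on the familiar correlation scale;
  `rescale = "none"` gives the raw map, whose β-bound and exact-inverse
  properties the tests assert.
* The map runs on the *signed* matrix: sign information is what later
  separates positive (functional association) from negative
  (regulatory-looking) edges.

## The RMT threshold

For each candidate cutoff *s* the retained matrix A (|ρ| ≥ s, zero rows
dropped) is eigendecomposed, degenerate levels are removed, the spectrum is
*unfolded* — a cubic smoothing spline is fit to the empirical cumulative
spectral density and evaluated at the eigenvalues, so the mean local
spacing becomes 1 — and the nearest-neighbour spacing distribution (NNSD)
is tested by χ² (30 equal bins on [0, 3], overflow pooled, bins with
expected count < 1 merged) against two universal laws: Poisson e^(−s),
the signature of superposed independent block spectra, and the Wigner
surmise (πs/2)e^(−πs²/4), the signature of a noise-coupled GOE-like
matrix. Below the right threshold, weak cross-module correlations couple
everything (Wigner); above it, the matrix decomposes into independent
modules (Poisson). The chosen threshold is the smallest grid point whose
Poisson χ² is below the critical value at `test_alpha` = 0.001 and stays
below it for the next `stability_window` (5) computable grid points.

Numerical choices, each of which proved load-bearing:

* *Spline flexibility*: equivalent degrees of freedom ⌈√n⌉ — stiff enough
  to leave level fluctuations intact, flexible enough to track the mean
  density. Calibration is exact on both ensembles: 500×500 GOE matrices
  reject Poisson and pass Wigner, i.i.d.-diagonal spectra pass Poisson, in
  20/20 seeds each.
* *Degeneracy removal* rather than jitter: graph fragments (paths, stars)
  contribute exact-zero eigenvalues; tiny jitter leaves a spike of
  near-zero spacings that spuriously rejects Poisson. Removing duplicate
  levels (tolerance 1e−10) is the behaviour that calibrates.
* *Validity guards*: a threshold is only testable if the retained matrix
  has at least `min_eigen` unique eigenvalues (100 in production, 40 in
  tests — below that the χ² has too few spacings) and mean degree at least
  `min_degree` (2): near-empty graphs have degeneracy-dominated spectra.
* *Windowed stability* instead of "all larger thresholds": the last
  computable grid point before the matrix empties is a dyad-dominated
  remnant whose verdict is noise; letting it veto every candidate made
  selection fail on otherwise clean inputs.

## Edges, topology, and the null

Edge rule: |deconvolved ρ| > threshold AND q < `q_max` (0.05); sign and
weight come from the deconvolved correlation; genes with no edge are not
nodes (the analysis concerns the connected fabric, not the input list).
Topology reports density 2m/(n(n−1)), the mean local clustering
coefficient over nodes of degree ≥ 2 (global transitivity is also
recorded; the mean-local variant is the default report), the diameter of
the largest connected component (the graph need not be connected), and the
degree distribution with its least-squares log–log power-law fit — R² of
log₁₀ freq(k) on log₁₀ k, the classic scale-free diagnostic, with a
maximum-likelihood exponent reported alongside. An Erdős–Rényi G(n, m)
graph with the same node and edge counts provides the binomial-degree
reference. Clustering and diameter treat edges as unsigned and unweighted.

## Clusters, hierarchy, hubs, roles

Cluster detection is multilevel greedy modularity (Louvain) on the
positive-edge, unweighted subgraph — standard modularity is undefined for
signed graphs, so negative edges are set aside for clustering and
reattached for the role and negative-edge analyses. The resolution
convention follows the biological reading that larger R merges more:
internally the null-model multiplier is γ = 1/R, R = 1 being standard
modularity. The heuristic has local optima, especially at coarse
resolutions, so each call runs `n_restarts` (5) seeded restarts and keeps
the best modularity; results are deterministic given the seed.

*Dominant* clusters meet `min_size` (10) — the size rule is a parameter
because "dominant" has no canonical definition; all other nodes are
*loose*. Across resolutions 1–15 the hierarchy links each cluster to the
next level's cluster containing the plurality of its nodes (ties to the
smallest id); two or more children sharing a parent is a merge event.
Cluster counts along the grid are recorded, not forced monotone —
modularity theory does not guarantee nesting.

Per node, kw counts same-cluster edges and kb cross-cluster edges
(kw + kb = degree); kb = 0 makes a node *intra-cluster*, otherwise
*inter-cluster*. The *hub* of a dominant cluster is its maximum-total-
degree member, ties broken by larger kw then lexicographic id; both
degrees are reported since "highest connection number" could be read
either way. Negative connection counts between gene groups are compared
with the Wilcoxon rank-sum test (exact when the pooled sample is ≤ 12 and
tie-free, else the tie-corrected normal approximation) because degree is
far from normal.

## Enrichment, DUF prediction, environment

Cluster function is operationalised as hypergeometric upper-tail
enrichment of category labels with BH control across all
(dominant cluster, category) pairs; the universe is the network's
annotated, non-DUF nodes — DUF labels are the quantity under prediction,
so they are held out of both the counts and the universe. A DUF gene
qualifies for prediction when it sits in a dominant cluster with kb = 0
and kw ≥ `min_within` (3; "firmly wired into one module" needs a cutoff
and the value is exposed). Its prediction is the cluster's enriched
categories ranked by q, with its annotated direct neighbours reported as
the supporting evidence. Environmental factors are correlated against raw
gene abundance profiles (Spearman + BH, `q_max` 0.05), counted per factor,
and tested for hypergeometric concentration of their linked genes within
clusters; no RMT threshold is applied to environment links — only FDR —
since they are bipartite associations, not network edges.

# The synthetic generator

Every planted property is a latent-factor construction: cluster *k* has a
factor f_k over samples; gene *g* in cluster *k* has latent value
z_g = w_g f_k + √(1−w_g²) ε_g with w_g = 0.95 for the hub and 0.8 for
members, so cluster-mate correlation is the loading product (hub–member
0.76 > member–member 0.64) and the hub is the most strongly wired gene.
Abundance is exp(z) — strictly increasing and positive, so planted rank
correlations survive exactly — and absence is imposed afterwards by
zeroing randomly chosen samples of non-core genes (zero = not detected),
matching detection semantics in a metagenome. Non-core presence counts are
uniform on [25, 44]; excluded genes get presence below 25.

Two design choices deserve emphasis:

* **Exact sample geometry.** Factors are built from exactly orthonormalised
  centred sample vectors: unrelated factors have sample correlation exactly
  0, nested children correlate with their parent at exactly the parent
  loading, anti-paired factors at exactly −√(1−0.1²) ≈ −0.995. At n = 45
  an i.i.d. construction leaves the *realised* factor correlation with a
  standard error of ~0.12–0.15, which makes planted cross-cluster structure
  unrecoverable or spurious depending on the seed — the planted truth would
  not be true of the sample the pipeline actually sees. With exact
  geometry, the only stochastic blur on planted correlations is gene-level
  noise, which averages out over gene pairs.
* **Compositional closure is real.** Per-sample normalisation induces
  negative correlation between large co-varying gene groups. The generator
  does not remove this (it is a property of relative abundance data);
  fixtures that probe cross-cluster structure therefore include enough
  background genes to dilute the effect, or work on unnormalised
  abundances when the property under test is the planted rank structure
  itself.

What the generator does *not* emulate: read sampling noise, assembly and
annotation error, compositional count totals (library sizes), taxonomic
structure, or spatial autocorrelation among sites. Passing tests therefore
demonstrate that the pipeline recovers structure of the kind it models —
latent-factor modules under monotone transforms and detection masking —
not that it is robust to every artefact of real metagenome processing.

# Test fixtures and study conditions

The dedicated fixtures fix geometry where the recovery property needs a
specific regime:

* *Threshold recovery*: 8 blocks × 20 genes, within-band |ρ| ~ U(0.85,
  0.95), noise band U(0.15, 0.35). Eight superposed block spectra give a
  clean Poisson NNSD above the noise band; below it the bands couple into
  one GOE-like matrix.
* *Hub / negative / DUF recovery*: raw-Spearman networks at fixed
  thresholds inside the planted-loading gap (0.6–0.7), all-core genes.
  These isolate loading→degree monotonicity and edge-sign logic from
  deconvolution artefacts (clique saturation equalises degrees; the
  eigenvalue map can manufacture strong negative entries) — stages that
  have their own oracles.
* *Hierarchy*: 4 sibling clusters × 15 genes under 2 parents at loading
  0.8, threshold 0.52, resolutions {1, 15}: siblings separate at R = 1 and
  merge pairwise at R = 15.
* *Partition recovery*: the classic 4 × 25 planted partition at p_in 0.5,
  p_out 0.02, the standard exactly-recoverable regime.

The flagship analysis (`analysis/`) runs 500 genes × 45 samples — 20
clusters of 20 genes, 60 background, 40 seeded below the prevalence floor —
through the full pipeline in a few seconds on one CPU; the test suite and
the acceptance script together stay within a few minutes.

# Degenerate inputs and tie-breaks

Constant genes: ρ = 0, p = 1. All-zero sample columns: error (relative
abundance undefined). Fewer than 4 samples: error. Graphs with no
qualifying edges: an empty network is legal; clustering of an empty graph
is an error. Runs whose clusters all fall below `min_size` skip the hub,
enrichment and prediction stages rather than fail. Hierarchy plurality
ties break to the smallest parent id; hub ties to larger kw then
lexicographic id; all stochastic stages derive per-stage sub-seeds from
the single run seed, so identical configurations reproduce byte-identical
artifacts.

# Known limitations

* The RMT criterion needs enough genes: below ~100 retained genes
  (`min_eigen`) the NNSD test is underpowered, and on small studies a
  fixed threshold (`threshold =`) is the honest alternative.
* At the conservative RMT cutoff the dominant clusters are typically
  disconnected components; modularity never merges disconnected clusters,
  so the hierarchy over resolutions is flat there. Hierarchical structure
  is visible at denser fixed thresholds — the resolution sweep is about
  coarse-graining a connected fabric, not a cure for a fragmented one.
* Printed node/edge bookkeeping in this package is conservation-exact by
  construction (sign counts, edge partitions, role handshakes and
  dominant/loose splits always sum); published tallies from comparable
  field studies do not always satisfy such identities, so cross-study
  comparisons should compare definitions before numbers.
* Spearman on zero-inflated non-core genes conflates co-detection with
  co-abundance; the prevalence filter bounds but does not remove this.
  Negative edges between non-core genes partly reflect disjoint detection
  patterns — biologically interpretable, but not regulation per se.
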