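---
title: "Methods: models, parameters and design choices in degnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in degnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degnet)
```

degnet implements the analysis chain typically applied to small case-control
bulk RNA-seq cohorts — for instance iPSC-derived neuronal cultures with four
affected and four control donors — and carries it through to the
protein-interaction-network and qPCR validation layers. This vignette is the
package's own account of the statistical machinery, the tunable parameters,
and the choices made where the design was genuinely open.

## Differential expression

### Model

Counts for gene $i$ in sample $j$ are modelled as negative binomial with
mean $s_j q_i$ and dispersion $\alpha_i$, parameterised so that

$$\mathrm{Var}(K_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2 .$$

The size factors $s_j$ are estimated by the median-of-ratios rule: over the
genes with strictly positive counts in every sample, $s_j$ is the median of
$k_{ij} / (\prod_{j'} k_{ij'})^{1/n}$, rescaled so the factors have geometric
mean one. The rescaling convention is cosmetic (only ratios of size factors
matter downstream) but makes normalized counts comparable across runs.

### Dispersion

With four samples per group, per-gene variance estimates are extremely
noisy. `estimate_dispersions()` therefore combines a per-gene
method-of-moments estimate (on normalized counts, with within-group pooling
so real group differences do not inflate the variance) with a parametric
mean-dispersion trend $\alpha(q) = a_0 + a_1/q$ fitted across genes by least
squares, and assigns each gene the **maximum** of its own estimate and the
trend value. The maximum rule deliberately over- rather than under-states
dispersion: with $n = 4$ per group the cost of an understated $\alpha$ is
anticonservative p-values, which the rule prevents. The floor
`alpha_floor = 1e-8` only guards against degenerate (e.g. constant) genes.

### Exact test

`nb_exact_test()` conditions on the total $S = k_A + k_B$ of the two group
sums and computes

$$p = \frac{\sum_{a:\, f(a) \le f(k_A)} f(a)}{\sum_{a=0}^{S} f(a)}, \qquad
  f(a) = \mathrm{NB}(a;\mu_A,\mathrm{size}_A)\,
         \mathrm{NB}(S-a;\mu_B,\mathrm{size}_B),$$

a two-sided test by probability ordering. Group-sum moments derive from the
pooled mean $\hat q = S/\sum_j s_j$ and the gene's dispersion:
$\mu_g = \hat q \sum_{j \in g} s_j$ and
$\mathrm{size}_g = (\sum_{j\in g} s_j)^2 / (\alpha \sum_{j\in g} s_j^2)$.
Because the partition sum is finite there is no tail-truncation error; ties
in $f$ are included with a $1 + 10^{-7}$ relative tolerance so floating-point
noise cannot split a tied partition. $S = 0$ carries no information and
returns $p = 1$.

Benjamini–Hochberg adjustment is implemented as the literal step-up rule and
cross-checked in the tests against both an independent sort-based oracle and
`p.adjust`.

### DEG selection and accounting

`select_degs()` applies the joint filter $|\log_2 \mathrm{FC}| \ge \log_2
f_{\min}$ and $p \le p_{\max}$. Fold changes are computed on normalized group
means with a pseudocount of 1 added to both means, so genes silent in one
group stay defined and finite. The significance column defaults to the raw
p-value — selections quoted as "$P < 0.05$" / "$P < 0.01$" tiers use raw
p-values — with the BH-adjusted column available via `p_column = "adj"`;
both are always reported in the result table, so either convention can be
audited. `partition_locus_groups()` tallies a selection over the four
biotype groups (protein-coding, ncRNA, pseudogene, other); genes missing
from the annotation are counted as "other" and logged rather than dropped.

## Clustering and PCA

Sample structure is assessed on $\log_2(\text{normalized count} + 1)$
values: pairwise Euclidean distances, average-linkage agglomerative
clustering, and column-centered two-component PCA. The log transform and
average linkage are conventional choices for count heatmaps; neither is
forced by the method, so both are isolated behind `transform_counts()` and
`hierarchical_cluster()` where they can be swapped. PCA signs follow the
largest-magnitude-loading-positive convention so plots are reproducible
across platforms.

## The DEG-seeded interaction network

`build_pin()` forms the subnetwork of a reference interactome induced by the
seed genes (typically the protein-coding DEGs mapped by symbol) together
with their first-degree interactors; the edge set is the full induced edge
set, not just seed-incident edges. Seeds absent from the interactome are
dropped and counted — `mapped_seed_fraction()` reports the mapping rate.
Identifier mapping is by uppercased gene symbol through the annotation
table: curated interaction databases are symbol-keyed while count matrices
are usually Ensembl-keyed, and a supplied mapping table is the only
reproducible bridge between the two.

The null model asks whether the observed seed set is more densely
interconnected than an arbitrary gene set of the same size:
`sample_random_pins()` draws seed sets uniformly from the interactome's
nodes (not from the full annotation universe, matching how the observed PIN
itself is built from mapped seeds only) and expands each the same way. Two
comparison surfaces are reported, because "the distribution of the
structural properties" admits both readings:

* two-sample Kolmogorov–Smirnov tests of the observed shortest-path-length
  and degree multisets against the pooled null multisets (these mirror
  published $D$ statistics for density/connectivity-type comparisons), and
* one-sided add-one empirical p-values for the scalar density (null $\ge$
  observed) and average shortest path length (null $\le$ observed),
  $p = (1 + \#\{\text{null at least as extreme}\})/(R + 1)$, which cannot be
  exactly zero at finite $R$.

ASPL is computed on the largest connected component (the component count is
reported alongside); path-length multisets are pooled as histograms so a
1000-replicate ensemble does not materialize tens of millions of values. No
degree-matched null is provided: the uniform-seed null is the stated
reference model, and degree matching would answer a different question.

## Enrichment

`fisher_enrichment()` is one-sided hypergeometric over-representation per
term with Bonferroni correction over the tested terms ($p_{\text{bonf}} =
\min(1, m p)$, significance at $p_{\text{bonf}} < 0.01$ by default). The
natural query for a network-level analysis is the PIN membership, with the
interactome's node set as universe — that is the pipeline default; an
annotation-wide universe is available by config. Depletion is intentionally
out of scope.

## qPCR quantification

`delta_ct()` averages technical replicates (arithmetic mean of Ct) before
subtracting the per-sample reference Ct; `ddct_fold_change()` uses
group-mean calibration, $\Delta\Delta C_t = \overline{\Delta C_t}_{case} -
\overline{\Delta C_t}_{control}$ and fold $= 2^{-\Delta\Delta C_t}$, the
appropriate form for unpaired cohort designs. Group comparison is a
two-sided pooled-variance Student's t-test (Welch via `var_equal = FALSE`).
Volcano calls require both a 2-fold change and $P < 0.05$ by default. No
amplification-efficiency correction is applied; the method assumes exact
doubling per cycle.

## What the synthetic data emulate — and what they do not

The generators exist so that every downstream stage can be exercised against
known truth:

* `simulate_counts()` draws NB counts with log-normal baseline means
  (`meanlog = 3.5`, `sdlog = 1.5`, i.e. a median of ~33 normalized counts
  with a realistic dynamic range), constant dispersion `0.1` (a typical
  bulk RNA-seq value), log-normal library-size factors (`sdlog = 0.25`),
  and planted effects of $|\log_2 FC| = 2$ in `de_fraction = 0.015` of
  genes, split evenly up/down and symmetrically about the baseline. The
  default shape — 25,000 genes, 4 vs 4 — mirrors the cohort design this
  pipeline targets; the planted fraction matches the few-hundred-DEG
  outcome such cohorts produce.
* `simulate_interactome()` uses preferential attachment (`attach_m = 2`)
  for a heavy-tailed degree distribution, with an optional planted module
  that adds each within-member edge with a stated probability. Module
  members must be drawn at random from the node set: planting on the
  earliest nodes of a preferential-attachment graph would plant on its
  hubs and confound the density comparison.
* `simulate_qpcr()` inverts the $2^{-\Delta\Delta C_t}$ model exactly at
  zero noise, which gives the quantification an exactness check.

Real data differ in ways the generators do not attempt: mean-dependent
dispersion trends, correlated genes, batch effects, zero inflation,
interactome ascertainment bias, and qPCR efficiency drift. Passing the
simulation-based tests therefore demonstrates correctness of the
implementation under its own model assumptions, not robustness to every
real-data pathology.

## Problem sizes and fixed parameters in the validation suite

The test suite and acceptance script use: 2,000-gene 4 vs 4 simulations for
type-I error and recovery (type-I error is required to be approximately
nominal and never anticonservative — the conservative dispersion rule
places it slightly below 0.05); a 1,000-node interactome with a 30-member
planted module at edge probability 0.3 and $R = 200$ null replicates for
topology power and calibration; and a 20,000-gene, 4,000-node end-to-end
run. These sizes were chosen as the smallest at which each statistical
property is stable across seeds.

## Known limitations

* The exact test is the classic per-gene NB conditional test; no GLM
  shrinkage estimators are provided, so complex designs (covariates,
  paired samples) are out of scope.
* Empirical topology p-values are bounded below by $1/(R+1)$; claims
  stronger than $p < 0.005$ need a larger ensemble.
* Symbol-based seed mapping silently merges genes that share a symbol
  across annotation releases; the mapped/unmapped accounting makes the
  loss visible but cannot repair it.
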