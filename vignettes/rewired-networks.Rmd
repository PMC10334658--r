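---
title: "Differential co-occurrence networks for multi-study microbiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-occurrence networks for multi-study microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microrewire)
```

## The problem

Case-control microbiome studies usually ask which taxa change in abundance
between disease and health. That question misses a second, complementary
signal: taxa whose *relationships* to the rest of the community change even
though their own abundance does not. `microrewire` implements an integrative
pipeline for exactly this comparison on lung (or any body-site) microbiome
data: multiple 16S cohorts are merged on their shared taxa, standard
diversity and differential-abundance screens are run, and the core analysis
builds one Pearson co-occurrence network per condition and classifies every
edge of their symmetric difference as

* **gained** — statistically significant only in the disease (case) state;
* **lost** — significant only in the healthy (control) state;
* **changed direction** — significant in both states with opposite
  correlation signs.

The per-node count of such rewired edges (the *rewiring degree*), together
with degree, betweenness, closeness, clustering coefficient and neighborhood
connectivity on the rewired graph, identifies hub taxa that a pure
differential-abundance analysis would overlook.

## Pipeline stages and their models

### Feature tables

The universal currency is a taxa x samples `feature_table` carrying
taxonomy lineages and per-sample metadata (`dataset`, `group` in
case/control). Counts are collapsed to a rank by summing across identical
lineage prefixes; taxa unassigned at that rank are pooled under a single
`unclassified` label so per-sample totals are conserved exactly
(`drop_unclassified = TRUE` removes them instead). Counts become
compositions with `to_relative()`. Multi-study integration restricts the
tables to the intersection of their taxon sets and concatenates the
samples; following common practice for merged relative-frequency tables the
restricted columns are **not** renormalized by default — the measured
proportions are kept — and `renormalize = TRUE` is available because the
right choice is genuinely ambiguous. Alpha diversity internally normalizes
its columns by their sums, so both conventions give consistent indices.

### Diversity

Alpha diversity per sample: observed richness, Shannon entropy
$H = -\sum_i p_i \ln p_i$ (natural log by default, configurable base), and
the Gini-Simpson index $D = 1 - \sum_i p_i^2$ (bounded in $[0,1]$; the
inverse form is a flag). Group differences are tested with the Wilcoxon
rank-sum test. Beta diversity uses Bray-Curtis dissimilarity
$BC_{jk} = \sum_i |x_{ij} - x_{ik}| / \sum_i (x_{ij} + x_{ik})$, ordinated
by principal coordinates (classical MDS; negative eigenvalues are reported
but excluded from coordinates, with no Lingoes/Cailliez correction), tested
globally with PERMANOVA (999 permutations by default; a seed is mandatory)
and checked for variance homogeneity with beta-dispersion (distance to the
group centroid in PCoA space, ANOVA on those distances). The centroid
variant was chosen over the spatial median; both appear in the literature
and the choice is declared, not inferred.

### Differential abundance

Each taxon is screened with Shapiro-Wilk (reported only — the group test is
rank-based regardless) and tested with the Wilcoxon rank-sum test, exact by
enumeration when $n_1 + n_2 \le 12$ without ties, otherwise the normal
approximation with midranks, tie correction and continuity correction. One
Benjamini-Hochberg family is formed per taxonomic level (cross-level
pooling was rejected: published per-level tables adjust within level), and
significance is called at $q < 0.05$. Zero-inflated taxa are tested as-is;
`min_prevalence` offers an optional filter.

### Taxon modules

DBSCAN clusters *taxa* (not samples): each taxon is a point whose
coordinates are its relative abundances across all samples, under Euclidean
distance. Defaults: `min_pts = 4`, profiles unscaled, and
`eps = "auto"` from the $(min\_pts - 1)$-nearest-neighbor distance profile.
The knee is defined as the largest log-scale jump between consecutive
sorted k-NN distances, taking the value on the dense side of the jump:
chord-based knee detection fails on abundance profiles because the sparse
regime rises smoothly over orders of magnitude rather than stepping. Module
labels are letters in discovery order; border points join the first cluster
that reaches them, with points processed in fixed row order, so runs are
deterministic. Since eps, minPts and scaling are unpublished for the
reference analyses, all three are explicit configuration.

### Co-occurrence and differential networks

Within each condition (datasets pooled), every unordered taxon pair is
tested by Pearson correlation of relative abundances,
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ against Student-t with $n-2$ df.
Condition-constant taxa are excluded with a notice. Edge "existence" is the
significance flag — no magnitude cutoff — and non-significant correlations
are retained in storage but treated as absent downstream (the
"non-significant correlations set to zero" convention). Two significance
modes exist: raw $p < \alpha$ (default $\alpha = 0.05$; matches the dense
edge counts typical of published co-occurrence networks) and `adjust =
"BH"`, one FDR family over all pairs at the level. Changed-direction
requires significance in **both** conditions: a sign flip of a
non-significant correlation is noise. This reading resolves a genuine
ambiguity in how rewiring classes are usually defined and is asserted in
the test suite's truth table. Hub calls use the published degree cutoffs:
$\ge 4$ at phylum level, $> 15$ at genus level; the family level has no
published cutoff and requires explicit configuration.

Centralities (degree, betweenness, closeness, local clustering,
neighborhood connectivity) are computed on the rewired graph with all edge
classes treated as plain undirected edges, using Cytoscape's conventions:
betweenness normalized by $(n-1)(n-2)/2$ and closeness component-local,
$C(v) = |R(v)| / \sum_{u \in R(v)} d(v,u)$ — published closeness values
above 0.5 on sparse differential networks are only consistent with the
component-local form. Shortest paths are unweighted; edge classes carry no
length.

## The synthetic generator

`make_paper_like_spec()` + `simulate_microbiome()` emulate the integrated
study design so that every downstream stage can be validated against known
ground truth. The generative family is logistic-normal/multinomial: per
sample, a latent Gaussian $z \sim N(\mu_g, D\Sigma_g D)$ is pushed through
a softmax and counts are drawn multinomially at a depth sampled
log-uniformly within the dataset's range. A Dirichlet-multinomial was
rejected because it cannot plant arbitrary signed pairwise correlation —
and signed, condition-specific correlation is precisely what gained / lost
/ changed-direction ground truth requires.

Defaults (chosen once, fixed):

* **Design**: four datasets with case/control sizes 245/231, 50/207, 27/26,
  25/24 (totals 347/488 at `scale = 1`), scaled and rounded per dataset;
  64 genera; per-dataset depth ranges log-uniform around $5 \times 10^4$.
* **Differential taxa**: 8 taxa depleted in cases by 1.0 latent log-units.
  The depletion direction mirrors the reduced alpha diversity expected in
  tumor tissue, and matters technically: an *enriched* taxon acquires a
  large compositional footprint in one condition and genuinely rewires the
  observed composition, contaminating the edge ground truth.
* **Condition-specific edges**: 10 case-only and 10 control-only pairs at
  latent $|r| = 0.8$ with alternating signs, plus 2 changed-direction pairs
  ($+0.8$ in case, $-0.8$ in control), all on disjoint taxon pairs so the
  latent correlation matrices stay block-diagonal and positive definite.
* **Modules**: four 4-taxon blocks at evenly spaced low-abundance latent
  means (levels $-0.5$ to $-2$), log-SD 0.3, within-module latent
  correlation 0.98 in *both* conditions. Three constraints force this
  design. Module mates must be near-coincident in Euclidean profile space;
  in a logistic-normal that tightness cannot come from a small log-SD
  alone, because every log-share carries the shared $-\log Z$ closure term
  (standard deviation ~0.05-0.08 here), which would dominate a quieter
  taxon and correlate it with everything. Tightness therefore comes from
  near-unit correlation. Planting that correlation in both conditions makes
  module pairs stable same-sign edges that never enter the rewired classes.
  And placing modules at low abundance keeps their collective co-movement
  from leaving a softmax footprint that would induce spurious cross-module
  correlation near the significance boundary.
* **Everything else**: baseline latent means $N(0, 0.5^2)$ and log-SD 0.5,
  a narrow band in which no taxon dominates the composition, closure-induced
  correlations stay far below detectability, and share distributions are
  light-tailed enough that the Pearson t reference stays calibrated in its
  far tail.

Per-dataset RNG streams derive from the master seed by fixed offsets
(`seed + 1009 * dataset_index`), so partial regeneration is reproducible.

What the generator deliberately does **not** emulate: sequencing error,
chimeras, taxonomy misassignment, batch effects beyond depth heterogeneity,
and within-condition mean differences between datasets. Passing recovery
tests therefore demonstrates that the pipeline's inference machinery is
correct and calibrated on data satisfying its assumptions — not that real
tissue microbiome data satisfy those assumptions.

## Validation design and problem sizes

The test suite validates three layers, at sizes chosen to keep the full run
in tens of seconds to a few minutes:

* **Algorithmic oracles**: all four node metrics against brute-force
  references (hand-rolled Floyd-Warshall and shortest-path counting) on 500
  random graphs of up to 12 nodes at $10^{-12}$ tolerance, and DBSCAN
  against a definition-based reference (core components ordered by smallest
  core index, borders to the earliest-discovered component) on 200 random
  instances of up to 50 points.
* **Statistical calibration**: PERMANOVA empirical type-I error within
  $[0.03, 0.07]$ at $\alpha = 0.05$ over 1000 label-permutation nulls (16
  samples, 199 permutations each); Pearson edge-test p-values uniform under
  independence (Kolmogorov-Smirnov over 2000 replicates at $n = 50$); BH
  q-values identical to the closed-form step-up rule.
* **End-to-end recovery** at study scale (`scale = 0.45`, about 156 cases
  and 219 controls, depth ~$5 \times 10^4$), averaged over 20 seeds: planted
  differential taxa recovered with sensitivity $\ge 0.9$ at FDR 0.05, and
  planted modules with adjusted Rand $\ge 0.9$ using the automatic knee
  eps, both on the full default plant. Gained/lost edge recovery
  ($F_1 \ge 0.9$) is measured on a plant containing *only* the
  condition-specific pairs (zero latent correlation elsewhere) — that is
  the property's defining condition — with `adjust = "BH"` on the edge
  tests.

The BH mode is used for all recovery analyses for an arithmetic reason
worth stating explicitly. With ~2000 taxon pairs per condition, raw
$\alpha = 0.05$ admits ~90 false edges per condition; nearly all are
significant in exactly one condition and so become false gained or lost
calls, overwhelming 10 planted pairs ($F_1 \approx 0.1$ no matter how good
the implementation). Under BH the expected number of false discoveries is
roughly $\alpha$ times the discovery count, so keeping the discovery set
lean matters too: when many true always-present edges are planted (the
module blocks), the admitted borderline false edges rise proportionally and
the achievable $F_1$ on ten planted pairs drops to ~0.85. This is a
property of FDR-thresholded differential networks, not of this
implementation, and it is why real rewired networks built at raw
$\alpha = 0.05$ should be read as screening hypotheses rather than
confirmed interactions.

## Known limitations

* Pearson correlation on relative abundances is blind to compositional
  closure; the package reproduces the published methodology rather than
  replacing it with compositionally aware estimators (SparCC-style
  approaches are out of scope). The generator quantifies how large closure
  effects can get; on real data with dominant taxa they can cross the
  significance boundary.
* Correlations pool samples across datasets within a condition; per-dataset
  stratified correlation is out of scope.
* The published eps/minPts/scaling for module detection and the exact
  significance convention behind the published edge counts are unknown, so
  exact reproduction of those counts is not a supported target; the
  package exposes every such knob as explicit configuration instead.
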