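---
title: "Selecting patient-specific PPI drug targets by Gibbs free-energy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting patient-specific PPI drug targets by Gibbs free-energy scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppitarget)
```

## The model

`ppitarget` ranks protein–protein interactions for inhibition, one
patient at a time, by combining a thermodynamic surrogate score with
local network topology. The ingredients are an undirected simple PPI
network (typically the union of several curated pathway maps) and one
patient's expression profile.

Expression is first min–max normalized within the patient,

$$c_g = \frac{x_g - \min_h x_h}{\max_h x_h - \min_h x_h} \in [0, 1],$$

and the normalized mRNA value $c_i$ is used as a surrogate for the
concentration of protein $i$. This is the model's central assumption —
transcript abundance stands in for protein abundance — and it is an
approximation: translation rates, protein stability and post-translational
regulation all decouple the two in real tissue.

Each network protein then receives a Gibbs free-energy contribution

$$G_i = c_i \,\ln\!\frac{c_i}{\sum_{j \in N[i]} c_j},$$

where $N[i]$ is the closed neighborhood of $i$ (the node and its
neighbors), restricted to nodes with expression data. Because the
denominator includes $c_i$ itself, the log argument never exceeds one and
$G_i \le 0$ always. $G$ is an entropy-like, dimensionless score on the
natural-log scale; no temperature factor or physical unit is attached,
and the mapping is deliberately treated as a score rather than an energy
equality. The interpretation: a protein that is itself highly expressed
*and* sits in a highly expressed neighborhood takes a strongly negative
$G_i$, marking it as thermodynamically important for the expressed
subnetwork.

The per-patient selection rule is then:

* **anchor** — the protein with the most negative $G_i$;
* **partner** — the anchor's covered neighbor with the largest $c_j$.

The anchor–partner edge is the interaction proposed for inhibition. The
two roles are asymmetric: the anchor is energy-selected, the partner
expression-selected. Across a cohort, per-sample pairs are tallied and
ranked by patient count (a Pareto table/chart).

Note what the rule is *not*: it does not remove the anchor from the
network (all its other interactions are left alone), and it involves no
topological filtration or persistent-homology step — adjacency is the
only topological input to the score.

## Parameters and defaults

| parameter | where | default | meaning |
|---|---|---|---|
| `log_transform` | `normalize_sample()`, `gibbs_targets()` | `FALSE` | apply $\log_2(x+1)$ before min–max; off because the score is defined on normalized raw values, but microarray-style intensities may warrant it |
| `ordered` | `aggregate_cohort()`, `gibbs_targets()` | `TRUE` | key cohort counts on the ordered (anchor, partner) pair, since the roles differ; `FALSE` merges A–B with B–A |
| `id_map` | `parse_kgml()`, `apply_id_map()` | none | optional two-column table mapping KGML identifiers (e.g. `hsa:5925`) to symbols (`RB1`); exact match, first mapping wins, unmapped ids pass through |
| `base` | `degree_entropy()` | `e` | natural log (nats); set 2 for bits |
| `normalized` | `betweenness_centrality()` | `FALSE` | raw endpoint-excluded path counts; `TRUE` divides by $\binom{n-1}{2}$ |

All quantities are dimensionless: concentrations live in $[0,1]$, Gibbs
scores on the natural-log scale of those concentrations.

## Numerical conventions and degenerate inputs

* $0 \ln 0 := 0$: a protein with $c_i = 0$ scores $G_i = 0$, by
  continuity of $x \ln x$. A node whose whole closed neighborhood is at
  zero (the $0/0$ case) also scores 0. Both conventions make silent
  genes harmless in anchor selection.
* An isolated covered node has ratio 1 and $G_i = 0$, so it can only be
  anchored when everything ties at zero — and it is then skipped anyway
  for lack of a partner.
* Missing expression values are excluded from the min–max range and from
  all neighbor sums; unexpressed nodes are neither scored nor eligible
  as anchor or partner. Exclusion was chosen over zero-imputation
  because the two are numerically identical in the sums but differ in
  eligibility, and fabricating a concentration of 0 would make absent
  genes look measured.
* A constant sample (max = min) cannot be rescaled; every gene is set to
  0.5 with a warning, the unique symmetric choice, so a pathological
  sample degrades a cohort run instead of aborting it.
* **Ties** — in anchor score and in partner expression — break to the
  lexicographically smallest node identifier (C-locale radix order).
  Nothing in the method prefers one tied node over another, so the only
  requirement is a total order that makes runs reproducible across
  platforms and graph-representation orders.
* **Fallback**: if the argmin-$G$ node has no covered neighbor, the next
  node in ascending-$G$ order is tried; a sample is skipped (and
  reported, never silently dropped) only when no scored node has a
  covered neighbor.
* Normalization is invariant to positive affine transforms of the raw
  sample and order-preserving; both properties are enforced by tests, as
  is agreement of the scoring and selection chain with independent
  brute-force re-implementations to $10^{-12}$.

## Network handling

KGML pathway files are read with entries of type `gene` contributing all
identifiers in their `name` attribute; `group` entries expand to their
components; relations clique-expand across the two entries' gene sets.
This expansion is the conservative gene-level reading of KGML's
complex/family entries, since the scoring operates on single proteins.
Relation direction and subtype are discarded — the score and the
selection rule use adjacency only — and self-loops are dropped (the
closed neighborhood already counts $c_i$ once; a loop would double-count)
but logged, and their endpoints kept as nodes. Pathways are merged by
exact-identifier union of node and edge sets, which matches a Cytoscape
network union when both sides use the same namespace; the optional
identifier map exists precisely so the namespace can be unified first.
Published merged-network sizes (e.g. a glioma pathway union of 144 nodes
and 517 edges) depend on the pathway-database release and are therefore
documented rather than asserted by tests.

## Auxiliary statistics

Two Introduction-level network descriptors are provided for
characterizing merged networks. `degree_entropy()` computes the Shannon
entropy of the node-degree distribution over degrees $\ge 1$ (isolated
nodes excluded); regular graphs give $H = 0$, the 3-leaf star gives
$-(\tfrac34\ln\tfrac34 + \tfrac14\ln\tfrac14) \approx 0.5623$ nats. The
underlying distribution $p(V)$ is genuinely ambiguous in the source
formula; the degree-distribution reading implemented here matches the
degree-entropy usage of the prior network-complexity literature, and the
alternative (a normalized per-node centrality distribution) is noted but
not implemented. `betweenness_centrality()` is the standard
endpoint-excluded, unnormalized betweenness (delegated to igraph's
Brandes algorithm and cross-checked in tests against exhaustive
shortest-path enumeration).

## The synthetic cohort generator

Real validation cohorts (TCGA glioma, GEO CLL) require controlled-access
downloads and a pinned pathway release, so the test bed is synthetic.
`simulate_cohort()` plants a known ground truth: per sample, every gene
sits at a background level (0.1), the planted anchor and its whole
neighborhood are boosted (0.9), the planted partner tops the
neighborhood (1.0), and independent Gaussian noise (sd `noise_sd`,
truncated at zero) is added per gene. The margins guarantee that at zero
noise the anchor holds the heaviest closed neighborhood and the partner
is its hottest neighbor, so the pipeline provably returns the planted
pair in every sample — on sparse anchors of degree ≥ 2 such as the
RB1 fixture; on dense graphs a well-connected partner can legitimately
out-score the anchor, which is a property of the method, not a generator
defect. Recovery then decays monotonically (statistically, over seeds)
as noise grows, which the tests verify over 20 seeds at noise sd 0, 0.1,
0.3 and 1.0.

What the generator does **not** emulate: the marginal distribution of
real expression data (library-size effects, heavy tails, gene–gene
correlation), batch structure, or realistic missingness. Passing the
planted-recovery tests therefore shows the selection machinery is
correct and noise-robust in the designed sense — not that the method's
biological ranking on real cohorts is validated.

## Problem sizes used in validation

The shipped suite checks: scoring against a brute-force double-loop
oracle on 100 random graphs of up to 20 nodes; end-to-end selection
against an exhaustive independent implementation on 100 random instances
of up to 12 nodes; betweenness against DFS path enumeration on 200
random connected graphs of up to 7 nodes; format round-trips on random
networks; normalization invariants on 1000 random samples; and
planted recovery on a 200-sample noise-free cohort plus 20-seed noise
curves at 50 samples per seed. These sizes make the exhaustive oracles
exact and keep the whole suite's runtime modest while exercising every
code path; the package itself runs comfortably on pathway-scale networks
(hundreds of nodes) and cohort-scale sample counts (hundreds of
patients).

## Known limitations

* mRNA-for-protein surrogacy, inherited from the model.
* Min–max normalization is outlier-sensitive: one extreme gene rescales
  the whole sample. The `log_transform` flag mitigates but does not
  remove this.
* Exactly one target edge per patient; proteins tied in $G$ or $c$ are
  resolved by an arbitrary (if deterministic) rule rather than reported
  as co-targets. `write_scores()` exposes the full ranking for manual
  inspection.
* Between-sample normalization (TPM, size factors, quantile) is out of
  scope; samples are treated independently by design.
* No drug-database lookup: the output is a ranked interaction table, and
  matching interactions to approved or investigational inhibitors is a
  separate, downstream step.
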