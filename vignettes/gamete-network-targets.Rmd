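---
title: "Prioritizing drug targets in sperm-egg interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing drug targets in sperm-egg interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gametePIN)
```

## The problem and the model

Fertilization begins with adhesion and fusion of the sperm and egg plasma
membranes, mediated by protein-protein interactions (PPIs) between
gamete-surface proteins. When this step fails, conventional in-vitro
fertilization fails with it, and no approved drug targets the process. A
network view offers a principled shortlist: proteins that are
*topologically essential* in the sperm-egg interaction network — highly
connected hubs and high-betweenness bottlenecks — are the natural
candidates for pharmacological modulation, because removing or inhibiting
them is most disruptive to the network.

`gametePIN` operationalizes this as a deterministic pipeline over two
compartment evidence sets:

1. build the sperm and egg PPI networks from per-pair evidence records;
2. intersect them (shared proteins, union of both compartments' edges
   among the shared proteins);
3. restrict to membrane candidates (signal peptide and/or transmembrane
   domain);
4. retain only high-confidence interactions via two parallel filters and
   union the results;
5. compute degree, betweenness, closeness, shortest-path and
   degree-distribution statistics;
6. call hubs and bottlenecks by the half-of-maximum criterion and join
   known drugs.

The assumptions are those of the underlying essentiality literature: the
network is an undirected simple graph, all edges are equally weighted, and
scale-free-like degree structure justifies reading high degree/betweenness
as essentiality.

## Confidence model

Evidence for a protein pair arrives as independent per-channel
probabilities $S_i \in [0,1]$ (database, experimental, text-mining, ...
channels). These are combined with the noisy-OR rule

$$S = 1 - \prod_i (1 - S_i),$$

the probability that at least one channel is correct under independence.
`combine_scores()` implements exactly this formula, with an empty channel
list combining to 0; no prior-correction or rescaling is applied. Two
filters then run in parallel over the membrane network's evidence:

* **functional**: keep records with $S > 0.700$. The cut is *strict*; the
  threshold is a `filter_config()` field, so the inclusive reading costs
  one argument.
* **physical**: keep records that are physical, supported by at least 3
  publications, conserved in at least one species, and have an MI
  (MINT-inspired) confidence score $\ge 0.431$ (*inclusive*). Records
  without an MI score fail this filter.

The two kept sets form two networks whose union — with every membrane
protein retained, so proteins filtered down to isolation stay visible at
degree 0 — is the analysis network. Each filter is monotone (raising any
score or support count never drops a kept record), idempotent and a
subset, and the test suite asserts all three properties on random
evidence.

## Topological statistics and their conventions

* **Degree**: incident edge count; isolated nodes report 0.
* **Betweenness** (normalized): $BC(v) = \sum_{s<t}
  \frac{\sigma_{st}(v)}{\sigma_{st}} \big/ \frac{(n-1)(n-2)}{2}$, with
  unreachable pairs contributing 0 and networks of fewer than 3 nodes
  defined as all-zero. The normalization keeps values in $[0,1]$,
  matching the convention of the network-analysis tools this workflow is
  modeled on (reference values like 0.2 on a 106-node network only make
  sense normalized).
* **Closeness**: reciprocal of the mean distance to *reachable* nodes
  (component-restricted), isolated nodes 0. This keeps values in $[0,1]$
  on disconnected networks. One consequence, verified in testing: adding
  an edge that bridges two components can *lower* an endpoint's
  closeness, because the newly reachable nodes are far; the usual
  "adding edges never hurts closeness" intuition holds only within
  connected graphs, and the property suite tests it there.
* **Path statistics**: histogram of shortest-path lengths over connected
  unordered pairs; the characteristic path length is their mean.
  Unreachable pairs are excluded rather than given penalty distances; a
  network with no connected pair reports `NA`, not 0.
* **Power-law fit**: the empirical distribution $P(k)$ over observed
  positive degrees (degree 0 excluded — $\log 0$ is undefined), one point
  per degree with no binning, fitted by ordinary least squares of
  $\log_{10} P(k)$ on $\log_{10} k$. The slope is the degree exponent and
  the fit's $R^2$ is reported. Note that unbinned least squares on raw
  $P(k)$ systematically flattens heavy tails: on preferential-attachment
  graphs whose asymptotic exponent is $-3$ it recovers roughly $-2.0$ to
  $-2.2$, because the many singleton degrees in the tail enter with equal
  weight. We keep the unbinned convention — it is the one the workflow's
  reference tools use and is fully deterministic — and the test suite
  asserts the exact closed-form OLS solution plus a sanity band (negative
  exponent, $R^2 > 0.6$) on scale-free inputs, rather than a sharp
  exponent value. Maximum-likelihood (Clauset-style) fitting with
  $x_{\min}$ selection is deliberately out of scope.

## Target calling

The half-of-maximum criterion is *relative*: hub iff degree $\ge
\max(\text{degree})/2$, bottleneck iff betweenness $\ge \max(BC)/2$. Both
thresholds are inclusive, because published centrality tables are rounded
(a protein printed at BC 0.1 with max 0.2 sits exactly on the boundary)
and because for integer degrees with odd maximum the two readings are
indistinguishable anyway. Putative targets are the hubs; bottleneck status
is an auxiliary flag. Ties in the ranking are broken by degree (desc),
then betweenness (desc), then gene symbol (asc) — a declared convention.
Drug lookup keys on gene symbol, as drug-target curation does; the bundled
table reproduces the known-drug associations for the six druggable
reference targets, preserving their names verbatim (including one curated
degree discrepancy, documented in `?reference_hub_table`).

```{r targets}
calls <- map_drugs(classify_targets(reference_hub_table()))
calls[calls$is_bottleneck, c("gene_symbol", "degree", "betweenness")]
```

## The synthetic-study generator

Real gamete interactomes from the era this workflow models cannot be
reconstructed from public snapshots, so the generator produces studies
with the statistical structure the analysis assumes, plus ground truth:

* a **shared scale-free core** of `n_shared = 80` proteins built by
  preferential attachment (`m = 2`), embedded in a sperm compartment of
  400 and an egg compartment of 120 proteins (roughly one-fifth of the
  motivating study's 2076/409, with the sperm:egg ratio preserved and
  headroom so the shared core fits in the egg compartment);
* **8 planted hubs**: shared, always membrane-annotated proteins wired to
  `hub_degree_fraction = 0.45` of the shared core (top-decile degree by
  construction) — the knowable stand-in for truly essential proteins in
  end-to-end recovery tests;
* **membrane annotation** at rate 0.63, the shared-membrane fraction of
  the motivating study (106/167);
* per-edge **evidence**: channel scores from Beta(8, 2) (mean 0.8) for
  true edges and Beta(2, 8) (mean 0.2) for spurious ones, which are added
  at 30% of the true edge count; physical flags at probability 0.6;
  publication counts Poisson(4); conservation counts Poisson(2); MI
  scores Beta(5, 3) for physical edges and absent otherwise. Publication,
  physical and conservation fields are independent of the truth label, so
  the *channel scores alone* separate signal from noise — a deliberate
  simplification that makes the functional filter's behaviour testable in
  isolation.

Everything is driven by a single integer seed; `write_study()` emits a
JSON sidecar of the full specification for provenance. What passing the
recovery tests shows is that the pipeline's plumbing and the relative
half-of-maximum criterion work as specified under separated score
distributions; it does *not* show that real evidence channels are
independent, that real score distributions are Beta-shaped, or that real
essential proteins are network hubs — those are modeling assumptions of
the approach itself.

```{r study}
study <- generate_study(study_spec(seed = 42))
run <- run_pipeline(study$sperm_evidence, study$egg_evidence,
                    study$annotations, verbose = FALSE)
sum(study$ground_truth$planted_hubs %in%
      run$targets$accession[run$targets$is_hub])
```

## Numerical and degenerate-input choices

* Self-interactions are rejected at parse time (the centrality definitions
  assume a simple graph); duplicate pairs are merged by per-field maximum
  (scores, publications, conservation) and logical OR (physical flag) — a
  deterministic convention that is conservative toward retention, adopted
  because multi-source evidence sets rarely document their own
  reconciliation.
* A network node missing from the annotation table is an error, never
  silently non-membrane.
* Empty inputs propagate: empty evidence gives empty networks, a
  membrane-free study completes with zero targets, and a network with no
  connected pairs reports an undefined (not zero) characteristic path
  length. A power-law fit needs at least two distinct positive degrees and
  errors otherwise; `run_pipeline()` records a missing fit rather than
  failing the run.
* Pipeline artifacts are written only after every stage has succeeded, so
  an aborted run leaves no partial outputs; aborts name the failing stage.
* Test problem sizes: centrality oracles run on 50 random graphs of up to
  60 nodes against an all-pairs BFS enumeration; hub recovery runs 20
  seeded studies at the default scale. These sizes make the full suite run
  in well under a minute while exercising every code path.

## Known limitations

* Evidence channels are treated as exchangeable probabilities; no
  channel-specific modeling (co-expression, neighborhood, ...) and no
  recomputation of MI scores from primary publications.
* Identifier handling is deliberately opaque: accessions are strings,
  gene-symbol mapping is taken from the annotation table, and no
  identifier-mapping service is consulted.
* The drug table is a static bundled curation; it replaces, not wraps, a
  commercial pathway-analysis lookup.
* Betweenness and closeness are unweighted and undirected; directed or
  confidence-weighted centralities are out of scope.
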