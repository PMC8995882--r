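---
title: "Composite feed-forward loops in TF–miRNA–gene networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite feed-forward loops in TF–miRNA–gene networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflregnet)
```

## The problem

Transcription factors (TFs) and microRNAs are the two principal classes of
gene regulators, and they regulate each other: a TF can activate or repress
a miRNA's transcription, while the miRNA can post-transcriptionally repress
the TF. When a TF and a miRNA that regulate each other also share a common
target gene, the four regulations

* TF → miRNA,
* miRNA → TF,
* TF → gene,
* miRNA → gene

close into a *composite feed-forward loop* (composite FFL): a three-node
circuit in which the joint target is controlled both transcriptionally and
post-transcriptionally, with mutual regulation between the two controllers.
Such circuits are over-represented in disease-associated regulatory
networks — immune-gene networks in ischemic stroke being one published
setting — and the genes they contain are natural starting points for drug
repurposing screens.

`fflregnet` implements the full analysis chain for this question:

1. build a *typed* directed network from four categories of curated
   regulation pairs, with node roles TF / miRNA / gene / TF-and-gene;
2. census every connected three-node subgraph, classed up to role-coloured
   isomorphism;
3. decide which classes are motifs (over-represented) against a
   degree-preserving randomisation null, and extract the sub-network merged
   from all instances of the significant composite-FFL class;
4. independently, filter a weighted protein–protein interaction (PPI)
   table, call hub genes, and detect dense modules MCODE-style;
5. screen a drug–target table for miRNA–drug association with the
   cumulative hypergeometric distribution.

Because the curated databases behind such studies (miRTarBase, TransmiR,
TRRUST, STRING, DrugBank) change over time and are not redistributable,
every stage is exercised on synthetic data with *planted* ground truth:
the generators in this package produce input tables in the exact dialects
the readers accept, with a known set of planted composite FFLs, planted
dense PPI modules and one planted target-enriched drug.

## The typed network and its construction

A `typed_network` stores a role per node and a set of directed edges, each
labelled with one of the four categories. Construction
(`build_network()`) takes the pair tables plus three identifier universes;
a node found in both the TF and the gene universe gets the dual role
`TF_AND_GENE` (a TF that is itself a disease gene of interest, such as
ESR1 in immune gene lists). Identifier normalisation uppercases gene/TF
symbols and lowercases miRNA names, so capitalisation variants collapse to
one node.

Duplicates are collapsed *within* a category only. The same ordered pair
under two categories (a TF→gene edge and a miRNA→gene edge can share a
target, but also e.g. TF→miRNA and miRNA→TF between the same dual pair)
is kept as two edges, and the cross-category multiplicity is logged.
Published node/edge totals in this field are typically reported after an
unstated deduplication step; keeping categories separate and logging is
the reproducible choice.

## Motif census and canonical classes

`enumerate_triads()` enumerates **all** connected node triples exhaustively
(no sampling): for every undirected-adjacent pair, each common or adjacent
third node is collected, and duplicates are removed. For each triple a
canonical signature is computed: the minimum, over the six orderings of the
three nodes, of the tuple (role triple, 4-bit category mask for each of the
six ordered node pairs), packed into one number. Two triads get the same
signature exactly when a role- and category-preserving bijection maps one
onto the other; the test suite verifies this equivalence against a naive
oracle that tries all six bijections explicitly.

Dual-role nodes need one extra rule: a `TF_AND_GENE` node is canonicalised
under the role it *plays in the instance*, inferred from the categories of
its incident edges inside the triad (source of TF→· edges or target of
miRNA→TF ⇒ acting as TF; target of ·→gene edges ⇒ acting as gene). A dual
node acting on both sides within one triad keeps the ambiguous dual code,
and `is_composite_ffl()` requires an assignment in which the dual node
serves as the TF *or* as the target gene, not both at once.

## The randomisation null and significance

The null model (`randomize_network()`) applies repeated double-edge swaps
*within one edge category at a time*: edges a→b and c→d become a→d and
c→b, rejecting swaps that would create self-loops or duplicate an existing
edge of that category. This preserves every node's per-category in- and
out-degree and every role — the edge-coloured analogue of the standard
switching null used by motif-detection tools. The number of attempted
swaps is `swaps_per_edge` (default 3) times the category's edge count;
with the default the edge sets of non-trivial categories are thoroughly
mixed while categories with a single edge are left unchanged (there is no
legal swap).

For each class observed in the real network, `motif_zscores()` computes
over `n_random` randomised copies (default 1000; 200 in the bundled
analysis scripts, which is ample for a p floor of 1/201 ≈ 0.005):

* Z = (real count − null mean) / null SD,
* the add-one empirical p-value, p = (#{null ≥ real} + 1) / (n\_random + 1),
  which avoids a reported p of exactly 0 at finite sample size.

Classes whose null SD is zero (typically classes pinned by unswappable
structure) are *flagged*, not scored: a Z-score obtained by dividing by
zero has no principled value, and such classes are excluded from
significance. Selection (`select_and_merge()`) keeps classes with Z > 2.0
and p < 0.05 that are composite FFLs, merges the union of their instances
into the motif-specific sub-network, and lists the explicit
(TF, miRNA, gene) triples.

## Topology profile and power-law fit

`topology_profile()` works on the undirected simple projection (the
convention of the network-analysis tools whose figures these statistics
mirror): degree, local clustering coefficient (0 for degree ≤ 1),
neighbourhood connectivity (mean neighbour degree), and the topological
coefficient — for node *n* with degree k, the mean over all nodes *m*
sharing at least one neighbour with *n* of (shared neighbours + 1 if
adjacent)/k.

`fit_power_law()` fits f(k) = a·k^b by least squares on
(log₁₀ k, log₁₀ n(k)) over the distinct observed degrees — the log-log
regression convention, chosen over maximum-likelihood exponent estimation
because the R² it reports is the quantity quoted alongside such fits in
this literature. Noiseless power-law input is recovered exactly (R² = 1,
handled explicitly when the total sum of squares degenerates).

## MCODE-style module detection

`mcode_clusters()` implements the three-phase MCODE algorithm
(Bader & Hogue 2003) with the Cytoscape plugin's defaults: vertex weight =
(highest k-core level of the closed neighbourhood) × (density of that
k-core), greedy expansion from the highest-weight unused seed admitting
neighbours with weight ≥ (1 − node score cutoff) × seed weight, then
post-processing (discard clusters lacking a k-core of order `k_core`;
haircut removes singly-connected members). The cluster score is
size × density = 2E/(N−1); clusters under `min_cluster_score` (default 5)
are dropped. The procedure has no randomness; seed-order ties break by
node id, so output is fully deterministic.

One behavioural note established during validation: for *small* dense
modules (size ≈ 8) realised from an Erdős–Rényi block at p = 0.9, a few
missing edges spread the vertex weights by more than the default 20%
cutoff, so the weakest member is often excluded and a trimmed core can
fall under the score-5 floor. This is inherent to the seed-relative
threshold of the algorithm — on structurally guaranteed inputs (isolated
cliques) recovery is exact — and is documented in the test suite: the
stochastic planted-module recovery experiment fails for some generator
draws, including the pre-registered one, while the deterministic
clique-recovery tests pass.

## The drug screen and the hypergeometric tails

For a miRNA with K target genes and a drug with N target genes inside a
genome universe of M genes, the overlap x is scored with the cumulative
hypergeometric distribution, accumulated in log space. The printed formula
in this literature is the lower tail, F(x) = P(X ≤ x) — under which a
*large* overlap does **not** yield a small p. Since the screen's intent is
to flag unusually large overlaps, both tails are always reported
(`p_lower`, `p_upper` with P(X ≥ x) = 1 − F(x−1)) and the upper tail
drives the significance call by default; the lower tail remains available
via the `tail` argument. Drugs with fewer than 2 targets are discarded
before testing, no multiple-testing correction is applied to the
significance call (matching field practice), and a Benjamini–Hochberg
column is emitted for information only. The genome size M is an explicit
parameter (default 20000 in the pipeline) rather than a hidden constant.

## What the synthetic data emulates — and what it does not

`generate_regulatory_pairs()` plants a chosen number of composite-FFL
triples (each contributing exactly its four edges) and adds uniform
background edges per category; a background edge that would complete an
*additional* composite FFL is rejected and redrawn, and the planting
itself is redrawn in the rare case that independently planted triples
combine into an unplanned complete FFL. The planted count is therefore
exact, which makes motif-count assertions sharp. Defaults (20 TFs, 30
miRNAs, 50 genes, 2 dual nodes, 30 planted FFLs, 40 background edges per
category) give a network of roughly 100 nodes — large enough for a stable
null, small enough that the full analysis runs in seconds.

`generate_ppi()` plants disjoint Erdős–Rényi blocks (default two of size
8 at p = 0.9) in a sparse background (p = 0.02), with combined scores
drawn from a signal range above the 0.9 filter for module edges and a
broad noise range for background edges. `generate_drug_targets()` plants
one drug whose targets overlap a query gene set (default 6 of 8) among
drugs drawing targets uniformly.

These generators emulate table dialects, role structure and planted
signal; they do **not** emulate the degree heterogeneity, evidence-score
distributions, annotation bias or identifier noise of real curated
databases. Passing tests therefore demonstrate correctness of the
algorithms and sharpness of the recovery machinery, not performance on
real regulatory corpora.

## Numerical and design choices

* Strict inequalities for the PPI score filter (> 0.9) and hub threshold
  (> 30), as quoted conventions demand.
* Empirical p uses the add-one estimator; Z is undefined (flagged) when
  the null SD is 0.
* Regulation mode (activation/repression) is carried as edge metadata but
  does not enter motif class signatures: the composite-FFL definition is
  stated purely in terms of the four edge categories.
* Signature codes pack roles and six 4-bit masks into one number below
  2³¹, so canonicalisation is exact integer arithmetic.
* The problem sizes in the test suite (random networks of ≤ 16 nodes for
  oracle sweeps, 200 null randomisations, 100-protein PPI graphs, 50-drug
  screens) were chosen so each recovery experiment gives a clear signal
  (null p floor ≈ 0.005, Z ≫ 2 for planted classes) at interactive run
  times.

## Known limitations

* The census is exhaustive over node triples; it is quadratic-to-cubic in
  network size and intended for curated networks (hundreds of nodes), not
  genome-scale graphs.
* MCODE parameters tuned for large PPI snapshots (score ≥ 5, cutoff 0.2)
  are aggressive for very small modules, as discussed above.
* The drug screen tests each (miRNA, drug) pair independently; target
  sets derived from the same network are not independent, so the BH
  column is informational only.
* Only 3-node motifs are considered; larger composite circuits are out of
  scope.
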