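---
title: "Mining literature-derived TF interaction networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining literature-derived TF interaction networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfnetminer)
```

# The problem

Transcription factors (TFs) act through transient, context-dependent
interactions, and no single data type ranks the TFs that matter for a
given disease. `tfnetminer` implements a multi-level, multi-parametric
strategy: mine a literature corpus for gene--gene associations, validate
the candidate pairs with two orthogonal biological filters (Gene
Ontology annotation distance and protein-structure contacts), assemble
the survivors into an undirected TF interaction network, and rank nodes
and TF-anchored modules by a combination of topological and biological
evidence, ending in hypergeometric pathway enrichment.

# Stage 1: corpus mining

Each abstract $d_i$ becomes an $M$-dimensional vector over the gene
thesaurus with tf*idf weights

$$W_{ik} = T_{ik}\,\log\frac{N}{n_k},$$

where $T_{ik}$ counts occurrences of any synonym of gene $k$ in
document $i$, $N$ is the corpus size and $n_k$ the number of documents
mentioning gene $k$. The association between genes $k$ and $l$ is the
cross-document dot product
$\mathrm{assoc}_{kl} = \sum_i W_{ik} W_{il}$, and a user-defined
threshold decides which pairs go forward.

Choices the formulas leave open, and how this package resolves them:

* **Log base.** Unstated in the standard formulation; base 10 by
  default, configurable, and recorded in the run manifest. The base
  only rescales all associations, so thresholding on a quantile is
  base-invariant.
* **Term frequency.** $T_{ik}$ is the raw occurrence count by default
  (`termFreq = "binary"` switches to presence/absence).
* **Dictionary matching.** Case-insensitive, token-boundary,
  longest-synonym-first with left-to-right resolution of overlaps; this
  is the conventional deterministic behaviour for dictionary NER. A
  synonym shared by two canonical ids is a load error rather than a
  silent choice.
* **Sentence segmentation.** Split after `.`, `!` or `?` followed by
  whitespace and an upper-case letter or digit; the regex is a
  parameter. This is dependency-free and deterministic, which matters
  more here than linguistic perfection because sentences are only used
  to count relation-trigger co-occurrences.
* **Threshold default.** "User-defined" in the method's definition; the
  default is the 95th percentile of the non-zero association scores, a
  scale-free choice that adapts to corpus size. Zero-score pairs are
  never retained, even at threshold zero, because a zero association
  carries no co-occurrence evidence at all.
* **Relation ties.** The relation label for a pair is the one whose
  trigger words co-occur with both genes in the most sentences; exact
  ties go to the lexicographically smallest label, for reproducibility.

# Stage 2: Gene Ontology validation

Candidate pairs are scored with the Czekanowski-Dice distance between
their GO annotation sets,

$$d(P_i, P_j) =
  \frac{|GO(P_i)\,\Delta\,GO(P_j)|}
       {|GO(P_i)\cup GO(P_j)| + |GO(P_i)\cap GO(P_j)|},$$

and a pair is accepted as interacting when $d < 1$, i.e. when the two
annotation sets are not disjoint. The per-aspect (BP/MF/CC) distances
are computed and reported as well, since they are informative when
interpreting individual edges, but edge acceptance uses the overall
distance: the network-construction rule does not restrict aspect. Two
empty annotation sets give an *undefined* distance (`NA`), which is
treated as non-interacting but kept distinguishable from a genuine
$d = 1$. Terms are compared exactly as annotated; ancestor closure over
the GO graph is deliberately out of scope.

Downstream scoring uses the similarity $1 - d$ as the edge weight.

TF flagging is annotation-driven: a protein is a TF when its GO terms
intersect a configured list covering the six TF functionalities (TF,
TF activator, TF co-activator, TF repressor, TF co-repressor activity,
DNA-binding transcription activity). The term list is data, not code,
because the functionalities are named rather than pinned to term ids in
the method's definition.

# Stage 3: structure-based validation

For pairs with mapped PDB structures, a six-step algorithm decides
structural support:

1. collect all structures of both proteins (all-vs-all pairing);
2. predict probable interface residues of each chain;
3. compute C-alpha--C-alpha distances between predicted residues;
4. count a predicted residue as *interacting* when it lies within
   6 &Aring; of any predicted residue of the partner chain;
5. score the structure pair as
   interacting residues / probable residues, satisfied at $\ge 10\%$;
6. call the protein pair interacting when $\ge 30\%$ of its structure
   pairs satisfy the criterion.

The interface predictor is pluggable. The shipped default is
deterministic and transparent: each residue scores a weighted sum of a
Kyte-Doolittle hydrophobicity value (scaled to $[0,1]$) and a
centroid-distance exposure proxy, and residues at or above the cutoff
(default 0.5) are predicted. An `"all"` predictor (every residue) is
provided for testing, and any function `f(chain, config)` can be
substituted. The denominator of the per-structure score is the union of
predicted residues on both chains, and all threshold comparisons are
inclusive; both readings are recorded in the manifest because the
formulas do not pin them down. Residues without a resolved C-alpha are
skipped and surface in a coverage statistic.

A pair with no mapped structures yields the distinct outcome
`no_structural_evidence`, never a negative call: in the intended use
most validated edges carry GO evidence only, and the network keeps them
with `structural_score = NA`. The per-edge structural score attached to
the network is the mean per-structure-pair interaction score, which
keeps it on the same $[0,1]$ scale as the similarity weight.

# Stage 4: network, topology, evidence tiers

The validated network is undirected and simple. Topology annotation
computes, per node: degree $k_i$; clustering coefficient
$C_i = 2n / (k_i(k_i - 1))$ with $C_i = 0$ for $k_i < 2$; and
betweenness $C_B(i) = \sum_{j<k} g_{jk}(i)/g_{jk}$. These are delegated
to igraph and verified against brute-force oracles in the test suite.

Raw betweenness is unbounded while the other three node features live
in $[0,1]$; mixing them unscaled would let betweenness dominate the
node strength. Betweenness is therefore additionally normalized by
$(n_c - 1)(n_c - 2)/2$ within each connected component of size $n_c$
(the maximum possible number of pair paths through a node of that
component), and the normalized value feeds the scoring while the raw
value is reported alongside.

Evidence tiers translate membership lists into annotations: proteins in
the disease-specific pathway list are HIGH, in the cancer/signalling
list MEDIUM, in any other pathway list LOW, and in none UNKNOWN. Edge
tiers follow the rule table exactly — HIGH for HIGH--HIGH, HIGH--MEDIUM
or HIGH--LOW; MEDIUM for MEDIUM--MEDIUM or MEDIUM--LOW; LOW for
LOW--LOW. UNKNOWN does not exist in the original rule table; it is
treated as LOW for the edge rule but flagged, which closes the table
without inventing evidence.

# Stage 5: node prioritization

Two node-level biological scores:

* **GO score**: the mean similarity $1 - d$ over a node's incident
  edges (isolated nodes score 0, flagged);
* **interaction propensity**: the node's mean structural edge score
  divided by the network-wide mean structural edge score.

Edges without structural data contribute 0 to both means but stay in
the denominators, provided the network has at least one structurally
scored edge; a network with none yields propensity 0 everywhere,
flagged. This mirrors the intended data situation — GO-only edges are
retained, structural evidence upweights where it exists — and resolves
the ambiguous denominator index set in the propensity formula as the
all-edge mean.

Node strength combines the four features (clustering, normalized
betweenness, GO score, propensity):

* *unweighted*: their arithmetic mean;
* *weighted* (default): $0.4 \cdot \text{propensity} + 0.2 \cdot
  (\text{clustering} + \text{betweenness} + \text{GO})$;
* *weighted_literal*: the printed form of the weighted combination, in
  which the propensity also appears inside the 0.2 bracket so the
  weights sum to 1.2.

The literal form double-counts the structural feature and is not
comparable in scale to the unweighted score; the default re-normalizes
to weights summing to 1 while preserving the stated 2:1 emphasis on the
structure-based feature. Both are available and every output records
the scheme. Ranking sorts by strength, ties broken by protein id.

Node--node association adds a feature that topology alone misses: for
each edge joining two TFs, the probability that nodes with $n_1$ and
$n_2$ partners out of $N$ share exactly $m$,

$$P(N, n_1, n_2, m) =
  \frac{(N-n_1)!\,(N-n_2)!\,n_1!\,n_2!}
       {N!\,m!\,(n_1-m)!\,(n_2-m)!\,(N-n_1-n_2+m)!},$$

evaluated in log-factorial space. Small values flag pairs sharing more
partners than chance expects; the table filters at $\alpha = 0.05$ on
raw p-values (matching the method's original usage) with
Benjamini-Hochberg q-values emitted as an extra column. $N$ is the
network protein count, not the full mined-entity count — the
interaction universe the neighbor counts live in. Note the method's
prose describes high p-values as significant, which contradicts its own
worked results (top associations at $p \approx 10^{-63}$); small-p =
significant is implemented.

# Stage 6: modules and their significance

A module is a connected induced subgraph containing at least one TF.
Enumeration follows the definition "all direct interactions of the
prioritized TFs": for each prioritized TF (top 50% of TFs by the active
strength scheme, configurable — the original cutoff is unstated), all
connected induced subgraphs of its ego network that contain the TF, of
sizes 3 up to a cap (default 8). Identical node sets are deduplicated.
Because the subgraph count is exponential in ego size, a per-TF guard
(default $10^5$) truncates enumeration with a logged warning; the
module table records whether truncation occurred.

The module score is the mean member node strength. The anchor-TF
p-value is an upper-tail hypergeometric,
$p = 1 - \sum_{i=0}^{k-1} \mathrm{pmf}(i)$, but the symbol list that
comes with it is internally inconsistent (it pairs module counts with
node totals and defines $k$ as "the module"). The package therefore
makes the parameter binding explicit and selectable, recording it in
every output:

* `"network"` (default, the symbols as listed): population $N$ =
  network nodes, successes $S$ = modules excluding the TF, draws $C$ =
  module size;
* `"modules"`: population = total modules, successes $I$ = modules
  containing the TF, draws $C$.

The threshold $k$ is taken as $I$, the observed number of modules
containing the anchor TF — the natural exceedance count to test. A
binding can be infeasible on a given network (e.g. more modules than
nodes under `"network"`); such modules get `NA` p-values with a warning
rather than aborting, and `NA` never passes the $p < 0.05$ filter.
Ranked output filters at $p < \alpha$ and sorts by score within each
size class, with a per-size count summary.

# Pathway enrichment

For a protein list of size $R$ against a pathway of size $n$ in a
background of $N$ genes with overlap $r$, the p-value is the
hypergeometric upper tail
$p = \sum_{i=\max(r,\,R+n-N)}^{\min(n,R)} P(i, n, R, N)$, computed in
log space; at the lower support bound the sum covers the whole support
and $p$ is exactly 1. The background defaults to the union of all
pathway genes (self-contained and conventional) and is overridable,
since the original analysis used the size of a licensed commercial
database that cannot be shipped. Functional groups come from an
optional label table; groups with more than 3 significant pathways are
*major*, with 3 or fewer *minor*, and groups with none are omitted.
Raw p-values decide significance (mirroring the original filter); BH
q-values are reported.

# The synthetic study conditions

All fixtures are pure functions of `(config, seed)`; each generator
draws from its own stream derived from the master seed by a stable
label, so adding a generator never perturbs the others.

The default corpus has 200 abstracts over a 30-gene thesaurus (6 TFs,
each gene with one synonym). Six planted pairs — a hub TF with three
interconnected partners plus two further TF-anchored pairs — are
co-mentioned in single-sentence relation statements in 15% of
documents each; every gene is independently background-mentioned in 5%
of documents; and a planted *null* pair matches the planted marginal
frequency while never sharing a document. These rates were chosen once
to emulate the regime the method targets: planted pairs co-occur an
order of magnitude more often than chance pairs, yet planted genes stay
rare enough that the idf factor does not extinguish their weights (a
gene mentioned in most documents scores near zero regardless of its
co-mentions — a real property of tf*idf worth preserving in the
fixture).

Annotations give each gene 6 GO terms; planted pairs share half of
them (pair-specific, accumulated for hub genes), guaranteeing
$d < 1$; other genes draw from a 40-term pool, so background pairs are
sometimes disjoint and genuinely fail the GO filter. TF genes carry one
term from the configured functionality list. Structures are CA-only
idealized helices written as PDB files: planted dimers sit 5 &Aring;
apart (inside the 6 &Aring; threshold), decoys 50 &Aring; apart; only
the geometric thresholds matter, so realism of the fold is explicitly
not attempted. Pathway collections plant one enriched set (about half
of its members drawn from the planted genes) among random pathways over
a 150-gene universe.

Network-level fixtures (`generateNetworkFixture`) plant signal directly
in a random graph: a hub TF with ~9 extra partners, 60% of them
interconnected, and high similarity/structural scores on its edges
(top-quartile values of all four features), and/or a three-node TF
clique whose members carry the highest strengths. These support the
recovery tests without paying the corpus-mining cost 100 times.

What the fixtures do **not** emulate: real linguistic variation
(negation, abbreviations, coordination), annotation bias and shallow
GO terms, crystallographic artefacts, or overlapping pathway
structure. Passing tests therefore demonstrate correctness of the
computations and recoverability of planted signal under clean
conditions, not performance on real literature.

# Problem sizes and numerical choices

The shipped tests verify the hypergeometric formulas exactly against
exhaustive enumeration for all parameter grids with $N \le 12$ and
against overflow-safe factorial-free products at $N = 10^4$ (relative
error below $10^{-9}$); topology against brute-force BFS path counting
on 200 random graphs of up to 12 nodes; module enumeration against
subset filtering on graphs of up to 10 nodes; hub recovery over 100
seeded network fixtures; enrichment calibration over 200 null pathway
collections; and full-pipeline determinism by re-running into the same
directory and comparing checksums. Upper-tail sums are computed
directly (not as $1 - \text{lower tail}$) to avoid cancellation, and
log-sum-exp is used for tail accumulation.

# Known limitations

* Dictionary NER only: no disambiguation, no abbreviation expansion.
* GO terms compared as annotated; no semantic similarity over the DAG.
* The default interface predictor is a deliberately simple
  physico-chemical heuristic; for serious structural work plug in a
  dedicated predictor.
* Module enumeration is exponential in ego size; the cap and guard
  bound it at the cost of completeness for very dense hubs (truncation
  is always reported).
* The module p-value formula is faithfully garbled; treat module
  p-values as a recorded, reproducible convention rather than a
  calibrated error rate, and prefer the module score for ranking.
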