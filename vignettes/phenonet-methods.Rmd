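---
title: "Methods: consensus differential expression, pathway overlap and phenotype networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus differential expression, pathway overlap and phenotype networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenonet)
```

## The problem

Transcriptome studies of the same disease tissue, run on different
microarray platforms and summarized by different normalization algorithms,
disagree on which genes are differentially expressed. `phenonet`
implements a conservative strategy for extracting a phenotype-specific
protein-interaction network from such a compendium: genes are called
differentially expressed only when two normalization routes and a
cross-dataset consensus agree; the resulting gene lists drive a gene-set
over-representation analysis; enriched pathways are linked into an overlap
network through shared differentially expressed genes (DEGs); the
phenotype's seed pathway plus its high-confidence interactors are
assembled into a core/shell protein-interaction network; and densely
interconnected protein complexes are detected in that network with an
MCODE-style algorithm.

## Consensus differential-expression calling

Every dataset is analyzed through two views: an *rma-like* view
(quantile-aligned log2 intensities) and a *mas5-like* view (linear-scale
intensities with present/absent detection calls). On the mas5-like view,
only genes with at least one present call in each group are analysed; the
others contribute a neutral call for that route, because the filter is a
precondition of that route's analysis only — the rma-like view still
speaks for the gene.

Per view, a gene gets a three-state call from a Welch *t* test (two-sided,
Welch–Satterthwaite degrees of freedom) and the linear fold change
case/control: `+` when FC ≥ 2 and p ≤ 0.05, `−` when FC ≤ 0.5 and p ≤
0.05, else `0`. Both thresholds are inclusive. We use a two-sided p; the
fold-change sign carries the direction of the effect.

Within a dataset the two routes combine into an evidence grade:
`[+,+]`, `[+,0]`, `[0,+]` (and the mirrored down grades), `none`, or
`conflict` for opposite signs. We deliberately keep the *orientation* of
single-route support — which route produced the `+` — because the
cross-dataset rule needs it: a gene is finally **up** iff

* some dataset shows `[+,+]`, or
* some dataset shows `[+,0]` and a *different* dataset shows `[0,+]`,

and no dataset shows any downregulation or a conflict. Two datasets that
both show `[+,0]` do **not** qualify: single-route support must come from
both routes across the compendium. Down is the mirror rule. A conflict
(`+` on one route, `−` on the other) conservatively blocks both final
calls. Genes absent from a platform are simply skipped by the rule.

Probe-level calls collapse to a gene by "any `+` and no `−`" (mirrored),
which mirrors the gene-level wording of the selection rules; a best-probe
collapse would be a reasonable alternative but is not what the rules
describe. The per-gene magnitude reported for network annotation is the
median across datasets of the rma-view log2 fold change — a single
published log2 value per gene does not fix an aggregation, and the median
is robust to one discordant dataset.

`stringency_counts()` implements the stricter "selected at least *k*
times by each algorithm" variant used to justify the *k* = 1 choice: at
*k* = 1 it provably coincides with the consensus rule, and counts are
non-increasing in *k*.

## Over-representation with EASE scores

Enrichment of a gene list in a catalog set is scored with the
hypergeometric upper tail (the one-tailed Fisher exact probability) and
with the EASE score, the same tail recomputed after removing one gene
from the observed overlap — the DAVID/EASE convention `P(X ≥ count − 1)`,
which penalizes terms supported by a single gene. Fold enrichment is
`(Count/List Total)/(Population Hits/Population Total)`. A term is
enriched iff EASE ≤ 0.05 **and** fold enrichment ≥ 1.5 (inclusive).
Selection uses the raw EASE score; Bonferroni and Benjamini–Hochberg
columns are reported for context only. The report's "Benjamini" column is
BH on the EASE score and "FDR" is BH on the unmodified Fisher tail; the
randomization-based FDR of some desktop tools is not reproducible and is
not attempted.

The background is configurable because the convention is genuinely
ambiguous: `"annotated"` (default) restricts Population Total to genes
carrying at least one catalog annotation, the convention of DAVID-style
tools; `"full-universe"` uses the whole platform union. Terms with zero
overlap are omitted from the report. Enriched terms in the categories
"human diseases" and "metabolism", and terms without protein–protein
interactions, are dropped before network construction: disease maps mix
causes and consequences of specific conditions, and metabolic maps
describe metabolite interconversions rather than protein signaling.

## Pathway-overlap network

For each catalog pathway, the *S-list* is its intersection with the union
of platform-measurable genes. Every unordered pair of pathways with at
least one process-tagged member (process–process allowed; a
signaling–signaling pair is not a candidate) is scored by the number of
up- and downregulated genes shared by the two S-lists; a pair becomes an
edge iff it shares ≥ 5 up **or** ≥ 5 down genes — the threshold applies to
each direction separately, never to the sum. Node size defaults to the
full pathway gene count (the `s_list` switch restricts it to measurable
genes, as it is not obvious which a rendered figure should use). No
statistical test is attached to the overlap counts; the raw threshold is
the method.

## Core/shell network assembly

The phenotype's seed-pathway proteins are the *core*. From a scored,
typed interaction table, only records with experimental evidence and
score ≥ 0.9 (inclusive) qualify. The network's nodes are the core plus
every node sharing a qualifying record with a core node (the *first
shell*); its edges are all qualifying records among those nodes —
shell–shell edges between first-shell nodes are retained, nodes reachable
only through shell nodes are not. The container is a mixed multigraph: a
pair may carry both an undirected binding record and a directed
activation/inhibition/PTM record, and the two are collapsed only by
`to_undirected_simple()`, which projects to a simple undirected graph for
topology summaries and complex detection.

Hub removal (`remove_node()`) deletes a node and its incident records; an
explicit `extra_edges` list reproduces curated removals that go beyond
the incident records (published bookkeeping can remove more edges than
the hub's degree; those extra removals are curation, not an algorithm,
so they must be supplied explicitly). Components are ordered by node
count, then edge count, then smallest node id — ties must be broken
somehow and the id rule keeps runs deterministic. Term-induced
subnetworks keep isolated members: in the full network they connect
through nodes outside the term union, and dropping them would misstate
the term's membership.

## MCODE-style complex detection

Vertex weight is the core-clustering coefficient times the core order:
for the closed neighborhood of *v*, take its highest *k*-core and set
`w(v) = k × 2E/(n(n−1))` of that core; vertices under the degree cutoff
get 0. Seeds are unvisited vertices in decreasing weight (ties by id);
greedy breadth-first expansion admits unvisited neighbors with
`w ≥ w(seed) × (1 − node_score_cutoff)`; complexes without a 2-core are
discarded; haircut iteratively removes members with intra-complex degree
< 2; fluff (off by default) may add dense-neighborhood boundary members.
All defaults (degree cutoff 2, node score cutoff 0.2, k-core 2, haircut
on, fluff off) follow the documented defaults of the MCODE v1.5.1 plugin,
since analyses that report using the plugin rarely state parameter
values. Scores are recomputed as density × size from the final node set.

## The synthetic-data generator

The generator exists so that every stage is testable with planted ground
truth and no downloads. It emulates: several independent two-group
datasets over one gene universe with per-dataset platform coverage
masking; log2 expression `Normal(baseline, sd)` with baselines
`Uniform(4, 12)` (a typical microarray dynamic range); planted up/down
genes shifted by ± `effect_log2` in cases wherever measured, with counts
fixed by `floor(n_genes × fraction)`; a mas5-like view derived from the
same latent signal plus independent log2 noise, so the two routes agree
imperfectly and the consensus rules actually bite; logistic
detection-call probabilities rising with within-sample expression
percentile (midpoint 0.25, slope 10 — low-intensity probes are mostly
absent, as in real detection calls); catalogs with planted enriched
sets loaded with a third of their slots from the true up-genes; and an
interactome whose background is Erdős–Rényi among shell nodes with
Beta(2, 5) scores, while attachment edges, planted complex edges and hub
edges draw from Beta(20, 1) conditioned into the qualifying (≥ 0.9)
region — attachment must survive score filtering or the first shell
would disintegrate, and planted complexes are defined as dense subgraphs
*among qualifying edges*.

The defaults for the reference study are 2,000 genes, 3 datasets, 5
cases vs 5 controls, effect 2 on the log2 scale against a within-group
sd of 0.5, full coverage — a small, strongly powered compendium. A
per-dataset effect-attenuation knob models between-study heterogeneity
but defaults to off, since the degree of heterogeneity in real
compendia is not well characterized.

What the generator does **not** emulate: probe-level PM/MM structure,
batch and array artifacts, correlated genes, realistic null fold-change
distributions. Passing the planted-recovery tests therefore demonstrates
the correctness of the selection logic under the stated statistical
model, not expected performance on real tissue data.

## Numerical and design notes

* Hypergeometric tails use the standard distribution functions in
  log-space; tests verify them against direct combinatorial summation to
  1e−12.
* Welch statistics are computed from the closed-form expressions and
  cross-checked against `stats::t.test(var.equal = FALSE)`.
* A zero pooled standard error with equal means yields t = 0, p = 1;
  with unequal means, the smallest representable positive p and a
  warning.
* All randomness flows from explicit integer seeds; equal seeds give
  byte-identical artifacts, including written files.
* Problem sizes in the tests and the acceptance script (2,000-gene
  studies, 12-term catalogs, 150-node interactomes, 25 replicate
  complex-recovery runs) were chosen as the smallest sizes at which the
  planted effects are unambiguous under the stated model.

## Known limitations

* The consensus rules are rule-based, not inferential: no moderated
  variance, no gene-level multiple-testing correction (raw p ≤ 0.05 by
  design), no effect-size shrinkage.
* The enrichment background conventions bracket, but cannot reproduce,
  the exact background of any specific desktop tool.
* Edge directions are taken from the interaction table as given; no
  direction inference is attempted.
* MCODE parameter defaults are assumed, not fitted; cluster counts are
  sensitive to them.
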