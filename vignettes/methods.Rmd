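---
title: "Methods: text-cube CaseOLAP scoring and knowledge-graph analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: text-cube CaseOLAP scoring and knowledge-graph analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caseolapr)
```

## The problem

A large share of what is known about the interplay between cardiac
calcium-regulating proteins, oxidative stress (OS), and cardiovascular
disease (CVD) is dispersed across bibliographic databases rather than
structured resources. This package turns a MeSH-indexed abstract corpus
into quantitative protein–disease association scores and a queryable
heterogeneous knowledge graph, following a text-cube / CaseOLAP design:
documents are grouped into (overlapping) disease-category cells by their
MeSH indexing, protein mentions are counted by dictionary matching, and the
resulting frequency matrix is converted into bounded association scores that
downstream analyses (PCA, clustering, graph queries, link prediction)
consume.

## Category membership

A MeSH descriptor carries one or more dot-delimited *tree numbers*
(`C14.280.067`); descent is positional, so the member set of a category with
root *r* is every descriptor having a tree number equal to *r* or starting
with `r.`. We deliberately use this dot-boundary string test rather than a
graph traversal: it is exactly how the MeSH hierarchy is encoded, requires
no separate parent table, and makes the expansion trivially idempotent and
monotone. The eight disease categories (CM, ARR, CHD, VD, IHD, CCS, VOO,
OHD) are defined by fixed root sets; OHD is a union of seven roots.

Documents are assigned to categories **by MeSH indexing only**, never by
matching disease names in text: the corpus definition is bibliographic, and
a document may legitimately sit in several cells. OS membership is a
per-phase flag (IOS/MOS/OOS) rather than a ninth category, because the
document- and protein-level overlap analyses cross OS phases *with* disease
categories. Documents carrying only OS descriptors are excluded from the
cube universe and reported.

The curated OS vocabulary cross-lists a small number of descriptors under
two subcategories (its per-phase counts add up to slightly more than the
number of unique descriptors). The loader keeps the first-seen
phase/subcategory and warns, so downstream phase counts are computed on
deduplicated descriptors.

## Mention detection

Mentions are found with a compiled dictionary matcher over the curated
primary names and synonyms: case-insensitive, at alphanumeric word
boundaries (a transition between `[A-Za-z0-9]` and anything else), with
longest-match-wins on overlapping spans. The boundary definition matters for
protein symbols ending in digits — `RyR2` must not match inside `RYR21` —
and hyphens inside synonyms match literally. Surface forms claimed by two
different proteins are rejected at load time, because a dictionary matcher
cannot disambiguate them. The matcher is implemented as a single
longest-first PCRE alternation with lookaround boundary guards, which gives
the same semantics as an Aho–Corasick automaton with leftmost-longest
resolution at the scale this pipeline works at.

Counting is per occurrence over `title + " " + abstract` by default (the
frequency-based popularity component expects occurrence mass); a binary
per-document mode is available as a switch because some deployments of
OLAP-style text scoring count document hits instead.

## CaseOLAP scoring

For protein $p$ and category $C$, with $tf(p,C)$ the aggregated occurrence
count and $total(C)=\sum_p tf(p,C)$:

$$Pop(p,C) = \frac{\ln(1+tf(p,C))}{\ln(1+total(C))},\qquad
rtf(p,C) = \frac{tf(p,C)}{total(C)},\qquad
Dist(p,C) = \frac{rtf(p,C)}{\sum_{C'} rtf(p,C')}$$

and the combined score is $S = Pop \cdot Dist \in [0,1]$. The published
description of CaseOLAP is verbal ("popularity" as within-category
frequency strength, "distinctiveness" as cross-category contrast, robust to
class imbalance); the exact normalisations are this package's own fixed
choice, isolated behind `compute_score_matrix()` so an alternative can be
swapped in. The choices are made to satisfy the verbal definition's
checkable consequences, which the test suite asserts: all three quantities
bounded in $[0,1]$; $S(p,C)=0$ exactly when $tf(p,C)=0$; distinctiveness
rows of mentioned proteins summing to 1; and — because $rtf$ is scale-free
in $total(C)$ — exact invariance of $Dist$ under $k$-fold replication of
any one category's documents, which is the class-imbalance robustness
property. Whether popularity should be normalised by the category total or
by the maximum per-protein frequency is not recoverable from the published
description; `popularity_denominator = "total"` is the default and `"max"`
is available as a configuration switch. Ranking ties are broken
lexicographically by protein id so all orderings are deterministic.

## Knowledge graph and association scores

The graph has four node types (protein, document, MeSH, pathway) and three
edge types (`mentions` with the occurrence count as an attribute, `assigns`,
`contains`). CaseOLAP scores are kept as a table beside the graph rather
than as a fourth edge type, mirroring the three-edge schema. Exports use the
graph-database bulk-import CSV dialect (`id:ID`, `:LABEL`, `:START_ID`,
`:END_ID`, `:TYPE`) and GraphML; both re-import to an identical graph, so a
live graph database is unnecessary for any analysis here.

Protein–OS *co-occurrence* is defined structurally, not textually: a
protein co-occurs with an OS molecule when some document both mentions the
protein and is assigned the molecule's descriptor. The OS-molecule score in
category $C$ is the arithmetic mean of $S(p,C)$ over co-occurring proteins;
the pathway score averages $S(p,C)\,(1-p)$ over the pathway's members
*restricted to the curated entity set* (reverse mapping), since only those
proteins carry scores. The pathway $p$-value is accepted as an input column
of the pathway table (an enrichment-style significance); it is not computed
here. Molecules or pathways with no supporting protein emit no row at all
rather than a zero score — presence in the output means support $\ge 1$
document (or member). By default co-occurrence is evaluated over the whole
cube universe; a `within_docs` argument restricts it to one category's cell
when a per-category reading is wanted.

Sunburst aggregation assigns each scored entity, as a leaf of its
vocabulary or pathway hierarchy, the sum of its scores over the categories
of interest (for example the ARR + CCS cluster); every internal node's
value is the sum of its children, so the root conserves the total leaf
mass exactly.

## Link prediction

Proteins and MeSH descriptors are never directly adjacent in this schema,
so the candidate universe is the full protein × MeSH product (asserted at
run time). Four common-neighbour measures are implemented —
common neighbours, Adamic–Adar, resource allocation, preferential
attachment — the topological similarity family that graph-data-science
toolkits offer for "closeness of a pair of nodes"; Adamic–Adar is the
default and the measure used is recorded in every output row. Degree-1
common neighbours are skipped in Adamic–Adar to avoid $1/\ln 1$; for
protein × MeSH pairs this cannot occur, because any common neighbour is a
document with edges to both endpoints. Scores are reported raw; rescaling
for heatmaps is a rendering concern. All four measures are checked against
an independent brute-force adjacency-matrix oracle, and Adamic–Adar
additionally against igraph's inverse-log-weighted similarity.

## Score-matrix analysis

PCA rows are restricted to scoring proteins; columns are mean-centred but
not variance-scaled, since all categories already share the $[0,1]$ score
scale. The sign of each component is fixed so its largest-magnitude loading
is positive. Clustering uses average linkage by default (a robust default
for bounded score profiles; complete and Ward are switches) on Euclidean
distances. The pairwise matrix backing heatmaps defaults to the
*correlation* between protein profiles: a $[-0.8, 1]$-style colour range is
meaningful for correlations but not for Euclidean distances, so the
dendrogram metric and the heatmap statistic are reported separately.
Constant profiles have no defined correlation; such pairs are recorded as 0
with a warning.

## The synthetic generator

The generator emulates what the analysis assumes about the real corpus and
nothing more: multi-membership category assignment (`p_multi_category`,
default 0.1), per-phase OS co-assignment (defaults 0.03/0.10/0.02 for
IOS/MOS/OOS, reflecting the dominance of modulation-phase literature),
document imbalance across categories (defaults proportional to the real
per-category publication counts, largest ≈ 11× smallest), and Poisson
per-document mention counts — the simplest count model consistent with
frequency-based scoring. Planted (protein, category) pairs draw
`Poisson(lambda_signal)` (default 2.0) against a background of
`Poisson(lambda_background)` (default 0.05). Mention counts are *realized
as surface forms in the abstract text* (primary names and synonyms shuffled
among filler tokens), so recovery tests exercise the matcher, the cube, the
aggregation and the scoring together, not just the arithmetic. It does not
emulate real English prose, MeSH indexing errors, or ambiguous synonymy —
so passing recovery tests demonstrates the pipeline's correctness under its
own assumptions, not robustness to noisy curation.

The `two_block` design adds the structure seen in real protein score
profiles: a heavy-tailed per-protein literature popularity
(lognormal, `sdlog = 1.5`) multiplying a base rate (1.0) in all categories,
with one block of proteins enriched (+0.5) in two focus categories
(ARR + CCS by default, 15 proteins) and a larger block enriched in the
remaining six (45 proteins). With this structure the first principal
component captures the shared popularity axis — an even, all-positive
combination of categories — and the second isolates the two-category
contrast, whose two dominant loadings identify the focus block. A share-
space argument shows why the popularity axis is needed: because the
distinctiveness of each protein sums to 1, a pure two-block design puts the
2-versus-6 contrast on PC1 with the two focus categories always dominating
its loadings. For repeated-simulation studies the generator also offers
`generate_count_matrix()`, which draws `tf(p,C) ~ Poisson(n_docs(C) ·
λ(p,C))` directly — the same marginal law that text realization, matching
and aggregation induce — so a 100-run PCA study costs seconds; single runs
of the full text pipeline are used wherever the matcher itself is under
test.

Problem sizes used by the packaged simulations: recovery runs use 8
categories × 200 documents (1600 abstracts), 100 proteins, 10 planted per
category; PCA structure-recovery uses 100 seeded two-block count-model runs
of 60 proteins × 8 categories × 150 documents. These sizes give stable
results (precision@10 of 1.0 and PC2 identification rates of 100/100 across
seeds) while keeping any single study under a few seconds.

## Numerical and degenerate-input choices

* `log1p` guards zero counts in popularity; empty categories score 0.
* An all-zero protein has distinctiveness identically 0 (not 1/8).
* Duplicate corpus records keep the first occurrence with a warning;
  unparseable or id-less records are hard errors naming the line.
* Pathway parent links are checked for cycles at load; p-values outside
  $[0,1]$ are rejected.
* Sunburst conservation is exact (same additions in tree and flat order for
  dyadic test values; floating-point associativity is the only caveat for
  arbitrary inputs).
* All stochastic behaviour flows from a single integer seed per
  configuration; the full pipeline is reproducible byte-for-byte.

## Known limitations

* Dictionary matching cannot resolve genuinely ambiguous synonyms; they are
  rejected at load rather than guessed at match time.
* The packaged vocabularies are synthetic stand-ins with the curated lists'
  counts and structure, not transcriptions of NLM/UniProt records; analyses
  of real corpora should supply real vocabulary tables in the same CSV/TSV
  layouts.
* Scores are computed from title + abstract only; full-text mention mass is
  out of scope.
* Link prediction here is purely topological; no edge-split evaluation or
  learned embeddings are provided.
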