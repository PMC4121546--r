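---
title: "Methods: entity networks, fuzzy retrieval and walk-based evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entity networks, fuzzy retrieval and walk-based evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litnet)
```

`litnet` turns a corpus of biomedical abstracts into a weighted entity
network, exposes it to fuzzy boolean querying with ranked article
provenance, and evaluates such networks with heuristic random walks
scored against a MeSH-style taxonomy. This vignette documents the
model, the tunable parameters and their defaults, the numerical
conventions, and what the shipped synthetic data can and cannot
establish.

## 1. From text to basic statements

Abstracts enter either as Medline XML (`read_medline_xml()`) or as one
plain-text file per abstract (`read_plaintext()`). Sentences are
segmented by a deterministic rule-based splitter with a biomedical
abbreviation exception list ("e.g.", "et al.", "Fig.", ...). A
rule-based splitter was chosen over a statistical one because the
downstream arithmetic depends only on sentence *numbers*, and
determinism makes every score reproducible from the raw text. Token
counts (for corpus statistics) are whitespace-delimited strings
containing at least one alphanumeric character after stripping
surrounding punctuation; the source method never specifies its
tokenizer, so absolute token counts are reproducible only relative to
this definition.

Entity mentions are produced by a pluggable extractor
(`extractor_config()`): a gazetteer with longest-match-wins semantics,
a naive noun-phrase chunker, or externally supplied TSV annotations.
The original pipeline used a statistical NER trained on a biomedical
corpus; that model is not reproducible, so the package decouples the
numerics from the extractor and tests everything on known mention
positions. Two conventions matter numerically: mentions count with
multiplicity (a term appearing twice in one sentence contributes two
pairs), and a shorter dictionary term inside a longer matched span is
not emitted — both are forced by the published worked arithmetic.

Per document, each unordered entity pair receives

$$cooc(x, y) = \sum_{(i,j)\,:\,|i-j| \le w} \frac{1}{|i-j| + 1}$$

over all mention position pairs, with window $w = 3$ sentences. Both
the kernel and the window are parameters of `cooc_params()`; the
defaults are pinned by the worked example, in which a distance-3 pair
contributes 1/4 while a distance-4 pair is dropped. No per-pair cap or
abstract-length normalisation is applied — the worked totals
(3.41666..., 3.25) show no evidence of either.

## 2. The corpus-wide knowledge base

Basic statements aggregate into the co-occurrence layer via
frequency-scaled pointwise mutual information:

$$fpmi(x,y) = F(x,y)\,\log_2\frac{p(x,y)}{p(x)\,p(y)},\qquad
p(x,y) = \frac{joint(x,y)}{|T|},\; p(x) = \frac{marg(x)}{|T|}$$

where $joint$ sums the pair's per-document scores, $marg$ sums over
*all* statements containing the term (joint ones included), $F$ is the
pair's document frequency and $|T|$ the total number of basic
statements. Normalising each distribution by $|T|$ is essential: with
raw sums inside the log the published example yields a negative value,
while the $|T|$-normalised form reproduces the printed 0.545 exactly
(the package verifies this in its acceptance suite).

Non-positive scores are filtered (they indicate disassociation); the
rest are divided by the nearest-rank 95th percentile of the positive
scores and clipped at 1, so roughly 5% of the scores saturate. The
percentile $P$ is a parameter; nearest-rank was chosen because it maps
a printed "a non-normalised score such that only 5% of the scores are
higher" directly onto an order statistic.

The similarity layer computes cosine similarity between co-occurrence
context vectors (each term's vector of aggregated co-occurrence
weights) and keeps pairs at or above 0.25. Candidate generation is
blocked on shared components, which is exactly lossless for positive
cosine. Norms are taken over full vectors even when small components
(< 0.01) would be suppressed in display — the published dot product
exceeds the visible-component sum, confirming this convention.

## 3. Indices and fuzzy querying

Three sparse matrices (`build_indices()`) expose the knowledge base:
the symmetric term index (max statement weight per pair, zero
diagonal), the binary term–statement incidence, and the
statement–source provenance matrix whose nonzero entries equal the
statement weight. Statement identifiers are the literal
`term_a|relation|term_b` string: stable across rebuilds and
self-describing; a cryptographic hash would add a dependency without
adding a property the contract needs.

One documented divergence: in the published toy example the text lists
a third source for the similarity statement while the printed
provenance matrix leaves it zero. The implementation follows the
textual rule (every listed source receives the statement weight); the
shipped fixture lists exactly the two sources that reproduce the
printed matrices entry-for-entry.

Atomic queries are resolved through a lemmatised full-text lookup: a
conservative plural stemmer (strip final "s" except after
"ss"/"us"/"is", "ies" to "y") plus trailing-`*` prefix wildcards and
boolean combinations inside the lookup string. No stemming library is
required; the contracted behaviour is exactly the unification of
singular/plural variants ("parkinsonism" matches "parkinsonisms").
Note that `NOT` inside a lookup is stem-aware like any other atom.

Query trees (`parse_query()`, precedence NOT > AND > OR) evaluate with
max/min/1−x fuzzy logic over the universe of indexed terms. The
result-term set, truncated to its top `k` terms (default 5), expands
to statements by a normalised dot product with the statement index:
with two terms per statement and normalisation 1/2 this is the
arithmetic mean of the two term degrees, which reproduces the printed
degrees 0.852 and 0.695 exactly and reconciles the "normalised dot
product" formula with the "arithmetic mean" gloss. The top statements
(default 7) expand to sources by a dot product with the provenance
index, normalised by the maximum.

## 4. Entity graphs and related articles

`build_entity_graph()` collapses relation types: one edge per term
pair, weight the maximum statement weight. The MeSH baseline graph
connects each document's annotated terms into a weight-1 clique.

The related-article index scores an entity pair by the best path of at
most 3 edges between them (weight = product of edge weights), then
propagates that weight to every pair of their source articles,
aggregating by maximum and pruning below 0.1. Because all weights are
at most 1, a walk revisiting a node can never beat the simple path
obtained by excising its cycles, so the package computes the exact
simple-path maximum with (max, ×) matrix products — verified in the
test suite against an exhaustive DFS path-enumeration oracle on random
graphs. "Length three" is read as three *edges*, matching the
displayed path shape; it is configurable.

Graph statistics use hop-based (unweighted) shortest paths; diameter
and average path length are computed per connected component and
averaged weighted by component size in nodes. Hop counts are
consistent with the magnitudes the method reports on real corpora
(average path lengths near 3 on small-world graphs).

## 5. Taxonomy similarity and random-walk evaluation

`load_mesh()` reads descriptor data (ASCII `MH`/`ENTRY`/`MN` records
or descriptor XML) into a term-to-tree-code map with a lemmatised
lookup. Free-text entities are assigned clusters by exact lemmatised
match, falling back to the longest contiguous token n-gram with a
match. Specific clusters are the matched codes; abstract clusters are
their top-level segments.

Similarity of two code sets is the maximum over code pairs of

$$sim(c_x, c_y) = \frac{2\,depth(LCS)}{depth(c_x) + depth(c_y)}$$

with the least common subsumer the longest shared segment prefix. The
maximum (not mean) over pairs follows the worked example, which
selects the only pair "with anything in common".

Walks order the current node's neighbours by one of four heuristics —
unvisited-first, heavier-edge-first, more-similar-first,
less-similar-first — with ties broken by node name so a fixed seed
gives bit-identical batches. The sorted list is scanned with
acceptance threshold starting at $e_i = 0.9$ and decaying
geometrically ($e \leftarrow e \cdot e_i$) on each rejection; if
nothing is accepted a uniform neighbour is drawn. For two neighbours
this gives P(head) = 0.9 + 0.1·(1−0.81)/2 = 0.9095, which the test
suite verifies by Monte-Carlo.

Twenty measures (A–T) score each walk: source–target, product, and
average step coherence (the average divides the sum of the $n-1$ step
similarities by the $n$ *nodes*, as printed — a deliberate fidelity
choice, flagged because it is not the natural mean); base-2 entropies
of abstract/specific cluster membership over path and envelope, and of
biconnected-component membership in the envelope subgraph; envelope
size, biconnected-component count and mean size, and mean local
clustering coefficient (degree < 2 contributes 0); and cluster
count/size statistics. Degenerate conventions: a single-node walk has
product coherence 1 (empty product) and average coherence 0; zero
clusters give entropy 0. The envelope of radius $r$ is the union of
hop-$r$ balls around path nodes.

`run_simulation_batch()` runs the full grid (4 heuristics × lengths
2/5/10/50 × radii 0–2, 100 repetitions in the reference setting) from
uniformly sampled start nodes and reports arithmetic means per
combination; the acceptance suite scales repetitions to 10 on a
200-node graph to stay within its time budget while still exercising
all 48 combinations, and checks bit-identical reruns under a fixed
seed.

Related-article indices are compared to a gold standard by average
precision and recall over shared keys (lists truncated to a top-k) and
by Pearson correlation of the ranks of articles present in both lists
(at least two shared items required; the reported fraction counts keys
with correlation ≥ 0.7).

## 6. Synthetic data: what it emulates, what it does not

`synthetic_corpus()` plants entity groups into templated
multi-sentence abstracts: 40 documents, 4 groups of 6 entities, 8
sentences, within-group mention rate 0.3 and cross-group rate 0.05 by
default. These sizes give each group enough co-mentions for a stable
positive-fPMI core while keeping full-pipeline tests under a second;
the rates encode the assumption that topical entities co-occur an
order of magnitude more often within a topic than across.
`synthetic_taxonomy()` places each group in its own top-level subtree,
and `synthetic_community_graph()` produces a planted-partition graph
(within-community edges 0.5–1, cross 0.01–0.5) with a matching
taxonomy. All generators are bit-reproducible under a seed.

The synthetic world does *not* emulate: real NER noise and boundary
ambiguity, skewed document lengths, polysemy, MeSH's depth and
synonym richness, or the heavy-tailed degree distributions of real
entity graphs. A green test therefore establishes algorithmic
correctness (the implementation computes the stated quantities) and
qualitative behaviour (e.g. similarity-preferring walks are more
coherent than dissimilarity-preferring ones on community structure),
not performance on real corpora — the published corpus-scale tables
require the original external data and are out of scope.

## 7. Numerical choices and known limitations

- fPMI of a pair whose score equals all its marginals is
  $\log_2(1/w)$: zero exactly at $w = 1$. A single-statement corpus is
  filtered out whenever its score exceeds 1 (negative fPMI); scores
  below 1 would survive. This edge case follows directly from the
  formula and is tested as such.
- Percentile: nearest-rank (ascending sort, index
  $\lceil P/100 \cdot n\rceil$); ties and duplicates therefore behave
  like order statistics, not interpolation.
- The similarity threshold (0.25), prune threshold (0.1), path cap
  (3 edges), top-k defaults (5 terms, 7 statements), acceptance base
  (0.9) and percentile (95) are all exposed as parameters with the
  reference values as defaults.
- The plural stemmer under-normalises (no derivational morphology) by
  design; supplying a dictionary that maps variants is the supported
  route for richer unification.
- Entity graphs are kept dense-matrix-sized in the related-article
  closure; for corpora with tens of thousands of entities a sparse
  (max, ×) implementation would be needed.
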