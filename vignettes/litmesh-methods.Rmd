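---
title: "Methods: literature-driven MeSH prioritisation and expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literature-driven MeSH prioritisation and expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litmesh)
```

## Scope and model

`litmesh` links three layers of biomedical evidence. The *literature
layer* is an ordered corpus of publication records (PMID, title,
authors, journal, ISO date, MeSH headings, linked GEO series and
platform accessions); order is taken from the retrieval source and
never recomputed, since relevance ranking is a property of the search
engine, not of this package. The *vocabulary layer* is the MeSH
hierarchy, modelled as a forest of dot-separated tree numbers in which
one descriptor may occupy several positions. The *expression layer* is
one GEO-style series held as the triplet pdata (sample phenotypes),
edata (probe-by-sample matrix) and tdata (probe-to-gene dictionary).

## MeSH structure conventions

Depth is the number of dot-fields of a tree number (`C04` has depth 1);
a virtual root at depth 0 sits above the category codes so that every
pair of descriptors is connected. For a multi-placement descriptor,
specificity uses the deepest placement, while the lowest common
ancestor and the shortest path optimise over all placement pairs —
the standard resolution in ontology similarity work. The path length
between two descriptors is

$$ l(a,b) \;=\; \min_{p_a, p_b} \big[ d(p_a) - d(\mathrm{lca}) \big] +
   \big[ d(p_b) - d(\mathrm{lca}) \big], $$

with $d(\cdot)$ the depth and the lca the longest common prefix of the
pair (depth 0 across categories). On a single-placement forest this is
the graph metric of the tree; with multiple placements it is a
semi-metric — the minimisation is applied only at the endpoints, so
the triangle inequality through a multi-placement intermediate term can
fail. The tests therefore check metric properties on single-placement
trees and check equality against a breadth-first-search oracle (plus
symmetry) on multi-placement trees.

Qualifiers (subheadings) are not modelled; prioritisation and
similarity operate on descriptors only, which is how the headings are
consumed downstream.

## Three-criteria prioritisation with Robust Rank Aggregation

The corpus's term universe (as descriptor UIs) is ranked three times:

* **specificity** — deepest placement, descending: deeper terms carry
  more information;
* **local abundance** — number of distinct corpus records annotated
  with the term, descending;
* **global abundance** — database-wide frequency from a background
  table, *ascending*: globally rare terms are more topic-discriminative.

The three directions implement a TF-IDF-like notion of "specific,
topic-enriched, globally rare". The hierarchy direction for global
abundance is a documented package choice; with the opposite direction
the aggregation would reward ubiquitous headings such as "Humans".
Ties are always broken by descriptor name ascending so every ranking
is fully deterministic. Terms are aggregated as UIs and reported with
their preferred names; terms missing from the background are imputed at
the background median and reported.

A term at 1-based position $i$ in a list of size $N$ has normalised
rank $r = i/N$; a term absent from a list gets the conservative worst
rank $r = 1$. With the term's ranks sorted ascending,
$r_{(1)} \le \dots \le r_{(n)}$ over the $n=3$ lists, the beta-score is
the exact upper binomial tail

$$ \beta_k \;=\; P\!\left( X \ge k \right), \qquad
   X \sim \mathrm{Binomial}\!\left(n,\, r_{(k)}\right), $$

the probability that at least $k$ of $n$ uniform null ranks fall at or
below $r_{(k)}$. The score is $\rho = \min_k \beta_k$, Bonferroni
corrected over the $n$ order statistics:
$p = \min(1,\, n\rho)$. Tails are computed exactly with `pbinom`
(no normal approximation; $n \le 3$ here), and the tests verify
agreement with a direct mass-summation oracle to $10^{-12}$ and
conservativeness of $p$ under $10^5$ uniform null draws.

## Semantic similarity

Six measures, all normalised to $[0,1]$ and interpreted as the
probability that two terms (or term sets) are similar, with 0.5 the
conventional inclusive significance threshold. $l$ is the path length
in edges, $h$ the lca depth, $D$ the tree's maximum depth:

| measure | form | identity |
|---|---|---|
| shortest path | $1 - l/(2D)$ | 1 |
| weighted link | $1 - L/L_{\max}$, edge into depth $d$ weighs $2^{-d}$, $L_{\max}=2\sum_{d\le D}2^{-d}$ | 1 |
| Wu–Palmer | $2h / (d_a + d_b)$ over the lca-maximising pair | 1 |
| Leacock–Chodorow | $-\ln\!\big[(l{+}1)/(2D)\big] \,/\, \ln(2D)$ | 1 |
| Li | $e^{-\alpha l}\tanh(\beta h)$, $\alpha=0.2$, $\beta=0.6$ | $\tanh(\beta d) < 1$ |
| Lord (IC) | $\mathrm{IC}(\mathrm{MICA}) / \max\{\mathrm{IC}(a), \mathrm{IC}(b)\}$ | 1 |

The normalisation denominators are package choices: the upstream
formulations fix only that scores land in $[0,1]$. Leacock–Chodorow
counts the path in nodes ($l+1$) so the identity case is finite and
maps to exactly 1. For Lord, information content is
$\mathrm{IC}(c) = -\ln\big[\mathrm{cum}(c)/\mathrm{total}\big]$ over a
table of *cumulative* occurrence counts (each node's mass includes its
descendants'; `ic_cumulative()` builds this from raw counts), the MICA
is the common ancestor maximising IC, and the pairwise denominator
$\max\{\mathrm{IC}(a),\mathrm{IC}(b)\}$ was chosen over a table-global
maximum because it is the only normalisation that keeps the identity at
exactly 1 for every term while preserving the $[0,1]$ bound (cumulative
counts are monotone along the hierarchy) and invariance to rescaling
the whole table. Li's identity value saturating below 1 is inherent to
that measure and documented rather than patched.

Set-versus-set comparison uses the best-match average
$\big(\sum_{a} \max_b s(a,b) + \sum_b \max_a s(a,b)\big) / (|A|+|B|)$,
the standard choice for ontology term sets; unresolvable terms are
excluded and reported, and an empty set after resolution is an error.

## Expression handling

Series-matrix parsing accepts the bang-prefixed metadata dialect with
the expression table between the table-begin/table-end markers;
non-numeric cells become missing values with a warning. Probe-to-gene
collapse uses the arithmetic mean of a gene's probes (missing values
excluded cell-wise); median and strongest-probe (max variance)
collapses are available as options, but the mean is the default
because it is the most common rule and preserves per-sample totals up
to probe multiplicity. Values are taken as deposited — no
re-normalisation or log-state detection is attempted.

Sample stratification is lexicon-based: each sample's phenotype values
are concatenated and matched case-insensitively against group keyword
lists (`default_lexicon()` ships cancer {tumor, tumour, cancer,
carcinoma, malignant, metasta} and normal {normal, control, healthy,
benign, adjacent}); the group with most keyword occurrences wins, ties
and zero hits give "unknown". This is deliberately simple and
transparent; free-text phenotype fields in real series can defeat any
keyword list, which is why the assignment, not just the flag, is
written out for inspection.

PCA is computed by singular value decomposition of the
gene-mean-centred matrix without gene scaling (z-scoring is its own
explicit step); missing values are gene-mean imputed and counted.
Component signs are fixed by making each component's
largest-magnitude loading positive, so scores do not flip across runs.
Sample clustering is agglomerative with Euclidean distance and
complete linkage (overridable); samples are sorted by name before
clustering so the merge tree cannot depend on column order. The
z-score step sets constant or under-observed rows to zero with a
warning rather than propagating NaN.

## Gene network

Nodes are the literature-associated genes with their association
scores, consumed as supplied by the linkage source (fixture or live
adapter) — the package never recomputes them, it only uses them for
ordering and display. Edges are exactly the induced subgraph of the
scored interactome on the node set, carrying the interactome
confidence score, with self-edges dropped and endpoints stored in
lexicographic order. Each edge is annotated with its co-citation
count — the number of corpus publications whose annotated gene set
contains both endpoints. The count is left raw (no rate normalisation
is defined without a denominator convention) and is emitted alongside
the interactome score; combining the two is left to the consumer.

## Synthetic bundle: what it emulates, and what it does not

`generate_fixtures()` emits, from one seed, a mutually consistent
bundle: vocabulary TSV, JSON-lines records, background frequencies, a
series-matrix file, a platform dictionary, an interactome, per-record
gene annotations and association scores. Its defaults are the study
conditions used throughout the tests and the acceptance script:

* vocabulary of 60 descriptors over 3 categories, depth 5, with ~15%
  multi-placement descriptors;
* 5 planted topic terms placed at maximum depth, carried by 80% of the
  30 records, with background counts of 10–100 against 10^4^–10^6^ for
  filler terms — i.e. simultaneously deep, topic-enriched and globally
  rare, the signature the prioritisation is built to detect;
* an expression series of 40 genes × 3 probes each over 100 samples
  (50 cancer / 50 normal — the scale of a mid-sized clinical series),
  unit-variance Gaussian noise, and a 2.0-sd group shift planted on 10
  genes;
* a 60-edge interactome over the annotated genes plus a few
  off-corpus genes, with uniform scores in [0.1, 1].

The sample size matters for the variable-gene recovery property: with
a 2-sd shift the planted genes' population variance is roughly double
the background, and ~50 samples per group are needed before variance
*estimates* separate the two groups reliably; this is a property of
the statistic, not of the implementation.

The generator emulates structure, not biology: headings are drawn
independently rather than co-occurring by topic, expression noise is
homoscedastic Gaussian with no batch structure, probe effects are
small and additive, and the interactome is uniform random rather than
scale-free. Passing tests therefore demonstrate correctness of the
computations and recoverability of planted signals under clean
conditions — not performance on real corpora or arrays.

## Numerical and degenerate-input choices

* Beta-scores via exact binomial tails; rank components validated to
  lie in (0,1].
* All similarity scores floored/capped into [0,1]; disjoint-category
  pairs score 0 under lca-based measures.
* Zero-variance rows: z-score 0 with a warning. Empty edge sets,
  corpora without headings, unmappable probes: explicit errors or
  reported exclusions, never silent drops.
* Ties everywhere break by name (descriptors) or sample/gene label,
  making every output byte-deterministic for a fixed seed; the
  end-to-end run is tested for byte-identity across invocations.

## Known limitations

* Live NCBI/GEO retrieval is behind the fetcher/file contracts but no
  network client ships; record order must be supplied by the caller.
* The exact numeric variants of the six similarity measures in other
  implementations differ in their normalisations; scores here satisfy
  the stated range, identity and threshold semantics but are not
  guaranteed to match other tools to the digit.
* The measured problem sizes (vocabularies of tens of descriptors,
  corpora of tens to a hundred records, one series of ~100 samples)
  are the package's test conditions; all algorithms are polynomial and
  scale to real MeSH (~30k descriptors) but placement-pair
  minimisation is quadratic in placements per descriptor pair.
* Tumour-purity and molecular-subtype classification are out of scope;
  the cancer/normal flag exists to support such downstream analyses,
  not to replace them.
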