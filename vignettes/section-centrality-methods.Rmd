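---
title: "Methods: ranking taxonomic sections by directed network centrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking taxonomic sections by directed network centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcrank)
```

## The problem

Genome-mining screens of a fungal genus yield, per genome, counts of
predicted natural-product features: backbone-enzyme classes of
biosynthetic gene clusters, putative metabolites with a percent sequence
match to known clusters, and candidate antimicrobial peptides (AMPs) with
free-text annotations. Individual genomes are noisy and unevenly sampled;
the informative unit of comparison is the infrageneric *section*, a
taxonomic grouping of related species. `bgcrank` formalizes "which
sections are the most promising producers, and which feature categories
are most broadly shared" as a centrality question on a small weighted
directed bipartite network.

## Model and procedure

**Aggregation.** For an analysis-specific count table $x(i, c)$ (species
$i$, feature category $c$) and a species-to-section map, the section
matrix is

$$w(s, c) = \frac{1}{n_s} \sum_{i \in s} x(i, c),$$

where $n_s$ is the number of species *assigned* to section $s$. Species
with no recorded count for a category contribute zero to the numerator
but stay in the denominator: the average is over the section's species,
not over its observations. The alternative (observed-only denominators)
would systematically inflate sparse sections, the opposite of what a
prioritization should do. `section_average()` is linear in the counts and
satisfies $w(s,c)\, n_s = \sum_{i \in s} x(i,c)$ exactly; both properties
are enforced by tests.

**Graph.** Each section and each category with at least one positive cell
becomes a node; every positive cell becomes one directed edge
$s \to c$ with weight $w(s, c)$. Zero cells produce no edge, and all-zero
categories are dropped by default (`keep_isolated = TRUE` retains them as
isolated feature nodes, which then share the uniform teleport mass).

**Strength.** $k_{out}(v)$ and $k_{in}(v)$ are the summed weights of the
edges leaving and entering $v$; in the bipartite layout feature nodes
have $k_{out} = 0$ and section nodes $k_{in} = 0$, and the two totals
balance globally.

**PageRank.** `pagerank()` computes the stationary distribution $\pi$ of
the damped random walk: from a node with out-edges the walker follows
edge $(v, u)$ with probability $w(v,u) / k_{out}(v)$; from a dangling
node (every feature node here) it jumps uniformly over *all* nodes; with
probability $1 - \alpha$ it teleports uniformly. Without the dangling
completion the bipartite chain would absorb all mass in the feature
layer, so uniform redistribution — the standard completion — is not
optional here.

**Broadcasting and receiving.** Receiving centrality is $\pi$ on the
graph as built: a feature is important when important sections point at
it with heavy edges. Broadcasting centrality is $\pi$ on the
edge-reversed graph: a section is influential when it points at strongly
receiving features. Operationalizing the broadcasting/receiving pair as
PageRank on the reversed versus original graph is an interpretation —
the terminology originates in work on directed communicability that gives
no PageRank formula — but it is the standard PageRank analogue and yields
the exact duality `broadcast(G) == receive(reverse(G))`, which the tests
assert on random graphs as an identity (same code path).

**Normalization and ranking.** Raw scores are min-max normalized to
$[0, 1]$ *within* the section nodes and *within* the feature nodes. The
per-class choice mirrors how the two node classes are read: each class is
displayed and ranked on its own axis, and in a pure bipartite graph the
off-role scores (receiving of sections, broadcasting of features) are
structurally constant and carry no signal — they normalize to all-zero
with a warning rather than fabricating a ranking. Ranks are assigned per
(class, measure) by descending raw score, ties broken by ascending label,
so rankings are total and deterministic.

## Binning and keyword rules

*Metabolite similarity split.* Hits are split at 75 percent match,
threshold inclusive in the high class.

*AMP percent-match bins.* Six bins — exactly 100, then 99.9–95.0,
94.9–90.0, 89.9–80.0, 79.9–70, 69.9–51.0 — implemented as half-open
intervals $[\ell, u)$ with an exact top bin, so a value like 89.95 that
falls inside a printed label gap is still decidable. Values strictly
below 51.0 (i.e. 50.9 and lower) are excluded, and the exclusion count is
always reported: silent drops would bias every downstream average.
Scheme validity (pairwise disjoint, full coverage of the retained range)
is checked on construction on a 0.01 grid, finer than the one-decimal
resolution of the data.

*Keyword categories.* Free-text annotations are matched case-insensitively
against ordered substring patterns; the first matching category wins and
unmatched annotations fall to a fallback label. Assignment of free text to
categories is not algorithmically canonical, so the scheme is explicit,
ordered and shipped as editable YAML (`inst/extdata/default_config.yaml`).
Top-$k$ annotation lists exclude the fallback category by default
(a flag restores it), and the per-species hypothetical-protein fraction
is undefined — absent, not zero — for species without hits. The
`amp_keywords` recipe restricts hits to at least 95 percent match before
categorization by default, matching how high-confidence annotation
summaries are usually drawn; `restrict_keywords_high_match = FALSE`
disables the restriction.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `damping` | 0.85 | Probability of following an edge vs teleporting; the canonical PageRank value, configurable because no principled alternative exists for these small dense graphs. |
| `tolerance` | 1e-10 | L1 stopping residual of the power iteration; far below the 1e-8 agreement demanded against a dense solve. |
| `max_iterations` | 1000 | Safety cap; non-convergence is an error carrying the last residual, never a silent partial answer. |
| `threshold` | 75 (%) | Metabolite similarity split point. |
| `high_match_cutoff` | 95 (%) | Restriction for keyword analyses. |
| `binarize` | `FALSE` | Replace weights by 1 in the PageRank step only, for sensitivity analysis; strengths always report true weights. |

PageRank is invariant to uniform rescaling of the weights (transition
probabilities are ratios), so only the *relative* section profile matters;
strengths scale linearly and carry the absolute magnitudes.

## The synthetic generator

The generator emulates the statistical shape of predictor output, not the
predictors: per-(species, category) counts are independent
Poisson($\lambda$) with $\lambda$ = `base_rate`, multiplied by
`effect_multiplier` $\ge 1$ in one planted section; each counted event
becomes a hit with a percent match drawn from a configurable distribution
(uniform on $[0, 100]$ by default, rounded to one decimal to match the
resolution of the bin edges) and an annotation drawn from a weighted
keyword pool. Each table draws from its own stream derived from the
master seed by a fixed offset, so generating the hit table never perturbs
the count draws.

Defaults are chosen once as a realistic genus-scale screen: 5 sections of
5 genomes (about the 26 genomes available for a well-sampled fungal
genus), 10 backbone categories, `base_rate = 4` (tens of predicted
clusters per genome spread over the classes), and a keyword pool
dominated by "hypothetical protein" (weight 0.5), reflecting how
uncharacterized proteins dominate real annotation screens.

What the model deliberately omits: overdispersion (real per-genome counts
are likely super-Poisson; a negative-binomial option would be the natural
extension for power studies), phylogenetic correlation between related
species, uneven section sizes, and any dependence of match percent on
category. Passing tests therefore demonstrate correctness of the
aggregation-and-centrality machinery under a known signal, not predictive
validity on real genomes.

## Numerical and degenerate-case choices

- Power iteration stops on the L1 residual; the returned vector is
  renormalized to sum exactly 1 and carries iteration count and final
  residual as attributes.
- Agreement with an independent dense linear solve
  $(I - \alpha M^\top)\pi = \frac{1-\alpha}{n}\mathbf{1}$ (dangling rows
  made uniform) is required to $10^{-8}$ on 100 random graphs of up to 8
  nodes.
- Degenerate min-max ranges map to all-zero with a warning: no variation,
  no ranking signal.
- Empty inputs fail loudly and early: an empty section matrix (e.g. the
  high-similarity recipe applied to hits that are all low-similarity)
  raises an error naming the pipeline stage, and partial output files are
  removed.
- The canonical TSV dialect forbids tabs and newlines inside fields, so
  write-then-read is the identity on valid tables; pipeline runs on
  identical inputs are byte-identical (the run manifest contains a config
  hash and no timestamps).

## Problem sizes in the test suite

The suite exercises the solver on 100 random directed weighted graphs of
2–8 nodes against the dense oracle, 50 graphs for the reversal duality,
a 0.1-grid sweep of the binning rules over $[0, 100]$, 100 random count
tables for the section-average identity, and 100 simulated screens
(4 sections × 5 species × 10 categories, `base_rate` 2, 5-fold planted
enrichment) for planted-signal recovery, requiring the planted section to
top the broadcast ranking in at least 95 of 100 runs. These sizes give
stable pass/fail behavior at sub-minute runtimes and match the scale of
the scientific use case, where graphs have tens of nodes.

## Known limitations

- Broadcasting/receiving as reversed/original PageRank is an
  interpretation (documented above), not the only possible
  operationalization of those terms.
- Per-class min-max normalization is likewise an interpretation of how
  paired bar panels are normalized; a joint-normalization mode would be a
  small extension.
- The package does not parse native predictor output (antiSMASH
  JSON/GenBank regions, raw AMP predictor tables); converters to the
  canonical TSV dialect are thin, deliberately separate adapters.
- Row order of heatmap-style matrices follows the taxonomy file; no
  phylogeny is computed or used for ordering.
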