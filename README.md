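# bgcrank

Comparative genome-mining screens of a fungal genus produce, for every
genome, tables of predicted natural-product features: counts of
biosynthetic backbone-enzyme classes (T1PKS, NRPS, terpene synthases, ...),
putative metabolite hits carrying a percent sequence match to known gene
clusters, and candidate antimicrobial peptides (AMPs) with free-text
functional annotations. The scientific question is comparative: **which
taxonomic sections of the genus are the most promising reservoirs of
natural products, and which feature categories are most broadly shared?**

`bgcrank` answers this with a weighted directed bipartite network. For each
analysis it:

1. aggregates per-genome counts to **per-section averages**
   `w(s, c) = (1 / n_s) * sum over species i in section s of x(i, c)`,
   where `n_s` counts *all* species assigned to section `s` (genomes with
   zero observations stay in the denominator);
2. builds the graph `G` with a node for every section `s` and feature
   category `c`, and a directed edge `s -> c` of weight `w(s, c)` for every
   positive cell;
3. computes per-node **strength** (`k_out(v) = sum of outgoing weights`,
   `k_in(v) = sum of incoming weights`) and the **broadcasting and
   receiving PageRank**: receiving is the stationary vector of the damped
   (`alpha = 0.85`), weight-proportional random walk on `G` (dangling mass
   redistributed uniformly), broadcasting is the same computation on the
   edge-reversed graph; both are **min-max normalized to [0, 1]** within
   the section nodes and within the feature nodes separately;
4. ranks nodes per class and measure by descending raw score, ties broken
   by ascending label.

Five shipped recipes mirror the screens such a study runs: `backbone`
(enzyme-class counts), `metabolites_high` / `metabolites_low` (putative
metabolites at `>= 75%` / `< 75%` match), `amp_bins` (AMP hits in the
percent-match bins 100, 99.9–95.0, 94.9–90.0, 89.9–80.0, 79.9–70,
69.9–51.0, everything below 51.0 excluded and the exclusion count
reported), and `amp_keywords` (annotation keyword categories such as
hypothetical protein, glycoside hydrolase family, cytochrome P450 family,
NRPS, ABC transporter, glycosyltransferase, peptidase).

Because the real inputs are genome-scale predictor runs, the package ships
a first-class synthetic generator: per-(species, category) counts are
Poisson with a configurable base rate and an optional multiplicative
enrichment planted in one section, so recovery of the planted section by
the broadcast ranking is an analytically predictable benchmark.

## Worked example

```r
library(bgcrank)

cfg <- simulation_config(n_sections = 4, species_per_section = 5,
                         base_rate = 2, planted_section = "Harzianum",
                         effect_multiplier = 5, seed = 20)
bundle <- simulate_bundle(cfg)
dir <- file.path(tempdir(), "demo")
write_fixture_bundle(dir, bundle$species, bundle$counts, bundle$hits)

run <- run_pipeline(pipeline_config(
  taxonomy = file.path(dir, "taxonomy.tsv"),
  counts = file.path(dir, "counts.tsv"),
  analysis = "backbone", out_dir = file.path(dir, "out"),
  log_level = "quiet"))
print(run)
```

```
bgcrank run: analysis 'backbone'
  sections: 4, feature categories: 10, edges: 40
  sections by broadcasting PageRank:
 rank            node     raw normalized
    1       Harzianum 0.28990   1.000000
    2     Trichoderma 0.09204   0.028295
    3  Brevicompactum 0.08735   0.005255
    4 Longibrachiatum 0.08628   0.000000
```

The section with the planted 5-fold enrichment (`Harzianum`) broadcasts
the most influence into the feature layer: its raw broadcasting PageRank
(0.290) is ~3x the other sections' and it takes normalized score 1.0 and
rank 1. `summary(run)` additionally names the top receiving feature, and
the output directory contains the section-average matrix, the edge list,
the full centrality table, the rank table and a JSON run manifest, all as
TSV/JSON.

A thin command-line wrapper with `simulate`, `run` and `rank` subcommands
is installed at `system.file("scripts", "bgcrank", package = "bgcrank")`;
the shipped YAML defaults for bins and keyword categories are at
`system.file("extdata", "default_config.yaml", package = "bgcrank")`.

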