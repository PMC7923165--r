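---
title: "Comparative signaling networks from phosphoproteomic target lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative signaling networks from phosphoproteomic target lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosnet)
```

## The problem

A tyrosine kinase such as SYK can suppress tumor growth in one tissue and
promote it in another. Quantitative phosphoproteomics produces, for each
cellular condition, a list of *targets*: proteins whose (tyrosine)
phosphorylation changes when the kinase is perturbed. A flat target list
says little about mechanism. `phosnet` turns per-condition target lists
into comparable signaling networks and asks where the conditions differ:
which pathways are enriched, how the reconstructed networks are wired, which
proteins change their interaction neighborhood between conditions, and along
which routes a signal can plausibly travel from the kinase to each target.

The pipeline has four stages, each usable on its own:

1. **Enrichment and selection** — score every pathway of a prior-knowledge
   database for target over-representation, then select pathways by
   significance plus a coverage rule.
2. **Network reconstruction** — embed the selected pathways into one
   directed protein network per condition; build a random-protein baseline
   through the identical procedure.
3. **Comparison** — topology diagnostics against the baseline; alignment of
   condition networks into a fusion network with presence labels and
   per-node rewiring scores.
4. **Propagation** — random-walk-weighted k-shortest and near-shortest
   paths from the focal kinase to its targets over a shared
   prior-knowledge network.

## Models and scores

### Pathway over-representation

For a pathway of size $n$ in a database whose universe holds $N$ proteins,
of which $K$ are targets and $k$ fall in the pathway, the one-sided Fisher
exact (hypergeometric tail) p-value is

$$p = \sum_{i=k}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

and the enrichment score is $ES = -\log_{10} p$ (the base is configurable).
Three decisions here were genuinely open and are worth stating:

* **Universe.** $N$ is the set of proteins the *source database* knows
  about (per-database universes), not the detected proteome. Targets
  outside the universe are dropped and counted; they still matter for
  interpretation, which is why the drop is logged.
* **Multiplicity.** Selection uses raw p-values at $\alpha = 0.05$ by
  default; Benjamini–Hochberg adjustment is available behind a flag
  (`p_adjust = "BH"`). Pathway databases overlap so strongly that the
  appropriate correction is debatable; the default mirrors common practice
  for this kind of ranking.
* **Coverage rule.** After keeping all significant pathways, targets not
  contained in any of them are covered greedily by the remaining pathways
  in ascending-p order (ties: larger overlap, then pathway id). Greedy by
  p prefers the most statistically supported covering pathway; the order
  matters only when several weak pathways could cover the same target.

Differential enrichment across conditions sorts pathways by the mean ES and
reports each condition's deviation from that mean (deviations sum to zero
per pathway). Bidirectional hierarchical clustering of the pathway-by-
condition ES matrix uses Euclidean distance and complete linkage by default;
with a constant matrix all distances are zero and merges follow input
order, which is the documented tie-break.

### Network reconstruction

Nodes are the union of the selected pathways' members; edges are the
database interactions with both endpoints in that set — including edges
whose endpoints sit in two *different* selected pathways, which is exactly
what creates the hyperconnected cross-pathway core these networks show.
Cleanup removes self-loops, merges duplicate directed edges (provenance and
source-database sets are unioned; an activate-versus-inhibit conflict
becomes `unknown`), and removes isolated nodes. The random baseline samples
pseudo-targets uniformly from the database universe (optionally from a
larger proteome pool) and runs the identical enrichment–selection–build
procedure, so any topological difference between a condition network and
the baseline is attributable to the data, not the method.

### Topology diagnostics

The scale-free diagnostic is the least-squares line on
$(\log_{10} d, \log_{10} f(d))$ over nonzero-frequency degrees of the
undirected projection; the quality criterion is the fit's $R^2$, matching
the "node connectivity" convention of the graphical network analyzers used
in this field, not a maximum-likelihood exponent estimate. Frequency-one
bins in the tail make this fit conservative: even strongly scale-free
graphs rarely exceed $R^2 \approx 0.7$ on raw bins, while size-matched
Erdős–Rényi graphs stay near zero — the *contrast* is the diagnostic.
Characteristic path length is the mean directed shortest-path hop count
over reachable ordered pairs; the clustering coefficient is the mean local
transitivity of the undirected projection with degree-<2 nodes contributing
zero. Closeness is harmonic (mean of inverse distances, unreachable
contributing zero), which stays defined on disconnected directed graphs;
betweenness is directed and normalized. Because "average path length
through a node" is used with two meanings, both are reported: the mean
distance from/to the focal node, and the mean length of shortest paths on
which it lies as an intermediate.

### Fusion and rewiring

Networks align by protein accession (nodes) and ordered source–target pair
(edges); sign and database provenance are deliberately ignored so edges are
not discriminated by their database of origin. Presence sets yield labels:
`common`, `<side>-exclusive`, or `shared`. The per-node rewiring score
between two sides is the Jaccard distance of incident directed edge sets,

$$r(v) = 1 - \frac{|E_a(v) \cap E_b(v)|}{|E_a(v) \cup E_b(v)|},$$

a transparent statistic chosen because the plugin-based score it stands in
for does not publish its formula; ranking agreement, not numeric equality,
is the goal. A degree-corrected variant
($r \cdot \sqrt{\min(|E_a|,|E_b|)}$) is available to de-emphasize
low-degree nodes whose single lost edge otherwise scores 1.

### Signal propagation

Under the random-walk weighting, an edge $u \to v$ weighs
$w = \log_2 \mathrm{outdeg}(u)$, so a path's weight is $-\log_2$ of the
probability that an unbiased random walk follows exactly that path; the
minimum-weight path is the maximum-probability walk. Paths are simple
(loopless) and enumerated in non-decreasing weight order by Yen's
algorithm; the ensemble keeps the $k$ best paths *and* every path within
$\varepsilon$ of the minimum (near-shortest extension). Defaults are
$k = 5$ and $\varepsilon = 1$ — one bit, i.e. paths down to half the best
walk probability. Ties are broken by lexicographic node sequence, making
the output fully deterministic. A target that is a direct neighbor of the
source always contributes its one-edge path regardless of weight rank,
since a documented direct interaction is mechanistically privileged. In
`all_pathways` mode every condition is propagated over one shared
prior-knowledge network built from the whole database; per-condition
enriched-only networks are supported but bias reachability, so the shared
network is the default for comparisons. An optional filter restricted to
GO-defined process groups (cell adhesion and motility, growth and death,
immunity, differentiation) narrows targets to one biological process.

## The synthetic study

Real inputs (curated pathway exports, supplementary target lists) cannot be
shipped, so the `synthetic_spec()` generators produce ground-truth-bearing
stand-ins for every stage. The canonical conditions are: a 2000-protein
interactome, 40 pathways of 20–60 members, 3 enriched pathways, $p_{in} =
0.7$, 150 targets per condition plus 20% down-regulated decoys, and
rewired pairs with $\rho = 0.5$ on 10 planted nodes.

Design choices that matter, and why:

* **Interactome.** Directed preferential attachment ($m = 3$), edges
  oriented from the well-connected core outward (signal flows from a
  receptor-proximal kinase to effectors), plus 0.5 triangle-closing edges
  per node with degree-weighted centers. Pure preferential attachment is
  scale-free but has vanishing clustering; the closure step gives the core
  the triangle density that makes small-world diagnostics meaningful.
* **Pathways.** Breadth-limited snowball samples (at most 3 random
  unvisited neighbors absorbed per expanded node). Unlimited breadth-first
  snowballs on a scale-free graph absorb the hub core immediately, making
  all pathways near-duplicates; the breadth limit keeps each pathway a
  locally connected module, so planted enrichment is a recoverable signal
  rather than an artifact of overlap.
* **Enriched pathways** are seeded at high-degree core nodes: in real data
  the kinase's target-enriched signaling pathways concentrate around
  receptor-proximal hubs.
* **Background draws** for target lists come from the whole interactome,
  not only the pathway universe, because real screens identify many
  proteins absent from curated databases; the enrichment stage drops and
  logs them exactly as it does for real data. The random baseline samples
  from the database universe, its documented default.

What the generators deliberately do **not** model: mass-spectrometry noise
and abundance effects, annotation bias (all synthetic pathways are equally
well curated), correlated membership between pathways of different
databases, and the directionality errors of real interaction databases.
Passing recovery tests on synthetic data therefore shows the *method* is
sound — planted enrichment ranks at the top, planted rewiring is found,
scale-free/small-world contrasts against the baseline point the right way —
not that any particular biological conclusion is correct.

## Numerical choices and degenerate inputs

* Hypergeometric tails come from `stats::phyper`; the test suite checks
  them against direct binomial-coefficient enumeration to $10^{-10}$
  relative error.
* `k = 0` overlap gives $p = 1$, $ES = 0$; an empty target list warns and
  returns all-ones.
* A constant ES matrix clusters deterministically in input order.
* Yen's search is capped at 5000 accepted paths per target as a safety
  valve; the cap is unreachable at the default $k$ and $\varepsilon$.
* Power-law fits require at least three distinct positive degrees and
  refuse regular graphs.
* Sub-seeds for independent generator streams are derived by hashing the
  master seed with a purpose label, keeping every derived seed below
  $2^{31}$.
* All simulation-based checks in the test suite use fixed seeds; study-
  scale problem sizes (2000-protein interactomes for enrichment recovery,
  1000-protein pairs for rewiring recovery, 20 replicate seeds) were chosen
  so the full pipeline is exercised end to end at desk scale.

## Known limitations

* The rewiring score is a Jaccard distance, not the (unpublished) plugin
  statistic it replaces; ranking agreement is the design goal.
* The random-walk weighting is one concrete instance of the "random walk
  plus weighted k-shortest paths" family; the scheme is pluggable
  (`weight_edges`), and hop-shortest (`unit`) is always available.
* Identifier handling is deliberately minimal: accessions are the only
  join key, isoform suffixes are stripped at read time, and no
  symbol-to-accession mapping is attempted. Unmappable rows fail loudly.
* GO annotation handling reads direct annotations only; no ontology
  ancestor closure is performed (term groups are supplied explicitly).
* The per-database universe makes enrichment p-values comparable within a
  database but not across databases; cross-database selection is therefore
  performed per source and unioned.

## A worked run

```{r, eval = FALSE}
spec <- synthetic_spec(seed = 1)
dir <- tempfile("study")
study <- write_synthetic_study(spec, dir)

cfg <- run_config(
  targets = list(cond1 = file.path(dir, "cond1_targets.tsv"),
                 cond2 = file.path(dir, "cond2_targets.tsv"),
                 cond3 = file.path(dir, "cond3_targets.tsv")),
  gmt = file.path(dir, "pathways.gmt"),
  sif = file.path(dir, "interactions.sif"),
  db_source = "sim",
  focal = study$db$universe[1],
  out_dir = file.path(dir, "results"),
  seed = 1)
manifest <- run_compare(cfg)
```

Every stage output lands in `out_dir` (enrichment and selection tables,
GraphML networks, the fusion network with rewiring attributes, the
propagation path ensemble) together with a manifest recording the
configuration and the MD5 checksum of every file; re-running the same
configuration reproduces the checksums exactly.
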