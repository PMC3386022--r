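---
title: "Designing and optimising minimal transcriptional signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and optimising minimal transcriptional signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmin)
```

This vignette is the package's own account of the method: the model
behind correlation-based target prediction, the knobs that matter, what
the synthetic benchmark does and does not emulate, and the numerical
and design choices made where the procedure left room.

## The prediction model and its assumptions

The working assumption is *guilt by association*: compounds that engage
overlapping protein targets perturb overlapping transcriptional
programs, so their expression profiles correlate — at least on the
genes that actually respond to the perturbation. Target prediction is
then a nearest-neighbour lookup:

1. Express every treatment instance relative to its experimental batch
   (`batch_mean_center()`), so that correlations reflect treatment
   response rather than batch provenance.
2. For a query instance, compute the Pearson correlation to every other
   instance over the signature's probesets only, excluding all
   instances of the query's own compound. Self-exclusion matters: a
   replicate or a concentration variant of the same molecule would be
   found first and would inflate performance while carrying zero new
   information about targets.
3. Take the union of the `k` nearest neighbours' target sets
   (`k` ∈ {1, 2, 3}) as the prediction; count success if it intersects
   the query compound's true target set.

The set-intersection success measure is deliberately lenient. Target
annotation matrices are extremely sparse — the reference annotation
counts (804 compounds × 4,428 targets, 19,871 pairs) populate about
0.56% of the matrix, computable with `annotation_density()` — so most
"false positives" of a stricter measure would be unverifiable rather
than wrong. Precision (mean |predicted ∩ true| / |predicted|) is
reported alongside for the same prediction, never optimised for.

Accuracy aggregates per treatment instance, not per compound: a
compound measured under six conditions contributes six queries. A
per-compound aggregation would weight promiscuous, heavily re-measured
compounds differently; instance-level scoring is the default because
each instance is an independent lookup a platform user would perform.

The chance floor is estimated by permuting whole target *sets* across
compounds (`shuffle_associations()`). Shuffling sets rather than
individual pairs preserves each compound's target count — and thus the
promiscuity structure that drives how often two random compounds share
a target — so the floor isolates the contribution of the expression
signal. Pair-level shuffling is available behind `unit = "pairs"` but
changes the marginal structure and with it the meaning of the null.

## Signature construction

**Expression criteria.** Seven unsupervised statistics, each computed
across all instances: highest/lowest mean, highest/lowest standard
deviation, highest/lowest mean absolute value, and the Shannon entropy
of binned expression. The design is deliberately target-blind; nothing
leaks from the annotation table into the signature.

**Shannon entropy.** Values are binned into 200 equal-width bins on
[−5, 8] — a range suited to log-scale, batch-centred expression, where
values are small and roughly centred on zero. Two conventions needed
fixing. Out-of-range values are *clamped* into the boundary bins rather
than dropped, so every instance contributes to every probeset's
histogram; dropping would silently reweight probesets with heavy tails.
The logarithm base is 2 (bits); any base gives the same ranking, so the
choice cannot alter a signature, but bits make `log2(bins)` the
self-evident ceiling.

**Network criteria.** Gene-level scores on a directed interaction
network with labelled edge modes: betweenness, closeness, degree,
in-degree and out-degree centralities, plus a regulator-distance score
(for each node reachable from at least one node that has an outgoing
`expression`-mode edge, the mean shortest-path length from all such
regulators that reach it, ranked descending to favour genes far
downstream of many regulators — a deliberately diverse set). Distances
count hops over edges of every mode, not only `expression` edges;
restricting the path to one mode would disconnect most of the graph.
Scores translate to probesets via the chip mapping table, highest
score first, ties by gene id then probeset id, duplicates kept at first
occurrence (`nodes_to_signature()`).

Choices worth stating: centralities use the *directed*, unweighted
graph (the in-/out-degree criteria are only meaningful directed; an
`undirected` switch exists for the path-based kinds). Betweenness is
unnormalised with fractional counting of tied shortest paths — only the
ranking is consumed, and the normaliser is a constant. Closeness is
(number of reachable nodes) / (sum of distances to them), with 0 for
sink nodes; this harmonic-free convention handles disconnected directed
graphs without special cases and is asserted against a brute-force
shortest-path oracle in the tests, as are betweenness and the
regulator-distance scores.

**The size ladder.** `size_ladder()` spans 16–4096 in half-log₂ steps,
*truncating* 2^(k/2) to an integer (22, 45, 90, 181, …): truncation,
not rounding, reproduces the conventional ladder (rounding would give
23 at 2^4.5). Designed signatures can be cut at any size on the ladder;
the classic single-size choice (top 300) is just one cut.

**Tie-breaking.** Everywhere a ranking is cut at k — criteria,
centralities, neighbour lists — ties break by id in C-locale radix
order. This costs nothing and makes every signature and neighbour list
reproducible across platforms and locales.

## The genetic algorithm

Individuals are fixed-size probeset sets. Per generation, the top
⌈elite_fraction · population⌉ by fitness survive unchanged; each
remaining slot is filled, with probability `crossover_rate`, by a
crossover of two distinct uniformly chosen elites, otherwise by a
mutation of one elite. Defaults mirror the reference protocol:
population 200, 150 generations, 20% elitism, 70%/30% crossover/
mutation (the rates partition offspring creation and must sum to 1).

The operators for fixed-size *sets* had to be defined here: crossover
samples |a| elements uniformly without replacement from the union of
the two parents; mutation replaces one uniformly chosen member with one
uniformly chosen outsider. Both preserve size and uniqueness by
construction, which keeps every individual a valid signature without
repair steps. The mutation rate applies per offspring, not per gene; a
per-gene rate would make the expected edit distance grow with signature
size and materially change the search dynamics.

Fitness is 1-NN prediction accuracy (the headline measure; `k` is
configurable) evaluated by a fast path that precomputes the
compound-pair target-sharing matrix once per dataset — the tests assert
its equality with `predict_and_score()`. Fitness values are cached by
the signature's sorted content, so elites are never re-scored and
revisited signatures are free. Elitism makes the best-fitness trace
non-decreasing by construction; the tests assert this exactly, per
generation, across seeded runs.

Parent selection is uniform over the elite pool — no fitness-
proportional roulette. With accuracy plateaus being broad and flat,
rank information beyond "elite or not" is mostly noise.

## Pathway enrichment

Over-representation uses the hypergeometric tail (one-sided Fisher's
exact test): with a universe of N genes, a pathway of K, a query of n
and an overlap of x, `p = P[X ≥ x]`. The universe is the intersection
of the collection's universe with the genes represented on the chip's
mapping table: genes the platform cannot see should not inflate
significance. This choice is configurable by passing a different
universe to `gene_set_collection()`. Raw p-values are the comparison
surface (reported as −log₁₀ p); Benjamini–Hochberg adjusted values ride
along. Absolute p-values depend strongly on the universe size, so only
the relative ranking of pathways is meaningful across collections.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` exists so that every stage runs and is testable
without any external download. It emulates, at desk scale, the
*statistical structure* the method relies on:

* batched treatment instances with replicates (default 100 compounds ×
  3 instances over 10 batches);
* a sparse compound-target matrix with heavy-tailed per-compound target
  counts — 1 + a truncated geometric draw (p = 0.35, capped at 10),
  giving many one-target compounds and a few promiscuous ones;
* activity records whose true pairs sit at ≤ 5 µM and whose decoy
  records (including non-IC50/Ki types) are eliminated by the potency
  filter, exercising it;
* an additive signal model: each of 40 targets owns an effect vector
  supported on a random quarter-to-three-quarters of the 32 informative
  probesets, with N(0, effect_size²) entries; an instance's expression
  is the sum of its compound's target effects, a per-batch per-probeset
  N(0, batch_sd²) offset, and i.i.d. N(0, noise_sd²) noise. Compounds
  sharing targets therefore correlate on informative probesets, which
  is precisely the premise the predictor exploits;
* a network whose `expression`-mode regulator feeds the informative
  genes and whose module edges ring the genes of each target, over a
  random background; and a GMT collection containing the planted
  informative-gene set among random sets.

Defaults are effect_size 2 (in noise-sd units), noise_sd 1, batch_sd
0.5 — a clearly recoverable signal. The effect-support choice (each
target perturbing 25–75% of the informative probesets) makes target
effect vectors overlap without being identical, so sharing one of
several targets still leaves a correlation footprint.

What it does *not* emulate: probe-level intensity distributions,
cell-line-specific biology, correlated (non-informative) gene modules,
dose–response structure, or the scale of a real compendium (thousands
of instances, tens of thousands of probesets). Absolute accuracies on
the benchmark are therefore far higher than anything achievable on real
compendium data, and the size at which random-signature accuracy
plateaus shifts with the informative fraction (32/1000 here). Passing
tests demonstrate that the machinery measures what it claims and that
the orderings — optimised ≥ designed ≥ random ≥ shuffled-annotation
floor — emerge when signal is present; they say nothing about effect
sizes in real data.

## Degenerate inputs and edge policies

* Batches with ≤ 5 instances (`min_batch_size`, configurable) are
  *dropped*, not left un-centred: an un-centred instance would carry
  its full batch offset into every correlation and contaminate the
  neighbour pool. The exclusion is logged, never silent. Whether such
  batches should instead be kept un-centred is genuinely open; dropping
  is this package's declared choice.
* Missing expression values are rejected at load; probeset-median
  imputation is available behind an explicit flag.
* A query whose profile is constant over the signature has no defined
  correlation; it is skipped with a message rather than scored as a
  failure. Constant candidates simply never rank.
* Orientation of a TSV expression table is auto-detected against the
  metadata's instance ids; if both or neither axis matches, loading
  errors and demands an explicit orientation rather than guessing.
* `0 · log 0 := 0` in the entropy; empty bins contribute nothing.

## Problem sizes used by the test-suite and acceptance script

The shipped experiments use the generator defaults (1,000 probesets, 32
informative, 100 compounds, 300 instances), a size ladder of 16–128
with 10 random draws and 5 shuffled-annotation replicates, and a GA of
population 50 for 30 generations at signature size 32 — sizes chosen so
the full suite and the acceptance script each complete in minutes on a
single core while the planted-recovery and ordering checks remain
decisively resolvable. Oracle-equivalence checks run exhaustively where
exhaustion is cheap: 1,000 random directed graphs of ≤ 8 nodes against
a shortest-path enumeration oracle, and every hypergeometric
configuration with a universe of ≤ 12 against full subset enumeration.

## Known limitations

* Correlation-based lookup cannot predict targets for compounds unlike
  anything annotated in the reference — coverage bounds accuracy, which
  is why neighbour candidates are restricted to annotated compounds by
  default (`restrict_to_annotated`; disabling it conflates annotation
  coverage with signal).
* The GA optimises accuracy on the given dataset; nothing guards
  against overfitting to the compendium's compound composition. On the
  synthetic benchmark the planted truth makes the recovered signal
  verifiable; on real data an external validation set would be needed.
* The F-measure and other recall/precision trade-off objectives are out
  of scope, as are GPU correlation kernels, probe-level processing
  (RMA/CEL), live StringDB or bioactivity-repository access, and
  proprietary pathway content; the enrichment machinery works against
  any GMT collection.
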