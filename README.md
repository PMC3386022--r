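# sigmin

Minimal transcriptional signatures for compound target prediction.

When cells are treated with a compound, the transcriptional response
carries a fingerprint of the proteins the compound engages. `sigmin`
asks how small a gene signature — a fixed-size, duplicate-free set of
probesets used for profile correlation — can be while still supporting
useful *guilt-by-association* target prediction, and provides the tools
to design, optimise and evaluate such signatures. It is aimed at
computational chemical biologists working with compound profiling panels
(microarray or bead-based), where signature size is directly
proportional to assay cost.

## The method

**Prediction.** Every *treatment instance* (one compound × concentration
× cell line × platform measurement) is a row of a batch mean-centred
expression matrix. For a query instance *q*, the *k* nearest neighbours
(k ≤ 3) are the instances with the highest Pearson correlation *r* over
the signature's probesets, with every instance of the query's own
compound excluded — a self-match carries zero information about targets.
The predicted target set is the union of the neighbours' annotated
target sets, and the prediction is successful if

> predicted(q) ∩ true(q) ≠ ∅.

**Accuracy** is the fraction of successful queries; **precision** (mean
|predicted ∩ true| / |predicted|) is reported alongside. The ground
truth is a compound→target table retaining pairs with IC50 or Ki ≤ 5 µM.
The chance floor is obtained by permuting whole target sets across
compounds (`shuffle_associations()`), which preserves the
polypharmacology structure exactly.

**Signature design.** Signatures are ranked cuts of per-probeset
statistics (mean, standard deviation, mean absolute expression, Shannon
entropy of expression binned into 200 bins on [−5, 8]), of
interaction-network topology (betweenness, closeness, degree, in-/out-
degree centralities, and mean shortest-path distance from upstream
`expression`-mode regulators), random draws over a half-log₂ size ladder
(16, 22, 32, …, 4096), or the output of a genetic algorithm: elitism
plus union-sampling crossover and single-element replacement mutation
over fixed-size probeset sets, with prediction accuracy as the fitness.

**Characterisation.** Signatures are compared by the overlap fraction of
the smaller signature, and interpreted by hypergeometric
over-representation of their genes in GMT pathway collections
(one-sided Fisher's exact test).

Because the original expression compendium and bioactivity repository
are not redistributable, the package ships a synthetic benchmark
generator (`generate_dataset()`) that plants target-driven signal: each
target perturbs a subset of 32 informative probesets, compounds sharing
targets therefore correlate, and batch offsets plus i.i.d. noise sit on
top. All pipeline stages run end-to-end against it, and recovery of the
planted truth is measurable.

## Worked example

```r
library(sigmin)

bundle <- generate_dataset(sim_config(seed = 11))
m <- batch_mean_center(bundle$expression)

stats <- matrix_stats(bundle$annotations)
sprintf("annotation density: %.2f%% (%d pairs)", stats$density_percent, stats$pairs)
#> "annotation density: 6.38% (255 pairs)"

# a designed signature: the 32 most variable probesets
sig <- rank_by_criterion(m, "max_sd", 32)
predict_and_score(m, sig, bundle$annotations, prediction_config(k_neighbors = 1))
#> ScoreReport: accuracy 0.9067, precision 0.6556 over 300 queries

# chance floor for the same signature
baseline <- random_baseline(m, sig, bundle$annotations, n_shuffles = 10, seed = 1)
sprintf("shuffled-annotation baseline: %.3f +/- %.3f", baseline$mean, baseline$sd)
#> "shuffled-annotation baseline: 0.159 +/- 0.035"

# evolve a 32-probeset signature instead of designing one
ga <- evolve(m, bundle$annotations,
             ga_config(signature_size = 32, population = 50,
                       generations = 30, seed = 11))
ga
#> GATrace: 30 generations, best fitness 0.9567 (gen0 best 0.9067)

rec <- truth_recovery_report(bundle, ga$best)
sprintf("planted probesets recovered: %.0f%%; planted pathway rank: %d",
        100 * rec$recovery, rec$planted_rank)
#> "planted probesets recovered: 84%; planted pathway rank: 1"
```

Reading: on 300 treatment instances of 100 annotated compounds, the
32-probeset maximum-variance signature predicts a correct target for
91% of queries versus a 16% shuffled-annotation floor; 30 generations
of evolution push a same-size signature to 96% while rediscovering 27
of the 32 planted informative probesets, and pathway enrichment of the
evolved signature ranks the planted gene set first. (Absolute
accuracies are far above what real compendium data yields — the
synthetic signal is deliberately recoverable; the orderings, not the
levels, are the point.)

`run_experiment()` sweeps all of the above over a size ladder and
returns the accuracy table, GA traces and the signature overlap matrix
in one call; `write_dataset()` / `load_expression()` and friends
round-trip everything through plain TSV/GMT files.

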