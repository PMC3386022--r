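# Genetic-algorithm optimisation of fixed-size signatures. Individuals are
# duplicate-free probeset sets of a fixed size; fitness is prediction
# accuracy. Elitism carries the top fraction unchanged, so best fitness is
# non-decreasing by construction; offspring come from union-sampling
# crossover or single-element replacement mutation, both of which preserve
# size and uniqueness.

#' Genetic algorithm configuration
#'
#' Defaults mirror the reference optimisation protocol: population 200,
#' 150 generations, 20% elitism, crossover rate 70%, mutation rate 30%
#' (the two rates partition offspring creation and must sum to 1).
#'
#' @param signature_size Size of every individual.
#' @param population Population size (at least 4).
#' @param generations Number of generations to evolve.
#' @param elite_fraction Fraction of the population carried unchanged
#'   (strictly between 0 and 1; at least 2 elites must result).
#' @param crossover_rate Probability an offspring is produced by crossover.
#' @param mutation_rate Probability an offspring is produced by mutation.
#' @param seed Integer seed making the whole run deterministic.
#' @return A `GAConfig` list.
#' @export
ga_config <- function(signature_size, population = 200, generations = 150,
                      elite_fraction = 0.20, crossover_rate = 0.70,
                      mutation_rate = 0.30, seed = 1) {
  stopifnot(signature_size >= 1, population >= 4, generations >= 1,
            elite_fraction > 0, elite_fraction < 1)
  if (abs(crossover_rate + mutation_rate - 1) > 1e-12) {
    stop("crossover_rate + mutation_rate must equal 1")
  }
  n_elite <- ceiling(elite_fraction * population)
  if (n_elite < 2) stop("elite pool must contain at least 2 individuals")
  structure(list(signature_size = as.integer(signature_size),
                 population = as.integer(population),
                 generations = as.integer(generations),
                 elite_fraction = elite_fraction,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "GAConfig")
}

# RNG-consuming kernels; the exported operators wrap them with a seed.
crossover_ids <- function(a, b) sample(union(a, b), length(a))

mutate_ids <- function(a, universe) {
  out <- setdiff(universe, a)
  if (length(out) == 0) stop("universe exhausted: nothing to mutate to")
  slot <- sample.int(length(a), 1L)
  a[slot] <- out[sample.int(length(out), 1L)]
  a
}

#' Crossover of two equal-size signatures
#'
#' The child is a uniform sample, without replacement, of `|a|` probesets
#' from the union of the parents, so size and uniqueness are preserved by
#' construction.
#'
#' @param a,b `GeneSignature`s of equal size.
#' @param seed Integer seed.
#' @return A child `GeneSignature` with `origin = "ga"`.
#' @export
crossover <- function(a, b, seed) {
  ia <- signature_ids(a)
  ib <- signature_ids(b)
  if (length(ia) != length(ib)) stop("crossover requires equal-size parents")
  withr::with_seed(seed, gene_signature(crossover_ids(ia, ib), origin = "ga"))
}

#' Single-element replacement mutation
#'
#' One uniformly chosen member of the signature is replaced by one
#' uniformly chosen probeset from outside it.
#'
#' @param a A `GeneSignature`.
#' @param universe Character vector of all available probeset ids, strictly
#'   larger than the signature.
#' @param seed Integer seed.
#' @return A mutated `GeneSignature` with `origin = "ga"`.
#' @export
mutate <- function(a, universe, seed) {
  ia <- signature_ids(a)
  universe <- as.character(universe)
  if (length(universe) <= length(ia)) {
    stop("universe must be larger than the signature")
  }
  withr::with_seed(seed, gene_signature(mutate_ids(ia, universe), origin = "ga"))
}

#' Evolve a fixed-size signature to maximise prediction accuracy
#'
#' Generation 0 is random signatures. Each later generation keeps the top
#' `ceiling(elite_fraction * population)` individuals by fitness unchanged
#' and fills the remainder with offspring: with probability
#' `crossover_rate` a crossover of two distinct uniformly chosen elites,
#' otherwise a mutation of one uniformly chosen elite. Fitness is
#' prediction accuracy ([predict_and_score()] semantics) at `k` nearest
#' neighbours, cached by signature content so a re-visited signature is
#' never re-scored.
#'
#' @param m An `ExpressionMatrix`.
#' @param annotations A `TargetAnnotationTable`.
#' @param cfg A [ga_config()].
#' @param pred_cfg A [prediction_config()]; default 1-NN.
#' @return A `GATrace` list: `trace` data frame (generation, worst, mean,
#'   best fitness), `best` (the best `GeneSignature` found), `best_fitness`,
#'   and `population` (final generation's id lists).
#' @export
evolve <- function(m, annotations, cfg, pred_cfg = prediction_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(cfg, "GAConfig"))
  universe <- probesets(m)
  if (cfg$signature_size > length(universe)) {
    stop("signature_size exceeds probeset universe")
  }
  evaluate <- accuracy_evaluator(m, annotations, k = pred_cfg$k_neighbors,
                                 restrict_to_annotated = pred_cfg$restrict_to_annotated)
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(ids) {
    key <- paste(sort(ids), collapse = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- evaluate(ids)
    cache[[key]] <- f
    f
  }
  n_elite <- ceiling(cfg$elite_fraction * cfg$population)

  withr::with_seed(cfg$seed, {
    pop <- replicate(cfg$population,
                     sample(universe, cfg$signature_size), simplify = FALSE)
    trace <- data.frame(generation = integer(0), worst = numeric(0),
                        mean = numeric(0), best = numeric(0))
    for (gen in 0:cfg$generations) {
      fit <- vapply(pop, fitness_of, numeric(1))
      ord <- order(fit, decreasing = TRUE)
      trace <- rbind(trace, data.frame(generation = gen,
                                       worst = min(fit), mean = mean(fit),
                                       best = max(fit)))
      if (gen == cfg$generations) {
        pop <- pop[ord]
        fit <- fit[ord]
        break
      }
      elites <- pop[ord[seq_len(n_elite)]]
      offspring <- lapply(seq_len(cfg$population - n_elite), function(i) {
        if (stats::runif(1) < cfg$crossover_rate) {
          parents <- sample.int(n_elite, 2L)
          crossover_ids(elites[[parents[1]]], elites[[parents[2]]])
        } else {
          parent <- elites[[sample.int(n_elite, 1L)]]
          # degenerate search space: nothing outside the signature to swap in
          if (length(universe) > cfg$signature_size) {
            mutate_ids(parent, universe)
          } else {
            parent
          }
        }
      })
      pop <- c(elites, offspring)
    }
    structure(list(trace = trace,
                   best = gene_signature(pop[[1]], origin = "ga"),
                   best_fitness = fit[1],
                   population = pop),
              class = "GATrace")
  })
}

#' @export
print.GATrace <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf(
    "GATrace: %d generations, best fitness %.4f (gen0 best %.4f)\n",
    n - 1L, x$best_fitness, x$trace$best[1]))
  invisible(x)
}
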