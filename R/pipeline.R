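# End-to-end experiment: normalise, build signatures over the size ladder
# (random draws, expression criteria, network criteria, optional GA),
# score every arm at one or more neighbour counts, and compare against the
# shuffled-annotation null.

#' Experiment configuration
#'
#' @param sizes Strictly increasing vector of signature sizes (see
#'   [size_ladder()]).
#' @param n_random_per_size Random signatures drawn per size; their
#'   accuracies are reported as mean and sd (default 50).
#' @param criteria Expression-statistic criteria to evaluate (see
#'   [rank_by_criterion()]); may be empty.
#' @param network_criteria Network criteria to evaluate (see
#'   [network_signature()]); may be empty.
#' @param k_neighbors Neighbour counts to score at (default `1:3`).
#' @param n_shuffles Shuffled-annotation replicates for the null arm
#'   (default 10; 0 disables the arm).
#' @param ga A [ga_config()] template evolved at every size, or `NULL` to
#'   skip the GA arm. Its `signature_size` is overridden per size.
#' @param seed Integer master seed.
#' @return An `ExperimentConfig` list.
#' @export
experiment_config <- function(sizes, n_random_per_size = 50,
                              criteria = c("max_sd", "min_sd", "max_mean",
                                           "min_mean", "max_abs_mean",
                                           "min_abs_mean", "shannon"),
                              network_criteria = character(0),
                              k_neighbors = 1:3, n_shuffles = 10,
                              ga = NULL, seed = 1) {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 1, all(diff(sizes) > 0), n_random_per_size >= 0)
  structure(list(sizes = sizes, n_random_per_size = n_random_per_size,
                 criteria = criteria, network_criteria = network_criteria,
                 k_neighbors = as.integer(k_neighbors),
                 n_shuffles = n_shuffles, ga = ga, seed = as.integer(seed)),
            class = "ExperimentConfig")
}

#' Run the end-to-end signature experiment
#'
#' Centres the bundle's expression matrix, then for every signature size
#' scores (a) the mean and sd over random signatures, (b) each expression
#' and network design criterion, (c) optionally a GA-optimised signature,
#' and (d) the shuffled-annotation null (scored with the random arm's
#' signatures, seed-paired). All accuracies use the set-intersection
#' success rule.
#'
#' @param bundle A `SyntheticBundle` (or any list with `expression`,
#'   `annotations`, and, if network criteria are requested, `network` and
#'   `map`).
#' @param cfg An [experiment_config()].
#' @param min_batch_size Passed to [batch_mean_center()].
#' @return An `ExperimentReport` list: `accuracy` (data frame: origin,
#'   size, k, mean, sd, n), `signatures` (designed and GA signatures),
#'   `ga_traces`, `overlap` (fraction-of-smaller matrix over designed/GA
#'   signatures), and the centred matrix.
#' @export
run_experiment <- function(bundle, cfg, min_batch_size = 5) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  m <- batch_mean_center(bundle$expression, min_batch_size = min_batch_size)
  annotations <- bundle$annotations
  universe <- probesets(m)
  evaluators <- lapply(cfg$k_neighbors, function(k) {
    accuracy_evaluator(m, annotations, k = k)
  })
  names(evaluators) <- as.character(cfg$k_neighbors)
  shuffled_tables <- if (cfg$n_shuffles > 0) {
    seeds <- withr::with_seed(cfg$seed,
                              sample.int(.Machine$integer.max, cfg$n_shuffles))
    lapply(seeds, function(s) shuffle_associations(annotations, seed = s))
  } else list()
  shuffled_evaluators <- lapply(shuffled_tables, function(t_shuf) {
    lapply(cfg$k_neighbors, function(k) accuracy_evaluator(m, t_shuf, k = k))
  })

  rows <- list()
  add_row <- function(origin, size, k, values) {
    rows[[length(rows) + 1L]] <<- data.frame(
      origin = origin, size = size, k = k,
      mean = mean(values), sd = if (length(values) > 1) stats::sd(values) else 0,
      n = length(values), stringsAsFactors = FALSE)
  }

  signatures <- list()
  ga_traces <- list()
  random_seeds <- withr::with_seed(
    cfg$seed + 1L,
    matrix(sample.int(.Machine$integer.max,
                      length(cfg$sizes) * max(1, cfg$n_random_per_size)),
           nrow = length(cfg$sizes)))

  for (si in seq_along(cfg$sizes)) {
    size <- cfg$sizes[si]
    if (size > length(universe)) {
      stop("signature size ", size, " exceeds probeset universe")
    }
    # random arm (and, on the same draws, the shuffled-annotation null)
    if (cfg$n_random_per_size > 0) {
      sigs <- lapply(seq_len(cfg$n_random_per_size), function(j) {
        random_signature(universe, size, seed = random_seeds[si, j])
      })
      for (ki in seq_along(cfg$k_neighbors)) {
        acc <- vapply(sigs, function(s) evaluators[[ki]](s$probeset_ids),
                      numeric(1))
        add_row("random", size, cfg$k_neighbors[ki], acc)
        if (length(shuffled_evaluators) > 0) {
          null_acc <- vapply(shuffled_evaluators, function(ev) {
            mean(vapply(sigs, function(s) ev[[ki]](s$probeset_ids), numeric(1)))
          }, numeric(1))
          add_row("shuffled_annotations", size, cfg$k_neighbors[ki], null_acc)
        }
      }
    }
    # designed arms
    for (crit in cfg$criteria) {
      sig <- rank_by_criterion(m, crit, size)
      signatures[[paste0(crit, "_", size)]] <- sig
      for (ki in seq_along(cfg$k_neighbors)) {
        add_row(crit, size, cfg$k_neighbors[ki], evaluators[[ki]](sig$probeset_ids))
      }
    }
    for (crit in cfg$network_criteria) {
      sig <- network_signature(bundle$network, bundle$map, crit, size)
      signatures[[paste0(crit, "_", size)]] <- sig
      for (ki in seq_along(cfg$k_neighbors)) {
        add_row(paste0("net_", crit), size, cfg$k_neighbors[ki],
                evaluators[[ki]](sig$probeset_ids))
      }
    }
    # GA arm
    if (!is.null(cfg$ga)) {
      ga_cfg <- cfg$ga
      ga_cfg$signature_size <- size
      ga_cfg$seed <- cfg$seed + 1000L + si
      run <- evolve(m, annotations, ga_cfg)
      signatures[[paste0("ga_", size)]] <- run$best
      ga_traces[[as.character(size)]] <- run$trace
      for (ki in seq_along(cfg$k_neighbors)) {
        add_row("ga", size, cfg$k_neighbors[ki],
                evaluators[[ki]](run$best$probeset_ids))
      }
    }
  }

  overlap <- NULL
  if (length(signatures) >= 2) {
    nm <- names(signatures)
    overlap <- matrix(NA_real_, length(nm), length(nm),
                      dimnames = list(nm, nm))
    for (i in seq_along(nm)) {
      for (j in seq_along(nm)) {
        overlap[i, j] <-
          signature_overlap(signatures[[i]], signatures[[j]])$fraction_of_smaller
      }
    }
  }

  structure(list(accuracy = do.call(rbind, rows),
                 signatures = signatures,
                 ga_traces = ga_traces,
                 overlap = overlap,
                 centred = m,
                 config = cfg),
            class = "ExperimentReport")
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat("ExperimentReport\n")
  cat(sprintf("  sizes: %s\n", paste(x$config$sizes, collapse = ", ")))
  arms <- unique(x$accuracy$origin)
  cat(sprintf("  arms: %s\n", paste(arms, collapse = ", ")))
  best <- x$accuracy[which.max(x$accuracy$mean), ]
  cat(sprintf("  best mean accuracy: %.4f (%s, size %d, %d-NN)\n",
              best$mean, best$origin, best$size, best$k))
  invisible(x)
}

#' Write an experiment report's tables
#'
#' Writes `accuracy.tsv`, `overlap.tsv` and one `trace_<size>.csv` per GA
#' run into a directory.
#'
#' @param report An `ExperimentReport`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ExperimentReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$accuracy, file.path(dir, "accuracy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$overlap)) {
    utils::write.table(data.frame(signature = rownames(report$overlap),
                                  report$overlap, check.names = FALSE),
                       file.path(dir, "overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (size in names(report$ga_traces)) {
    utils::write.csv(report$ga_traces[[size]],
                     file.path(dir, paste0("trace_", size, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
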