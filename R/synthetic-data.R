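# Synthetic benchmark generator. Emulates the statistical structure the
# analysis assumes: batched treatment instances with replicates, a sparse
# compound-target matrix with heavy-tailed per-compound target counts, and
# expression profiles in which compounds sharing targets correlate on a
# small set of informative probesets. The signal model is additive: target
# effect vectors + per-batch offsets + i.i.d. noise.

#' Simulation configuration
#'
#' Defaults give a desk-scale analogue of a compound-profiling screen:
#' 100 compounds x 3 replicate instances spread over 10 batches, 1,000
#' probesets of which 32 carry target-driven signal, 40 targets, and a
#' sparse annotation matrix whose per-compound target counts are
#' heavy-tailed (a few promiscuous compounds, many specific ones).
#'
#' @param n_probesets Number of probesets (default 1000).
#' @param n_informative Number of probesets carrying target signal
#'   (default 32).
#' @param n_compounds Number of compounds (default 100).
#' @param n_targets Number of targets (default 40).
#' @param replicates_per_compound Treatment instances per compound
#'   (default 3).
#' @param n_batches Number of experimental batches (default 10).
#' @param target_geom_prob Success probability of the geometric draw behind
#'   per-compound target counts: counts are 1 + a geometric draw truncated
#'   at `max_targets_per_compound` (default 0.35).
#' @param max_targets_per_compound Truncation of the per-compound target
#'   count (default 10).
#' @param effect_size Scale of target effect-vector entries, in units of
#'   the noise standard deviation (default 2).
#' @param noise_sd Standard deviation of i.i.d. Gaussian measurement noise
#'   (default 1).
#' @param batch_sd Standard deviation of per-batch, per-probeset Gaussian
#'   offsets (default 0.5).
#' @param decoy_fraction Fraction of extra weak activity records (> 5 uM,
#'   filtered out by the potency cutoff) added to the activity table
#'   (default 0.3).
#' @param seed Integer seed; generation is fully deterministic.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_probesets = 1000, n_informative = 32,
                       n_compounds = 100, n_targets = 40,
                       replicates_per_compound = 3, n_batches = 10,
                       target_geom_prob = 0.35,
                       max_targets_per_compound = 10,
                       effect_size = 2.0, noise_sd = 1.0, batch_sd = 0.5,
                       decoy_fraction = 0.3, seed = 1) {
  cfg <- list(n_probesets = as.integer(n_probesets),
              n_informative = as.integer(n_informative),
              n_compounds = as.integer(n_compounds),
              n_targets = as.integer(n_targets),
              replicates_per_compound = as.integer(replicates_per_compound),
              n_batches = as.integer(n_batches),
              target_geom_prob = target_geom_prob,
              max_targets_per_compound = as.integer(max_targets_per_compound),
              effect_size = effect_size, noise_sd = noise_sd,
              batch_sd = batch_sd, decoy_fraction = decoy_fraction,
              seed = as.integer(seed))
  if (cfg$n_informative > cfg$n_probesets) {
    stop("n_informative exceeds n_probesets")
  }
  stopifnot(cfg$n_probesets >= 1, cfg$n_compounds >= 2, cfg$n_targets >= 1,
            cfg$replicates_per_compound >= 1, cfg$n_batches >= 1,
            cfg$max_targets_per_compound >= 1,
            cfg$effect_size >= 0, cfg$noise_sd >= 0, cfg$batch_sd >= 0)
  structure(cfg, class = "SimConfig")
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Generate a synthetic benchmark bundle
#'
#' Produces every input the pipeline consumes, plus the ground truth needed
#' to measure recovery:
#' * a raw `ExpressionMatrix` (instances x probesets) with batch structure;
#' * activity records whose true pairs have potency <= 5 uM and whose decoy
#'   records do not survive the cutoff;
#' * a directed interaction network whose module edges connect genes of
#'   co-occurring targets, with background edges and at least one
#'   `"expression"`-mode regulator;
#' * a probeset-gene map and a gene-set collection containing one planted
#'   set (the informative genes) among random sets;
#' * the truth: planted informative probesets and per-target effect
#'   vectors.
#'
#' Each target's effect vector is supported on a random subset (between a
#' quarter and three quarters) of the informative probesets, with Gaussian
#' entries scaled by `effect_size`; an instance's expression is the sum of
#' its compound's target effects, its batch offset and noise.
#'
#' @param cfg A [sim_config()].
#' @return A `SyntheticBundle` list: `expression`, `activities`,
#'   `annotations` (the potency-filtered table), `network`, `map`,
#'   `collection`, `truth`, `config`.
#' @export
generate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(cfg$seed, {
    probeset_ids <- pad_ids("ps", cfg$n_probesets)
    gene_ids <- pad_ids("g", cfg$n_probesets)
    map <- data.frame(probeset_id = probeset_ids, gene_id = gene_ids,
                      stringsAsFactors = FALSE)
    compound_ids <- pad_ids("c", cfg$n_compounds)
    target_ids <- pad_ids("t", cfg$n_targets)

    informative <- sort(sample(probeset_ids, cfg$n_informative))
    informative_idx <- match(informative, probeset_ids)

    # per-target effect vectors on a random subset of informative probesets
    lo <- max(1L, floor(cfg$n_informative / 4))
    hi <- max(lo, floor(3 * cfg$n_informative / 4))
    effects <- lapply(target_ids, function(t) {
      support <- sample(informative_idx, sample(lo:hi, 1L))
      v <- numeric(cfg$n_probesets)
      v[support] <- stats::rnorm(length(support), sd = cfg$effect_size)
      v
    })
    names(effects) <- target_ids

    # heavy-tailed target counts: 1 + truncated geometric
    extra <- pmin(stats::rgeom(cfg$n_compounds, cfg$target_geom_prob),
                  cfg$max_targets_per_compound - 1L)
    compound_targets <- lapply(seq_len(cfg$n_compounds), function(i) {
      sort(sample(target_ids, min(1L + extra[i], cfg$n_targets)))
    })
    names(compound_targets) <- compound_ids

    # activity records: potent true pairs plus weak decoys
    true_pairs <- data.frame(
      compound_id = rep(compound_ids, lengths(compound_targets)),
      target_id = unlist(compound_targets, use.names = FALSE),
      stringsAsFactors = FALSE)
    n_true <- nrow(true_pairs)
    true_pairs$activity_type <- sample(c("IC50", "Ki"), n_true, replace = TRUE)
    true_pairs$activity_um <- stats::runif(n_true, 0.001, 5)
    n_decoy <- ceiling(cfg$decoy_fraction * n_true)
    decoys <- data.frame(
      compound_id = sample(compound_ids, n_decoy, replace = TRUE),
      target_id = sample(target_ids, n_decoy, replace = TRUE),
      activity_type = sample(c("IC50", "Ki", "EC50"), n_decoy, replace = TRUE),
      activity_um = stats::runif(n_decoy, 5.5, 50),
      stringsAsFactors = FALSE)
    activities <- rbind(true_pairs[, names(decoys)], decoys)
    activities <- activities[sample.int(nrow(activities)), , drop = FALSE]
    rownames(activities) <- NULL

    # treatment instances: replicates per compound, random batch labels
    n_inst <- cfg$n_compounds * cfg$replicates_per_compound
    instances <- data.frame(
      instance_id = pad_ids("i", n_inst),
      compound_id = rep(compound_ids, each = cfg$replicates_per_compound),
      batch_id = sample(pad_ids("b", cfg$n_batches), n_inst, replace = TRUE),
      cell_line = sample(c("MCF7", "PC3", "HL60"), n_inst, replace = TRUE),
      concentration_um = signif(stats::runif(n_inst, 0.1, 10), 3),
      platform = "HT_HG-U133A",
      stringsAsFactors = FALSE)

    # expression: sum of target effects + batch offset + noise
    signal <- matrix(0, n_inst, cfg$n_probesets)
    for (i in seq_len(n_inst)) {
      for (t in compound_targets[[instances$compound_id[i]]]) {
        signal[i, ] <- signal[i, ] + effects[[t]]
      }
    }
    batch_offsets <- matrix(stats::rnorm(cfg$n_batches * cfg$n_probesets,
                                         sd = cfg$batch_sd),
                            cfg$n_batches, cfg$n_probesets,
                            dimnames = list(pad_ids("b", cfg$n_batches), NULL))
    noise <- matrix(stats::rnorm(n_inst * cfg$n_probesets, sd = cfg$noise_sd),
                    n_inst, cfg$n_probesets)
    values <- signal + batch_offsets[instances$batch_id, , drop = FALSE] + noise
    dimnames(values) <- list(instances$instance_id, probeset_ids)
    expression <- expression_matrix(values, instances, centred = FALSE)

    # network: regulator(s) with 'expression' out-edges into informative
    # genes, module edges among genes of co-occurring targets, background
    informative_genes <- map$gene_id[match(informative, map$probeset_id)]
    regulator <- "TF01"
    reg_edges <- data.frame(source = regulator, target = informative_genes,
                            mode = "expression", stringsAsFactors = FALSE)
    module_edges <- do.call(rbind, lapply(target_ids, function(t) {
      g <- map$gene_id[match(probeset_ids[effects[[t]] != 0], map$probeset_id)]
      if (length(g) < 2) return(NULL)
      pairs <- cbind(g, c(g[-1], g[1])) # ring through the target's genes
      data.frame(source = pairs[, 1], target = pairs[, 2], mode = "binding",
                 stringsAsFactors = FALSE)
    }))
    n_bg <- 4L * cfg$n_probesets %/% 2L
    background <- data.frame(
      source = sample(gene_ids, n_bg, replace = TRUE),
      target = sample(gene_ids, n_bg, replace = TRUE),
      mode = sample(c("binding", "activation", "inhibition"), n_bg,
                    replace = TRUE),
      stringsAsFactors = FALSE)
    background <- background[background$source != background$target, ]
    edges <- unique(rbind(reg_edges, module_edges, background))
    network <- interaction_network(edges)

    # gene sets: the planted set (informative genes) among random sets
    sets <- list(planted_module = informative_genes)
    for (i in seq_len(20)) {
      sets[[sprintf("random_set_%02d", i)]] <-
        sample(gene_ids, sample(10:50, 1L))
    }
    collection <- gene_set_collection(sets, universe = gene_ids)

    annotations <- build_annotations(activities, cutoff = 5.0)

    structure(list(
      expression = expression,
      activities = activities,
      annotations = annotations,
      network = network,
      map = map,
      collection = collection,
      truth = list(informative_probesets = informative,
                   informative_genes = informative_genes,
                   effects = effects,
                   compound_targets = compound_targets,
                   planted_set = "planted_module"),
      config = cfg
    ), class = "SyntheticBundle")
  })
}

#' @export
print.SyntheticBundle <- function(x, ...) {
  cat(sprintf(
    "SyntheticBundle: %d instances x %d probesets, %d compounds, %d targets (seed %d)\n",
    nrow(x$expression$values), ncol(x$expression$values),
    x$config$n_compounds, x$config$n_targets, x$config$seed))
  invisible(x)
}

#' How much of the planted truth does a signature recover?
#'
#' @param bundle A `SyntheticBundle`.
#' @param sig A `GeneSignature`.
#' @return A list with `recovery` (fraction of planted informative
#'   probesets present in the signature), `planted_rank` (rank of the
#'   planted gene set in the signature's enrichment table; 1 is best) and
#'   the `enrichment` table itself.
#' @export
truth_recovery_report <- function(bundle, sig) {
  stopifnot(inherits(bundle, "SyntheticBundle"))
  planted <- bundle$truth$informative_probesets
  ids <- signature_ids(sig)
  recovery <- length(intersect(ids, planted)) / length(planted)
  enr <- enrich(sig, bundle$map, bundle$collection)
  rank <- match(bundle$truth$planted_set, enr$set)
  list(recovery = recovery, planted_rank = rank, enrichment = enr)
}

#' Write a synthetic bundle to plain-text files
#'
#' Writes `expr.tsv`, `meta.tsv`, `activities.tsv`, `edges.tsv`, `map.tsv`
#' and `pathways.gmt` into a directory, in the formats the loaders read.
#'
#' @param bundle A `SyntheticBundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "SyntheticBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(bundle$expression, file.path(dir, "expr.tsv"),
                   file.path(dir, "meta.tsv"))
  utils::write.table(bundle$activities, file.path(dir, "activities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  edges <- igraph::as_data_frame(bundle$network, what = "edges")
  names(edges)[1:2] <- c("source", "target")
  utils::write.table(edges, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$map, file.path(dir, "map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(bundle$collection, file.path(dir, "pathways.gmt"))
  invisible(dir)
}
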