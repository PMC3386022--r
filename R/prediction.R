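# Guilt-by-association target prediction: Pearson-correlation nearest
# neighbours over a signature's probesets, with all instances of the query
# compound barred from the candidate pool (a self-match carries no target
# information), scored by the set-intersection accuracy and by precision.

#' Prediction configuration
#'
#' @param k_neighbors Number of nearest neighbours whose target sets are
#'   pooled (the reference analysis uses at most 3; headline accuracy is
#'   1-NN).
#' @param correlation Similarity measure; only `"pearson"` is supported.
#' @param restrict_to_annotated If `TRUE` (default), only instances of
#'   annotated compounds are neighbour candidates; unannotated neighbours
#'   would predict nothing and conflate coverage with signal.
#' @return A `PredictionConfig` list.
#' @export
prediction_config <- function(k_neighbors = 1, correlation = "pearson",
                              restrict_to_annotated = TRUE) {
  stopifnot(k_neighbors >= 1)
  correlation <- match.arg(correlation, "pearson")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 correlation = correlation,
                 restrict_to_annotated = isTRUE(restrict_to_annotated)),
            class = "PredictionConfig")
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over the standard estimator that rejects the degenerate
#' cases (short or constant vectors) for which the coefficient is
#' undefined, instead of silently returning `NA`.
#'
#' @param x,y Numeric vectors of equal length, at least 3, neither
#'   constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
  stats::cor(x, y, method = "pearson")
}

# Correlation of every instance against every other over the signature's
# probesets. Rows with zero variance get NA correlations (handled by the
# callers: such queries are skipped, such candidates never rank).
instance_correlations <- function(m, sig) {
  xs <- subset_probesets(m, sig)$values
  if (ncol(xs) < 3) {
    warning("signature has fewer than 3 probesets; correlations are fragile")
  }
  suppressWarnings(stats::cor(t(xs)))
}

# Top-k candidates for one query, given its correlation row, excluding the
# query compound's own instances. Ties at equal correlation break by
# instance id.
top_neighbors <- function(cor_row, candidate_ids, k) {
  keep <- !is.na(cor_row)
  cor_row <- cor_row[keep]
  candidate_ids <- candidate_ids[keep]
  if (length(candidate_ids) < k) {
    stop("fewer than k = ", k, " eligible neighbour candidates")
  }
  ord <- order(cor_row, candidate_ids, method = "radix",
               decreasing = c(TRUE, FALSE))
  idx <- ord[seq_len(k)]
  data.frame(instance_id = candidate_ids[idx], correlation = cor_row[idx],
             stringsAsFactors = FALSE)
}

#' Nearest neighbours of one treatment instance
#'
#' Correlations are computed on the signature's probesets only. Every
#' instance of the query's compound is excluded from the candidate pool, so
#' a replicate or concentration variation of the query molecule can never
#' be its own neighbour.
#'
#' @param m An `ExpressionMatrix`.
#' @param sig A `GeneSignature` present in `m`.
#' @param query Instance id of the query.
#' @param cfg A [prediction_config()].
#' @param annotations Optional `TargetAnnotationTable`; required when
#'   `cfg$restrict_to_annotated` is `TRUE`.
#' @return Data frame of `instance_id`, `correlation`, ordered by
#'   decreasing correlation (ties by id).
#' @export
nearest_neighbors <- function(m, sig, query, cfg = prediction_config(),
                              annotations = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  ids <- instance_ids(m)
  qi <- match(query, ids)
  if (is.na(qi)) stop("query instance not in matrix: ", query)
  C <- instance_correlations(m, sig)
  if (all(is.na(C[qi, -qi]))) stop("undefined correlation: constant query profile")
  query_compound <- m$instances$compound_id[qi]
  eligible <- m$instances$compound_id != query_compound
  if (cfg$restrict_to_annotated) {
    if (is.null(annotations)) {
      stop("annotations required when restrict_to_annotated is TRUE")
    }
    eligible <- eligible & m$instances$compound_id %in% names(annotations)
  }
  top_neighbors(C[qi, eligible], ids[eligible], cfg$k_neighbors)
}

#' Predict targets for every annotated instance and score the signature
#'
#' Every instance whose compound has target annotations is a query. The
#' predicted target set is the union of the k nearest neighbours' target
#' sets; a prediction is successful when it intersects the query compound's
#' true target set. Accuracy is the fraction of successful queries;
#' precision is the mean over queries of |predicted and true| /
#' |predicted|. Queries with a constant profile over the signature (their
#' correlation is undefined) are skipped with a message.
#'
#' @param m An `ExpressionMatrix`.
#' @param sig A `GeneSignature`.
#' @param annotations A `TargetAnnotationTable` (the ground truth).
#' @param cfg A [prediction_config()].
#' @return A `ScoreReport` list: `accuracy`, `precision`, `n_queries`, and
#'   `per_query` (data frame with query id, compound, neighbour ids and
#'   correlations, predicted/true target strings, success, precision
#'   contribution).
#' @export
predict_and_score <- function(m, sig, annotations, cfg = prediction_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(annotations, "TargetAnnotationTable"))
  ids <- instance_ids(m)
  compound <- m$instances$compound_id
  annotated <- compound %in% names(annotations)
  if (length(unique(compound[annotated])) < 2) {
    stop("need at least 2 annotated compounds in the matrix")
  }
  C <- instance_correlations(m, sig)
  candidate_mask <- if (cfg$restrict_to_annotated) annotated else rep(TRUE, length(ids))

  queries <- which(annotated)
  skipped <- 0L
  rows <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- queries[i]
    if (all(is.na(C[q, -q]))) { # constant profile over the signature
      skipped <- skipped + 1L
      next
    }
    eligible <- candidate_mask & compound != compound[q]
    nb <- top_neighbors(C[q, eligible], ids[eligible], cfg$k_neighbors)
    nb_compounds <- compound[match(nb$instance_id, ids)]
    predicted <- sort(unique(unlist(annotations[intersect(nb_compounds,
                                                          names(annotations))],
                                    use.names = FALSE)))
    true <- annotations[[compound[q]]]
    hit <- length(intersect(predicted, true))
    rows[[i]] <- data.frame(
      query_instance = ids[q],
      query_compound = compound[q],
      neighbor_instances = paste(nb$instance_id, collapse = ";"),
      neighbor_correlations = paste(formatC(nb$correlation, digits = 6,
                                            format = "g"), collapse = ";"),
      predicted_targets = paste(predicted, collapse = ";"),
      true_targets = paste(true, collapse = ";"),
      success = hit > 0,
      precision = if (length(predicted) == 0) 0 else hit / length(predicted),
      stringsAsFactors = FALSE
    )
  }
  if (skipped > 0) {
    message("predict_and_score: skipped ", skipped,
            " query instance(s) with constant profile over the signature")
  }
  per_query <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_query) || nrow(per_query) == 0) {
    stop("no scorable query instance")
  }
  structure(list(accuracy = mean(per_query$success),
                 precision = mean(per_query$precision),
                 n_queries = nrow(per_query),
                 per_query = per_query),
            class = "ScoreReport")
}

#' @export
print.ScoreReport <- function(x, ...) {
  cat(sprintf("ScoreReport: accuracy %.4f, precision %.4f over %d queries\n",
              x$accuracy, x$precision, x$n_queries))
  invisible(x)
}

# Fast fitness path used by the genetic algorithm and the size-ladder
# sweeps: same accuracy as predict_and_score (asserted in the tests) but
# without assembling per-query records. Returns a closure so the
# per-dataset work (compound sharing matrix, candidate masks) is done once
# per matrix, not once per signature.
accuracy_evaluator <- function(m, annotations, k = 1,
                               restrict_to_annotated = TRUE) {
  X <- m$values
  compound <- m$instances$compound_id
  annotated <- compound %in% names(annotations)
  queries <- which(annotated)
  compounds <- names(annotations)
  # compound x compound: do the two target sets intersect?
  targets <- sort(unique(unlist(annotations, use.names = FALSE)))
  inc <- matrix(0L, length(compounds), length(targets),
                dimnames = list(compounds, targets))
  for (i in seq_along(compounds)) inc[i, annotations[[i]]] <- 1L
  share <- tcrossprod(inc) > 0
  comp_idx <- match(compound, compounds)
  candidate <- if (restrict_to_annotated) annotated else rep(TRUE, length(compound))
  ids <- instance_ids(m)

  function(sig_ids) {
    Xs <- X[, sig_ids, drop = FALSE]
    C <- suppressWarnings(stats::cor(t(Xs)))
    successes <- 0L
    n_scored <- 0L
    for (q in queries) {
      row <- C[q, ]
      elig <- candidate & compound != compound[q] & !is.na(row)
      if (!any(elig)) next
      n_scored <- n_scored + 1L
      kk <- min(k, sum(elig))
      re <- row[elig]
      ord <- order(re, ids[elig], method = "radix",
                   decreasing = c(TRUE, FALSE))
      nb <- which(elig)[ord[seq_len(kk)]]
      if (any(share[comp_idx[q], comp_idx[nb]])) successes <- successes + 1L
    }
    if (n_scored == 0L) return(NA_real_)
    successes / n_scored
  }
}

#' Accuracy of guessing under shuffled annotations
#'
#' Repeats [predict_and_score()] against independently shuffled
#' compound-target tables. The resulting accuracy distribution is the
#' chance baseline every designed signature must exceed.
#'
#' @param m An `ExpressionMatrix`.
#' @param sig A `GeneSignature`.
#' @param annotations A `TargetAnnotationTable`.
#' @param cfg A [prediction_config()].
#' @param n_shuffles Number of shuffled replicates.
#' @param seed Integer seed; replicate seeds are derived from it.
#' @return A list with `mean`, `sd`, and the per-shuffle `accuracies`.
#' @export
random_baseline <- function(m, sig, annotations, cfg = prediction_config(),
                            n_shuffles = 20, seed = 1) {
  stopifnot(n_shuffles >= 1)
  shuffle_seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max, n_shuffles))
  acc <- vapply(shuffle_seeds, function(s) {
    t_shuf <- shuffle_associations(annotations, seed = s)
    predict_and_score(m, sig, t_shuf, cfg)$accuracy
  }, numeric(1))
  list(mean = mean(acc), sd = stats::sd(acc), accuracies = acc)
}
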