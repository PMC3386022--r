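# Potency-filtered compound-target annotations: the ground truth for
# guilt-by-association prediction, and the shuffled-association null.

#' Read compound activity records
#'
#' @param path TSV with header `compound_id`, `target_id`, `activity_type`,
#'   `activity_um`.
#' @return Data frame of activity records.
#' @export
read_activity_records <- function(path) {
  if (!file.exists(path)) stop("activity file not found: ", path)
  rec <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("compound_id", "target_id", "activity_type", "activity_um")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols) > 0) {
    stop("activity table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  rec
}

#' Build a potency-filtered compound-target annotation table
#'
#' Keeps the pair (compound, target) if any IC50 or Ki record for it has an
#' activity at or below the cutoff (the cutoff is inclusive). Records with
#' other activity types are dropped with a message. Compounds left with no
#' target after filtering are absent from the result.
#'
#' @param records Data frame with columns `compound_id`, `target_id`,
#'   `activity_type` (IC50/Ki; others dropped), `activity_um` (micromolar,
#'   positive).
#' @param cutoff Potency cutoff in micromolar (default 5).
#' @param allowed_types Activity types retained (default `c("IC50", "Ki")`).
#' @return A `TargetAnnotationTable`: named list mapping compound_id to a
#'   character vector of target ids, with the cutoff stored as an attribute.
#' @export
build_annotations <- function(records, cutoff = 5.0,
                              allowed_types = c("IC50", "Ki")) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (any(records$activity_um <= 0)) stop("activity_um must be positive")
  type_ok <- records$activity_type %in% allowed_types
  if (any(!type_ok)) {
    message("build_annotations: dropped ", sum(!type_ok),
            " record(s) with activity type outside {",
            paste(allowed_types, collapse = ", "), "}")
  }
  keep <- type_ok & records$activity_um <= cutoff
  kept <- records[keep, c("compound_id", "target_id")]
  kept <- unique(kept)
  if (nrow(kept) == 0) {
    message("build_annotations: no pair survives the ", cutoff, " uM cutoff")
    mapping <- list()
  } else {
    mapping <- lapply(
      split(as.character(kept$target_id), as.character(kept$compound_id)),
      function(t) sort(unique(t))
    )
  }
  annotation_table(mapping, cutoff)
}

#' Construct a TargetAnnotationTable from a compound -> targets mapping
#'
#' @param mapping Named list; each element a non-empty character vector of
#'   target ids for one compound.
#' @param potency_cutoff Cutoff (micromolar) the mapping was filtered at.
#' @return A `TargetAnnotationTable`.
#' @export
annotation_table <- function(mapping, potency_cutoff = 5.0) {
  stopifnot(is.list(mapping))
  if (length(mapping) > 0) {
    stopifnot(!is.null(names(mapping)), all(nzchar(names(mapping))))
    if (any(lengths(mapping) == 0)) stop("empty target set in mapping")
    mapping <- lapply(mapping, function(t) sort(unique(as.character(t))))
  }
  structure(mapping, potency_cutoff = potency_cutoff,
            class = "TargetAnnotationTable")
}

#' @export
print.TargetAnnotationTable <- function(x, ...) {
  cat(sprintf(
    "TargetAnnotationTable: %d compounds, %d targets, %d pairs (cutoff %g uM)\n",
    length(x), length(unique(unlist(x))), sum(lengths(x)),
    attr(x, "potency_cutoff")))
  invisible(x)
}

#' Summary statistics of the compound-target matrix
#'
#' Reports how sparse the annotation matrix is and how target counts are
#' distributed over compounds (polypharmacology structure).
#'
#' @param t A `TargetAnnotationTable`.
#' @return A list with `compounds`, `targets`, `pairs`, `density_percent`
#'   (100 x pairs / (compounds x targets)), `per_compound_counts` (named
#'   integer vector), `min_targets`, `max_targets`, `n_single_target`
#'   (compounds with exactly one target) and `n_five_plus` (compounds with
#'   at least five).
#' @export
matrix_stats <- function(t) {
  stopifnot(inherits(t, "TargetAnnotationTable"), length(t) > 0)
  counts <- lengths(t)
  n_compounds <- length(t)
  n_targets <- length(unique(unlist(t)))
  n_pairs <- sum(counts)
  list(
    compounds = n_compounds,
    targets = n_targets,
    pairs = n_pairs,
    density_percent = annotation_density(n_compounds, n_targets, n_pairs),
    per_compound_counts = counts,
    min_targets = min(counts),
    max_targets = max(counts),
    n_single_target = sum(counts == 1L),
    n_five_plus = sum(counts >= 5L)
  )
}

#' Density of a compound-target matrix, in percent
#'
#' @param compounds,targets,pairs Counts of annotated compounds, distinct
#'   targets, and compound-target pairs.
#' @return `100 * pairs / (compounds * targets)`.
#' @export
annotation_density <- function(compounds, targets, pairs) {
  stopifnot(compounds > 0, targets > 0, pairs >= 0)
  100 * pairs / (compounds * targets)
}

#' Shuffle compound-target associations (null model)
#'
#' Permutes the target sets across compound ids uniformly at random: each
#' compound receives some compound's complete original target set, so the
#' multiset of per-compound target counts is preserved exactly. This is the
#' null against which signature-driven accuracy is compared.
#'
#' @param t A `TargetAnnotationTable` with at least two compounds.
#' @param seed Integer seed; the shuffle is deterministic given the seed.
#' @param unit `"sets"` (default) permutes whole target sets; `"pairs"`
#'   instead re-assigns each (compound, target) pair's compound uniformly,
#'   which preserves the pair count but not per-compound counts.
#' @return A shuffled `TargetAnnotationTable`.
#' @export
shuffle_associations <- function(t, seed, unit = c("sets", "pairs")) {
  stopifnot(inherits(t, "TargetAnnotationTable"), length(t) >= 2)
  unit <- match.arg(unit)
  withr::with_seed(seed, {
    if (unit == "sets") {
      perm <- sample.int(length(t))
      shuffled <- unclass(t)[perm]
      names(shuffled) <- names(t)
    } else {
      compounds <- names(t)
      pairs <- data.frame(
        compound_id = rep(compounds, lengths(t)),
        target_id = unlist(t, use.names = FALSE)
      )
      pairs$compound_id <- sample(compounds, nrow(pairs), replace = TRUE)
      pairs <- unique(pairs)
      shuffled <- split(pairs$target_id, pairs$compound_id)
    }
    annotation_table(shuffled, attr(t, "potency_cutoff"))
  })
}
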