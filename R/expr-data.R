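# Expression matrix container and batch normalisation.
#
# The unit of observation is a treatment instance: one (compound,
# concentration, cell line, platform) expression measurement. Instances are
# rows, probesets columns; all correlation work downstream operates on rows.

#' Construct an ExpressionMatrix
#'
#' Bundles a numeric instances-by-probesets matrix with per-instance
#' metadata. Expression values are assumed to be on a log scale (e.g. RMA
#' output); the package never re-summarises probe-level data.
#'
#' @param values Numeric matrix, instances in rows, probesets in columns.
#'   Row names are instance ids, column names probeset ids.
#' @param instances Data frame with one row per instance. Required columns:
#'   `instance_id`, `compound_id`, `batch_id`; optional: `cell_line`,
#'   `concentration_um`, `platform`. Row order must match `values`.
#' @param centred Logical flag: has batch mean-centring been applied?
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, instances, centred = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values), is.data.frame(instances))
  required <- c("instance_id", "compound_id", "batch_id")
  missing_cols <- setdiff(required, names(instances))
  if (length(missing_cols) > 0) {
    stop("instance metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  instances$instance_id <- as.character(instances$instance_id)
  instances$compound_id <- as.character(instances$compound_id)
  instances$batch_id <- as.character(instances$batch_id)
  if (nrow(values) != nrow(instances)) {
    stop("dimension mismatch: ", nrow(values), " matrix rows vs ",
         nrow(instances), " metadata rows")
  }
  if (is.null(rownames(values))) rownames(values) <- instances$instance_id
  if (!identical(rownames(values), instances$instance_id)) {
    stop("matrix row names do not match metadata instance_id order")
  }
  if (anyDuplicated(instances$instance_id)) {
    stop("duplicate instance_id: ",
         paste(unique(instances$instance_id[duplicated(instances$instance_id)]),
               collapse = ", "))
  }
  if (is.null(colnames(values))) stop("matrix lacks probeset column names")
  if (anyDuplicated(colnames(values))) {
    stop("duplicate probeset: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  if (any(instances$compound_id == "")) stop("empty compound_id")
  if (any(instances$batch_id == "")) stop("empty batch_id")
  if (anyNA(values)) stop("expression matrix contains missing values")
  structure(
    list(values = values, instances = instances, centred = isTRUE(centred)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d treatment instances x %d probesets (%s)\n",
    nrow(x$values), ncol(x$values),
    if (x$centred) "batch mean-centred" else "raw"
  ))
  cat(sprintf("  compounds: %d  batches: %d\n",
              length(unique(x$instances$compound_id)),
              length(unique(x$instances$batch_id))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Probeset ids of an ExpressionMatrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of probeset ids, in matrix column order.
#' @export
probesets <- function(m) colnames(m$values)

#' Instance ids of an ExpressionMatrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of instance ids, in matrix row order.
#' @export
instance_ids <- function(m) m$instances$instance_id

read_tsv_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  body <- tab[, -1L, drop = FALSE]
  non_numeric <- !vapply(body, is.numeric, logical(1))
  if (any(non_numeric)) {
    stop("non-numeric cell(s) in column(s): ",
         paste(names(body)[non_numeric], collapse = ", "))
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  mat
}

read_gct_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "#1.2") {
    stop("not a GCT 1.2 file (missing #1.2 header)")
  }
  dims <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]])
  if (length(dims) < 2 || anyNA(dims)) stop("malformed GCT dimension line")
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-(1:2)]
  if (length(sample_ids) != dims[2]) {
    stop("GCT declares ", dims[2], " samples but header has ",
         length(sample_ids))
  }
  body_lines <- lines[-(1:3)]
  body_lines <- body_lines[nzchar(body_lines)]
  if (length(body_lines) != dims[1]) {
    stop("GCT declares ", dims[1], " rows but body has ", length(body_lines))
  }
  fields <- strsplit(body_lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != dims[2] + 2L)) {
    stop("GCT body row width does not match declared dimensions")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  num <- vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(v)) stop("non-numeric cell in GCT body")
    v
  }, numeric(dims[2]))
  # vapply returns samples x rows; transpose to probesets x samples
  mat <- if (dims[2] == 1L) matrix(num, ncol = 1L) else t(num)
  rownames(mat) <- ids
  colnames(mat) <- sample_ids
  mat
}

#' Load an expression matrix with instance metadata
#'
#' Reads a tab-separated expression table (probesets x instances or
#' instances x probesets; orientation auto-detected against the metadata)
#' or a GCT 1.2 file, joins per-instance metadata, and returns a raw
#' (un-centred) [expression_matrix()].
#'
#' Orientation detection: if the column header ids are all found in the
#' metadata's `instance_id`, columns are taken to be instances; if instead
#' the first-column ids are all instance ids, rows are. If both or neither
#' interpretation fits, an explicit `orientation` is required.
#'
#' @param path Expression TSV or GCT 1.2 file. First column of a TSV holds
#'   row ids.
#' @param metadata_path TSV with header `instance_id`, `compound_id`,
#'   `batch_id` and optionally `cell_line`, `concentration_um`, `platform`.
#' @param orientation `"auto"` (default), `"instances_in_columns"` or
#'   `"instances_in_rows"`.
#' @param impute_missing If `TRUE`, missing expression values are replaced
#'   by the probeset median; by default missing values are an error.
#' @return An `ExpressionMatrix` with `centred = FALSE`.
#' @export
load_expression <- function(path, metadata_path,
                            orientation = c("auto", "instances_in_columns",
                                            "instances_in_rows"),
                            impute_missing = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)

  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("instance_id", "compound_id", "batch_id")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  meta$instance_id <- as.character(meta$instance_id)

  first_line <- readLines(path, n = 1L)
  is_gct <- identical(trimws(first_line), "#1.2")
  mat <- if (is_gct) read_gct_matrix(path) else read_tsv_matrix(path)

  if (is_gct) {
    # GCT is by definition features x samples
    mat <- t(mat)
  } else {
    cols_are_instances <- all(colnames(mat) %in% meta$instance_id)
    rows_are_instances <- all(rownames(mat) %in% meta$instance_id)
    flip <- switch(orientation,
      instances_in_columns = TRUE,
      instances_in_rows = FALSE,
      auto = {
        if (cols_are_instances && rows_are_instances) {
          stop("orientation ambiguous: both axes match metadata instance ids; ",
               "pass orientation= explicitly")
        }
        if (!cols_are_instances && !rows_are_instances) {
          stop("orientation undetectable: neither axis matches metadata ",
               "instance ids")
        }
        cols_are_instances
      }
    )
    if (flip) mat <- t(mat)
  }

  if (anyDuplicated(rownames(mat))) {
    stop("duplicate instance row(s): ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate probeset: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  }
  unknown <- setdiff(rownames(mat), meta$instance_id)
  if (length(unknown) > 0) {
    stop("instance(s) lacking metadata: ", paste(unknown, collapse = ", "))
  }
  if (anyNA(mat)) {
    if (!impute_missing) {
      stop("expression matrix contains missing values ",
           "(set impute_missing = TRUE for probeset-median imputation)")
    }
    n_imputed <- sum(is.na(mat))
    for (j in seq_len(ncol(mat))) {
      nas <- is.na(mat[, j])
      if (any(nas)) mat[nas, j] <- stats::median(mat[, j], na.rm = TRUE)
    }
    message("imputed ", n_imputed, " missing value(s) with probeset medians")
  }

  meta <- meta[match(rownames(mat), meta$instance_id), , drop = FALSE]
  rownames(meta) <- NULL
  expression_matrix(mat, meta, centred = FALSE)
}

#' Batch mean-centring of expression values
#'
#' Within every batch containing more than `min_batch_size` treatment
#' instances, subtracts each probeset's within-batch mean, so that values
#' become expression relative to the batch average. Instances in batches at
#' or below the threshold are excluded from the returned matrix (an
#' un-centred instance would carry its full batch offset into every
#' correlation); a message reports how many were dropped.
#'
#' @param m A raw `ExpressionMatrix` (`centred = FALSE`).
#' @param min_batch_size Batches must have strictly more instances than this
#'   to be centred (default 5).
#' @return A centred `ExpressionMatrix` containing only instances from
#'   batches large enough to centre.
#' @export
batch_mean_center <- function(m, min_batch_size = 5) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$centred) stop("matrix is already centred")
  batch <- m$instances$batch_id
  sizes <- table(batch)
  keep_batches <- names(sizes)[sizes > min_batch_size]
  keep <- batch %in% keep_batches
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("batch_mean_center: excluded ", n_dropped,
            " instance(s) in ", sum(!(names(sizes) %in% keep_batches)),
            " batch(es) of size <= ", min_batch_size)
  }
  if (!any(keep)) stop("no batch has more than ", min_batch_size, " instances")
  vals <- m$values[keep, , drop = FALSE]
  batch <- batch[keep]
  for (b in keep_batches) {
    rows <- batch == b
    mu <- colMeans(vals[rows, , drop = FALSE])
    vals[rows, ] <- sweep(vals[rows, , drop = FALSE], 2L, mu)
  }
  meta <- m$instances[keep, , drop = FALSE]
  rownames(meta) <- NULL
  expression_matrix(vals, meta, centred = TRUE)
}

#' Restrict an expression matrix to a signature's probesets
#'
#' @param m An `ExpressionMatrix`.
#' @param sig A [gene_signature()] (or bare character vector of probeset
#'   ids) whose probesets must all be present in `m`.
#' @return An `ExpressionMatrix` with columns restricted to the signature's
#'   probesets, in signature order; instances unchanged.
#' @export
subset_probesets <- function(m, sig) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  ids <- signature_ids(sig)
  missing <- setdiff(ids, colnames(m$values))
  if (length(missing) > 0) {
    stop("probeset(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  expression_matrix(m$values[, ids, drop = FALSE], m$instances,
                    centred = m$centred)
}

#' Write an expression matrix and its metadata as TSV
#'
#' Companion to [load_expression()]: writes the matrix probesets-in-rows
#' (first column `probeset_id`) and the metadata table.
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output expression TSV path.
#' @param metadata_path Output metadata TSV path (optional).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(m, path, metadata_path = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  tab <- data.frame(probeset_id = colnames(m$values),
                    t(m$values), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.table(m$instances, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
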