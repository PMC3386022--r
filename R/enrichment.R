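# Hypergeometric over-representation of a signature's genes in pathway
# gene sets (one-sided Fisher's exact test), against any GMT collection.

#' Construct a gene-set collection
#'
#' Sets are restricted to the universe; sets left empty are dropped with a
#' message.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Character vector of gene ids; defaults to the union of
#'   all sets.
#' @return A `GeneSetCollection` list with `sets` and `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    message("gene_set_collection: dropped ", sum(empty),
            " empty set(s) after restriction to the universe")
    sets <- sets[!empty]
  }
  structure(list(sets = sets, universe = universe), class = "GeneSetCollection")
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: tab-separated lines of set name, description,
#'   then member gene ids.
#' @param universe Optional explicit universe; defaults to the union of
#'   all sets.
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  gene_set_collection(fgsea::gmtPathways(path), universe)
}

#' Write a gene-set collection as GMT
#'
#' @param coll A `GeneSetCollection`.
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions
#'   (GMT column 2; defaults to `"na"`).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(coll, path, descriptions = NULL) {
  stopifnot(inherits(coll, "GeneSetCollection"))
  lines <- vapply(names(coll$sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, desc, coll$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric tail p-value for a set overlap
#'
#' Probability of drawing an overlap equal to or greater than the observed
#' one when `query_n` genes are drawn from a universe of `universe_n`
#' containing `pathway_k` pathway members:
#' \deqn{p = \sum_{i=x}^{\min(K, n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' Identical to a one-sided Fisher's exact test.
#'
#' @param universe_n Universe size N.
#' @param pathway_k Pathway size K (within the universe).
#' @param query_n Query set size n.
#' @param overlap_x Observed overlap x.
#' @return p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(universe_n, pathway_k, query_n, overlap_x) {
  stopifnot(universe_n >= 1, pathway_k >= 0, query_n >= 0, overlap_x >= 0)
  if (pathway_k > universe_n || query_n > universe_n) {
    stop("pathway and query sizes must not exceed the universe")
  }
  if (overlap_x > min(pathway_k, query_n)) {
    stop("overlap exceeds min(pathway, query) size")
  }
  stats::phyper(overlap_x - 1, pathway_k, universe_n - pathway_k, query_n,
                lower.tail = FALSE)
}

#' Pathway enrichment of a signature
#'
#' The signature's probesets are translated to genes (deduplicated); the
#' test universe is the intersection of the collection's universe with the
#' genes represented on the chip (i.e. appearing in the mapping table).
#' Each set gets a hypergeometric tail p-value for its overlap with the
#' query; results are sorted by ascending p (ties by set name) and carry a
#' Benjamini-Hochberg adjusted p alongside the raw one.
#'
#' @param sig A `GeneSignature`.
#' @param map Data frame with columns `probeset_id`, `gene_id`.
#' @param coll A `GeneSetCollection`.
#' @return Data frame with columns `set`, `set_size`, `overlap`, `p`,
#'   `neg_log10_p`, `p_adjusted`.
#' @export
enrich <- function(sig, map, coll) {
  stopifnot(inherits(coll, "GeneSetCollection"), is.data.frame(map),
            all(c("probeset_id", "gene_id") %in% names(map)))
  ids <- signature_ids(sig)
  chip_genes <- unique(map$gene_id)
  universe <- intersect(coll$universe, chip_genes)
  query <- intersect(unique(map$gene_id[map$probeset_id %in% ids]), universe)
  if (length(query) == 0) stop("signature maps to no gene in the universe")
  res <- lapply(names(coll$sets), function(nm) {
    s <- intersect(coll$sets[[nm]], universe)
    x <- length(intersect(query, s))
    p <- hypergeom_pvalue(length(universe), length(s), length(query), x)
    data.frame(set = nm, set_size = length(s), overlap = x, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$neg_log10_p <- -log10(res$p)
  res$p_adjusted <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}
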