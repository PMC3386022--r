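# Network-derived signatures: score genes by the topology of a directed
# interaction network (STRING-actions-like edge list with an edge mode),
# then translate top-ranked genes into probeset signatures via the chip's
# probeset-gene mapping.

#' Build a directed interaction network
#'
#' @param edges Data frame with columns `source`, `target`, `mode` (edge
#'   mode label, e.g. `"binding"`, `"activation"`, `"expression"`).
#'   Duplicate (source, target, mode) triples are collapsed.
#' @return An [igraph::igraph] directed graph with a `mode` edge attribute.
#' @export
interaction_network <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "mode") %in% names(edges)))
  edges <- unique(edges[, c("source", "target", "mode")])
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  g
}

#' Read an interaction network from an edge-list TSV
#'
#' @param path TSV with header `source`, `target`, `mode`.
#' @return A directed igraph graph with a `mode` edge attribute.
#' @export
read_interaction_network <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  edges <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
  interaction_network(edges)
}

#' Read a probeset-gene mapping table
#'
#' @param path TSV with header `probeset_id`, `gene_id`; many-to-many
#'   pairs are allowed.
#' @return Data frame with columns `probeset_id`, `gene_id`.
#' @export
read_probeset_gene_map <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  map <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("probeset_id", "gene_id") %in% names(map)))
  unique(map[, c("probeset_id", "gene_id")])
}

#' Node centrality scores
#'
#' Centralities on the directed, unweighted graph. `betweenness` counts,
#' for each node, the shortest directed paths between ordered pairs of
#' other nodes that pass through it, fractionally when several shortest
#' paths tie (unnormalised; only the ranking is used downstream).
#' `closeness` is (number of nodes reachable) / (sum of shortest-path
#' distances to them), with 0 for nodes that reach nothing. The degree
#' kinds are raw edge counts, ignoring edge mode.
#'
#' @param net A directed igraph graph.
#' @param kind One of `betweenness`, `closeness`, `degree`, `in_degree`,
#'   `out_degree`.
#' @param undirected If `TRUE`, path-based centralities treat edges as
#'   undirected.
#' @return Named numeric vector, one score per node.
#' @export
centrality_scores <- function(net, kind, undirected = FALSE) {
  stopifnot(igraph::is_igraph(net), igraph::vcount(net) > 0)
  kinds <- c("betweenness", "closeness", "degree", "in_degree", "out_degree")
  if (!kind %in% kinds) {
    stop("unknown centrality kind '", kind, "'; expected one of: ",
         paste(kinds, collapse = ", "))
  }
  switch(kind,
    betweenness = igraph::betweenness(net, directed = !undirected,
                                      weights = NA, normalized = FALSE),
    closeness = {
      mode <- if (undirected) "all" else "out"
      d <- igraph::distances(net, mode = mode, weights = NA)
      diag(d) <- Inf
      apply(d, 1L, function(row) {
        fin <- is.finite(row)
        if (!any(fin)) 0 else sum(fin) / sum(row[fin])
      })
    },
    degree = igraph::degree(net, mode = "all", loops = TRUE),
    in_degree = igraph::degree(net, mode = "in", loops = TRUE),
    out_degree = igraph::degree(net, mode = "out", loops = TRUE)
  )
}

#' Regulator nodes of a network
#'
#' A regulator (transcriptional modifier) is any node with at least one
#' outgoing edge of mode `"expression"`.
#'
#' @param net A directed igraph graph with a `mode` edge attribute.
#' @return Character vector of regulator node names.
#' @export
regulator_nodes <- function(net) {
  stopifnot(igraph::is_igraph(net))
  modes <- igraph::edge_attr(net, "mode")
  if (is.null(modes)) stop("network has no 'mode' edge attribute")
  expr_edges <- which(modes == "expression")
  if (length(expr_edges) == 0) return(character(0))
  heads <- igraph::ends(net, expr_edges, names = TRUE)[, 1L]
  sort(unique(heads))
}

#' Mean distance from upstream regulators
#'
#' For every non-regulator node reachable from at least one regulator,
#' the score is the mean shortest directed path length over all regulators
#' that reach it. Distances count edge hops over all edge modes. Regulators
#' themselves and nodes no regulator reaches receive no score. Used
#' descending: high scores select a diverse set of genes far downstream of
#' expression regulators.
#'
#' @param net A directed igraph graph with a `mode` edge attribute and at
#'   least one `"expression"`-mode edge.
#' @return Named numeric vector of scores for scored nodes only.
#' @export
regulator_distance_scores <- function(net) {
  regs <- regulator_nodes(net)
  if (length(regs) == 0) stop("no regulatory node (outgoing 'expression' edge) in network")
  d <- igraph::distances(net, v = regs, mode = "out", weights = NA)
  targets <- setdiff(colnames(d), regs)
  scores <- vapply(targets, function(v) {
    dv <- d[, v]
    fin <- is.finite(dv) & dv > 0
    if (!any(fin)) NA_real_ else mean(dv[fin])
  }, numeric(1))
  scores[!is.na(scores)]
}

#' Convert node scores into a probeset signature
#'
#' Traverses nodes in descending score order (ties broken by gene id),
#' appending every probeset mapped to each node (ties by probeset id),
#' until `k` distinct probesets are collected. A probeset mapped to several
#' genes is kept once, at its first occurrence.
#'
#' @param scores Named numeric vector of node scores.
#' @param map Data frame with columns `probeset_id`, `gene_id`.
#' @param k Signature size.
#' @param origin Origin label for the resulting signature.
#' @return A `GeneSignature` of size `k`.
#' @export
nodes_to_signature <- function(scores, map, k, origin = "network") {
  stopifnot(is.numeric(scores), !is.null(names(scores)),
            is.data.frame(map),
            all(c("probeset_id", "gene_id") %in% names(map)))
  ord <- order_stat_then_id(scores, names(scores), decreasing_stat = TRUE)
  genes <- names(scores)[ord]
  out <- character(0)
  for (g in genes) {
    ps <- sort(map$probeset_id[map$gene_id == g], method = "radix")
    out <- c(out, setdiff(ps, out))
    if (length(out) >= k) break
  }
  if (length(out) < k) {
    stop("only ", length(out), " probesets map to scored nodes; k = ", k)
  }
  gene_signature(out[seq_len(k)], origin = origin)
}

#' Network-based signature in one step
#'
#' Scores nodes by a topological criterion and converts the ranking into a
#' probeset signature.
#'
#' @param net A directed igraph graph.
#' @param map Probeset-gene mapping data frame.
#' @param criterion One of the [centrality_scores()] kinds or
#'   `"regulator_distance"`.
#' @param k Signature size.
#' @return A `GeneSignature`.
#' @export
network_signature <- function(net, map, criterion, k) {
  scores <- if (criterion == "regulator_distance") {
    regulator_distance_scores(net)
  } else {
    centrality_scores(net, criterion)
  }
  nodes_to_signature(scores, map, k, origin = criterion)
}
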