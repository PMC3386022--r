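# Brute-force oracles, written independently of the implementation paths
# they check: shortest-path quantities from adjacency-matrix powers, and
# hypergeometric tail probabilities from exhaustive subset enumeration.

# Shortest-path distances and shortest-path counts for a directed graph
# given as a 0/1 adjacency matrix. The number of walks of length k from s
# to t is (A^k)[s, t]; the first k with a positive entry is the distance,
# and every minimal-length walk is a shortest path.
oracle_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  Ak <- diag(n)
  for (k in seq_len(n)) {
    Ak <- Ak %*% adj
    newly <- is.infinite(d) & Ak > 0
    diag(newly) <- FALSE
    d[newly] <- k
    sigma[newly] <- Ak[newly]
  }
  diag(d) <- 0
  list(d = d, sigma = sigma)
}

# Unnormalised fractional betweenness: for node v, sum over ordered pairs
# (s, t), s != v != t, of the fraction of shortest s-t paths through v.
oracle_betweenness <- function(adj) {
  p <- oracle_paths(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    through <- outer(p$d[, v], p$d[v, ], "+") == p$d &
      is.finite(p$d) & p$d > 0
    through[v, ] <- FALSE
    through[, v] <- FALSE
    diag(through) <- FALSE
    if (!any(through)) return(0)
    contrib <- outer(p$sigma[, v], p$sigma[v, ]) / p$sigma
    sum(contrib[through])
  }, numeric(1))
}

# Closeness as (number of reachable nodes) / (sum of distances to them).
oracle_closeness <- function(adj) {
  d <- oracle_paths(adj)$d
  diag(d) <- Inf
  apply(d, 1L, function(row) {
    fin <- is.finite(row)
    if (!any(fin)) 0 else sum(fin) / sum(row[fin])
  })
}

# Mean shortest-path distance from the regulators that reach each
# non-regulator node; nodes reached by no regulator are dropped.
oracle_regulator_distance <- function(adj, regulators) {
  d <- oracle_paths(adj)$d
  n <- nrow(adj)
  targets <- setdiff(seq_len(n), regulators)
  out <- vapply(targets, function(v) {
    dv <- d[regulators, v]
    fin <- is.finite(dv) & dv > 0
    if (!any(fin)) NA_real_ else mean(dv[fin])
  }, numeric(1))
  names(out) <- as.character(targets)
  out[!is.na(out)]
}

# Random directed graph on n nodes as an edge data frame with modes; every
# graph has at least one edge.
random_digraph_edges <- function(n, p_edge = 0.3,
                                 modes = c("binding", "activation",
                                           "expression")) {
  repeat {
    adj <- matrix(stats::runif(n * n) < p_edge, n, n)
    diag(adj) <- FALSE
    if (any(adj)) break
  }
  idx <- which(adj, arr.ind = TRUE)
  edges <- data.frame(source = paste0("n", idx[, 1]),
                      target = paste0("n", idx[, 2]),
                      mode = sample(modes, nrow(idx), replace = TRUE),
                      stringsAsFactors = FALSE)
  list(adj = adj * 1, edges = edges)
}

# Exact hypergeometric tail by enumerating every n-subset of an N-element
# universe whose first K elements form the pathway.
oracle_hypergeom_tail <- function(N, K, n, x) {
  if (n == 0) return(if (x == 0) 1 else NA_real_)
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= x)
}
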