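# Gene signatures: fixed-size, duplicate-free probeset sets, constructed
# from expression statistics, at random, or downstream by the genetic
# algorithm; plus the half-logarithmic size ladder and overlap comparison.

#' Construct a GeneSignature
#'
#' @param probeset_ids Ordered, duplicate-free character vector of probeset
#'   ids.
#' @param origin Label recording how the signature was built (a criterion
#'   name, `"random"` or `"ga"`).
#' @return An object of class `GeneSignature`.
#' @export
gene_signature <- function(probeset_ids, origin = "manual") {
  probeset_ids <- as.character(probeset_ids)
  if (length(probeset_ids) < 1) stop("signature must contain at least one probeset")
  if (anyDuplicated(probeset_ids)) {
    stop("duplicate probeset in signature: ",
         paste(unique(probeset_ids[duplicated(probeset_ids)]), collapse = ", "))
  }
  structure(list(probeset_ids = probeset_ids, size = length(probeset_ids),
                 origin = origin),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature of %d probesets (origin: %s)\n", x$size, x$origin))
  shown <- utils::head(x$probeset_ids, 6L)
  cat("  ", paste(shown, collapse = ", "),
      if (x$size > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.GeneSignature <- function(x) x$size

# Accept either a GeneSignature or a bare character vector of ids.
signature_ids <- function(sig) {
  if (inherits(sig, "GeneSignature")) sig$probeset_ids else as.character(sig)
}

# Locale-independent ordering: primary key a numeric statistic, secondary
# key the probeset id (C collation), so rankings cut at k deterministically.
order_stat_then_id <- function(stat, ids, decreasing_stat) {
  order(stat, ids, method = "radix", decreasing = c(decreasing_stat, FALSE))
}

#' Rank probesets by an expression statistic and keep the top k
#'
#' Statistics are computed across all instances of the matrix (the design
#' is unsupervised: target annotations play no role). Criteria: highest or
#' lowest mean expression (`max_mean`/`min_mean`), highest or lowest
#' standard deviation (`max_sd`/`min_sd`), highest or lowest mean absolute
#' expression (`max_abs_mean`/`min_abs_mean`), and highest Shannon entropy
#' of binned expression values (`shannon`). Ties are broken by probeset id
#' so the cut at k is deterministic.
#'
#' @param m An `ExpressionMatrix`.
#' @param criterion One of `max_mean`, `min_mean`, `max_sd`, `min_sd`,
#'   `max_abs_mean`, `min_abs_mean`, `shannon`.
#' @param k Signature size; at most the number of probesets.
#' @param bins,range_lo,range_hi Binning for the `shannon` criterion; see
#'   [shannon_entropy()].
#' @return A `GeneSignature` of size `k` with `origin = criterion`.
#' @export
rank_by_criterion <- function(m, criterion, k, bins = 200,
                              range_lo = -5, range_hi = 8) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  criteria <- c("max_mean", "min_mean", "max_sd", "min_sd",
                "max_abs_mean", "min_abs_mean", "shannon")
  if (!criterion %in% criteria) {
    stop("unknown criterion '", criterion, "'; expected one of: ",
         paste(criteria, collapse = ", "))
  }
  x <- m$values
  if (k < 1 || k > ncol(x)) {
    stop("k = ", k, " out of range [1, ", ncol(x), "]")
  }
  n <- nrow(x)
  stat <- switch(criterion,
    max_mean = ,
    min_mean = colMeans(x),
    max_sd = ,
    min_sd = {
      mu <- colMeans(x)
      sqrt(pmax(colMeans(x^2) - mu^2, 0) * n / (n - 1))
    },
    max_abs_mean = ,
    min_abs_mean = colMeans(abs(x)),
    shannon = apply(x, 2L, shannon_entropy, bins = bins,
                    range_lo = range_lo, range_hi = range_hi)
  )
  descending <- criterion %in% c("max_mean", "max_sd", "max_abs_mean", "shannon")
  ord <- order_stat_then_id(stat, colnames(x), descending)
  gene_signature(colnames(x)[ord[seq_len(k)]], origin = criterion)
}

#' Shannon entropy of binned expression values
#'
#' Values are histogrammed into `bins` equal-width bins spanning
#' `[range_lo, range_hi]`; values outside the range are clamped into the
#' boundary bins so every observation contributes. Entropy is
#' \eqn{-\sum_i p_i \log_2 p_i} over occupied bins (bits), with
#' \eqn{0 \log 0 := 0}.
#'
#' @param values Numeric vector (one probeset's expression across
#'   instances).
#' @param bins Number of bins (default 200).
#' @param range_lo,range_hi Histogram range (defaults -5 and 8, suited to
#'   log-scale, batch-centred expression).
#' @return Entropy in bits, in `[0, log2(bins)]`.
#' @export
shannon_entropy <- function(values, bins = 200, range_lo = -5, range_hi = 8) {
  stopifnot(bins >= 2, range_lo < range_hi)
  if (length(values) == 0) stop("empty value vector")
  width <- (range_hi - range_lo) / bins
  idx <- floor((values - range_lo) / width) + 1
  idx <- pmin(pmax(idx, 1), bins)
  p <- tabulate(idx, nbins = bins) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Draw a random signature
#'
#' Uniform sample of `k` probesets without replacement; deterministic for a
#' fixed seed. Random signatures are the yardstick that designed and
#' optimised signatures must beat.
#'
#' @param universe Character vector of available probeset ids.
#' @param k Signature size.
#' @param seed Integer seed.
#' @return A `GeneSignature` with `origin = "random"`.
#' @export
random_signature <- function(universe, k, seed) {
  universe <- as.character(universe)
  if (k > length(universe)) {
    stop("k = ", k, " exceeds universe size ", length(universe))
  }
  withr::with_seed(seed, gene_signature(sample(universe, k), origin = "random"))
}

#' Overlap between two signatures
#'
#' The maximum possible overlap equals the size of the smaller signature,
#' so the shared count is also expressed as a percentage of the smaller
#' signature.
#'
#' @param a,b `GeneSignature`s (or character vectors of probeset ids).
#' @return A list with `shared` (count) and `fraction_of_smaller`
#'   (percentage).
#' @export
signature_overlap <- function(a, b) {
  ia <- signature_ids(a)
  ib <- signature_ids(b)
  shared <- length(intersect(ia, ib))
  list(shared = shared,
       fraction_of_smaller = 100 * shared / min(length(ia), length(ib)))
}

#' Half-logarithmic ladder of signature sizes
#'
#' Sizes from `2^from` to `2^to` in half-log2 steps, truncated to integers:
#' with the defaults, 16, 22, 32, 45, 64, 90, 128, 181, 256, 362, 512, 724,
#' 1024, 1448, 2048, 2896, 4096.
#'
#' @param from,to Exponents of the smallest and largest size (defaults 4
#'   and 12).
#' @return Strictly increasing integer vector of sizes.
#' @export
size_ladder <- function(from = 4, to = 12) {
  stopifnot(from < to)
  as.integer(floor(2^seq(from, to, by = 0.5)))
}

#' Write a signature to a plain-text file
#'
#' One probeset id per line; lines starting with `#` are comments.
#'
#' @param sig A `GeneSignature`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "GeneSignature"))
  writeLines(c(paste0("# origin: ", sig$origin), sig$probeset_ids), path)
  invisible(path)
}

#' Read a signature from a plain-text file
#'
#' @param path File with one probeset id per line; `#` lines ignored.
#' @param origin Origin label for the signature (default `"file"`).
#' @return A `GeneSignature`.
#' @export
read_signature <- function(path, origin = "file") {
  lines <- trimws(readLines(path))
  ids <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_signature(ids, origin = origin)
}
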