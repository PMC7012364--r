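#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeometric}(N, K, n)}: drawing `n` query genes
#' from a universe of `N` of which `K` belong to the gene set, observing
#' `k` or more in the overlap.
#'
#' @param k overlap count.
#' @param K gene-set size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return The one-sided p-value.
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) ",
         "and K, n <= N", call. = FALSE)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Tests a query gene list (e.g. the coregulated target genes of the
#' lncRNA network) against every set of a collection with the one-sided
#' hypergeometric test, BH-adjusting across the collection.  Gene sets
#' are first intersected with the universe; query genes outside the
#' universe are dropped with a warning.
#'
#' @param query_genes character vector of query gene symbols.
#' @param universe_genes character vector defining the background
#'   (typically all symbols on the platform).
#' @param collection a [parse_gmt()] collection.
#' @return Data frame sorted by `p` ascending with columns `set`, `k`,
#'   `K`, `n`, `N`, `p`, `adj_p`, `overlap` (semicolon-joined).
#' @export
enrich <- function(query_genes, universe_genes, collection) {
  universe <- unique(as.character(universe_genes))
  if (length(universe) == 0)
    stop("empty universe", call. = FALSE)
  if (length(collection) == 0)
    stop("empty gene-set collection", call. = FALSE)
  query <- unique(as.character(query_genes))
  outside <- setdiff(query, universe)
  if (length(outside))
    warning(length(outside), " query gene(s) outside the universe ",
            "dropped", call. = FALSE)
  query <- intersect(query, universe)
  N <- length(universe); n <- length(query)
  rows <- lapply(collection, function(s) {
    members <- intersect(unique(s$genes), universe)
    overlap <- intersect(query, members)
    data.frame(set = s$name, k = length(overlap), K = length(members),
               n = n, N = N,
               p = hypergeom_p(length(overlap), length(members), n, N),
               overlap = paste(sort(overlap), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- adjust_bh(out$p)
  out <- out[order(out$p, out$set),
             c("set", "k", "K", "n", "N", "p", "adj_p", "overlap")]
  rownames(out) <- NULL
  out
}
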