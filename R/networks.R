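#' Pearson correlation with its t-test
#'
#' Sample Pearson correlation of two equal-length vectors together with
#' the two-sided p-value of the no-correlation test,
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2} degrees of freedom.
#' A perfect correlation (`|r| = 1`) gives p = 0 by convention.
#'
#' @param x,y numeric vectors of common length `n >= 3` with nonzero
#'   variance.
#' @return List with elements `r`, `p`, `n`.
#' @export
pearson_with_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n)
    stop("x and y must have equal length", call. = FALSE)
  if (n < 3)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero-variance vector", call. = FALSE)
  r <- stats::cor(x, y)
  p <- cor_pvalue(r, n)
  list(r = r, p = p, n = n)
}

# two-sided p for the Pearson no-correlation t-test; vectorized
cor_pvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  perfect <- !is.na(r) & abs(r) >= 1
  p[perfect] <- 0
  rest <- !is.na(r) & !perfect
  t <- r[rest] * sqrt(n - 2) / sqrt(1 - r[rest]^2)
  p[rest] <- 2 * stats::pt(-abs(t), df = n - 2)
  p
}

#' Build the lncRNA-mRNA coexpression network
#'
#' Scans every (lncRNA, mRNA) probe pair and keeps an edge when the
#' Pearson correlation across **all** samples of the matrix exceeds the
#' threshold (strictly) and the correlation-test p-value falls below
#' `alpha` (strictly).  In the default absolute mode the rule is
#' `|r| > r_threshold`, so strong negative relationships also yield
#' edges; signed mode keeps `r > r_threshold` only.  An mRNA connected to
#' a lncRNA this way is that lncRNA's predicted target gene.
#'
#' Zero-variance probes cannot be correlated and are skipped with a
#' message; their count is stored in the `n_skipped_zero_var` attribute.
#'
#' @param em an [expression_matrix()]; correlations use all its samples.
#' @param lnc_ids,mrna_ids probe ids of the candidate lncRNAs and mRNAs
#'   (typically the DE lists of one contrast); must exist in the matrix.
#' @param r_threshold correlation threshold (default 0.8, strict).
#' @param alpha p-value cutoff (default 0.05, strict; no multiplicity
#'   correction unless `adjust = TRUE`).
#' @param signed if `TRUE`, threshold `r` itself rather than `|r|`.
#' @param adjust if `TRUE`, BH-adjust the correlation p-values over all
#'   scanned pairs before applying `alpha`.
#' @return A `"CoexpressionNetwork"` data frame with columns `lnc`,
#'   `mrna`, `r`, `p`, `n`, sorted by lnc then mrna.
#' @export
build_coexpression <- function(em, lnc_ids, mrna_ids, r_threshold = 0.8,
                               alpha = 0.05, signed = FALSE,
                               adjust = FALSE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  empty <- structure(
    data.frame(lnc = character(0), mrna = character(0), r = numeric(0),
               p = numeric(0), n = integer(0), stringsAsFactors = FALSE),
    r_threshold = r_threshold, alpha = alpha, signed = signed,
    n_skipped_zero_var = 0L, class = c("CoexpressionNetwork",
                                       "data.frame"))
  if (length(lnc_ids) == 0 || length(mrna_ids) == 0) return(empty)
  unknown <- setdiff(c(lnc_ids, mrna_ids), rownames(em$values))
  if (length(unknown))
    stop("probe id(s) not in matrix: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  n <- ncol(em$values)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  X <- em$values[lnc_ids, , drop = FALSE]
  Y <- em$values[mrna_ids, , drop = FALSE]
  const_x <- apply(X, 1, stats::sd) == 0
  const_y <- apply(Y, 1, stats::sd) == 0
  n_skipped <- sum(const_x) + sum(const_y)
  if (n_skipped > 0) {
    message(n_skipped, " zero-variance probe(s) skipped in ",
            "coexpression scan")
    X <- X[!const_x, , drop = FALSE]
    Y <- Y[!const_y, , drop = FALSE]
    if (nrow(X) == 0 || nrow(Y) == 0) {
      attr(empty, "n_skipped_zero_var") <- n_skipped
      return(empty)
    }
  }
  R <- stats::cor(t(X), t(Y))
  P <- matrix(cor_pvalue(as.vector(R), n), nrow(R), ncol(R))
  Padj <- if (adjust) matrix(adjust_bh(as.vector(P)), nrow(P), ncol(P))
    else P
  mag <- if (signed) R else abs(R)
  keep <- which(!is.na(R) & mag > r_threshold & Padj < alpha,
                arr.ind = TRUE)
  edges <- data.frame(lnc = rownames(R)[keep[, 1]],
                      mrna = colnames(R)[keep[, 2]],
                      r = R[keep], p = Padj[keep],
                      n = rep.int(n, nrow(keep)),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$lnc, edges$mrna), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, r_threshold = r_threshold, alpha = alpha,
            signed = signed, n_skipped_zero_var = n_skipped,
            class = c("CoexpressionNetwork", "data.frame"))
}

#' Predicted target genes of one lncRNA
#'
#' @param network a [build_coexpression()] result.
#' @param lnc_id lncRNA probe id; an id absent from the network yields an
#'   empty set.
#' @return Character vector of mRNA ids coexpressed with `lnc_id`.
#' @export
target_genes <- function(network, lnc_id) {
  unique(network$mrna[network$lnc == lnc_id])
}

#' Derive the lncRNA-lncRNA coregulation network
#'
#' Two lncRNAs coregulate when they are coexpressed with at least one
#' common mRNA; the edge weight is the number of shared target genes.
#'
#' @param network a [build_coexpression()] result.
#' @return A `"CoregulationNetwork"` data frame with columns `lnc_a`,
#'   `lnc_b` (unordered pairs, `lnc_a < lnc_b`), `weight`,
#'   `shared_targets` (semicolon-joined, sorted).  The attribute
#'   `coregulated_targets` holds the sorted union of all shared targets.
#' @export
build_coregulation <- function(network) {
  tg <- split(network$mrna, network$lnc)
  tg <- lapply(tg, unique)
  lncs <- sort(names(tg))
  rows <- list()
  all_shared <- character(0)
  if (length(lncs) >= 2) {
    pairs <- utils::combn(lncs, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      shared <- intersect(tg[[a]], tg[[b]])
      if (length(shared) == 0) next
      shared <- sort(shared)
      all_shared <- c(all_shared, shared)
      rows[[length(rows) + 1]] <-
        data.frame(lnc_a = a, lnc_b = b, weight = length(shared),
                   shared_targets = paste(shared, collapse = ";"),
                   stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lnc_a = character(0), lnc_b = character(0),
               weight = integer(0), shared_targets = character(0),
               stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(edges, coregulated_targets = sort(unique(all_shared)),
            class = c("CoregulationNetwork", "data.frame"))
}
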