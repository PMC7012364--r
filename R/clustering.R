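#' Correlation distance matrix
#'
#' Pairwise distance `1 - Pearson r` between the rows (or columns) of a
#' matrix: 0 for identical profiles, 2 for perfect anti-correlation.
#'
#' @param values numeric matrix, or an [expression_matrix()].
#' @param axis `"rows"` (probes) or `"cols"` (samples).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(values, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (inherits(values, "ExpressionMatrix")) values <- values$values
  X <- if (axis == "rows") t(values) else values
  if (ncol(X) < 2)
    stop("need at least 2 items to compute distances", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate input: constant item ",
         colnames(X)[which(sds == 0)[1]], call. = FALSE)
  d <- 1 - stats::cor(X)
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerates items under complete linkage (inter-cluster distance =
#' maximum pairwise member distance), which guarantees monotone
#' nondecreasing merge heights.  Delegates to `stats::hclust`.
#'
#' @param d symmetric distance matrix (e.g. [correlation_distance()]) or
#'   a `stats::dist` object.
#' @return An `hclust` tree (`merge`, `height`, `order`, `labels`).
#' @export
complete_linkage <- function(d) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
      stop("distance matrix must be symmetric", call. = FALSE)
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "complete")
}

#' Newick serialization of a dendrogram
#'
#' @param hc an `hclust` tree.
#' @param path optional output file; when `NULL` the newick string is
#'   returned.
#' @return The newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Order a matrix by dendrograms and standardize rows for display
#'
#' Permutes rows and columns to the dendrogram leaf orders and z-scores
#' each row (display convention only; statistics never use the scaled
#' values).  Constant rows become all-zero with a message.  Optionally
#' writes the ordered scaled matrix as TSV and renders a heatmap image.
#'
#' @param values numeric matrix or [expression_matrix()].
#' @param row_hc,col_hc `hclust` trees whose labels match the row and
#'   column names.
#' @param out_tsv,out_png optional output paths.
#' @return List with `values` (ordered, row-standardized matrix),
#'   `row_order`, `col_order` (label vectors).
#' @export
heatmap_order <- function(values, row_hc, col_hc, out_tsv = NULL,
                          out_png = NULL) {
  if (inherits(values, "ExpressionMatrix")) values <- values$values
  if (!setequal(row_hc$labels, rownames(values)) ||
      !setequal(col_hc$labels, colnames(values)))
    stop("dendrogram labels do not match matrix dimnames", call. = FALSE)
  ro <- row_hc$labels[row_hc$order]
  co <- col_hc$labels[col_hc$order]
  x <- values[ro, co, drop = FALSE]
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  const <- sd == 0
  if (any(const)) {
    message(sum(const), " constant row(s) rendered as zero after ",
            "standardization")
    sd[const] <- 1
  }
  z <- (x - mu) / sd
  if (!is.null(out_tsv))
    utils::write.table(data.frame(probe_id = rownames(z), z,
                                  check.names = FALSE),
                       out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(out_png))
    pheatmap::pheatmap(z, cluster_rows = FALSE, cluster_cols = FALSE,
                       show_rownames = nrow(z) <= 60,
                       show_colnames = ncol(z) <= 60,
                       filename = out_png, silent = TRUE)
  list(values = z, row_order = ro, col_order = co)
}
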