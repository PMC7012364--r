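#' Export a network edge table as SIF, GraphML or TSV
#'
#' Accepts the edge tables produced by [build_coexpression()] (columns
#' `lnc`, `mrna`, `r`, `p`, `n`) or [build_coregulation()] (columns
#' `lnc_a`, `lnc_b`, `weight`, `shared_targets`).  The SIF interaction
#' label is `"coexpression"` for lncRNA-mRNA edges and `"coregulation"`
#' for lncRNA-lncRNA edges; GraphML and TSV carry every edge attribute.
#' Node kind (`lncRNA` / `mRNA`) and, when supplied, a per-node regulation
#' direction (sign of the log2 fold change) are emitted as node
#' attributes in GraphML.
#'
#' @param edges edge data frame (see above).
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @param path output file path.
#' @param node_direction optional named vector (`"up"` / `"down"`, named by
#'   node id) recording regulation direction.
#' @return Invisibly, `path`.
#' @export
export_network <- function(edges, format = c("sif", "graphml", "tsv"),
                           path, node_direction = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop(
                       "unknown network format: ", format[1],
                       " (use sif, graphml or tsv)", call. = FALSE))
  if (all(c("lnc", "mrna") %in% names(edges))) {
    from <- edges$lnc; to <- edges$mrna
    interaction <- "coexpression"
    kinds <- c(stats::setNames(rep("lncRNA", length(from)), from),
               stats::setNames(rep("mRNA", length(to)), to))
  } else if (all(c("lnc_a", "lnc_b") %in% names(edges))) {
    from <- edges$lnc_a; to <- edges$lnc_b
    interaction <- "coregulation"
    kinds <- stats::setNames(rep("lncRNA", length(c(from, to))),
                             c(from, to))
  } else {
    stop("edge table must have columns lnc/mrna or lnc_a/lnc_b",
         call. = FALSE)
  }
  attr_cols <- setdiff(names(edges),
                       c("lnc", "mrna", "lnc_a", "lnc_b"))
  switch(format,
    sif = writeLines(if (length(from)) paste(from, interaction, to,
                                             sep = "\t") else character(0),
                     path),
    tsv = utils::write.table(edges, path, sep = "\t", quote = FALSE,
                             row.names = FALSE),
    graphml = {
      nodes <- unique(c(from, to))
      g <- igraph::graph_from_data_frame(
        cbind(data.frame(from = from, to = to, stringsAsFactors = FALSE),
              edges[attr_cols]),
        directed = FALSE,
        vertices = data.frame(name = nodes,
                              kind = kinds[!duplicated(names(kinds))][nodes],
                              stringsAsFactors = FALSE))
      igraph::E(g)$interaction <- rep(interaction, igraph::ecount(g))
      if (!is.null(node_direction)) {
        dir <- rep(NA_character_, length(nodes))
        hit <- nodes %in% names(node_direction)
        dir[hit] <- node_direction[nodes[hit]]
        igraph::V(g)$direction <- dir
      }
      igraph::write_graph(g, path, format = "graphml")
    })
  invisible(path)
}
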