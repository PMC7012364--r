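#' Load a platform probe annotation table
#'
#' Reads a tab-separated probe-to-symbol table (the usual export of a
#' microarray platform annotation) into the probe annotation frame used
#' throughout the pipeline.  Cells mapping one probe to several symbols
#' (delimited by `"///"` or `";"`) keep the first listed symbol by
#' default, with the number of multi-mapped probes reported by message;
#' alternatively such probes can be dropped.
#'
#' @param path TSV path with a header row.
#' @param probe_col,symbol_col,id_col column names for the probe id, gene
#'   symbol and (optional) gene id; `id_col = NULL` if absent.
#' @param multi `"first"` (keep first listed symbol) or `"drop"` (drop
#'   multi-mapped probes).
#' @return Data frame with columns `probe_id`, `gene_symbol` (`NA` when
#'   the cell was empty), `gene_id`, `is_lncrna` (initialized `FALSE`).
#' @export
load_platform_annotation <- function(path, probe_col = "probe_id",
                                     symbol_col = "gene_symbol",
                                     id_col = "gene_id",
                                     multi = c("first", "drop")) {
  multi <- match.arg(multi)
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  for (col in c(probe_col, symbol_col))
    if (!col %in% names(tab))
      stop("annotation format error: missing column '", col, "'",
           call. = FALSE)
  sym_raw <- trimws(tab[[symbol_col]])
  is_multi <- grepl("///|;", sym_raw)
  if (any(is_multi))
    message(sum(is_multi), " probe(s) map to multiple symbols (",
            multi, ")")
  sym <- trimws(vapply(strsplit(sym_raw, "\\s*(///|;)\\s*"),
                       function(x) if (length(x)) x[1] else "",
                       character(1)))
  gid <- if (!is.null(id_col) && id_col %in% names(tab))
    trimws(tab[[id_col]]) else rep(NA_character_, nrow(tab))
  ann <- data.frame(probe_id = trimws(tab[[probe_col]]),
                    gene_symbol = ifelse(sym == "", NA_character_, sym),
                    gene_id = ifelse(is.na(gid) | gid == "",
                                     NA_character_, gid),
                    is_lncrna = FALSE, stringsAsFactors = FALSE)
  if (multi == "drop") ann <- ann[!is_multi, , drop = FALSE]
  if (anyDuplicated(ann$probe_id))
    stop("annotation format error: duplicate probe id ",
         ann$probe_id[duplicated(ann$probe_id)][1], call. = FALSE)
  rownames(ann) <- NULL
  ann
}

#' Flag lncRNA probes by gene-type lookup
#'
#' Sets `is_lncrna` to `TRUE` for every probe whose gene symbol is present
#' in `gene_type_map` with a type in `lncrna_biotypes`; all other probes
#' (including probes without a symbol or with a symbol absent from the
#' map) are treated as ordinary gene probes, so the two counts always
#' partition the full probe list.
#'
#' @param annotation probe annotation frame
#'   (see [load_platform_annotation()]).
#' @param gene_type_map named character vector of gene types keyed by
#'   symbol (see [parse_gtf_gene_types()]).
#' @param lncrna_biotypes character vector of long-noncoding type strings.
#' @return The annotation with `is_lncrna` updated and an attribute
#'   `counts = c(n_lncrna_probes = , n_gene_probes = )`.
#' @export
flag_lncrna_probes <- function(annotation, gene_type_map,
                               lncrna_biotypes = default_lncrna_biotypes()) {
  stopifnot(is.data.frame(annotation),
            all(c("probe_id", "gene_symbol") %in% names(annotation)))
  lnc_symbols <- names(gene_type_map)[gene_type_map %in% lncrna_biotypes]
  annotation$is_lncrna <- !is.na(annotation$gene_symbol) &
    annotation$gene_symbol %in% lnc_symbols
  n_lnc <- sum(annotation$is_lncrna)
  attr(annotation, "counts") <- c(n_lncrna_probes = n_lnc,
                                  n_gene_probes = nrow(annotation) - n_lnc)
  annotation
}
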