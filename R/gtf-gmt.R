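#' Long-noncoding biotypes recognized by default
#'
#' The GENCODE release family aggregates several historical biotypes under
#' the long-noncoding umbrella; this is the default set used to flag
#' lncRNA genes.  Override it wherever a `lncrna_biotypes` argument is
#' accepted.
#'
#' @return Character vector of gene_type strings.
#' @export
default_lncrna_biotypes <- function() {
  c("lncRNA", "lincRNA", "antisense", "antisense_RNA",
    "processed_transcript", "sense_intronic", "sense_overlapping",
    "3prime_overlapping_ncRNA", "3prime_overlapping_ncrna",
    "bidirectional_promoter_lncRNA", "macro_lncRNA", "non_coding")
}

#' Extract a gene-symbol to gene-type map from a GTF annotation
#'
#' Keeps gene-level records only (feature column `"gene"`) and returns one
#' entry per distinct `gene_name`.  Records without a `gene_name`
#' attribute are skipped with a warning reporting the count.  Symbols are
#' matched downstream by case-sensitive exact comparison after whitespace
#' trimming.
#'
#' @param path path to a 9-column tab-separated GTF file with `gene_name`
#'   and `gene_type` attributes (GENCODE style).
#' @return Named character vector: `gene_type` keyed by `gene_name`.
#' @export
parse_gtf_gene_types <- function(path) {
  lines <- readLines(path)
  data_lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  nfields <- lengths(strsplit(data_lines, "\t", fixed = TRUE))
  if (any(nfields < 9))
    stop("GTF format error: line with ", min(nfields),
         " columns (9 required)", call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr@elementMetadata)
  md <- md[!is.na(md$type) & as.character(md$type) == "gene", , drop = FALSE]
  if (nrow(md) == 0) return(stats::setNames(character(0), character(0)))
  if (is.null(md$gene_name)) md$gene_name <- NA_character_
  if (is.null(md$gene_type)) md$gene_type <- NA_character_
  n_skipped <- sum(is.na(md$gene_name))
  if (n_skipped > 0)
    warning(n_skipped, " gene record(s) without gene_name skipped",
            call. = FALSE)
  md <- md[!is.na(md$gene_name), , drop = FALSE]
  sym <- trimws(md$gene_name)
  typ <- trimws(md$gene_type)
  keep <- !duplicated(sym)
  stats::setNames(typ[keep], sym[keep])
}

#' Parse a GMT gene-set collection
#'
#' Tab-separated lines of the form `name<TAB>description<TAB>gene...`.
#' Duplicate member symbols within a set are removed; sets are returned in
#' file order.
#'
#' @param path GMT file path.
#' @return A `"GeneSetCollection"`: list of `list(name, description,
#'   genes)` with unique set names.
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT format error at line ", i, ": ", length(f),
           " fields (need name, description, >= 1 gene)", call. = FALSE)
    list(name = f[1], description = f[2], genes = unique(f[-(1:2)]))
  })
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("GMT format error: duplicate set name ", nm[duplicated(nm)][1],
         call. = FALSE)
  structure(sets, names = nm, class = "GeneSetCollection")
}

#' Write a gene-set collection in GMT format
#'
#' @param collection a [parse_gmt()]-style collection.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  writeLines(vapply(collection, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"),
    character(1)), path)
  invisible(path)
}
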