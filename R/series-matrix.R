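#' Parse a GEO series-matrix expression file
#'
#' Reads the text distribution format used by GEO series: "!"-prefixed
#' metadata lines plus a tab-separated probe-by-sample table enclosed in
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers.
#' Quoted tokens are unquoted; the standard `null` token (and empty or
#' `NA` cells) become missing values.
#'
#' Group labels are pulled from `!Sample_characteristics` metadata lines:
#' any such line whose entries look like `"<key>: <label>"` with the given
#' `characteristics_key` assigns one label per sample.  Files without a
#' matching line parse fine with unassigned groups.
#'
#' Series matrices are assumed to hold log2-scale intensities; when the
#' observed maximum exceeds `log2_threshold` the values are taken to be on
#' the raw scale and `log2(x + 1)` is applied (with a message).
#'
#' @param path file path.
#' @param characteristics_key key prefix identifying the group
#'   characteristics line (default `"group"`).
#' @param log2_threshold matrix maximum above which values are considered
#'   unlogged; set to `Inf` to disable the transform.
#' @return An [expression_matrix()].
#' @export
parse_series_matrix <- function(path, characteristics_key = "group",
                                log2_threshold = 50) {
  lines <- readLines(path)
  unq <- function(x) gsub('^"|"$', "", x)
  begin <- grep("^!series_matrix_table_begin", lines)
  if (length(begin) == 0)
    stop("series-matrix format error: missing !series_matrix_table_begin ",
         "marker in ", path, call. = FALSE)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(end) == 0 || end[1] <= begin[1])
    stop("series-matrix format error: missing !series_matrix_table_end ",
         "marker in ", path, call. = FALSE)
  begin <- begin[1]; end <- end[1]
  if (end - begin < 2)
    stop("series-matrix format error: empty data table", call. = FALSE)
  tab_lines <- lines[(begin + 1):(end - 1)]
  fields <- strsplit(tab_lines, "\t", fixed = TRUE)
  header <- unq(fields[[1]])
  sample_ids <- header[-1]
  ncol_exp <- length(header)
  widths <- lengths(fields)
  if (any(widths != ncol_exp)) {
    bad <- which(widths != ncol_exp)[1]
    stop("series-matrix format error: ragged row at line ",
         begin + bad, " (", widths[bad], " fields, expected ", ncol_exp,
         ")", call. = FALSE)
  }
  body <- fields[-1]
  probe_ids <- vapply(body, function(f) unq(f[1]), character(1))
  if (anyDuplicated(probe_ids))
    stop("series-matrix format error: duplicate probe id ",
         probe_ids[duplicated(probe_ids)][1], call. = FALSE)
  n_probes <- length(body)
  values <- matrix(NA_real_, n_probes, length(sample_ids),
                   dimnames = list(probe_ids, sample_ids))
  if (n_probes > 0) {
    raw <- unq(unlist(lapply(body, `[`, -1)))
    missing_tok <- raw %in% c("null", "NA", "")
    num <- suppressWarnings(as.numeric(raw))
    if (any(is.na(num) & !missing_tok))
      stop("series-matrix format error: non-numeric value '",
           raw[is.na(num) & !missing_tok][1], "'", call. = FALSE)
    values[] <- matrix(num, n_probes, length(sample_ids), byrow = TRUE)
  }

  groups <- NULL
  meta <- lines[grep("^!Sample_characteristics", lines)]
  key_re <- paste0("^", characteristics_key, "\\s*:\\s*")
  for (m in meta) {
    f <- unq(strsplit(m, "\t", fixed = TRUE)[[1]])[-1]
    if (length(f) == length(sample_ids) && all(grepl(key_re, f))) {
      groups <- stats::setNames(trimws(sub(key_re, "", f)), sample_ids)
      break
    }
  }

  if (n_probes > 0 && any(is.finite(values)) &&
      max(values, na.rm = TRUE) > log2_threshold) {
    message("series matrix looks unlogged (max > ", log2_threshold,
            "); applying log2(x + 1)")
    values <- log2(values + 1)
  }
  expression_matrix(values, groups)
}

#' Write an expression matrix in series-matrix format
#'
#' Emits the dialect [parse_series_matrix()] accepts; values are written
#' with 17 significant digits so that `parse(write(m))` reproduces the
#' matrix bit-exactly.  Missing values are written as the standard `null`
#' token; group labels (when assigned) are recorded on a
#' `!Sample_characteristics_ch1` line as `"group: <label>"`.
#'
#' @param em an [expression_matrix()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_series_matrix <- function(em, path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  q <- function(x) paste0('"', x, '"')
  sid <- colnames(em$values)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste0("!Series_title\t", q("lncoexnet expression matrix")),
               paste(c("!Sample_geo_accession", q(sid)), collapse = "\t")),
             con)
  if (!all(is.na(em$groups)))
    writeLines(paste(c("!Sample_characteristics_ch1",
                       q(paste0("group: ", em$groups))), collapse = "\t"),
               con)
  writeLines("!series_matrix_table_begin", con)
  writeLines(paste(c(q("ID_REF"), q(sid)), collapse = "\t"), con)
  if (nrow(em$values) > 0) {
    txt <- sprintf("%.17g", em$values)
    txt[is.na(em$values)] <- "null"
    txt <- matrix(txt, nrow(em$values), ncol(em$values))
    writeLines(paste(q(rownames(em$values)),
                     apply(txt, 1, paste, collapse = "\t"), sep = "\t"),
               con)
  }
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}
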