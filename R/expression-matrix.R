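#' Expression matrix with sample group labels
#'
#' Lightweight container for a log2-scale probe-by-sample expression grid.
#' Rows are probes, columns are samples; each sample carries exactly one
#' group label (typically `"control"`, `"dysplasia"`, `"cancer"`, but any
#' label set is accepted).  Values are log2 intensities; missing
#' measurements are `NA`.
#'
#' @param values numeric matrix with unique, non-empty rownames (probe ids)
#'   and colnames (sample ids).
#' @param groups character vector of group labels, either named by sample id
#'   or in column order; `NULL` leaves all samples unassigned (`NA`).
#' @return An object of class `"ExpressionMatrix"`: a list with elements
#'   `values` (the matrix) and `groups` (named character vector, one label
#'   per sample).
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' em <- expression_matrix(m, c(s1 = "control", s2 = "control", s3 = "cancer"))
#' dim(em)
#' @export
expression_matrix <- function(values, groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  pid <- rownames(values)
  sid <- colnames(values)
  if (nrow(values) > 0 && (is.null(pid) || anyNA(pid) || any(pid == "")))
    stop("`values` must have non-empty rownames (probe ids)", call. = FALSE)
  if (is.null(sid) || anyNA(sid) || any(sid == ""))
    stop("`values` must have non-empty colnames (sample ids)", call. = FALSE)
  if (anyDuplicated(pid))
    stop("duplicate probe ids: ", paste(unique(pid[duplicated(pid)]),
         collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]),
         collapse = ", "), call. = FALSE)
  if (is.null(groups)) {
    groups <- rep(NA_character_, ncol(values))
    names(groups) <- sid
  } else {
    groups <- as.character(stats::setNames(groups, names(groups)))
    if (is.null(names(groups))) {
      if (length(groups) != ncol(values))
        stop("unnamed `groups` must have one label per sample", call. = FALSE)
      names(groups) <- sid
    }
    if (!setequal(names(groups), sid))
      stop("`groups` names must match the sample ids exactly", call. = FALSE)
    groups <- groups[sid]
  }
  structure(list(values = values, groups = groups),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "probes x",
      ncol(x$values), "samples\n")
  tab <- table(x$groups, useNA = "ifany")
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Sample ids belonging to one group
#'
#' @param em an [expression_matrix()].
#' @param group group label.
#' @return Character vector of sample ids with that label.
#' @export
group_samples <- function(em, group) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  names(em$groups)[!is.na(em$groups) & em$groups == group]
}
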