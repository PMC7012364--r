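#' Per-probe two-group summary statistics
#'
#' For one pairwise contrast, computes for every probe the two group means
#' on the log2 scale, their difference (the log2 fold change), the pooled
#' residual variance
#' \deqn{s^2 = \frac{(n_a-1)s_a^2 + (n_b-1)s_b^2}{n_a + n_b - 2}}
#' and the residual degrees of freedom \eqn{n_a + n_b - 2}.  Probes with
#' any missing value among the two groups' samples are excluded from the
#' contrast (keeping the residual degrees of freedom uniform, which the
#' empirical-Bayes prior fit relies on); the number excluded is reported
#' in the `n_excluded` attribute.
#'
#' @param em an [expression_matrix()].
#' @param group_a,group_b group labels; the log2 fold change is
#'   mean(`group_a`) - mean(`group_b`).
#' @return A `"ContrastStats"` data frame with columns `probe_id`,
#'   `mean_a`, `mean_b`, `log2fc`, `s2`, `df`, `n_a`, `n_b` and attributes
#'   `contrast`, `n_excluded`.
#' @export
contrast_statistics <- function(em, group_a, group_b) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  sa <- group_samples(em, group_a)
  sb <- group_samples(em, group_b)
  if (length(sa) < 2 || length(sb) < 2)
    stop("each group needs at least 2 samples (", group_a, ": ",
         length(sa), ", ", group_b, ": ", length(sb), ")", call. = FALSE)
  xa <- em$values[, sa, drop = FALSE]
  xb <- em$values[, sb, drop = FALSE]
  complete <- stats::complete.cases(cbind(xa, xb))
  n_excluded <- sum(!complete)
  if (n_excluded > 0)
    message(n_excluded, " probe(s) with missing values excluded from ",
            group_a, "_vs_", group_b)
  xa <- xa[complete, , drop = FALSE]
  xb <- xb[complete, , drop = FALSE]
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  out <- data.frame(probe_id = rownames(em$values)[complete],
                    mean_a = ma, mean_b = mb, log2fc = ma - mb,
                    s2 = ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2),
                    df = na + nb - 2, n_a = na, n_b = nb,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, contrast = paste0(group_a, "_vs_", group_b),
            n_excluded = n_excluded, class = c("ContrastStats",
                                               "data.frame"))
}

# invert the trigamma function by Newton iteration (monotone decreasing)
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 50) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    step <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + step
    if (abs(step) < tol * x) break
  }
  x
}

#' Fit the empirical-Bayes variance prior by moments on log-variances
#'
#' Under the hierarchical model in which the true probe variances follow a
#' scaled inverse-chi-square prior with `d0` degrees of freedom and scale
#' `s0_sq`, the observed residual variances satisfy
#' \eqn{s^2 / s_0^2 \sim F(df, d_0)}.  The hyperparameters are recovered
#' by matching the first two moments of \eqn{\log s^2} through the
#' digamma/trigamma identities for log-chi-square variables: the excess of
#' \eqn{\mathrm{var}(\log s^2)} over the pure sampling dispersion
#' \eqn{\psi'(df/2)} equals \eqn{\psi'(d_0/2)}, inverted by Newton
#' iteration (tolerance 1e-8).  When the observed dispersion does not
#' exceed the sampling dispersion the prior is degenerate:
#' `d0 = Inf` and `s0_sq = mean(s2)`.  Finite estimates above 1e6 are
#' reported as `Inf`.
#'
#' @param s2 vector of residual variances (zeros are ignored; at least 10
#'   positive values required).
#' @param df common residual degrees of freedom of `s2`.
#' @return An `"EBPrior"` list with elements `d0` and `s0_sq`.
#' @references Smyth, G.K. (2004) Linear models and empirical Bayes
#'   methods for assessing differential expression in microarray
#'   experiments. Stat. Appl. Genet. Mol. Biol. 3, Article 3.
#' @export
estimate_eb_prior <- function(s2, df) {
  s2 <- s2[!is.na(s2)]
  pos <- s2[s2 > 0]
  if (length(pos) == 0)
    stop("cannot estimate variance prior: all variances are zero",
         call. = FALSE)
  if (length(pos) < 10)
    stop("cannot estimate variance prior: fewer than 10 positive ",
         "variances", call. = FALSE)
  if (length(pos) < length(s2))
    message(length(s2) - length(pos),
            " zero variance(s) ignored in prior fit")
  z <- log(pos)
  evar <- stats::var(z) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)
    return(structure(list(d0 = Inf, s0_sq = mean(pos)), class = "EBPrior"))
  d0 <- 2 * trigamma_inverse(evar)
  if (d0 >= 1e6)
    return(structure(list(d0 = Inf, s0_sq = mean(pos)), class = "EBPrior"))
  s0_sq <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  structure(list(d0 = d0, s0_sq = s0_sq), class = "EBPrior")
}

#' @export
print.EBPrior <- function(x, ...) {
  cat(sprintf("EBPrior: d0 = %s, s0_sq = %.6g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' Moderated t-statistics for one contrast
#'
#' Shrinks each probe's pooled variance toward the prior scale,
#' \deqn{\tilde{s}^2 = \frac{d_0 s_0^2 + df\, s^2}{d_0 + df},}
#' forms \eqn{t = \mathrm{log2fc} / \sqrt{\tilde{s}^2 (1/n_a + 1/n_b)}}
#' and computes two-sided p-values from the t distribution on
#' \eqn{df + d_0} degrees of freedom (standard normal when `d0 = Inf`).
#' With `d0 = 0` this is exactly the classical pooled two-sample t-test.
#' A zero posterior variance with a nonzero fold change yields an
#' infinite statistic with p = 0; a zero fold change yields t = 0, p = 1.
#'
#' @param stats a [contrast_statistics()] result.
#' @param prior an [estimate_eb_prior()] result (or any list with `d0`,
#'   `s0_sq`).
#' @return A `"DEResult"` data frame: `probe_id`, `log2fc`, `s2`,
#'   `posterior_s2`, `moderated_t`, `total_df`, `raw_p`, `adj_p`
#'   (Benjamini-Hochberg across the contrast's probes), with the
#'   `contrast` and `prior` attributes carried along.
#' @export
moderated_t <- function(stats, prior) {
  stopifnot(inherits(stats, "ContrastStats"),
            is.list(prior), prior$d0 >= 0, is.finite(prior$s0_sq),
            prior$s0_sq >= 0)
  d0 <- prior$d0; s0 <- prior$s0_sq
  post <- if (is.infinite(d0)) rep(s0, nrow(stats)) else
    (d0 * s0 + stats$df * stats$s2) / (d0 + stats$df)
  se <- sqrt(post * (1 / stats$n_a + 1 / stats$n_b))
  t <- ifelse(stats$log2fc == 0, 0, stats$log2fc / se)
  total_df <- stats$df + d0
  p <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(t)) else
    2 * stats::pt(-abs(t), df = total_df)
  p[is.infinite(t)] <- 0
  p[stats$log2fc == 0] <- 1
  out <- data.frame(probe_id = stats$probe_id, log2fc = stats$log2fc,
                    s2 = stats$s2, posterior_s2 = post, moderated_t = t,
                    total_df = total_df, raw_p = p,
                    adj_p = adjust_bh(p), stringsAsFactors = FALSE)
  structure(out, contrast = attr(stats, "contrast"), prior = prior,
            class = c("DEResult", "data.frame"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment from the definition:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, returned in
#' input order.  Agrees with `stats::p.adjust(method = "BH")` up to
#' floating-point association order.
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

#' Moderated differential expression for one pairwise contrast
#'
#' Convenience wrapper chaining [contrast_statistics()],
#' [estimate_eb_prior()] (fit on that contrast's pooled variances) and
#' [moderated_t()].
#'
#' @inheritParams contrast_statistics
#' @param prior optional pre-computed [estimate_eb_prior()]; fitted from
#'   the contrast's variances when `NULL`.
#' @return A `"DEResult"` data frame (see [moderated_t()]).
#' @export
de_contrast <- function(em, group_a, group_b, prior = NULL) {
  cs <- contrast_statistics(em, group_a, group_b)
  if (is.null(prior))
    prior <- estimate_eb_prior(cs$s2, df = cs$df[1])
  moderated_t(cs, prior)
}

#' Select differentially expressed probes
#'
#' Applies the screening rule: fold change strictly greater than
#' `fold_bound` or strictly less than `1/fold_bound` (i.e.
#' `|log2fc| > log2(fold_bound)`), and BH-adjusted p strictly below
#' `alpha`.  Both inequalities are strict, so a fold change of exactly 2
#' or an adjusted p of exactly 0.05 is never selected.
#'
#' @param de a `"DEResult"` data frame.
#' @param fold_bound fold-change bound (default 2).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return A `"DEGSet"` data frame: `probe_id`, `log2fc`, `adj_p`,
#'   `direction` (`"up"`/`"down"`), with `contrast`, `fold_bound`,
#'   `alpha` attributes.
#' @export
select_degs <- function(de, fold_bound = 2, alpha = 0.05) {
  stopifnot(is.data.frame(de),
            all(c("probe_id", "log2fc", "adj_p") %in% names(de)))
  keep <- abs(de$log2fc) > log2(fold_bound) & de$adj_p < alpha
  out <- data.frame(probe_id = de$probe_id[keep],
                    log2fc = de$log2fc[keep], adj_p = de$adj_p[keep],
                    direction = ifelse(de$log2fc[keep] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, contrast = attr(de, "contrast"),
            fold_bound = fold_bound, alpha = alpha,
            class = c("DEGSet", "data.frame"))
}

#' Three-way Venn partition of id sets
#'
#' Splits the union of three sets into the seven disjoint Venn regions.
#' The `abc` region (members of all three sets) is the "shared among the
#' three groups" list used to pick out probes differential in every
#' pairwise contrast.
#'
#' @param set_a,set_b,set_c character vectors.
#' @return A `"VennPartition"` list with elements `a_only`, `b_only`,
#'   `c_only`, `ab`, `ac`, `bc`, `abc` and a `counts` element of the seven
#'   region sizes.
#' @export
venn_partition <- function(set_a, set_b, set_c) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  c_ <- unique(as.character(set_c))
  abc <- intersect(intersect(a, b), c_)
  ab <- setdiff(intersect(a, b), abc)
  ac <- setdiff(intersect(a, c_), abc)
  bc <- setdiff(intersect(b, c_), abc)
  regions <- list(a_only = setdiff(a, union(b, c_)),
                  b_only = setdiff(b, union(a, c_)),
                  c_only = setdiff(c_, union(a, b)),
                  ab = ab, ac = ac, bc = bc, abc = abc)
  structure(c(regions, list(counts = lengths(regions))),
            class = "VennPartition")
}

#' Split a DEG set into lncRNA and mRNA probe lists
#'
#' @param degs a [select_degs()] result (or any frame with `probe_id`).
#' @param annotation probe annotation with `is_lncrna` flags covering
#'   every selected probe.
#' @return List with character vectors `lnc` and `mrna` partitioning the
#'   selected probes.
#' @export
split_lncrna <- function(degs, annotation) {
  ids <- degs$probe_id
  missing <- setdiff(ids, annotation$probe_id)
  if (length(missing))
    stop("probes missing from annotation: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  flag <- stats::setNames(annotation$is_lncrna, annotation$probe_id)[ids]
  list(lnc = ids[flag], mrna = ids[!flag])
}
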