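# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the pooled t and BH step-up are written from
# their textbook definitions, the network scans are naive double loops.

# classical pooled two-sample t-test, vectorized over probe rows
oracle_pooled_t <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  t <- (ma - mb) / sqrt(s2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# Benjamini-Hochberg step-up from the definition, as an explicit double
# loop: sort ascending, q_(i) = min_{j>=i} p_(j) * m / j, cap at 1,
# restore input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive coexpression scan with cor.test, the same threshold rule
oracle_coexpression <- function(values, lnc_ids, mrna_ids,
                                r_threshold = 0.8, alpha = 0.05,
                                signed = FALSE) {
  rows <- list()
  for (l in lnc_ids) for (g in mrna_ids) {
    ct <- cor.test(values[l, ], values[g, ])
    r <- unname(ct$estimate)
    mag <- if (signed) r else abs(r)
    if (mag > r_threshold && ct$p.value < alpha)
      rows[[length(rows) + 1]] <- data.frame(
        lnc = l, mrna = g, r = r, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(lnc = character(0), mrna = character(0), r = numeric(0))
}

# pairwise shared-target intersections by brute force
oracle_coregulation <- function(network) {
  lncs <- sort(unique(network$lnc))
  out <- list()
  for (i in seq_along(lncs)) for (j in seq_along(lncs)) {
    if (i >= j) next
    a <- unique(network$mrna[network$lnc == lncs[i]])
    b <- unique(network$mrna[network$lnc == lncs[j]])
    shared <- intersect(a, b)
    if (length(shared))
      out[[length(out) + 1]] <- list(lnc_a = lncs[i], lnc_b = lncs[j],
                                     weight = length(shared),
                                     shared = sort(shared))
  }
  out
}

# small dataset used by several files
tiny_config <- function(...) {
  args <- modifyList(list(n_control = 8, n_dysplasia = 6, n_cancer = 10,
                          n_probes = 120, frac_lncrna = 0.1,
                          n_de_per_contrast = 5, planted_log2fc = 2,
                          n_modules = 2, module_size = 4,
                          module_rho = 0.9, noise_sd = 0.5, seed = 11),
                     list(...))
  do.call(simulation_config, args)
}

random_em <- function(n_probes, n_samples, seed = 1,
                      groups = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * n_samples, mean = 8, sd = 1.5),
              n_probes, n_samples,
              dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  expression_matrix(m, groups)
}

# vectors whose sample Pearson correlation is exactly 0.8 in floating
# point: orthogonal mean-zero sign patterns with 4/5-3/5 weights
exact_r08_pair <- function(reps = 8) {
  x <- rep(c(1, -1, 1, -1), reps)
  y <- 4 * x + 3 * rep(c(1, 1, -1, -1), reps)
  list(x = x, y = y)
}
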