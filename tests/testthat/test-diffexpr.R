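two_group_em <- function(a, b) {
  # one probe per row of a/b lists; builds a matrix with groups g1/g2
  na <- length(a[[1]]); nb <- length(b[[1]])
  m <- t(mapply(c, a, b))
  rownames(m) <- sprintf("p%d", seq_along(a))
  colnames(m) <- sprintf("s%d", seq_len(na + nb))
  expression_matrix(m, rep(c("g1", "g2"), c(na, nb)))
}

test_that("contrast statistics reproduce hand-computed pooled moments", {
  em <- two_group_em(list(c(1, 2, 3), c(3, 3, 3)),
                     list(c(2, 4, NA), c(1, 1, 1)))
  # p2: identical-ish groups, no missing: lfc = 3 - 1 = 2
  expect_message(cs <- contrast_statistics(em, "g1", "g2"), "1 probe")
  expect_equal(attr(cs, "n_excluded"), 1L)
  expect_equal(cs$probe_id, "p2")
  expect_equal(cs$log2fc, 2)
  expect_equal(cs$s2, 0)

  # a = (1,2,3), b = (2,4): lfc = 2 - 3 = -1, s2 = (2*1 + 1*2)/3 = 4/3
  m <- rbind(p1 = c(1, 2, 3, 2, 4))
  colnames(m) <- paste0("s", 1:5)
  em2 <- expression_matrix(m, rep(c("g1", "g2"), c(3, 2)))
  cs2 <- contrast_statistics(em2, "g1", "g2")
  expect_equal(cs2$log2fc, -1)
  expect_equal(cs2$s2, 4 / 3)
  expect_equal(cs2$df, 3)

  expect_error(contrast_statistics(em2, "g2", "nope"), "at least 2")
})

test_that("EB prior: degenerate, hand-sized and simulated cases", {
  expect_error(estimate_eb_prior(rep(0, 20), df = 4), "all variances")

  # zero excess dispersion -> infinite prior df at the common value
  pr <- estimate_eb_prior(rep(2.5, 50), df = 10)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 2.5)

  # alternating {1,2} at df = 4: the observed log-variance dispersion
  # (0.134) is below the sampling dispersion trigamma(2) = 0.645, so the
  # moment fit correctly degenerates to an infinite-df prior
  pr12 <- estimate_eb_prior(rep(c(1, 2), 5), df = 4)
  expect_identical(pr12$d0, Inf)
  expect_equal(pr12$s0_sq, 1.5)

  # a genuinely overdispersed set exercises the finite-d0 branch; compare
  # against an independent uniroot inversion of the digamma/trigamma
  # moment equations
  s2 <- rep(c(0.1, 10), 5)
  df <- 4
  pr <- estimate_eb_prior(s2, df)
  z <- log(s2)
  evar <- var(z) - trigamma(df / 2)
  d0_oracle <- 2 * uniroot(function(x) trigamma(x) - evar,
                           c(1e-3, 1e3), tol = 1e-12)$root
  s0_oracle <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                     digamma(d0_oracle / 2) - log(d0_oracle / 2))
  expect_gt(pr$d0, 0)
  expect_equal(pr$d0, d0_oracle, tolerance = 1e-6)
  expect_equal(pr$s0_sq, s0_oracle, tolerance = 1e-6)

  # recovery from the generative scaled-F model
  set.seed(20151)
  s2 <- 1 * rf(20000, df1 = 10, df2 = 4)
  pr <- estimate_eb_prior(s2, df = 10)
  expect_lt(abs(pr$d0 - 4), 0.5)
  expect_lt(abs(pr$s0_sq - 1), 0.05)
})

test_that("moderated t matches hand arithmetic and its limits", {
  cs <- structure(data.frame(probe_id = "p1", mean_a = 1, mean_b = 0,
                             log2fc = 1, s2 = 1, df = 4, n_a = 3,
                             n_b = 3),
                  contrast = "a_vs_b",
                  class = c("ContrastStats", "data.frame"))
  mt <- moderated_t(cs, list(d0 = 4, s0_sq = 1))
  expect_equal(mt$posterior_s2, 1)
  expect_equal(mt$moderated_t, 1 / sqrt(2 / 3))
  expect_equal(mt$total_df, 8)
  expect_equal(mt$raw_p, 2 * pt(-1 / sqrt(2 / 3), df = 8))

  # zero fold change -> t = 0, p = 1
  cs$log2fc <- 0
  mt0 <- moderated_t(cs, list(d0 = 4, s0_sq = 1))
  expect_equal(mt0$moderated_t, 0)
  expect_equal(mt0$raw_p, 1)

  # zero posterior variance with nonzero fold change -> infinite t, p = 0
  cs$log2fc <- 1; cs$s2 <- 0
  mtinf <- moderated_t(cs, list(d0 = 0, s0_sq = 1))
  expect_true(is.infinite(mtinf$moderated_t))
  expect_equal(mtinf$raw_p, 0)

  # d0 = Inf uses the normal reference
  mtn <- moderated_t(cs, list(d0 = Inf, s0_sq = 1))
  expect_equal(mtn$raw_p, 2 * pnorm(-abs(mtn$moderated_t)))
})

test_that("d0 = 0 reduces to the classical pooled t on random instances", {
  for (seed in 1:20) {
    em <- random_em(50, 12, seed = seed,
                    groups = rep(c("g1", "g2"), each = 6))
    cs <- contrast_statistics(em, "g1", "g2")
    mt <- moderated_t(cs, list(d0 = 0, s0_sq = 1))
    xa <- em$values[, 1:6]; xb <- em$values[, 7:12]
    oracle <- oracle_pooled_t(xa, xb)
    expect_lt(max(abs(mt$moderated_t - oracle$t)), 1e-10)
    expect_lt(max(abs(mt$raw_p - oracle$p)), 1e-10)
  }
})

test_that("moderated pipeline agrees with the limma implementation", {
  skip_if_not_installed("limma")
  set.seed(5)
  m <- matrix(rnorm(300 * 12, sd = runif(300, 0.3, 2)), 300, 12,
              dimnames = list(paste0("p", 1:300), paste0("s", 1:12)))
  groups <- rep(c("a", "b"), each = 6)
  em <- expression_matrix(m, groups)
  cs <- contrast_statistics(em, "a", "b")
  design <- stats::model.matrix(~ factor(groups, levels = c("b", "a")))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_lt(max(abs(cs$s2 - fit$sigma^2)), 1e-12)

  # hyperparameters estimated from the same variances agree closely
  pr <- estimate_eb_prior(cs$s2, df = cs$df[1])
  expect_equal(pr$d0, fit$df.prior, tolerance = 0.02)
  expect_equal(pr$s0_sq, fit$s2.prior, tolerance = 0.01)

  # with limma's own prior injected the statistics match to precision
  mt <- moderated_t(cs, list(d0 = fit$df.prior, s0_sq = fit$s2.prior))
  expect_lt(max(abs(mt$moderated_t - fit$t[, 2])), 1e-10)
  expect_lt(max(abs(mt$raw_p - fit$p.value[, 2])), 1e-10)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.1, 1.2)), "0, 1")
  expect_error(adjust_bh(c(0.1, NA)), "0, 1")

  for (seed in 1:20) {
    set.seed(seed)
    p <- runif(75)^2
    q <- adjust_bh(p)
    expect_identical(q, oracle_bh(p))
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    # adjusted values preserve the raw-p ranking
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("DEG selection applies strict fold-change and alpha bounds", {
  de <- structure(
    data.frame(probe_id = c("up", "at_fold", "at_alpha", "down", "weak"),
               log2fc = c(log2(2.1), 1, log2(3), -1.5, 0.5),
               adj_p = c(0.01, 0.001, 0.05, 0.0, 0.01), raw_p = 0,
               stringsAsFactors = FALSE),
    contrast = "a_vs_b", class = c("DEResult", "data.frame"))
  degs <- select_degs(de, fold_bound = 2, alpha = 0.05)
  # fold change 2.1 & p 0.01 in; exactly 2.0 out; p exactly 0.05 out
  expect_setequal(degs$probe_id, c("up", "down"))
  expect_equal(degs$direction[degs$probe_id == "up"], "up")
  expect_equal(degs$direction[degs$probe_id == "down"], "down")
})

test_that("venn partition enumerates the seven regions", {
  v <- venn_partition(c("a", "b", "c"), c("b", "c"), "c")
  expect_equal(v$abc, "c")
  expect_equal(v$ab, "b")
  expect_equal(v$a_only, "a")
  expect_equal(sum(v$counts), 3)
  expect_equal(unname(v$counts[c("b_only", "c_only", "ac", "bc")]),
               rep(0L, 4))

  same <- venn_partition(1:5, 1:5, 1:5)
  expect_equal(sum(same$counts), 5)
  expect_equal(unname(same$counts["abc"]), 5L)

  disj <- venn_partition("x", "y", "z")
  expect_equal(unname(disj$counts[c("a_only", "b_only", "c_only")]),
               rep(1L, 3))
  expect_equal(sum(disj$counts), 3)
})

test_that("lncRNA/mRNA split partitions a DEG set by annotation", {
  ann <- data.frame(probe_id = paste0("p", 1:5),
                    gene_symbol = paste0("g", 1:5), gene_id = NA,
                    is_lncrna = c(TRUE, FALSE, TRUE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  degs <- data.frame(probe_id = paste0("p", 1:5),
                     stringsAsFactors = FALSE)
  parts <- split_lncrna(degs, ann)
  expect_equal(parts$lnc, c("p1", "p3"))
  expect_equal(parts$mrna, c("p2", "p4", "p5"))
  expect_setequal(c(parts$lnc, parts$mrna), degs$probe_id)
  # brute-force filter oracle
  expect_equal(parts$lnc, degs$probe_id[ann$is_lncrna])

  none <- split_lncrna(data.frame(probe_id = c("p2", "p4")), ann)
  expect_length(none$lnc, 0)
  expect_error(split_lncrna(data.frame(probe_id = "p9"), ann),
               "missing from annotation")
})

test_that("type-I error is calibrated on null data", {
  ds <- generate_dataset(simulation_config(
    n_control = 20, n_dysplasia = 10, n_cancer = 40, n_probes = 5000,
    n_de_per_contrast = 0, n_modules = 0, noise_sd = 0.5, seed = 42))
  de <- de_contrast(ds$matrix, "cancer", "control")
  frac <- mean(de$raw_p < 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / 5000)
  expect_lt(abs(frac - 0.05), se3)
  expect_lte(nrow(select_degs(de)), 5)
})

test_that("planted effects are recovered at the screening thresholds", {
  ds <- generate_dataset(simulation_config(
    n_control = 20, n_dysplasia = 10, n_cancer = 40, n_probes = 5000,
    n_de_per_contrast = 200, planted_log2fc = 2, n_modules = 0,
    noise_sd = 0.5, seed = 42))
  imp <- implied_log2fc(ds$truth)
  for (ct in default_contrasts()) {
    ab <- strsplit(ct, "_vs_")[[1]]
    degs <- select_degs(de_contrast(ds$matrix, ab[1], ab[2]))
    planted <- ds$truth$de[[ct]]$probe_id
    truly_de <- imp$probe_id[imp[[ct]] != 0]
    sens <- mean(planted %in% degs$probe_id)
    fdp <- if (nrow(degs)) mean(!degs$probe_id %in% truly_de) else 0
    expect_gte(sens, 0.90)
    expect_lte(fdp, 0.10)
  }
})
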