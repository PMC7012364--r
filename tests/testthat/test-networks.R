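test_that("pearson_with_test handles the closed-form cases", {
  x <- 1:6
  res <- pearson_with_test(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)

  # orthogonal deviations -> r = 0, p = 1
  res0 <- pearson_with_test(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(res0$r, 0)
  expect_equal(res0$p, 1)

  # r = 0.8 at n = 229: t = 0.8 sqrt(227) / 0.6 ~ 20.09, p < 1e-15
  t229 <- 0.8 * sqrt(227) / 0.6
  expect_equal(t229, 20.088, tolerance = 1e-4)
  expect_lt(2 * pt(-t229, df = 227), 1e-15)

  expect_error(pearson_with_test(1:3, 1:4), "equal length")
  expect_error(pearson_with_test(1:2, 1:2), "at least 3")
  expect_error(pearson_with_test(rep(1, 5), 1:5), "zero-variance")
})

test_that("pearson_with_test is symmetric and matches cor.test", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(15); y <- rnorm(15)
    a <- pearson_with_test(x, y)
    b <- pearson_with_test(y, x)
    expect_identical(a$r, b$r)
    expect_identical(a$p, b$p)
    ct <- cor.test(x, y)
    expect_equal(a$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(a$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("coexpression build equals the exhaustive brute-force scan", {
  for (seed in 1:5) {
    em <- random_em(20, 12, seed = seed)
    lnc <- rownames(em$values)[1:8]
    mrna <- rownames(em$values)[9:20]
    # loosened thresholds so random data actually yields edges
    net <- build_coexpression(em, lnc, mrna, r_threshold = 0.3,
                              alpha = 0.2)
    oracle <- oracle_coexpression(em$values, lnc, mrna,
                                  r_threshold = 0.3, alpha = 0.2)
    expect_equal(nrow(net), nrow(oracle))
    key <- function(d) sort(paste(d$lnc, d$mrna))
    expect_equal(key(net), key(oracle))
    signed <- build_coexpression(em, lnc, mrna, r_threshold = 0.3,
                                 alpha = 0.2, signed = TRUE)
    oracle_s <- oracle_coexpression(em$values, lnc, mrna, 0.3, 0.2,
                                    signed = TRUE)
    expect_equal(key(signed), key(oracle_s))
    expect_true(all(signed$r > 0.3))
  }
})

test_that("a planted perfect edge is found and nothing else", {
  set.seed(3)
  base <- 1:6
  m <- rbind(L1 = base, G1 = 2 * base, G2 = sample(base))
  colnames(m) <- paste0("s", 1:6)
  em <- expression_matrix(m)
  net <- build_coexpression(em, "L1", c("G1", "G2"))
  expect_equal(nrow(net), 1)
  expect_equal(net$lnc, "L1")
  expect_equal(net$mrna, "G1")
  expect_equal(net$r, 1)
  expect_equal(net$n, 6)
})

test_that("the correlation threshold is strict: r exactly 0.8 is out", {
  pair <- exact_r08_pair()
  expect_identical(cor(pair$x, pair$y), 0.8)  # fixture sanity
  m <- rbind(L1 = pair$x, G1 = pair$y, G2 = pair$x * 1.5 + 2)
  colnames(m) <- paste0("s", seq_along(pair$x))
  em <- expression_matrix(m)
  net <- build_coexpression(em, "L1", c("G1", "G2"), r_threshold = 0.8,
                            alpha = 0.05)
  # G1 sits exactly on the bound (tiny p) and must be excluded; the
  # affine copy G2 (r = 1) stays
  expect_equal(net$mrna, "G2")
})

test_that("degenerate and empty inputs are handled", {
  em <- random_em(6, 10, seed = 2)
  expect_equal(nrow(build_coexpression(em, character(0),
                                       rownames(em$values))), 0)
  expect_error(build_coexpression(em, "nope", rownames(em$values)[1]),
               "not in matrix")
  em$values["p001", ] <- 5
  expect_message(net <- build_coexpression(em, "p001", "p002"),
                 "zero-variance")
  expect_equal(nrow(net), 0)
  expect_equal(attr(net, "n_skipped_zero_var"), 1L)
})

test_that("target sets follow the adjacency and coregulation intersects", {
  net <- structure(
    data.frame(lnc = c("L1", "L1", "L2", "L2", "L3"),
               mrna = c("G1", "G2", "G2", "G3", "G9"),
               r = 0.9, p = 1e-6, n = 20, stringsAsFactors = FALSE),
    class = c("CoexpressionNetwork", "data.frame"))
  expect_setequal(target_genes(net, "L1"), c("G1", "G2"))
  expect_length(target_genes(net, "absent"), 0)

  coreg <- build_coregulation(net)
  expect_equal(nrow(coreg), 1)
  expect_equal(coreg$lnc_a, "L1")
  expect_equal(coreg$lnc_b, "L2")
  expect_equal(coreg$weight, 1)
  expect_equal(coreg$shared_targets, "G2")
  expect_equal(attr(coreg, "coregulated_targets"), "G2")

  # identical target sets of size k -> weight k
  net2 <- net
  net2$lnc <- rep(c("La", "Lb"), c(3, 2))
  net2$mrna <- c("G1", "G2", "G3", "G1", "G2")
  # La targets {G1,G2,G3}, Lb {G1,G2}
  coreg2 <- build_coregulation(net2)
  expect_equal(coreg2$weight, 2)
  expect_equal(coreg2$shared_targets, "G1;G2")
})

test_that("coregulation matches brute force on random networks", {
  for (seed in 1:5) {
    set.seed(seed)
    net <- data.frame(
      lnc = sample(paste0("L", 1:6), 40, replace = TRUE),
      mrna = sample(paste0("G", 1:15), 40, replace = TRUE),
      stringsAsFactors = FALSE)
    net <- net[!duplicated(net), ]
    coreg <- build_coregulation(net)
    oracle <- oracle_coregulation(net)
    expect_equal(nrow(coreg), length(oracle))
    for (i in seq_along(oracle)) {
      row <- coreg[coreg$lnc_a == oracle[[i]]$lnc_a &
                     coreg$lnc_b == oracle[[i]]$lnc_b, ]
      expect_equal(row$weight, oracle[[i]]$weight)
      expect_equal(row$shared_targets,
                   paste(oracle[[i]]$shared, collapse = ";"))
      # weight bounded by the smaller target set
      sizes <- c(length(unique(net$mrna[net$lnc == row$lnc_a])),
                 length(unique(net$mrna[net$lnc == row$lnc_b])))
      expect_lte(row$weight, min(sizes))
    }
    expect_equal(attr(coreg, "coregulated_targets"),
                 sort(unique(unlist(lapply(oracle, `[[`, "shared")))))
  }
})

test_that("planted module edges are recovered across 229 samples", {
  ds <- generate_dataset(simulation_config(
    n_control = 45, n_dysplasia = 17, n_cancer = 167, n_probes = 400,
    frac_lncrna = 0.05, n_de_per_contrast = 0, n_modules = 5,
    module_size = 8, module_rho = 0.9, seed = 77))
  hubs <- names(ds$truth$modules)
  mrna <- ds$annotation$probe_id[!ds$annotation$is_lncrna]
  net <- build_coexpression(ds$matrix, hubs, mrna)
  planted <- unlist(lapply(hubs, function(h)
    paste(h, ds$truth$modules[[h]])))
  found <- paste(net$lnc, net$mrna)
  expect_gte(mean(planted %in% found), 0.95)

  # with rho = 0 (independent probes) false edges are rarer than alpha
  ds0 <- generate_dataset(simulation_config(
    n_control = 45, n_dysplasia = 17, n_cancer = 167, n_probes = 400,
    frac_lncrna = 0.05, n_de_per_contrast = 0, n_modules = 0,
    seed = 78))
  lnc0 <- ds0$annotation$probe_id[ds0$annotation$is_lncrna]
  mrna0 <- ds0$annotation$probe_id[!ds0$annotation$is_lncrna][1:100]
  net0 <- build_coexpression(ds0$matrix, lnc0, mrna0)
  expect_lt(nrow(net0) / (length(lnc0) * length(mrna0)), 0.05)
})
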