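test_that("DE filter keeps shifted features and drops identical ones", {
  set.seed(1)
  n_feat <- 40
  base <- matrix(rexp(n_feat * 20, rate = 0.2), n_feat,
                 dimnames = list(sprintf("f%02d", 1:n_feat), NULL))
  case <- base
  case[1:5, ] <- case[1:5, ] + 40      # strong shift on 5 features
  control <- base
  sel <- de_filter(case, control)
  expect_true(all(sprintf("f%02d", 1:5) %in% sel))
  expect_false(any(sprintf("f%02d", 6:40) %in% sel))

  # identical feature has rank-sum p = 1 -> never selected
  p_adj <- attr(sel, "p_adjusted")
  expect_true(all(p_adj[sprintf("f%02d", 6:40)] > 0.9))
})

test_that("DE filter applies Bonferroni arithmetic and detection filter", {
  set.seed(2)
  n <- 20
  case <- matrix(rexp(50 * n), 50, dimnames = list(paste0("f", 1:50), NULL))
  control <- matrix(rexp(50 * n), 50, dimnames = list(paste0("f", 1:50), NULL))
  case[1, ] <- control[1, ] + 10
  # feature observed in too few samples is dropped before testing
  case[2, 1:16] <- 0
  control[2, 1:16] <- 0
  sel <- de_filter(case, control)
  p_adj <- attr(sel, "p_adjusted")
  expect_false("f2" %in% names(p_adj))
  # Bonferroni: adjusted p = raw p times number of tested features (capped)
  raw <- suppressWarnings(wilcox.test(log2(case[1, ] + 1),
                                      log2(control[1, ] + 1),
                                      exact = FALSE)$p.value)
  expect_equal(unname(p_adj["f1"]), min(raw * length(p_adj), 1))
  expect_true("f1" %in% sel)

  expect_error(de_filter(case[, 1:2], control[, 1:2]), "3 samples")
})

test_that("KNN imputation fills from the nearest observed rows", {
  x <- rand_expr(6, 5, seed = 3)
  expect_identical(knn_impute(x), x)  # complete data: no-op

  # identical rows: the common value is restored
  xi <- matrix(rep(c(1, 2, 3, 4, 5), each = 4), 4, 5,
               dimnames = list(paste0("r", 1:4), paste0("c", 1:5)))
  xi[2, 3] <- NA
  expect_equal(knn_impute(xi, k = 2)[2, 3], 3)

  # hand-computed 5x4 fixture with k = 2: row distances to r1 are
  # r2: sqrt(0.03), r3: sqrt(12), r4: sqrt(27), r5: sqrt(48) over shared
  # observed columns, so the donors for (r1, c4) are r2 and r3
  xf <- rbind(r1 = c(1, 2, 3, NA),
              r2 = c(1.1, 2.1, 3.1, 4),
              r3 = c(3, 4, 5, 6),
              r4 = c(4, 5, 6, 7),
              r5 = c(5, 6, 7, 8))
  colnames(xf) <- paste0("c", 1:4)
  expect_equal(knn_impute(xf, k = 2)["r1", "c4"], mean(c(4, 6)))

  xbad <- xf
  xbad[1, ] <- NA
  expect_error(knn_impute(xbad), "no observed")
})

test_that("differential correlation matrix obeys Pearson identities", {
  set.seed(4)
  n1 <- 30
  A1 <- matrix(rnorm(8 * n1), 8, dimnames = list(paste0("g", 1:8), NULL))
  B1 <- A1[1:4, , drop = FALSE]  # miRNAs duplicate the first four genes
  rownames(B1) <- paste0("m", 1:4)
  A2 <- matrix(rnorm(8 * 25), 8, dimnames = list(paste0("g", 1:8), NULL))
  B2 <- matrix(rnorm(4 * 25), 4, dimnames = list(paste0("m", 1:4), NULL))
  dc <- differential_matrix(A1, A2, B1, B2)
  expect_equal(unname(diag(dc$X1[1:4, ])), rep(1, 4))
  expect_true(all(abs(dc$X1) <= 1 + 1e-12))
  expect_true(all(abs(dc$X2) <= 1 + 1e-12))
  expect_equal(dc$X, dc$X1 - dc$X2)

  # row centering/scaling leaves the correlations identical to raw Pearson
  raw <- cor(t(A1), t(B1))
  expect_equal(unname(dc$X1), unname(raw), tolerance = 1e-12)

  # independent large-sample condition-2: correlations concentrate near 0
  set.seed(5)
  A2b <- matrix(rnorm(8 * 500), 8, dimnames = list(paste0("g", 1:8), NULL))
  B2b <- matrix(rnorm(4 * 500), 4, dimnames = list(paste0("m", 1:4), NULL))
  dcb <- differential_matrix(A1, A2b, B1, B2b)
  expect_lt(max(abs(dcb$X2)), 0.2)
})

test_that("equal conditions give a zero differential matrix", {
  set.seed(6)
  A <- matrix(rnorm(10 * 20), 10, dimnames = list(paste0("g", 1:10), NULL))
  B <- matrix(rnorm(3 * 20), 3, dimnames = list(paste0("m", 1:3), NULL))
  dc <- differential_matrix(A, A, B, B)
  expect_equal(max(abs(dc$X)), 0)
})

test_that("the pipeline recovers a planted differential block", {
  dd <- simulate_diffcoexpr_data(n_genes = 150, n_mirnas = 30,
                                 gene_block = 20, mirna_block = 5,
                                 rho = 0.8, seed = 7)
  dc <- differential_matrix(dd$A1, dd$A2, dd$B1, dd$B2)
  mods <- diff_coexpr_modules(dc, dd$network, n_modules = 3, sigma = 0.5,
                              target_nnz_gene = 20, kv_mirna = 5,
                              restarts = 3, seed = 8)
  expect_identical(length(mods), 3L)
  m1 <- mods[[1]]
  expect_gte(length(intersect(m1$genes, dd$gene_block)), 18)  # >= 90%
  expect_gte(length(intersect(m1$samples, dd$mirna_block)), 5)
  expect_true(all(c("adpcc_mean", "n_gene_edges") %in% names(m1$stats)))
  # the planted module's differential correlation beats the matrix average
  expect_gt(m1$stats$adpcc_mean, mean(abs(dc$X)))
})

test_that("network regularization pulls modules toward connected genes", {
  # paired comparison over 20 planted instances: the sigma > 0 module
  # induces at least as many prior-network edges as the sigma = 0 module
  # on average, and wins or ties in the clear majority of instances
  diffs <- vapply(1:20, function(s) {
    dd <- simulate_diffcoexpr_data(n_genes = 80, n_mirnas = 20,
                                   gene_block = 12, mirna_block = 4,
                                   rho = 0.5, p_in = 0.6, p_out = 0.05,
                                   seed = 20 + s)
    dc <- differential_matrix(dd$A1, dd$A2, dd$B1, dd$B2)
    e <- vapply(c(2, 0), function(sg) suppressWarnings(
      diff_coexpr_modules(dc, dd$network, n_modules = 1, sigma = sg,
                          target_nnz_gene = 12, kv_mirna = 4,
                          restarts = 2, seed = 1)[[1]]$stats$n_gene_edges),
      numeric(1))
    e[1] - e[2]
  }, numeric(1))
  expect_gte(mean(diffs), 0)
  expect_gte(sum(diffs >= 0), 12)
})

test_that("the adPCC permutation test calibrates and detects", {
  dd <- simulate_diffcoexpr_data(n_genes = 100, n_mirnas = 25,
                                 gene_block = 15, mirna_block = 5,
                                 rho = 0.8, seed = 9)
  dc <- differential_matrix(dd$A1, dd$A2, dd$B1, dd$B2)
  # planted block: smallest achievable p-value
  planted <- make_module(dd$gene_block, dd$mirna_block)
  res <- adpcc_test(dc, planted, n_perm = 199, seed = 1)
  expect_equal(res$p, 1 / 200)
  # permutation statistics concentrate around the global mean |X|
  expect_equal(mean(res$null), mean(abs(dc$X)), tolerance = 0.05)
  expect_error(adpcc_test(dc, planted, n_perm = 50), "at least 100")
})
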