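test_that("z-score member filter handles degenerate and literal cases", {
  # zero spread of magnitudes keeps every nonzero member
  u <- c(0.5, 0.5, 0.5, 0, 0)
  v <- c(0.7, 0.7, 0)
  m <- extract_module(u, v, threshold = 0.5)
  expect_identical(m$genes, c("g1", "g2", "g3"))
  expect_identical(m$samples, c("s1", "s2"))

  # threshold 0 keeps every nonzero member
  set.seed(1)
  u2 <- c(rnorm(4), 0, 0)
  m2 <- extract_module(u2, v, threshold = 0)
  expect_identical(m2$genes, paste0("g", 1:4))

  # fewer than two nonzeros are kept verbatim with a warning
  expect_warning(m3 <- extract_module(c(0, 1, 0), v, threshold = 1),
                 "verbatim")
  expect_identical(m3$genes, "g2")
})

test_that("z-score filter applies the magnitude outlier rule", {
  # |values| = (1, 1, 1, 5): mu = 2, sd = 2, z = (0.5, 0.5, 0.5, 1.5)
  u <- c(1, -1, 1, 5, 0)
  v <- c(1, 1, 0)
  m <- extract_module(u, v, threshold = 1.0)
  expect_identical(m$genes, "g4")      # only the outlier exceeds z = 1
  m_all <- extract_module(u, v, threshold = 0.4)
  expect_identical(m_all$genes, paste0("g", 1:4))
})

test_that("modularity is mean absolute pairwise correlation", {
  # identical profiles: modularity 1
  x <- rand_expr(6, 8, seed = 2)
  x[2, ] <- 2 * x[1, ] + 3      # affine copy: |r| = 1
  mod <- make_module(c("g001", "g002"), colnames(x))
  expect_equal(module_modularity(x, mod), 1)

  # hand check against an independent correlation routine
  mod3 <- make_module(c("g003", "g004", "g005"), colnames(x)[1:4])
  w <- cor(t(x[3:5, 1:4]))
  diag(w) <- 0
  expect_equal(module_modularity(x, mod3), sum(abs(w)) / (3 * 2))

  # invariance to per-gene affine rescaling and to gene order
  x2 <- x
  x2[3, ] <- -5 * x2[3, ] + 1
  expect_equal(module_modularity(x2, mod3), module_modularity(x, mod3))
  mod3r <- make_module(rev(mod3$genes), mod3$samples)
  expect_equal(module_modularity(x, mod3r), module_modularity(x, mod3))

  expect_error(module_modularity(x, make_module("g001", colnames(x))),
               "at least 2")
})

test_that("duplicated-profile modules score near 1, independent genes near 0", {
  set.seed(3)
  base <- rnorm(1000)
  dup <- rbind(base, base * 1.5, base + 2, -base)
  ind <- matrix(rnorm(4 * 1000), 4)
  x <- rbind(dup, ind)
  rownames(x) <- paste0("g", 1:8)
  colnames(x) <- paste0("s", 1:1000)
  m_dup <- make_module(paste0("g", 1:4), colnames(x))
  m_ind <- make_module(paste0("g", 5:8), colnames(x))
  expect_equal(module_modularity(x, m_dup), 1)
  expect_lt(module_modularity(x, m_ind), 0.1)
})

test_that("modularity significance separates real from random modules", {
  set.seed(4)
  base <- rnorm(60)
  x <- rbind(t(replicate(5, base + rnorm(60, sd = 0.1))),
             matrix(rnorm(45 * 60), 45))
  rownames(x) <- paste0("g", 1:50)
  colnames(x) <- paste0("s", 1:60)
  m <- make_module(paste0("g", 1:5), colnames(x))
  expect_lt(modularity_pvalue(x, m, n_random = 100, seed = 1), 0.01)
  expect_error(modularity_pvalue(x, m, n_random = 10), "at least 20")

  # a random module is not significant against its own null
  set.seed(5)
  rnd <- make_module(sample(rownames(x)[6:50], 5), colnames(x))
  p <- modularity_pvalue(x, rnd, n_random = 60, seed = 2)
  expect_gt(p, 0.01)
})

test_that("interaction enrichment is a right-tailed hypergeometric test", {
  net <- rand_network(15, prob = 0.3, seed = 5, ids = paste0("g", 1:15))
  # no induced edges: p near 1, score near 0
  iso <- make_module(c("g1", "g2"), character(0))
  A <- as.matrix(net$adjacency)
  pick_disconnected <- function() {
    for (i in 1:14) for (j in (i + 1):15) {
      if (A[i, j] == 0) return(c(i, j))
    }
  }
  ij <- pick_disconnected()
  m0 <- make_module(paste0("g", ij), character(0))
  enr0 <- interaction_enrichment(net, m0)
  expect_identical(enr0$n_edges, 0L)
  expect_gt(enr0$p, 0.5)
  expect_lt(enr0$score, 0.31)
  expect_false(enr0$significant)

  # among same-size modules, more induced edges means a smaller p-value
  size4 <- combn(15, 4)[, seq(1, 1300, by = 40)]
  stats4 <- apply(size4, 2, function(g) {
    enr <- interaction_enrichment(net, make_module(paste0("g", g),
                                                   character(0)))
    c(enr$n_edges, enr$p)
  })
  ord <- order(stats4[1, ])
  expect_true(all(diff(stats4[2, ord]) <= 1e-12))

  # single-gene module degenerates to p = 1
  one <- interaction_enrichment(net, make_module("g1", character(0)))
  expect_identical(one$p, 1)
  expect_identical(one$score, 0)
})

test_that("enrichment p-value matches exhaustive enumeration on 5 nodes", {
  # universe: 5 genes, m = 4 edges; module: 3 genes inducing 3 edges
  edges <- rbind(c("a", "b"), c("a", "c"), c("b", "c"), c("d", "e"))
  net <- gene_network(edges, c("a", "b", "c", "d", "e"))
  mod <- make_module(c("a", "b", "c"), character(0))
  enr <- interaction_enrichment(net, mod)
  # all C(10, 3) ways to choose N_i = 3 of the N = 10 vertex pairs; count
  # draws containing >= 3 of the m = 4 true edges
  all_pairs <- t(combn(5, 2))
  is_edge <- apply(all_pairs, 1, function(pr) {
    any(apply(rbind(match(edges[, 1], c("a", "b", "c", "d", "e")),
                    match(edges[, 2], c("a", "b", "c", "d", "e"))), 2,
              function(e) all(sort(e) == sort(pr))))
  })
  draws <- combn(10, 3)
  hits <- apply(draws, 2, function(s) sum(is_edge[s]) >= 3)
  expect_equal(enr$p, mean(hits))
  expect_equal(enr$score, -log10(mean(hits)))
})

test_that("module overlap flags identical and clears disjoint pairs", {
  a <- make_module(paste0("g", 1:10), paste0("s", 1:8))
  b <- make_module(paste0("g", 1:10), paste0("s", 1:8))
  ov <- module_overlap(a, b, n_genes = 200, n_samples = 100)
  expect_lt(ov$p_genes, 1e-10)
  expect_true(ov$significant)

  c_ <- make_module(paste0("g", 11:20), paste0("s", 9:16))
  ov2 <- module_overlap(a, c_, n_genes = 200, n_samples = 100)
  expect_gt(ov2$p_genes, 0.5)
  expect_false(ov2$significant)

  # worked overlap against the hypergeometric survival function
  d_ <- make_module(paste0("g", c(1:5, 21:27)), paste0("s", 1:8))
  ov3 <- module_overlap(a, d_, n_genes = 100, n_samples = 100)
  expect_equal(ov3$p_genes, phyper(4, 10, 90, 12, lower.tail = FALSE))
})

test_that("a 40-module set yields 780 pairwise comparisons", {
  set.seed(6)
  mods <- structure(lapply(1:40, function(k) {
    make_module(sample(paste0("g", 1:500), 20),
                sample(paste0("s", 1:100), 10), index = k)
  }), class = "module_set")
  tab <- module_overlap_table(mods, n_genes = 500, n_samples = 100)
  expect_identical(nrow(tab), 780L)
})
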