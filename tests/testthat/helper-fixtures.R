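# shared in-code fixtures; everything is generated, nothing read from disk

# write a small expression TSV and return its path
write_expr_fixture <- function(x, path = tempfile(fileext = ".tsv")) {
  tab <- cbind(gene = rownames(x), as.data.frame(x))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random expression matrix with ids
rand_expr <- function(p, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(p * n), p, n,
         dimnames = list(sprintf("g%03d", 1:p), sprintf("s%03d", 1:n)))
}

# Erdos-Renyi gene_network over p nodes
rand_network <- function(p, prob = 0.2, seed = 1, ids = sprintf("g%03d", 1:p)) {
  set.seed(seed)
  m <- matrix(runif(p * p) < prob, p)
  m[lower.tri(m, diag = TRUE)] <- FALSE
  e <- which(m, arr.ind = TRUE)
  gene_network(cbind(ids[e[, 1]], ids[e[, 2]]), ids)
}

# pairwise-difference form of the Laplacian quadratic form (independent of
# the matrix-product implementation)
quadform_pairwise <- function(net, u) {
  A <- as.matrix(net$adjacency)
  d <- rowSums(A)
  s <- ifelse(d > 0, u / sqrt(d), 0)
  total <- 0
  p <- length(u)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (A[i, j] != 0) total <- total + (s[i] - s[j])^2
    }
  }
  as.numeric(total / 2)
}

# simple module record for stats tests
make_module <- function(genes, samples, index = 1L, d = 1) {
  structure(list(module_index = as.integer(index), genes = genes,
                 samples = samples,
                 weights = stats::setNames(rep(1, length(c(genes, samples))),
                                           c(genes, samples)),
                 d = d, stats = list()),
            class = "module_record")
}
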