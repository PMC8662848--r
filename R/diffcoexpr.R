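#' Differential-expression prefilter for matched two-condition data
#'
#' Reproduces the preprocessing used before differential co-expression
#' analysis: features detected (nonzero, non-missing) in too few samples are
#' dropped (a feature is removed when the fraction of zero or missing raw
#' values across both conditions exceeds `max_zero_frac`), raw values are
#' log2-transformed with a +1 offset, and a two-sided Wilcoxon rank-sum test
#' per feature compares the conditions with Bonferroni control: features
#' with `p * n_tested < alpha` are selected.
#'
#' @param case,control Numeric features-by-samples matrices on the raw scale
#'   with shared rownames.
#' @param alpha Family-wise error level (default 0.05).
#' @param max_zero_frac Detection filter threshold (default 0.7).
#' @return Character vector of selected feature IDs, with attribute
#'   `p_adjusted` (named Bonferroni-adjusted p-values of all tested
#'   features).
#' @export
de_filter <- function(case, control, alpha = 0.05, max_zero_frac = 0.7) {
  shared <- intersect(rownames(case), rownames(control))
  if (!length(shared)) stop("case and control share no feature IDs")
  if (ncol(case) < 3L || ncol(control) < 3L) {
    stop("need at least 3 samples per condition")
  }
  case <- case[shared, , drop = FALSE]
  control <- control[shared, , drop = FALSE]
  zero_frac <- rowMeans(cbind(case == 0 | is.na(case),
                              control == 0 | is.na(control)))
  keep <- zero_frac <= max_zero_frac
  if (!any(keep)) stop("no feature passes the detection filter")
  case <- log2(case[keep, , drop = FALSE] + 1)
  control <- log2(control[keep, , drop = FALSE] + 1)
  pvals <- vapply(rownames(case), function(f) {
    suppressWarnings(
      wilcox.test(case[f, ], control[f, ], alternative = "two.sided",
                  exact = FALSE)$p.value)
  }, numeric(1))
  p_adj <- pmin(pvals * length(pvals), 1)
  selected <- names(p_adj)[!is.na(p_adj) & p_adj < alpha]
  if (!length(selected)) {
    stop("no differentially expressed feature at alpha = ", alpha,
         "; consider relaxing alpha")
  }
  structure(selected, p_adjusted = p_adj)
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' Fills each missing cell with the mean of the observed values, in that
#' column, of the `k` nearest rows. Row distance is the Euclidean distance
#' over the columns observed in both rows; only rows observed in the target
#' column are eligible neighbours.
#'
#' @param x Numeric matrix with `NA` marking missing cells; every row needs
#'   at least one observed entry.
#' @param k Number of neighbours (default 10).
#' @return `x` with no missing entries.
#' @export
knn_impute <- function(x, k = 10L) {
  x <- as.matrix(x)
  if (!anyNA(x)) return(x)
  obs <- !is.na(x)
  if (any(rowSums(obs) == 0L)) {
    stop("row with no observed entries: ",
         rownames(x)[which(rowSums(obs) == 0L)[1L]])
  }
  filled <- x
  need <- which(rowSums(!obs) > 0L)
  for (i in need) {
    miss_cols <- which(!obs[i, ])
    # squared distances over shared observed columns, to every other row
    shared <- obs & rep(obs[i, ], each = nrow(x))
    diffs <- sweep(x, 2L, x[i, ])^2
    diffs[!shared] <- NA_real_
    d2 <- rowSums(diffs, na.rm = TRUE)
    d2[rowSums(shared) == 0L] <- Inf
    d2[i] <- Inf
    for (j in miss_cols) {
      donors <- which(obs[, j] & is.finite(d2))
      if (!length(donors)) {
        stop("no donor row observed in column ", colnames(x)[j] %||% j)
      }
      nb <- donors[order(d2[donors])][seq_len(min(k, length(donors)))]
      filled[i, j] <- mean(x[nb, j])
    }
  }
  filled
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Differential miRNA-gene correlation matrix
#'
#' Builds the condition-wise Pearson correlation matrices between genes and
#' miRNAs and their difference. Rows of all four matrices are centered and
#' scaled first (which leaves Pearson correlations unchanged);
#' `X1[g, m]` is the correlation of gene `g` and miRNA `m` across the
#' condition-1 samples, `X2` likewise for condition 2, and `X = X1 - X2` is
#' the differential correlation matrix whose large-magnitude entries mark
#' miRNA-gene pairs whose co-expression differs between conditions.
#'
#' @param A1,A2 Genes-by-samples expression for conditions 1 and 2 (shared
#'   rownames; `A1` shares samples with `B1`, `A2` with `B2`).
#' @param B1,B2 miRNAs-by-samples expression for conditions 1 and 2.
#' @return Object of class `diff_correlation`: list with `X1`, `X2`
#'   (entries in `[-1, 1]`) and `X` (entries in `[-2, 2]`).
#' @export
differential_matrix <- function(A1, A2, B1, B2) {
  stopifnot(ncol(A1) == ncol(B1), ncol(A2) == ncol(B2),
            identical(rownames(A1), rownames(A2)),
            identical(rownames(B1), rownames(B2)))
  cor_gm <- function(A, B) {
    out <- suppressWarnings(cor(t(.row_scale(A)), t(.row_scale(B))))
    if (anyNA(out)) {
      warning("zero-variance row(s); correlations set to 0")
      out[is.na(out)] <- 0
    }
    out
  }
  X1 <- cor_gm(A1, B1)
  X2 <- cor_gm(A2, B2)
  structure(list(X1 = X1, X2 = X2, X = X1 - X2), class = "diff_correlation")
}

.row_scale <- function(m) {
  ctr <- m - rowMeans(m)
  sds <- sqrt(rowSums(ctr^2) / (ncol(m) - 1L))
  sds[sds == 0] <- 1
  ctr / sds
}

#' Identify differentially co-expressed miRNA-gene modules
#'
#' Runs the sparse network-regularized factorization on a differential
#' correlation matrix `X` (genes in rows, miRNAs in columns): the Laplacian
#' penalty attaches to the gene side, the L0 cardinality bound to the miRNA
#' side, and successive modules come from deflation with random restarts.
#' Each returned module records its average adPCC (mean `|X|` over the
#' module's submatrix), its induced gene-edge count in the prior network,
#' and its singular value.
#'
#' @param dc A [differential_matrix()] result.
#' @param gene_net A [gene_network()] over the rows of `dc$X`.
#' @param n_modules Number of modules (default 10).
#' @param sigma Network weight.
#' @param target_nnz_gene Gene-support target per factor (default 100,
#'   capped at the number of genes).
#' @param kv_mirna miRNA cardinality bound per factor (default 10, capped at
#'   the number of miRNAs).
#' @param z_threshold z-score member filter passed to [extract_module()]
#'   (default 0: keep every nonzero member).
#' @param restarts,seed,control Passed to the deflation engine.
#' @return A `module_set`; each record's `stats` holds `adpcc_mean`,
#'   `n_gene_edges`, and `interaction_score`.
#' @export
diff_coexpr_modules <- function(dc, gene_net, n_modules = 10L, sigma = 0,
                                target_nnz_gene = 100L, kv_mirna = 10L,
                                z_threshold = 0, restarts = 5L, seed = NULL,
                                control = snsvd_control()) {
  stopifnot(is(dc, "diff_correlation"))
  X <- dc$X
  lap <- network_laplacian(gene_net)
  if (nrow(lap$L) != nrow(X)) stop("network does not match gene rows of X")
  target_nnz_gene <- min(target_nnz_gene, nrow(X))
  kv_mirna <- min(kv_mirna, ncol(X))
  res <- .deflate(X, lap, lambda = 0, sigma = sigma, kv = kv_mirna,
                  n_factors = n_modules, n_restarts = restarts,
                  target_nnz = target_nnz_gene, control = control,
                  seed = seed)
  mods <- lapply(seq_along(res$factors), function(k) {
    f <- res$factors[[k]]
    m <- extract_module(f$u, f$v, threshold = z_threshold,
                        gene_ids = rownames(X), sample_ids = colnames(X),
                        index = k, d = f$d)
    enr <- interaction_enrichment(gene_net, m)
    sub <- X[m$genes, m$samples, drop = FALSE]
    m$stats <- list(adpcc_mean = mean(abs(sub)),
                    n_gene_edges = enr$n_edges,
                    interaction_score = enr$score)
    m
  })
  structure(mods, class = "module_set")
}

#' Permutation test for a module's average adPCC
#'
#' Tests whether a module's mean absolute differential correlation exceeds
#' chance: the statistic is the mean of `|X|` over the module's
#' genes-by-miRNAs submatrix, the null draws `n_perm` same-shape submatrices
#' with uniformly resampled random row and column index sets, and the
#' p-value is `(1 + #[null >= observed]) / (1 + n_perm)`.
#'
#' @param dc A [differential_matrix()] result.
#' @param module A `module_record` over `dc`'s genes and miRNAs.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @return List with `p`, `statistic`, and the `null` statistics.
#' @export
adpcc_test <- function(dc, module, n_perm = 199L, seed = NULL) {
  stopifnot(is(dc, "diff_correlation"))
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  absX <- abs(dc$X)
  gi <- match(module$genes, rownames(absX))
  mi <- match(module$samples, colnames(absX))
  if (anyNA(gi) || anyNA(mi)) stop("module members missing from X")
  stat <- mean(absX[gi, mi, drop = FALSE])
  null <- vapply(seq_len(n_perm), function(b) {
    rg <- sample.int(nrow(absX), length(gi))
    rm_ <- sample.int(ncol(absX), length(mi))
    mean(absX[rg, rm_, drop = FALSE])
  }, numeric(1))
  list(p = (1 + sum(null >= stat)) / (1 + n_perm),
       statistic = stat, null = null)
}

#' Simulate matched two-condition expression with a planted
#' differential-correlation block
#'
#' Generates a synthetic matched expression set for the differential
#' co-expression pipeline: in condition 1 a latent factor drives a block of
#' genes and a block of miRNAs (pairwise gene-miRNA correlation about
#' `rho`), while condition 2 is independent noise, so the planted block has
#' differential correlation about `rho`. The prior gene network connects
#' block genes with probability `p_in` and all other pairs with `p_out`.
#'
#' @param n_genes,n_mirnas Feature counts.
#' @param n_samples1,n_samples2 Samples per condition.
#' @param gene_block,mirna_block Sizes of the planted blocks (leading
#'   features).
#' @param rho Within-block correlation in condition 1 (default 0.8).
#' @param p_in,p_out Network edge probabilities inside / outside the planted
#'   gene block.
#' @param seed Integer seed.
#' @return List with matrices `A1`, `A2` (genes) and `B1`, `B2` (miRNAs),
#'   the gene `network`, and the planted `gene_block` / `mirna_block` IDs.
#' @export
simulate_diffcoexpr_data <- function(n_genes = 300L, n_mirnas = 40L,
                                     n_samples1 = 100L, n_samples2 = 100L,
                                     gene_block = 20L, mirna_block = 5L,
                                     rho = 0.8, p_in = 0.5, p_out = 0.05,
                                     seed = 1L) {
  set.seed(seed)
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  mirna_ids <- sprintf("mir%03d", seq_len(n_mirnas))
  s1 <- sprintf("t%03d", seq_len(n_samples1))
  s2 <- sprintf("n%03d", seq_len(n_samples2))
  latent <- rnorm(n_samples1)
  block_row <- function(in_block) {
    if (in_block) sqrt(rho) * latent + sqrt(1 - rho) * rnorm(n_samples1)
    else rnorm(n_samples1)
  }
  A1 <- t(vapply(seq_len(n_genes) <= gene_block, block_row,
                 numeric(n_samples1)))
  B1 <- t(vapply(seq_len(n_mirnas) <= mirna_block, block_row,
                 numeric(n_samples1)))
  A2 <- matrix(rnorm(n_genes * n_samples2), n_genes)
  B2 <- matrix(rnorm(n_mirnas * n_samples2), n_mirnas)
  dimnames(A1) <- list(gene_ids, s1)
  dimnames(B1) <- list(mirna_ids, s1)
  dimnames(A2) <- list(gene_ids, s2)
  dimnames(B2) <- list(mirna_ids, s2)
  pairs <- which(upper.tri(matrix(TRUE, n_genes, n_genes)), arr.ind = TRUE)
  prob <- ifelse(pairs[, 1L] <= gene_block & pairs[, 2L] <= gene_block,
                 p_in, p_out)
  sel <- runif(nrow(pairs)) < prob
  net <- gene_network(cbind(gene_ids[pairs[sel, 1L]],
                            gene_ids[pairs[sel, 2L]]),
                      nodes = gene_ids)
  list(A1 = A1, A2 = A2, B1 = B1, B2 = B2, network = net,
       gene_block = gene_ids[seq_len(gene_block)],
       mirna_block = mirna_ids[seq_len(mirna_block)])
}
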