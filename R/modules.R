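# z-score member filter over the nonzero entries of one loading vector:
# z_i = ||w_i| - mu| / s with mu, s the mean and sd of the nonzero
# magnitudes; members with z > threshold are kept. Degenerate cases: fewer
# than two nonzeros are kept verbatim (warning); zero spread keeps all.
.zscore_select <- function(w, threshold) {
  nz <- which(w != 0)
  if (length(nz) < 2L) {
    warning("fewer than 2 nonzero loadings; members kept verbatim")
    return(nz)
  }
  a <- abs(w[nz])
  s <- sd(a)
  if (is.na(s) || s == 0) return(nz)
  z <- abs(a - mean(a)) / s
  nz[z > threshold]
}

#' Extract a gene/sample module from one factor pair
#'
#' Turns the nonzero patterns of a sparse singular pair `(u, v)` into a
#' module by the absolute z-score filter: over the nonzero loadings of each
#' vector, magnitudes further than `threshold` standard deviations from the
#' mean magnitude mark their gene (or sample) as a module member. A zero
#' spread of magnitudes keeps every nonzero member.
#'
#' @param u,v Numeric loading vectors (typically from a [snsvd()] factor).
#' @param threshold Nonnegative z-score cut (default 1).
#' @param gene_ids,sample_ids Identifiers; default to `names(u)`/`names(v)`.
#' @param index Module index stored in the record.
#' @param d Singular value stored in the record.
#' @return A `module_record`: list with `module_index`, `genes`, `samples`,
#'   member loading `weights`, `d`, and an initially empty `stats` list.
#' @export
extract_module <- function(u, v, threshold = 1, gene_ids = names(u),
                           sample_ids = names(v), index = 1L, d = NA_real_) {
  stopifnot(threshold >= 0)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_along(u))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(v))
  gi <- .zscore_select(u, threshold)
  si <- .zscore_select(v, threshold)
  structure(list(module_index = as.integer(index),
                 genes = gene_ids[gi], samples = sample_ids[si],
                 weights = c(setNames(u[gi], gene_ids[gi]),
                             setNames(v[si], sample_ids[si])),
                 d = d, stats = list()),
            class = "module_record")
}

#' Extract all modules from a fitted factorization
#'
#' @param fit A fitted [snsvd()] object.
#' @param threshold z-score cut passed to [extract_module()].
#' @return A `module_set`: list of `module_record`s.
#' @export
extract_modules <- function(fit, threshold = 1) {
  stopifnot(is(fit, "snsvd"))
  mods <- lapply(seq_along(fit$d), function(k) {
    extract_module(fit$u[, k], fit$v[, k], threshold = threshold,
                   index = k, d = fit$d[k])
  })
  structure(mods, class = "module_set")
}

#' @export
print.module_record <- function(x, ...) {
  cat(sprintf("Module %d: %d genes, %d samples (d = %.4g)\n",
              x$module_index, length(x$genes), length(x$samples), x$d))
  if (length(x$stats)) {
    cat("  stats:", paste(names(x$stats),
                          signif(unlist(x$stats), 4),
                          sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.module_set <- function(x, ...) {
  cat("Module set with", length(x), "module(s)\n")
  for (m in x) print(m)
  invisible(x)
}

#' Modularity score of a module
#'
#' Mean absolute pairwise Pearson correlation of the module's genes across
#' the module's samples (self-correlations forced to zero and excluded):
#' `Modularity = sum_ij |w_ij| / (p_k (p_k - 1))`. Lies in `[0, 1]`; high
#' values mean the module's genes are strongly co-expressed on its samples.
#'
#' @param expr Numeric genes-by-samples expression matrix containing the
#'   module's genes and samples.
#' @param module A `module_record` (needs >= 2 genes and >= 2 samples).
#' @return Scalar modularity in `[0, 1]`.
#' @export
module_modularity <- function(expr, module) {
  genes <- module$genes
  samples <- module$samples
  if (length(genes) < 2L || length(samples) < 2L) {
    stop("modularity needs at least 2 genes and 2 samples")
  }
  sub <- expr[genes, samples, drop = FALSE]
  w <- suppressWarnings(cor(t(sub)))
  if (anyNA(w)) {
    warning("zero-variance gene(s) in module; correlations set to 0")
    w[is.na(w)] <- 0
  }
  diag(w) <- 0
  pk <- length(genes)
  sum(abs(w)) / (pk * (pk - 1))
}

#' Significance of a module's modularity
#'
#' Compares the module's modularity against `n_random` size-matched random
#' gene sets (drawn without replacement from all genes of `expr`, scored on
#' the module's samples) with a one-sided Wilcoxon signed-rank test on the
#' differences `module_score - random_score_i`.
#'
#' @param expr Numeric genes-by-samples expression matrix.
#' @param module A `module_record`.
#' @param n_random Number of random gene sets (>= 20).
#' @param seed Optional integer seed.
#' @return One-sided p-value that the module outscores random gene sets.
#' @export
modularity_pvalue <- function(expr, module, n_random = 100L, seed = NULL) {
  if (n_random < 20L) stop("n_random must be at least 20")
  if (!is.null(seed)) set.seed(seed)
  score <- module_modularity(expr, module)
  k <- length(module$genes)
  random_scores <- vapply(seq_len(n_random), function(i) {
    rnd <- module
    rnd$genes <- sample(rownames(expr), k)
    module_modularity(expr, rnd)
  }, numeric(1))
  suppressWarnings(
    wilcox.test(score - random_scores, alternative = "greater")$p.value)
}

# -log10 transform mapping a p-value to an enrichment score; the
# significance convention puts the cut at score > 1.3 (p < 0.05)
enrichment_score <- function(p) -log10(p)

#' Gene-gene interaction enrichment of a module
#'
#' Right-tailed hypergeometric test of whether the module's genes induce
#' more network edges than expected by chance: with `N = choose(n, 2)`
#' potential edges over the `n` network genes, `m` actual edges, and
#' `N_i = choose(n_i, 2)` potential edges over the module's `n_i` genes, the
#' p-value is `P(Y >= m_i)` for `Y ~ Hypergeometric(N, m, N_i)` where `m_i`
#' is the induced edge count. The enrichment score is `-log10(p)`; scores
#' above 1.3 (p < 0.05) flag significantly inter-connected modules.
#'
#' @param net A [gene_network()].
#' @param module A `module_record` (or character vector of gene IDs).
#' @return List with `p`, `score`, `n_genes`, `n_edges` (induced), and
#'   `significant`.
#' @export
interaction_enrichment <- function(net, module) {
  genes <- if (is.character(module)) module else module$genes
  genes <- intersect(genes, net$nodes)
  n <- length(net$nodes)
  m <- nrow(net$edges)
  n_i <- length(genes)
  if (n_i < 2L) {
    return(list(p = 1, score = 0, n_genes = n_i, n_edges = 0L,
                significant = FALSE))
  }
  sub <- net$adjacency[genes, genes]
  m_i <- as.integer(Matrix::nnzero(sub) / 2)
  N <- choose(n, 2)
  N_i <- choose(n_i, 2)
  p <- phyper(m_i - 1, m, N - m, N_i, lower.tail = FALSE)
  s <- enrichment_score(p)
  list(p = p, score = s, n_genes = n_i, n_edges = m_i,
       significant = s > 1.3)
}

#' Overlap significance between two modules
#'
#' Right-tailed hypergeometric tests on the gene-set and sample-set overlaps
#' of two modules drawn from common universes; the pair is flagged as
#' significantly overlapping when both p-values fall below 0.05.
#'
#' @param mod_a,mod_b `module_record`s.
#' @param n_genes Size of the gene universe.
#' @param n_samples Size of the sample universe.
#' @return List with `p_genes`, `p_samples`, `significant`.
#' @export
module_overlap <- function(mod_a, mod_b, n_genes, n_samples) {
  right_tail <- function(overlap, size_a, size_b, universe) {
    if (size_a == 0L || size_b == 0L) return(1)
    phyper(overlap - 1, size_a, universe - size_a, size_b,
           lower.tail = FALSE)
  }
  pg <- right_tail(length(intersect(mod_a$genes, mod_b$genes)),
                   length(mod_a$genes), length(mod_b$genes), n_genes)
  ps <- right_tail(length(intersect(mod_a$samples, mod_b$samples)),
                   length(mod_a$samples), length(mod_b$samples), n_samples)
  list(p_genes = pg, p_samples = ps,
       significant = pg < 0.05 && ps < 0.05)
}

#' Pairwise overlap census of a module set
#'
#' Runs [module_overlap()] on every unordered pair of modules
#' (`K * (K - 1) / 2` comparisons for `K` modules).
#'
#' @param modules A `module_set`.
#' @param n_genes,n_samples Universe sizes, as in [module_overlap()].
#' @return Data frame with one row per module pair: indices, both p-values,
#'   and the significance flag.
#' @export
module_overlap_table <- function(modules, n_genes, n_samples) {
  K <- length(modules)
  pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1L]
    b <- pairs[r, 2L]
    ov <- module_overlap(modules[[a]], modules[[b]], n_genes, n_samples)
    data.frame(module_a = a, module_b = b, p_genes = ov$p_genes,
               p_samples = ov$p_samples, significant = ov$significant)
  })
  do.call(rbind, out)
}

#' Write a module set to disk
#'
#' Writes one TSV row per (module, member) with columns `module_index`,
#' `member_id`, `member_type` (`gene`/`sample`) and `weight`, plus a JSON
#' sidecar (same path with extension `.json`) holding each module's singular
#' value and statistics. [read_modules()] restores the set losslessly.
#'
#' @param modules A nonempty `module_set`.
#' @param path Output TSV path.
#' @return Invisibly, the TSV path.
#' @export
write_modules <- function(modules, path) {
  if (!length(modules)) stop("refusing to write an empty module set")
  rows <- lapply(modules, function(m) {
    ids <- c(m$genes, m$samples)
    data.frame(module_index = m$module_index,
               member_id = ids,
               member_type = rep(c("gene", "sample"),
                                 c(length(m$genes), length(m$samples))),
               weight = as.numeric(m$weights[ids]))
  })
  tab <- do.call(rbind, rows)
  tab$weight <- sprintf("%.17g", tab$weight)  # full-precision round trip
  ok <- tryCatch({
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write modules to ", path, ": ",
                        conditionMessage(ok))
  side <- lapply(modules, function(m) {
    list(module_index = m$module_index, d = m$d, stats = m$stats)
  })
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.sidecar_path <- function(path) {
  sub("\\.[^.]*$", "", path) |> paste0(".json")
}

#' Read a module set written by [write_modules()]
#'
#' @param path TSV path given to [write_modules()].
#' @return A `module_set`.
#' @export
read_modules <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = c("integer", "character", "character",
                                   "numeric"))
  side <- jsonlite::read_json(.sidecar_path(path), simplifyVector = FALSE)
  meta <- setNames(side, vapply(side, function(s) as.character(s$module_index),
                                character(1)))
  mods <- lapply(split(tab, tab$module_index), function(sub) {
    idx <- sub$module_index[1L]
    g <- sub$member_id[sub$member_type == "gene"]
    s <- sub$member_id[sub$member_type == "sample"]
    mi <- meta[[as.character(idx)]]
    structure(list(module_index = idx, genes = g, samples = s,
                   weights = setNames(sub$weight, sub$member_id),
                   d = if (is.null(mi$d)) NA_real_ else as.numeric(mi$d),
                   stats = if (is.null(mi$stats)) list()
                           else lapply(mi$stats, function(x) x)),
              class = "module_record")
  })
  mods <- mods[order(vapply(mods, `[[`, integer(1), "module_index"))]
  names(mods) <- NULL
  structure(mods, class = "module_set")
}
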