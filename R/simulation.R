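#' Simulate a rank-one signal with a planted-partition prior network
#'
#' Generates the benchmark design used throughout the package's simulation
#' study: binary singular vectors `u` (length `p`) and `v` (length `n`) whose
#' first `support` entries are 1, an observation matrix
#' `X = u v' + gamma * E` with `E` i.i.d. standard normal, and an undirected
#' prior network over the rows of `X` in which pairs of true-support genes
#' are connected with probability `p11` and all other pairs with probability
#' `p12`. Fully reproducible from `(seed, replicate)`.
#'
#' @param p Number of genes (default 200).
#' @param n Number of samples (default 100).
#' @param support Number of leading nonzero entries in `u` and `v`
#'   (default 50).
#' @param gamma Noise scale (default 0.04, the midpoint of the benchmark
#'   grid `0.02..0.06`).
#' @param p11 Within-support edge probability (default 0.3).
#' @param p12 Edge probability for all other pairs (default 0.1).
#' @param seed Master seed.
#' @param replicate Replicate index; distinct replicates get independent
#'   noise and networks under one master seed.
#' @return List of class `snsvd_sim`: `X` (with gene/sample dimnames),
#'   `network` (a [gene_network()]), and the true support index vectors
#'   `u_support`, `v_support`.
#' @export
simulate_snsvd_data <- function(p = 200L, n = 100L, support = 50L,
                                gamma = 0.04, p11 = 0.3, p12 = 0.1,
                                seed = 1L, replicate = 1L) {
  stopifnot(support <= min(p, n), p11 >= 0, p11 <= 1, p12 >= 0, p12 <= 1,
            gamma >= 0)
  set.seed(.sub_seed(seed, replicate))
  gene_ids <- sprintf("g%0*d", nchar(p), seq_len(p))
  sample_ids <- sprintf("s%0*d", nchar(n), seq_len(n))
  u <- as.numeric(seq_len(p) <= support)
  v <- as.numeric(seq_len(n) <= support)
  X <- tcrossprod(u, v) + gamma * matrix(rnorm(p * n), p, n)
  dimnames(X) <- list(gene_ids, sample_ids)
  pairs <- which(upper.tri(matrix(TRUE, p, p)), arr.ind = TRUE)
  prob <- ifelse(pairs[, 1L] <= support & pairs[, 2L] <= support, p11, p12)
  sel <- runif(nrow(pairs)) < prob
  net <- gene_network(cbind(gene_ids[pairs[sel, 1L]],
                            gene_ids[pairs[sel, 2L]]),
                      nodes = gene_ids)
  structure(list(X = X, network = net,
                 u_support = which(u != 0), v_support = which(v != 0)),
            class = "snsvd_sim")
}

#' Support-recovery metrics
#'
#' Scores the nonzero pattern of an estimated singular vector against the
#' true support: sensitivity `TP / (TP + FN)` (fraction of true nonzero
#' entries recovered), specificity `TN / (TN + FP)` (fraction of true zero
#' entries kept zero), and accuracy `(TP + TN) / length`.
#'
#' @param u_est,v_est Estimated vectors (only the nonzero pattern is used).
#' @param u_support,v_support Integer indices of the true nonzero entries.
#' @return Data frame with rows `u` and `v` and columns `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
score_recovery <- function(u_est, v_est, u_support, v_support) {
  one <- function(est, truth) {
    hit <- which(est != 0)
    tp <- length(intersect(hit, truth))
    fp <- length(setdiff(hit, truth))
    fn <- length(setdiff(truth, hit))
    tn <- length(est) - tp - fp - fn
    c(sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      accuracy = (tp + tn) / length(est))
  }
  out <- rbind(u = one(u_est, u_support), v = one(v_est, v_support))
  data.frame(vector = rownames(out), out, row.names = NULL)
}

# hard projection onto the k largest magnitudes (ties: smallest index),
# renormalized to unit L2 norm
.force_support <- function(u, k) {
  if (sum(u != 0) == k) return(u)
  keep <- order(-abs(u), seq_along(u))[seq_len(k)]
  out <- numeric(length(u))
  out[keep] <- u[keep]
  names(out) <- names(u)
  .normalize(out)
}

#' Simulation benchmark of the network-regularized and plain sparse SVD
#'
#' Replicates the simulation benchmark: for each noise level `gamma` it
#' generates `n_reps` instances via [simulate_snsvd_data()] and fits each
#' with (a) the network-regularized solver (`snsvd`: the given `sigma`,
#' `lambda` tuned per replicate so `u` carries exactly `support` nonzeros,
#' `kv = support`) and (b) the plain L0 sparse SVD baseline (`l0svd`:
#' `sigma = 0`, hard top-`support` projection on both vectors). Both methods
#' see the same instance and the same random initialization (paired design).
#'
#' @param gammas Noise levels to sweep (default `seq(0.02, 0.06, by = 0.005)`).
#' @param methods Subset of `c("snsvd", "l0svd")`.
#' @param n_reps Replicates per noise level (default 50).
#' @param sigma Network weight for the `snsvd` method (default 0.5, the
#'   value selected by 5-fold cross-validation on this design).
#' @param p,n,support,p11,p12 Generator parameters, see
#'   [simulate_snsvd_data()].
#' @param seed Master seed.
#' @param control A [snsvd_control()] list.
#' @param summarize If `TRUE` (default) aggregate over replicates; if
#'   `FALSE` return one row per (gamma, method, replicate, vector), useful
#'   for paired method comparisons.
#' @return Data frame with one row per (gamma, method, vector) holding mean
#'   sensitivity, specificity and accuracy over replicates (or the
#'   per-replicate table when `summarize = FALSE`).
#' @export
run_benchmark <- function(gammas = seq(0.02, 0.06, by = 0.005),
                          methods = c("snsvd", "l0svd"), n_reps = 50L,
                          sigma = 0.5, p = 200L, n = 100L, support = 50L,
                          p11 = 0.3, p12 = 0.1, seed = 1L,
                          control = snsvd_control(), summarize = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  cells <- list()
  for (gi in seq_along(gammas)) {
    gmm <- gammas[gi]
    for (r in seq_len(n_reps)) {
      sim <- simulate_snsvd_data(p = p, n = n, support = support,
                                 gamma = gmm, p11 = p11, p12 = p12,
                                 seed = seed, replicate = gi * 1000L + r)
      lap <- network_laplacian(sim$network)
      set.seed(.sub_seed(seed, 500000L + gi * 1000L + r))
      u0 <- rnorm(p)
      v0 <- rnorm(n)
      for (m in methods) {
        fit <- if (m == "snsvd") {
          lam <- suppressWarnings(
            as.numeric(tune_lambda(sim$X, lap, sigma = sigma, kv = support,
                                   target_nnz = support, u0 = u0, v0 = v0,
                                   control = control)))
          f <- snsvd_rank1(sim$X, lap, lambda = lam, sigma = sigma,
                           kv = support, u0 = u0, v0 = v0, control = control)
          # comparability contract: every method reports exactly `support`
          # nonzeros; project onto the top-`support` magnitudes when lambda
          # tuning cannot land on the target exactly
          f$u <- .force_support(f$u, support)
          f
        } else {
          snsvd_rank1(sim$X, lambda = 0, sigma = 0, kv = support,
                      u0 = u0, v0 = v0, ku = support, control = control)
        }
        sc <- score_recovery(fit$u, fit$v, sim$u_support, sim$v_support)
        cells[[length(cells) + 1L]] <- data.frame(
          gamma = gmm, method = m, replicate = r, vector = sc$vector,
          sensitivity = sc$sensitivity, specificity = sc$specificity,
          accuracy = sc$accuracy)
      }
    }
  }
  long <- do.call(rbind, cells)
  rownames(long) <- NULL
  if (!summarize) return(long)
  agg <- stats::aggregate(
    long[, c("sensitivity", "specificity", "accuracy")],
    by = long[, c("gamma", "method", "vector")], FUN = mean)
  agg <- agg[order(agg$gamma, agg$method, agg$vector), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
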