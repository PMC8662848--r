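#' Fit a sparse network-regularized SVD
#'
#' Extracts `k` sparse singular factors of a genes-by-samples expression
#' matrix, regularizing the gene-side vectors toward sparsity (L1 weight
#' `lambda`, or a target support size `nnz_u`) and toward smoothness over a
#' prior gene interaction network (weight `sigma` on the normalized-Laplacian
#' quadratic form), with an L0 cardinality bound `kv` on the sample-side
#' vectors. Factors beyond the first are obtained by deflation
#' (`X <- X - d u v'`); each factor is fitted from `restarts` independent
#' standard-normal initializations and the run with the lowest final
#' Lagrangian value is kept.
#'
#' @param X Numeric genes-by-samples matrix (e.g. from [read_expression()]);
#'   must be complete (impute first, see [knn_impute()]).
#' @param network Optional [gene_network()] over the rows of `X`; required
#'   when `sigma > 0`. A precomputed [network_laplacian()] is also accepted.
#' @param k Number of factors to extract.
#' @param lambda Nonnegative L1 weight on the gene-side vectors. Ignored
#'   when `nnz_u` is given.
#' @param sigma Nonnegative network weight.
#' @param kv Cardinality bound on each sample-side vector.
#' @param nnz_u Optional target number of nonzero genes per factor; when
#'   given, `lambda` is re-tuned for every factor via [tune_lambda()]
#'   (deflation changes the residual's scale).
#' @param restarts Random restarts per factor (default 5).
#' @param seed Optional integer seed for the restart initializations.
#' @param control A [snsvd_control()] list.
#' @return An object of class `snsvd`: list with loading matrices `u`
#'   (`p x k`) and `v` (`n x k`), singular values `d`, per-factor fit
#'   details in `factors`, the deflation `residual_norm`, and the matched
#'   `call`. Supports `print()`, `summary()`, `coef()`, `fitted()`,
#'   `residuals()` and `plot()`.
#' @examples
#' set.seed(1)
#' sim <- simulate_snsvd_data(p = 60, n = 30, support = 15, gamma = 0.05)
#' fit <- snsvd(sim$X, sim$network, k = 1, sigma = 0.5, kv = 15,
#'              nnz_u = 15, seed = 1)
#' fit
#' @export
snsvd <- function(X, network = NULL, k = 1L, lambda = 0, sigma = 0,
                  kv = ncol(X), nnz_u = NULL, restarts = 5L, seed = NULL,
                  control = snsvd_control()) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values; impute before fitting")
  stopifnot(k >= 1L, restarts >= 1L)
  lap <- NULL
  if (!is.null(network)) {
    lap <- if (is(network, "snsvd_laplacian")) network
           else network_laplacian(network)
    if (nrow(lap$L) != nrow(X)) {
      stop("network size (", nrow(lap$L), ") does not match nrow(X) (",
           nrow(X), ")")
    }
  }
  if (sigma > 0 && is.null(lap)) stop("sigma > 0 requires a network")
  res <- .deflate(X, lap, lambda = lambda, sigma = sigma, kv = kv,
                  n_factors = k, n_restarts = restarts,
                  target_nnz = nnz_u, control = control, seed = seed)
  factors <- res$factors
  if (!length(factors)) stop("no non-degenerate factor could be extracted")
  U <- do.call(cbind, lapply(factors, `[[`, "u"))
  V <- do.call(cbind, lapply(factors, `[[`, "v"))
  colnames(U) <- colnames(V) <- paste0("factor", seq_along(factors))
  structure(list(u = U, v = V,
                 d = vapply(factors, `[[`, numeric(1), "d"),
                 factors = factors,
                 residual_norm = res$residual_norm,
                 X = X, lambda = lambda, sigma = sigma, kv = kv,
                 nnz_u = nnz_u, call = match.call()),
            class = "snsvd")
}

#' @export
print.snsvd <- function(x, ...) {
  cat("Sparse network-regularized SVD\n")
  cat("  data:", nrow(x$X), "genes x", ncol(x$X), "samples\n")
  cat("  factors:", length(x$d),
      sprintf("| sigma = %g | kv = %d\n", x$sigma, x$kv))
  cat("  singular values:", paste(signif(x$d, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.snsvd <- function(object, ...) {
  tab <- data.frame(
    factor = seq_along(object$d),
    d = object$d,
    nnz_u = colSums(object$u != 0),
    nnz_v = colSums(object$v != 0),
    iterations = vapply(object$factors, `[[`, integer(1), "n_iters"),
    converged = vapply(object$factors, `[[`, logical(1), "converged"))
  structure(list(table = tab, residual_norm = object$residual_norm,
                 total_norm = sqrt(sum(object$X^2))),
            class = "summary.snsvd")
}

#' @export
print.summary.snsvd <- function(x, ...) {
  cat("Sparse network-regularized SVD: factor summary\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("residual Frobenius norm: %.4g (%.1f%% of total)\n",
              x$residual_norm, 100 * x$residual_norm / x$total_norm))
  invisible(x)
}

#' Extract loading matrices from a fitted factorization
#'
#' @param object A fitted [snsvd()] object.
#' @param side `"genes"` for the gene-side loadings `u`, `"samples"` for the
#'   sample-side loadings `v`, `"d"` for the singular values.
#' @param ... Unused.
#' @export
coef.snsvd <- function(object, side = c("genes", "samples", "d"), ...) {
  switch(match.arg(side),
         genes = object$u,
         samples = object$v,
         d = object$d)
}

#' @export
fitted.snsvd <- function(object, ...) {
  object$u %*% (object$d * t(object$v))
}

#' @export
residuals.snsvd <- function(object, ...) {
  object$X - fitted(object)
}

#' Diagnostic plots for a fitted factorization
#'
#' `type = "objective"` draws the per-factor Lagrangian traces across outer
#' iterations (each should be non-increasing); `type = "scree"` draws the
#' singular values.
#'
#' @param x A fitted [snsvd()] object.
#' @param type Plot flavour.
#' @param ... Passed to the underlying plot call.
#' @export
plot.snsvd <- function(x, type = c("objective", "scree"), ...) {
  type <- match.arg(type)
  if (type == "scree") {
    plot(seq_along(x$d), x$d, type = "b", xlab = "factor",
         ylab = "singular value", ...)
  } else {
    traces <- lapply(x$factors, `[[`, "objective")
    len <- max(lengths(traces))
    mat <- vapply(traces, function(tr) c(tr, rep(NA, len - length(tr))),
                  numeric(len))
    graphics::matplot(mat, type = "l", lty = 1, xlab = "outer iteration",
                      ylab = "Lagrangian objective", ...)
  }
  invisible(x)
}
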