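#' Soft-thresholding operator
#'
#' The proximal map of the L1 norm, `S(a, lambda) = sign(a) * (|a| - lambda)_+`.
#' Vectorized over `a`.
#'
#' @param a Numeric vector.
#' @param lambda Nonnegative threshold.
#' @return `sign(a) * pmax(abs(a) - lambda, 0)`.
#' @examples
#' soft_threshold(c(3, -0.5, 2), 1)
#' @export
soft_threshold <- function(a, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  sign(a) * pmax(abs(a) - lambda, 0)
}

#' Solver control parameters
#'
#' @param max_iter Maximum alternating (outer) iterations.
#' @param tol Outer convergence tolerance on
#'   `max(||u_t - u_{t-1}||_2, ||v_t - v_{t-1}||_2)`.
#' @param max_sweeps Maximum coordinate-descent sweeps per u-update.
#' @param inner_tol Sup-norm tolerance on the normalized u between sweeps.
#' @return A list of class `snsvd_control`.
#' @export
snsvd_control <- function(max_iter = 200L, tol = 1e-6,
                          max_sweeps = 50L, inner_tol = 1e-6) {
  stopifnot(max_iter >= 1L, tol > 0, max_sweeps >= 1L, inner_tol > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 max_sweeps = as.integer(max_sweeps), inner_tol = inner_tol),
            class = "snsvd_control")
}

# CSC pieces of W for the C++ kernel; empty slots when no network term
.w_slots <- function(lap, sigma, p) {
  if (is.null(lap) || sigma == 0) {
    return(list(p = integer(0), i = integer(0), x = numeric(0)))
  }
  W <- as(lap$W, "CsparseMatrix")
  if (nrow(W) != p) stop("network size does not match number of genes")
  list(p = W@p, i = W@i, x = W@x)
}

#' Network-smoothed u-update
#'
#' One gene-side update of the alternating solver: with `z = X v` fixed, runs
#' Gauss-Seidel coordinate sweeps of
#' `u_j <- S(z_j + sigma * W_j u, lambda)` (newest values used within a
#' sweep), renormalizing to unit L2 norm after each sweep, until the
#' normalized vector stabilizes. If every coordinate thresholds to zero the
#' zero vector is returned with attribute `degenerate = TRUE`.
#'
#' @param X Numeric genes-by-samples matrix.
#' @param v Unit-norm sample-side vector.
#' @param lap An [network_laplacian()] result, or `NULL` for no network term.
#' @param lambda Nonnegative L1 weight.
#' @param sigma Nonnegative network weight.
#' @param u_init Warm-start vector of length `nrow(X)`.
#' @param max_sweeps,tol Inner iteration controls.
#' @return Unit-norm numeric vector (or zero vector flagged degenerate),
#'   with attribute `sweeps`.
#' @export
snsvd_update_u <- function(X, v, lap = NULL, lambda = 0, sigma = 0,
                           u_init = NULL, max_sweeps = 50L, tol = 1e-6) {
  p <- nrow(X)
  if (length(v) != ncol(X)) stop("length of v does not match ncol(X)")
  z <- drop(X %*% v)
  if (is.null(u_init)) u_init <- rep(1 / sqrt(p), p)
  w <- .w_slots(lap, sigma, p)
  res <- cd_update_u(z, w$p, w$i, w$x, lambda, sigma,
                     as.numeric(u_init), as.integer(max_sweeps), tol)
  u <- res$u
  if (all(u == 0)) {
    attr(u, "degenerate") <- TRUE
  }
  attr(u, "sweeps") <- res$sweeps
  u
}

#' L0-projected v-update
#'
#' With `z_v = X' u` fixed, keeps the `kv` entries of `z_v` with largest
#' absolute value, zeroes the rest, and normalizes to unit L2 norm. Ties at
#' the `kv`-th order statistic are broken in favour of the smallest index.
#'
#' @param X Numeric genes-by-samples matrix.
#' @param u Unit-norm gene-side vector.
#' @param kv Cardinality bound, `1 <= kv <= ncol(X)`.
#' @return Unit-norm vector with at most `kv` nonzeros; the zero vector with
#'   attribute `degenerate = TRUE` when `X' u = 0`.
#' @export
snsvd_update_v <- function(X, u, kv) {
  n <- ncol(X)
  if (length(u) != nrow(X)) stop("length of u does not match nrow(X)")
  if (kv < 1L || kv > n) stop("kv must lie in [1, ncol(X)]")
  zv <- drop(crossprod(X, u))
  if (all(zv == 0)) {
    v <- numeric(n)
    attr(v, "degenerate") <- TRUE
    return(v)
  }
  keep <- order(-abs(zv), seq_along(zv))[seq_len(kv)]
  v <- numeric(n)
  v[keep] <- zv[keep]
  v / .l2(v)
}

# u-subproblem Lagrangian h(u) = -u'z + lambda*||u||_1 + (sigma/2) u'Lu,
# used for the monotone acceptance safeguard and restart comparison
.u_objective <- function(u, z, lap, lambda, sigma) {
  val <- -sum(u * z) + lambda * sum(abs(u))
  if (!is.null(lap) && sigma > 0) {
    val <- val + 0.5 * sigma * as.numeric(Matrix::crossprod(u, lap$L %*% u))
  }
  val
}

.zero_factor <- function(p, n, gene_ids = NULL, sample_ids = NULL) {
  structure(list(u = setNames(numeric(p), gene_ids),
                 v = setNames(numeric(n), sample_ids),
                 d = 0, n_iters = 0L, objective = numeric(0),
                 converged = FALSE, degenerate = TRUE),
            class = "snsvd_factor")
}

#' Rank-one sparse network-regularized SVD
#'
#' Fits a single sparse singular triplet `(u, v, d)` of `X` by alternating a
#' network-smoothed soft-threshold update of `u` ([snsvd_update_u()]) with an
#' L0 projection of `v` ([snsvd_update_v()]). The recorded objective is the
#' Lagrangian
#' `F(u, v) = -u' X v + lambda * ||u||_1 + (sigma/2) * u' L u`
#' over unit-norm `u`, `v` with `||v||_0 <= kv`; a monotone safeguard accepts
#' a u-update only if it does not increase its subproblem objective, so the
#' trace is non-increasing by construction. Setting `ku` replaces the
#' penalized u-update by a hard top-`ku` projection (the plain L0 sparse SVD
#' baseline, equivalent to `sigma = 0`).
#'
#' @param X Numeric genes-by-samples matrix.
#' @param lap Optional [network_laplacian()]; required when `sigma > 0`.
#' @param lambda Nonnegative L1 weight on `u`.
#' @param sigma Nonnegative network weight on `u`.
#' @param kv Cardinality bound on `v` (default `ncol(X)`: no truncation).
#' @param u0,v0 Optional initial vectors; standard-normal draws by default.
#' @param ku Optional cardinality bound on `u` for the L0-baseline update
#'   (ignores `lambda`/`sigma`).
#' @param control A [snsvd_control()] list.
#' @return An object of class `snsvd_factor`: list with unit vectors `u`,
#'   `v`, singular value `d = u' X v >= 0`, iteration count `n_iters`,
#'   `objective` trace, and flags `converged` / `degenerate`.
#' @examples
#' X <- tcrossprod(c(2, 0, 0), c(1, 0))  # rank-one, no noise
#' f <- snsvd_rank1(X, kv = 1)
#' f$d
#' @export
snsvd_rank1 <- function(X, lap = NULL, lambda = 0, sigma = 0, kv = ncol(X),
                        u0 = NULL, v0 = NULL, ku = NULL,
                        control = snsvd_control()) {
  X <- as.matrix(X)
  p <- nrow(X)
  n <- ncol(X)
  stopifnot(lambda >= 0, sigma >= 0, kv >= 1L, kv <= n)
  if (sigma > 0 && is.null(lap)) stop("sigma > 0 requires a network Laplacian")
  gene_ids <- rownames(X)
  sample_ids <- colnames(X)
  if (is.null(u0)) u0 <- rnorm(p)
  if (is.null(v0)) v0 <- rnorm(n)
  if (all(u0 == 0) || all(v0 == 0)) stop("u0 and v0 must be nonzero")
  u <- .normalize(as.numeric(u0))
  v <- .normalize(as.numeric(v0))
  w <- .w_slots(lap, sigma, p)
  obj <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (t in seq_len(control$max_iter)) {
    iters <- t
    z <- drop(X %*% v)
    if (!is.null(ku)) {
      keep <- order(-abs(z), seq_along(z))[seq_len(ku)]
      u_new <- numeric(p)
      u_new[keep] <- z[keep]
      if (all(u_new == 0)) return(.zero_factor(p, n, gene_ids, sample_ids))
      u_new <- u_new / .l2(u_new)
    } else {
      res <- cd_update_u(z, w$p, w$i, w$x, lambda, sigma, u,
                         control$max_sweeps, control$inner_tol)
      u_new <- res$u
      if (all(u_new == 0)) return(.zero_factor(p, n, gene_ids, sample_ids))
      # monotone safeguard: keep the previous u if the sweep result is worse
      if (.u_objective(u_new, z, lap, lambda, sigma) >
          .u_objective(u, z, lap, lambda, sigma) + 1e-12) {
        u_new <- u
      }
    }
    v_new <- snsvd_update_v(X, u_new, kv)
    if (isTRUE(attr(v_new, "degenerate"))) {
      return(.zero_factor(p, n, gene_ids, sample_ids))
    }
    obj[t] <- .u_objective(u_new, drop(X %*% v_new), lap, lambda, sigma)
    delta <- max(.l2(u_new - u), .l2(v_new - v))
    u <- u_new
    v <- as.numeric(v_new)
    if (delta < control$tol) {
      converged <- TRUE
      break
    }
  }
  d <- as.numeric(crossprod(u, X %*% v))
  if (d < 0) {  # sign convention: singular value nonnegative
    v <- -v
    d <- -d
  }
  structure(list(u = setNames(u, gene_ids), v = setNames(v, sample_ids),
                 d = d, n_iters = iters, objective = obj,
                 converged = converged, degenerate = FALSE),
            class = "snsvd_factor")
}

#' @export
print.snsvd_factor <- function(x, ...) {
  cat("Sparse network-regularized singular factor\n")
  cat(sprintf("  d = %.4g | nnz(u) = %d/%d | nnz(v) = %d/%d\n",
              x$d, sum(x$u != 0), length(x$u), sum(x$v != 0), length(x$v)))
  cat(sprintf("  %d outer iteration(s), converged: %s\n",
              x$n_iters, x$converged))
  invisible(x)
}
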