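#' Normalized graph Laplacian and smoothing operator
#'
#' Computes the normalized Laplacian `L` of a gene network together with the
#' smoothing operator `W = D^{-1/2} A D^{-1/2}` used by the coordinate-descent
#' update of the gene-side singular vector. Entries follow the degree-aware
#' definition: `L[i,i] = 1` where the degree `d_i > 0` and `0` for isolated
#' nodes; `L[i,j] = -A[i,j] / sqrt(d_i d_j)` on edges. `W` has an exactly zero
#' diagonal and all-zero rows for isolated nodes, so the network term of the
#' update vanishes for genes outside the network.
#'
#' @param net A [gene_network()].
#' @return An object of class `snsvd_laplacian`: list with sparse symmetric
#'   matrices `L` and `W` and the integer degree vector `degrees`.
#' @examples
#' net <- gene_network(cbind("g1", "g2"), nodes = c("g1", "g2", "g3"))
#' lap <- network_laplacian(net)
#' as.matrix(lap$L)
#' @export
network_laplacian <- function(net) {
  stopifnot(is(net, "gene_network"))
  A <- net$adjacency
  d <- Matrix::rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dhalf <- Matrix::Diagonal(x = inv_sqrt)
  W <- Matrix::forceSymmetric(Dhalf %*% A %*% Dhalf)
  L <- Matrix::Diagonal(x = as.numeric(d > 0)) - W
  structure(list(L = as(L, "generalMatrix"),
                 W = as(W, "generalMatrix"),
                 degrees = setNames(as.integer(d), net$nodes)),
            class = "snsvd_laplacian")
}

#' Laplacian quadratic form
#'
#' Evaluates `u' L u`, the smoothness penalty of a loading vector over the
#' network: it equals `(1/2) * sum_ij A[i,j] * (u_i/sqrt(d_i) - u_j/sqrt(d_j))^2`,
#' so it is zero when connected genes have proportionally equal loadings and
#' grows as loadings disagree across edges.
#'
#' @param lap An `snsvd_laplacian`.
#' @param u Numeric vector of length equal to the number of network nodes.
#' @return Nonnegative scalar `u' L u`.
#' @export
laplacian_quadform <- function(lap, u) {
  stopifnot(is(lap, "snsvd_laplacian"))
  if (length(u) != nrow(lap$L)) {
    stop("length of u (", length(u), ") does not match network size (",
         nrow(lap$L), ")")
  }
  as.numeric(Matrix::crossprod(u, lap$L %*% u))
}
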