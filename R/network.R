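#' Construct a gene interaction network
#'
#' Builds an undirected, unweighted network over an ordered node universe
#' (normally the rownames of an expression matrix). Self-loops are dropped,
#' duplicate and reversed edges are collapsed, and edges touching nodes
#' outside the universe are discarded with a warning. Nodes in the universe
#' with no surviving edge are kept as isolated vertices (degree 0).
#'
#' @param edges Two-column character matrix or data frame of edge endpoints.
#' @param nodes Ordered character vector of node identifiers; defines the
#'   row/column order of the adjacency matrix.
#' @return An object of class `gene_network`: a list with `nodes`, `edges`
#'   (deduplicated two-column matrix), and `adjacency` (sparse symmetric
#'   binary [Matrix::sparseMatrix()] with zero diagonal).
#' @examples
#' net <- gene_network(cbind(c("g1", "g2"), c("g2", "g3")),
#'                     nodes = c("g1", "g2", "g3", "g4"))
#' network_degrees(net)
#' @export
gene_network <- function(edges, nodes) {
  if (anyDuplicated(nodes)) {
    stop("duplicate node identifiers in network universe")
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have exactly two columns")
  storage.mode(edges) <- "character"
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  inside <- edges[, 1L] %in% nodes & edges[, 2L] %in% nodes
  if (any(!inside)) {
    warning(sum(!inside), " edge(s) dropped: endpoint outside node universe")
    edges <- edges[inside, , drop = FALSE]
  }
  if (nrow(edges) == 0L && length(keep)) {
    stop("no network edges remain after restriction to the node universe")
  }
  # canonical orientation by node order, then dedup
  i <- match(edges[, 1L], nodes)
  j <- match(edges[, 2L], nodes)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  uniq <- !duplicated(cbind(lo, hi))
  lo <- lo[uniq]
  hi <- hi[uniq]
  p <- length(nodes)
  adj <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = 1,
                              dims = c(p, p), dimnames = list(nodes, nodes))
  structure(list(nodes = nodes,
                 edges = cbind(from = nodes[lo], to = nodes[hi]),
                 adjacency = adj),
            class = "gene_network")
}

#' Read a gene network edge list
#'
#' Accepts a two-column TSV edge list or a three-column SIF file
#' (`nodeA relation nodeB`; the relation column is ignored). Edges are
#' restricted to `node_universe` per [gene_network()].
#'
#' @param path Path to the edge-list file.
#' @param node_universe Ordered node identifiers to align the network to.
#' @param delimiter Field separator, default tab.
#' @return A `gene_network` object.
#' @export
read_network <- function(path, node_universe, delimiter = "\t") {
  if (!file.exists(path)) stop("network file not found: ", path)
  dat <- read.table(path, header = FALSE, sep = delimiter, quote = "",
                    comment.char = "", colClasses = "character",
                    stringsAsFactors = FALSE)
  edges <- switch(as.character(ncol(dat)),
    "2" = cbind(dat[[1L]], dat[[2L]]),
    "3" = cbind(dat[[1L]], dat[[3L]]),  # SIF: nodeA relation nodeB
    stop("network file must have 2 (edge list) or 3 (SIF) columns, found ",
         ncol(dat)))
  net <- gene_network(edges, node_universe)
  message("read network: ", length(net$nodes), " nodes, ",
          nrow(net$edges), " edges")
  net
}

#' Node degrees of a gene network
#'
#' @param net A `gene_network`.
#' @return Named integer vector of degrees (row sums of the adjacency).
#' @export
network_degrees <- function(net) {
  d <- Matrix::rowSums(net$adjacency)
  setNames(as.integer(d), net$nodes)
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene interaction network\n")
  cat("  nodes:", length(x$nodes), "\n")
  cat("  edges:", nrow(x$edges), "\n")
  cat("  isolated nodes:", sum(network_degrees(x) == 0L), "\n")
  invisible(x)
}
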