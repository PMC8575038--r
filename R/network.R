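#' Construct an undirected gene network
#'
#' A `gene_network` stores an undirected, optionally weighted gene adjacency.
#' Internally it keeps a symmetric numeric adjacency matrix with zero
#' diagonal; weights must be finite and non-negative. Duplicate edges are
#' collapsed keeping the maximum weight, self-loops are dropped with a
#' warning, and a directed edge list is symmetrized.
#'
#' @param edges A data frame with columns `from`, `to` and optionally
#'   `weight` (defaults to 1).
#' @param nodes Character vector of node identifiers. Defaults to the union
#'   of identifiers appearing in `edges`; supply explicitly to keep isolated
#'   nodes.
#' @return An object of class `gene_network` with elements `nodes`
#'   (character) and `adjacency` (symmetric numeric matrix).
#' @examples
#' net <- gene_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' network_degrees(net)
#' @export
gene_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  assert_that(all(c("from", "to") %in% names(edges)),
    "edges must have columns 'from' and 'to'")
  if (!"weight" %in% names(edges)) edges$weight <- 1
  assert_that(all(is.finite(edges$weight)), "edge weights must be finite")
  assert_that(all(edges$weight >= 0), "edge weights must be non-negative",
    class = "stratabench_value_error")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)

  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$from, edges$to)))
  } else {
    nodes <- as.character(nodes)
    assert_that(!anyDuplicated(nodes), "duplicate node identifiers")
    assert_that(all(c(edges$from, edges$to) %in% nodes),
      "edges reference nodes absent from `nodes`")
  }
  n <- length(nodes)
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    i <- match(edges$from, nodes)
    j <- match(edges$to, nodes)
    # collapse duplicates / reciprocal directed edges with max weight
    for (e in seq_along(i)) {
      w <- max(adj[i[e], j[e]], edges$weight[e])
      adj[i[e], j[e]] <- w
      adj[j[e], i[e]] <- w
    }
  }
  new_gene_network(adj)
}

#' Coerce a symmetric adjacency matrix to a gene network
#'
#' @param adjacency Square symmetric numeric matrix with node names as
#'   dimnames; the diagonal is zeroed.
#' @return A `gene_network`.
#' @export
as_gene_network <- function(adjacency) {
  assert_that(isTRUE(all.equal(unname(adjacency), unname(t(adjacency)))),
    "adjacency must be symmetric")
  new_gene_network(adjacency)
}

new_gene_network <- function(adjacency) {
  assert_that(is.matrix(adjacency) && nrow(adjacency) == ncol(adjacency),
    "adjacency must be square")
  assert_that(!is.null(rownames(adjacency)), "adjacency must carry node names")
  diag(adjacency) <- 0
  structure(
    list(nodes = rownames(adjacency), adjacency = adjacency),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  deg <- network_degrees(x)
  cat(sprintf(
    "<gene_network> %d nodes, %d edges, mean connectivity %.3f\n",
    length(x$nodes), sum(x$adjacency > 0) / 2, mean(deg)
  ))
  invisible(x)
}

#' Node degrees / weighted connectivity of a gene network
#'
#' For an unweighted network this is the edge count per node; for a weighted
#' network the row sum of edge weights (the WGCNA "connectivity").
#'
#' @param net A `gene_network`.
#' @return Named numeric vector, one entry per node.
#' @export
network_degrees <- function(net) {
  rowSums(net$adjacency)
}

#' Tidy the edge list of a gene network
#'
#' @param x A `gene_network`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `weight`, one row per
#'   undirected edge (from < to).
#' @export
tidy.gene_network <- function(x, ...) {
  adj <- x$adjacency
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  tibble(
    from = x$nodes[idx[, 1]],
    to = x$nodes[idx[, 2]],
    weight = adj[idx]
  )
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency,
    mode = "undirected", weighted = TRUE, diag = FALSE)
}
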