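# Per-patient seed selection and random walk with restart. Seeds are the
# patient's top-ranked disease genes split by fold-change sign; the walk
# diffuses them over the gene network and its stationary distribution ranks
# all genes by proximity to the seeds.

#' Select per-sample seed genes from disease gene lists
#'
#' Genes are standardized across samples (per-gene z-score); within each
#' sample the up-regulated list is ranked by descending z and the
#' down-regulated list by ascending z, and the top `top_n` of each become
#' that sample's seeds. Ties break by gene identifier. Setting
#' `ranking = "raw"` ranks on raw expression instead.
#'
#' @param expr Genes x samples matrix.
#' @param up_genes,down_genes Disjoint disease gene lists split by
#'   fold-change sign; genes absent from `expr` are dropped with a warning.
#' @param top_n Seeds per direction (default 50). If it exceeds both list
#'   lengths the full lists are used with a warning.
#' @param ranking `"zscore"` (default) or `"raw"`.
#' @return A `sample_seeds` object: per sample a list with `up` and `down`
#'   seed gene vectors. `tidy()` returns a long tibble.
#' @export
select_seed_genes <- function(expr, up_genes, down_genes, top_n = 50,
                              ranking = c("zscore", "raw")) {
  ranking <- match.arg(ranking)
  validate_expression(expr)
  assert_that(length(intersect(up_genes, down_genes)) == 0,
    "up and down gene lists must be disjoint")
  assert_that(is_count(top_n), "top_n must be a positive count")
  absent <- setdiff(c(up_genes, down_genes), rownames(expr))
  if (length(absent) > 0) {
    warn(sprintf("%d disease gene(s) absent from expression; dropped",
      length(absent)))
  }
  up <- intersect(up_genes, rownames(expr))
  down <- intersect(down_genes, rownames(expr))
  assert_that(length(up) > 0 && length(down) > 0,
    "both gene lists must intersect the expression matrix")
  if (top_n > length(up) && top_n > length(down)) {
    warn("top_n exceeds both list lengths; using full lists")
  }
  scores <- if (ranking == "zscore") {
    t(scale(t(expr)))
  } else {
    expr
  }
  pick <- function(genes, sample, decreasing) {
    z <- scores[genes, sample]
    ord <- order(if (decreasing) -z else z, genes)
    genes[ord][seq_len(min(top_n, length(genes)))]
  }
  out <- lapply(colnames(expr), function(s) {
    list(up = pick(up, s, TRUE), down = pick(down, s, FALSE))
  })
  names(out) <- colnames(expr)
  structure(out, class = "sample_seeds")
}

#' @export
print.sample_seeds <- function(x, ...) {
  cat(sprintf("<sample_seeds> %d samples, %d up / %d down seeds each\n",
    length(x), length(x[[1]]$up), length(x[[1]]$down)))
  invisible(x)
}

#' @export
tidy.sample_seeds <- function(x, ...) {
  purrr::imap(unclass(x), function(s, nm) {
    tibble(sample_id = nm,
      gene = c(s$up, s$down),
      direction = rep(c("up", "down"), c(length(s$up), length(s$down))))
  }) |> dplyr::bind_rows()
}

#' Random walk with restart over a gene network
#'
#' Iterates `p <- (1 - restart) * W %*% p + restart * p0` with `p0` uniform
#' over the seed genes until the L1 change drops below `tol`, and returns
#' the fixed point (the per-gene affinity vector). `W` is either the
#' symmetrically normalized adjacency `D^-1/2 A D^-1/2` (the normalized
#' graph Laplacian's diffusion kernel, the default) or the column-normalized
#' transition matrix `A D^-1`, under which total probability is conserved.
#'
#' The walk runs on the network's largest connected component; seeds
#' outside it are dropped with a warning and genes outside it receive
#' affinity 0.
#'
#' @param net A [gene_network()].
#' @param seeds Character vector of seed genes, or a list of such vectors
#'   to propagate several seed sets in one batched iteration.
#' @param restart Restart probability in (0, 1] (default 0.75).
#' @param normalization `"symmetric"` or `"row_stochastic"`.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return Named affinity vector over all network nodes, or a nodes x
#'   seed-sets matrix when `seeds` is a list.
#' @export
rwr_propagate <- function(net, seeds, restart = 0.75,
                          normalization = c("symmetric", "row_stochastic"),
                          tol = 1e-10, max_iter = 10000) {
  normalization <- match.arg(normalization)
  assert_that(restart > 0 && restart <= 1, "restart must be in (0,1]")
  single <- !is.list(seeds)
  seed_sets <- if (single) list(seeds) else seeds

  g <- as_igraph(net)
  comp <- igraph::components(g)
  lcc <- net$nodes[comp$membership == which.max(comp$csize)]
  a <- net$adjacency[lcc, lcc, drop = FALSE]
  deg <- rowSums(a)
  assert_that(all(deg > 0), "network has no edges",
    class = "stratabench_seed_error")

  w <- switch(normalization,
    symmetric = {
      dinv <- 1 / sqrt(deg)
      a * outer(dinv, dinv)
    },
    row_stochastic = {
      # columns sum to 1 so p <- W p conserves total probability
      sweep(a, 2, deg, "/")
    })

  p0 <- vapply(seed_sets, function(s) {
    s <- unique(as.character(s))
    kept <- intersect(s, lcc)
    if (length(kept) < length(s)) {
      warn(sprintf("%d seed(s) outside the largest connected component",
        length(s) - length(kept)))
    }
    assert_that(length(kept) > 0, "no seed gene in the network",
      class = "stratabench_seed_error")
    v <- numeric(length(lcc))
    v[match(kept, lcc)] <- 1 / length(kept)
    v
  }, numeric(length(lcc)))

  p <- p0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    p_new <- (1 - restart) * (w %*% p) + restart * p0
    resid <- max(colSums(abs(p_new - p)))
    p <- p_new
    if (resid < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf("RWR did not converge in %d iterations (residual %.3g)",
      max_iter, resid), class = "stratabench_convergence_error")
  }
  out <- matrix(0, length(net$nodes), length(seed_sets),
    dimnames = list(net$nodes, names(seed_sets)))
  out[lcc, ] <- p
  if (single) out[, 1] else out
}
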