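# Co-expression network construction and module machinery: hard/soft
# thresholding of absolute Spearman correlations, the scale-free topology
# criterion, topological overlap, static-cut module detection and
# eigen-genes.

spearman_abs <- function(expr) {
  assert_that(ncol(expr) >= 3, "need at least 3 samples for correlation",
    class = "stratabench_value_error")
  rho <- abs(cor(t(expr), method = "spearman"))
  rho[!is.finite(rho)] <- 0
  rho
}

#' Build a co-expression adjacency from expression
#'
#' Computes absolute Spearman correlations between genes and either
#' hard-thresholds them (edge iff `|rho| >= param`, unweighted) or raises
#' them to a soft power (`weight = |rho|^param`). The diagonal is excluded.
#'
#' @param expr Genes x samples numeric matrix.
#' @param mode `"hard"` (threshold in (0,1)) or `"soft"` (integer
#'   power of at least 1).
#' @param param Threshold or power. Hard thresholds of 0.475 and 0.525 and
#'   soft powers 6 and 4 are typical choices for breast- and prostate-like
#'   cohorts respectively; tune with [tune_threshold()].
#' @return A [gene_network()] over the genes of `expr`.
#' @export
build_adjacency <- function(expr, mode = c("hard", "soft"), param) {
  mode <- match.arg(mode)
  validate_expression(expr)
  rho <- spearman_abs(expr)
  if (mode == "hard") {
    assert_that(param > 0 && param < 1, "hard threshold must be in (0,1)")
    adj <- (rho >= param) * 1
  } else {
    assert_that(param >= 1 && param == as.integer(param),
      "soft power must be an integer >= 1")
    adj <- rho^param
  }
  diag(adj) <- 0
  new_gene_network(adj)
}

#' Scale-free topology fit index
#'
#' Regresses `log10 p(k)` on `log10 k` over logarithmic connectivity bins
#' (default 10; empty bins dropped) and returns the signed fit index:
#' R-squared of the regression when the slope is negative (a decreasing
#' degree distribution, as scale-free topology requires), 0 otherwise.
#'
#' @param degrees Per-node degree or weighted connectivity (non-negative).
#' @param n_bins Number of logarithmic bins.
#' @return Signed fit index in `[0, 1]`.
#' @export
scale_free_r2 <- function(degrees, n_bins = 10) {
  degrees <- degrees[degrees > 0]
  assert_that(length(unique(degrees)) >= 2,
    "degenerate degree distribution: fewer than 2 distinct positive degrees",
    class = "stratabench_degenerate_error")
  lk <- log10(degrees)
  breaks <- seq(min(lk), max(lk), length.out = n_bins + 1)
  bin <- cut(lk, breaks = breaks, include.lowest = TRUE)
  counts <- tapply(degrees, bin, length)
  kmean <- tapply(degrees, bin, mean)
  keep <- !is.na(counts) & counts > 0
  assert_that(sum(keep) >= 2, "fewer than 2 occupied connectivity bins",
    class = "stratabench_degenerate_error")
  x <- log10(kmean[keep])
  y <- log10(counts[keep] / sum(counts[keep]))
  fit <- stats::lm.fit(cbind(1, x), y)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    abort("degenerate degree distribution: constant bin frequencies",
      class = "stratabench_degenerate_error")
  }
  r2 <- 1 - ssr / sst
  slope <- fit$coefficients[2]
  if (is.na(slope) || slope >= 0) 0 else unname(r2)
}

#' Tune a correlation threshold or soft power by scale-free fit
#'
#' Evaluates each candidate parameter, computes the network's connectivity
#' distribution and its scale-free fit index, and returns the smallest
#' parameter reaching `r2_target`. If none reaches the target the best
#' (argmax) parameter is returned with `reached_target = FALSE` and a
#' warning.
#'
#' @param expr Genes x samples matrix.
#' @param mode `"hard"` or `"soft"` (see [build_adjacency()]).
#' @param grid Ascending candidate thresholds/powers.
#' @param r2_target Scale-free fit index to reach (default 0.8).
#' @return A `threshold_tuning` list: `param` (chosen), `reached_target`,
#'   and `diagnostics` (tibble: param, r2, mean_degree). `tidy()` returns
#'   the diagnostics.
#' @export
tune_threshold <- function(expr, mode = c("hard", "soft"), grid,
                           r2_target = 0.8) {
  mode <- match.arg(mode)
  assert_that(length(grid) >= 1 && !is.unsorted(grid),
    "grid must be non-empty and ascending")
  diag_rows <- purrr::map(grid, function(p) {
    net <- build_adjacency(expr, mode = mode, param = p)
    deg <- network_degrees(net)
    r2 <- tryCatch(scale_free_r2(deg),
      stratabench_degenerate_error = function(e) NA_real_)
    tibble(param = p, r2 = r2, mean_degree = mean(deg))
  })
  diagnostics <- dplyr::bind_rows(diag_rows)
  if (all(is.na(diagnostics$r2))) {
    abort("degenerate degree distribution at every candidate parameter",
      class = "stratabench_tuning_error")
  }
  hit <- which(!is.na(diagnostics$r2) & diagnostics$r2 >= r2_target)
  if (length(hit) > 0) {
    chosen <- grid[hit[1]]
    reached <- TRUE
  } else {
    chosen <- grid[which.max(diagnostics$r2)]
    reached <- FALSE
    warn(sprintf(
      "no candidate reached scale-free R^2 target %.2f; returning argmax %.3g",
      r2_target, chosen))
  }
  structure(
    list(param = chosen, reached_target = reached, mode = mode,
      r2_target = r2_target, diagnostics = diagnostics),
    class = "threshold_tuning"
  )
}

#' @export
print.threshold_tuning <- function(x, ...) {
  cat(sprintf("<threshold_tuning> mode=%s chosen=%.4g (target R^2 %.2f%s)\n",
    x$mode, x$param, x$r2_target,
    if (x$reached_target) ", reached" else ", NOT reached"))
  print(x$diagnostics)
  invisible(x)
}

#' @export
tidy.threshold_tuning <- function(x, ...) x$diagnostics

#' Topological overlap similarity
#'
#' For adjacency `a` in `[0,1]` with zero diagonal, the topological overlap
#' between genes i and j credits shared neighbors:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#' with `TOM_ii = 1`. Symmetric, bounded in `[0, 1]`.
#'
#' @param net A [gene_network()] with weights in `[0, 1]`.
#' @return Genes x genes numeric similarity matrix.
#' @export
tom_similarity <- function(net) {
  a <- net$adjacency
  assert_that(all(a >= 0 & a <= 1), "adjacency weights must lie in [0,1]",
    class = "stratabench_value_error")
  k <- rowSums(a)
  shared <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect gene modules from a TOM similarity
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed fraction of the maximum merge height; clusters smaller
#' than `min_module_size` are relabeled 0 (unassigned). Remaining module
#' labels are contiguous positive integers ordered by decreasing size.
#'
#' @param tom Square symmetric similarity matrix (e.g. [tom_similarity()]).
#' @param min_module_size Smallest cluster kept as a module (default 10).
#' @param cut_height Cut as a fraction of the maximum merge height
#'   (default 0.99).
#' @return A `module_assignment`: named integer vector (gene -> module,
#'   0 = unassigned) with attribute `sizes`. `tidy()` gives a tibble.
#' @export
detect_modules <- function(tom, min_module_size = 10, cut_height = 0.99) {
  assert_that(is.matrix(tom) && nrow(tom) == ncol(tom), "tom must be square")
  assert_that(min_module_size >= 2, "min_module_size must be >= 2")
  genes <- rownames(tom) %||% as.character(seq_len(nrow(tom)))
  if (nrow(tom) < min_module_size) {
    warn("fewer genes than min_module_size: all genes unassigned")
    return(new_module_assignment(setNames(rep(0L, nrow(tom)), genes)))
  }
  diss <- 1 - tom
  tree <- hclust(as.dist(diss), method = "average")
  h <- cut_height * max(tree$height)
  raw <- cutree(tree, h = h)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- rep(0L, length(raw))
  if (length(keep) > 0) {
    kept_sizes <- sizes[as.character(keep)]
    ord <- keep[order(-kept_sizes, keep)]
    for (idx in seq_along(ord)) {
      labels[raw == ord[idx]] <- idx
    }
  }
  new_module_assignment(setNames(labels, genes))
}

new_module_assignment <- function(labels) {
  sizes <- table(labels[labels > 0])
  structure(labels, sizes = sizes, class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  sizes <- attr(x, "sizes")
  cat(sprintf("<module_assignment> %d genes, %d modules (%d unassigned)\n",
    length(x), length(sizes), sum(unclass(x) == 0)))
  invisible(x)
}

#' @export
tidy.module_assignment <- function(x, ...) {
  tibble(gene = names(x), module = as.integer(unclass(x)))
}

#' Module eigen-genes
#'
#' The eigen-gene of a module is the first principal component of the
#' standardized module submatrix (samples x module genes), scaled to unit
#' norm and sign-aligned so it correlates non-negatively with the module's
#' mean expression profile. One-gene modules fall back to the gene's
#' standardized profile (flagged).
#'
#' @param expr Genes x samples matrix.
#' @param modules A `module_assignment` (or named integer vector); label 0
#'   is ignored.
#' @return An `eigengene_matrix`: samples x modules numeric matrix with
#'   attributes `var_explained` (per-module fraction) and `singleton`
#'   (logical flags). `tidy()` returns a long tibble.
#' @export
compute_eigengenes <- function(expr, modules) {
  validate_expression(expr)
  labels <- unclass(modules)
  labels <- labels[names(labels) %in% rownames(expr)]
  mods <- sort(unique(labels[labels > 0]))
  assert_that(length(mods) > 0, "no assigned modules")
  samples <- colnames(expr)
  em <- matrix(NA_real_, length(samples), length(mods),
    dimnames = list(samples, paste0("ME", mods)))
  varexp <- numeric(length(mods))
  singleton <- logical(length(mods))
  for (i in seq_along(mods)) {
    gs <- names(labels)[labels == mods[i]]
    x <- t(expr[gs, , drop = FALSE])      # samples x genes
    x <- scale(x)
    x[!is.finite(x)] <- 0
    if (length(gs) == 1) {
      warn(sprintf("module %d has a single gene; using its profile", mods[i]))
      v <- x[, 1]
      e <- v / sqrt(sum(v^2))
      varexp[i] <- 1
      singleton[i] <- TRUE
    } else {
      sv <- svd(x, nu = 1, nv = 0)
      e <- sv$u[, 1]
      varexp[i] <- sv$d[1]^2 / sum(sv$d^2)
    }
    profile <- rowMeans(x)
    if (isTRUE(sd(profile) > 0) && cor(e, profile) < 0) e <- -e
    em[, i] <- e
  }
  structure(em,
    var_explained = setNames(varexp, colnames(em)),
    singleton = setNames(singleton, colnames(em)),
    class = c("eigengene_matrix", "matrix", "array"))
}

#' @export
tidy.eigengene_matrix <- function(x, ...) {
  as_tibble(unclass(x), rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id",
      names_to = "module", values_to = "eigengene")
}

#' @export
glance.eigengene_matrix <- function(x, ...) {
  tibble(
    module = colnames(x),
    var_explained = as.numeric(attr(x, "var_explained")),
    singleton = as.logical(attr(x, "singleton"))
  )
}
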