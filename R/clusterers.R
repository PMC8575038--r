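# Clustering layer: correlation distance, a divisive (DIANA)
# implementation with deterministic tie-breaking, and seeded adapters for
# k-means (k-means++ restarts), Gaussian mixtures and agglomerative
# hierarchical clustering.

new_cluster_fit <- function(labels, k, method, params = list(),
                            diagnostics = list()) {
  labels <- canonicalize_labels(labels)
  assert_that(length(unique(labels)) == k,
    "clustering result must use all k labels")
  structure(
    list(labels = labels, k = k, method = method, params = params,
      diagnostics = diagnostics),
    class = "cluster_fit"
  )
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat(sprintf("<cluster_fit> %s, k=%d, sizes: %s\n", x$method, x$k,
    paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' @export
tidy.cluster_fit <- function(x, ...) {
  tibble(sample_id = names(x$labels), cluster = as.integer(x$labels))
}

#' @export
glance.cluster_fit <- function(x, ...) {
  tibble(method = x$method, k = x$k, n = length(x$labels),
    min_size = min(table(x$labels)))
}

#' Correlation-based dissimilarity between samples
#'
#' `d(x, y) = 1 - cor(x, y)` (Pearson) over the samples' feature vectors;
#' values lie in `[0, 2]`. The convention for pathway-level features, where
#' profile shape matters more than magnitude.
#'
#' @param features An `embedding` (samples x features), a
#'   `pathway_embedding` (pathways x samples, transposed internally), or a
#'   plain samples x features matrix.
#' @return A `dissimilarity` object: symmetric samples x samples matrix
#'   with zero diagonal and attribute `metric = "correlation"`.
#' @export
correlation_dissimilarity <- function(features) {
  xm <- if (inherits(features, "pathway_embedding")) {
    t(unclass(features))
  } else {
    unclass(features)
  }
  assert_that(ncol(xm) >= 2, "need at least 2 features per sample")
  sds <- apply(xm, 1, sd)
  if (any(sds == 0)) {
    bad <- rownames(xm)[which(sds == 0)[1]] %||% which(sds == 0)[1]
    abort(sprintf("constant feature vector for sample '%s': correlation undefined",
      bad), class = "stratabench_value_error")
  }
  d <- 1 - cor(t(xm))
  d[d < 0] <- 0  # numerical guard; exact anti-correlation gives 2
  diag(d) <- 0
  structure(d, metric = "correlation",
    class = c("dissimilarity", "matrix", "array"))
}

euclidean_dissimilarity <- function(xm) {
  d <- as.matrix(dist(unclass(xm)))
  structure(d, metric = "euclidean",
    class = c("dissimilarity", "matrix", "array"))
}

as_dissimilarity <- function(x) {
  if (inherits(x, "dissimilarity")) return(x)
  assert_that(is.matrix(x) && nrow(x) == ncol(x) &&
      isTRUE(all.equal(unname(x), unname(t(x)))) && all(diag(x) == 0) &&
      all(x >= 0), "not a valid dissimilarity matrix")
  structure(x, metric = attr(x, "metric") %||% "unknown",
    class = c("dissimilarity", "matrix", "array"))
}

# One divisive step: split `idx` (indices into d) into remainder and
# splinter group per Kaufman & Rousseeuw. Deterministic; ties break on the
# lowest sample index.
diana_split <- function(d, idx) {
  avg_to <- function(i, group) {
    if (length(group) == 0) return(0)
    mean(d[i, group])
  }
  avg_d <- vapply(idx, function(i) avg_to(i, setdiff(idx, i)), 0)
  start <- idx[which.max(avg_d)]  # which.max takes first (lowest index) tie
  splinter <- start
  rest <- setdiff(idx, start)
  while (length(rest) > 1) {
    diffs <- vapply(rest, function(i) {
      avg_to(i, setdiff(rest, i)) - avg_to(i, splinter)
    }, 0)
    if (max(diffs) <= 0) break
    mover <- rest[which.max(diffs)]
    splinter <- c(splinter, mover)
    rest <- setdiff(rest, mover)
  }
  list(remainder = rest, splinter = splinter)
}

#' Divisive hierarchical clustering (DIANA)
#'
#' Kaufman-Rousseeuw divisive analysis: starting from one all-sample
#' cluster, repeatedly split the cluster with the largest diameter (maximal
#' pairwise dissimilarity). A split seeds a splinter group with the object
#' of maximal average dissimilarity to its cluster-mates, then moves over
#' any object closer (on average) to the splinter group than to the
#' remainder, largest difference first, until no move qualifies. After
#' `k - 1` splits the current clusters are returned. Fully deterministic;
#' all ties break toward the lowest sample index.
#'
#' @param d A `dissimilarity` matrix (or any symmetric non-negative matrix
#'   with zero diagonal).
#' @param k Number of clusters, `2 <= k <= n`.
#' @return A `cluster_fit`; the divisive split sequence is kept in
#'   `$diagnostics$splits` (each element: parent, remainder, splinter, as
#'   sample names).
#' @export
diana_cluster <- function(d, k) {
  d <- as_dissimilarity(d)
  n <- nrow(d)
  assert_that(is_count(k) && k >= 2, "k must be an integer >= 2",
    class = "stratabench_value_error")
  assert_that(k <= n, "k exceeds the number of samples",
    class = "stratabench_value_error")
  ids <- rownames(d) %||% as.character(seq_len(n))
  clusters <- list(seq_len(n))
  splits <- list()
  while (length(clusters) < k) {
    diam <- vapply(clusters, function(cl) {
      if (length(cl) < 2) -1 else max(d[cl, cl])
    }, 0)
    cand <- which(diam >= 0 & vapply(clusters, length, 1L) >= 2)
    # largest diameter; ties -> cluster holding the lowest sample index
    cand <- cand[order(-diam[cand],
      vapply(clusters[cand], min, 1L))]
    target <- cand[1]
    sp <- diana_split(d, clusters[[target]])
    splits[[length(splits) + 1]] <- list(
      parent = ids[clusters[[target]]],
      remainder = ids[sp$remainder],
      splinter = ids[sp$splinter]
    )
    clusters[[target]] <- sp$remainder
    clusters[[length(clusters) + 1]] <- sp$splinter
  }
  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  names(labels) <- ids
  new_cluster_fit(labels, k, "diana",
    diagnostics = list(splits = splits))
}

kmeanspp_init <- function(xm, k) {
  n <- nrow(xm)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((xm - matrix(xm[centers[1], ], n, ncol(xm),
    byrow = TRUE))^2)
  for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums((xm - matrix(xm[centers[j], ], n, ncol(xm),
      byrow = TRUE))^2))
  }
  xm[centers, , drop = FALSE]
}

#' Run a standard clustering algorithm
#'
#' Adapters for the partitioners used alongside [diana_cluster()]:
#' `kmeans` (100 seeded k-means++ restarts, best within-cluster sum of
#' squares kept), `gmm` (Gaussian mixture, full covariance, mean-shrinkage
#' prior 0.01), and agglomerative hierarchical clustering with average,
#' complete or Ward linkage. `kmeans`, `gmm` and `hc_ward` require
#' coordinate features (Euclidean geometry); `hc_average` / `hc_complete`
#' also accept a `dissimilarity` matrix.
#'
#' @param x An `embedding` (samples x dims) or, for `hc_average` /
#'   `hc_complete`, a `dissimilarity` matrix.
#' @param method One of `"kmeans"`, `"gmm"`, `"hc_average"`,
#'   `"hc_complete"`, `"hc_ward"`.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param n_start k-means restarts (default 100).
#' @return A `cluster_fit`.
#' @export
run_partitioner <- function(x, method = c("kmeans", "gmm", "hc_average",
                              "hc_complete", "hc_ward"),
                            k, seed = 1, n_start = 100) {
  method <- match.arg(method)
  assert_that(is_count(k) && k >= 2, "k must be an integer >= 2",
    class = "stratabench_value_error")
  is_diss <- inherits(x, "dissimilarity")
  if (is_diss && method %in% c("kmeans", "gmm", "hc_ward")) {
    abort(sprintf("method '%s' requires coordinate features, not a dissimilarity",
      method), class = "stratabench_contract_error")
  }

  if (method %in% c("hc_average", "hc_complete")) {
    d <- if (is_diss) {
      x
    } else if (identical(embedding_distance(x), "correlation")) {
      correlation_dissimilarity(x)
    } else {
      euclidean_dissimilarity(x)
    }
    tree <- hclust(as.dist(unclass(d)),
      method = sub("hc_", "", method))
    labels <- cutree(tree, k = k)
    names(labels) <- rownames(d)
    return(new_cluster_fit(labels, k, method))
  }

  xm <- unclass(x)
  assert_that(k < nrow(xm), "k must be below the number of samples",
    class = "stratabench_value_error")

  if (method == "hc_ward") {
    tree <- hclust(dist(xm), method = "ward.D2")
    labels <- cutree(tree, k = k)
    names(labels) <- rownames(xm)
    return(new_cluster_fit(labels, k, method))
  }

  if (method == "kmeans") {
    best <- NULL
    for (r in seq_len(n_start)) {
      fit <- with_seed(derive_seed(seed, "kmeans", r), {
        init <- kmeanspp_init(xm, k)
        suppressWarnings(kmeans(xm, centers = init, iter.max = 100))
      })
      if (length(unique(fit$cluster)) == k &&
          (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
        best <- fit
      }
    }
    assert_that(!is.null(best), "k-means produced no valid partition",
      class = "stratabench_fit_error")
    labels <- setNames(best$cluster, rownames(xm))
    return(new_cluster_fit(labels, k, "kmeans",
      params = list(n_start = n_start),
      diagnostics = list(tot_withinss = best$tot.withinss)))
  }

  # gmm: full covariance with a mean-shrinkage prior; refit on failure or
  # empty clusters with a perturbed seed, up to 5 attempts.
  # Mclust resolves mclustBIC in the caller's frame, so bind it locally.
  mclustBIC <- mclust::mclustBIC
  for (attempt in seq_len(5)) {
    fit <- with_seed(derive_seed(seed, "gmm", attempt), {
      tryCatch(
        suppressWarnings(mclust::Mclust(xm, G = k, modelNames = "VVV",
          prior = mclust::priorControl(shrinkage = 0.01),
          verbose = FALSE)),
        error = function(e) NULL)
    })
    if (!is.null(fit) && length(unique(fit$classification)) == k) {
      labels <- setNames(fit$classification, rownames(xm))
      return(new_cluster_fit(labels, k, "gmm",
        params = list(shrinkage = 0.01),
        diagnostics = list(loglik = fit$loglik)))
    }
  }
  abort("GMM failed to produce k non-empty clusters after 5 attempts",
    class = "stratabench_fit_error")
}
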