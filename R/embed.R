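# Uniform adapter over dimensionality-reduction methods so reduced
# expression (DR-CL) and pathway-knowledge features (BK-CL) are
# interchangeable downstream.

#' Reduce features to a sample embedding
#'
#' Projects samples into a low-dimensional space behind a uniform contract.
#' `"pca"` is deterministic (sign convention: each component's largest-
#' magnitude loading is non-negative) and tagged with Euclidean downstream
#' distance; `"identity"` passes the feature matrix through transposed to
#' samples x features and tags correlation distance (the convention for
#' pathway-level features). The contract reserves `"tsne"` and `"umap"`
#' slots for delegated stochastic embedders (typical settings: perplexity
#' 45, 20 neighbors); no implementation is bundled and requesting them
#' raises an unsupported-method error.
#'
#' @param x Genes x samples expression matrix or pathways x samples
#'   `pathway_embedding` (rows = features, columns = samples).
#' @param method `"pca"` or `"identity"`.
#' @param n_dims Output dimensions (PCA; must be < n_samples).
#' @param seed Integer seed, recorded for stochastic methods.
#' @return An `embedding`: samples x dims matrix with attributes `method`,
#'   `distance` (`"euclidean"` or `"correlation"`) and `seed`.
#' @export
reduce_dimensionality <- function(x, method = c("pca", "identity", "tsne",
                                    "umap"),
                                  n_dims = 2, seed = 1) {
  method <- match.arg(method)
  if (method %in% c("tsne", "umap")) {
    abort(sprintf("method '%s' is a reserved adapter slot with no bundled implementation",
      method), class = "stratabench_unsupported_error")
  }
  xm <- t(unclass(x))   # samples x features
  assert_that(all(is.finite(xm)), "features must be finite")
  if (method == "identity") {
    return(structure(xm, method = "identity", distance = "correlation",
      seed = seed, class = c("embedding", "matrix", "array")))
  }
  assert_that(is_count(n_dims) && n_dims < nrow(xm),
    "n_dims must be a positive count below the number of samples",
    class = "stratabench_value_error")
  pc <- prcomp(xm, center = TRUE, scale. = FALSE, rank. = n_dims)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(scores, method = "pca", distance = "euclidean", seed = seed,
    var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_dims)],
    class = c("embedding", "matrix", "array"))
}

#' @export
tidy.embedding <- function(x, ...) {
  as_tibble(unclass(x), rownames = "sample_id")
}

embedding_distance <- function(x) attr(x, "distance") %||% "euclidean"
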