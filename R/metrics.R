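# The evaluation protocol's metric layer: silhouette separability, label
# agreement (NMI / ARI), batch-aware cNMI, co-clustering Jaccard, resampled
# clustering stability, the module relevance score, and the informative-
# pathway filter.

#' Average silhouette width
#'
#' For each sample, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a` is
#' the mean dissimilarity to the sample's own cluster and `b` the smallest
#' mean dissimilarity to any other cluster. Singleton clusters contribute
#' `s = 0`, as does the degenerate `a = b = 0` case. Returns the mean over
#' samples, in `[-1, 1]`.
#'
#' @param d A `dissimilarity` matrix.
#' @param labels A `cluster_fit` or per-sample label vector (k >= 2).
#' @return Average silhouette width (scalar).
#' @export
silhouette_width <- function(d, labels) {
  d <- as_dissimilarity(d)
  lv <- as_label_vector(labels)
  assert_that(length(lv) == nrow(d), "labels and dissimilarity disagree")
  ks <- unique(lv)
  assert_that(length(ks) >= 2, "silhouette undefined for k = 1",
    class = "stratabench_value_error")
  s <- vapply(seq_along(lv), function(i) {
    own <- which(lv == lv[i])
    if (length(own) == 1) return(0)
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ks, lv[i]), function(kk) {
      mean(d[i, lv == kk])
    }, 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}

contingency <- function(a, b) {
  table(factor(a), factor(b))
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Agreement between two labelings (NMI or ARI)
#'
#' NMI is mutual information normalized by `sqrt(H(a) H(b))` (defined as 0
#' when either entropy is zero); ARI is the Rand index adjusted under the
#' permutation model.
#'
#' @param a,b Label vectors (or `cluster_fit`s) of equal length.
#' @param metric `"nmi"` or `"ari"`.
#' @return Scalar score; NMI in `[0, 1]`, ARI `<= 1`.
#' @export
label_agreement <- function(a, b, metric = c("nmi", "ari")) {
  metric <- match.arg(metric)
  a <- as_label_vector(a)
  b <- as_label_vector(b)
  assert_that(length(a) == length(b), "label vectors differ in length",
    class = "stratabench_value_error")
  tab <- contingency(a, b)
  n <- sum(tab)
  if (metric == "nmi") {
    pa <- rowSums(tab) / n
    pb <- colSums(tab) / n
    ha <- entropy_nat(pa)
    hb <- entropy_nat(pb)
    if (ha == 0 || hb == 0) return(0)
    pj <- tab / n
    mi <- 0
    for (i in seq_len(nrow(tab))) {
      for (j in seq_len(ncol(tab))) {
        if (pj[i, j] > 0) {
          mi <- mi + pj[i, j] * log(pj[i, j] / (pa[i] * pb[j]))
        }
      }
    }
    return(min(1, mi / sqrt(ha * hb)))
  }
  # ARI from the contingency table
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  ex <- sum_comb(rowSums(tab)) * sum_comb(colSums(tab)) / choose(n, 2)
  mx <- (sum_comb(rowSums(tab)) + sum_comb(colSums(tab))) / 2
  if (mx == ex) return(ifelse(idx == ex, 1, 0))
  (idx - ex) / (mx - ex)
}

#' Batch-corrected NMI (cNMI)
#'
#' `NMI(labels, subtype) - NMI(labels, batch)`: rewards concordance with
#' the biological subtype while penalizing association with the batch
#' variable. Range `[-1, 1]`. Samples missing either reference label are
#' dropped pairwise.
#'
#' @param labels Cluster labels (or `cluster_fit`).
#' @param subtype,batch Reference labelings; `NA`s allowed.
#' @return Scalar cNMI, with attribute `n_used`.
#' @export
cnmi <- function(labels, subtype, batch) {
  lv <- as_label_vector(labels)
  assert_that(length(subtype) == length(lv) && length(batch) == length(lv),
    "reference labelings must match labels in length",
    class = "stratabench_value_error")
  keep <- !is.na(subtype) & !is.na(batch)
  assert_that(any(!is.na(subtype)), "all subtype labels missing",
    class = "stratabench_missing_error")
  out <- label_agreement(lv[keep], subtype[keep], "nmi") -
    label_agreement(lv[keep], batch[keep], "nmi")
  attr(out, "n_used") <- sum(keep)
  out
}

#' Co-clustering Jaccard similarity
#'
#' Over all unordered sample pairs: the number of pairs co-clustered in
#' both labelings divided by the number co-clustered in either. 1 when both
#' co-clustered sets are empty.
#'
#' @param a,b Label vectors (or `cluster_fit`s) of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
coclustering_jaccard <- function(a, b) {
  a <- as_label_vector(a)
  b <- as_label_vector(b)
  assert_that(length(a) == length(b), "label vectors differ in length",
    class = "stratabench_value_error")
  # pair counts via the contingency table: together in both = sum C(n_ij,2)
  tab <- contingency(a, b)
  both <- sum(choose(tab, 2))
  in_a <- sum(choose(rowSums(tab), 2))
  in_b <- sum(choose(colSums(tab), 2))
  either <- in_a + in_b - both
  if (either == 0) return(1)
  both / either
}

#' Clustering stability under cross-validation resampling
#'
#' Fits the pipeline on the full data to get reference labels, then for
#' each of `repeats x folds` resamples drops one fold's samples, reruns the
#' full pipeline (feature extraction included) on the retained samples, and
#' compares the resample labels to the reference restricted to those
#' samples via co-clustering Jaccard and ARI. The classic protocol is 20
#' repeats of 5-fold CV, i.e. 100 resamples of 80% of the cohort.
#'
#' @param pipeline `function(expr, seed)` returning a `cluster_fit` or a
#'   named label vector over the columns of `expr`.
#' @param expr Genes x samples matrix handed to the pipeline.
#' @param folds CV folds (>= 2, default 5).
#' @param repeats CV repeats (default 20).
#' @param seed Integer seed (fold assignment and pipeline sub-seeds).
#' @return A `stability_report`: tibble with columns `resample_id`,
#'   `repeat_id`, `fold`, `jaccard`, `ari`, `n_retained`; `glance()` gives
#'   means and SDs. Failed resamples are recorded as `NA` (an error is
#'   raised if more than half fail).
#' @export
stability_resample <- function(pipeline, expr, folds = 5, repeats = 20,
                               seed = 1) {
  assert_that(is_count(folds) && folds >= 2, "folds must be >= 2")
  assert_that(is_count(repeats), "repeats must be >= 1")
  n <- ncol(expr)
  reference <- as_label_vector(pipeline(expr, derive_seed(seed, "ref")))
  assert_that(length(reference) == n, "pipeline must label every sample")

  rows <- list()
  rid <- 0
  for (rep_i in seq_len(repeats)) {
    fold_of <- with_seed(derive_seed(seed, "folds", rep_i),
      sample(rep(seq_len(folds), length.out = n)))
    for (fold_i in seq_len(folds)) {
      rid <- rid + 1
      retain <- which(fold_of != fold_i)
      res <- tryCatch({
        sub <- expr[, retain, drop = FALSE]
        lab <- as_label_vector(pipeline(sub, derive_seed(seed, "rs", rid)))
        ref_sub <- reference[retain]
        c(jaccard = coclustering_jaccard(lab, ref_sub),
          ari = label_agreement(lab, ref_sub, "ari"))
      }, error = function(e) c(jaccard = NA_real_, ari = NA_real_))
      rows[[rid]] <- tibble(resample_id = rid, repeat_id = rep_i,
        fold = fold_i, jaccard = res[["jaccard"]], ari = res[["ari"]],
        n_retained = length(retain))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (mean(is.na(out$jaccard)) > 0.5) {
    abort("pipeline failed on more than half of the resamples",
      class = "stratabench_stability_error")
  }
  structure(out, folds = folds, repeats = repeats, seed = seed,
    class = c("stability_report", class(out)))
}

#' @export
glance.stability_report <- function(x, ...) {
  tibble(
    n_resamples = nrow(x),
    folds = attr(x, "folds"),
    repeats = attr(x, "repeats"),
    mean_jaccard = mean(x$jaccard, na.rm = TRUE),
    sd_jaccard = sd(x$jaccard, na.rm = TRUE),
    mean_ari = mean(x$ari, na.rm = TRUE),
    sd_ari = sd(x$ari, na.rm = TRUE),
    n_failed = sum(is.na(x$jaccard))
  )
}

#' Gene-module relevance score of a clustering
#'
#' For each module eigen-gene, count the clusters whose one-hot indicator
#' has Spearman correlation `>= alpha` (`S+`) or `<= -alpha` (`S-`) with
#' it. The module's value is `(min(1, S+) + min(1, S-)) / (S+ + S-)` —
#' rewarding modules tied to exactly one cluster per direction — or `beta`
#' when no cluster passes the threshold. The score is the unweighted mean
#' over modules, in `[0, 1]`.
#'
#' @param eigengenes An `eigengene_matrix` (samples x modules) or plain
#'   matrix.
#' @param labels A `cluster_fit` or label vector over the same samples
#'   (k >= 2).
#' @param alpha Correlation-count threshold in (0, 1); default 0.5.
#' @param beta Fallback value for unassociated modules in `[0, 1]`;
#'   default 0, which penalizes clusterings that fail to separate module
#'   expression.
#' @return Scalar score with attribute `per_module`.
#' @export
module_score <- function(eigengenes, labels, alpha = 0.5, beta = 0) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  assert_that(beta >= 0 && beta <= 1, "beta must be in [0,1]")
  em <- unclass(eigengenes)
  lv <- as_label_vector(labels)
  assert_that(nrow(em) == length(lv),
    "eigengenes and labels cover different samples")
  ks <- sort(unique(lv))
  assert_that(length(ks) >= 2, "module score needs k >= 2",
    class = "stratabench_value_error")
  onehot <- vapply(ks, function(kk) as.numeric(lv == kk),
    numeric(length(lv)))
  per_module <- vapply(seq_len(ncol(em)), function(i) {
    e <- em[, i]
    if (sd(e) == 0) {
      warn(sprintf("zero-variance eigen-gene in column %d; skipped", i))
      return(NA_real_)
    }
    rho <- suppressWarnings(cor(e, onehot, method = "spearman"))[1, ]
    s_pos <- sum(rho >= alpha, na.rm = TRUE)
    s_neg <- sum(rho <= -alpha, na.rm = TRUE)
    if (s_pos + s_neg == 0) {
      beta
    } else {
      (min(1, s_pos) + min(1, s_neg)) / (s_pos + s_neg)
    }
  }, 0)
  names(per_module) <- colnames(em) %||% paste0("ME", seq_len(ncol(em)))
  out <- mean(per_module, na.rm = TRUE)
  attr(out, "per_module") <- per_module
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  out
}

#' Pathways that separate the clusters
#'
#' Kruskal-Wallis test of each pathway's adjusted scores across clusters,
#' Benjamini-Hochberg correction over pathways, and a filtered ranking of
#' those below the adjusted-p threshold. Constant pathway rows are skipped
#' (recorded in the `skipped` attribute).
#'
#' @param embedding A `pathway_embedding` (pathways x samples).
#' @param labels A `cluster_fit` or label vector (k >= 2).
#' @param p_threshold Adjusted-p cutoff (default 0.05).
#' @return Tibble (`pathway`, `statistic`, `p_value`, `p_adjusted`) sorted
#'   ascending by p, filtered at the threshold.
#' @export
informative_pathways <- function(embedding, labels, p_threshold = 0.05) {
  em <- unclass(embedding)
  lv <- as_label_vector(labels)
  assert_that(ncol(em) == length(lv),
    "embedding and labels cover different samples")
  assert_that(length(unique(lv)) >= 2, "need k >= 2",
    class = "stratabench_value_error")
  g <- factor(lv)
  res <- purrr::map(rownames(em), function(p) {
    x <- em[p, ]
    if (length(unique(x)) == 1) {
      return(tibble(pathway = p, statistic = NA_real_, p_value = NA_real_))
    }
    kw <- kruskal.test(x, g)
    tibble(pathway = p, statistic = unname(kw$statistic),
      p_value = kw$p.value)
  }) |> dplyr::bind_rows()
  skipped <- res$pathway[is.na(res$p_value)]
  res <- res[!is.na(res$p_value), , drop = FALSE]
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  out <- res |>
    dplyr::filter(.data$p_adjusted < p_threshold) |>
    dplyr::arrange(.data$p_value)
  attr(out, "skipped") <- skipped
  out
}
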