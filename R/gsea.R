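# Pre-ranked gene set enrichment on a per-gene ranking statistic, and the
# assembly of sparse pathway embeddings from per-sample enrichment results.

#' Pre-ranked gene set enrichment
#'
#' Genes are sorted by descending ranking statistic (ties broken by gene
#' identifier); the running sum increments `|score|^weight_exponent`
#' (normalized over the set) at set members and decrements `1/(N - |set|)`
#' elsewhere. The enrichment score (ES) is the signed maximum deviation of
#' this walk from zero. The null distribution comes from random gene-label
#' subsets of matching size — either `n_perm` sampled permutations or, with
#' `null = "exhaustive"`, every possible subset. NES divides ES by the mean
#' magnitude of same-sign null scores; the permutation p-value is
#' `(1 + #{|null| >= |ES|, same sign}) / (1 + #same-sign nulls)`.
#'
#' @param scores Named, finite per-gene ranking statistic (e.g. RWR
#'   affinities).
#' @param sets Named list of gene vectors; members absent from `scores` are
#'   dropped, and sets outside `[min_size, max_size]` after filtering are
#'   skipped (recorded in the `skipped` attribute).
#' @param weight_exponent Weight on |score| in the running sum (default 1;
#'   0 gives the classic unweighted Kolmogorov-Smirnov statistic).
#' @param n_perm Number of permutations (default 1000).
#' @param min_size,max_size Set-size window (defaults 5 and 500).
#' @param seed Integer seed for the permutation null.
#' @param null `"permutation"` or `"exhaustive"` (enumerates all
#'   `choose(N, s)` subsets; only sensible for small universes).
#' @return A tibble with columns `set`, `es`, `nes`, `p_value`,
#'   `n_more_extreme`, `size_used`; skipped sets in `attr(, "skipped")`.
#' @export
preranked_gsea <- function(scores, sets, weight_exponent = 1, n_perm = 1000,
                           min_size = 5, max_size = 500, seed = 1,
                           null = c("permutation", "exhaustive")) {
  null <- match.arg(null)
  assert_that(is.numeric(scores) && !is.null(names(scores)),
    "scores must be a named numeric vector")
  assert_that(all(is.finite(scores)), "scores must be finite")
  if (length(unique(scores)) == 1) {
    abort("all ranking scores are equal; ranking is degenerate",
      class = "stratabench_degenerate_error")
  }
  genes <- names(scores)
  ord <- order(-scores, genes)
  ranked <- genes[ord]
  w <- abs(scores[ord])^weight_exponent
  n <- length(ranked)

  filtered <- lapply(sets, function(s) which(ranked %in% s))
  sizes <- vapply(filtered, length, 1L)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  skipped <- tibble(
    set = names(sets)[!keep],
    size_used = sizes[!keep],
    reason = ifelse(sizes[!keep] < min_size | sizes[!keep] == 0,
      "below min_size", "above max_size or covers universe")
  )

  null_for_size <- function(s) {
    if (null == "permutation") {
      with_seed(derive_seed(seed, "gsea-null", s),
        gsea_null_perm(w, s, n_perm))
    } else {
      gsea_null_exhaustive(w, combn(n, s))
    }
  }
  null_cache <- new.env(parent = emptyenv())

  kept_names <- names(sets)[keep]
  nk <- length(kept_names)
  es_v <- nes_v <- p_v <- numeric(nk)
  nx_v <- sz_v <- integer(nk)
  for (i in seq_len(nk)) {
    hits <- filtered[[kept_names[i]]]
    s <- length(hits)
    es <- gsea_es(w, hits)
    key <- as.character(s)
    if (is.null(null_cache[[key]])) null_cache[[key]] <- null_for_size(s)
    nulls <- null_cache[[key]]
    same_sign <- if (es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    # count at-least-as-extreme nulls; exact ties are real (the running sum
    # is piecewise rational) so compare within summation rounding
    n_extreme <- sum(abs(same_sign) >= abs(es) - 1e-12)
    es_v[i] <- es
    nes_v[i] <- if (es == 0 || length(same_sign) == 0) {
      0
    } else {
      es / mean(abs(same_sign))
    }
    p_v[i] <- (1 + n_extreme) / (1 + length(same_sign))
    nx_v[i] <- n_extreme
    sz_v[i] <- s
  }
  out <- tibble(set = kept_names, es = es_v, nes = nes_v, p_value = p_v,
    n_more_extreme = nx_v, size_used = sz_v)
  attr(out, "skipped") <- skipped
  out
}

#' Assemble a sparse pathway embedding from per-sample enrichment
#'
#' The adjusted score of a pathway in a sample is `NES * (-log10 p)` under
#' the default transform, so pathways with p near 1 vanish and the matrix
#' is sparse. The `nes_times_logp` variant multiplies by `log10 p` instead
#' (flipping the enrichment sign). Entries with p above
#' `significance_floor` are set to 0; pathways skipped in a sample get 0.
#'
#' @param results Named list (by sample) of [preranked_gsea()] tibbles, or
#'   a single tibble with a `sample_id` column.
#' @param transform `"nes_times_neglog10p"` (default) or `"nes_times_logp"`.
#' @param significance_floor p-values above this are zeroed (default 1 =
#'   no floor).
#' @return A `pathway_embedding`: pathways x samples numeric matrix with a
#'   `provenance` attribute.
#' @export
build_pathway_embedding <- function(results,
                                    transform = c("nes_times_neglog10p",
                                      "nes_times_logp"),
                                    significance_floor = 1) {
  transform <- match.arg(transform)
  if (is.data.frame(results)) {
    assert_that("sample_id" %in% names(results),
      "tibble input needs a sample_id column")
    results <- split(results, results$sample_id)
  }
  pathways <- sort(unique(unlist(lapply(results, function(r) r$set))))
  for (r in results) {
    extra <- setdiff(r$set, pathways)
    assert_that(length(extra) == 0, "inconsistent pathway universes",
      class = "stratabench_assembly_error")
  }
  emb <- matrix(0, length(pathways), length(results),
    dimnames = list(pathways, names(results)))
  sgn <- if (transform == "nes_times_neglog10p") -1 else 1
  for (s in names(results)) {
    r <- results[[s]]
    val <- r$nes * sgn * log10(r$p_value)
    val[!is.finite(val) | r$p_value > significance_floor] <- 0
    emb[r$set, s] <- val
  }
  structure(emb,
    provenance = list(transform = transform,
      significance_floor = significance_floor),
    class = c("pathway_embedding", "matrix", "array"))
}

#' @export
tidy.pathway_embedding <- function(x, ...) {
  as_tibble(unclass(x), rownames = "pathway") |>
    tidyr::pivot_longer(-"pathway",
      names_to = "sample_id", values_to = "score")
}

#' Network-driven pathway enrichment features (RWR + pre-ranked GSEA)
#'
#' The full feature extractor: per-sample seed genes are selected from the
#' up-/down-regulated disease lists ([select_seed_genes()]), diffused over
#' the gene network by random walk with restart ([rwr_propagate()]), and
#' the resulting affinity vectors are scored against the gene set
#' collection by pre-ranked GSEA ([preranked_gsea()]). In the default
#' split mode the up- and down-seed walks run separately, the down run's
#' NES is negated, and the two adjusted-score matrices are summed — so
#' positive pathway scores associate with up-regulated seed genes and
#' negative scores with down-regulated ones. `combine = "single"` runs one
#' walk on the union of seeds.
#'
#' @param expr Genes x samples matrix.
#' @param network A [gene_network()].
#' @param up_genes,down_genes Disease gene lists split by fold-change sign.
#' @param sets Gene set collection (named list).
#' @param top_n Seeds per direction (default 50).
#' @param restart RWR restart probability (default 0.75).
#' @param normalization RWR normalization (default `"symmetric"`).
#' @param weight_exponent,n_perm,min_size,max_size See [preranked_gsea()].
#' @param transform,significance_floor See [build_pathway_embedding()].
#' @param combine `"split"` (default) or `"single"`.
#' @param seed Integer seed (permutation nulls; one sub-seed per sample).
#' @return A `pathway_embedding` (pathways x samples).
#' @export
rwr_fgsea_embedding <- function(expr, network, up_genes, down_genes, sets,
                                top_n = 50, restart = 0.75,
                                normalization = "symmetric",
                                weight_exponent = 1, n_perm = 1000,
                                min_size = 5, max_size = 500,
                                transform = "nes_times_neglog10p",
                                significance_floor = 1,
                                combine = c("split", "single"), seed = 1) {
  combine <- match.arg(combine)
  seeds <- select_seed_genes(expr, up_genes, down_genes, top_n = top_n)
  samples <- names(seeds)

  gsea_one <- function(affinity, sample_seed) {
    preranked_gsea(affinity, sets, weight_exponent = weight_exponent,
      n_perm = n_perm, min_size = min_size, max_size = max_size,
      seed = sample_seed)
  }

  if (combine == "single") {
    aff <- rwr_propagate(network,
      lapply(seeds, function(s) c(s$up, s$down)),
      restart = restart, normalization = normalization)
    res <- lapply(samples, function(s) {
      gsea_one(aff[, s], derive_seed(seed, "gsea", s))
    })
    names(res) <- samples
    return(build_pathway_embedding(res, transform = transform,
      significance_floor = significance_floor))
  }

  aff_up <- rwr_propagate(network, lapply(seeds, `[[`, "up"),
    restart = restart, normalization = normalization)
  aff_down <- rwr_propagate(network, lapply(seeds, `[[`, "down"),
    restart = restart, normalization = normalization)
  res_up <- lapply(samples, function(s) {
    gsea_one(aff_up[, s], derive_seed(seed, "gsea-up", s))
  })
  res_down <- lapply(samples, function(s) {
    r <- gsea_one(aff_down[, s], derive_seed(seed, "gsea-down", s))
    r$nes <- -r$nes
    r
  })
  names(res_up) <- names(res_down) <- samples
  emb_up <- build_pathway_embedding(res_up, transform = transform,
    significance_floor = significance_floor)
  emb_down <- build_pathway_embedding(res_down, transform = transform,
    significance_floor = significance_floor)
  pathways <- sort(union(rownames(emb_up), rownames(emb_down)))
  emb <- matrix(0, length(pathways), length(samples),
    dimnames = list(pathways, samples))
  emb[rownames(emb_up), ] <- emb[rownames(emb_up), ] + unclass(emb_up)
  emb[rownames(emb_down), ] <- emb[rownames(emb_down), ] + unclass(emb_down)
  structure(emb,
    provenance = list(transform = transform,
      significance_floor = significance_floor, restart = restart,
      normalization = normalization, top_n = top_n, n_perm = n_perm,
      combine = combine),
    class = c("pathway_embedding", "matrix", "array"))
}
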