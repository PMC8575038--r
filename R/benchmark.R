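# Orchestration: run the (feature space x clusterer x k) grid over
# cross-validation resamples, record the five evaluation criteria as a long
# metric table, aggregate, select best-by-sum per embedding, and compute
# the first Pareto frontier.

#' Registered metric directions
#'
#' Direction of preference for every metric the benchmark records or
#' derives.
#'
#' @return Named character vector (`"maximize"` / `"minimize"`).
#' @export
metric_directions <- function() {
  c(silhouette = "maximize",
    stability_jaccard = "maximize",
    stability_ari = "maximize",
    nmi_subtype = "maximize",
    ari_subtype = "maximize",
    nmi_batch = "minimize",
    nmi_batch2 = "minimize",
    cnmi = "maximize",
    module_score = "maximize",
    survival_p = "minimize",
    survival_nlp = "maximize",
    batch_inverse = "maximize")
}

#' Assemble a benchmark configuration
#'
#' @param embeddings Named list of embedding specs; each a list with
#'   `method` (`"pca"`, `"identity"` or `"rwr_fgsea"`) plus method
#'   parameters (`n_dims` for pca; `top_n`, `restart`, `n_perm`,
#'   `min_size`, `max_size` for rwr_fgsea).
#' @param clusterers Character vector from `"diana"`, `"kmeans"`, `"gmm"`,
#'   `"hc_average"`, `"hc_complete"`, `"hc_ward"`.
#' @param k_range Integer vector of cluster counts (all >= 2).
#' @param folds,repeats Stability resampling scheme (defaults 5 and 20,
#'   i.e. 100 resamples).
#' @param alpha,beta Module score parameters (defaults 0.5 and 0).
#' @param covariates Baseline covariate columns for the survival LRT.
#' @param followup_cap Optional follow-up cap in days.
#' @param module_power Soft power for the module-detection co-expression
#'   network (default 6).
#' @param module_min_size,module_cut Module detection parameters.
#' @param seed Master seed; all component seeds derive from it.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(embeddings, clusterers, k_range = 2:6,
                             folds = 5, repeats = 20, alpha = 0.5,
                             beta = 0, covariates = character(),
                             followup_cap = NULL, module_power = 6,
                             module_min_size = 10, module_cut = 0.99,
                             seed = 1) {
  assert_that(is.list(embeddings) && length(embeddings) > 0 &&
      !is.null(names(embeddings)) && all(nzchar(names(embeddings))),
    "embeddings must be a non-empty named list",
    class = "stratabench_config_error")
  for (e in embeddings) {
    assert_that(!is.null(e$method) &&
        e$method %in% c("pca", "identity", "rwr_fgsea"),
      "unknown embedding method", class = "stratabench_config_error")
  }
  allowed <- c("diana", "kmeans", "gmm", "hc_average", "hc_complete",
    "hc_ward")
  assert_that(all(clusterers %in% allowed),
    sprintf("clusterers must be among: %s", paste(allowed, collapse = ", ")),
    class = "stratabench_config_error")
  assert_that(all(k_range >= 2), "k_range must be >= 2",
    class = "stratabench_config_error")
  assert_that(folds >= 2 && repeats >= 1, "need folds >= 2, repeats >= 1",
    class = "stratabench_config_error")
  structure(list(
    embeddings = embeddings, clusterers = clusterers,
    k_range = as.integer(k_range), folds = folds, repeats = repeats,
    alpha = alpha, beta = beta, covariates = covariates,
    followup_cap = followup_cap, module_power = module_power,
    module_min_size = module_min_size, module_cut = module_cut,
    seed = seed
  ), class = "benchmark_config")
}

# Build the feature-extraction closure for one embedding spec.
feature_fn <- function(spec, knowledge) {
  method <- spec$method
  if (method == "rwr_fgsea") {
    assert_that(!is.null(knowledge$network) && !is.null(knowledge$sets) &&
        !is.null(knowledge$up_genes) && !is.null(knowledge$down_genes),
      "rwr_fgsea embeddings require knowledge inputs (network, sets, gene lists)",
      class = "stratabench_config_error")
    function(expr, seed) {
      rwr_fgsea_embedding(expr, knowledge$network, knowledge$up_genes,
        knowledge$down_genes, knowledge$sets,
        top_n = spec$top_n %||% 50, restart = spec$restart %||% 0.75,
        n_perm = spec$n_perm %||% 1000,
        min_size = spec$min_size %||% 5, max_size = spec$max_size %||% 500,
        seed = seed)
    }
  } else if (method == "pca") {
    function(expr, seed) {
      reduce_dimensionality(expr, "pca", n_dims = spec$n_dims %||% 2,
        seed = seed)
    }
  } else {
    function(expr, seed) reduce_dimensionality(expr, "identity", seed = seed)
  }
}

feature_dissimilarity <- function(features) {
  if (inherits(features, "pathway_embedding") ||
      identical(embedding_distance(features), "correlation")) {
    correlation_dissimilarity(features)
  } else {
    euclidean_dissimilarity(features)
  }
}

cluster_features <- function(features, clusterer, k, seed) {
  if (clusterer == "diana") {
    diana_cluster(feature_dissimilarity(features), k)
  } else if (clusterer %in% c("hc_average", "hc_complete")) {
    run_partitioner(feature_dissimilarity(features), clusterer, k,
      seed = seed)
  } else {
    assert_that(!inherits(features, "pathway_embedding") &&
        identical(embedding_distance(features), "euclidean"),
      sprintf("clusterer '%s' requires Euclidean coordinate features",
        clusterer),
      class = "stratabench_contract_error")
    run_partitioner(features, clusterer, k, seed = seed)
  }
}

combo_compatible <- function(spec, clusterer) {
  !(spec$method %in% c("rwr_fgsea", "identity") &&
      clusterer %in% c("kmeans", "gmm", "hc_ward"))
}

#' Run the benchmark grid
#'
#' For every embedding x clusterer x k combination and every resample of
#' `repeats` repeats of `folds`-fold cross-validation, recomputes features
#' and clusters on the retained samples and records: silhouette, stability
#' (co-clustering Jaccard and ARI against the full-data reference
#' restricted to the retained samples), NMI/ARI against the subtype
#' labels, NMI against each batch variable, cNMI, the module relevance
#' score, and the survival LRT p-value. Coordinate-requiring clusterers
#' (kmeans/gmm/hc_ward) are skipped for correlation-convention feature
#' spaces, as in the correlation-distance workflow. Combinations failing
#' on the full data are recorded as missing and skipped.
#'
#' @param expr Genes x samples expression matrix.
#' @param clinical Clinical tibble (`sample_id`, `time`, `event`, optional
#'   `subtype`, `batch`, `batch2`, covariates).
#' @param config A [benchmark_config()].
#' @param knowledge Optional list with `network`, `sets`, `up_genes`,
#'   `down_genes`, and optionally `modules` (a `module_assignment`;
#'   computed from the data when absent).
#' @return A long metric tibble (`embedding`, `clusterer`, `k`,
#'   `resample_id`, `metric`, `value`), with `resample_id = 0` holding the
#'   full-data reference fit's metrics.
#' @export
run_benchmark <- function(expr, clinical, config, knowledge = NULL) {
  assert_that(inherits(config, "benchmark_config"),
    "config must come from benchmark_config()",
    class = "stratabench_config_error")
  validate_expression(expr)
  n <- ncol(expr)
  assert_that(all(config$k_range <= n - 1),
    "k_range must stay below the number of samples",
    class = "stratabench_config_error")
  assert_that(all(colnames(expr) %in% clinical$sample_id),
    "clinical table must cover all samples",
    class = "stratabench_config_error")
  clin <- clinical[match(colnames(expr), clinical$sample_id), , drop = FALSE]
  subtype <- clin$subtype %||% rep(NA_character_, n)
  batch_vars <- intersect(c("batch", "batch2"), names(clin))

  modules <- knowledge$modules %||% {
    net <- build_adjacency(expr, "soft", config$module_power)
    detect_modules(tom_similarity(net),
      min_module_size = config$module_min_size,
      cut_height = config$module_cut)
  }

  records <- list()
  push <- function(embedding, clusterer, k, resample_id, metric, value) {
    records[[length(records) + 1]] <<- tibble(
      embedding = embedding, clusterer = clusterer, k = k,
      resample_id = resample_id, metric = metric, value = value)
  }

  measure <- function(features, fit, sample_idx, embedding, clusterer, k,
                      resample_id) {
    d <- feature_dissimilarity(features)
    lab <- fit$labels
    push(embedding, clusterer, k, resample_id, "silhouette",
      silhouette_width(d, lab))
    st <- subtype[sample_idx]
    if (!all(is.na(st))) {
      push(embedding, clusterer, k, resample_id, "nmi_subtype",
        label_agreement(lab, st, "nmi"))
      push(embedding, clusterer, k, resample_id, "ari_subtype",
        label_agreement(lab, st, "ari"))
    }
    for (bv in batch_vars) {
      nm <- if (bv == "batch") "nmi_batch" else "nmi_batch2"
      push(embedding, clusterer, k, resample_id, nm,
        label_agreement(lab, clin[[bv]][sample_idx], "nmi"))
    }
    if (!all(is.na(st)) && length(batch_vars) > 0) {
      push(embedding, clusterer, k, resample_id, "cnmi",
        as.numeric(cnmi(lab, st, clin[[batch_vars[1]]][sample_idx])))
    }
    eg <- compute_eigengenes(expr[, sample_idx, drop = FALSE], modules)
    push(embedding, clusterer, k, resample_id, "module_score",
      as.numeric(module_score(eg, lab, alpha = config$alpha,
        beta = config$beta)))
    cl <- cox_lrt(clin[sample_idx, , drop = FALSE], lab,
      covariates = config$covariates, followup_cap = config$followup_cap)
    push(embedding, clusterer, k, resample_id, "survival_p", cl$p_value)
  }

  for (emb_name in names(config$embeddings)) {
    spec <- config$embeddings[[emb_name]]
    ffun <- feature_fn(spec, knowledge)
    for (clusterer in config$clusterers) {
      if (!combo_compatible(spec, clusterer)) {
        message(sprintf(
          "skipping %s + %s: clusterer requires Euclidean features",
          emb_name, clusterer))
        next
      }
      for (k in config$k_range) {
        ref <- tryCatch({
          feats <- ffun(expr, derive_seed(config$seed, emb_name, "feat", 0))
          fit <- cluster_features(feats, clusterer, k,
            derive_seed(config$seed, emb_name, clusterer, k, 0))
          list(features = feats, fit = fit)
        }, error = function(e) e)
        if (inherits(ref, "error")) {
          warn(sprintf("combination %s/%s/k=%d failed on full data: %s",
            emb_name, clusterer, k, conditionMessage(ref)))
          next
        }
        measure(ref$features, ref$fit, seq_len(n), emb_name, clusterer,
          k, 0L)

        rid <- 0L
        for (rep_i in seq_len(config$repeats)) {
          fold_of <- with_seed(
            derive_seed(config$seed, "folds", rep_i),
            sample(rep(seq_len(config$folds), length.out = n)))
          for (fold_i in seq_len(config$folds)) {
            rid <- rid + 1L
            retain <- which(fold_of != fold_i)
            res <- tryCatch({
              sub <- expr[, retain, drop = FALSE]
              feats <- ffun(sub,
                derive_seed(config$seed, emb_name, "feat", rid))
              fit <- cluster_features(feats, clusterer, k,
                derive_seed(config$seed, emb_name, clusterer, k, rid))
              list(features = feats, fit = fit)
            }, error = function(e) e)
            if (inherits(res, "error")) {
              push(emb_name, clusterer, k, rid, "stability_jaccard",
                NA_real_)
              next
            }
            ref_sub <- ref$fit$labels[retain]
            push(emb_name, clusterer, k, rid, "stability_jaccard",
              coclustering_jaccard(res$fit$labels, ref_sub))
            push(emb_name, clusterer, k, rid, "stability_ari",
              label_agreement(res$fit$labels, ref_sub, "ari"))
            measure(res$features, res$fit, retain, emb_name, clusterer,
              k, rid)
          }
        }
      }
    }
  }
  dplyr::bind_rows(records)
}

#' Aggregate a long metric table per combination
#'
#' Means and SDs per (embedding, clusterer, k, metric) over resamples
#' (the full-data reference record, `resample_id = 0`, is excluded).
#' Survival p-values additionally aggregate as the median of `-log10 p`
#' (derived metric `survival_nlp`), and a derived `batch_inverse =
#' 1 - mean batch NMI` makes all selection criteria point the same way.
#'
#' @param table Long metric tibble from [run_benchmark()].
#' @return Tibble (`embedding`, `clusterer`, `k`, `metric`, `value`, `sd`,
#'   `n`).
#' @export
aggregate_metrics <- function(table) {
  tab <- dplyr::filter(as_tibble(table), .data$resample_id > 0)
  if (nrow(tab) == 0) tab <- as_tibble(table)
  base <- tab |>
    dplyr::group_by(.data$embedding, .data$clusterer, .data$k,
      .data$metric) |>
    dplyr::summarise(
      value = mean(.data$value, na.rm = TRUE),
      sd = ifelse(sum(!is.na(.data$value)) > 1,
        sd(.data$value, na.rm = TRUE), 0),
      n = sum(!is.na(.data$value)),
      .groups = "drop")
  surv <- tab |>
    dplyr::filter(.data$metric == "survival_p", !is.na(.data$value)) |>
    dplyr::group_by(.data$embedding, .data$clusterer, .data$k) |>
    dplyr::summarise(
      metric = "survival_nlp",
      value = median(-log10(.data$value)),
      sd = ifelse(dplyr::n() > 1, sd(-log10(.data$value)), 0),
      n = dplyr::n(), .groups = "drop")
  batch <- base |>
    dplyr::filter(.data$metric == "nmi_batch") |>
    dplyr::mutate(metric = "batch_inverse", value = 1 - .data$value)
  dplyr::bind_rows(base, surv, batch) |>
    dplyr::arrange(.data$embedding, .data$clusterer, .data$k, .data$metric)
}

scale_01 <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) {
    return(rep(0, length(x)))
  }
  (x - rng[1]) / diff(rng)
}

#' Best clusterer per embedding by summed criteria
#'
#' Min-max scales each selected metric to `[0, 1]` across all
#' combinations (flipping minimized metrics), sums them, averages the sum
#' over k per (embedding, clusterer), and returns the best clusterer for
#' each embedding. Ties break by stability, then silhouette, then
#' lexicographic clusterer name (flagged).
#'
#' @param aggregated Output of [aggregate_metrics()].
#' @param metrics Criteria entering the sum; default the five-criterion
#'   protocol: silhouette, stability (Jaccard), batch inverse, module
#'   score, survival relevance.
#' @param directions Named direction overrides (see
#'   [metric_directions()]).
#' @return Tibble (`embedding`, `clusterer`, `sum_score`, `tie`).
#' @export
best_by_sum <- function(aggregated,
                        metrics = c("silhouette", "stability_jaccard",
                          "batch_inverse", "module_score",
                          "survival_nlp"),
                        directions = metric_directions()) {
  present <- intersect(metrics, unique(aggregated$metric))
  missing <- setdiff(metrics, present)
  if (length(missing) > 0) {
    warn(sprintf("metric(s) absent from table, dropped from the sum: %s",
      paste(missing, collapse = ", ")))
  }
  assert_that(length(present) > 0, "no selected metric present")
  wide <- aggregated |>
    dplyr::filter(.data$metric %in% present) |>
    dplyr::select("embedding", "clusterer", "k", "metric", "value") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value")
  for (m in present) {
    x <- wide[[m]]
    if (length(unique(x[!is.na(x)])) <= 1) {
      warn(sprintf("metric '%s' constant across combinations; contributes 0",
        m))
    }
    x <- scale_01(x)
    if (identical(directions[[m]], "minimize")) x <- 1 - x
    wide[[paste0(".s_", m)]] <- x
  }
  wide$sum_score <- rowSums(wide[paste0(".s_", present)], na.rm = TRUE)
  per <- wide |>
    dplyr::group_by(.data$embedding, .data$clusterer) |>
    dplyr::summarise(
      sum_score = mean(.data$sum_score),
      stability = if ("stability_jaccard" %in% present) {
        mean(.data$stability_jaccard, na.rm = TRUE)
      } else {
        NA_real_
      },
      silhouette = if ("silhouette" %in% present) {
        mean(.data$silhouette, na.rm = TRUE)
      } else {
        NA_real_
      },
      .groups = "drop")
  per |>
    dplyr::group_by(.data$embedding) |>
    dplyr::group_modify(function(g, key) {
      ord <- order(-g$sum_score, -replace(g$stability, is.na(g$stability), -Inf),
        -replace(g$silhouette, is.na(g$silhouette), -Inf), g$clusterer)
      g <- g[ord, , drop = FALSE]
      tie <- nrow(g) > 1 && isTRUE(all.equal(g$sum_score[1], g$sum_score[2]))
      tibble(clusterer = g$clusterer[1], sum_score = g$sum_score[1],
        tie = tie)
    }) |>
    dplyr::ungroup()
}

#' First Pareto frontier of method combinations
#'
#' Returns every combination not dominated by any other, where combination
#' A dominates B when A is at least as good on every criterion (after
#' direction alignment) and strictly better on at least one.
#'
#' @param criteria A numeric matrix (combinations x criteria) or a data
#'   frame whose numeric columns are the criteria (id columns preserved).
#' @param directions Per-criterion `"maximize"`/`"minimize"`; either a
#'   vector matching the criteria columns or a named vector (defaults to
#'   [metric_directions()] lookups, `"maximize"` for unknown names).
#' @return A `pareto_front` list: `front` (row indices, input order),
#'   `dominated` (indices), and `criteria` (the aligned matrix). When
#'   `criteria` is a data frame, `$table` holds its front rows.
#' @export
pareto_front <- function(criteria, directions = NULL) {
  df <- NULL
  if (is.data.frame(criteria)) {
    df <- as_tibble(criteria)
    num <- vapply(df, is.numeric, TRUE)
    if ("k" %in% names(num)) num["k"] <- FALSE
    mat <- as.matrix(df[, num, drop = FALSE])
  } else {
    mat <- as.matrix(criteria)
  }
  assert_that(nrow(mat) >= 1 && ncol(mat) >= 2,
    "need >= 1 combination and >= 2 criteria")
  if (is.null(directions)) {
    reg <- metric_directions()
    directions <- unname(reg[colnames(mat) %||% character(ncol(mat))])
    directions[is.na(directions)] <- "maximize"
    if (length(directions) == 0) directions <- rep("maximize", ncol(mat))
  }
  if (length(directions) == 1) directions <- rep(directions, ncol(mat))
  aligned <- mat
  for (j in seq_len(ncol(mat))) {
    if (identical(directions[[j]], "minimize")) aligned[, j] <- -aligned[, j]
  }
  n <- nrow(aligned)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(aligned[j, ] >= aligned[i, ]) &&
          any(aligned[j, ] > aligned[i, ])) {
        dominated[i] <- TRUE
        break
      }
    }
  }
  out <- list(front = which(!dominated), dominated = which(dominated),
    criteria = aligned)
  if (!is.null(df)) out$table <- df[!dominated, , drop = FALSE]
  structure(out, class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("<pareto_front> %d of %d combinations non-dominated\n",
    length(x$front), nrow(x$criteria)))
  invisible(x)
}
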