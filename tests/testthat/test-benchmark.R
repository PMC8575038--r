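small_cohort <- function(seed = 17) {
  simulate_cohort(n_genes = 60, n_samples = 36, k_subtypes = 2,
    n_modules = 4, seed = seed)
}

small_config <- function(...) {
  benchmark_config(
    embeddings = list(pca2 = list(method = "pca", n_dims = 2)),
    clusterers = "kmeans", k_range = 2:3, folds = 2, repeats = 2,
    module_power = 2, module_min_size = 5, seed = 5, ...)
}

test_that("configuration is validated up front", {
  expect_error(benchmark_config(list(), "kmeans"),
    class = "stratabench_config_error")
  expect_error(
    benchmark_config(list(e = list(method = "nope")), "kmeans"),
    class = "stratabench_config_error")
  expect_error(
    benchmark_config(list(e = list(method = "pca")), "kmedoids"),
    class = "stratabench_config_error")
  expect_error(
    benchmark_config(list(e = list(method = "pca")), "kmeans", k_range = 1:3),
    class = "stratabench_config_error")
  expect_error(
    benchmark_config(list(e = list(method = "pca")), "kmeans", folds = 1),
    class = "stratabench_config_error")
  # BK-CL embeddings demand knowledge inputs
  co <- small_cohort()
  cfg <- benchmark_config(
    embeddings = list(bk = list(method = "rwr_fgsea")),
    clusterers = "diana", k_range = 2, folds = 2, repeats = 1)
  expect_error(run_benchmark(co$expression, co$clinical, cfg),
    class = "stratabench_config_error")
})

test_that("the grid yields folds x repeats resample records per metric", {
  co <- small_cohort()
  cfg <- small_config()
  tab <- suppressWarnings(
    run_benchmark(co$expression, co$clinical, cfg))
  counts <- tab |>
    dplyr::filter(.data$resample_id > 0) |>
    dplyr::count(.data$embedding, .data$clusterer, .data$k, .data$metric)
  # 2 folds x 2 repeats = 4 resample records for every metric and k
  expect_true(all(counts$n == 4))
  expect_setequal(unique(counts$k), 2:3)
  # reference records exist (resample_id 0) for non-stability metrics
  ref <- tab |> dplyr::filter(.data$resample_id == 0)
  expect_true(all(c("silhouette", "nmi_subtype", "cnmi", "module_score",
    "survival_p") %in% ref$metric))
})

test_that("the benchmark is deterministic given config and seed", {
  co <- small_cohort()
  cfg <- small_config()
  t1 <- suppressWarnings(run_benchmark(co$expression, co$clinical, cfg))
  t2 <- suppressWarnings(run_benchmark(co$expression, co$clinical, cfg))
  expect_identical(t1, t2)
})

test_that("aggregation matches a group-by oracle and transforms survival", {
  set.seed(8)
  tab <- tidyr::expand_grid(
    embedding = c("e1", "e2"), clusterer = "diana", k = 2:3,
    resample_id = 1:5, metric = c("silhouette", "survival_p"))
  tab$value <- runif(nrow(tab))
  agg <- aggregate_metrics(tab)

  # arithmetic-mean oracle for the plain metric
  orc <- aggregate(value ~ embedding + k,
    data = tab[tab$metric == "silhouette", ], FUN = mean)
  for (i in seq_len(nrow(orc))) {
    got <- agg$value[agg$embedding == orc$embedding[i] &
      agg$k == orc$k[i] & agg$metric == "silhouette"]
    expect_equal(got, orc$value[i], tolerance = 1e-12)
  }
  # survival aggregates as median -log10 p under a derived metric
  sub <- tab[tab$metric == "survival_p" & tab$embedding == "e1" &
    tab$k == 2, ]
  got <- agg$value[agg$embedding == "e1" & agg$k == 2 &
    agg$metric == "survival_nlp"]
  expect_equal(got, median(-log10(sub$value)), tolerance = 1e-12)

  # single record: mean = value, sd = 0
  one <- tibble::tibble(embedding = "e", clusterer = "c", k = 2L,
    resample_id = 1L, metric = "silhouette", value = 0.4)
  agg1 <- aggregate_metrics(one)
  expect_equal(agg1$value, 0.4)
  expect_equal(agg1$sd, 0)
})

test_that("best-by-sum scales, sums and breaks ties as documented", {
  agg <- tibble::tibble(
    embedding = "e1",
    clusterer = rep(c("a", "b", "c"), each = 2),
    k = rep(2:3, 3),
    metric = rep("silhouette", 6),
    value = c(0.9, 0.8, 0.3, 0.2, 0.5, 0.4),
    sd = 0, n = 4) |>
    dplyr::bind_rows(tibble::tibble(
      embedding = "e1", clusterer = rep(c("a", "b", "c"), each = 2),
      k = rep(2:3, 3), metric = "stability_jaccard",
      value = c(1, 0.9, 0.6, 0.5, 0.7, 0.6), sd = 0, n = 4))
  best <- suppressWarnings(best_by_sum(agg,
    metrics = c("silhouette", "stability_jaccard")))
  # hand-computed min-max scaled sums: a dominates everywhere
  expect_equal(best$clusterer, "a")
  expect_false(best$tie)

  # identical combinations tie and resolve lexicographically
  agg2 <- agg
  agg2$value[agg2$clusterer == "b"] <- agg2$value[agg2$clusterer == "a"]
  best2 <- suppressWarnings(best_by_sum(agg2,
    metrics = c("silhouette", "stability_jaccard")))
  expect_equal(best2$clusterer, "a")
  expect_true(best2$tie)
})

test_that("the Pareto front equals the dominance oracle", {
  # worked example: maximizing both coordinates
  mat <- rbind(c(1, 2), c(2, 1), c(0, 0))
  pf <- pareto_front(mat, directions = "maximize")
  expect_equal(pf$front, c(1, 2))

  expect_equal(pareto_front(rbind(c(1, 1)), "maximize")$front, 1)

  for (sd in 1:20) {
    set.seed(sd)
    nc <- sample(2:5, 1)
    m <- matrix(runif(sample(50:200, 1) * nc), ncol = nc)
    pf <- pareto_front(m, directions = "maximize")
    expect_equal(pf$front, pareto_oracle(m))
  }

  # row order invariance (up to the index mapping)
  set.seed(99)
  m <- matrix(runif(60), ncol = 3)
  perm <- sample(nrow(m))
  f1 <- pareto_front(m, "maximize")$front
  f2 <- pareto_front(m[perm, ], "maximize")$front
  expect_setequal(perm[f2], f1)
})

test_that("a pure-noise embedding never reaches the Pareto front", {
  on_front <- vapply(1:5, function(sd) {
    co <- simulate_cohort(n_genes = 60, n_samples = 40, k_subtypes = 2,
      n_modules = 4, seed = sd)
    cfg <- benchmark_config(
      embeddings = list(
        pca2 = list(method = "pca", n_dims = 2),
        noise = list(method = "pca", n_dims = 2)),
      clusterers = "kmeans", k_range = 2, folds = 2, repeats = 2,
      module_power = 2, module_min_size = 5, seed = sd)
    # corrupt the second embedding by destroying the signal: the noise
    # embedding sees a permuted expression matrix
    expr_noise <- co$expression
    set.seed(sd)
    expr_noise[] <- sample(expr_noise)
    tab1 <- suppressWarnings(run_benchmark(co$expression, co$clinical,
      benchmark_config(embeddings = list(pca2 = list(method = "pca",
        n_dims = 2)), clusterers = "kmeans", k_range = 2, folds = 2,
        repeats = 2, module_power = 2, module_min_size = 5, seed = sd)))
    tab2 <- suppressWarnings(run_benchmark(expr_noise, co$clinical,
      benchmark_config(embeddings = list(noise = list(method = "pca",
        n_dims = 2)), clusterers = "kmeans", k_range = 2, folds = 2,
        repeats = 2, module_power = 2, module_min_size = 5, seed = sd)))
    agg <- aggregate_metrics(dplyr::bind_rows(tab1, tab2))
    wide <- agg |>
      dplyr::filter(.data$metric %in% c("nmi_subtype", "module_score",
        "survival_nlp")) |>
      dplyr::select("embedding", "clusterer", "k", "metric", "value") |>
      tidyr::pivot_wider(names_from = "metric", values_from = "value")
    pf <- pareto_front(wide)
    "noise" %in% pf$table$embedding
  }, TRUE)
  expect_equal(sum(on_front), 0)
})
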