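make_diss <- function(d) {
  structure(d, class = c("dissimilarity", "matrix", "array"))
}

test_that("silhouette matches hand computation and the per-point oracle", {
  # two tight, far-apart pairs on a line: 0, 0.1, 10, 10.1
  pts <- c(0, 0.1, 10, 10.1)
  d <- abs(outer(pts, pts, "-"))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_gte(silhouette_width(make_diss(d), c(1, 1, 2, 2)), 0.95)

  # coincident points split arbitrarily: a = b = 0 convention gives 0
  d0 <- matrix(0, 4, 4)
  expect_equal(silhouette_width(make_diss(d0), c(1, 1, 2, 2)), 0)

  # random instances against the oracle, and the reference implementation
  for (sd in 1:5) {
    set.seed(sd)
    x <- matrix(rnorm(40), 20, 2)
    d <- as.matrix(dist(x))
    labels <- sample(1:3, 20, replace = TRUE)
    if (length(unique(labels)) < 2) next
    mine <- silhouette_width(make_diss(d), labels)
    expect_equal(mine, silhouette_oracle(d, labels), tolerance = 1e-12)
    if (requireNamespace("cluster", quietly = TRUE)) {
      ref <- mean(cluster::silhouette(labels, dmatrix = d)[, "sil_width"])
      expect_equal(mine, ref, tolerance = 1e-12)
    }
  }
  expect_error(silhouette_width(make_diss(d0), rep(1, 4)),
    class = "stratabench_value_error")
})

test_that("NMI and ARI match their contingency-table oracles", {
  expect_equal(label_agreement(c(1, 1, 2, 2), c(1, 1, 2, 2), "nmi"), 1)
  expect_equal(label_agreement(c(1, 1, 2, 2), c(2, 2, 1, 1), "ari"), 1)
  # zero-entropy convention
  expect_equal(label_agreement(c(1, 2, 1, 2), rep(1, 4), "nmi"), 0)

  # the two canonical 4-point contingency cases
  expect_equal(label_agreement(c(1, 1, 2, 2), c(1, 2, 1, 2), "ari"),
    ari_oracle(c(1, 1, 2, 2), c(1, 2, 1, 2)), tolerance = 1e-12)

  for (sd in 1:10) {
    set.seed(sd)
    a <- sample(1:3, 25, replace = TRUE)
    b <- sample(1:4, 25, replace = TRUE)
    expect_equal(label_agreement(a, b, "nmi"), nmi_oracle(a, b),
      tolerance = 1e-12)
    expect_equal(label_agreement(a, b, "ari"), ari_oracle(a, b),
      tolerance = 1e-12)
    expect_equal(label_agreement(a, b, "ari"),
      mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_error(label_agreement(1:3, 1:4), class = "stratabench_value_error")
})

test_that("cNMI has the documented limit and symmetry behavior", {
  set.seed(2)
  n <- 400
  subtype <- sample(1:3, n, replace = TRUE)
  batch <- sample(1:2, n, replace = TRUE)  # independent of subtype
  expect_gte(cnmi(subtype, subtype, batch), 0.9)   # ~ +1
  expect_lte(cnmi(batch, subtype, batch), -0.9)    # ~ -1
  expect_equal(as.numeric(cnmi(subtype, subtype, subtype)), 0)

  # antisymmetry in the two reference labelings
  labels <- sample(1:3, n, replace = TRUE)
  expect_equal(as.numeric(cnmi(labels, subtype, batch)),
    -as.numeric(cnmi(labels, batch, subtype)), tolerance = 1e-12)

  expect_error(cnmi(labels, rep(NA, n), batch),
    class = "stratabench_missing_error")
})

test_that("co-clustering Jaccard matches pair enumeration", {
  expect_equal(coclustering_jaccard(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(coclustering_jaccard(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(coclustering_jaccard(c(1, 1, 1), c(1, 1, 2)), 1 / 3,
    tolerance = 1e-12)
  expect_equal(coclustering_jaccard(1:4, 4:1), 1)  # all singletons

  for (sd in 1:10) {
    set.seed(sd)
    a <- sample(1:3, 15, replace = TRUE)
    b <- sample(1:3, 15, replace = TRUE)
    expect_equal(coclustering_jaccard(a, b), jaccard_oracle(a, b),
      tolerance = 1e-12)
    # symmetry and label-permutation invariance
    expect_equal(coclustering_jaccard(a, b), coclustering_jaccard(b, a))
    expect_equal(coclustering_jaccard(a, b),
      coclustering_jaccard(4 - a, b))
  }
})

test_that("module score reproduces the defining hand cases", {
  set.seed(6)
  n <- 40
  labels <- rep(1:2, each = n / 2)
  # one module tracking cluster 1: with binary indicators the correlation
  # with c2 is the exact negative, so S+ = S- = 1 and the value is 1
  e <- as.numeric(labels == 1) + rnorm(n, sd = 0.05)
  em <- cbind(ME1 = e)
  expect_equal(as.numeric(module_score(em, labels, alpha = 0.5)), 1)

  # two positively-tracked clusters and none past -alpha: (1 + 0)/2 = 0.5
  # (k = 5 so the complement clusters stay above the negative threshold)
  labels5 <- rep(1:5, each = 10)
  e5 <- as.numeric(labels5 %in% c(1, 2))  # rho ~ +0.61 with c1, c2; -0.41 others
  expect_equal(
    as.numeric(module_score(cbind(ME1 = e5), labels5, alpha = 0.5)), 0.5)

  # no association anywhere falls back to beta
  e0 <- rnorm(40)
  expect_equal(
    as.numeric(module_score(cbind(ME1 = e0), labels, alpha = 0.99,
      beta = 0)), 0)
  expect_equal(
    as.numeric(module_score(cbind(ME1 = e0), labels, alpha = 0.99,
      beta = 0.25)), 0.25)
})

test_that("module score equals the brute-force oracle on random instances", {
  worst <- 0
  for (sd in 1:30) {
    set.seed(sd)
    n <- sample(20:40, 1)
    n_mod <- sample(1:6, 1)
    k <- sample(2:5, 1)
    em <- matrix(rnorm(n * n_mod), n, n_mod)
    labels <- sample(seq_len(k), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    alpha <- runif(1, 0.1, 0.7)
    mine <- as.numeric(module_score(em, labels, alpha = alpha, beta = 0))
    canon <- match(labels, unique(labels))
    orc <- module_score_oracle(em, canon, alpha, 0)
    worst <- max(worst, abs(mine - orc))
  }
  expect_lt(worst, 1e-12)
})

test_that("informative pathway filter skips constants and calibrates", {
  set.seed(4)
  emb <- matrix(rnorm(20 * 60), 20, 60,
    dimnames = list(sprintf("P%02d", 1:20), sprintf("s%02d", 1:60)))
  labels <- rep(1:2, each = 30)
  emb["P01", ] <- labels * 2           # perfectly separating
  emb["P02", ] <- 1                    # constant -> skipped
  res <- informative_pathways(structure(emb, class = c("pathway_embedding",
    "matrix", "array")), labels, p_threshold = 1)
  expect_identical(attr(res, "skipped"), "P02")
  expect_identical(res$pathway[1], "P01")

  # permuted labels give uniform p-values
  pvals <- vapply(1:200, function(i) {
    set.seed(i)
    kruskal_p <- informative_pathways(
      structure(emb["P03", , drop = FALSE],
        class = c("pathway_embedding", "matrix", "array")),
      sample(labels), p_threshold = 1.0000001)$p_value
    kruskal_p[1]
  }, 0)
  # rank ties make the KW p-values discrete; the KS tie warning is expected
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("stability is exactly 1 for a resample-invariant pipeline", {
  expr <- random_expression(10, 30, seed = 5)
  hash_pipeline <- function(e, seed) {
    setNames(as.integer(substr(colnames(e), 4, 4) %in% c("1", "3", "5",
      "7", "9")) + 1L, colnames(e))
  }
  rep_ <- stability_resample(hash_pipeline, expr, folds = 5, repeats = 4,
    seed = 2)
  expect_equal(nrow(rep_), 20)
  expect_true(all(rep_$jaccard == 1))
  expect_true(all(rep_$ari == 1))
  g <- glance(rep_)
  expect_equal(g$mean_jaccard, 1)
  expect_equal(g$n_failed, 0)
})

test_that("stable pipelines score high on separated data", {
  co <- simulate_cohort(n_genes = 60, n_samples = 60, subtype_effect = 4,
    seed = 12)
  pipeline <- function(e, seed) {
    emb <- reduce_dimensionality(e, "pca", n_dims = 2)
    run_partitioner(emb, "kmeans", 3, seed = seed, n_start = 10)
  }
  rep_ <- stability_resample(pipeline, co$expression, folds = 5,
    repeats = 4, seed = 3)
  expect_gte(mean(rep_$jaccard), 0.9)
})

test_that("Cox LRT has the right df, detects effects and respects nesting", {
  co <- simulate_cohort(n_samples = 100, seed = 31)
  res <- cox_lrt(co$clinical,
    setNames(co$truth$true_subtype, co$clinical$sample_id))
  expect_equal(res$df, 2)  # k - 1
  expect_s3_class(glance(res), "tbl_df")

  # cluster labels identical to a baseline categorical covariate add no
  # information: statistic ~ 0, p ~ 1
  clin <- co$clinical
  clin$grp <- factor(co$truth$true_subtype)
  res0 <- suppressWarnings(cox_lrt(clin,
    setNames(co$truth$true_subtype, clin$sample_id), covariates = "grp"))
  expect_lt(res0$statistic, 1e-6)
  expect_gt(res0$p_value, 0.999)

  # follow-up cap excludes long-followup samples
  res_cap <- cox_lrt(co$clinical,
    setNames(co$truth$true_subtype, co$clinical$sample_id),
    followup_cap = stats::median(co$clinical$time))
  expect_lte(res_cap$n_used, ceiling(nrow(co$clinical) / 2) + 1)

  # power: HR 3 at n = 300 with ~30% censoring
  hits <- vapply(1:30, function(sd) {
    subtype <- rep(1:2, each = 150)
    sv <- simulate_survival(subtype, c(1, 3), seed = sd)
    clin <- tibble::tibble(sample_id = paste0("s", 1:300), time = sv$time,
      event = sv$event)
    cox_lrt(clin, setNames(subtype, clin$sample_id))$p_value < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
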