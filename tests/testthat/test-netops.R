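test_that("hard and soft adjacency follow the correlation rules", {
  set.seed(1)
  base <- rnorm(30)
  expr <- rbind(g1 = base, g2 = base * 2 + 1,     # perfectly correlated
    g3 = rnorm(30), g4 = rnorm(30))
  colnames(expr) <- paste0("s", 1:30)
  hard <- build_adjacency(expr, "hard", 0.475)
  expect_equal(hard$adjacency["g1", "g2"], 1)
  expect_true(all(hard$adjacency %in% c(0, 1)))

  soft <- build_adjacency(expr, "soft", 1)
  expect_equal(soft$adjacency["g1", "g2"], 1, tolerance = 1e-12)
  soft6 <- build_adjacency(expr, "soft", 6)
  expect_equal(soft6$adjacency, soft$adjacency^6, tolerance = 1e-12,
    ignore_attr = TRUE)

  expect_error(build_adjacency(expr[, 1:2], "hard", 0.5),
    class = "stratabench_value_error")
})

test_that("raising the hard threshold never adds edges", {
  expr <- random_expression(25, 20, seed = 3)
  prev <- NULL
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    net <- build_adjacency(expr, "hard", thr)
    if (!is.null(prev)) {
      expect_true(all(net$adjacency <= prev))
    }
    prev <- net$adjacency
  }
  # threshold near 1 on noise-only data leaves (almost surely) no edges
  expect_equal(sum(build_adjacency(expr, "hard", 0.999)$adjacency), 0)
})

test_that("scale-free fit index separates power-law from regular/random", {
  # degrees drawn exactly as p(k) proportional to k^-2
  k <- 1:100
  counts <- round(1e5 * k^(-2))
  degrees <- rep(k, counts)
  r2_power <- scale_free_r2(degrees)
  expect_gte(r2_power, 0.95)

  expect_error(scale_free_r2(rep(4, 50)),
    class = "stratabench_degenerate_error")

  set.seed(42)
  er <- igraph::sample_gnp(1000, 0.01)
  r2_er <- scale_free_r2(igraph::degree(er))
  expect_lt(r2_er, r2_power)
})

test_that("threshold tuning picks the smallest parameter reaching the target", {
  # synthetic diagnostics path: modular expression reaches high R^2 at a
  # moderate threshold
  co <- simulate_cohort(n_genes = 100, n_samples = 60, seed = 9)
  tuned <- suppressWarnings(
    tune_threshold(co$expression, "hard", grid = c(0.3, 0.5, 0.7, 0.9),
      r2_target = 0.5))
  expect_s3_class(tuned, "threshold_tuning")
  diag_tab <- tidy(tuned)
  expect_equal(nrow(diag_tab), 4)
  if (tuned$reached_target) {
    ok <- which(!is.na(diag_tab$r2) & diag_tab$r2 >= 0.5)
    expect_equal(tuned$param, diag_tab$param[ok[1]])
  }

  # grid of one value returns that value
  one <- suppressWarnings(tune_threshold(co$expression, "hard",
    grid = 0.5, r2_target = 0))
  expect_equal(one$param, 0.5)

  # unreachable target sets the warning flag and returns the argmax
  expect_warning(
    best <- tune_threshold(co$expression, "hard", grid = c(0.3, 0.5),
      r2_target = 0.999),
    "no candidate")
  expect_false(best$reached_target)
  d2 <- tidy(best)
  expect_equal(best$param, d2$param[which.max(d2$r2)])
})

test_that("TOM matches the closed form and the brute-force oracle", {
  # complete graph: off-diagonal TOM identically 1
  for (n in c(5, 9)) {
    a <- matrix(1, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
    diag(a) <- 0
    tom <- tom_similarity(new_gene_network(a))
    expect_equal(unname(tom), matrix(1, n, n), tolerance = 1e-12)
  }

  # no edge, no shared neighbors -> 0
  a <- two_clique_adjacency(3, 3)
  tom <- tom_similarity(new_gene_network(a))
  expect_equal(tom["g1", "g4"], 0)

  # random weighted graphs against the triple loop, plus bounds/symmetry
  for (sd in 1:5) {
    a <- random_graph_adjacency(12, p = 0.4, weighted = TRUE, seed = sd)
    tom <- tom_similarity(new_gene_network(a))
    expect_equal(tom, tom_oracle(a), tolerance = 1e-12)
    expect_equal(tom, t(tom), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }

  bad <- two_clique_adjacency(3, 3) * 2
  expect_error(tom_similarity(new_gene_network(bad)),
    class = "stratabench_value_error")
})

test_that("module detection recovers planted cliques and honors limits", {
  a <- two_clique_adjacency(10, 10)
  tom <- tom_similarity(new_gene_network(a))
  mods <- detect_modules(tom, min_module_size = 5, cut_height = 0.5)
  expect_equal(length(attr(mods, "sizes")), 2)
  expect_equal(label_agreement(unclass(mods), rep(1:2, each = 10), "ari"), 1)

  # cut at full height keeps everything together
  all_one <- detect_modules(tom, min_module_size = 5, cut_height = 1.0)
  expect_equal(length(attr(all_one, "sizes")), 1)
  expect_true(all(unclass(all_one) == 1))

  # min size above n leaves all genes unassigned
  expect_warning(none <- detect_modules(tom[1:4, 1:4], min_module_size = 10),
    "unassigned")
  expect_true(all(unclass(none) == 0))
})

test_that("module detection recovers planted partitions from cohort data", {
  hits <- vapply(1:20, function(sd) {
    co <- simulate_cohort(n_genes = 100, n_samples = 30, seed = sd,
      module_fraction = 1, n_modules = 4)
    kn <- simulate_knowledge(co$truth, p_in = 0.9, p_out = 0.02, seed = sd)
    tom <- tom_similarity(kn$network)
    mods <- detect_modules(tom, min_module_size = 10, cut_height = 0.9)
    truth <- co$truth$true_modules[names(mods)]
    label_agreement(unclass(mods), truth, "ari") >= 0.9
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("eigen-genes match the eigendecomposition oracle and align sign", {
  # module of identical genes: eigen-gene correlates 1 with each member
  base <- rnorm(30)
  expr <- rbind(g1 = base, g2 = base, g3 = base, g4 = rnorm(30))
  colnames(expr) <- paste0("s", 1:30)
  mods <- setNames(c(1L, 1L, 1L, 0L), rownames(expr))
  eg <- compute_eigengenes(expr, mods)
  expect_equal(abs(cor(eg[, 1], base)), 1, tolerance = 1e-10)
  expect_gte(cor(eg[, 1], base), 0)  # sign-aligned with the mean profile

  # negating the module genes negates the eigen-gene but keeps alignment
  eg_neg <- compute_eigengenes(-expr, mods)
  expect_gte(cor(eg_neg[, 1], rowMeans(scale(t(-expr[1:3, ])))), 0)

  # explained variance equals the top eigenvalue fraction of the
  # standardized module covariance (brute force)
  expr5 <- random_expression(5, 30, seed = 6)
  mods5 <- setNames(rep(1L, 5), rownames(expr5))
  eg5 <- compute_eigengenes(expr5, mods5)
  x <- scale(t(expr5))
  ev <- eigen(stats::cov(x))$values
  expect_equal(unname(attr(eg5, "var_explained")[1]),
    ev[1] * (nrow(x) - 1) / sum(ev * (nrow(x) - 1)), tolerance = 1e-10)
  expect_equal(sum(eg5[, 1]^2), 1, tolerance = 1e-10)  # unit norm

  # single-gene module flagged
  mods_s <- setNames(c(1L, 2L, 2L, 2L, 2L), rownames(expr5))
  expect_warning(eg_s <- compute_eigengenes(expr5, mods_s), "single gene")
  expect_true(attr(eg_s, "singleton")[["ME1"]])
})
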