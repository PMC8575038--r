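# stratabench

Disease-subtype discovery from bulk gene expression, and the benchmarking
protocol to judge it. `stratabench` implements two families of patient
stratification workflows — dimensionality-reduction clustering (DR-CL:
PCA-style embeddings, Euclidean geometry) and biological-knowledge-driven
clustering (BK-CL: pathway-level patient features, correlation distance) —
together with a five-criterion evaluation protocol and Pareto-front model
selection, all runnable end to end on seeded synthetic cohorts with known
ground truth.

## The core method

The package's centerpiece is a network-driven pathway enrichment feature
extractor. For each patient:

1. **Seeds** — a disease gene panel split by fold-change sign is ranked by
   the patient's standardized expression (per-gene z-scores); the top 50
   up- and down-regulated genes become the patient's seed sets.
2. **Diffusion** — each seed set starts a random walk with restart on a
   gene network, iterating `p <- (1 - r) W p + r p0` with restart
   `r = 0.75` and `W = D^(-1/2) A D^(-1/2)`; the fixed point scores every
   gene by network proximity to the patient's dysregulated genes.
3. **Enrichment** — the affinity vector is scored against a gene set
   collection by pre-ranked GSEA (weighted Kolmogorov–Smirnov running sum,
   permutation null, sign-matched NES).
4. **Embedding** — pathway scores `NES x (-log10 p)` form a sparse
   pathways x samples matrix; unenriched pathways vanish. Down-seed runs
   enter with negated NES, so score sign tracks regulation direction.

Downstream, the embedding (or a reduced expression matrix) is clustered —
including a full deterministic implementation of divisive hierarchical
clustering (DIANA) — and every (embedding, clusterer, k) combination is
scored on five criteria: average silhouette width; clustering stability
over 20 repeats of 5-fold cross-validation (co-clustering Jaccard / ARI
against the full-data reference); subtype concordance net of batch
association (NMI and cNMI = subtype NMI − batch NMI); a gene-module
relevance score built on co-expression eigen-genes,
`score = E[(min(1, S+) + min(1, S-)) / (S+ + S-)]` with `S±` counting
cluster indicators whose Spearman correlation with a module eigen-gene
passes `±alpha`; and survival relevance via a Cox proportional-hazards
likelihood-ratio test (`2 (ll_alt - ll_base)`, `k - 1` df). Non-dominated
combinations form the first Pareto frontier.

A seeded generator (`simulate_cohort()`, `simulate_knowledge()`,
`simulate_survival()`) produces module-structured expression with planted
subtypes, batch effects, aligned gene sets, a planted-partition gene
network and cluster-dependent survival, so the full pipeline is testable
without any external data.

## Worked example

```r
library(stratabench)

cohort    <- simulate_cohort(seed = 42)                 # 200 genes x 120 samples, 3 subtypes
knowledge <- simulate_knowledge(cohort$truth, seed = 42)

emb <- rwr_fgsea_embedding(cohort$expression, knowledge$network,
  cohort$truth$up_genes, cohort$truth$down_genes, knowledge$sets,
  n_perm = 250, seed = 42)

fit <- diana_cluster(correlation_dissimilarity(emb), k = 3)
fit
#> <cluster_fit> diana, k=3, sizes: 42/40/38

label_agreement(fit, cohort$truth$true_subtype[names(fit$labels)], "nmi")
#> [1] 0.9392836

cox_lrt(cohort$clinical, fit$labels, covariates = "age")
#> <cox_lrt> chi^2 = 15.455 on 2 df, p = 0.000441 (n = 120, events = 77)

net <- build_adjacency(cohort$expression, "soft", 6)
mods <- detect_modules(tom_similarity(net), min_module_size = 10)
eg  <- compute_eigengenes(cohort$expression, mods)
module_score(eg, fit$labels, alpha = 0.5)
#> [1] 1

head(informative_pathways(emb, fit, p_threshold = 0.01), 3)
#> # A tibble: 3 x 4
#>   pathway statistic  p_value p_adjusted
#>   <chr>       <dbl>    <dbl>      <dbl>
#> 1 SET02       101.  1.11e-22   2.21e-21
#> 2 SET05        97.4 7.21e-22   7.21e-21
#> 3 SET17        94.4 3.23e-21   2.15e-20
```

The clustering recovers the three planted subtypes almost perfectly
(NMI 0.94), separates survival beyond the age covariate (LRT p = 4.4e-4),
attains the maximal module relevance score, and the module-aligned gene
sets dominate the informative-pathway ranking.

The grid runner ties everything together:

```r
cfg <- benchmark_config(
  embeddings = list(pca2 = list(method = "pca", n_dims = 2),
                    bk   = list(method = "rwr_fgsea", n_perm = 250)),
  clusterers = c("kmeans", "diana", "hc_average"),
  k_range = 2:4, covariates = "age", seed = 1)
metrics <- run_benchmark(cohort$expression, cohort$clinical, cfg,
  knowledge = list(network = knowledge$network, sets = knowledge$sets,
    up_genes = cohort$truth$up_genes, down_genes = cohort$truth$down_genes))
agg <- aggregate_metrics(metrics)
best_by_sum(agg)                     # best clusterer per embedding
wide <- agg |>
  dplyr::filter(metric %in% c("silhouette", "stability_jaccard",
    "batch_inverse", "module_score", "survival_nlp")) |>
  dplyr::select(embedding, clusterer, k, metric, value) |>
  tidyr::pivot_wider(names_from = metric, values_from = value)
pareto_front(wide)                   # first Pareto frontier
```

A thin command-line front end (`exec/subtype-bench`) exposes `simulate`
and `run` subcommands over YAML configurations.

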