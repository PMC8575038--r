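# Synthetic cohort generator. Expression follows a module latent-factor
# model: each gene module has one latent factor per sample, subtypes shift a
# subtype-specific subset of module factors, batches add constants to random
# gene subsets, and i.i.d. Gaussian noise sits on top. This gives
# co-expression module detection, eigen-genes and pathway enrichment real
# correlated structure to find, while batch and survival effects are planted
# with known ground truth. All draws come from named sub-streams derived
# from the seed, so outputs are fully deterministic.

#' Simulate a subtype-structured expression cohort
#'
#' Generates a log-scale expression matrix with `n_modules` correlated gene
#' modules, `k_subtypes` planted subtypes that shift subtype-specific module
#' factors by `subtype_effect` standard-deviation units, additive batch
#' effects, Gaussian noise, and a clinical table with cluster-dependent
#' exponential survival and an independent age covariate.
#'
#' Each subtype up-shifts one dedicated module and down-shifts another
#' (disjoint across subtypes when `n_modules >= 2 * k_subtypes`, the
#' default), so subtypes differ in how disease genes distribute over
#' modules. Modules up-shifted by some subtype (and down-shifted by none)
#' supply the up-regulated disease gene list, and conversely for the
#' down-regulated list — emulating a disease-gene panel split by
#' fold-change sign.
#'
#' @param n_genes,n_samples Cohort dimensions.
#' @param k_subtypes Number of planted subtypes (>= 2).
#' @param n_modules Number of correlated gene modules (default
#'   `2 * k_subtypes`, giving each subtype disjoint signature modules).
#' @param subtype_effect Module-factor shift per signature entry, in SD
#'   units of the latent factor.
#' @param batch_effect Additive batch offset scale, in SD units; 0 disables
#'   batch structure.
#' @param n_batches Levels of each batch variable.
#' @param n_batch_vars Number of batch variables (1 or 2; e.g. tissue
#'   source site and plate).
#' @param noise_sd Residual Gaussian noise SD.
#' @param module_fraction Fraction of genes assigned to modules; the rest
#'   are unstructured background genes.
#' @param hazard_ratios Per-subtype multiplicative hazards (first = 1);
#'   default evenly spaced from 1 to 3.
#' @param baseline_rate Baseline event rate, events per day.
#' @param censor_rate Independent exponential censoring rate; default
#'   `0.9 * baseline_rate` (roughly 30% censoring under the default hazard
#'   ratios).
#' @param seed Integer seed; outputs are deterministic given the seed.
#' @return A list with `expression` (genes x samples matrix), `clinical`
#'   (tibble: sample_id, time, event, subtype, batch, age, ...) and `truth`
#'   (list: true_subtype, true_batch, true_modules, up_genes, down_genes,
#'   hazard_ratios, signature matrix).
#' @examples
#' cohort <- simulate_cohort(n_genes = 60, n_samples = 30, seed = 1)
#' dim(cohort$expression)
#' @export
simulate_cohort <- function(n_genes = 200, n_samples = 120, k_subtypes = 3,
                            n_modules = 2 * k_subtypes, subtype_effect = 4,
                            batch_effect = 1, n_batches = 2,
                            n_batch_vars = 1, noise_sd = 1,
                            module_fraction = 0.8, hazard_ratios = NULL,
                            baseline_rate = 1 / 1500, censor_rate = NULL,
                            seed = 1) {
  assert_that(is_count(n_genes) && is_count(n_samples), "counts must be positive")
  assert_that(is_count(k_subtypes) && k_subtypes >= 2, "k_subtypes must be >= 2")
  assert_that(is_count(n_modules), "n_modules must be >= 1")
  assert_that(k_subtypes <= n_samples, "k_subtypes exceeds n_samples",
    class = "stratabench_value_error")
  assert_that(n_batch_vars %in% 1:2, "n_batch_vars must be 1 or 2")

  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n_samples))

  # gene -> module map (0 = unstructured background)
  n_mod_genes <- floor(module_fraction * n_genes)
  modules <- rep(0L, n_genes)
  modules[seq_len(n_mod_genes)] <- rep(seq_len(n_modules),
    length.out = n_mod_genes)
  modules <- sort(modules, decreasing = FALSE)
  names(modules) <- genes

  # balanced, shuffled subtype and batch labels
  subtype <- with_seed(derive_seed(seed, "subtype"),
    sample(rep(seq_len(k_subtypes), length.out = n_samples)))
  batches <- lapply(seq_len(n_batch_vars), function(v) {
    with_seed(derive_seed(seed, "batch", v),
      sample(rep(seq_len(n_batches), length.out = n_samples)))
  })

  # Subtype signatures over modules: each subtype up-shifts its own
  # dedicated module and down-shifts another, so every pair of subtypes
  # differs in how disease genes distribute across modules — the feature
  # that seed/diffusion (knowledge-driven) workflows can see. Fully
  # disjoint when n_modules >= 2 * k_subtypes (the default); smaller
  # module counts wrap around and subtypes then share signature modules.
  signature <- matrix(0L, k_subtypes, n_modules)
  for (t in seq_len(k_subtypes)) {
    up_m <- ((2 * (t - 1)) %% n_modules) + 1
    down_m <- ((2 * (t - 1) + 1) %% n_modules) + 1
    signature[t, up_m] <- signature[t, up_m] + 1L
    signature[t, down_m] <- signature[t, down_m] - 1L
  }

  # module latent factors and gene loadings
  z <- with_seed(derive_seed(seed, "factors"),
    matrix(rnorm(n_modules * n_samples), n_modules, n_samples))
  z <- z + t(signature[subtype, , drop = FALSE]) * subtype_effect
  loading <- with_seed(derive_seed(seed, "loadings"),
    runif(n_genes, 0.7, 1.0))

  expr <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples))
  in_mod <- modules > 0
  expr[in_mod, ] <- loading[in_mod] * z[modules[in_mod], , drop = FALSE]
  expr[!in_mod, ] <- with_seed(derive_seed(seed, "background"),
    matrix(rnorm(sum(!in_mod) * n_samples), sum(!in_mod), n_samples))
  expr <- expr + with_seed(derive_seed(seed, "noise"),
    matrix(rnorm(n_genes * n_samples, sd = noise_sd), n_genes, n_samples))

  # additive batch offsets on a random 30% gene subset per batch variable
  if (batch_effect > 0) {
    for (v in seq_len(n_batch_vars)) {
      affected <- with_seed(derive_seed(seed, "batchgenes", v),
        sample(n_genes, size = max(1, round(0.3 * n_genes))))
      centers <- seq(-1, 1, length.out = n_batches) * batch_effect
      expr[affected, ] <- expr[affected, ] +
        rep(centers[batches[[v]]], each = length(affected))
    }
  }

  # disease gene lists: a module is "up" when some subtype up-shifts it
  # and none down-shifts it, and conversely
  up_shift <- apply(signature, 2, max)
  down_shift <- apply(signature, 2, min)
  up_mods <- which(up_shift > 0 & down_shift >= 0)
  down_mods <- which(down_shift < 0 & up_shift <= 0)
  up_genes <- genes[in_mod][modules[in_mod] %in% up_mods]
  down_genes <- genes[in_mod][modules[in_mod] %in% down_mods]

  if (is.null(hazard_ratios)) {
    hazard_ratios <- seq(1, 3, length.out = k_subtypes)
  }
  assert_that(length(hazard_ratios) == k_subtypes && all(hazard_ratios > 0),
    "need one positive hazard ratio per subtype")
  if (is.null(censor_rate)) censor_rate <- 0.9 * baseline_rate
  surv <- simulate_survival(subtype, hazard_ratios,
    baseline_rate = baseline_rate, censor_rate = censor_rate,
    seed = derive_seed(seed, "survival"))

  age <- with_seed(derive_seed(seed, "age"), rnorm(n_samples, 60, 10))

  clinical <- tibble(
    sample_id = samples,
    time = surv$time,
    event = surv$event,
    has_survival = TRUE,
    subtype = paste0("S", subtype),
    batch = paste0("B", batches[[1]]),
    age = age
  )
  if (n_batch_vars == 2) clinical$batch2 <- paste0("P", batches[[2]])

  truth <- list(
    true_subtype = setNames(subtype, samples),
    true_batch = lapply(batches, setNames, samples),
    true_modules = modules,
    up_genes = up_genes,
    down_genes = down_genes,
    hazard_ratios = hazard_ratios,
    signature = signature
  )
  list(expression = expr, clinical = clinical, truth = truth)
}

#' Simulate module-aligned gene sets and a planted-partition gene network
#'
#' Gene sets: a fraction are "aligned", drawing 90% of their members from a
#' single true module and the rest uniformly; the remainder are uniform
#' random sets. The network is a planted-partition graph over the cohort's
#' genes: within-module edge probability `p_in`, all other pairs `p_out`.
#'
#' @param truth The `truth` component of [simulate_cohort()].
#' @param n_sets Number of gene sets (> 0).
#' @param aligned_fraction Fraction of sets aligned to a module.
#' @param set_size Integer range (min, max) of set sizes.
#' @param p_in,p_out Within-/between-module edge probabilities
#'   (`0 <= p_out < p_in <= 1`).
#' @param seed Integer seed.
#' @return A list with `sets` (named list of gene vectors; attribute
#'   `aligned_module` maps set -> module, NA for random sets) and `network`
#'   (a [gene_network()]).
#' @export
simulate_knowledge <- function(truth, n_sets = 20, aligned_fraction = 0.5,
                               set_size = c(10, 30), p_in = 0.9,
                               p_out = 0.02, seed = 1) {
  assert_that(is_count(n_sets), "n_sets must be a positive count",
    class = "stratabench_value_error")
  assert_that(aligned_fraction >= 0 && aligned_fraction <= 1,
    "aligned_fraction must be in [0,1]")
  assert_that(p_out >= 0 && p_out < p_in && p_in <= 1,
    "need 0 <= p_out < p_in <= 1")
  modules <- truth$true_modules
  genes <- names(modules)
  n_modules <- max(modules)

  n_aligned <- round(aligned_fraction * n_sets)
  sets <- with_seed(derive_seed(seed, "sets"), {
    lapply(seq_len(n_sets), function(i) {
      s <- sample(seq(set_size[1], set_size[2]), 1)
      if (i <= n_aligned) {
        m <- ((i - 1) %% n_modules) + 1
        pool <- genes[modules == m]
        # cap the size so the module can supply >= 90% of members
        s <- min(s, floor(length(pool) / 0.9))
        n_core <- ceiling(0.9 * s)
        core <- sample(pool, n_core)
        filler <- sample(setdiff(genes, core), s - n_core)
        c(core, filler)
      } else {
        sample(genes, min(s, length(genes)))
      }
    })
  })
  names(sets) <- sprintf("SET%02d", seq_len(n_sets))
  attr(sets, "aligned_module") <- setNames(
    c(((seq_len(n_aligned) - 1) %% n_modules) + 1,
      rep(NA_integer_, n_sets - n_aligned)),
    names(sets))

  adj <- with_seed(derive_seed(seed, "network"), {
    n <- length(genes)
    a <- matrix(0, n, n, dimnames = list(genes, genes))
    same <- outer(modules, modules, function(x, y) x == y & x > 0)
    prob <- ifelse(same, p_in, p_out)
    u <- matrix(0, n, n)
    ut <- upper.tri(u)
    u[ut] <- runif(sum(ut))
    a[ut] <- as.numeric(u[ut] < prob[ut])
    a + t(a)
  })
  list(sets = sets, network = new_gene_network(adj))
}

#' Simulate cluster-dependent exponential survival
#'
#' Event times are exponential with rate `baseline_rate * HR(subtype)`;
#' censoring is independent exponential with rate `censor_rate`. Observed
#' time is the minimum, the event indicator marks whether the event came
#' first.
#'
#' @param subtype Per-sample subtype labels (integer or character).
#' @param hazard_ratios One multiplier per subtype level (reference level
#'   HR = 1 by convention), named by level or given in level-sort order.
#' @param baseline_rate,censor_rate Positive rates, events per day.
#' @param seed Integer seed.
#' @return A tibble with columns `time` and `event`.
#' @export
simulate_survival <- function(subtype, hazard_ratios,
                              baseline_rate = 1 / 1500,
                              censor_rate = 0.9 / 1500, seed = 1) {
  assert_that(baseline_rate > 0 && censor_rate > 0, "rates must be > 0")
  levels_ <- sort(unique(as.character(subtype)))
  if (is.null(names(hazard_ratios))) {
    assert_that(length(hazard_ratios) == length(levels_),
      "need one hazard ratio per subtype level",
      class = "stratabench_value_error")
    names(hazard_ratios) <- levels_
  }
  unknown <- setdiff(as.character(subtype), names(hazard_ratios))
  assert_that(length(unknown) == 0,
    sprintf("unknown subtype label(s): %s", paste(unknown, collapse = ", ")),
    class = "stratabench_value_error")
  n <- length(subtype)
  rate <- baseline_rate * hazard_ratios[as.character(subtype)]
  with_seed(derive_seed(seed, "survtimes"), {
    t_event <- rexp(n, rate = rate)
    t_cens <- if (is.infinite(censor_rate)) rep(0, n) else rexp(n, censor_rate)
    tibble(
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
  })
}
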