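---
title: "Methods: network-driven pathway features and multi-criterion subtype evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-driven pathway features and multi-criterion subtype evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratabench)
```

## The problem

Molecular subtypes of a disease — groups of patients whose tumors share
expression programs, and often prognosis — are usually sought by clustering
gene expression profiles. Two families of workflows compete. *Dimensionality
reduction* workflows (DR-CL) compress the expression matrix (PCA, t-SNE,
UMAP) and cluster samples in the reduced space with Euclidean geometry.
*Biological-knowledge-driven* workflows (BK-CL) first translate each
patient's profile into pathway-level features using curated gene sets and
interaction networks, then cluster those features with correlation distance.
stratabench implements both, plus the evaluation protocol needed to compare
them fairly: separability, stability under resampling, concordance with
known subtypes net of batch structure, gene-module relevance, and survival
relevance, combined by Pareto-front model selection.

## The knowledge-driven feature extractor

The package's core is a per-patient network-diffusion enrichment embedding:

1. **Seed selection.** A disease gene panel is split into up- and
   down-regulated lists by fold-change sign. Genes are standardized across
   samples (per-gene z-score), and for each sample the `top_n` (default 50)
   up-list genes by descending z and down-list genes by ascending z become
   that patient's seed sets. Ranking on z-scores rather than raw expression
   prevents constitutively abundant genes from dominating every patient's
   seed list; ranking on raw values remains available
   (`ranking = "raw"`).
2. **Random walk with restart.** Each seed set is diffused over an
   undirected gene network by iterating
   $p_{t+1} = (1-r)\,W p_t + r\,p_0$ with restart $r = 0.75$ and $p_0$
   uniform on the seeds. $W$ is by default the symmetrically normalized
   adjacency $D^{-1/2} A D^{-1/2}$ (the diffusion kernel associated with
   the normalized graph Laplacian); a column-normalized transition matrix
   is available when exact probability conservation is wanted. The walk
   runs on the largest connected component; the fixed point ranks every
   gene by proximity to the patient's dysregulated genes.
3. **Pre-ranked GSEA.** The affinity vector is scored against a gene set
   collection with a weighted Kolmogorov–Smirnov running sum
   (weight exponent 1). The null distribution is built from random
   gene-position subsets of matching size — `n_perm` sampled permutations,
   or every subset exhaustively on small universes. NES divides ES by the
   mean magnitude of same-sign null scores; the permutation p-value is
   $(1 + \#\{|\mathrm{null}| \ge |ES|,\ \text{same sign}\}) /
   (1 + \#\text{same-sign nulls})$.
4. **Embedding assembly.** The adjusted score of a pathway in a sample is
   $\mathrm{NES} \times (-\log_{10} p)$, so unenriched pathways
   ($p \approx 1$) vanish and the embedding is sparse. Multiplying by
   $\log_{10} p$ directly (which flips the enrichment sign) is kept as the
   `nes_times_logp` variant for compatibility; the default preserves the
   sign of enrichment, which is what correlation-distance clustering
   consumes. Up- and down-seed walks run separately and the down run's NES
   is negated before the two score matrices are summed, so positive
   pathway scores associate with up-regulated disease genes and negative
   scores with down-regulated ones. A single combined walk is available
   (`combine = "single"`).

The permutation count trades precision of small p-values against runtime;
1000 is the package default, and the bundled end-to-end analyses use 250,
which bounds $-\log_{10} p$ at about 2.4 and is ample for clustering-grade
features.

## Co-expression networks, modules and the module score

Gene–gene adjacency is built from absolute Spearman correlations — robust
to the heavy tails of log-expression — either hard-thresholded
(edge iff $|\rho| \ge \tau$; typical $\tau$ 0.475–0.525) or soft-powered
($|\rho|^\beta$, typical powers 4–6). The parameter is tuned by the
scale-free topology criterion: over logarithmic connectivity bins (10 by
default), regress $\log_{10} p(k)$ on $\log_{10} k$ and report the signed
fit index ($R^2$ if the slope is negative, else 0); `tune_threshold()`
returns the smallest parameter whose index reaches `r2_target`
(default 0.8, configurable — when no candidate reaches it the argmax is
returned with a flag).

Topological overlap converts adjacency into a similarity crediting shared
neighborhoods,
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
(\min(k_i, k_j) + 1 - a_{ij})$, and modules come from average-linkage
hierarchical clustering of $1 - \mathrm{TOM}$ with a *static* cut at a
fixed fraction of the maximum merge height (default 0.99) and a minimum
module size (default 10). A static cut was chosen over dynamic tree
cutting deliberately: it is fully deterministic, has two transparent
parameters, and recovers planted partitions reliably at the scales this
package targets; clusters below the size floor are relabeled "unassigned"
(module 0). Each module's eigen-gene is the first principal component of
the standardized module submatrix, unit-norm and sign-aligned with the
module's mean profile.

The module relevance score of a clustering asks whether each module's
eigen-gene singles out few clusters: with $S^\pm_i$ the number of cluster
indicators whose Spearman correlation with eigen-gene $i$ passes $\pm\alpha$,
a module contributes $(\min(1, S^+_i) + \min(1, S^-_i)) / (S^+_i + S^-_i)$,
or $\beta$ when nothing passes; the score averages modules (unweighted).
$\alpha$ defaults to 0.5 — operationalizing "strongly correlated" — and
$\beta$ to 0, which penalizes clusterings that fail to separate any module's
expression. Both are surfaced as arguments and recorded in output metadata.

## Clustering

Correlation distance $d = 1 - \mathrm{cor}(x, y)$ serves the pathway
feature space; Euclidean distance serves reduced expression. DIANA —
divisive hierarchical clustering — is implemented in full: the
largest-diameter cluster is split by seeding a splinter group with the
most-estranged object and moving objects while their average dissimilarity
favors the splinter side; after $k - 1$ splits the partition is returned.
Every tie breaks toward the lowest sample index, making the algorithm
bit-reproducible. k-means uses 100 seeded k-means++ restarts (best
within-cluster sum of squares kept); Gaussian mixtures use full
covariances with a mean-shrinkage prior of 0.01 to avoid degenerate
components; agglomerative linkages (average, complete, Ward) cut at $k$.
Methods that require Euclidean geometry (k-means, GMM, Ward) are not
offered correlation-distance inputs — the benchmark grid skips those
combinations rather than silently coercing.

## The evaluation protocol

* **Separability** — average silhouette width on the feature space's own
  distance; singletons contribute 0.
* **Stability** — 20 repeats of 5-fold cross-validation: each of the 100
  resamples drops one fold, reruns the *entire* pipeline (feature
  extraction included) on the retained 80%, and compares to the full-data
  reference restricted to those samples by co-clustering Jaccard and ARI.
  Clustering the retained (training) portion, rather than the held-out
  fold, keeps 80% of samples per resample and matches the reference
  restriction naturally.
* **Subtype concordance, batch-adjusted** — NMI against known subtypes,
  NMI against batch variables, and cNMI = subtype NMI − batch NMI (the
  plain difference; no rescaling). NMI normalizes mutual information by
  $\sqrt{H\cdot H'}$, with the zero-entropy convention NMI = 0.
* **Module relevance** — the module score above.
* **Clinical relevance** — a Cox proportional-hazards likelihood-ratio
  test: covariate-only baseline versus baseline plus $k-1$ cluster
  indicators, $\chi^2$ on $k-1$ df. Covariates are configuration inputs
  (the package does not select them), a follow-up cap can exclude
  long-follow-up outliers, and a Schoenfeld-type diagnostic is attached
  but never gates results.

`run_benchmark()` records all criteria per resample in a long metric
table. Aggregation uses arithmetic means (and SDs), except survival
p-values, which aggregate as the median of $-\log_{10} p$ — a monotone
transform that keeps the criterion commensurate with the others after
min–max scaling. Selection offers `best_by_sum()` (each criterion min–max
scaled to [0, 1] across combinations, minimized criteria flipped — batch
association enters as $1 - \mathrm{NMI}_\mathrm{batch}$ — summed, and
averaged over $k$; ties break by stability, then silhouette, then name)
and `pareto_front()` (non-dominated combinations under the same
direction alignment).

## The synthetic cohort generator

Real cohorts of the kind this framework targets cannot ship with a
package, so a seeded generator produces cohorts with known ground truth:

* **Expression** follows a module latent-factor model: module $m$ has one
  latent factor per sample; a gene in module $m$ is its loading
  (uniform in 0.7–1) times the factor, plus i.i.d. Gaussian noise
  (`noise_sd`, default 1 SD). 80% of genes belong to modules; the rest are
  background noise.
* **Subtypes** shift module factors: each subtype up-shifts one dedicated
  module and down-shifts another by `subtype_effect` (default 4 SD).
  The dedicated-module design guarantees that every pair of subtypes
  differs in the *relative allocation* of disease genes across modules.
  This matters specifically for the knowledge-driven workflow: seed genes
  are constrained to the disease lists, so two subtypes that shift the
  same modules in the same proportions — however different their
  magnitudes — would produce indistinguishable diffusion profiles. With
  the default `n_modules = 2 * k_subtypes` the signature modules are
  disjoint.
* **Disease gene lists** are the genes of modules some subtype up-shifts
  (and none down-shifts), and conversely — emulating a disease-gene panel
  intersected with differential expression, split by fold-change sign.
* **Batch effects** add a per-level constant (levels evenly spaced in
  $\pm$`batch_effect`) to a random 30% gene subset; one batch variable by
  default, two supported (emulating source site and plate).
* **Survival** is exponential with per-subtype hazard ratios (default
  evenly spaced 1–3), independent exponential censoring at
  `0.9 * baseline_rate` (roughly 30% censoring under the defaults), and
  a baseline rate of 1/1500 events per day — median survival on the order
  of three years for the reference subtype, a realistic oncology scale.
* **Knowledge** aligned to the truth: half the gene sets draw 90% of
  members from one module (sizes capped so that is feasible), the rest are
  uniform; the gene network is a planted partition with within-module edge
  probability 0.9 and background 0.02.

Every component draws from its own named sub-stream derived from the
master seed, so outputs are identical across platforms and independent of
evaluation order.

What the generator does *not* emulate: count-level noise and library-size
variation (values are already log-scale Gaussian), gene-specific baseline
abundance, overlapping or hierarchical modules, network hubs and
scale-free topology in the knowledge network, informative censoring, and
covariates correlated with subtype. Tests passing on these cohorts
demonstrate that the machinery recovers structure it is designed to see,
not that it will rank methods correctly on any real data set.

## Numerical choices and edge cases

* GSEA running-sum ties resolve to the negative extreme (the convention of
  reference implementations); zero-weight hit sets fall back to unweighted
  increments.
* RWR convergence is declared at an L1 change below `1e-10` (cap 10,000
  iterations); seeds outside the largest component are dropped with a
  warning, and an empty seed set after restriction is an error, not a
  silent zero vector.
* Correlation dissimilarity clamps tiny negative rounding residues to 0;
  constant sample profiles raise an error naming the sample.
* Silhouette uses the $a = b = 0 \Rightarrow s = 0$ convention; NMI of a
  constant labeling is 0; Jaccard of two all-singleton labelings is 1.
* Eigen-gene sign alignment falls back to "no flip" when the module mean
  profile is constant; one-gene modules use the gene's standardized
  profile and are flagged.
* The GMM adapter refits up to 5 times with derived seeds if a component
  empties, then errors; k-means keeps the best of 100 restarts that uses
  all $k$ labels.

## Problem sizes used in the bundled analyses

The shipped tests and the acceptance script run entirely on synthetic
data at deliberately modest scales, chosen to exercise every code path
while keeping a full run comfortable on a laptop: default cohorts of 200
genes x 120 samples with 3 subtypes, 20 gene sets, 250 GSEA permutations
for end-to-end runs (1000 remains the API default), 100 cohort seeds for
recovery rates, 400 null and 100 alternative seeds for survival
calibration and power, and one full 20 x 5-fold stability pass (100
resamples). Oracle-equivalence checks use graphs up to 50 nodes (RWR),
universes up to 8 genes (exhaustive GSEA nulls), matrices up to 20 genes
(topological overlap), and up to 200-point criteria matrices (Pareto).

## Known limitations

* t-SNE and UMAP adapter slots are reserved but not bundled; PCA and the
  identity adapter cover the shipped workflows.
* The GSEA implementation uses plain permutation p-values; very small
  p-values saturate at $1/(n_\mathrm{perm}+1)$ rather than being refined
  adaptively.
* Module detection uses a static tree cut, not dynamic tree cutting, and
  no module merging by eigen-gene similarity.
* The Cox layer fits proportional hazards only; competing risks and
  time-varying effects are out of scope.
* Signed co-expression networks and block-wise module detection for very
  large gene universes are not implemented.
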