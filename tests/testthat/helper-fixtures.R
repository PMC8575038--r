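# Shared fixtures and independent oracle implementations. Oracles are kept
# deliberately naive (loops, closed forms) and separate from the package's
# code paths.

random_expression <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
    dimnames = list(sprintf("g%03d", seq_len(n_genes)),
      sprintf("s%03d", seq_len(n_samples))))
}

# adjacency of two disjoint cliques of the given sizes
two_clique_adjacency <- function(size1 = 10, size2 = 10) {
  n <- size1 + size2
  a <- matrix(0, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  a[1:size1, 1:size1] <- 1
  a[(size1 + 1):n, (size1 + 1):n] <- 1
  diag(a) <- 0
  a
}

random_graph_adjacency <- function(n, p = 0.3, weighted = FALSE, seed = 1) {
  set.seed(seed)
  a <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  ut <- upper.tri(a)
  edge <- runif(sum(ut)) < p
  w <- if (weighted) runif(sum(ut)) else 1
  a[ut] <- edge * w
  a + t(a)
}

# dense linear-solve RWR oracle: p = r (I - (1-r) W)^{-1} p0
rwr_oracle <- function(w, p0, restart) {
  n <- nrow(w)
  solve(diag(n) - (1 - restart) * w) %*% p0 * restart
}

# brute-force triple-loop TOM
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (u in seq_len(n)) shared <- shared + a[i, u] * a[u, j]
      tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# naive running-sum GSEA ES over every position
es_oracle <- function(scores, set, exponent = 1) {
  ord <- order(-scores, names(scores))
  ranked <- names(scores)[ord]
  w <- abs(scores[ord])^exponent
  hit <- ranked %in% set
  wsum <- sum(w[hit])
  inc <- if (wsum > 0) w * hit / wsum else hit / sum(hit)
  dec <- (!hit) / (length(ranked) - sum(hit))
  walk <- cumsum(inc - dec)
  maxdev <- max(c(walk, 0))
  mindev <- min(c(walk, 0))
  # ties within rounding resolve to the negative extreme, as in the kernel
  if (maxdev - (-mindev) > 1e-12) maxdev else mindev
}

# contingency-table NMI/ARI oracles
nmi_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (pij[i, j] > 0) mi <- mi + pij[i, j] * log(pij[i, j] / (pi_[i] * pj_[j]))
  }
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  if (h(pi_) == 0 || h(pj_) == 0) return(0)
  unname(mi / sqrt(h(pi_) * h(pj_)))
}

ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- function(x) sum(choose(x, 2))
  idx <- sc(as.vector(tab))
  ex <- sc(rowSums(tab)) * sc(colSums(tab)) / choose(n, 2)
  mx <- (sc(rowSums(tab)) + sc(colSums(tab))) / 2
  if (mx == ex) return(ifelse(idx == ex, 1, 0))
  (idx - ex) / (mx - ex)
}

# pair-enumeration Jaccard oracle
jaccard_oracle <- function(a, b) {
  n <- length(a)
  pairs <- combn(n, 2)
  in_a <- a[pairs[1, ]] == a[pairs[2, ]]
  in_b <- b[pairs[1, ]] == b[pairs[2, ]]
  if (sum(in_a | in_b) == 0) return(1)
  sum(in_a & in_b) / sum(in_a | in_b)
}

# per-point silhouette oracle
silhouette_oracle <- function(d, labels) {
  n <- length(labels)
  mean(vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(kk) {
      mean(d[i, which(labels == kk)])
    }, 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0))
}

# direct loop module-score oracle with its own Spearman (rank + Pearson)
module_score_oracle <- function(em, labels, alpha, beta) {
  spearman <- function(x, y) {
    rx <- rank(x)
    ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  ks <- sort(unique(labels))
  vals <- numeric(ncol(em))
  for (m in seq_len(ncol(em))) {
    sp <- sn <- 0
    for (kk in ks) {
      rho <- spearman(em[, m], as.numeric(labels == kk))
      if (rho >= alpha) sp <- sp + 1
      if (rho <= -alpha) sn <- sn + 1
    }
    vals[m] <- if (sp + sn == 0) beta else (min(1, sp) + min(1, sn)) / (sp + sn)
  }
  mean(vals)
}

# O(n^2) dominance oracle (maximization on all columns)
pareto_oracle <- function(mat) {
  n <- nrow(mat)
  which(vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && all(mat[j, ] >= mat[i, ]) && any(mat[j, ] > mat[i, ])
    }, TRUE))
  }, TRUE))
}
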