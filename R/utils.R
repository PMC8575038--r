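# Internal helpers shared across modules.

# Deterministic sub-seed derivation: every stochastic component draws its own
# seed from the master seed and a string key, so independent stages never share
# a stream and runs are reproducible across platforms. Plain 32-bit polynomial
# hash folded into [0, 2^31 - 2].
derive_seed <- function(master_seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- as.double(master_seed %% 2147483647L)
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a locally-set RNG seed, restoring the caller's RNG
# state afterwards so library code never disturbs the user's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Relabel an integer/character label vector so cluster ids are 1..k in order
# of first appearance.
canonicalize_labels <- function(labels) {
  f <- match(labels, unique(labels))
  names(f) <- names(labels)
  f
}

assert_that <- function(ok, msg, class = "stratabench_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == as.integer(x) && x >= 1
}

# Validate a genes x samples expression matrix.
validate_expression <- function(expr) {
  assert_that(is.matrix(expr) && is.numeric(expr),
    "expression must be a numeric matrix (genes x samples)")
  assert_that(!is.null(rownames(expr)) && !is.null(colnames(expr)),
    "expression matrix must have gene rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(expr)), "duplicate gene identifiers",
    class = "stratabench_duplicate_id")
  assert_that(!anyDuplicated(colnames(expr)), "duplicate sample identifiers",
    class = "stratabench_duplicate_id")
  assert_that(all(is.finite(expr)), "expression values must all be finite")
  assert_that(nrow(expr) >= 2 && ncol(expr) >= 2,
    "need at least 2 genes and 2 samples")
  invisible(expr)
}

# Extract an integer label vector from a cluster_fit or plain vector.
as_label_vector <- function(labels) {
  if (inherits(labels, "cluster_fit")) {
    return(labels$labels)
  }
  if (is.factor(labels)) labels <- as.character(labels)
  lv <- canonicalize_labels(labels)
  lv
}
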