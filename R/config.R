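# YAML run configuration mirroring benchmark_config(), for scripted /
# command-line use.

#' Read a benchmark configuration from YAML
#'
#' The document mirrors [benchmark_config()]: top-level keys `embeddings`
#' (a map of name -> spec with `method` and parameters), `clusterers`,
#' `k_range` (either a list or `[min, max]` under `from`/`to`), and the
#' scalar options (`folds`, `repeats`, `alpha`, `beta`, `covariates`,
#' `followup_cap`, `module_power`, `seed`). Optional `paths` entries
#' (`expression`, `clinical`, `network`, `gene_sets`, `up_genes`,
#' `down_genes`, `out_dir`) are passed through for the caller to resolve.
#'
#' @param path Path to a YAML file.
#' @return A `benchmark_config` with attribute `paths`.
#' @export
read_benchmark_config <- function(path) {
  doc <- yaml::read_yaml(path)
  assert_that(!is.null(doc$embeddings) && !is.null(doc$clusterers),
    "config must define embeddings and clusterers",
    class = "stratabench_config_error")
  k_range <- doc$k_range
  if (is.list(k_range) && !is.null(k_range$from)) {
    k_range <- seq(k_range$from, k_range$to)
  }
  cfg <- benchmark_config(
    embeddings = doc$embeddings,
    clusterers = unlist(doc$clusterers),
    k_range = unlist(k_range) %||% 2:6,
    folds = doc$folds %||% 5,
    repeats = doc$repeats %||% 20,
    alpha = doc$alpha %||% 0.5,
    beta = doc$beta %||% 0,
    covariates = unlist(doc$covariates) %||% character(),
    followup_cap = doc$followup_cap,
    module_power = doc$module_power %||% 6,
    module_min_size = doc$module_min_size %||% 10,
    module_cut = doc$module_cut %||% 0.99,
    seed = doc$seed %||% 1
  )
  attr(cfg, "paths") <- doc$paths
  cfg
}
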