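# Readers and writers for the plain-text formats the framework touches:
# expression matrices, GMT gene set collections, edge lists, clinical tables
# and long-format metric tables. All parsing is locale-independent (decimal
# point, tab/comma separated).

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene expression matrix
#'
#' Expects a TSV/CSV with a header row, one row per gene, the first column
#' holding gene identifiers and the remaining columns one sample each.
#' Values are log-scale expression.
#'
#' @param path Path to a delimited text file (`.tsv`/`.txt` tab, `.csv`
#'   comma).
#' @return A numeric matrix (genes x samples) with gene rownames and sample
#'   colnames, in file order.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  df <- readr::read_delim(path, delim = delim_for(path),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE)
  assert_that(nrow(df) > 0 && ncol(df) >= 2, "empty expression file",
    class = "stratabench_parse_error")
  genes <- df[[1]]
  assert_that(!anyDuplicated(genes), "duplicate gene identifiers in file",
    class = "stratabench_duplicate_id")
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
    dimnames = list(genes, names(df)[-1]))
  assert_that(!anyNA(vals), "non-numeric expression cell",
    class = "stratabench_parse_error")
  validate_expression(vals)
}

#' Write a gene expression matrix
#'
#' @param expr Numeric matrix (genes x samples) with dimnames.
#' @param path Output path; extension decides the delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- as_tibble(expr, rownames = "gene_id")
  readr::write_delim(df, path, delim = delim_for(path), progress = FALSE)
  invisible(path)
}

#' Read a GMT gene set collection
#'
#' One set per tab-separated line: name, description, then member genes.
#' Duplicate members within a line are removed with a warning.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors (the collection), with a
#'   `description` attribute (named character vector).
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) > 0, "empty GMT file",
    class = "stratabench_parse_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3
  if (any(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", which(bad)[1]),
      class = "stratabench_parse_error")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  assert_that(!anyDuplicated(nm), "duplicate gene set names",
    class = "stratabench_duplicate_id")
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(sets, function(s) sum(duplicated(s)), 1L))
  if (ndup > 0) {
    warn(sprintf("removed %d duplicate member gene(s) within sets", ndup))
    sets <- lapply(sets, unique)
  }
  names(sets) <- nm
  attr(sets, "description") <- setNames(desc, nm)
  sets
}

#' Write a GMT gene set collection
#'
#' @param sets Named list of character vectors; an optional `description`
#'   attribute supplies the second GMT column (defaults to the set name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene network from an edge list
#'
#' Accepts a 2- or 3-column delimited file (source, target, optional
#' weight) with a header row. Directed input is symmetrized: each directed
#' edge contributes one undirected edge; duplicates collapse to the maximum
#' weight; self-loops are dropped with a warning.
#'
#' @param path Path to the edge list (TSV/CSV).
#' @param symmetrize Kept for interface clarity; the stored network is
#'   always undirected (default `TRUE`).
#' @return A [gene_network()].
#' @export
read_network <- function(path, symmetrize = TRUE) {
  df <- readr::read_delim(path, delim = delim_for(path),
    show_col_types = FALSE, progress = FALSE)
  assert_that(ncol(df) >= 2, "edge list needs at least 2 columns",
    class = "stratabench_parse_error")
  edges <- tibble(from = as.character(df[[1]]), to = as.character(df[[2]]))
  if (ncol(df) >= 3) edges$weight <- as.numeric(df[[3]])
  gene_network(edges)
}

#' Write a gene network as an undirected edge list
#'
#' @param net A `gene_network`.
#' @param path Output path (TSV/CSV by extension).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  readr::write_delim(tidy(net), path, delim = delim_for(path),
    progress = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Maps arbitrary column names onto the framework's clinical schema:
#' sample identifier, follow-up time (days), event indicator (0/1), optional
#' subtype and batch labels, and any number of covariate columns. Rows with
#' missing time or event are retained but flagged in `has_survival`.
#'
#' @param path Path to a CSV/TSV with a header.
#' @param column_map Named list/character vector mapping schema names
#'   (`sample_id`, `time`, `event`, optionally `subtype`, `batch`,
#'   `covariates` as a character vector) to file column names.
#' @return A tibble with canonical columns `sample_id`, `time`, `event`,
#'   `has_survival`, plus `subtype`/`batch` and covariates when mapped.
#' @export
read_clinical <- function(path, column_map) {
  df <- readr::read_delim(path, delim = delim_for(path),
    show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "time", "event")
  for (key in need) {
    assert_that(!is.null(column_map[[key]]),
      sprintf("column_map must provide '%s'", key),
      class = "stratabench_config_error")
  }
  mapped <- unlist(column_map, use.names = FALSE)
  missing_cols <- setdiff(mapped, names(df))
  assert_that(length(missing_cols) == 0,
    sprintf("mapped column(s) absent from file: %s",
      paste(missing_cols, collapse = ", ")),
    class = "stratabench_config_error")

  out <- tibble(
    sample_id = as.character(df[[column_map$sample_id]]),
    time = as.numeric(df[[column_map$time]]),
    event = as.numeric(df[[column_map$event]])
  )
  assert_that(!anyDuplicated(out$sample_id), "duplicate sample identifiers",
    class = "stratabench_duplicate_id")
  ev <- out$event[!is.na(out$event)]
  assert_that(all(ev %in% c(0, 1)), "event column must be 0/1",
    class = "stratabench_value_error")
  assert_that(all(out$time[!is.na(out$time) & !is.na(out$event)] > 0 |
      is.na(out$time)), "follow-up time must be > 0",
    class = "stratabench_value_error")
  out$has_survival <- !is.na(out$time) & !is.na(out$event)
  if (!is.null(column_map$subtype)) {
    out$subtype <- as.character(df[[column_map$subtype]])
  }
  if (!is.null(column_map$batch)) {
    out$batch <- as.character(df[[column_map$batch]])
  }
  for (cov in column_map$covariates %||% character()) {
    out[[cov]] <- df[[cov]]
  }
  out
}

#' Write a long-format metric table
#'
#' @param table A metric tibble with columns `embedding`, `clusterer`, `k`,
#'   `resample_id`, `metric`, `value` (extra columns are preserved).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_metrics()]
#' @export
write_metrics <- function(table, path) {
  cols <- c("embedding", "clusterer", "k", "resample_id", "metric", "value")
  assert_that(all(cols %in% names(table)),
    "metric table missing canonical columns")
  table <- dplyr::arrange(as_tibble(table),
    .data$embedding, .data$clusterer, .data$k, .data$resample_id, .data$metric)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Read a long-format metric table
#'
#' @param path CSV written by [write_metrics()].
#' @return A tibble.
#' @export
read_metrics <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Drop near-zero-variance genes
#'
#' Removes genes whose variance falls below `var_threshold` or whose most
#' frequent value covers more than `freq_threshold` of samples — the usual
#' near-zero-variance filter applied before co-expression analysis.
#'
#' @param expr Genes x samples numeric matrix.
#' @param var_threshold Minimum per-gene variance (default `1e-8`).
#' @param freq_threshold Maximum fraction of samples sharing the modal value
#'   (default `0.95`).
#' @return The filtered matrix; number of dropped genes reported via message.
#' @export
filter_low_variance <- function(expr, var_threshold = 1e-8,
                                freq_threshold = 0.95) {
  validate_expression(expr)
  v <- apply(expr, 1, var)
  modal <- apply(expr, 1, function(x) max(tabulate(match(x, unique(x)))))
  drop <- v < var_threshold | modal / ncol(expr) > freq_threshold
  if (any(drop)) {
    message(sprintf("filter_low_variance: dropping %d gene(s)", sum(drop)))
  }
  expr[!drop, , drop = FALSE]
}
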