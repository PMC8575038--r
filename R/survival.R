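# Clinical relevance of a clustering: Cox proportional-hazards
# likelihood-ratio test of cluster membership on top of a covariate-only
# baseline model.

#' Cox likelihood-ratio test for cluster survival differences
#'
#' Fits a baseline Cox proportional-hazards model on the given covariates
#' and an alternative model adding `k - 1` cluster indicator terms; the
#' statistic is `2 * (ll_alt - ll_base)` on `k - 1` degrees of freedom.
#' Samples with missing survival, incomplete covariates, or follow-up
#' beyond `followup_cap` are excluded. Hazard ratios are reported versus
#' the first cluster. A Schoenfeld-type proportional-hazards diagnostic is
#' attached but never gates the result.
#'
#' @param clinical Tibble with `sample_id`, `time`, `event` and any
#'   covariate columns (see [read_clinical()]).
#' @param labels A `cluster_fit` or named label vector; names must match
#'   `sample_id`s.
#' @param covariates Character vector of baseline covariate column names
#'   (default none).
#' @param followup_cap Exclude samples with follow-up beyond this many
#'   days (default `NULL` = no cap); typical choices are 3000 days for
#'   breast and 2000 for prostate cohorts.
#' @return A `cox_lrt` object: list with `statistic`, `df`, `p_value`,
#'   `hazard_ratios` (tibble), `n_used`, `n_events`, `ph_diagnostic`.
#'   `glance()`/`tidy()` methods provided. Returns with `p_value = NA` and
#'   a `failure` message if the fit does not converge.
#' @export
cox_lrt <- function(clinical, labels, covariates = character(),
                    followup_cap = NULL) {
  lv <- as_label_vector(labels)
  ids <- names(lv)
  assert_that(!is.null(ids), "labels must be named by sample_id")
  df <- as_tibble(clinical)
  assert_that(all(c("sample_id", "time", "event") %in% names(df)),
    "clinical table missing sample_id/time/event")
  missing_cov <- setdiff(covariates, names(df))
  assert_that(length(missing_cov) == 0,
    sprintf("covariate column(s) absent: %s",
      paste(missing_cov, collapse = ", ")),
    class = "stratabench_config_error")

  df <- df[match(ids, df$sample_id), , drop = FALSE]
  df$cluster <- factor(lv)
  keep <- !is.na(df$time) & !is.na(df$event)
  if (!is.null(followup_cap)) keep <- keep & df$time <= followup_cap
  if (length(covariates) > 0) {
    keep <- keep & complete.cases(df[, covariates, drop = FALSE])
  }
  df <- df[keep, , drop = FALSE]
  df$cluster <- droplevels(df$cluster)
  assert_that(nlevels(df$cluster) >= 2,
    "fewer than 2 clusters among samples with survival data",
    class = "stratabench_value_error")
  k <- nlevels(df$cluster)

  base_rhs <- if (length(covariates) > 0) {
    paste(covariates, collapse = " + ")
  } else {
    "1"
  }
  f_base <- stats::as.formula(paste("survival::Surv(time, event) ~", base_rhs))
  f_alt <- stats::as.formula(paste("survival::Surv(time, event) ~",
    base_rhs, "+ cluster"))

  fit <- tryCatch({
    m_base <- survival::coxph(f_base, data = df)
    m_alt <- survival::coxph(f_alt, data = df)
    list(base = m_base, alt = m_alt)
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(statistic = NA_real_, df = k - 1,
      p_value = NA_real_, hazard_ratios = tibble(),
      n_used = nrow(df), n_events = sum(df$event),
      failure = conditionMessage(fit)), class = "cox_lrt"))
  }

  ll_base <- if (length(covariates) > 0) {
    fit$base$loglik[2]
  } else {
    fit$base$loglik[1]
  }
  stat <- 2 * (fit$alt$loglik[2] - ll_base)
  stat <- max(0, stat)
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)

  co <- summary(fit$alt)$coefficients
  cl_rows <- grepl("^cluster", rownames(co))
  hr <- tibble(
    cluster = sub("^cluster", "", rownames(co)[cl_rows]),
    hazard_ratio = exp(co[cl_rows, "coef"]),
    se = co[cl_rows, "se(coef)"],
    p_value = co[cl_rows, "Pr(>|z|)"]
  )
  ev_by_cluster <- tapply(df$event, df$cluster, sum)
  if (any(ev_by_cluster == 0)) {
    warn("cluster(s) with zero events; hazard ratios unreliable")
  }
  ph <- tryCatch(
    as.data.frame(survival::cox.zph(fit$alt)$table),
    error = function(e) NULL)

  structure(list(
    statistic = unname(stat), df = k - 1, p_value = unname(p),
    hazard_ratios = hr, n_used = nrow(df), n_events = sum(df$event),
    ph_diagnostic = ph, covariates = covariates,
    followup_cap = followup_cap
  ), class = "cox_lrt")
}

#' @export
print.cox_lrt <- function(x, ...) {
  cat(sprintf("<cox_lrt> chi^2 = %.3f on %d df, p = %.3g (n = %d, events = %d)\n",
    x$statistic, x$df, x$p_value, x$n_used, x$n_events))
  invisible(x)
}

#' @export
glance.cox_lrt <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
    n_used = x$n_used, n_events = x$n_events)
}

#' @export
tidy.cox_lrt <- function(x, ...) {
  x$hazard_ratios
}
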