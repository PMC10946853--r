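## Readers / writers --------------------------------------------------------

#' Column mapping for delimited survival data
#'
#' Names the columns of a delimited file holding clustered right-censored
#' survival data and states which status value means "event observed".
#' Files in the opposite convention (1 = censored) are ingested by
#' setting `event_value = 0`.
#'
#' @param time,status,cluster Column names.
#' @param covariates Character vector of covariate column names to carry
#'   along (may be empty).
#' @param event_value Status value meaning "event".
#' @return A list of class `dcox_mapping`.
#' @export
dcox_column_mapping <- function(time = "time", status = "status",
                                cluster = "cluster",
                                covariates = character(),
                                event_value = 1) {
  structure(list(time = time, status = status, cluster = cluster,
                 covariates = as.character(covariates),
                 event_value = event_value),
            class = "dcox_mapping")
}

#' Read clustered survival data from a delimited file
#'
#' Reads a comma-delimited file with a header, validates it (positive
#' times, binary status after mapping, no missing values) and returns a
#' normalized tibble with columns `time`, `status` (1 = event), `cluster`
#' (re-coded to integers in first-appearance order) and the mapped
#' covariates.
#'
#' @param path File path.
#' @param mapping A [dcox_column_mapping()].
#' @return A tibble.
#' @export
read_survival_csv <- function(path, mapping = dcox_column_mapping()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  spec <- dcox_spec("weibull", scale = mapping$covariates)
  dd <- dcox_data(raw, spec, time = mapping$time, status = mapping$status,
                  cluster = mapping$cluster,
                  event_value = mapping$event_value)
  out <- tibble(time = dd$time, status = dd$event, cluster = dd$cluster)
  for (cv in mapping$covariates) out[[cv]] <- raw[[cv]]
  out
}

#' Write a fit report
#'
#' Serializes the estimates, convergence diagnostics and (optionally)
#' confidence intervals of a fit to JSON (machine-readable, lossless for
#' the estimates) or TSV (human-readable table). The report always
#' contains a `sigma2` row, flagged when the estimate sits on the
#' boundary.
#'
#' @param fit A `dcox_fit`.
#' @param path Output file path.
#' @param intervals Optional interval tibble (e.g. from
#'   [confint.dcox_fit()]).
#' @param format `"json"` or `"tsv"`.
#' @param seed Seed to record in the report, if any.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, intervals = NULL,
                             format = c("json", "tsv"), seed = NULL) {
  format <- match.arg(format)
  est <- coef(fit)
  if (format == "json") {
    rep <- list(
      software = paste0("doublecox ", as.character(packageVersion("doublecox"))),
      seed = seed,
      family = fit$spec$family,
      scale_covariates = as.list(fit$spec$scale_covariates),
      shape_covariates = as.list(fit$spec$shape_covariates),
      n = fit$nobs, n_clusters = fit$n_clusters, n_events = fit$n_events,
      estimates = as.list(est),
      loglik = fit$loglik, converged = fit$converged,
      n_iter = fit$n_iter, gradient_norm = fit$gradient_norm,
      method = fit$method, boundary = fit$boundary,
      intervals = intervals
    )
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    tab <- tibble(term = names(est), estimate = unname(est))
    if (!is.null(intervals))
      tab <- dplyr::left_join(tab, as_tibble(intervals), by = "term",
                              suffix = c("", ".ci"))
    tab$boundary <- tab$term == "sigma2" & fit$boundary
    readr::write_tsv(tab, path)
  }
  invisible(path)
}

#' Read a JSON fit report
#'
#' @param path Path to a JSON report written by [write_fit_report()].
#' @return A list with the report contents; `estimates` is a named
#'   numeric vector.
#' @export
read_fit_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$estimates <- unlist(rep$estimates)
  rep
}
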