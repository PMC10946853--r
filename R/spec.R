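#' Model specification for a double-Cox frailty model
#'
#' A specification names the baseline hazard family and the covariate columns
#' entering the two Cox-regression terms: one multiplying the hazard's scale,
#' one modulating its shape parameter as `b * exp(beta_shape %*% u)`.
#' An empty `shape` reduces the model to the classical scale-only
#' (single-Cox) parametric frailty model.
#'
#' @param family `"weibull"` or `"gompertz"`.
#' @param scale Character vector of covariate column names for the scale
#'   Cox term (may be empty).
#' @param shape Character vector of covariate column names for the shape
#'   Cox term (may be empty).
#' @return An object of class `dcox_spec`.
#' @examples
#' dcox_spec("gompertz", scale = c("success", "score"))
#' @export
dcox_spec <- function(family = c("weibull", "gompertz"),
                      scale = character(),
                      shape = character()) {
  family <- match.arg(family)
  stopifnot(is.character(scale), is.character(shape))
  structure(
    list(family = family,
         scale_covariates = as.character(scale),
         shape_covariates = as.character(shape)),
    class = "dcox_spec"
  )
}

#' @export
print.dcox_spec <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = " + ") else "(none)"
  cat("<dcox_spec> ", x$family,
      "\n  scale covariates: ", fmt(x$scale_covariates),
      "\n  shape covariates: ", fmt(x$shape_covariates), "\n", sep = "")
  invisible(x)
}

#' Parameter vector of a double-Cox frailty model
#'
#' Bundles the baseline scale `a > 0`, baseline shape `b > 0`, the two
#' Cox-regression coefficient vectors and the frailty variance
#' `sigma2 >= 0` (variance of the mean-one gamma frailty; `sigma2 = 0`
#' is the no-frailty model).
#'
#' @param a Baseline scale, positive.
#' @param b Baseline shape, positive.
#' @param beta_scale Numeric vector of scale Cox coefficients (possibly
#'   length 0), optionally named.
#' @param beta_shape Numeric vector of shape Cox coefficients.
#' @param sigma2 Frailty variance, non-negative.
#' @return An object of class `dcox_params`.
#' @examples
#' dcox_params(a = 1e-4, b = 0.1, sigma2 = 1)
#' @export
dcox_params <- function(a, b, beta_scale = numeric(), beta_shape = numeric(),
                        sigma2 = 0) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(sigma2), length(sigma2) == 1L, is.finite(sigma2),
            is.numeric(beta_scale), is.numeric(beta_shape))
  if (a <= 0) abort("`a` must be positive.")
  if (b <= 0) abort("`b` must be positive.")
  if (sigma2 < 0) abort("`sigma2` must be non-negative.")
  structure(
    list(a = a, b = b,
         beta_scale = beta_scale, beta_shape = beta_shape,
         sigma2 = sigma2),
    class = "dcox_params"
  )
}

#' @export
print.dcox_params <- function(x, digits = 4, ...) {
  cat("<dcox_params> a = ", signif(x$a, digits),
      ", b = ", signif(x$b, digits),
      ", sigma2 = ", signif(x$sigma2, digits), "\n", sep = "")
  if (length(x$beta_scale))
    cat("  beta_scale:", paste(signif(x$beta_scale, digits), collapse = ", "), "\n")
  if (length(x$beta_shape))
    cat("  beta_shape:", paste(signif(x$beta_shape, digits), collapse = ", "), "\n")
  invisible(x)
}

## check params against a spec; recycle/validate coefficient lengths
check_params_spec <- function(params, spec) {
  ps <- length(spec$scale_covariates)
  ph <- length(spec$shape_covariates)
  if (length(params$beta_scale) != ps)
    abort(sprintf("`beta_scale` has length %d but the spec lists %d scale covariate(s).",
                  length(params$beta_scale), ps))
  if (length(params$beta_shape) != ph)
    abort(sprintf("`beta_shape` has length %d but the spec lists %d shape covariate(s).",
                  length(params$beta_shape), ph))
  invisible(TRUE)
}

## Internal model frame: validated arrays extracted from a data frame.
## time > 0, event in {0,1}, cluster re-coded to 1..Ncl in first-appearance
## order, covariate matrices in spec order.
dcox_data <- function(data, spec, time = "time", status = "status",
                      cluster = "cluster", event_value = 1) {
  data <- as.data.frame(data)
  for (col in c(time, status, cluster))
    if (!col %in% names(data))
      abort(sprintf("Column '%s' not found in `data`.", col))
  covs <- unique(c(spec$scale_covariates, spec$shape_covariates))
  missing_covs <- setdiff(covs, names(data))
  if (length(missing_covs))
    abort(paste0("Covariate column(s) not found in `data`: ",
                 paste(missing_covs, collapse = ", ")))
  tt <- as.numeric(data[[time]])
  st <- data[[status]]
  cl <- data[[cluster]]
  bad <- which(!is.finite(tt) | tt <= 0)
  if (length(bad))
    abort(sprintf("Non-positive or missing time at row(s): %s.",
                  paste(head(bad, 5L), collapse = ", ")))
  uv <- unique(st)
  if (length(uv) > 2L)
    abort("Status column has more than two distinct values.")
  if (!event_value %in% uv && length(uv) == 2L)
    abort(sprintf("`event_value` (%s) does not occur in the status column.",
                  format(event_value)))
  event <- as.integer(st == event_value)
  if (anyNA(event)) abort("Missing values in the status column.")
  if (anyNA(cl)) abort("Missing values in the cluster column.")
  cl_id <- match(cl, unique(cl))
  Us <- as_cov_matrix(data, spec$scale_covariates)
  Uh <- as_cov_matrix(data, spec$shape_covariates)
  if (anyNA(Us) || anyNA(Uh)) abort("Missing values in covariate columns.")
  list(time = tt, event = event, cluster = cl_id,
       cluster_labels = unique(cl),
       Us = Us, Uh = Uh,
       d = as.vector(rowsum(event, cl_id)),
       n = length(tt), n_clusters = max(cl_id))
}

as_cov_matrix <- function(data, cols) {
  if (!length(cols)) return(matrix(numeric(), nrow = nrow(data), ncol = 0L))
  m <- as.matrix(as.data.frame(lapply(data[cols], as.numeric)))
  colnames(m) <- cols
  m
}

param_names <- function(spec, sigma2 = TRUE) {
  nm <- c("log(a)", "log(b)",
          if (length(spec$scale_covariates))
            paste0("scale_", spec$scale_covariates),
          if (length(spec$shape_covariates))
            paste0("shape_", spec$shape_covariates))
  if (sigma2) nm <- c(nm, "sigma2")
  nm
}

## pack/unpack between a dcox_params object and the estimation-scale vector
## (log a, log b, beta_scale, beta_shape[, log sigma2])
pack_params <- function(params, with_sigma2 = TRUE) {
  c(log(params$a), log(params$b), params$beta_scale, params$beta_shape,
    if (with_sigma2) log(max(params$sigma2, 1e-12)))
}

unpack_params <- function(theta, spec, with_sigma2 = TRUE) {
  ps <- length(spec$scale_covariates)
  ph <- length(spec$shape_covariates)
  k <- 2L + ps + ph
  dcox_params(
    a = exp(theta[1L]), b = exp(theta[2L]),
    beta_scale = if (ps) theta[2L + seq_len(ps)] else numeric(),
    beta_shape = if (ph) theta[2L + ps + seq_len(ph)] else numeric(),
    sigma2 = if (with_sigma2) exp(theta[k + 1L]) else 0
  )
}
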