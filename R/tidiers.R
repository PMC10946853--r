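#' Tidy a double-Cox fit
#'
#' One row per model parameter on its natural scale, with standard
#' errors (delta method for `a`, `b`) and confidence intervals: Wald for
#' the baseline and Cox-regression parameters, the boundary mixture for
#' the frailty variance, or profile intervals for everything when
#' `conf.method = "profile"`.
#'
#' @param x A `dcox_fit`.
#' @param conf.int Add interval columns?
#' @param conf.level Confidence level.
#' @param conf.method `"wald"` or `"profile"`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error` and,
#'   when requested, `conf.low`, `conf.high`, `conf.method`.
#' @export
tidy.dcox_fit <- function(x, conf.int = FALSE, conf.level = 0.95,
                          conf.method = c("wald", "profile"), ...) {
  conf.method <- match.arg(conf.method)
  est <- coef(x)
  info <- tryCatch(dcox_information(x), error = function(e) NULL)
  se <- rep(NA_real_, length(est))
  if (!is.null(info)) {
    se_infer <- sqrt(pmax(diag(info$vcov), 0))
    ## delta method: SE(a) = a * SE(log a), same for b
    se <- c(est[1] * se_infer[1], est[2] * se_infer[2],
            se_infer[-c(1, 2)])
  }
  out <- tibble(term = names(est), estimate = unname(est),
                std.error = unname(se))
  if (conf.int) {
    ci <- if (conf.method == "profile")
      dcox_profile_ci(x, info = info, level = conf.level)
    else
      dplyr::bind_rows(dcox_wald_ci(x, info, conf.level),
                       dcox_mixture_ci(x, info, conf.level))
    out <- dplyr::left_join(
      out,
      dplyr::select(ci, "term", conf.low = "lower", conf.high = "upper",
                    conf.method = "method"),
      by = "term")
  }
  out
}

#' Glance at a double-Cox fit
#'
#' @param x A `dcox_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the log-likelihood, AIC, sample
#'   structure, the frailty variance estimate and the convergence /
#'   boundary flags.
#' @export
glance.dcox_fit <- function(x, ...) {
  k <- length(x$theta) + as.integer(!x$with_sigma2)
  tibble(
    family = x$spec$family,
    logLik = x$loglik,
    AIC = 2 * k - 2 * x$loglik,
    nobs = x$nobs,
    n_clusters = x$n_clusters,
    n_events = x$n_events,
    sigma2 = x$params$sigma2,
    boundary = x$boundary,
    converged = x$converged,
    n_iter = x$n_iter,
    method = x$method
  )
}

#' Plot fitted marginal survival curves
#'
#' Draws the frailty-integrated survival curve of a fitted model for one
#' or more covariate settings.
#'
#' @param object A `dcox_fit`.
#' @param newdata Data frame of covariate settings, one curve per row
#'   (`NULL` for a covariate-free spec).
#' @param times Time grid; defaults to 200 points spanning the observed
#'   times.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcox_fit <- function(object, newdata = NULL, times = NULL, ...) {
  times <- times %||% seq(0, max(object$dd$time), length.out = 200L)
  covs <- unique(c(object$spec$scale_covariates,
                   object$spec$shape_covariates))
  if (is.null(newdata) && length(covs)) {
    # default to the baseline setting: all covariates at zero
    newdata <- as_tibble(setNames(as.list(rep(0, length(covs))), covs))
  }
  settings <- if (is.null(newdata)) tibble(.setting = "baseline")
    else dplyr::mutate(as_tibble(newdata),
                       .setting = paste0("setting ", dplyr::row_number()))
  curves <- purrr::map_dfr(seq_len(nrow(settings)), function(i) {
    nd <- if (is.null(newdata)) NULL else settings[i, , drop = FALSE]
    tibble(time = times,
           survival = dcox_survival(times, object$spec, object$params, nd),
           setting = settings$.setting[i])
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$setting)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time", y = "marginal survival S(t | u)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
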