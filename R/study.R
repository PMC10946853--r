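## Simulation studies: bias and coverage over a scenario grid ---------------

#' Configuration of a bias / coverage simulation study
#'
#' @param grid A list of [dcox_sim_config()] scenarios.
#' @param replications Replications per scenario.
#' @param ci_methods For coverage studies: any of `"wald"`,
#'   `"boundary_mixture"`, `"profile"`.
#' @param level Nominal confidence level.
#' @param seed Master seed; each replication derives its own substream
#'   seed from it, so a replication is reproducible in isolation and the
#'   study output does not depend on the worker count.
#' @param parallel_workers Number of forked workers (1 = serial).
#' @param fit_control A [dcox_control()] used for every fit.
#' @return An object of class `dcox_study_config`.
#' @export
dcox_study_config <- function(grid, replications = 300L,
                              ci_methods = "wald", level = 0.95,
                              seed = 1L, parallel_workers = 1L,
                              fit_control = dcox_control()) {
  if (inherits(grid, "dcox_sim_config")) grid <- list(grid)
  stopifnot(length(grid) >= 1L,
            all(vapply(grid, inherits, logical(1), "dcox_sim_config")),
            replications >= 1L,
            all(ci_methods %in% c("wald", "boundary_mixture", "profile")))
  structure(
    list(grid = grid, replications = as.integer(replications),
         ci_methods = ci_methods, level = level,
         seed = as.integer(seed),
         parallel_workers = as.integer(parallel_workers),
         fit_control = fit_control),
    class = "dcox_study_config"
  )
}

## substream seed for (config index, replication); kept below 2^31
derive_seed <- function(master, config_idx, rep) {
  as.integer((as.numeric(master %% 1000003L) * 8191 +
                config_idx * 524287 + rep * 127) %% 2147483629 + 1)
}

truth_vector <- function(config) {
  p <- config$params
  sp <- config$spec
  setNames(
    c(p$a, p$b, p$beta_scale, p$beta_shape, p$sigma2),
    c("a", "b",
      if (length(p$beta_scale)) paste0("scale_", sp$scale_covariates),
      if (length(p$beta_shape)) paste0("shape_", sp$shape_covariates),
      "sigma2")
  )
}

config_cols <- function(cfg, idx) {
  tibble(config = idx, family = cfg$family, n = cfg$n,
         n_clusters = cfg$n_clusters, p_cens = cfg$p_cens,
         p_success = cfg$p_success,
         sigma2_true = cfg$params$sigma2)
}

study_lapply <- function(sc, tasks, fun) {
  if (sc$parallel_workers > 1L) {
    parallel::mclapply(tasks, fun, mc.cores = sc$parallel_workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(tasks, fun)
  }
}

## run one replication: simulate + fit (+ optional intervals)
run_replication <- function(sc, config, idx, r, theta, spec_fit = NULL,
                            ci_fun = NULL) {
  dat <- dcox_simulate(config, seed = derive_seed(sc$seed, idx, r),
                       theta = theta)
  spec <- spec_fit %||% config$spec
  fit <- tryCatch(
    suppressWarnings(dcox_fit(dat, spec, control = sc$fit_control)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(list(ok = FALSE))
  out <- list(ok = fit$converged, coef = coef(fit))
  if (!is.null(ci_fun) && fit$converged)
    out$intervals <- tryCatch(ci_fun(fit, sc$level, sc$ci_methods),
                              error = function(e) NULL)
  out
}

#' Bias study over a scenario grid
#'
#' For each scenario, generates `replications` datasets, fits the model
#' by marginal ML, and summarizes per-parameter mean estimate, bias,
#' empirical SD and Monte-Carlo standard error over the converged fits.
#' Non-converged replications are skipped and counted; a scenario cell
#' with more than 20% failures is flagged.
#'
#' @param sc A [dcox_study_config()].
#' @param spec_fit Optional [dcox_spec()] to fit instead of each
#'   scenario's generative spec (e.g. an over-parametrized model on
#'   scale-only data). Parameters absent from the generative truth are
#'   assigned truth 0.
#' @return A tibble of class `dcox_study_result` (one row per scenario x
#'   parameter) with attribute `"replications"`.
#' @export
dcox_run_bias_study <- function(sc, spec_fit = NULL) {
  stopifnot(inherits(sc, "dcox_study_config"))
  rows <- purrr::imap(sc$grid, function(config, idx) {
    theta <- if (config$p_cens > 0)
      dcox_calibrate_theta(config, seed = derive_seed(sc$seed, idx, 0L))
    else NULL
    reps <- study_lapply(sc, seq_len(sc$replications), function(r)
      run_replication(sc, config, idx, r, theta, spec_fit))
    ok <- vapply(reps, function(x) isTRUE(x$ok), logical(1))
    est <- do.call(rbind, lapply(reps[ok], `[[`, "coef"))
    truth <- truth_vector(config)
    full <- setNames(rep(0, ncol(est)), colnames(est))
    full[intersect(names(truth), names(full))] <-
      truth[intersect(names(truth), names(full))]
    m <- colMeans(est)
    s <- apply(est, 2, sd)
    dplyr::bind_cols(
      config_cols(config, idx)[rep(1, ncol(est)), ],
      tibble(parameter = colnames(est), truth = unname(full),
             mean_estimate = unname(m), bias = unname(m - full),
             sd = unname(s), mc_se = unname(s / sqrt(sum(ok))),
             n_converged = sum(ok), n_failed = sum(!ok),
             flagged = mean(!ok) > 0.2)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dcox_study_result", class(out))
  attr(out, "replications") <- sc$replications
  attr(out, "kind") <- "bias"
  out
}

## default per-replication interval builder
default_ci_fun <- function(fit, level, methods) {
  pieces <- list()
  if (any(c("wald", "boundary_mixture") %in% methods)) {
    info <- dcox_information(fit)
    if ("wald" %in% methods)
      pieces$wald <- dcox_wald_ci(fit, info, level)
    if ("boundary_mixture" %in% methods)
      pieces$mix <- dcox_mixture_ci(fit, info, level)
  }
  if ("profile" %in% methods)
    pieces$profile <- dcox_profile_ci(fit, level = level)
  dplyr::bind_rows(pieces)[, c("term", "lower", "upper", "method")]
}

#' Coverage study over a scenario grid
#'
#' As [dcox_run_bias_study()], additionally computing the requested
#' confidence intervals on every converged replication and reporting the
#' empirical coverage of the truth per parameter and method, with a
#' binomial standard error.
#'
#' @inheritParams dcox_run_bias_study
#' @param ci_fun Interval builder `function(fit, level, methods)`
#'   returning a data frame with columns `term`, `lower`, `upper`,
#'   `method`; the default computes the package's Wald, boundary-mixture
#'   and profile intervals. Exposed so tests can substitute degenerate
#'   intervals.
#' @return A tibble of class `dcox_study_result` (one row per scenario x
#'   parameter x method).
#' @export
dcox_run_coverage_study <- function(sc, spec_fit = NULL,
                                    ci_fun = default_ci_fun) {
  stopifnot(inherits(sc, "dcox_study_config"), length(sc$ci_methods) >= 1L)
  rows <- purrr::imap(sc$grid, function(config, idx) {
    theta <- if (config$p_cens > 0)
      dcox_calibrate_theta(config, seed = derive_seed(sc$seed, idx, 0L))
    else NULL
    reps <- study_lapply(sc, seq_len(sc$replications), function(r)
      run_replication(sc, config, idx, r, theta, spec_fit, ci_fun))
    ok <- vapply(reps, function(x)
      isTRUE(x$ok) && !is.null(x$intervals), logical(1))
    ints <- dplyr::bind_rows(lapply(which(ok), function(i)
      dplyr::mutate(reps[[i]]$intervals, .rep = i)))
    truth <- truth_vector(config)
    full_terms <- unique(ints$term)
    truth_full <- setNames(rep(0, length(full_terms)), full_terms)
    truth_full[intersect(names(truth), full_terms)] <-
      truth[intersect(names(truth), full_terms)]
    cells <- dplyr::group_by(ints, .data$term, .data$method)
    cov <- dplyr::summarise(
      cells,
      coverage = mean(.data$lower <= truth_full[unique(.data$term)] &
                        truth_full[unique(.data$term)] <= .data$upper),
      n = dplyr::n(), .groups = "drop")
    dplyr::bind_cols(
      config_cols(config, idx)[rep(1, nrow(cov)), ],
      tibble(parameter = cov$term, method = cov$method,
             truth = unname(truth_full[cov$term]),
             coverage = cov$coverage,
             coverage_se = sqrt(cov$coverage * (1 - cov$coverage) / cov$n),
             n_converged = sum(ok), n_failed = sum(!ok),
             flagged = mean(!ok) > 0.2)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dcox_study_result", class(out))
  attr(out, "replications") <- sc$replications
  attr(out, "kind") <- "coverage"
  out
}

#' Long-format study summary table
#'
#' Pivots a study result into a long table (scenario columns + parameter
#' + metric + value + Monte-Carlo SE), suitable for TSV export and for
#' lossless round-tripping.
#'
#' @param result A `dcox_study_result`.
#' @return A tibble with columns `config`, `family`, `n`, `n_clusters`,
#'   `p_cens`, `p_success`, `sigma2_true`, `parameter`, (`method`,)
#'   `metric`, `value`, `mc_se`.
#' @export
dcox_study_table <- function(result) {
  stopifnot(inherits(result, "dcox_study_result"))
  id <- c("config", "family", "n", "n_clusters", "p_cens", "p_success",
          "sigma2_true", "parameter")
  if (identical(attr(result, "kind"), "coverage")) {
    out <- tidyr::pivot_longer(
      dplyr::select(as_tibble(result), dplyr::all_of(c(id, "method")),
                    "truth", "coverage"),
      cols = c("truth", "coverage"),
      names_to = "metric", values_to = "value")
    se_map <- result$coverage_se
    names(se_map) <- paste(result$config, result$parameter, result$method)
    out$mc_se <- ifelse(out$metric == "coverage",
                        se_map[paste(out$config, out$parameter, out$method)],
                        NA_real_)
  } else {
    out <- tidyr::pivot_longer(
      dplyr::select(as_tibble(result), dplyr::all_of(id),
                    "truth", "mean_estimate", "bias", "sd"),
      cols = c("truth", "mean_estimate", "bias", "sd"),
      names_to = "metric", values_to = "value")
    se_map <- result$mc_se
    names(se_map) <- paste(result$config, result$parameter)
    out$mc_se <- ifelse(out$metric %in% c("mean_estimate", "bias"),
                        se_map[paste(out$config, out$parameter)],
                        NA_real_)
  }
  out
}

#' @export
autoplot.dcox_study_result <- function(object, ...) {
  kind <- attr(object, "kind") %||% "bias"
  df <- as_tibble(object)
  if (kind == "coverage") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter,
                                     y = .data$coverage,
                                     colour = .data$method)) +
      ggplot2::geom_point(position = ggplot2::position_dodge(0.4)) +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$coverage - 2 * .data$coverage_se,
                     ymax = .data$coverage + 2 * .data$coverage_se),
        width = 0.2, position = ggplot2::position_dodge(0.4)) +
      ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed") +
      ggplot2::facet_wrap(~config) +
      ggplot2::labs(y = "empirical coverage", x = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$bias)) +
      ggplot2::geom_col() +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$bias - 2 * .data$mc_se,
                     ymax = .data$bias + 2 * .data$mc_se), width = 0.2) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::facet_wrap(~config) +
      ggplot2::labs(y = "bias (mean estimate - truth)", x = NULL) +
      ggplot2::theme_minimal()
  }
}
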