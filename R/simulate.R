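## Synthetic clustered survival data ----------------------------------------
##
## The generator mirrors the simulation design used to study the model: a
## binary covariate "success" ~ Bernoulli(p_success) and a continuous
## "score" ~ Normal(0, 0.2) (variance), independent; one gamma frailty per
## cluster (mean 1, variance sigma2); event times by inverse-cumulative-
## hazard sampling from a unit exponential; censoring times Uniform(0,
## theta) with theta calibrated by Monte-Carlo root finding so that the
## population censoring probability equals p_cens.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Simulation scenario configuration
#'
#' Bundles a generative truth and the structural knobs of a simulated
#' clustered-survival scenario. The covariates are named `success`
#' (Bernoulli) and `score` (normal); `params$beta_scale` /
#' `params$beta_shape` attach to `(success, score)` in that order, so a
#' length-0 vector means the corresponding Cox term is absent.
#'
#' @param family `"weibull"` or `"gompertz"`.
#' @param params A [dcox_params()] giving the generative truth.
#' @param n Total sample size `N`.
#' @param n_clusters Number of clusters; subjects are allocated in equal
#'   blocks of `n / n_clusters` (any remainder spread over the first
#'   clusters).
#' @param p_cens Population censoring rate in `[0, 1)`; 0 disables
#'   censoring.
#' @param p_success Success probability of the binary covariate.
#' @param score_mean,score_var Mean and variance of the continuous
#'   covariate.
#' @param n_calibration Monte-Carlo sample size used to calibrate the
#'   censoring bound `theta`.
#' @return An object of class `dcox_sim_config`.
#' @export
dcox_sim_config <- function(family = c("weibull", "gompertz"),
                            params, n, n_clusters, p_cens = 0,
                            p_success = 0.25,
                            score_mean = 0, score_var = 0.2,
                            n_calibration = 1e6) {
  family <- match.arg(family)
  stopifnot(inherits(params, "dcox_params"),
            n >= n_clusters, n_clusters >= 1,
            p_cens >= 0, p_cens < 1,
            p_success >= 0, p_success <= 1, score_var > 0)
  covs <- c("success", "score")
  spec <- dcox_spec(family,
                    scale = covs[seq_along(params$beta_scale)],
                    shape = covs[seq_along(params$beta_shape)])
  structure(
    list(family = family, params = params, spec = spec,
         n = as.integer(n), n_clusters = as.integer(n_clusters),
         p_cens = p_cens, p_success = p_success,
         score_mean = score_mean, score_var = score_var,
         n_calibration = as.integer(n_calibration)),
    class = "dcox_sim_config"
  )
}

#' Draw the simulation covariates
#'
#' `success ~ Bernoulli(p_success)` and
#' `score ~ Normal(score_mean, score_var)`, independent.
#'
#' @param n Number of subjects.
#' @inheritParams dcox_sim_config
#' @param seed Optional integer seed (the caller's RNG state is
#'   restored afterwards).
#' @return A tibble with columns `success` and `score`.
#' @export
dcox_sample_covariates <- function(n, p_success, score_mean = 0,
                                   score_var = 0.2, seed = NULL) {
  with_seed(seed, tibble(
    success = rbinom(n, 1L, p_success),
    score = rnorm(n, score_mean, sqrt(score_var))
  ))
}

#' Draw shared frailties
#'
#' One gamma frailty per cluster with mean 1 and variance `sigma2`
#' (shape `1/sigma2`, scale `sigma2`); all ones when `sigma2 = 0`.
#'
#' @param n_clusters Number of clusters.
#' @param sigma2 Frailty variance.
#' @inheritParams dcox_sample_covariates
#' @return A tibble with columns `z` and `log_z`.
#' @export
dcox_sample_frailty <- function(n_clusters, sigma2, seed = NULL) {
  z <- with_seed(seed, {
    if (sigma2 < sigma2_floor) rep(1, n_clusters)
    else rgamma(n_clusters, shape = 1 / sigma2, scale = sigma2)
  })
  tibble(z = z, log_z = log(z))
}

## event times for a covariate tibble + per-subject frailty, vectorized
draw_event_times <- function(config, covariates, z_row, e = NULL) {
  p <- config$params
  sp <- config$spec
  Us <- as_cov_matrix(covariates, sp$scale_covariates)
  Uh <- as_cov_matrix(covariates, sp$shape_covariates)
  n <- nrow(covariates)
  eta_s <- if (ncol(Us)) drop(Us %*% p$beta_scale) else rep(0, n)
  eta_h <- if (ncol(Uh)) drop(Uh %*% p$beta_shape) else rep(0, n)
  e <- e %||% rexp(n)
  inv_cumhaz_internal(config$family, e, p$a, p$b, eta_s, eta_h, z_row)
}

calibrate_theta_impl <- function(config) {
  n <- config$n_calibration
  covs <- dcox_sample_covariates(n, config$p_success, config$score_mean,
                                 config$score_var)
  z <- if (config$params$sigma2 < sigma2_floor) rep(1, n)
       else rgamma(n, shape = 1 / config$params$sigma2,
                   scale = config$params$sigma2)
  T_ev <- draw_event_times(config, covs, z)
  ## P(censored | theta) on the fixed MC sample: E[min(T, theta)] / theta
  p_cens_at <- function(theta) mean(pmin(T_ev, theta)) / theta
  lo <- unname(quantile(T_ev, 0.001))
  hi <- unname(quantile(T_ev, 0.999))
  while (p_cens_at(lo) < config$p_cens) lo <- lo / 4
  it <- 0L
  while (p_cens_at(hi) > config$p_cens) {
    hi <- hi * 4
    it <- it + 1L
    if (it > 60L) abort("Could not bracket the censoring calibration root.")
  }
  uniroot(function(th) p_cens_at(th) - config$p_cens,
          lower = lo, upper = hi, tol = 1e-10 * hi)$root
}

#' Calibrate the uniform-censoring upper bound
#'
#' Finds `theta` such that, under `C ~ Uniform(0, theta)` independent of
#' the event time `T` drawn from the full generative model, the
#' population censoring probability `P(C < T)` equals `p_cens`. Uses the
#' smooth conditional form `p(theta) = E[min(T, theta)] / theta` on a
#' fixed Monte-Carlo sample of `n_calibration` event times (common random
#' numbers, so the root is deterministic given the seed), solved by
#' bracketed root finding.
#'
#' @param config A [dcox_sim_config()] with `p_cens > 0`.
#' @inheritParams dcox_sample_covariates
#' @return The calibrated `theta` (a positive scalar), or `Inf` when
#'   `p_cens = 0` (no censoring).
#' @export
dcox_calibrate_theta <- function(config, seed = NULL) {
  stopifnot(inherits(config, "dcox_sim_config"))
  if (config$p_cens == 0) return(Inf)
  with_seed(seed, calibrate_theta_impl(config))
}

#' Simulate a clustered right-censored survival dataset
#'
#' Draws covariates, one shared gamma frailty per cluster, event times by
#' inverting the conditional cumulative hazard at a unit-exponential
#' deviate, and (when `p_cens > 0`) censoring times
#' `Uniform(0, theta)`. The observed time is `min(T, C)` with
#' `status = 1` when the event is observed.
#'
#' @param config A [dcox_sim_config()].
#' @inheritParams dcox_sample_covariates
#' @param theta Optional pre-calibrated censoring bound (from
#'   [dcox_calibrate_theta()]); calibrated on the fly when `NULL` and
#'   `p_cens > 0`.
#' @return A tibble with columns `time`, `status` (1 = event), `cluster`,
#'   `success`, `score`; the calibrated `theta` is attached as attribute
#'   `"theta"`.
#' @export
dcox_simulate <- function(config, seed = NULL, theta = NULL) {
  stopifnot(inherits(config, "dcox_sim_config"))
  with_seed(seed, {
    if (config$p_cens > 0 && is.null(theta))
      theta <- calibrate_theta_impl(config)
    n <- config$n
    ncl <- config$n_clusters
    base <- n %/% ncl
    sizes <- rep(base, ncl) + (seq_len(ncl) <= n %% ncl)
    cluster <- rep(seq_len(ncl), times = sizes)
    covs <- dcox_sample_covariates(n, config$p_success, config$score_mean,
                                   config$score_var)
    z <- dcox_sample_frailty(ncl, config$params$sigma2)$z
    T_ev <- draw_event_times(config, covs, z[cluster])
    if (config$p_cens > 0) {
      C <- runif(n, 0, theta)
      time <- pmin(T_ev, C)
      status <- as.integer(T_ev <= C)
    } else {
      time <- T_ev
      status <- rep(1L, n)
    }
    out <- tibble(time = time, status = status, cluster = cluster,
                  success = covs$success, score = covs$score)
    attr(out, "theta") <- theta %||% Inf
    out
  })
}
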