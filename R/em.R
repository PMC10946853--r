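## EM estimation ------------------------------------------------------------
##
## Standard gamma-frailty EM. Because the frailty posterior for cluster i is
## gamma with shape 1/s2 + d_i and rate 1/s2 + H_i, the E-step reduces to the
## posterior mean
##     w_i = (1 + s2 d_i) / (1 + s2 H_i),
## and the M-step maximizes the conditional log-likelihood with log w_i as a
## fixed additive offset on the scale linear predictor (the frailty enters
## the hazard multiplicatively). The frailty variance is then updated by a
## one-dimensional maximization of the *marginal* log-likelihood in s2 at
## the current regression parameters. Each half-step increases the marginal
## log-likelihood, so the sweep trace is monotone; the fixed point coincides
## with the direct marginal-ML optimum.

em_posterior_log_mean <- function(dd, spec, params) {
  rt <- row_terms(spec$family, dd, params$a, params$b,
                  params$beta_scale, params$beta_shape)
  Hs <- as.vector(rowsum(exp(rt$logH), dd$cluster))
  s2 <- params$sigma2
  w <- if (s2 < sigma2_floor) rep(1, dd$n_clusters)
       else (1 + s2 * dd$d) / (1 + s2 * Hs)
  log(w)[dd$cluster]
}

dcox_fit_em_impl <- function(dd, spec, control, start = NULL) {
  theta <- start %||% start_values(dd, spec)
  k <- length(theta)
  zeta <- theta[-k]
  log_s2 <- theta[k]
  inner_control <- modifyList(control, list(multistart = 1L))
  ll <- loglik_engine(dd, spec, unpack_params(theta, spec, TRUE))
  ll_trace <- ll
  converged <- FALSE
  oscillated <- FALSE
  it <- 0L
  for (it in seq_len(control$em_max_iterations)) {
    params <- unpack_params(c(zeta, log_s2), spec, TRUE)
    ## E-step
    offset <- em_posterior_log_mean(dd, spec, params)
    ## M-step: conditional fit at fixed posterior frailty means
    m <- fit_core(dd, spec, zeta, inner_control, with_sigma2 = FALSE,
                  offset = offset)
    zeta_new <- m$theta
    ## s2 update: 1-D marginal-likelihood search at the new zeta
    prof <- function(ls2)
      loglik_engine(dd, spec, unpack_params(c(zeta_new, ls2), spec, TRUE))
    opt <- optimize(prof, interval = c(-30, 5), maximum = TRUE, tol = 1e-10)
    log_s2_new <- opt$maximum
    ll_new <- opt$objective
    ll0 <- loglik_engine(dd, spec,
                         unpack_params(zeta_new, spec, FALSE))
    if (ll0 > ll_new) {          # boundary beats the interior 1-D optimum
      ll_new <- ll0
      log_s2_new <- -30
    }
    if (ll_new < ll - 1e-6) {
      oscillated <- TRUE
      break
    }
    delta <- max(abs(c(zeta_new - zeta, log_s2_new - log_s2)))
    moved <- abs(ll_new - ll)
    zeta <- zeta_new
    log_s2 <- log_s2_new
    ll <- ll_new
    ll_trace <- c(ll_trace, ll)
    if (moved < control$em_tolerance && delta < 1e-8) {
      converged <- TRUE
      break
    }
  }
  boundary <- exp(log_s2) < control$boundary_epsilon
  with_sigma2 <- !boundary
  if (boundary) {
    final <- fit_core(dd, spec, zeta, inner_control, with_sigma2 = FALSE)
    theta_out <- final$theta
    ll <- final$loglik
    gn <- final$gradient_norm
  } else {
    theta_out <- c(zeta, log_s2)
    gn <- max(abs(loglik_grad_engine(dd, spec,
                                     unpack_params(theta_out, spec, TRUE),
                                     TRUE)))
  }
  core <- list(theta = theta_out, loglik = ll,
               converged = converged && !oscillated,
               n_iter = it, gradient_norm = gn)
  fit <- new_dcox_fit(dd, spec, control, core, with_sigma2, "em", boundary)
  fit$ll_trace <- ll_trace
  if (oscillated)
    warn("EM log-likelihood decreased; fit flagged as not converged.")
  fit
}

#' One EM sweep (E-step, M-step, frailty-variance update)
#'
#' Runs a single sweep of the gamma-frailty EM starting from the
#' parameters of `fit` and returns the updated parameter vector on the
#' estimation scale together with the marginal log-likelihood after the
#' sweep. At the marginal-ML optimum a sweep is a fixed point.
#'
#' @param fit A converged `dcox_fit`.
#' @return A list with `theta` and `loglik`.
#' @export
dcox_em_sweep <- function(fit) {
  dd <- fit$dd
  spec <- fit$spec
  theta <- if (fit$with_sigma2) fit$theta else c(fit$theta, -30)
  k <- length(theta)
  params <- unpack_params(theta, spec, TRUE)
  offset <- em_posterior_log_mean(dd, spec, params)
  inner_control <- modifyList(fit$control, list(multistart = 1L))
  m <- fit_core(dd, spec, theta[-k], inner_control, with_sigma2 = FALSE,
                offset = offset)
  prof <- function(ls2)
    loglik_engine(dd, spec, unpack_params(c(m$theta, ls2), spec, TRUE))
  opt <- optimize(prof, interval = c(-30, 5), maximum = TRUE, tol = 1e-10)
  list(theta = c(m$theta, opt$maximum), loglik = opt$objective)
}
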