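## Observed information and confidence intervals ----------------------------
##
## The information is computed on the "inference scale": (log a, log b,
## beta_scale, beta_shape, sigma2) — logs for the positive baseline
## parameters (whose Wald intervals are back-transformed), the frailty
## variance on its natural scale so that its variance feeds the
## truncated-normal / point-mass boundary mixture directly.

## loglik as a function of the inference-scale vector
infer_loglik_fn <- function(dd, spec) {
  function(x) {
    k <- length(x)
    s2 <- max(x[k], 0)
    p <- unpack_params(x[-k], spec, with_sigma2 = FALSE)
    p$sigma2 <- s2
    loglik_engine(dd, spec, p)
  }
}

infer_theta <- function(fit) {
  th <- if (fit$with_sigma2) fit$theta[-length(fit$theta)] else fit$theta
  c(th, fit$params$sigma2)
}

## central-difference Hessian with per-coordinate steps; coordinates with a
## lower bound at 0 (the frailty variance) are centered at >= 2h so the
## stencil stays in the domain
num_hessian <- function(f, x, lower0 = logical(length(x))) {
  k <- length(x)
  h <- (.Machine$double.eps)^0.25 * pmax(abs(x), 1e-2)
  x0 <- x
  x0[lower0] <- pmax(x0[lower0], 2 * h[lower0])
  H <- matrix(NA_real_, k, k)
  f0 <- f(x0)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x0 + ei) - 2 * f0 + f(x0 - ei)) / h[i]^2
    if (i < k) for (j in (i + 1L):k) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- (f(x0 + ei + ej) - f(x0 + ei - ej) -
                    f(x0 - ei + ej) + f(x0 - ei - ej)) / (4 * h[i] * h[j])
      H[j, i] <- H[i, j]
    }
  }
  (H + t(H)) / 2
}

#' Observed information and estimate covariance
#'
#' Computes the central-difference Hessian of the negative marginal
#' log-likelihood at the estimates, on the inference scale
#' `(log a, log b, beta_scale, beta_shape, sigma2)`, inverts it (with a
#' pseudo-inverse fallback when the Hessian is singular or indefinite,
#' flagged via `reliable = FALSE`), and derives `kappa`, the standard
#' deviation of `sqrt(N) * sigma2_hat` used by the boundary mixture
#' interval.
#'
#' @param fit A `dcox_fit`.
#' @return An object of class `dcox_information`: `vcov` (covariance of
#'   the estimates), `hessian`, `kappa`, `k`, `reliable`, `terms`.
#' @export
dcox_information <- function(fit) {
  dd <- fit$dd
  spec <- fit$spec
  x <- infer_theta(fit)
  k <- length(x)
  lower0 <- c(rep(FALSE, k - 1L), TRUE)
  f <- infer_loglik_fn(dd, spec)
  Hn <- num_hessian(function(z) -f(z), x, lower0)
  reliable <- TRUE
  ev <- eigen(Hn, symmetric = TRUE)
  if (any(ev$values <= 0) ||
      max(ev$values) / min(ev$values) > 1e12) {
    reliable <- FALSE
    warn("Observed information is singular or badly conditioned; intervals from it are flagged unreliable.")
    pos <- pmax(ev$values, max(ev$values) * 1e-12)
    V <- ev$vectors %*% diag(1 / pos, k) %*% t(ev$vectors)
  } else {
    V <- ev$vectors %*% diag(1 / ev$values, k) %*% t(ev$vectors)
  }
  V <- (V + t(V)) / 2
  terms <- param_names(spec)
  dimnames(V) <- dimnames(Hn) <- list(terms, terms)
  structure(
    list(vcov = V, hessian = Hn,
         kappa = sqrt(max(fit$nobs * V[k, k], 0)),
         k = k, reliable = reliable, terms = terms),
    class = "dcox_information"
  )
}

#' @export
print.dcox_information <- function(x, ...) {
  cat("<dcox_information> k = ", x$k,
      ", kappa = ", signif(x$kappa, 5),
      if (!x$reliable) "  [UNRELIABLE]", "\n", sep = "")
  invisible(x)
}

## Wald intervals -----------------------------------------------------------

#' Wald (SE-based) confidence intervals
#'
#' Normal-theory intervals from the inverse observed information:
#' `estimate +/- z * SE` on the inference scale, back-transformed by
#' exponentiation for `a` and `b`. The frailty variance is excluded —
#' use [dcox_mixture_ci()] (boundary-aware) or [dcox_profile_ci()] for it.
#'
#' @param fit A `dcox_fit`.
#' @param info Optional precomputed [dcox_information()].
#' @param level Confidence level.
#' @return A tibble with columns `term`, `estimate`, `lower`, `upper`,
#'   `level`, `method`, `reliable`.
#' @export
dcox_wald_ci <- function(fit, info = NULL, level = 0.95) {
  info <- info %||% dcox_information(fit)
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(diag(info$vcov), 0))
  x <- infer_theta(fit)
  k <- info$k
  idx <- seq_len(k - 1L)                 # all but sigma2
  lower <- x[idx] - z * se[idx]
  upper <- x[idx] + z * se[idx]
  est <- x[idx]
  ## back-transform the two log-scale baseline parameters
  logpos <- 1:2
  est[logpos] <- exp(est[logpos])
  lower[logpos] <- exp(lower[logpos])
  upper[logpos] <- exp(upper[logpos])
  terms <- c("a", "b", info$terms[setdiff(idx, logpos)])
  tibble(term = terms, estimate = est, lower = lower, upper = upper,
         level = level, method = "wald", reliable = info$reliable)
}

## Boundary mixture for sigma2 ----------------------------------------------
##
## Asymptotically sqrt(N) * sigma2_hat follows a mixture of a truncated
## normal TN(nu, kappa^2, 0, Inf) with weight Phi(nu/kappa) and a point
## mass at zero with weight Phi(-nu/kappa); with the plug-in nu =
## sqrt(N) * sigma2_hat the mixture CDF on x >= 0 collapses to
## Phi((x - nu)/kappa), carrying an atom of Phi(-nu/kappa) at 0.

mixture_cdf <- function(x, nu, kappa) {
  ifelse(x < 0, 0, pnorm((x - nu) / kappa))
}

mixture_quantile <- function(p, nu, kappa) {
  pmax(0, nu + kappa * qnorm(p))
}

#' Boundary-aware mixture interval for the frailty variance
#'
#' Confidence interval for `sigma2` built from the asymptotic mixture of
#' a truncated normal and a point mass at zero that governs a variance
#' component at or near its boundary. Endpoints are closed-form quantiles
#' of the plug-in mixture, mapped back to the `sigma2` scale; the lower
#' endpoint is exactly 0 whenever the mixture's atom covers the lower
#' tail probability (in particular whenever `sigma2_hat = 0`).
#'
#' @inheritParams dcox_wald_ci
#' @return A one-row tibble (`term = "sigma2"`, method
#'   `"boundary_mixture"`).
#' @export
dcox_mixture_ci <- function(fit, info = NULL, level = 0.95) {
  info <- info %||% dcox_information(fit)
  alpha <- 1 - level
  sqn <- sqrt(fit$nobs)
  nu <- sqn * fit$params$sigma2
  kappa <- info$kappa
  lower <- mixture_quantile(alpha / 2, nu, kappa) / sqn
  upper <- mixture_quantile(1 - alpha / 2, nu, kappa) / sqn
  tibble(term = "sigma2", estimate = fit$params$sigma2,
         lower = lower, upper = upper, level = level,
         method = "boundary_mixture", reliable = info$reliable)
}

## Profile-likelihood intervals ---------------------------------------------

## maximize the loglik with estimation-scale coordinate j fixed at v;
## start from `start` (free coordinates); returns list(loglik, free)
profile_inner <- function(dd, spec, j, v, start, control) {
  k_full <- length(start) + 1L
  negll <- function(fr) {
    th <- numeric(k_full)
    th[-j] <- fr
    th[j] <- v
    val <- loglik_engine(dd, spec, unpack_params(th, spec, TRUE))
    if (!is.finite(val)) return(1e10)
    -val
  }
  neggr <- function(fr) {
    th <- numeric(k_full)
    th[-j] <- fr
    th[j] <- v
    g <- -loglik_grad_engine(dd, spec, unpack_params(th, spec, TRUE), TRUE)
    if (!all(is.finite(g))) g[] <- 0
    g[-j]
  }
  lower <- rep(-Inf, k_full)
  upper <- rep(Inf, k_full)
  lower[k_full] <- -30
  upper[k_full] <- 6
  res <- nlminb(start, negll, neggr,
                lower = lower[-j], upper = upper[-j],
                control = list(iter.max = control$max_iterations,
                               rel.tol = 1e-12))
  list(loglik = -res$objective, free = res$par)
}

#' Profile-likelihood confidence intervals
#'
#' Inverts the likelihood-ratio test: an endpoint `v` of the interval for
#' one parameter satisfies `2 * (l_hat - l_profile(v)) = qchisq(level, 1)`
#' (3.84 at the 95% level), where `l_profile` re-maximizes the marginal
#' log-likelihood over all remaining parameters (with `sigma2` kept
#' non-negative). Roots are bracketed outward from the Wald endpoints with
#' warm-started inner maximizations. For `sigma2` the profile respects the
#' boundary: if the threshold is not crossed below the estimate the lower
#' endpoint is 0. A side on which the profile never crosses the threshold
#' within the expanding bracket yields an infinite endpoint with a
#' warning.
#'
#' @inheritParams dcox_wald_ci
#' @param parm Character vector of parameter names to profile (as in the
#'   rows of [tidy()]: `"a"`, `"b"`, `"scale_<cov>"`, `"shape_<cov>"`,
#'   `"sigma2"`); default all.
#' @param endpoint_tol Required accuracy `|2 * dl - chisq|` at the
#'   endpoints.
#' @return A tibble with one row per profiled parameter, method
#'   `"profile"`.
#' @export
dcox_profile_ci <- function(fit, parm = NULL, info = NULL, level = 0.95,
                            endpoint_tol = 1e-3) {
  spec <- fit$spec
  dd <- fit$dd
  control <- modifyList(fit$control, list(multistart = 1L))
  crit <- qchisq(level, 1)
  l_hat <- fit$loglik
  theta_full <- if (fit$with_sigma2) fit$theta else c(fit$theta, -30)
  k <- length(theta_full)
  est_names <- param_names(spec, sigma2 = FALSE)   # estimation-scale names
  out_names <- c("a", "b", est_names[-(1:2)], "sigma2")
  parm <- parm %||% out_names
  bad <- setdiff(parm, out_names)
  if (length(bad))
    abort(paste0("Unknown parameter(s): ", paste(bad, collapse = ", ")))
  wald <- tryCatch(dcox_wald_ci(fit, info = info, level = level),
                   error = function(e) NULL)
  rows <- purrr::map(parm, function(nm) {
    j <- match(nm, out_names)
    is_sigma2 <- nm == "sigma2"
    is_logpar <- j %in% 1:2
    ## profiling coordinate value at the MLE, on the profiling scale
    v_hat <- if (is_sigma2) fit$params$sigma2 else theta_full[j]
    ## profile loglik at v (profiling scale), warm-started
    warm <- new.env(parent = emptyenv())
    warm$free <- theta_full[-j]
    pl <- function(v) {
      vv <- if (is_sigma2) {
        if (v <= 0) -30 else log(v)
      } else v
      res <- profile_inner(dd, spec, j, vv, warm$free, control)
      warm$free <- res$free
      res$loglik
    }
    g <- function(v) 2 * (l_hat - pl(v)) - crit
    ## initial step out: Wald half-width on the profiling scale
    step0 <- profile_step(fit, wald, nm, j, v_hat)
    lo <- profile_root(g, v_hat, -step0, is_sigma2, endpoint_tol)
    hi <- profile_root(g, v_hat, step0, FALSE, endpoint_tol)
    lower <- lo; upper <- hi
    if (is_logpar) {
      lower <- exp(lo); upper <- exp(hi)
    }
    est <- if (is_sigma2) fit$params$sigma2
           else if (is_logpar) exp(theta_full[j]) else theta_full[j]
    tibble(term = nm, estimate = est, lower = lower, upper = upper,
           level = level, method = "profile", reliable = TRUE)
  })
  dplyr::bind_rows(rows)
}

## reasonable bracketing step from the Wald interval when available
profile_step <- function(fit, wald, nm, j, v_hat) {
  if (!is.null(wald) && nm %in% wald$term && nm != "sigma2") {
    row <- wald[wald$term == nm, ]
    if (j %in% 1:2) {
      s <- (log(row$upper) - log(row$lower)) / 2
    } else {
      s <- (row$upper - row$lower) / 2
    }
    if (is.finite(s) && s > 0) return(s)
  }
  if (nm == "sigma2") return(max(fit$params$sigma2, 0.25))
  0.5
}

## one-sided root search: expand from v_hat by `step` (signed) until the
## threshold is crossed, then uniroot; boundary-limited for sigma2's lower
## side
profile_root <- function(g, v_hat, step, floor_zero, endpoint_tol) {
  v <- v_hat + step
  if (floor_zero) v <- max(v, 0)
  for (i in 1:40) {
    if (floor_zero && v <= 0) {
      if (g(0) < 0) return(0)          # threshold never crossed above 0
      break
    }
    if (g(v) >= 0) break
    v <- v_hat + 2 * (v - v_hat)
    if (floor_zero) v <- max(v, 0)
    if (i == 40) {
      warn("Profile likelihood is flat; interval endpoint unbounded.")
      return(sign(step) * Inf)
    }
  }
  lower <- min(v_hat, v)
  upper <- max(v_hat, v)
  if (floor_zero) lower <- max(lower, 0)
  r <- uniroot(g, lower = lower, upper = upper, tol = 1e-10)
  ## polish to the requested residual accuracy
  if (abs(g(r$root)) > endpoint_tol)
    r <- uniroot(g, lower = lower, upper = upper, tol = 1e-14)
  r$root
}

## Coverage -----------------------------------------------------------------

#' Empirical coverage of a set of confidence intervals
#'
#' Fraction of replications whose interval contains the true value,
#' reported with a binomial standard error.
#'
#' @param intervals Data frame with columns `lower` and `upper`, one row
#'   per replication.
#' @param truth The true parameter value.
#' @return A one-row tibble: `coverage`, `se`, `n`.
#' @export
coverage_probability <- function(intervals, truth) {
  stopifnot(all(c("lower", "upper") %in% names(intervals)),
            nrow(intervals) >= 1L)
  hit <- intervals$lower <= truth & truth <= intervals$upper
  p <- mean(hit)
  tibble(coverage = p, se = sqrt(p * (1 - p) / length(hit)),
         n = length(hit))
}

#' @export
confint.dcox_fit <- function(object, parm = NULL, level = 0.95,
                             method = c("wald", "profile", "mixture"),
                             ...) {
  method <- match.arg(method)
  out <- switch(method,
    wald = {
      info <- dcox_information(object)
      dplyr::bind_rows(dcox_wald_ci(object, info, level),
                       dcox_mixture_ci(object, info, level))
    },
    profile = dcox_profile_ci(object, parm = parm, level = level),
    mixture = dcox_mixture_ci(object, level = level)
  )
  if (!is.null(parm) && method != "profile")
    out <- out[out$term %in% parm, ]
  out
}
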