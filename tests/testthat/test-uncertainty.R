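seeded_gompertz_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      cfg <- dcox_sim_config("gompertz",
                             gomp_truth(1, c(0.5, 1), c(0.05, 0.1)),
                             n = 800, n_clusters = 80, p_cens = 0)
      fit <<- dcox_fit(dcox_simulate(cfg, seed = 71), cfg$spec)
    }
    fit
  }
})

test_that("observed information is symmetric and matches an independent Hessian", {
  fit <- seeded_gompertz_fit()
  info <- dcox_information(fit)
  expect_identical(info$hessian, t(info$hessian))
  expect_identical(info$vcov, t(info$vcov))
  expect_equal(info$kappa^2, fit$nobs * info$vcov["sigma2", "sigma2"],
               tolerance = 1e-10)
  skip_if_not_installed("pracma")
  f <- doublecox:::infer_loglik_fn(fit$dd, fit$spec)
  x <- doublecox:::infer_theta(fit)
  H_oracle <- -pracma::hessian(f, x)
  expect_equal(info$hessian, H_oracle, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("exponential sub-model information for the log rate equals the event count", {
  # d mu - e^mu R in mu = log(rate): second derivative -e^mu R = -d at MLE
  cfg <- dcox_sim_config("weibull", dcox_params(10, 1, sigma2 = 0),
                         n = 400, n_clusters = 8, p_cens = 0)
  dat <- dcox_simulate(cfg, seed = 5)
  fit <- suppressWarnings(dcox_fit(dat, dcox_spec("weibull")))
  info <- dcox_information(fit)
  d <- sum(dat$status)
  expect_equal(info$hessian["log(a)", "log(a)"], d, tolerance = 1e-4 * d)
})

test_that("Wald intervals have the right half-width and back-transform", {
  fit <- seeded_gompertz_fit()
  info <- dcox_information(fit)
  ci <- dcox_wald_ci(fit, info, level = 0.95)
  z <- qnorm(0.975)
  # beta rows: half-width equals z * SE on the natural scale
  se_score <- sqrt(info$vcov["scale_score", "scale_score"])
  row <- ci[ci$term == "scale_score", ]
  expect_equal(unname((row$upper - row$lower) / 2), z * se_score,
               tolerance = 1e-10)
  # a: symmetric on the log scale hence asymmetric about the estimate
  rowa <- ci[ci$term == "a", ]
  expect_equal(log(rowa$upper) - log(rowa$estimate),
               log(rowa$estimate) - log(rowa$lower), tolerance = 1e-10)
  expect_gt((rowa$upper - rowa$estimate) - (rowa$estimate - rowa$lower), 0)
  expect_false("sigma2" %in% ci$term)
})

test_that("the boundary mixture CDF/quantile pair is consistent and matches Monte Carlo", {
  nu <- 1.7; kappa <- 1.3
  # quantile inverts the CDF wherever the CDF is continuous and increasing
  for (p in seq(0.05, 0.95, by = 0.05)) {
    q <- doublecox:::mixture_quantile(p, nu, kappa)
    if (q > 0)
      expect_equal(doublecox:::mixture_cdf(q, nu, kappa), p, tolerance = 1e-10)
    else
      expect_lte(p, doublecox:::mixture_cdf(0, nu, kappa))
  }
  # total mass 1
  expect_equal(doublecox:::mixture_cdf(Inf, nu, kappa), 1)
  # the mixture is the zero-censored normal: MC oracle with 1e6 draws
  set.seed(404)
  draws <- pmax(0, rnorm(1e6, nu, kappa))
  for (p in c(0.025, 0.5, 0.975)) {
    expect_equal(doublecox:::mixture_quantile(p, nu, kappa),
                 unname(quantile(draws, p)), tolerance = 2e-3)
  }
  # at sigma2_hat = 0 the atom has weight 1/2 and the lower endpoint is 0
  expect_equal(doublecox:::mixture_cdf(0, 0, kappa), 0.5)
  expect_identical(doublecox:::mixture_quantile(0.025, 0, kappa), 0)
})

test_that("the mixture interval converges to Wald far from the boundary and floors at 0", {
  fit <- seeded_gompertz_fit()
  info <- dcox_information(fit)
  ci <- dcox_mixture_ci(fit, info)
  # here sigma2_hat is many SEs above zero: plain Wald on the natural scale
  se <- info$kappa / sqrt(fit$nobs)
  expect_equal(ci$lower, fit$params$sigma2 - qnorm(0.975) * se,
               tolerance = 1e-10)
  expect_equal(ci$upper, fit$params$sigma2 + qnorm(0.975) * se,
               tolerance = 1e-10)
  expect_gte(ci$lower, 0)
})

test_that("profile intervals satisfy the likelihood-ratio endpoint equation", {
  fit <- seeded_gompertz_fit()
  ci <- dcox_profile_ci(fit, parm = c("scale_success", "sigma2"))
  crit <- qchisq(0.95, 1)
  ctrl <- utils::modifyList(fit$control, list(multistart = 1L))
  # recompute the profile log-likelihood at the returned endpoints
  check_endpoint <- function(term, value, profiling_scale_value, j) {
    pl <- doublecox:::profile_inner(fit$dd, fit$spec, j,
                                    profiling_scale_value,
                                    fit$theta[-j], ctrl)$loglik
    2 * (fit$loglik - pl)
  }
  # scale_success is coordinate 3 on the estimation scale
  row <- ci[ci$term == "scale_success", ]
  expect_equal(check_endpoint("scale_success", row$lower, row$lower, 3L),
               crit, tolerance = 1e-3)
  expect_equal(check_endpoint("scale_success", row$upper, row$upper, 3L),
               crit, tolerance = 1e-3)
  # sigma2 is the last coordinate, profiled on the natural scale
  k <- length(fit$theta)
  rs <- ci[ci$term == "sigma2", ]
  expect_equal(check_endpoint("sigma2", rs$upper, log(rs$upper), k),
               crit, tolerance = 1e-3)
  # the MLE lies inside its own interval
  expect_lt(row$lower, row$estimate)
  expect_gt(row$upper, row$estimate)
  expect_true(rs$lower <= rs$estimate & rs$estimate <= rs$upper)
})

test_that("Wald and profile intervals agree in the quadratic large-N limit", {
  cfg <- dcox_sim_config("weibull", weib_truth(1, c(0.5, 1), c(0.05, 0.1)),
                         n = 10000, n_clusters = 100, p_cens = 0)
  fit <- dcox_fit(dcox_simulate(cfg, seed = 77), cfg$spec)
  info <- dcox_information(fit)
  w <- dcox_wald_ci(fit, info)
  p <- dcox_profile_ci(fit, parm = "scale_success", info = info)
  width_w <- with(w[w$term == "scale_success", ], upper - lower)
  width_p <- with(p, upper - lower)
  expect_lt(abs(width_p - width_w) / width_w, 0.05)
})

test_that("coverage_probability counts hits with a binomial SE", {
  ints <- tibble::tibble(lower = c(-Inf, -Inf), upper = c(Inf, Inf))
  expect_equal(coverage_probability(ints, 3.2)$coverage, 1)
  miss <- tibble::tibble(lower = c(1, 2), upper = c(1.5, 2.5))
  expect_equal(coverage_probability(miss, 0)$coverage, 0)
  # textbook sanity: 95% normal-mean intervals cover ~95%
  set.seed(99)
  n <- 30
  reps <- 2000
  x <- matrix(rnorm(n * reps), nrow = reps)
  m <- rowMeans(x)
  half <- qnorm(0.975) / sqrt(n)
  cov <- coverage_probability(tibble::tibble(lower = m - half,
                                             upper = m + half), 0)
  expect_equal(cov$coverage, 0.95, tolerance = 3 * cov$se / 0.95 + 0.01)
  expect_equal(cov$se, sqrt(cov$coverage * (1 - cov$coverage) / reps))
})
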