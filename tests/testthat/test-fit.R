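test_that("maximum likelihood recovers the generating parameters at large N", {
  pp <- weib_truth(1, c(0.5, 1), c(0.05, 0.1))
  cfg <- dcox_sim_config("weibull", pp, n = 4000, n_clusters = 100,
                         p_cens = 0)
  dat <- dcox_simulate(cfg, seed = 21)
  fit <- dcox_fit(dat, cfg$spec)
  expect_true(fit$converged)
  est <- coef(fit)
  truth <- c(a = 20, b = 1.5, scale_success = 0.5, scale_score = 1,
             shape_success = 0.05, shape_score = 0.1, sigma2 = 1)
  # loose single-replication check: each estimate within plausible
  # sampling error of the truth
  expect_equal(unname(est["b"]), 1.5, tolerance = 0.1)
  expect_equal(unname(est["scale_score"]), 1, tolerance = 0.35)
  expect_equal(unname(est["sigma2"]), 1, tolerance = 0.5)
  # the fitted optimum can never fall below the likelihood at the truth
  expect_gte(fit$loglik, dcox_loglik(dat, cfg$spec, pp) - 1e-6)
})

test_that("no-frailty fits satisfy the score identity sum(H) = events", {
  # at any interior optimum with sigma2 = 0 the score in log a forces the
  # total fitted cumulative hazard to equal the event count; for b = 1 this
  # is the exponential MLE a_hat = total time / events
  cfg <- dcox_sim_config("weibull", dcox_params(10, 1, sigma2 = 0),
                         n = 600, n_clusters = 10, p_cens = 0)
  dat <- dcox_simulate(cfg, seed = 5)
  fit <- suppressWarnings(dcox_fit(dat, dcox_spec("weibull")))
  expect_true(fit$boundary)
  H_hat <- sum(dcox_cumhaz(dat$time, fit$spec, fit$params))
  expect_equal(H_hat, sum(dat$status), tolerance = 1e-6)
  # b_hat close to 1, and then a_hat close to the exponential MLE
  expect_equal(unname(coef(fit)["b"]), 1, tolerance = 0.05)
  expect_equal(unname(coef(fit)["a"]), sum(dat$time) / sum(dat$status),
               tolerance = 0.1)
})

test_that("frailty variance lands on the boundary for frailty-free data", {
  cfg <- dcox_sim_config("weibull", weib_truth(0, c(0.5, 1), c(0.05, 0.1)),
                         n = 1000, n_clusters = 100, p_cens = 0)
  n_boundary <- 0L
  for (s in 1:7) {
    fit <- suppressWarnings(dcox_fit(dcox_simulate(cfg, seed = s), cfg$spec))
    if (fit$boundary) n_boundary <- n_boundary + 1L
    expect_identical(fit$params$sigma2 == 0, fit$boundary)
  }
  expect_gt(n_boundary, 3L)  # majority of replications
})

test_that("all-censored data is rejected for frailty models", {
  dat <- tibble::tibble(time = 1:4, status = 0, cluster = c(1, 1, 2, 2))
  expect_error(dcox_fit(dat, dcox_spec("weibull")), "censored")
})

test_that("estimates are equivariant under covariate shifts (scale term)", {
  cfg <- dcox_sim_config("gompertz",
                         gomp_truth(1, beta_scale = c(-0.5, -1)),
                         n = 500, n_clusters = 25, p_cens = 0)
  dat <- dcox_simulate(cfg, seed = 9)
  sp <- dcox_spec("gompertz", scale = c("success", "score"))
  fit1 <- dcox_fit(dat, sp)
  shifted <- dplyr::mutate(dat, success = success + 2)
  fit2 <- dcox_fit(shifted, sp)
  # shifting u by c rescales a by exp(c * beta); beta itself is unchanged
  expect_equal(coef(fit2)[["scale_success"]], coef(fit1)[["scale_success"]],
               tolerance = 1e-3)
  expect_equal(log(coef(fit2)[["a"]]) + 2 * coef(fit2)[["scale_success"]],
               log(coef(fit1)[["a"]]), tolerance = 1e-3)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
})

test_that("the reduced scale-only model nests inside the double-Cox model", {
  cfg <- dcox_sim_config("gompertz",
                         gomp_truth(2, beta_scale = c(-0.5, -1)),
                         n = 1500, n_clusters = 100, p_cens = 0)
  dat <- dcox_simulate(cfg, seed = 17)
  reduced <- dcox_fit(dat, dcox_spec("gompertz", scale = c("success", "score")))
  full <- dcox_fit(dat, full_spec("gompertz"))
  expect_lte(reduced$loglik, full$loglik + 1e-6)
  # scale coefficients agree between the two fits within sampling noise
  # (the superfluous shape term inflates the variance but not the target)
  expect_lt(abs(coef(full)[["scale_success"]] -
                  coef(reduced)[["scale_success"]]), 0.3)
})

test_that("EM and direct maximization agree", {
  cfg <- dcox_sim_config("gompertz",
                         gomp_truth(1, c(0.5, 1), c(0.05, 0.1)),
                         n = 600, n_clusters = 60, p_cens = 0)
  dat <- dcox_simulate(cfg, seed = 31)
  fit_d <- dcox_fit(dat, cfg$spec)
  fit_e <- dcox_fit(dat, cfg$spec, method = "em")
  expect_true(fit_e$converged)
  expect_equal(fit_e$theta, fit_d$theta, tolerance = 1e-4)
  expect_equal(fit_e$loglik, fit_d$loglik, tolerance = 1e-6)
})

test_that("one EM sweep from the direct optimum is (numerically) a fixed point", {
  cfg <- dcox_sim_config("gompertz", gomp_truth(1, c(0.5, 1)),
                         n = 500, n_clusters = 50, p_cens = 0)
  dat <- dcox_simulate(cfg, seed = 41)
  fit <- dcox_fit(dat, cfg$spec)
  sw <- dcox_em_sweep(fit)
  expect_lt(max(abs(sw$theta - fit$theta)), 1e-4)
})

test_that("the EM marginal log-likelihood trace is monotone non-decreasing", {
  cfg <- dcox_sim_config("weibull", weib_truth(1, c(0.5, 1)),
                         n = 300, n_clusters = 30, p_cens = 0)
  dat <- dcox_simulate(cfg, seed = 51)
  fit <- dcox_fit(dat, cfg$spec, method = "em")
  tr <- fit$ll_trace
  expect_gt(length(tr), 3L)
  expect_true(all(diff(tr) > -1e-8))
})

test_that("multistart never returns a worse optimum than the plain start", {
  cfg <- dcox_sim_config("weibull", weib_truth(2, c(0.5, 1), c(0.05, 0.1)),
                         n = 400, n_clusters = 40, p_cens = 0)
  dat <- dcox_simulate(cfg, seed = 61)
  f1 <- suppressWarnings(dcox_fit(dat, cfg$spec,
                                  control = dcox_control(multistart = 1)))
  f3 <- suppressWarnings(dcox_fit(dat, cfg$spec,
                                  control = dcox_control(multistart = 3)))
  expect_gte(f3$loglik, f1$loglik - 1e-8)
})
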