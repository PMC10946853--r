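test_that("covariate sampler matches its design", {
  z <- dcox_sample_covariates(100, p_success = 0, seed = 1)
  expect_true(all(z$success == 0))
  big <- dcox_sample_covariates(1e5, p_success = 0.25, seed = 2)
  expect_lt(abs(var(big$score) - 0.2), 0.01)
  expect_lt(abs(mean(big$success) - 0.25), 0.01)
  expect_lt(abs(cor(big$success, big$score)), 0.01)
})

test_that("frailty sampler has gamma(1/s2, s2) law with mean 1", {
  ones <- dcox_sample_frailty(50, sigma2 = 0, seed = 1)
  expect_identical(ones$z, rep(1, 50))
  expect_identical(ones$log_z, rep(0, 50))
  fr <- dcox_sample_frailty(1e5, sigma2 = 2, seed = 3)
  expect_equal(mean(fr$z), 1, tolerance = 0.02)
  expect_equal(var(fr$z), 2, tolerance = 0.1)
  ks <- suppressWarnings(
    ks.test(fr$z, function(q) pgamma(q, shape = 0.5, scale = 2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("censoring calibration matches the analytic exponential solution", {
  # Weibull with b = 1, no frailty: T ~ Exp(rate 1/a), for which
  # P(censored | theta) = 1 - (1 - e^(-lambda theta)) / (lambda theta)
  # complement form: p(theta) = (1 - exp(-l t))/(l t) is P(event)... use
  # the package's definition p_cens = E[min(T, theta)]/theta directly:
  # E[min(T,theta)]/theta = (1 - e^(-lambda theta)) / (lambda theta)
  a <- 10; lambda <- 1 / a; p_cens <- 0.4
  cfg <- dcox_sim_config("weibull", dcox_params(a, 1, sigma2 = 0),
                         n = 100, n_clusters = 10, p_cens = p_cens,
                         n_calibration = 1e6)
  analytic <- uniroot(function(th) (1 - exp(-lambda * th)) / (lambda * th) - p_cens,
                      c(0.1, 500), tol = 1e-12)$root
  th_hat <- dcox_calibrate_theta(cfg, seed = 11)
  expect_equal(th_hat, analytic, tolerance = 0.002)
  # no censoring requested: sentinel
  cfg0 <- dcox_sim_config("weibull", dcox_params(a, 1, sigma2 = 0),
                          n = 100, n_clusters = 10, p_cens = 0)
  expect_identical(dcox_calibrate_theta(cfg0), Inf)
})

test_that("theta is monotone in the requested censoring rate", {
  base <- function(p) dcox_sim_config("gompertz", gomp_truth(1),
                                      n = 100, n_clusters = 10, p_cens = p,
                                      n_calibration = 2e5)
  th <- vapply(c(0.2, 0.4, 0.8), function(p)
    dcox_calibrate_theta(base(p), seed = 13), numeric(1))
  expect_true(all(diff(th) < 0))   # more censoring -> smaller theta
})

test_that("generated datasets hit the requested censoring rate", {
  # many clusters so the shared frailty barely correlates the empirical rate
  cfg <- dcox_sim_config("weibull", weib_truth(1, c(0.5, 1), c(0.05, 0.1)),
                         n = 1e5, n_clusters = 1e4, p_cens = 0.4,
                         n_calibration = 1e6)
  dat <- dcox_simulate(cfg, seed = 19)
  expect_lt(abs(mean(dat$status == 0) - 0.4), 0.012)
  # no censoring: all rows are events
  cfg0 <- dcox_sim_config("weibull", weib_truth(1), n = 500,
                          n_clusters = 10, p_cens = 0)
  expect_true(all(dcox_simulate(cfg0, seed = 2)$status == 1))
})

test_that("generated times follow the marginal survival law across clusters", {
  # one subject per cluster: unconditional times are iid with survival
  # (1 + s2 H)^(-1/s2)
  cfg <- dcox_sim_config("gompertz", gomp_truth(1), n = 2e4,
                         n_clusters = 2e4, p_cens = 0)
  dat <- dcox_simulate(cfg, seed = 23)
  sp <- dcox_spec("gompertz")
  cdf <- function(q) 1 - dcox_survival(q, sp, gomp_truth(1))
  ks <- suppressWarnings(ks.test(dat$time, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster sharing induces the gamma-frailty Kendall tau", {
  # pairs in the same cluster have tau = s2 / (s2 + 2); s2 = 2 -> 1/2
  cfg <- dcox_sim_config("weibull", weib_truth(2), n = 8000,
                         n_clusters = 4000, p_cens = 0)
  dat <- dcox_simulate(cfg, seed = 29)
  first <- dat[!duplicated(dat$cluster), ]
  second <- dat[duplicated(dat$cluster), ]
  tau <- cor(first$time, second$time, method = "kendall")
  expect_equal(tau, 0.5, tolerance = 0.04)
})

test_that("simulation is reproducible and allocates clusters in blocks", {
  cfg <- dcox_sim_config("weibull", weib_truth(1, c(0.5, 1)), n = 103,
                         n_clusters = 10, p_cens = 0)
  d1 <- dcox_simulate(cfg, seed = 37)
  d2 <- dcox_simulate(cfg, seed = 37)
  expect_identical(d1, d2)
  sizes <- as.vector(table(d1$cluster))
  expect_equal(sort(unique(sizes)), c(10, 11))
  expect_equal(sum(sizes), 103)
  # the caller's RNG stream is left untouched
  set.seed(1); before <- .Random.seed
  invisible(dcox_simulate(cfg, seed = 37))
  expect_identical(.Random.seed, before)
})

test_that("refitting simulated data recovers the truth end to end", {
  pp <- gomp_truth(1, c(-0.5, -1))
  cfg <- dcox_sim_config("gompertz", pp, n = 3000, n_clusters = 100,
                         p_cens = 0)
  fit <- dcox_fit(dcox_simulate(cfg, seed = 43), cfg$spec)
  expect_equal(coef(fit)[["scale_success"]], -0.5, tolerance = 0.2)
  expect_equal(coef(fit)[["scale_score"]], -1, tolerance = 0.25)
  expect_equal(coef(fit)[["b"]], 0.1, tolerance = 0.015)
})
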