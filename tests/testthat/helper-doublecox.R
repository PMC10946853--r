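# shared fixtures: all data is generated in code, tiny and seeded

# Table-of-truth parameter settings used throughout: a Gompertz baseline
# with a realistic human life expectancy and a Weibull baseline with a
# realistic device lifetime
gomp_truth <- function(sigma2 = 1, beta_scale = numeric(),
                       beta_shape = numeric())
  dcox_params(1e-4, 0.1, beta_scale, beta_shape, sigma2 = sigma2)

weib_truth <- function(sigma2 = 1, beta_scale = numeric(),
                       beta_shape = numeric())
  dcox_params(20, 1.5, beta_scale, beta_shape, sigma2 = sigma2)

# a small deterministic clustered dataset (no RNG)
tiny_data <- function() {
  tibble::tibble(
    time = c(2, 5, 9, 1.5, 7, 3, 12, 4),
    status = c(1, 0, 1, 1, 1, 0, 1, 1),
    cluster = c("a", "a", "a", "b", "b", "c", "c", "c"),
    success = c(1, 0, 0, 1, 1, 0, 0, 1),
    score = c(0.3, -0.2, 0.1, 0.5, -0.4, 0.0, 0.25, -0.1)
  )
}

full_spec <- function(family)
  dcox_spec(family, scale = c("success", "score"),
            shape = c("success", "score"))

# random small instance for likelihood cross-checks; parameter and time
# ranges keep per-cluster cumulative hazards moderate so boundary-continuity
# comparisons are meaningful
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(5:20, 1)
  ncl <- sample(1:4, 1)
  fam <- sample(c("weibull", "gompertz"), 1)
  pp <- if (fam == "weibull") {
    dcox_params(exp(runif(1, 2, 4)), runif(1, 0.8, 1.5),
                rnorm(2, 0, 0.5), rnorm(2, 0, 0.1),
                sigma2 = runif(1, 0.1, 5))
  } else {
    dcox_params(exp(runif(1, -9, -7)), runif(1, 0.05, 0.15),
                rnorm(2, 0, 0.5), rnorm(2, 0, 0.1),
                sigma2 = runif(1, 0.1, 5))
  }
  dat <- tibble::tibble(
    time = runif(n, 0.5, 15),
    status = rbinom(n, 1, 0.7),
    cluster = sample(seq_len(ncl), n, replace = TRUE),
    success = rbinom(n, 1, 0.5),
    score = rnorm(n, 0, sqrt(0.2))
  )
  # every cluster label must occur
  dat$cluster <- c(seq_len(ncl), dat$cluster[-seq_len(ncl)])
  list(data = dat, spec = full_spec(fam), params = pp)
}
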