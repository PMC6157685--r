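test_that("the linear predictor is the component sum it claims to be", {
  spec <- model_spec("browsed_shoots")
  set.seed(12)
  theta <- random_theta(spec)
  rows <- data.frame(g = sample(1:6, 12, TRUE), y = sample(1:3, 12, TRUE),
                     t = sample(c(0, 0.5, 1), 12, TRUE),
                     i = sample(1:8, 12, TRUE))
  eta <- linear_predictor(theta, rows, spec)
  # independent element-by-element summation oracle
  for (j in seq_len(nrow(rows))) {
    expect_equal(eta[j],
                 theta$alpha[rows$g[j], rows$y[j]] +
                 theta$beta[rows$g[j], rows$y[j]] * rows$t[j] +
                 theta$u[rows$i[j]] + theta$eps[j])
  }
  # all parameters zero -> 0
  theta0 <- list(alpha = matrix(0, 6, 3), beta = matrix(0, 6, 3),
                 u = rep(0, 8), eps = rep(0, 12))
  expect_equal(linear_predictor(theta0, rows, spec), rep(0, 12))
  # at t = 0 the slope vanishes exactly
  rows0 <- transform(rows, t = 0)
  expect_equal(linear_predictor(theta, rows0, spec),
               theta$alpha[cbind(rows$g, rows$y)] + theta$u[rows$i] +
                 theta$eps)
  # no-slope models ignore beta entirely
  fspec <- model_spec("flowers")
  expect_equal(linear_predictor(theta, rows, fspec),
               linear_predictor(theta, rows0, fspec))
  expect_error(linear_predictor(theta, transform(rows, g = 9), spec),
               "out of range")
})

test_that("zero-inflated Poisson log-likelihood has the right special cases", {
  spec <- model_spec("browsed_shoots")
  set.seed(3)
  theta <- random_theta(spec)
  rows <- data.frame(g = 1, y = 1, t = 0, i = 1, response = 0:11)
  # psi = 1: the mixture degenerates to the plain Poisson
  theta$psi <- 1
  plain <- model_spec("flowers")  # poisson without zero-inflation
  expect_equal(obs_loglik(theta, rows, spec),
               obs_loglik(theta, rows, plain))
  # closed-form mixture at zero: psi = 0.5, exp(-lambda) = 0.5 -> p = 0.75
  theta0 <- list(alpha = matrix(log(log(2)), 1, 1), beta = matrix(0, 1, 1),
                 u = 0, eps = 0, psi = 0.5)
  row0 <- data.frame(g = 1, y = 1, t = 0, i = 1, response = 0)
  expect_equal(exp(obs_loglik(theta0, row0, spec)), 0.75)
  expect_error(obs_loglik(theta, transform(rows, response = -1), spec),
               "non-negative")
})

test_that("every family's likelihood is a normalized distribution", {
  set.seed(21)
  zip <- model_spec("browsed_shoots")
  for (k in 1:10) {
    theta <- random_theta(zip, n_groups = 1, n_years = 1, n_ramets = 1,
                          n_obs = 1)
    lam <- exp(linear_predictor(theta, data.frame(g = 1, y = 1, t = 0, i = 1),
                                zip))
    y_max <- max(50, ceiling(lam + 12 * sqrt(lam)))
    rows <- data.frame(g = 1, y = 1, t = 0, i = 1, response = 0:y_max)
    theta$eps <- rep(theta$eps, y_max + 1)  # same obs effect on the grid
    expect_equal(sum(exp(obs_loglik(theta, rows, zip))), 1, tolerance = 1e-8)
  }
  # binomial sums to one over 0..n
  bin <- model_spec("grazed_ratio")
  theta <- random_theta(bin, n_obs = 26)
  theta$eps <- rep(theta$eps[1], 26)  # one observation effect over the grid
  rows <- data.frame(g = 2, y = 1, t = 0.5, i = 3, response = 0:25,
                     trials = 25)
  expect_equal(sum(exp(obs_loglik(theta, rows, bin))), 1, tolerance = 1e-10)
  expect_error(obs_loglik(theta, transform(rows, response = 30), bin),
               "trials")
  # gaussian integrates to one
  gau <- model_spec("dry_mass")
  theta <- random_theta(gau, n_obs = 1)
  f <- function(yv) {
    vapply(yv, function(v) exp(obs_loglik(
      theta, data.frame(g = 1, y = 1, t = 0.5, i = 2, response = v), gau)),
      numeric(1))
  }
  expect_equal(stats::integrate(f, -Inf, Inf)$value, 1, tolerance = 1e-6)
})

test_that("log prior matches a term-by-term oracle and handles support", {
  spec <- model_spec("browsed_shoots")
  priors <- prior_spec()
  set.seed(8)
  for (k in 1:5) {
    theta <- random_theta(spec)
    expected <- sum(dnorm(theta$alpha, 0, sqrt(1000), log = TRUE)) +
      sum(dnorm(theta$beta, 0, sqrt(1000), log = TRUE)) +
      log(1 / 100) + sum(dnorm(theta$u, 0, theta$sigma_u, log = TRUE)) +
      log(1 / 100) + sum(dnorm(theta$eps, 0, theta$sigma_eps, log = TRUE))
    expect_equal(log_prior(theta, priors, spec), expected)
  }
  # the normal prior on a coefficient is maximized at its mean
  theta <- random_theta(spec)
  at0 <- theta; at0$alpha[1, 1] <- 0
  at1 <- theta; at1$alpha[1, 1] <- 2.5
  expect_gt(log_prior(at0, priors, spec), log_prior(at1, priors, spec))
  # outside uniform support the contribution is -Inf, not an error
  bad <- theta; bad$sigma_u <- 150
  expect_identical(log_prior(bad, priors, spec), -Inf)
  bad2 <- theta; bad2$psi <- 1.2
  expect_identical(log_prior(bad2, priors, spec), -Inf)
  # literal-sd prior reading is available
  tight <- prior_spec(coef_value = 0.001, coef_reading = "sd")
  th <- random_theta(spec)
  expect_lt(log_prior(th, tight, spec), log_prior(th, priors, spec))
})

test_that("log posterior is prior plus likelihood on a real design", {
  sim <- small_sim(seed = 13)
  design <- build_design(sim$observations, model_spec("dry_mass"))
  set.seed(5)
  theta <- list(alpha = matrix(rnorm(18, -2, 0.3), 6, 3),
                beta = matrix(rnorm(18, 0.5, 0.2), 6, 3),
                u = rnorm(length(design$ramet_levels), 0, 0.3),
                sigma_u = 0.4, sigma_resid = 0.4)
  lp <- log_posterior(theta, design, prior_spec())
  expect_equal(lp, log_prior(theta, prior_spec(), design$spec) +
                 sum(obs_loglik(theta, design$rows, design$spec)))
  expect_true(is.finite(lp))
})
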