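test_that("retained-draw bookkeeping is exact for both profiles", {
  paper <- mcmc_settings("paper")
  expect_equal(paper$n_chains, 4L)
  expect_equal(paper$n_iter, 200000L)
  expect_equal(paper$n_discard, 100000L)
  expect_equal(paper$thin, 20L)
  expect_equal(n_retained(paper), 20000L)
  expect_equal(n_retained(mcmc_settings("test")), 4 * (7000 - 2000) / 5)
  expect_equal(n_retained(mcmc_settings(n_chains = 3, n_iter = 100,
                                        n_discard = 40, thin = 7)),
               3 * ((100 - 40) %/% 7))
  expect_error(mcmc_settings(n_iter = 100, n_discard = 100), "n_iter")
})

test_that("a short run retains exactly the draws the settings imply", {
  sim <- small_sim(seed = 3, n_years = 1)
  design <- build_design(sim$observations, model_spec("dry_mass", years = 1))
  s <- sample_posterior(design, settings = mcmc_settings(
    n_chains = 2, n_iter = 100, n_discard = 40, thin = 3, seed = 2))
  per_par <- n_retained(s$settings)
  df <- as.data.frame(s)
  expect_true(all(table(df$parameter) == per_par))
  expect_equal(per_par, 2 * ((100 - 40) %/% 3))
})

test_that("sampling is deterministic given the seed", {
  sim <- small_sim(seed = 5, n_years = 1)
  design <- build_design(sim$observations, model_spec("dry_mass", years = 1))
  st <- mcmc_settings(n_chains = 2, n_iter = 600, n_discard = 200, thin = 2,
                      seed = 11)
  s1 <- sample_posterior(design, settings = st)
  s2 <- sample_posterior(design, settings = st)
  expect_identical(lapply(s1$mcmc, unclass), lapply(s2$mcmc, unclass))
  s3 <- sample_posterior(design, settings = mcmc_settings(
    n_chains = 2, n_iter = 600, n_discard = 200, thin = 2, seed = 12))
  expect_false(identical(get_draws(s1, "sigma_u"), get_draws(s3, "sigma_u")))
})

test_that("the sampler leaves the global RNG state untouched", {
  sim <- small_sim(seed = 5, n_years = 1)
  design <- build_design(sim$observations, model_spec("dry_mass", years = 1))
  set.seed(99)
  before <- .Random.seed
  invisible(sample_posterior(design, settings = tiny_settings(seed = 4)))
  expect_identical(.Random.seed, before)
})

test_that("Gelman-Rubin matches an independently coded textbook formula", {
  set.seed(42)
  for (k in 1:20) {
    n <- sample(20:60, 1)
    m <- sample(2:5, 1)
    x <- matrix(rnorm(n * m, mean = rep(runif(m, -1, 1), each = n)), n, m)
    # direct transcription of the between/within variance formula
    W <- mean(apply(x, 2, var))
    B <- n * var(colMeans(x))
    expected <- sqrt(((n - 1) / n * W + B / n) / W)
    expect_equal(gelman_rubin(x), expected)
  }
  # agrees with coda's estimator up to its degrees-of-freedom correction
  x <- matrix(rnorm(4000), 1000, 4)
  ml <- coda::mcmc.list(apply(x, 2, coda::mcmc, simplify = FALSE))
  expect_equal(gelman_rubin(x),
               unname(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1]),
               tolerance = 0.01)
})

test_that("Gelman-Rubin handles degenerate and near-identical chains", {
  # permuted copies of one chain: between-chain variance ~ 0
  set.seed(1)
  base <- rnorm(500)
  x <- cbind(base, sample(base), sample(base))
  expect_lt(abs(gelman_rubin(x) - 1), 0.01)
  # constant distinct chains: zero within-variance diverges
  expect_identical(gelman_rubin(cbind(c(1, 1, 1), c(2, 2, 2))), Inf)
  expect_identical(gelman_rubin(cbind(c(3, 3), c(3, 3))), 1)
  expect_error(gelman_rubin(matrix(rnorm(10), 10, 1)), "2 chains")
})

test_that("chains simulated iid from one distribution pass the 1.1 rule", {
  set.seed(7)
  rhats <- replicate(50, gelman_rubin(matrix(rnorm(4 * 500), 500, 4)))
  expect_true(all(rhats < 1.1))
})

test_that("convergence report applies the R-hat < 1.1 acceptance rule", {
  sim <- small_sim(seed = 5, n_years = 1)
  design <- build_design(sim$observations, model_spec("dry_mass", years = 1))
  s <- sample_posterior(design, settings = tiny_settings(seed = 9))
  rep_ok <- check_convergence(s)
  expect_s3_class(rep_ok, "convergence_report")
  expect_equal(nrow(rep_ok), length(parameter_names(s)))

  # force a failure by faking one R-hat
  s_bad <- s
  s_bad$rhat[["sigma_u"]] <- 1.5
  rep_bad <- check_convergence(s_bad)
  expect_false(attr(rep_bad, "overall"))
  expect_true("sigma_u" %in% rep_bad$parameter[!rep_bad$pass])
  # all-1.0 passes
  s_good <- s
  s_good$rhat[] <- 1.0
  expect_true(attr(check_convergence(s_good), "overall"))
})

test_that("with no data the sampler reproduces the priors", {
  st <- mcmc_settings(n_chains = 2, n_iter = 6000, n_discard = 1000,
                      thin = 1, seed = 21)
  pr <- sample_prior(model_spec("browsed_shoots"), settings = st)
  sig <- get_draws(pr, "sigma_u")
  # sigma_u ~ uniform(0, 100): mean 50, sd 100/sqrt(12)
  expect_equal(mean(sig), 50, tolerance = 0.05)
  expect_equal(sd(sig), 100 / sqrt(12), tolerance = 0.05)
  expect_equal(mean(get_draws(pr, "psi")), 0.5, tolerance = 0.05)
})

test_that("posterior matches the closed-form conjugate normal posterior", {
  # known residual sd, single cell, ramet effects suppressed: the intercept
  # posterior is exactly normal with precision tau0 + n/sigma^2
  set.seed(14)
  n <- 60
  yv <- rnorm(n, 1.8, 1)
  obs <- data.frame(
    block_id = sprintf("B%02d", seq_len(n)), transect_id = "T1",
    treatment = "control", distance_class = 0L, ramet_id = "R1",
    year = 1L, census = 1L, days_since_treatment = 0L,
    height_cm = 16, stem_diameter_mm = 2^((yv - 0.97104 * 4 + 7.52070) / 1.417),
    n_shoots = 0L, n_leaves = 10L, n_grazed_leaves = 0L,
    n_browsed_shoots = 0L, n_flowers = 0L, n_berries = NA_integer_,
    alive = TRUE)
  spec <- model_spec("dry_mass", years = 1, groups = "control")
  design <- build_design(obs, spec)
  expect_equal(design$rows$response, yv, tolerance = 1e-10)

  priors <- prior_spec(ranef_sd_upper = 1e-6)  # no ramet-level variation
  s <- sample_posterior(design, priors = priors,
                        settings = mcmc_settings(n_chains = 4, n_iter = 3000,
                                                 n_discard = 1000, thin = 1,
                                                 seed = 31),
                        fixed_resid_sd = 1)
  dr <- get_draws(s, "alpha", group = "control", year = 1)
  tau_post <- 0.001 + n / 1^2
  m_post <- sum(yv) / tau_post
  sd_post <- 1 / sqrt(tau_post)
  ess <- coda::effectiveSize(coda::mcmc(dr))
  mcse_mean <- sd(dr) / sqrt(ess)
  mcse_sd <- sd(dr) / sqrt(2 * ess)
  expect_lt(abs(mean(dr) - m_post), 3 * mcse_mean)
  expect_lt(abs(sd(dr) - sd_post), 3 * mcse_sd)
})
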