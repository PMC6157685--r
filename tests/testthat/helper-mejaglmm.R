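# Shared fixtures: everything is generated in code at test time.

# small field layout used by most fit-based tests (4 blocks instead of 10)
small_sim <- function(seed = 101, ...) {
  simulate_dataset(simulation_config(seed = seed, n_blocks = 4, ...))
}

# very short chains for structural tests (not for inference quality)
tiny_settings <- function(seed = 1) {
  mcmc_settings(n_chains = 2, n_iter = 1200, n_discard = 400, thin = 2,
                seed = seed)
}

# assemble a posterior_samples object from explicit per-chain draw matrices
# (columns named like "alpha[1,1]"), for tests that need exact draw control
fake_samples <- function(chains, spec, group_levels = treatment_groups(),
                         year_levels = 1:3) {
  ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
  out <- list(mcmc = ml, settings = NULL, priors = prior_spec(), spec = spec,
              group_levels = group_levels, year_levels = year_levels,
              n_obs = 0L)
  class(out) <- "posterior_samples"
  out$rhat <- stats::setNames(rep(1, coda::nvar(ml)), coda::varnames(ml))
  out
}

# a minimal hand-written valid census table (one ramet, two censuses, plus
# a control ramet) used by validation tests
valid_obs_fixture <- function() {
  data.frame(
    block_id = "B01",
    transect_id = c("T1", "T1", "T1", "T2", "T2", "T2"),
    treatment = c("meja", "meja", "meja", "control", "control", "control"),
    distance_class = 0L,
    ramet_id = "R1",
    year = 1L,
    census = c(1L, 2L, 3L, 1L, 2L, 3L),
    days_since_treatment = c(0L, 30L, 72L, 0L, 30L, 72L),
    height_cm = 15.0,
    stem_diameter_mm = 2.2,
    n_shoots = 4L,
    n_leaves = c(20L, 22L, 25L, 18L, 18L, 21L),
    n_grazed_leaves = c(2L, 3L, 5L, 1L, 2L, 2L),
    n_browsed_shoots = c(0L, 1L, 0L, 0L, 0L, 2L),
    n_flowers = 3L,
    n_berries = c(NA, 1L, 2L, NA, 0L, 1L),
    alive = TRUE,
    stringsAsFactors = FALSE
  )
}

# random parameter vector within prior support for likelihood/prior oracles
random_theta <- function(spec, n_groups = 6, n_years = 3, n_ramets = 8,
                         n_obs = 12) {
  list(alpha = matrix(rnorm(n_groups * n_years), n_groups, n_years),
       beta = matrix(rnorm(n_groups * n_years, 0, 0.5), n_groups, n_years),
       u = rnorm(n_ramets, 0, 0.5),
       eps = rnorm(n_obs, 0, 0.3),
       sigma_u = runif(1, 0.2, 2),
       sigma_eps = runif(1, 0.2, 2),
       sigma_resid = runif(1, 0.2, 2),
       psi = runif(1, 0.05, 0.95))
}
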