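#' MCMC run settings
#'
#' Two named profiles are provided. `"paper"` is the full protocol: four
#' chains of 200,000 iterations each, the first 100,000 discarded as the
#' adaptation/burn-in phase, and every 20th retained iteration kept, giving
#' 4 x (200,000 - 100,000) / 20 = 20,000 final posterior draws per
#' parameter. `"test"` is a desk-scale profile (4 chains x 7,000 iterations,
#' 2,000 discarded, thin 5 = 4,000 draws) that keeps interactive runs and
#' the test suite fast; it is a shorter run of the identical protocol, not a
#' different algorithm. Any field can be overridden.
#'
#' The discard count includes the sampler's internal adaptation, so retained
#' draw accounting is exact regardless of backend warm-up semantics.
#'
#' @param profile `"test"` (default) or `"paper"`.
#' @param n_chains number of Markov chains.
#' @param n_iter total iterations per chain (including discarded).
#' @param n_discard iterations discarded from the start of each chain.
#' @param thin keep every `thin`-th iteration after discarding.
#' @param seed integer seed controlling chain RNG states and initial values.
#' @return an object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(profile = c("test", "paper"), n_chains = NULL,
                          n_iter = NULL, n_discard = NULL, thin = NULL,
                          seed = 1L) {
  profile <- match.arg(profile)
  def <- switch(profile,
    test = list(n_chains = 4L, n_iter = 7000L, n_discard = 2000L, thin = 5L),
    paper = list(n_chains = 4L, n_iter = 200000L, n_discard = 100000L,
                 thin = 20L))
  s <- list(profile = profile,
            n_chains = as.integer(n_chains %||% def$n_chains),
            n_iter = as.integer(n_iter %||% def$n_iter),
            n_discard = as.integer(n_discard %||% def$n_discard),
            thin = as.integer(thin %||% def$thin),
            seed = as.integer(seed))
  stopifnot(s$n_chains >= 1, s$n_iter > s$n_discard, s$n_discard >= 0,
            s$thin >= 1)
  class(s) <- "mcmc_settings"
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Retained posterior draw count implied by MCMC settings
#'
#' `n_chains * floor((n_iter - n_discard) / thin)`, the bookkeeping the
#' full protocol resolves to 20,000 draws.
#'
#' @param settings an [mcmc_settings()].
#' @return integer total retained draws per parameter.
#' @export
n_retained <- function(settings) {
  settings$n_chains * ((settings$n_iter - settings$n_discard) %/% settings$thin)
}

#' @export
print.mcmc_settings <- function(x, ...) {
  cat(sprintf("MCMC settings [%s]: %d chains x %d iterations, discard %d, thin %d -> %d retained draws (seed %d)\n",
              x$profile, x$n_chains, x$n_iter, x$n_discard, x$thin,
              n_retained(x), x$seed))
  invisible(x)
}

# ---- JAGS model construction -------------------------------------------

# JAGS distributions use precision; scale priors per the prior_spec reading.
jags_scale_prior <- function(sigma_name, tau_name, priors) {
  if (priors$scale_reading == "sigma_uniform") {
    sprintf("  %s ~ dunif(0, %g)\n  %s <- pow(%s, -2)\n",
            sigma_name, priors$scale_sd_upper, tau_name, sigma_name)
  } else {
    v <- paste0("v_", sigma_name)
    sprintf("  %s ~ dunif(0, %g)\n  %s <- 1 / %s\n  %s <- sqrt(%s)\n",
            v, priors$scale_sd_upper, tau_name, v, sigma_name, v)
  }
}

# Build the JAGS model string for a model_spec + prior_spec. With
# include_likelihood = FALSE only the top-level priors remain (prior
# sampling mode).
jags_model_string <- function(spec, priors, include_likelihood = TRUE,
                              fixed_resid_sd = NULL) {
  coef_prec <- if (priors$coef_reading == "precision") priors$coef_value
               else priors$coef_value^-2
  lines <- "model {\n"

  if (include_likelihood) {
    eta <- "alpha[g[j], yr[j]]"
    if (spec$has_seasonal_slope) eta <- paste0(eta, " + beta[g[j], yr[j]] * t[j]")
    eta <- paste0(eta, " + u[id[j]]")
    if (spec$block_effect) eta <- paste0(eta, " + b[blk[j]]")
    if (spec$overdispersed) eta <- paste0(eta, " + eps[j]")
    obs <- switch(spec$family,
      gaussian = "    Y[j] ~ dnorm(eta[j], tau_resid)\n",
      binomial = "    logit(p[j]) <- eta[j]\n    Y[j] ~ dbin(p[j], Ntr[j])\n",
      poisson = if (spec$zero_inflated) {
        paste0("    z[j] ~ dbern(psi)\n",
               "    lambda[j] <- exp(eta[j])\n",
               "    Y[j] ~ dpois(z[j] * lambda[j] + 1.0E-10)\n")
      } else {
        "    Y[j] ~ dpois(exp(eta[j]))\n"
      })
    lines <- paste0(lines,
      "  for (j in 1:N) {\n",
      "    eta[j] <- ", eta, "\n",
      obs,
      if (spec$overdispersed) "    eps[j] ~ dnorm(0, tau_eps)\n" else "",
      "  }\n",
      "  for (i in 1:NI) { u[i] ~ dnorm(0, tau_u) }\n",
      if (spec$block_effect)
        "  for (k in 1:NB) { b[k] ~ dnorm(0, tau_b) }\n" else "")
    lines <- paste0(lines,
      "  for (a in 1:NG) {\n",
      "    for (yv in 1:NY) {\n",
      sprintf("      alpha[a, yv] ~ dnorm(%g, %g)\n", priors$coef_mean, coef_prec),
      if (spec$has_seasonal_slope)
        sprintf("      beta[a, yv] ~ dnorm(%g, %g)\n", priors$coef_mean, coef_prec)
      else "",
      "    }\n  }\n")
  }

  lines <- paste0(lines,
    sprintf("  sigma_u ~ dunif(0, %g)\n  tau_u <- pow(sigma_u, -2)\n",
            priors$ranef_sd_upper))
  if (spec$block_effect) {
    lines <- paste0(lines,
      sprintf("  sigma_b ~ dunif(0, %g)\n  tau_b <- pow(sigma_b, -2)\n",
              priors$ranef_sd_upper))
  }
  if (spec$family == "gaussian") {
    lines <- paste0(lines,
      if (!is.null(fixed_resid_sd))
        sprintf("  tau_resid <- %.15g\n", fixed_resid_sd^-2)
      else jags_scale_prior("sigma_resid", "tau_resid", priors))
  }
  if (spec$overdispersed) {
    lines <- paste0(lines, jags_scale_prior("sigma_eps", "tau_eps", priors))
  }
  if (spec$zero_inflated) {
    lines <- paste0(lines, "  psi ~ dunif(0, 1)\n")
  }
  paste0(lines, "}\n")
}

# run fn with a temporary RNG state derived from seed, restoring afterwards
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fn()
}

# Initial values for one chain. Coefficients start near 0 rather than from
# the near-flat prior: a draw at sd ~ 31.6 overflows exp() in log-link
# models before the sampler can recover.
draw_inits <- function(spec, priors, design, chain_seed,
                       fixed_resid_sd = NULL, include_likelihood = TRUE) {
  ini <- list(.RNG.name = "base::Mersenne-Twister",
              .RNG.seed = chain_seed)
  # scale inits stay well inside the uniform support, whatever its bound
  sd_init <- function(upper) stats::runif(1, 0.1, 0.6) * min(upper, 5)
  # under the inverse-uniform reading the stochastic node is the variance
  scale_init <- function(name, upper) {
    s <- sd_init(sqrt(upper))
    if (priors$scale_reading == "sigma_uniform") {
      stats::setNames(list(sd_init(upper)), name)
    } else {
      stats::setNames(list(s^2), paste0("v_", name))
    }
  }
  ini$sigma_u <- sd_init(priors$ranef_sd_upper)
  if (include_likelihood) {
    G <- length(design$group_levels)
    Y <- length(design$year_levels)
    ini$alpha <- matrix(stats::rnorm(G * Y, 0, 1), G, Y)
    if (spec$has_seasonal_slope) {
      ini$beta <- matrix(stats::rnorm(G * Y, 0, 0.5), G, Y)
    }
    if (spec$block_effect) ini$sigma_b <- sd_init(priors$ranef_sd_upper)
    if (spec$overdispersed) {
      ini <- c(ini, scale_init("sigma_eps", priors$scale_sd_upper))
    }
    if (spec$family == "gaussian" && is.null(fixed_resid_sd)) {
      ini <- c(ini, scale_init("sigma_resid", priors$scale_sd_upper))
    }
    if (spec$zero_inflated) {
      ini$psi <- stats::runif(1, 0.3, 0.9)
      ini$z <- rep(1L, nrow(design$rows))  # all-on state is always feasible
    }
  }
  ini
}

monitored_parameters <- function(spec, fixed_resid_sd = NULL,
                                 include_likelihood = TRUE) {
  vars <- "sigma_u"
  if (include_likelihood) {
    vars <- c("alpha", if (spec$has_seasonal_slope) "beta", vars,
              if (spec$block_effect) "sigma_b")
  }
  if (spec$family == "gaussian" && is.null(fixed_resid_sd)) {
    vars <- c(vars, "sigma_resid")
  }
  if (spec$overdispersed) vars <- c(vars, "sigma_eps")
  if (spec$zero_inflated) vars <- c(vars, "psi")
  vars
}

#' Sample the posterior of a means-parameterized GLMM
#'
#' Fits the model declared by the design's [model_spec()] with JAGS using
#' the protocol in `settings`: `n_chains` chains of `n_iter` iterations,
#' the first `n_discard` discarded (covering adaptation), every `thin`-th
#' retained iteration kept. Latent states (the per-observation
#' overdispersion effects and zero-inflation indicators, and the per-ramet
#' intercepts) are sampled but not retained unless `monitor_ranef = TRUE`;
#' the monitored set is the declared parameters: `alpha`, `beta`,
#' `sigma_u`, `sigma_resid`/`sigma_eps`, `psi` as applicable.
#'
#' The run is deterministic given `settings$seed`: chain RNG states and
#' initial values derive from it, and the global RNG state is left
#' untouched. If the backend fails to initialize (non-finite density at the
#' initial values), new initial values are drawn and the fit retried a few
#' times before erroring.
#'
#' @param design a [build_design()] result.
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param monitor_ranef also retain the per-ramet random intercepts `u`.
#' @param fixed_resid_sd optionally hold the Gaussian residual sd fixed at a
#'   known value instead of sampling it (validation runs).
#' @param quiet suppress JAGS progress output.
#' @return an object of class `posterior_samples`: retained draws (a
#'   `coda::mcmc.list` in `$mcmc`), the settings, priors and design metadata
#'   used, and per-parameter Gelman-Rubin statistics in `$rhat`.
#' @export
sample_posterior <- function(design, priors = prior_spec(),
                             settings = mcmc_settings(),
                             monitor_ranef = FALSE, fixed_resid_sd = NULL,
                             quiet = TRUE) {
  stopifnot(inherits(design, "model_design"))
  if (nrow(design$rows) == 0) {
    stop("design is empty; use sample_prior() to sample priors alone")
  }
  spec <- design$spec
  rows <- design$rows
  dat <- list(N = nrow(rows), NI = length(design$ramet_levels),
              NG = length(design$group_levels),
              NY = length(design$year_levels),
              g = rows$g, yr = rows$y, id = rows$i, Y = rows$response)
  if (spec$has_seasonal_slope) dat$t <- rows$t
  if (spec$family == "binomial") dat$Ntr <- rows$trials
  if (spec$block_effect) {
    dat$blk <- rows$block
    dat$NB <- length(design$block_levels)
  }
  model_txt <- jags_model_string(spec, priors, TRUE, fixed_resid_sd)
  vars <- monitored_parameters(spec, fixed_resid_sd)
  if (monitor_ranef) vars <- c(vars, "u")

  mcmc <- run_jags(model_txt, dat, vars, settings,
                   function(chain_seed) draw_inits(spec, priors, design,
                                                   chain_seed, fixed_resid_sd),
                   quiet = quiet)

  out <- list(mcmc = mcmc, settings = settings, priors = priors, spec = spec,
              group_levels = design$group_levels,
              year_levels = design$year_levels,
              n_obs = nrow(rows))
  class(out) <- "posterior_samples"
  out$rhat <- if (settings$n_chains >= 2) {
    vapply(parameter_names(out), function(p) gelman_rubin(out, p), numeric(1))
  } else {
    stats::setNames(rep(NA_real_, length(parameter_names(out))),
                    parameter_names(out))
  }
  out
}

#' Sample the priors alone
#'
#' Runs the identical MCMC machinery on a model containing only the
#' top-level prior declarations (no data, no latent hierarchy), so that the
#' marginal prior of bounded parameters can be checked against its stated
#' distribution -- e.g. the ramet random-effect sd should reproduce
#' uniform(0, 100) with mean about 50.
#'
#' @inheritParams sample_posterior
#' @param spec a [model_spec()] (decides which scale/psi priors exist).
#' @return a `posterior_samples` object of prior draws.
#' @export
sample_prior <- function(spec, priors = prior_spec(),
                         settings = mcmc_settings(), quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  model_txt <- jags_model_string(spec, priors, include_likelihood = FALSE)
  vars <- monitored_parameters(spec, include_likelihood = FALSE)
  mcmc <- run_jags(model_txt, list(), vars, settings,
                   function(chain_seed) list(.RNG.name = "base::Mersenne-Twister",
                                             .RNG.seed = chain_seed),
                   quiet = quiet)
  out <- list(mcmc = mcmc, settings = settings, priors = priors, spec = spec,
              group_levels = character(), year_levels = integer(), n_obs = 0L)
  out$rhat <- vapply(coda::varnames(mcmc),
                     function(p) gelman_rubin_matrix(draw_matrix(mcmc, p)),
                     numeric(1))
  class(out) <- "posterior_samples"
  out
}

# shared JAGS driver: compile (with retry-from-new-inits), burn in, sample
run_jags <- function(model_txt, dat, vars, settings, init_fn, quiet = TRUE,
                     max_retries = 3) {
  n_adapt <- min(1000L, settings$n_discard)
  chain_seeds <- settings$seed * 1000L + seq_len(settings$n_chains)
  attempt <- 0L
  repeat {
    inits <- with_seed(settings$seed + attempt * 7919L, function() {
      lapply(chain_seeds + attempt * 104729L, init_fn)
    })
    jm <- tryCatch(
      withCallingHandlers(
        rjags::jags.model(textConnection(model_txt), data = dat,
                          inits = inits, n.chains = settings$n_chains,
                          n.adapt = n_adapt, quiet = quiet),
        warning = function(w) {
          # adaptation is capped at the discard budget on purpose
          if (grepl("[Aa]daptation incomplete", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) e)
    if (!inherits(jm, "error")) break
    attempt <- attempt + 1L
    if (attempt > max_retries) {
      stop("initialization failed after ", max_retries, " retries: ",
           conditionMessage(jm))
    }
  }
  if (settings$n_discard > n_adapt) {
    stats::update(jm, settings$n_discard - n_adapt,
                  progress.bar = if (quiet) "none" else "text")
  }
  rjags::coda.samples(jm, variable.names = vars,
                      n.iter = settings$n_iter - settings$n_discard,
                      thin = settings$thin,
                      progress.bar = if (quiet) "none" else "text")
}

# ---- posterior_samples accessors ---------------------------------------

#' Monitored parameter names of a fit
#' @param samples a `posterior_samples` object.
#' @return character vector, e.g. `"alpha[2,1]"`, `"sigma_u"`.
#' @export
parameter_names <- function(samples) {
  coda::varnames(samples$mcmc)
}

# draws of one parameter as a (draws per chain) x (chains) matrix
draw_matrix <- function(mcmc, parameter) {
  if (!parameter %in% coda::varnames(mcmc)) {
    stop("unknown parameter: ", parameter)
  }
  vapply(mcmc, function(ch) as.numeric(ch[, parameter]),
         numeric(nrow(mcmc[[1]])))
}

#' Extract retained draws of one parameter
#'
#' Draws are returned pooled across chains in a fixed order (chain-major),
#' so element `k` of two different parameters always comes from the same
#' (chain, iteration) -- the pairing posterior contrasts rely on.
#'
#' Coefficients can be addressed by field labels: `get_draws(s, "alpha",
#' group = "meja_d0", year = 2)` resolves the group/year cell to the
#' underlying `alpha[g,y]` element.
#'
#' @param samples a `posterior_samples` object.
#' @param parameter parameter name (`"alpha"`, `"beta"`, `"sigma_u"`, ...).
#' @param group,year optional group label and study year identifying a
#'   coefficient cell.
#' @return numeric vector of pooled draws.
#' @export
get_draws <- function(samples, parameter, group = NULL, year = NULL) {
  if (!is.null(group) || !is.null(year)) {
    g <- match(group, samples$group_levels)
    y <- match(year, samples$year_levels)
    if (is.na(g)) stop("unknown group: ", group)
    if (is.na(y)) stop("unknown year: ", year)
    indexed <- sprintf("%s[%d,%d]", parameter, g, y)
    # JAGS drops the index suffix when the coefficient array is 1 x 1
    if (indexed %in% coda::varnames(samples$mcmc) || g > 1 || y > 1) {
      parameter <- indexed
    }
  }
  as.numeric(draw_matrix(samples$mcmc, parameter))
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("Posterior samples (%s): %d parameters, %d retained draws (%d chains), %d observations\n",
              x$spec$response, length(parameter_names(x)),
              coda::niter(x$mcmc) * coda::nchain(x$mcmc),
              coda::nchain(x$mcmc), x$n_obs))
  if (all(is.finite(x$rhat))) {
    cat(sprintf("  max R-hat: %.3f\n", max(x$rhat)))
  }
  invisible(x)
}

#' Tidy draws data frame
#'
#' @param x a `posterior_samples` object.
#' @param ... unused.
#' @return data frame with columns `parameter`, `chain`, `draw`, `value`.
#' @export
as.data.frame.posterior_samples <- function(x, ...) {
  pars <- parameter_names(x)
  nit <- coda::niter(x$mcmc)
  nch <- coda::nchain(x$mcmc)
  do.call(rbind, lapply(pars, function(p) {
    m <- draw_matrix(x$mcmc, p)
    data.frame(parameter = p,
               chain = rep(seq_len(nch), each = nit),
               draw = rep(seq_len(nit), nch),
               value = as.numeric(m))
  }))
}

#' Export retained draws as tidy CSV
#'
#' @param samples a `posterior_samples` object.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}
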