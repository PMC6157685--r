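#' Linear predictor of the means-parameterized GLMM
#'
#' On the link scale, observation `j` of ramet `i` in group `g` and year `y`
#' has
#' \deqn{\eta_j = \alpha_{g,y} + \beta_{g,y} t_j + u_i + \varepsilon_j,}
#' where the `beta` term is present only for models with a seasonal slope and
#' the observation-level effect `eps` only for overdispersed models.
#'
#' @param theta parameter list with elements `alpha` (groups x years matrix),
#'   `beta` (matrix, or `NULL` for no-slope models), `u` (per-ramet vector),
#'   and for overdispersed models `eps` (per-observation vector); scale
#'   parameters (`sigma_u`, `sigma_eps`, `sigma_resid`, `psi`) are carried
#'   alongside for the likelihood/prior evaluators.
#' @param rows design rows (data frame with `g`, `y`, `t`, `i`), e.g.
#'   `design$rows` or a subset of it.
#' @param spec the [model_spec()].
#' @return numeric vector of link-scale linear predictors, one per row.
#' @export
linear_predictor <- function(theta, rows, spec) {
  g <- rows$g
  y <- rows$y
  if (any(g < 1 | g > nrow(theta$alpha)) || any(y < 1 | y > ncol(theta$alpha))) {
    stop("group/year index out of range")
  }
  eta <- theta$alpha[cbind(g, y)]
  if (spec$has_seasonal_slope) {
    eta <- eta + theta$beta[cbind(g, y)] * rows$t
  }
  eta <- eta + theta$u[rows$i]
  if (spec$overdispersed) {
    j <- if (!is.null(rows$j)) rows$j else seq_len(nrow(rows))
    eta <- eta + theta$eps[j]
  }
  eta
}

#' Per-observation log-likelihood
#'
#' Evaluates the observation model on the log scale:
#' * Gaussian: `y ~ Normal(eta, sigma_resid)`;
#' * binomial: `k ~ Binomial(n, logit^-1(eta))`;
#' * Poisson: `y ~ Poisson(exp(eta))`;
#' * zero-inflated Poisson: a latent Bernoulli state with probability `psi`
#'   of being "on" is marginalized out,
#'   \eqn{p(y) = (1-\psi) 1\{y=0\} + \psi\,\mathrm{Pois}(y; e^\eta)}.
#'
#' @inheritParams linear_predictor
#' @return numeric vector of log-likelihood contributions, one per row.
#' @export
obs_loglik <- function(theta, rows, spec) {
  eta <- linear_predictor(theta, rows, spec)
  y <- rows$response
  switch(spec$family,
    gaussian = stats::dnorm(y, mean = eta, sd = theta$sigma_resid, log = TRUE),
    binomial = {
      if (any(y < 0) || any(y > rows$trials)) {
        stop("binomial response must satisfy 0 <= k <= trials")
      }
      stats::dbinom(y, size = rows$trials, prob = stats::plogis(eta),
                    log = TRUE)
    },
    poisson = {
      if (any(y < 0)) stop("counts must be non-negative")
      if (spec$zero_inflated) {
        lam <- exp(eta)
        # marginal ZIP pmf; stable via direct mixture (psi in [0,1])
        log((1 - theta$psi) * (y == 0) +
            theta$psi * stats::dpois(y, lam))
      } else {
        stats::dpois(y, exp(eta), log = TRUE)
      }
    })
}

#' Log prior density of a parameter vector
#'
#' Sums the log prior contributions defined by a [prior_spec()]: normal
#' terms for every intercept and slope, hierarchical normal terms for the
#' ramet random intercepts given `sigma_u` and (for overdispersed models)
#' the observation-level effects given `sigma_eps`, uniform terms for the
#' scale parameters and for `psi`. Parameters outside the prior support
#' yield `-Inf` (not an error), so the function can serve directly as the
#' prior part of a log-posterior.
#'
#' @param theta parameter list (see [linear_predictor()]).
#' @param priors a [prior_spec()].
#' @param spec the [model_spec()].
#' @return a single finite number, or `-Inf` outside the support.
#' @export
log_prior <- function(theta, priors, spec) {
  sd0 <- coef_prior_sd(priors)
  lp <- sum(stats::dnorm(theta$alpha, priors$coef_mean, sd0, log = TRUE))
  if (spec$has_seasonal_slope) {
    lp <- lp + sum(stats::dnorm(theta$beta, priors$coef_mean, sd0, log = TRUE))
  }
  in_unif <- function(v, upper) is.finite(v) && v > 0 && v < upper
  # log prior density of a residual/observation-scale sd under the reading
  scale_ld <- function(sigma) {
    if (priors$scale_reading == "sigma_uniform") {
      if (!in_unif(sigma, priors$scale_sd_upper)) return(-Inf)
      -log(priors$scale_sd_upper)
    } else {
      # variance ~ U(0, upper): p(sigma) = 2 sigma / upper on (0, sqrt(upper))
      if (!is.finite(sigma) || sigma <= 0 || sigma^2 >= priors$scale_sd_upper) {
        return(-Inf)
      }
      log(2 * sigma) - log(priors$scale_sd_upper)
    }
  }
  if (!in_unif(theta$sigma_u, priors$ranef_sd_upper)) return(-Inf)
  lp <- lp - log(priors$ranef_sd_upper) +
    sum(stats::dnorm(theta$u, 0, theta$sigma_u, log = TRUE))
  if (spec$family == "gaussian") {
    lp <- lp + scale_ld(theta$sigma_resid)
  }
  if (spec$overdispersed) {
    lp <- lp + scale_ld(theta$sigma_eps) +
      sum(stats::dnorm(theta$eps, 0, theta$sigma_eps, log = TRUE))
  }
  if (!is.finite(lp)) return(-Inf)
  if (spec$zero_inflated) {
    if (!(is.finite(theta$psi) && theta$psi >= 0 && theta$psi <= 1)) {
      return(-Inf)
    }
    # psi ~ U(0,1): density 1, contributes 0
  }
  lp
}

#' Unnormalized log posterior
#'
#' `log_prior()` plus the sum of [obs_loglik()] over all design rows. Used
#' for validation and debugging; sampling itself is delegated to the MCMC
#' backend.
#'
#' @param theta parameter list.
#' @param design a [build_design()] result.
#' @param priors a [prior_spec()].
#' @return a single number (possibly `-Inf`).
#' @export
log_posterior <- function(theta, design, priors) {
  lp <- log_prior(theta, priors, design$spec)
  if (!is.finite(lp)) return(lp)
  lp + sum(obs_loglik(theta, design$rows, design$spec))
}
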