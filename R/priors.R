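#' Prior specification for the Bayesian GLMMs
#'
#' The default priors are deliberately uninformative:
#' * treatment intercepts and seasonal slopes: normal with mean 0 and
#'   precision 0.001 (sd about 31.6 on the link scale). The protocol this
#'   package follows is usually quoted as "mean 0, standard deviation 0.001",
#'   which in the JAGS `dnorm(mean, precision)` convention denotes precision;
#'   a literal-sd reading would be extremely informative and contradict the
#'   intent, but it is available via `coef_reading = "sd"`.
#' * the ramet random-intercept standard deviation: uniform(0, 100)
#'   (`ranef_sd_upper`).
#' * residual and observation-level scales: by default the standard
#'   deviation is uniform(0, `scale_sd_upper`) and the precision is its
#'   inverse square (`scale_reading = "sigma_uniform"`). The alternative
#'   reading `"inverse_uniform"` puts the uniform on the variance and takes
#'   the precision as its reciprocal.
#' * the zero-inflation probability `psi`: uniform(0, 1).
#'
#' @param coef_mean prior mean for intercepts/slopes.
#' @param coef_value prior scale parameter for intercepts/slopes, read per
#'   `coef_reading`.
#' @param coef_reading `"precision"` (default) or `"sd"`.
#' @param ranef_sd_upper upper bound of the uniform prior on the ramet
#'   random-intercept sd.
#' @param scale_sd_upper upper bound of the uniform prior on residual /
#'   observation-level scales.
#' @param scale_reading `"sigma_uniform"` (sd uniform, precision = sd^-2,
#'   default) or `"inverse_uniform"` (variance uniform, precision = 1/var).
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(coef_mean = 0, coef_value = 0.001,
                       coef_reading = c("precision", "sd"),
                       ranef_sd_upper = 100, scale_sd_upper = 100,
                       scale_reading = c("sigma_uniform", "inverse_uniform")) {
  coef_reading <- match.arg(coef_reading)
  scale_reading <- match.arg(scale_reading)
  stopifnot(is.finite(coef_mean), is.finite(coef_value), coef_value > 0,
            ranef_sd_upper > 0, scale_sd_upper > 0)
  out <- list(coef_mean = coef_mean, coef_value = coef_value,
              coef_reading = coef_reading,
              ranef_sd_upper = ranef_sd_upper,
              scale_sd_upper = scale_sd_upper,
              scale_reading = scale_reading)
  class(out) <- "prior_spec"
  out
}

# normal sd implied by the coefficient prior under its reading
coef_prior_sd <- function(priors) {
  if (priors$coef_reading == "precision") 1 / sqrt(priors$coef_value)
  else priors$coef_value
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Priors: coef ~ N(%g, sd=%.4g) [%s reading]; ranef sd ~ U(0,%g);\n",
              x$coef_mean, coef_prior_sd(x), x$coef_reading, x$ranef_sd_upper))
  cat(sprintf("        scales ~ %s with upper %g; psi ~ U(0,1)\n",
              x$scale_reading, x$scale_sd_upper))
  invisible(x)
}
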