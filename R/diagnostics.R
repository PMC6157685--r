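# Gelman-Rubin potential scale reduction factor on a draws x chains matrix.
gelman_rubin_matrix <- function(x) {
  m <- ncol(x)
  n <- nrow(x)
  if (m < 2) stop("Gelman-Rubin diagnostic requires at least 2 chains")
  chain_means <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B_over_n <- stats::var(chain_means)          # = B / n
  if (W == 0) {
    return(if (B_over_n == 0) 1 else Inf)
  }
  var_plus <- (n - 1) / n * W + B_over_n
  sqrt(var_plus / W)
}

#' Gelman-Rubin convergence diagnostic (potential scale reduction factor)
#'
#' Compares between-chain and within-chain variance for one parameter:
#' with `m` chains of `n` retained draws, within-chain variance
#' \eqn{W = \frac{1}{m}\sum_c s_c^2}, between-chain variance
#' \eqn{B = \frac{n}{m-1}\sum_c (\bar x_c - \bar x)^2}, pooled variance
#' estimate \eqn{\widehat{var}^+ = \frac{n-1}{n} W + \frac{B}{n}} and
#' \eqn{\hat R = \sqrt{\widehat{var}^+ / W}}. Values near 1 indicate the
#' chains have mixed; the acceptance rule used throughout this package is
#' \eqn{\hat R < 1.1}.
#'
#' Degenerate chains with zero within-chain variance but distinct means
#' (e.g. stuck chains) report `Inf`.
#'
#' @param samples a `posterior_samples` object, or a numeric matrix with one
#'   column per chain.
#' @param parameter parameter name (required for `posterior_samples` input).
#' @return the scalar potential scale reduction factor.
#' @export
gelman_rubin <- function(samples, parameter = NULL) {
  x <- if (inherits(samples, "posterior_samples")) {
    if (is.null(parameter)) stop("parameter name required")
    draw_matrix(samples$mcmc, parameter)
  } else {
    as.matrix(samples)
  }
  gelman_rubin_matrix(x)
}

#' Convergence acceptance report
#'
#' Applies the acceptance rule R-hat < `threshold` (default 1.1) to every
#' monitored parameter; the fit as a whole passes only if every parameter
#' does.
#'
#' @param samples a `posterior_samples` object.
#' @param threshold acceptance threshold on R-hat.
#' @return an object of class `convergence_report`: data frame
#'   (`parameter`, `rhat`, `pass`) with attributes `overall` (logical) and
#'   `threshold`.
#' @export
check_convergence <- function(samples, threshold = 1.1) {
  stopifnot(inherits(samples, "posterior_samples"))
  rhat <- samples$rhat
  out <- data.frame(parameter = names(rhat), rhat = as.numeric(rhat),
                    pass = is.finite(rhat) & rhat < threshold,
                    row.names = NULL)
  attr(out, "overall") <- all(out$pass)
  attr(out, "threshold") <- threshold
  class(out) <- c("convergence_report", "data.frame")
  out
}

#' @export
print.convergence_report <- function(x, ...) {
  ok <- attr(x, "overall")
  cat(sprintf("Convergence (R-hat < %g): %s; max R-hat %.4f\n",
              attr(x, "threshold"), if (ok) "PASS" else "FAIL",
              max(x$rhat)))
  if (!ok) {
    bad <- x[!x$pass, , drop = FALSE]
    cat("  failing:", paste(sprintf("%s (%.3f)", bad$parameter, bad$rhat),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

# Count modes of pooled draws from a kernel density estimate. Peaks below
# `prominence` (relative to the highest peak) are ignored; two peaks are
# one mode when the valley between them stays above `valley` times the
# lower peak (a "shoulder" rather than a separate mode). Scale-free in the
# draws: the default bandwidth and the relative thresholds are invariant
# under affine transformations.
count_modes <- function(draws, prominence = 0.1, valley = 0.9) {
  if (length(unique(draws)) < 2) return(1L)
  d <- stats::density(draws, n = 512)
  y <- d$y / max(d$y)
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) == 0) peaks <- which.max(y)
  peaks <- peaks[y[peaks] >= prominence]
  if (length(peaks) <= 1) return(max(1L, length(peaks)))
  peaks <- peaks[order(peaks)]
  modes <- peaks[1]
  for (p in peaks[-1]) {
    prev <- modes[length(modes)]
    v <- min(y[prev:p])
    if (v <= valley * min(y[prev], y[p])) {
      modes <- c(modes, p)              # genuine dip: separate mode
    } else if (y[p] > y[prev]) {
      modes[length(modes)] <- p         # shoulder: keep the higher peak
    }
  }
  length(modes)
}

#' Posterior density summaries and multimodality screening
#'
#' Summarizes each monitored parameter's pooled draws (mean, sd, quantiles)
#' and applies an automated version of the visual posterior-density check:
#' a kernel density estimate is scanned for local maxima, small wiggles are
#' ignored, and a parameter is flagged when more than one well-separated
#' mode remains. The flag is advisory -- it marks posteriors whose shape
#' deserves inspection, it does not fail a fit by itself.
#'
#' @param samples a `posterior_samples` object.
#' @param outdir optional directory; when given, one density plot per
#'   parameter is written there as PNG.
#' @param prominence minimum peak height relative to the highest peak for a
#'   local maximum to count.
#' @param valley a dip between two peaks must fall below this fraction of
#'   the lower peak to separate two modes (shallower dips are shoulders).
#' @return an object of class `density_report`: data frame with columns
#'   `parameter`, `mean`, `sd`, `q2.5`, `q50`, `q97.5`, `n_modes`,
#'   `multimodal`.
#' @export
posterior_density_report <- function(samples, outdir = NULL,
                                     prominence = 0.1, valley = 0.9) {
  stopifnot(inherits(samples, "posterior_samples"))
  pars <- parameter_names(samples)
  rows <- lapply(pars, function(p) {
    dr <- get_draws(samples, p)
    q <- stats::quantile(dr, c(0.025, 0.5, 0.975), names = FALSE)
    nm <- count_modes(dr, prominence, valley)
    data.frame(parameter = p, mean = mean(dr), sd = stats::sd(dr),
               q2.5 = q[1], q50 = q[2], q97.5 = q[3],
               n_modes = nm, multimodal = nm > 1)
  })
  out <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (p in pars) {
      f <- file.path(outdir, paste0("density_", gsub("[^A-Za-z0-9_.-]", "_", p),
                                    ".png"))
      grDevices::png(f, width = 600, height = 400)
      graphics::plot(stats::density(get_draws(samples, p)), main = p,
                     xlab = "value")
      grDevices::dev.off()
    }
  }
  class(out) <- c("density_report", "data.frame")
  out
}

#' @export
print.density_report <- function(x, ...) {
  n_flag <- sum(x$multimodal)
  cat(sprintf("Posterior densities: %d parameters, %d flagged multimodal\n",
              nrow(x), n_flag))
  if (n_flag > 0) {
    cat("  flagged:", paste(x$parameter[x$multimodal], collapse = ", "), "\n")
  }
  invisible(x)
}
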