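#' Run the full analysis workflow
#'
#' Orchestrates the end-to-end protocol for a census table: for each
#' requested response, build the means-parameterized design, sample the
#' posterior, run convergence and posterior-shape diagnostics, and compute
#' the MeJA-versus-control contrast table. Models that fail a stage are
#' recorded in the manifest with their error and do not stop the remaining
#' models; the run errors only if every model fails.
#'
#' Each model gets its own seed derived from `settings$seed`, so a rerun
#' with the same inputs reproduces the report exactly.
#'
#' @param observations a census table (`ramet_obs` data frame) or a path to
#'   one ([read_observations()]).
#' @param outdir optional output directory; when given, per-model draw and
#'   contrast CSVs, a JSON manifest, density plots and a combined text
#'   report are written there.
#' @param specs named list of [model_spec()]s (default: all five
#'   responses).
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param make_plots write per-parameter density PNGs under `outdir`.
#' @param quiet suppress sampler progress.
#' @return an object of class `analysis_report`: per-model results
#'   (`samples`, `convergence`, `densities`, `contrasts` or `error`) plus a
#'   `manifest` data frame with per-model status
#'   (`converged`/`flagged`/`failed`).
#' @export
run_analysis <- function(observations, outdir = NULL,
                         specs = default_model_specs(),
                         priors = prior_spec(), settings = mcmc_settings(),
                         make_plots = FALSE, quiet = TRUE) {
  if (is.character(observations)) {
    observations <- read_observations(observations)
  }
  if (length(specs) < 1) stop("at least one model spec required")
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  models <- list()
  manifest <- list()
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    name <- names(specs)[k] %||% spec$response
    model_settings <- settings
    model_settings$seed <- settings$seed + k * 101L
    res <- tryCatch({
      design <- build_design(observations, spec)
      samples <- sample_posterior(design, priors, model_settings,
                                  quiet = quiet)
      conv <- check_convergence(samples)
      dens <- posterior_density_report(
        samples,
        outdir = if (make_plots && !is.null(outdir))
          file.path(outdir, paste0("densities_", name)) else NULL)
      ctr <- contrast_table(samples)
      list(samples = samples, design = design, convergence = conv,
           densities = dens, contrasts = ctr)
    }, error = function(e) list(error = conditionMessage(e)))
    models[[name]] <- res
    status <- if (!is.null(res$error)) "failed"
      else if (!attr(res$convergence, "overall")) "flagged"
      else if (any(res$densities$multimodal)) "flagged"
      else "converged"
    manifest[[name]] <- data.frame(
      response = name, status = status,
      n_obs = if (is.null(res$error)) res$samples$n_obs else NA_integer_,
      max_rhat = if (is.null(res$error)) max(res$samples$rhat) else NA_real_,
      seed = model_settings$seed,
      error = res$error %||% "",
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  if (all(manifest$status == "failed")) {
    stop("all models failed: ",
         paste(manifest$error, collapse = " | "))
  }
  out <- list(models = models, manifest = manifest, settings = settings,
              priors = priors, outdir = outdir)
  class(out) <- "analysis_report"
  if (!is.null(outdir)) write_report(out, outdir)
  out
}

# write the report bundle: draws + contrasts per model, manifest, text table
write_report <- function(report, outdir) {
  ok <- Filter(function(m) is.null(m$error), report$models)
  for (name in names(ok)) {
    write_draws(ok[[name]]$samples,
                file.path(outdir, paste0("draws_", name, ".csv")))
    utils::write.csv(ok[[name]]$contrasts,
                     file.path(outdir, paste0("contrasts_", name, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(manifest = report$manifest,
         settings = unclass(report$settings),
         priors = unclass(report$priors)),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  writeLines(format_contrast_report(lapply(ok, `[[`, "contrasts")),
             file.path(outdir, "contrast_report.txt"))
  invisible(outdir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report\n")
  print(x$manifest[, c("response", "status", "n_obs", "max_rhat")])
  invisible(x)
}

#' Calibration and parameter-recovery harness
#'
#' Repeatedly simulates a dataset from `config` (with per-replicate seeds
#' derived from `seed`), fits the requested responses, and aggregates:
#'
#' * coverage: fraction of true intercepts/slopes inside their central 95%
#'   credible interval;
#' * bias: mean (posterior mean - truth) over coefficients;
#' * tier rates: fraction of MeJA-versus-control contrasts reaching each
#'   significance tier. Under [null_scenario()] all true contrasts are
#'   zero, so the tier-`*`-or-beyond rate estimates the procedure's type-I
#'   error (nominally about 5% for the two-sided 0.05 tier).
#'
#' @param config a [simulation_config()].
#' @param replicates number of simulated datasets.
#' @param seed integer seed for the replicate stream.
#' @param responses which responses to fit per replicate.
#' @param priors,settings fit configuration (see [sample_posterior()]).
#' @param quiet suppress progress.
#' @return an object of class `recovery_summary`: list with `coverage`,
#'   `bias`, `tier_rates`, `per_replicate` (data frame of per-replicate
#'   coverage and tier counts) and `contrasts` (all contrast rows with
#'   replicate ids).
#' @export
recover_calibration <- function(config, replicates = 10, seed = 1L,
                                responses = "dry_mass",
                                priors = prior_spec(),
                                settings = mcmc_settings(), quiet = TRUE) {
  stopifnot(replicates >= 1)
  per_rep <- list()
  all_contrasts <- list()
  covered <- 0L
  total <- 0L
  bias_sum <- 0
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- seed + r * 1009L
    sim <- simulate_dataset(cfg)
    rep_cov <- 0L
    rep_tot <- 0L
    rep_star <- 0L
    rep_ncontr <- 0L
    for (resp in responses) {
      spec <- model_spec(resp, years = seq_len(config$n_years))
      design <- build_design(sim$observations, spec)
      fit_settings <- settings
      fit_settings$seed <- cfg$seed + match(resp, names(.responses))
      samples <- sample_posterior(design, priors, fit_settings, quiet = quiet)
      truth <- sim$truth
      for (par in c("alpha", if (spec$has_seasonal_slope) "beta")) {
        for (grp in samples$group_levels) {
          for (yr in samples$year_levels) {
            tv <- truth$value[truth$response == resp &
                              truth$parameter == par &
                              truth$group == grp & truth$year == yr]
            dr <- get_draws(samples, par, group = grp, year = yr)
            ci <- stats::quantile(dr, c(0.025, 0.975), names = FALSE)
            hit <- tv >= ci[1] && tv <= ci[2]
            rep_cov <- rep_cov + hit
            rep_tot <- rep_tot + 1L
            bias_sum <- bias_sum + (mean(dr) - tv)
          }
        }
      }
      ctr <- contrast_table(samples)
      ctr$replicate <- r
      all_contrasts[[length(all_contrasts) + 1L]] <- ctr
      rep_star <- rep_star + sum(ctr$tier %in% c("*", "**", "***"))
      rep_ncontr <- rep_ncontr + nrow(ctr)
    }
    covered <- covered + rep_cov
    total <- total + rep_tot
    per_rep[[r]] <- data.frame(replicate = r, coverage = rep_cov / rep_tot,
                               n_coef = rep_tot,
                               star_rate = rep_star / rep_ncontr,
                               n_contrasts = rep_ncontr)
  }
  contrasts <- do.call(rbind, all_contrasts)
  tiers <- c("***", "**", "*", "(*)", "ns")
  tier_rates <- vapply(tiers, function(tt) mean(contrasts$tier == tt),
                       numeric(1))
  out <- list(coverage = covered / total, bias = bias_sum / total,
              tier_rates = tier_rates,
              per_replicate = do.call(rbind, per_rep),
              contrasts = contrasts)
  class(out) <- "recovery_summary"
  out
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Recovery over %d replicate(s): 95%% CI coverage %.3f, mean bias %+.4f\n",
              nrow(x$per_replicate), x$coverage, x$bias))
  cat("  tier rates:",
      paste(sprintf("%s=%.4f", names(x$tier_rates), x$tier_rates),
            collapse = "  "), "\n")
  invisible(x)
}
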