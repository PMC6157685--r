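#' Treatment groups of the transect design
#'
#' The means parameterization compares six groups: untreated control ramets
#' at distance 0 on control transects, the MeJA-treated ramet itself
#' (`meja_d0`), and its untreated neighbours at increasing distance classes
#' along the treated transects (`meja_d1` 10--40 cm, `meja_d2` 40--80 cm,
#' `meja_d3` 80--150 cm, `meja_d4` 400--530 cm).
#'
#' @return character vector of the six group labels in canonical order
#'   (control first).
#' @export
treatment_groups <- function() {
  c("control", "meja_d0", "meja_d1", "meja_d2", "meja_d3", "meja_d4")
}

.responses <- list(
  dry_mass = list(family = "gaussian", link = "identity",
                  overdispersed = FALSE, zero_inflated = FALSE,
                  has_seasonal_slope = TRUE),
  grazed_ratio = list(family = "binomial", link = "logit",
                      overdispersed = TRUE, zero_inflated = FALSE,
                      has_seasonal_slope = TRUE),
  browsed_shoots = list(family = "poisson", link = "log",
                        overdispersed = TRUE, zero_inflated = TRUE,
                        has_seasonal_slope = TRUE),
  flowers = list(family = "poisson", link = "log",
                 overdispersed = TRUE, zero_inflated = FALSE,
                 has_seasonal_slope = FALSE),
  berries = list(family = "poisson", link = "log",
                 overdispersed = TRUE, zero_inflated = FALSE,
                 has_seasonal_slope = FALSE)
)

#' Declare one of the five response models
#'
#' Each response has a fixed family/link pairing and error structure:
#'
#' | response | family | link | overdispersion | zero-inflation | seasonal slope |
#' |---|---|---|---|---|---|
#' | `dry_mass` (log2 allometric dry mass) | Gaussian | identity | -- | -- | yes |
#' | `grazed_ratio` (grazed / total leaves) | binomial | logit | OLRE | -- | yes |
#' | `browsed_shoots` | Poisson | log | OLRE | yes | yes |
#' | `flowers` | Poisson | log | OLRE | -- | no |
#' | `berries` | Poisson | log | OLRE | -- | no |
#'
#' OLRE is an observation-level random effect: an extra normal deviate on the
#' link scale per observation that absorbs overdispersion relative to the
#' binomial/Poisson variance. Zero-inflation is a latent Bernoulli "on/off"
#' state per observation with shared probability `psi` mixed with the Poisson
#' count. Flower and berry counts are yearly (last census of each season), so
#' no within-season slope applies to them.
#'
#' The model is means-parameterized: every group-by-year cell receives its
#' own intercept `alpha[g, y]` (and seasonal slope `beta[g, y]` where
#' applicable) on the link scale, rather than deviations from a reference
#' level. All models carry a per-ramet random intercept for the repeated
#' measurements. A block random effect is available as an optional extension
#' (`block_effect = TRUE`) but is off by default: with mortality-driven
#' unbalanced panels it tends to prevent convergence.
#'
#' @param response one of `"dry_mass"`, `"grazed_ratio"`, `"browsed_shoots"`,
#'   `"flowers"`, `"berries"`.
#' @param years integer vector of study years modelled (default 1:3).
#' @param groups treatment group labels (subset of [treatment_groups()],
#'   canonical order; must include `"control"` for contrasts).
#' @param time_coding `"slot"` codes the three censuses as season time
#'   0, 0.5, 1; `"days"` codes them proportionally to the year-1 census days
#'   0, 30, 72 after treatment (0, 0.417, 1).
#' @param include_control_neighbors if `TRUE`, untreated neighbour ramets on
#'   control transects are pooled into the control group; by default only
#'   distance-0 control ramets define the control, matching the comparisons
#'   "in relation to the control at distance 0".
#' @param block_effect include a block-level random intercept (optional
#'   extension, default `FALSE`).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response = names(.responses),
                       years = 1:3,
                       groups = treatment_groups(),
                       time_coding = c("slot", "days"),
                       include_control_neighbors = FALSE,
                       block_effect = FALSE) {
  response <- match.arg(response)
  time_coding <- match.arg(time_coding)
  unknown <- setdiff(groups, treatment_groups())
  if (length(unknown) > 0) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(years) < 1 || any(years < 1)) stop("years must be >= 1")
  spec <- c(list(response = response), .responses[[response]],
            list(years = as.integer(sort(years)),
                 groups = groups[order(match(groups, treatment_groups()))],
                 time_coding = time_coding,
                 include_control_neighbors = include_control_neighbors,
                 block_effect = block_effect))
  class(spec) <- "model_spec"
  spec
}

#' All five response model specifications
#'
#' @inheritParams model_spec
#' @return named list of [model_spec()] objects, one per response.
#' @export
default_model_specs <- function(years = 1:3, groups = treatment_groups(),
                                time_coding = "slot",
                                include_control_neighbors = FALSE,
                                block_effect = FALSE) {
  specs <- lapply(names(.responses), model_spec, years = years,
                  groups = groups, time_coding = time_coding,
                  include_control_neighbors = include_control_neighbors,
                  block_effect = block_effect)
  names(specs) <- names(.responses)
  specs
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec: %s ~ %s(%s)%s%s\n", x$response, x$family, x$link,
              if (x$overdispersed) " + OLRE" else "",
              if (x$zero_inflated) " + zero-inflation" else ""))
  cat(sprintf("  groups: %s\n", paste(x$groups, collapse = ", ")))
  cat(sprintf("  years: %s; seasonal slope: %s (time coding: %s)\n",
              paste(x$years, collapse = ","),
              if (x$has_seasonal_slope) "yes" else "no", x$time_coding))
  invisible(x)
}

# season-time value for a census index under a spec's coding
season_time <- function(census, time_coding) {
  switch(time_coding,
         slot = (census - 1) / 2,
         days = c(0, 30, 72)[census] / 72)
}

#' Build the means-parameterized model design from census records
#'
#' Converts validated observations into the per-observation index structure
#' the likelihood and the sampler consume: group index, year index, season
#' time, ramet index, response value and (for the binomial model) trials.
#'
#' Rows are dropped (and counted in `$excluded`) when the ramet is dead or
#' the response is missing, when the binomial model has zero leaves (no
#' trials), or when the ramet belongs to no modelled group (untreated
#' neighbours on control transects, unless
#' `include_control_neighbors = TRUE`). Flower and berry models use only the
#' last census of each year. The dry-mass response is the log2-scale
#' allometric prediction from [log2_dry_mass()], which the Gaussian
#' identity-link model fits directly.
#'
#' @param records a census table ([read_observations()] or
#'   [simulate_dataset()]).
#' @param spec a [model_spec()].
#' @return an object of class `model_design`: a list with `rows` (data frame
#'   with columns `g`, `y`, `t`, `i`, `response`, `trials`, `block`),
#'   level vectors (`group_levels`, `year_levels`, `ramet_levels`,
#'   `block_levels`), coefficient counts `n_coef`, and exclusion counts
#'   `excluded`.
#' @export
build_design <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.data.frame(records)

  group <- ifelse(x$treatment == "meja",
                  paste0("meja_d", x$distance_class),
                  ifelse(x$distance_class == 0 | spec$include_control_neighbors,
                         "control", NA_character_))
  excluded <- list(control_neighbor = sum(is.na(group)))
  keep <- !is.na(group) & group %in% spec$groups & x$year %in% spec$years

  excluded$dead <- sum(keep & !x$alive)
  keep <- keep & x$alive

  if (spec$response %in% c("flowers", "berries")) {
    last_census <- max(x$census)
    keep <- keep & x$census == last_census
  }

  resp <- switch(spec$response,
    dry_mass = log2_dry_mass(ifelse(keep, x$stem_diameter_mm, NA),
                             ifelse(keep, x$height_cm, NA),
                             ifelse(keep, x$n_shoots, NA)),
    grazed_ratio = x$n_grazed_leaves,
    browsed_shoots = x$n_browsed_shoots,
    flowers = x$n_flowers,
    berries = x$n_berries)
  excluded$missing_response <- sum(keep & is.na(resp))
  keep <- keep & !is.na(resp)

  trials <- rep(NA_integer_, nrow(x))
  if (spec$family == "binomial") {
    trials <- x$n_leaves
    excluded$zero_trials <- sum(keep & (is.na(trials) | trials == 0))
    keep <- keep & !is.na(trials) & trials > 0
  } else {
    excluded$zero_trials <- 0L
  }

  if (!any(keep)) stop("no usable observations for response ", spec$response)

  x <- x[keep, , drop = FALSE]
  group <- group[keep]
  resp <- resp[keep]
  trials <- trials[keep]

  ramet_key <- paste(x$block_id, x$transect_id, x$ramet_id, sep = "/")
  ramet_levels <- sort(unique(ramet_key))
  block_levels <- sort(unique(x$block_id))

  rows <- data.frame(
    g = match(group, spec$groups),
    y = match(x$year, spec$years),
    t = if (spec$has_seasonal_slope) season_time(x$census, spec$time_coding)
        else 0,
    i = match(ramet_key, ramet_levels),
    response = as.numeric(resp),
    trials = trials,
    block = match(x$block_id, block_levels)
  )

  design <- list(
    rows = rows,
    spec = spec,
    group_levels = spec$groups,
    year_levels = spec$years,
    ramet_levels = ramet_levels,
    block_levels = block_levels,
    n_coef = list(
      alpha = length(spec$groups) * length(spec$years),
      beta = if (spec$has_seasonal_slope)
        length(spec$groups) * length(spec$years) else 0L),
    excluded = excluded
  )
  class(design) <- "model_design"
  design
}

#' @export
print.model_design <- function(x, ...) {
  cat(sprintf("Model design (%s): %d observations, %d ramets, %d groups x %d years\n",
              x$spec$response, nrow(x$rows), length(x$ramet_levels),
              length(x$group_levels), length(x$year_levels)))
  cat(sprintf("  coefficients: %d intercepts, %d slopes; excluded rows: %s\n",
              x$n_coef$alpha, x$n_coef$beta,
              paste(sprintf("%s=%d", names(x$excluded),
                            unlist(x$excluded)), collapse = ", ")))
  invisible(x)
}

#' Export a model design for audit
#'
#' Writes the per-observation design rows (indices, season time, response,
#' trials) as CSV so a fitted model's input can be inspected outside R.
#'
#' @param design a [build_design()] result.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "model_design"))
  out <- design$rows
  out$group <- design$group_levels[out$g]
  out$year <- design$year_levels[out$y]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
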