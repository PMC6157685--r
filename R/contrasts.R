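#' Draw-wise posterior difference
#'
#' Subtracts two parameters' retained draws element-wise, pairing draws by
#' their (chain, iteration) position within one joint MCMC run. Because the
#' parameters are sampled jointly, the draw-wise difference is a sample
#' from the posterior of the difference.
#'
#' @param a,b numeric draw vectors of equal length, extracted from the same
#'   `posterior_samples` object (e.g. via [get_draws()]).
#' @return numeric vector `a - b`.
#' @export
posterior_difference <- function(a, b) {
  if (length(a) != length(b)) {
    stop("draw vectors must have equal length (same posterior run)")
  }
  a - b
}

# tier thresholds: smallest threshold exceeding twice the minimum tail mass
.tiers <- c("***" = 0.001, "**" = 0.01, "*" = 0.05, "(*)" = 0.1)

#' Classify a posterior difference into a significance tier
#'
#' From the draws of a difference (MeJA group minus control), computes the
#' fractions of posterior mass below and above zero and assigns a star
#' tier from the smaller tail: with \eqn{p_{tail} = \min(P(d<0), P(d>0))},
#' the tier is the smallest threshold in \{0.001, 0.01, 0.05, 0.1\}
#' with \eqn{2 p_{tail}} below it (`***`, `**`, `*`, `(*)`), otherwise
#' `ns`. Doubling the minimum tail gives the conventional two-sided star
#' semantics; both raw fractions are always reported so a one-sided reading
#' can be recovered. Exact zeros are counted separately and split evenly
#' between the two tails for tier purposes (relevant only for degenerate
#' draws).
#'
#' The sign convention: positive effects mean the MeJA-side quantity is
#' higher than the control.
#'
#' @param diff numeric vector of difference draws.
#' @param thresholds named numeric vector of tier thresholds (ascending).
#' @return an object of class `contrast_result`: list with `effect`
#'   (posterior mean difference), `frac_below`, `frac_above`, `frac_zero`,
#'   `p_tail`, `tier`.
#' @export
classify_contrast <- function(diff, thresholds = .tiers) {
  if (length(diff) == 0) stop("empty difference draws")
  n <- length(diff)
  n_below <- sum(diff < 0)
  n_above <- sum(diff > 0)
  n_zero <- n - n_below - n_above
  p_tail <- (min(n_below, n_above) + n_zero / 2) / n
  two_sided <- 2 * p_tail
  hit <- which(two_sided < thresholds)
  tier <- if (length(hit) > 0) names(thresholds)[min(hit)] else "ns"
  out <- list(effect = mean(diff),
              frac_below = n_below / n,
              frac_above = n_above / n,
              frac_zero = n_zero / n,
              p_tail = p_tail,
              tier = tier)
  class(out) <- "contrast_result"
  out
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("effect %+.4f  [below %.4f | above %.4f]  tier %s\n",
              x$effect, x$frac_below, x$frac_above, x$tier))
  invisible(x)
}

#' Posterior contrast table: every MeJA group against the control
#'
#' For each MeJA group, study year, and model component (intercept, and
#' seasonal slope where the model has one), subtracts the control group's
#' posterior draws from the MeJA group's draws draw-by-draw and classifies
#' the difference with [classify_contrast()]. For no-slope models (flowers,
#' berries) the slope rows are omitted; formatted reports show them as NA.
#'
#' @param samples a `posterior_samples` object from a fit whose groups
#'   include `"control"` and at least one MeJA group.
#' @param thresholds tier thresholds passed to [classify_contrast()].
#' @return a `contrast_table` data frame with columns `response`, `group`,
#'   `year`, `component`, `effect`, `frac_below`, `frac_above`, `p_tail`,
#'   `tier`.
#' @export
contrast_table <- function(samples, thresholds = .tiers) {
  stopifnot(inherits(samples, "posterior_samples"))
  groups <- samples$group_levels
  if (!"control" %in% groups) stop("fit does not include a control group")
  meja <- setdiff(groups, "control")
  if (length(meja) == 0) stop("fit includes no MeJA group to contrast")
  components <- c("intercept",
                  if (samples$spec$has_seasonal_slope) "slope")
  par_of <- c(intercept = "alpha", slope = "beta")

  rows <- list()
  for (grp in meja) {
    for (yr in samples$year_levels) {
      for (comp in components) {
        d <- posterior_difference(
          get_draws(samples, par_of[[comp]], group = grp, year = yr),
          get_draws(samples, par_of[[comp]], group = "control", year = yr))
        cl <- classify_contrast(d, thresholds)
        rows[[length(rows) + 1L]] <- data.frame(
          response = samples$spec$response, group = grp, year = yr,
          component = comp, effect = cl$effect,
          frac_below = cl$frac_below, frac_above = cl$frac_above,
          p_tail = cl$p_tail, tier = cl$tier)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Format contrast tables as a publication-style text report
#'
#' Lays out effects as one row per response and one intercept/slope column
#' pair per year, with star annotations and NA for inapplicable slopes --
#' one block per MeJA group.
#'
#' @param tables a `contrast_table` or list of them (one per response).
#' @param digits digits for effect values.
#' @return character vector of report lines, invisibly printed with `cat()`
#'   by [print()]; use `writeLines()` to save.
#' @export
format_contrast_report <- function(tables, digits = 2) {
  if (inherits(tables, "contrast_table")) tables <- list(tables)
  tab <- do.call(rbind, lapply(tables, as.data.frame))
  years <- sort(unique(tab$year))
  lines <- character()
  fmt_cell <- function(sub) {
    if (nrow(sub) == 0) return("NA")
    paste0(formatC(sub$effect, digits = digits, format = "f"),
           ifelse(sub$tier == "ns", "", sub$tier))
  }
  for (grp in unique(tab$group)) {
    lines <- c(lines, sprintf("== %s vs control ==", grp))
    header <- c(sprintf("%-16s", "response"),
                sprintf("%12s", paste0("y", rep(years, each = 2), "_",
                                       c("int", "slope"))))
    lines <- c(lines, paste(header, collapse = ""))
    for (resp in unique(tab$response)) {
      cells <- character()
      for (yr in years) {
        for (comp in c("intercept", "slope")) {
          sub <- tab[tab$group == grp & tab$response == resp &
                     tab$year == yr & tab$component == comp, , drop = FALSE]
          cells <- c(cells, sprintf("%12s", fmt_cell(sub)))
        }
      }
      lines <- c(lines, paste0(sprintf("%-16s", resp),
                               paste(cells, collapse = "")))
    }
    lines <- c(lines, "")
  }
  c(lines,
    "Significance: *** 2p<0.001, ** 2p<0.01, * 2p<0.05, (*) 2p<0.1;",
    "positive effects mean higher values in the MeJA group than the control.")
}
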