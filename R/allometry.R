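# Allometric coefficients for bilberry ramet dry mass, estimated in an
# earlier destructive-harvest study; treated as fixed constants here.
.allometry <- c(ds = 1.41700, h = 0.97104, shoots = 0.44153, intercept = -7.52070)

#' Nondestructive dry-mass estimation from ramet size measures
#'
#' Bilberry ramet dry mass is estimated without harvesting from three field
#' measurements: stem diameter at ground level (`DS`, mm), ramet height
#' (`H`, cm) and the number of annual shoots (`AS`). The estimator is linear
#' on the log2 scale,
#'
#' \deqn{\log_2 DM = 1.41700\,\log_2 DS + 0.97104\,\log_2 H +
#'       0.44153\,\log_2(AS + 1) - 7.52070,}
#'
#' with coefficients taken from a published destructive calibration; they are
#' not re-estimated here. `dry_mass()` returns the back-transformed mass
#' \eqn{2^{\log_2 DM}} in the calibration study's dry-mass units.
#'
#' All arguments are vectorized and recycled. `NA` inputs (e.g. dead ramets
#' with unrecorded sizes) propagate to `NA` outputs.
#'
#' @param stem_diameter_mm stem diameter at ground level, mm; must be > 0.
#' @param height_cm ramet height from ground to crown, cm; must be > 0.
#' @param n_shoots number of annual shoots; non-negative integer (0 allowed:
#'   the estimator uses `log2(AS + 1)`).
#' @return `log2_dry_mass()`: numeric vector of log2 dry mass.
#'   `dry_mass()`: numeric vector of strictly positive dry mass.
#' @examples
#' log2_dry_mass(1, 1, 0)        # the intercept, -7.5207
#' dry_mass(2.1, 15.5, 4)
#' @export
log2_dry_mass <- function(stem_diameter_mm, height_cm, n_shoots) {
  n <- max(length(stem_diameter_mm), length(height_cm), length(n_shoots))
  ds <- rep_len(as.numeric(stem_diameter_mm), n)
  h <- rep_len(as.numeric(height_cm), n)
  as_ <- rep_len(as.numeric(n_shoots), n)
  if (any(ds <= 0, na.rm = TRUE) || any(h <= 0, na.rm = TRUE)) {
    stop("stem_diameter_mm and height_cm must be strictly positive (log2 undefined)")
  }
  if (any(as_ < 0, na.rm = TRUE)) {
    stop("n_shoots must be non-negative")
  }
  .allometry[["ds"]] * log2(ds) + .allometry[["h"]] * log2(h) +
    .allometry[["shoots"]] * log2(as_ + 1) + .allometry[["intercept"]]
}

#' @rdname log2_dry_mass
#' @export
dry_mass <- function(stem_diameter_mm, height_cm, n_shoots) {
  2^log2_dry_mass(stem_diameter_mm, height_cm, n_shoots)
}
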