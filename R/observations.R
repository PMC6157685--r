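#' Column set of the long-format census table
#'
#' One row per ramet per census. Identifiers locate a ramet in the field
#' design (block, transect within block, distance class along the transect);
#' the remaining columns are the size measures and herbivory/reproduction
#' counts recorded at that census. Dead ramets keep their rows with
#' `alive = FALSE` and missing measurements so panels stay rectangular in
#' structure while models drop the unusable rows.
#'
#' @return character vector of column names in canonical order.
#' @export
observation_columns <- function() {
  c("block_id", "transect_id", "treatment", "distance_class", "ramet_id",
    "year", "census", "days_since_treatment", "height_cm", "stem_diameter_mm",
    "n_shoots", "n_leaves", "n_grazed_leaves", "n_browsed_shoots",
    "n_flowers", "n_berries", "alive")
}

.count_cols <- c("n_shoots", "n_leaves", "n_grazed_leaves",
                 "n_browsed_shoots", "n_flowers", "n_berries")

#' Validate a census table against the observation data model
#'
#' Checks every row against the design's structural rules:
#' * `treatment` is `"control"` or `"meja"`; `distance_class` is 0--4;
#'   `census` is 1--3; `year` and `days_since_treatment` are non-negative;
#' * counts are non-negative and `n_grazed_leaves <= n_leaves`;
#' * live ramets have positive `height_cm` and `stem_diameter_mm`;
#' * berries are not recorded at the very first census of year 1 (counting
#'   started at the second census of the treatment year), so `n_berries`
#'   must be missing there;
#' * mortality is absorbing: once a ramet is recorded dead it cannot
#'   reappear alive at a later census.
#'
#' @param x data frame with the columns of [observation_columns()].
#' @return data frame of problems with columns `row`, `field`, `problem`;
#'   zero rows when the table is valid.
#' @export
validate_observations <- function(x) {
  x <- as.data.frame(x)
  missing <- setdiff(observation_columns(), names(x))
  if (length(missing) > 0) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  probs <- list()
  flag <- function(rows, field, problem) {
    rows <- which(rows %in% TRUE)  # NA-safe
    if (length(rows) > 0) {
      probs[[length(probs) + 1L]] <<- data.frame(
        row = rows, field = field, problem = problem)
    }
  }

  flag(!x$treatment %in% c("control", "meja"), "treatment",
       "must be 'control' or 'meja'")
  flag(!x$distance_class %in% 0:4, "distance_class", "must be in 0..4")
  flag(!x$census %in% 1:3, "census", "must be in 1..3")
  flag(!is.na(x$year) & x$year < 1, "year", "must be >= 1")
  flag(x$days_since_treatment < 0, "days_since_treatment", "must be >= 0")
  for (cc in .count_cols) {
    flag(x[[cc]] < 0, cc, "counts must be >= 0")
  }
  flag(x$n_grazed_leaves > x$n_leaves, "n_grazed_leaves",
       "cannot exceed n_leaves")
  flag(x$alive & (is.na(x$height_cm) | x$height_cm <= 0), "height_cm",
       "must be > 0 for live ramets")
  flag(x$alive & (is.na(x$stem_diameter_mm) | x$stem_diameter_mm <= 0),
       "stem_diameter_mm", "must be > 0 for live ramets")
  flag(x$year == 1 & x$census == 1 & !is.na(x$n_berries), "n_berries",
       "berries are not recorded at year 1, census 1")

  # absorbing mortality within each ramet's time series
  key <- paste(x$block_id, x$transect_id, x$ramet_id, sep = "\r")
  ord <- order(key, x$year, x$census)
  dead_seen <- stats::ave(!x$alive[ord], key[ord], FUN = function(v) {
    c(FALSE, cumsum(v)[-length(v)] > 0)  # a death at any earlier census
  })
  bad <- ord[which(dead_seen & x$alive[ord])]
  if (length(bad) > 0) {
    probs[[length(probs) + 1L]] <- data.frame(
      row = bad, field = "alive", problem = "ramet recorded alive after death")
  }

  if (length(probs) == 0) {
    return(data.frame(row = integer(), field = character(),
                      problem = character()))
  }
  out <- do.call(rbind, probs)
  out[order(out$row), , drop = FALSE]
}

#' Read a long-format census table
#'
#' Reads the comma-separated, UTF-8 census table (header row, empty fields
#' for missing values) and validates every row against the observation data
#' model. Rows failing validation abort the read with a message naming the
#' offending rows, so invalid field data cannot silently enter a model fit.
#'
#' @param path path to a CSV file with the columns of
#'   [observation_columns()].
#' @return a `ramet_obs` data frame (one row per ramet per census).
#' @seealso [write_observations()], [validate_observations()]
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       fileEncoding = "UTF-8")
  missing <- setdiff(observation_columns(), names(x))
  if (length(missing) > 0) {
    stop("format error: missing columns: ", paste(missing, collapse = ", "))
  }
  x <- x[observation_columns()]
  x$alive <- as.logical(x$alive)
  for (cc in c("distance_class", "year", "census", "days_since_treatment",
               .count_cols)) {
    x[[cc]] <- as.integer(x[[cc]])
  }
  probs <- validate_observations(x)
  if (nrow(probs) > 0) {
    msg <- paste(sprintf("row %d: %s %s", probs$row, probs$field,
                         probs$problem), collapse = "; ")
    stop("validation error: ", msg)
  }
  class(x) <- c("ramet_obs", "data.frame")
  x
}

#' Write a long-format census table
#'
#' Writes records as CSV with the documented header and stable column order;
#' missing values become empty fields. Records are validated before writing.
#'
#' @param records data frame of observations (see [observation_columns()]).
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(records, path) {
  records <- as.data.frame(records)
  probs <- validate_observations(records)
  if (nrow(probs) > 0) {
    stop("validation error: refusing to write ", nrow(probs),
         " invalid row(s); first: row ", probs$row[1], " (", probs$field[1],
         " ", probs$problem[1], ")")
  }
  utils::write.csv(records[observation_columns()], path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @export
print.ramet_obs <- function(x, ...) {
  n_ramet <- length(unique(paste(x$block_id, x$transect_id, x$ramet_id)))
  cat(sprintf("Census table: %d observations of %d ramets, years %s\n",
              nrow(x), n_ramet,
              paste(range(x$year), collapse = "-")))
  NextMethod()
}
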